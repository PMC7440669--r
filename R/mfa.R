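#' Flux dataset in the 13C-MFA table shape
#'
#' A flux dataset is a reaction-by-strain matrix of measured fluxes: rows
#' are central-carbon-metabolism reactions (possibly isozyme families such
#' as pfkA/pfkB), columns are a wild-type reference (one or more
#' replicates, names starting with `WT`) plus single-knockout strains, and
#' one row carries the glucose uptake used for normalisation.
#'
#' @param values numeric matrix (reactions x strains) with dimnames.
#' @param glucose_row row name holding glucose uptake (default `GLCpts`).
#' @param formatted logical flag set by [format_flux_dataset()].
#' @return a `flux_dataset` object.
#' @export
flux_dataset <- function(values, glucose_row = "GLCpts", formatted = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(list(values = values, glucose_row = glucose_row,
                 formatted = formatted),
            class = "flux_dataset")
}

#' @export
print.flux_dataset <- function(x, ...) {
  cat(sprintf("flux_dataset: %d reactions x %d strains%s\n",
              nrow(x$values), ncol(x$values),
              if (x$formatted) " (formatted)" else ""))
  invisible(x)
}

#' Format a raw flux dataset against a metabolic network
#'
#' Pre-processing steps: (i) dataset rows are mapped onto network reaction
#' ids via the mapping table, flipping signs where the measurement
#' convention opposes the model direction; (ii) isozyme families mapping
#' to the same model reaction are averaged into a single row; (iii) all
#' wild-type replicate columns (names starting with `WT`) are averaged
#' into one `WT` column; (iv) every column is rescaled so that its glucose
#' uptake equals the model uptake; (v) rows without a model reaction are
#' dropped.  Re-applying the formatter to a formatted dataset is a no-op.
#'
#' @param raw a `flux_dataset`.
#' @param net a `metabolic_network` whose reaction ids define the target
#'   namespace.
#' @param mapping data frame with columns `dataset`, `model`, `sign`
#'   (default: identity mapping on row names already matching the model).
#' @param model_uptake glucose uptake magnitude of the model (default 10).
#' @return a formatted `flux_dataset`.
#' @export
format_flux_dataset <- function(raw, net, mapping = NULL, model_uptake = 10) {
  stopifnot(inherits(raw, "flux_dataset"))
  if (raw$formatted) return(raw)
  vals <- raw$values
  if (is.null(mapping)) {
    mapping <- data.frame(dataset = rownames(vals), model = rownames(vals),
                          sign = 1, stringsAsFactors = FALSE)
  }
  if (!raw$glucose_row %in% mapping$dataset) {
    mapping <- rbind(mapping, data.frame(dataset = raw$glucose_row,
                                         model = raw$glucose_row, sign = 1))
  }
  keep <- rownames(vals) %in% mapping$dataset
  vals <- vals[keep, , drop = FALSE]
  if (!raw$glucose_row %in% rownames(vals)) {
    stop(sprintf("glucose uptake row '%s' missing from dataset", raw$glucose_row))
  }
  idx <- match(rownames(vals), mapping$dataset)
  vals <- vals * mapping$sign[idx]
  model_ids <- mapping$model[idx]
  in_model <- model_ids %in% net$rxns$id | model_ids == raw$glucose_row
  vals <- vals[in_model, , drop = FALSE]
  model_ids <- model_ids[in_model]
  # average isozyme families into one row per model reaction
  agg <- rowsum(vals, group = model_ids)
  agg <- agg / as.vector(table(model_ids))  # both sorted by group label
  # average WT replicate columns
  wt_cols <- grepl("^WT", colnames(agg))
  if (!any(wt_cols)) stop("dataset has no wild-type (WT*) column")
  wt_mean <- rowMeans(agg[, wt_cols, drop = FALSE])
  agg <- cbind(WT = wt_mean, agg[, !wt_cols, drop = FALSE])
  # normalise every strain to the model glucose uptake
  glc <- abs(agg[raw$glucose_row, ])
  if (any(glc < 1e-9)) stop("zero glucose uptake in a strain column")
  agg <- sweep(agg, 2, model_uptake / glc, `*`)
  flux_dataset(agg, glucose_row = raw$glucose_row, formatted = TRUE)
}

#' Extract per-reaction flux ranges from a formatted dataset
#'
#' Minimum and maximum of each reaction's flux across all strain columns;
#' the spread of a reaction across the knockout panel is read as its
#' catalytic range.
#'
#' @param dataset a formatted `flux_dataset`.
#' @param include_uptake keep the glucose-uptake row (default FALSE).
#' @return a `flux_range_set` with provenance `"MFA"`.
#' @export
extract_ranges <- function(dataset, include_uptake = FALSE) {
  stopifnot(inherits(dataset, "flux_dataset"))
  vals <- dataset$values
  if (!include_uptake) {
    vals <- vals[setdiff(rownames(vals), dataset$glucose_row), , drop = FALSE]
  }
  flux_range_set(rownames(vals),
                 apply(vals, 1, min), apply(vals, 1, max),
                 provenance = "MFA")
}

#' Apply flux ranges as reaction bounds
#'
#' Replaces the bounds of every reaction named in the range set; all other
#' reactions are untouched.  When the constrained model becomes
#' infeasible, the error names the applied ranges.
#'
#' @param net a `metabolic_network`.
#' @param ranges a `flux_range_set`.
#' @param check verify feasibility with an FBA solve (default TRUE).
#' @return the constrained network.
#' @export
apply_ranges <- function(net, ranges, check = TRUE) {
  missing <- setdiff(ranges$reaction, net$rxns$id)
  if (length(missing) > 0) {
    stop("range set names unknown reaction(s): ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(ranges))) {
    net <- set_bounds(net, ranges$reaction[i],
                      lower = ranges$min[i], upper = ranges$max[i])
  }
  if (check && nrow(ranges) > 0) {
    ok <- tryCatch({ optimize_fba(net); TRUE }, error = function(e) FALSE)
    if (!ok) {
      stop("network infeasible after applying ranges for: ",
           paste(ranges$reaction, collapse = ", "))
    }
  }
  net
}

#' MOMA-derived flux ranges over a knockout panel
#'
#' Simulates each knockout with MOMA against the wild-type reference and
#' records, for each measured reaction, the span of fluxes over all
#' knockout solutions plus the reference itself.
#'
#' @param net the wild-type `metabolic_network` (biomass objective).
#' @param knockouts reaction ids to knock out one at a time.
#' @param measured reaction ids to record (default: the knockouts).
#' @param reference optional precomputed wild-type `flux_distribution`
#'   (pFBA); computed when `NULL`.
#' @return a `flux_range_set` with provenance `"MOMA-scan"`.
#' @export
moma_range_scan <- function(net, knockouts, measured = knockouts,
                            reference = NULL) {
  if (is.null(reference)) reference <- optimize_pfba(net)
  sols <- list(reference$fluxes[measured])
  for (ko in knockouts) {
    fd <- tryCatch(moma_knockout(net, reference, ko), error = function(e) {
      warning(sprintf("knockout '%s' skipped: %s", ko, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(fd)) sols[[length(sols) + 1]] <- fd$fluxes[measured]
  }
  mat <- do.call(cbind, sols)
  flux_range_set(measured, apply(mat, 1, min), apply(mat, 1, max),
                 provenance = "MOMA-scan")
}

#' Compare two flux range sets
#'
#' @param a,b `flux_range_set` objects sharing reaction ids.
#' @return data frame per shared reaction: widths, which set is wider
#'   (`"a"`, `"b"` or `"equal"`), and the overlap interval (NA when
#'   disjoint).
#' @export
compare_ranges <- function(a, b) {
  shared <- intersect(a$reaction, b$reaction)
  if (length(shared) == 0) stop("range sets share no reaction ids")
  ia <- match(shared, a$reaction); ib <- match(shared, b$reaction)
  wa <- a$max[ia] - a$min[ia]; wb <- b$max[ib] - b$min[ib]
  lo <- pmax(a$min[ia], b$min[ib]); hi <- pmin(a$max[ia], b$max[ib])
  empty <- lo > hi
  data.frame(reaction = shared, width_a = wa, width_b = wb,
             wider = ifelse(abs(wa - wb) < 1e-9, "equal",
                            ifelse(wa > wb, "a", "b")),
             overlap_min = ifelse(empty, NA_real_, lo),
             overlap_max = ifelse(empty, NA_real_, hi),
             stringsAsFactors = FALSE)
}
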