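#' Cap the non-growth-associated maintenance reaction
#'
#' Limits the `ATPM` flux (ATP -> ADP + Pi) to at most `limit`; the lower
#' bound is clamped down when it exceeds the new ceiling, so `limit = 0`
#' switches maintenance hydrolysis off entirely.  Re-application with the
#' same limit is a no-op.
#'
#' @param net a `metabolic_network` containing `ATPM`.
#' @param limit maximum flux in mmol gDW^-1 hr^-1 (default 7.6, the
#'   wild-type maintenance level on glucose minimal medium).
#' @return the modified network.
#' @export
cap_atpm <- function(net, limit = 7.6) {
  if (!"ATPM" %in% net$rxns$id) stop("ATPM reaction absent from network")
  b <- reaction_bounds(net, "ATPM")
  set_bounds(net, "ATPM", lower = min(b[["lower"]], limit), upper = limit)
}

#' Load the futile-cycle candidate table
#'
#' The candidates are the reaction families observed to dissipate ATP,
#' NAD(P)H or proton-motive force in antagonistic pairs (e.g. PFK/FBP,
#' PYK/PPS, PPC/PPCK, THD2/NADTRHD, the malic-enzyme bypass, transport
#' loops).  Each entry names the member that is capped -- the partner
#' inactive or low-flux in the wild type -- together with the reaction that
#' closes the cycle and the co-factor dissipated.
#'
#' @param path YAML file; defaults to the copy shipped with the package.
#' @return data frame with columns `cap`, `partner`, `cofactor`, `note`.
#' @export
curation_candidates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "curation_candidates.yml", package = "cobaflux")
  }
  cfg <- yaml::read_yaml(path)
  do.call(rbind, lapply(cfg$candidates, function(x) {
    data.frame(cap = x$cap, partner = x$partner, cofactor = x$cofactor,
               note = x$note %||% "", stringsAsFactors = FALSE)
  }))
}

#' Detect active futile co-factor cycles against a wild-type reference
#'
#' A candidate cycle is reported when the engineered flux through its
#' cappable member exceeds the wild-type flux magnitude by more than the
#' high-flux threshold.  Cycles are ordered by decreasing excess flux, ties
#' broken by reaction id.
#'
#' @param engineered a `flux_distribution` of the engineered model.
#' @param wildtype a `flux_distribution` of the wild-type reference
#'   (biomass-optimal pFBA).
#' @param candidates candidate table from [curation_candidates()].
#' @param threshold high-flux threshold in mmol gDW^-1 hr^-1 (default 1).
#' @return data frame of detected cycles (`cap`, `partner`, `cofactor`,
#'   `flux`, `wt_flux`, `excess`), empty when none.
#' @export
detect_futile_cycles <- function(engineered, wildtype,
                                 candidates = curation_candidates(),
                                 threshold = 1.0) {
  ev <- if (inherits(engineered, "flux_distribution")) engineered$fluxes else engineered
  wv <- if (inherits(wildtype, "flux_distribution")) wildtype$fluxes else wildtype
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    rid <- candidates$cap[i]
    if (!rid %in% names(ev)) next
    wt <- if (rid %in% names(wv)) abs(wv[[rid]]) else 0
    fl <- abs(ev[[rid]])
    excess <- fl - wt
    if (excess > threshold) {
      rows[[length(rows) + 1]] <- data.frame(
        cap = rid, partner = candidates$partner[i],
        cofactor = candidates$cofactor[i], flux = fl, wt_flux = wt,
        excess = excess, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cap = character(0), partner = character(0),
                      cofactor = character(0), flux = numeric(0),
                      wt_flux = numeric(0), excess = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$excess, out$cap), , drop = FALSE]
}

#' Iterative futile-cycle curation ("whack-a-mole")
#'
#' Implements the step-wise manual curation loop: the maintenance reaction
#' is first capped at the wild-type level, then the model is re-optimised
#' and the highest-excess futile cycle has its cappable member bounded to
#' the wild-type flux magnitude (zero when the wild type does not use the
#' reaction).  Detection and capping repeat until no cycle exceeds the
#' threshold or `max_iterations` is reached.  A cap that renders the model
#' infeasible is rolled back and flagged in the log.
#'
#' @param net an engineered `metabolic_network` (medium already applied).
#' @param wt_reference a `flux_distribution` from the biomass-optimal
#'   wild-type pFBA under the same condition.
#' @param atpm_limit maintenance cap (default 7.6); `NULL` skips capping.
#' @param candidates candidate table from [curation_candidates()].
#' @param threshold high-flux threshold (default 1).
#' @param max_iterations iteration ceiling (default 50).
#' @return list with `network` (curated), `log` (one row per applied cap:
#'   iteration, reaction, old/new bound, WT flux, status), `solution`
#'   (final pFBA `flux_distribution`) and `converged`.
#' @export
curate_model <- function(net, wt_reference, atpm_limit = 7.6,
                         candidates = curation_candidates(),
                         threshold = 1.0, max_iterations = 50) {
  if (!is.null(atpm_limit)) net <- cap_atpm(net, atpm_limit)
  log <- list()
  converged <- FALSE
  sol <- optimize_pfba(net)
  for (it in seq_len(max_iterations)) {
    cyc <- detect_futile_cycles(sol, wt_reference, candidates, threshold)
    if (nrow(cyc) == 0) { converged <- TRUE; break }
    rid <- cyc$cap[1]
    cap <- abs(zero_na(wt_reference$fluxes[rid]))
    old <- reaction_bounds(net, rid)
    trial <- set_bounds(net, rid,
                        lower = if (old[["lower"]] < 0) -cap else max(old[["lower"]], 0),
                        upper = cap)
    status <- "applied"
    new_sol <- tryCatch(optimize_pfba(trial), error = function(e) NULL)
    if (is.null(new_sol)) {
      status <- "rolled-back (infeasible)"
      trial <- net
      new_sol <- sol
      candidates <- candidates[candidates$cap != rid, , drop = FALSE]
    }
    log[[length(log) + 1]] <- data.frame(
      iteration = it, reaction = rid, partner = cyc$partner[1],
      cofactor = cyc$cofactor[1], old_upper = old[["upper"]],
      new_bound = cap, wt_flux = cap, excess = cyc$excess[1],
      status = status, stringsAsFactors = FALSE)
    net <- trial
    sol <- new_sol
  }
  log_df <- if (length(log) > 0) do.call(rbind, log) else
    data.frame(iteration = integer(0), reaction = character(0),
               partner = character(0), cofactor = character(0),
               old_upper = numeric(0), new_bound = numeric(0),
               wt_flux = numeric(0), excess = numeric(0),
               status = character(0))
  attr(log_df, "terminal_status") <- if (converged) "converged" else "max-iterations"
  list(network = net, log = log_df, solution = sol, converged = converged)
}

#' Write a curation log as a tab-separated audit file
#' @param log the `log` element of a [curate_model()] result.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_curation_log <- function(log, file) {
  utils::write.table(log, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
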