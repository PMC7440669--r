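#' Pathway definitions for the engineered producer variants
#'
#' Pathway definitions live in a human-editable YAML file
#' (`inst/extdata/pathways.yml`).  Each variant lists its introduced
#' reactions (production, transport and sink), the target metabolite and its
#' formula, the sink/objective reaction, and the declared ATP and NAD(P)H
#' coefficients: the summed stoichiometric coefficients of the introduced
#' reactions from acetyl-CoA to the final target (negative values are
#' co-factor demand).
#'
#' @param path YAML file; defaults to the copy shipped with the package.
#' @return named list of `pathway_definition` objects.
#' @export
load_pathway_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathways.yml", package = "cobaflux")
  }
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg$variants), function(v) {
    spec <- cfg$variants[[v]]
    rxns <- lapply(spec$reactions, function(rid) {
      entry <- cfg$reactions[[rid]]
      if (is.null(entry)) stop(sprintf("pathway '%s' uses undefined reaction '%s'", v, rid))
      list(id = rid, name = entry$name, equation = entry$equation)
    })
    structure(list(
      name = v,
      description = spec$description,
      reactions = rxns,
      objective = spec$objective,
      sink_reaction = spec$objective,
      target_metabolite = spec$target_metabolite,
      target_formula = spec$target_formula,
      terminal_reaction = spec$terminal_reaction,
      atp = spec$atp, nadh = spec$nadh, nadph = spec$nadph,
      expected_reactions = spec$expected_reactions,
      expected_metabolites = spec$expected_metabolites,
      metabolite_meta = cfg$metabolites
    ), class = "pathway_definition")
  })
  names(out) <- names(cfg$variants)
  out
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat(sprintf("pathway_definition '%s': %d reactions -> %s (ATP %g, NAD(P)H %g)\n",
              x$name, length(x$reactions), x$target_metabolite,
              x$atp, x$nadh + x$nadph))
  invisible(x)
}

#' Summed co-factor coefficients of a pathway definition
#'
#' Sums the stoichiometric coefficients of `atp_c`, `nadh_c` and `nadph_c`
#' over all introduced reactions and compares them with the declared
#' coefficients of the definition.
#'
#' @param pd a `pathway_definition`.
#' @return list with `atp`, `nadh`, `nadph`, `nadph_pool` sums and logical
#'   `consistent`.
#' @export
check_pathway_coefficients <- function(pd) {
  tot <- c(atp_c = 0, nadh_c = 0, nadph_c = 0)
  for (r in pd$reactions) {
    st <- parse_reaction_equation(r$equation)$stoichiometry
    for (m in names(tot)) tot[m] <- tot[m] + zero_na(st[m])
  }
  consistent <- isTRUE(all.equal(unname(tot["atp_c"]), pd$atp)) &&
    isTRUE(all.equal(unname(tot["nadh_c"] + tot["nadph_c"]), pd$nadh + pd$nadph)) &&
    isTRUE(all.equal(unname(tot["nadph_c"]), pd$nadph))
  list(atp = unname(tot["atp_c"]), nadh = unname(tot["nadh_c"]),
       nadph = unname(tot["nadph_c"]),
       nadph_pool = unname(tot["nadh_c"] + tot["nadph_c"]),
       consistent = consistent)
}

#' Add an engineered pathway to a base network
#'
#' Returns a new network (the base is unmodified) with the pathway's
#' production, transport and sink reactions added and the sink set as the
#' objective.  Intermediate metabolites introduced by the pathway must be
#' both produced and consumed; a dangling intermediate is rejected.
#'
#' @param base a `metabolic_network` (usually the wild-type core model).
#' @param pathway a `pathway_definition`, or a variant name resolved via
#'   [load_pathway_definitions()].
#' @return the engineered `metabolic_network`.
#' @export
add_pathway <- function(base, pathway) {
  if (is.character(pathway)) {
    defs <- load_pathway_definitions()
    if (!pathway %in% names(defs)) {
      stop(sprintf("unknown variant '%s'; available: %s", pathway,
                   paste(names(defs), collapse = ", ")))
    }
    pathway <- defs[[pathway]]
  }
  stopifnot(inherits(pathway, "pathway_definition"))
  net <- base
  if (length(pathway$reactions) == 0) return(net)
  dup <- intersect(vapply(pathway$reactions, `[[`, "", "id"), net$rxns$id)
  if (length(dup) > 0) {
    stop(sprintf("pathway reaction id(s) already present in base network: %s",
                 paste(dup, collapse = ", ")))
  }
  before <- net$mets$id
  for (r in pathway$reactions) {
    net <- add_reaction(net, r$id, r$equation, name = r$name %||% r$id,
                        metabolite_meta = pathway$metabolite_meta)
  }
  new_mets <- setdiff(net$mets$id, before)
  terminal <- pathway$target_metabolite
  for (m in new_mets) {
    col <- net$S[m, ]
    if (m != terminal && (all(col <= 0) || all(col >= 0))) {
      stop(sprintf("pathway metabolite '%s' is dangling (only %s)", m,
                   if (all(col <= 0)) "consumed" else "produced"))
    }
  }
  net <- set_objective(net, pathway$objective)
  net$annotation$variant <- pathway$name
  net$annotation$pathway_reactions <- vapply(pathway$reactions, `[[`, "", "id")
  net$annotation$target_metabolite <- pathway$target_metabolite
  net$annotation$target_formula <- pathway$target_formula
  net$annotation$terminal_reaction <- pathway$terminal_reaction
  net
}

#' Build the full model catalogue
#'
#' Constructs the wild-type network plus the eight engineered variants, each
#' with its sink reaction as objective (biomass for the wild type).
#'
#' @param core base network; defaults to [load_core_model()].
#' @param definitions list from [load_pathway_definitions()].
#' @param condition optional [medium_condition()] applied to every model.
#' @return named list of `metabolic_network` objects (WT first).
#' @export
build_catalog <- function(core = load_core_model(),
                          definitions = load_pathway_definitions(),
                          condition = NULL) {
  models <- c(list(WT = core), lapply(definitions, add_pathway, base = core))
  if (!is.null(condition)) models <- lapply(models, apply_medium, condition = condition)
  models
}
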