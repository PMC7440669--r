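#' Load the bundled reduced E. coli core network
#'
#' The wild-type model is the published E. coli core stoichiometric network
#' restricted to growth on minimal glucose medium: the uptake routes for the
#' alternative substrates (fructose, fumarate, malate, 2-oxoglutarate,
#' glutamate, glutamine, pyruvate) and the lactate and acetaldehyde secretion
#' routes are removed, leaving 77 reactions over 63 metabolites.  Fatty-acid
#' synthesis and all butanol-pathway reactions are absent; they are introduced
#' per variant by [add_pathway()].
#'
#' The non-growth-associated maintenance reaction `ATPM` (ATP -> ADP + Pi) is
#' an output of interest rather than a fixed demand here, so its lower bound
#' is governed by the `ngam` argument instead of the file default.
#'
#' @param path directory holding `ecoli_core_reduced_reactions.tsv` and
#'   `ecoli_core_reduced_metabolites.tsv`; defaults to the copies shipped
#'   with the package.
#' @param ngam non-growth-associated maintenance in mmol gDW^-1 hr^-1,
#'   applied as the `ATPM` lower bound (default 7.6).
#' @return a `metabolic_network` with the biomass reaction as objective.
#' @export
load_core_model <- function(path = NULL, ngam = 7.6) {
  if (is.null(path)) path <- system.file("extdata", package = "cobaflux")
  rfile <- file.path(path, "ecoli_core_reduced_reactions.tsv")
  mfile <- file.path(path, "ecoli_core_reduced_metabolites.tsv")
  if (!file.exists(rfile) || !file.exists(mfile)) {
    stop("core model tables not found under ", path)
  }
  net <- read_network_tables(rfile, mfile)
  if (length(objective_id(net)) == 0) stop("core model has no objective")
  net$annotation$model <- "ecoli_core_reduced"
  net$annotation$variant <- "WT"
  net$annotation$objective <- objective_id(net)
  if (!is.null(ngam)) {
    if (!"ATPM" %in% net$rxns$id) stop("ATPM reaction absent from core model")
    net <- set_bounds(net, "ATPM", lower = ngam)
  }
  net
}

#' Read a network from tab-separated reaction/metabolite tables
#'
#' @param reactions_file TSV with columns `id`, `name`, `equation`,
#'   `lower_bound`, `upper_bound`, `objective`.
#' @param metabolites_file TSV with columns `id`, `name`, `formula`,
#'   `compartment`.
#' @return a `metabolic_network`.
#' @export
read_network_tables <- function(reactions_file, metabolites_file) {
  rx <- utils::read.delim(reactions_file, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  mt <- utils::read.delim(metabolites_file, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  need <- c("id", "equation", "lower_bound", "upper_bound")
  if (!all(need %in% names(rx))) {
    stop("reaction table lacks column(s): ",
         paste(setdiff(need, names(rx)), collapse = ", "))
  }
  if (anyNA(rx$lower_bound) || anyNA(rx$upper_bound)) {
    stop(sprintf("reaction '%s' has missing flux bounds",
                 rx$id[which(is.na(rx$lower_bound) | is.na(rx$upper_bound))[1]]))
  }
  if (is.null(rx$name)) rx$name <- rx$id
  if (is.null(rx$objective)) rx$objective <- 0
  if (is.null(mt$formula)) mt$formula <- ""
  if (is.null(mt$compartment)) mt$compartment <- "c"
  mt$formula[is.na(mt$formula)] <- ""
  st <- lapply(rx$equation, function(e) parse_reaction_equation(e)$stoichiometry)
  names(st) <- rx$id
  metabolic_network(
    metabolites = mt[, c("id", "name", "formula", "compartment")],
    reactions = data.frame(id = rx$id, name = rx$name,
                           lower_bound = as.numeric(rx$lower_bound),
                           upper_bound = as.numeric(rx$upper_bound),
                           objective = as.logical(rx$objective > 0),
                           stringsAsFactors = FALSE),
    stoichiometry = st)
}

#' Write a network as tab-separated reaction/metabolite tables
#' @param net a `metabolic_network`.
#' @param reactions_file,metabolites_file output paths.
#' @return invisibly, the two file paths.
#' @export
write_network_tables <- function(net, reactions_file, metabolites_file) {
  eqs <- vapply(net$rxns$id, function(rid) {
    format_reaction_equation(reaction_stoichiometry(net, rid),
                             reversible = reaction_bounds(net, rid)[1] < 0)
  }, character(1))
  rx <- data.frame(id = net$rxns$id, name = net$rxns$name, equation = eqs,
                   lower_bound = net$rxns$lower_bound,
                   upper_bound = net$rxns$upper_bound,
                   objective = as.integer(net$rxns$objective))
  utils::write.table(rx, reactions_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$mets, metabolites_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(reactions_file, metabolites_file))
}

#' Medium condition
#'
#' Exchange bounds for a minimal-glucose medium.  Uptake limits are given as
#' negative lower bounds on the exchange reactions; the aerobic preset allows
#' oxygen uptake up to 10 mmol gDW^-1 hr^-1 and the anaerobic preset forbids
#' oxygen uptake entirely.
#'
#' @param glucose glucose uptake bound (negative = uptake), default -10.
#' @param oxygen oxygen uptake bound, default -10.
#' @param other named numeric vector of additional exchange lower bounds.
#' @return a `medium_condition` object.
#' @export
medium_condition <- function(glucose = -10, oxygen = -10, other = numeric(0)) {
  if (oxygen < -10 - 1e-9 && oxygen != -1000) {
    stop("aerobic oxygen uptake magnitude must not exceed 10")
  }
  structure(list(glucose = glucose, oxygen = oxygen, other = other),
            class = "medium_condition")
}

#' @rdname medium_condition
#' @export
aerobic_medium <- function() medium_condition(glucose = -10, oxygen = -10)

#' @rdname medium_condition
#' @export
anaerobic_medium <- function() medium_condition(glucose = -10, oxygen = 0)

#' Apply a medium condition to a network
#'
#' Updates the lower bounds of the glucose and oxygen exchange reactions (and
#' of any additional exchanges named in the condition); all other bounds are
#' untouched.  Applying the same condition twice is a no-op.
#'
#' @param net a `metabolic_network`.
#' @param condition a [medium_condition()].
#' @return the modified network, with `annotation$condition` set.
#' @export
apply_medium <- function(net, condition) {
  stopifnot(inherits(condition, "medium_condition"))
  ex <- c(EX_glc__D_e = condition$glucose, EX_o2_e = condition$oxygen,
          condition$other)
  for (rid in names(ex)) {
    if (!rid %in% net$rxns$id) {
      stop(sprintf("exchange reaction '%s' absent from network", rid))
    }
    net <- set_bounds(net, rid, lower = ex[[rid]])
  }
  net$annotation$condition <-
    if (condition$oxygen == 0) "anaerobic" else "aerobic"
  net
}
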