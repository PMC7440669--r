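#' Stoichiometric metabolic network
#'
#' A `metabolic_network` bundles the stoichiometric matrix of a
#' constraint-based model with reaction bounds, an objective reaction and
#' metabolite/reaction metadata.  Fluxes are expressed in
#' mmol gDW^-1 hr^-1 throughout.
#'
#' @param metabolites data frame with columns `id`, `name`, `formula`,
#'   `compartment`.
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` and logical `objective`.
#' @param stoichiometry named list mapping each reaction id to a named numeric
#'   vector of metabolite coefficients (negative = consumed).
#' @param annotation free-form list; the package uses `model`, `variant`,
#'   `pathway_reactions`, `objective`, `target_metabolite`, `target_formula`
#'   and `terminal_reaction`.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              annotation = list()) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  metabolites$id <- as.character(metabolites$id)
  reactions$id <- as.character(reactions$id)
  if (anyDuplicated(metabolites$id)) stop("duplicated metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicated reaction ids")
  S <- Matrix::Matrix(0, nrow = nrow(metabolites), ncol = nrow(reactions),
                      dimnames = list(metabolites$id, reactions$id),
                      sparse = TRUE)
  for (rid in names(stoichiometry)) {
    st <- stoichiometry[[rid]]
    missing <- setdiff(names(st), metabolites$id)
    if (length(missing) > 0) {
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   rid, paste(missing, collapse = ", ")))
    }
    S[names(st), rid] <- st
  }
  net <- structure(list(mets = metabolites, rxns = reactions, S = S,
                        annotation = annotation),
                   class = "metabolic_network")
  validate_network(net)
  net
}

#' Validate the structural invariants of a network
#'
#' Checks that bounds are ordered (`lower <= upper`) and that every stored
#' stoichiometric entry refers to a known metabolite.  Called by all
#' network-modifying functions.
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly; errors describe the offending reaction.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  bad <- net$rxns$lower_bound > net$rxns$upper_bound
  if (any(bad)) {
    stop(sprintf("reaction '%s' has lower bound above upper bound",
                 net$rxns$id[which(bad)[1]]))
  }
  if (!identical(rownames(net$S), net$mets$id) ||
      !identical(colnames(net$S), net$rxns$id)) {
    stop("stoichiometric matrix dimnames out of sync with metadata")
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  obj <- objective_id(x)
  cat(sprintf("metabolic_network '%s': %d metabolites x %d reactions\n",
              x$annotation$variant %||% x$annotation$model %||% "?",
              nrow(x$mets), nrow(x$rxns)))
  cat(sprintf("  objective: %s\n", if (length(obj)) obj else "<none>"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numbers of reactions and metabolites
#' @param net a `metabolic_network`.
#' @return integer count.
#' @export
n_reactions <- function(net) nrow(net$rxns)

#' @rdname n_reactions
#' @export
n_metabolites <- function(net) nrow(net$mets)

#' @rdname n_reactions
#' @export
reaction_ids <- function(net) net$rxns$id

#' @rdname n_reactions
#' @export
metabolite_ids <- function(net) net$mets$id

#' Objective reaction id of a network
#' @param net a `metabolic_network`.
#' @return character id (length 0 when unset).
#' @export
objective_id <- function(net) net$rxns$id[net$rxns$objective]

#' Set the objective reaction
#' @param net a `metabolic_network`.
#' @param rid reaction id to maximise.
#' @return the modified network.
#' @export
set_objective <- function(net, rid) {
  if (!rid %in% net$rxns$id) stop(sprintf("unknown reaction '%s'", rid))
  net$rxns$objective <- net$rxns$id == rid
  net$annotation$objective <- rid
  net
}

#' Reaction bounds
#' @param net a `metabolic_network`.
#' @param rid reaction id.
#' @return numeric `c(lower, upper)`.
#' @export
reaction_bounds <- function(net, rid) {
  i <- match(rid, net$rxns$id)
  if (is.na(i)) stop(sprintf("unknown reaction '%s'", rid))
  c(lower = net$rxns$lower_bound[i], upper = net$rxns$upper_bound[i])
}

#' Set reaction bounds
#' @param net a `metabolic_network`.
#' @param rid reaction id.
#' @param lower,upper new bounds; `NA` keeps the current value.
#' @return the modified network.
#' @export
set_bounds <- function(net, rid, lower = NA, upper = NA) {
  i <- match(rid, net$rxns$id)
  if (is.na(i)) stop(sprintf("unknown reaction '%s'", rid))
  if (!is.na(lower)) net$rxns$lower_bound[i] <- lower
  if (!is.na(upper)) net$rxns$upper_bound[i] <- upper
  validate_network(net)
}

#' Stoichiometry of one reaction
#' @param net a `metabolic_network`.
#' @param rid reaction id.
#' @return named numeric vector of nonzero coefficients.
#' @export
reaction_stoichiometry <- function(net, rid) {
  if (!rid %in% net$rxns$id) stop(sprintf("unknown reaction '%s'", rid))
  col <- net$S[, rid]
  col[col != 0]
}

#' Parse a reaction equation string
#'
#' Equations use the convention `"2 accoa_c -> aacoa_c + coa_c"`; `"<->"`
#' marks reversibility and an empty side denotes an exchange/sink
#' (`"btoh_e ->"`).
#'
#' @param equation equation string.
#' @return list with `stoichiometry` (named numeric, negative = substrate)
#'   and logical `reversible`.
#' @export
parse_reaction_equation <- function(equation) {
  equation <- trimws(equation)
  reversible <- grepl("<->|<=>", equation)
  parts <- strsplit(equation, "<->|<=>|-->|->", perl = TRUE)[[1]]
  if (length(parts) > 2) stop(sprintf("malformed equation: '%s'", equation))
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (identical(txt, "") || is.na(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "\\+")[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (tm in terms) {
      tok <- strsplit(tm, "\\s+")[[1]]
      if (length(tok) == 1) {
        coef <- 1; met <- tok
      } else if (length(tok) == 2 && !is.na(suppressWarnings(as.numeric(tok[1])))) {
        coef <- as.numeric(tok[1]); met <- tok[2]
      } else {
        stop(sprintf("malformed term '%s' in equation '%s'", tm, equation))
      }
      out[met] <- zero_na(out[met]) + sign * coef
    }
    out
  }
  lhs <- parse_side(parts[1], -1)
  rhs <- if (length(parts) == 2) parse_side(parts[2], 1) else numeric(0)
  st <- lhs
  for (m in names(rhs)) st[m] <- zero_na(st[m]) + rhs[m]
  st <- st[st != 0]
  list(stoichiometry = st, reversible = reversible)
}

zero_na <- function(x) if (length(x) == 0 || is.na(x)) 0 else as.numeric(x)

#' Format a stoichiometry vector as an equation string
#' @param stoichiometry named numeric vector (negative = substrate).
#' @param reversible logical.
#' @return equation string.
#' @export
format_reaction_equation <- function(stoichiometry, reversible = FALSE) {
  fmt <- function(v) {
    paste(vapply(names(v), function(m) {
      c0 <- abs(v[[m]])
      if (c0 == 1) m else sprintf("%g %s", c0, m)
    }, character(1)), collapse = " + ")
  }
  lhs <- stoichiometry[stoichiometry < 0]
  rhs <- stoichiometry[stoichiometry > 0]
  paste(fmt(lhs), if (reversible) "<->" else "->", fmt(rhs))
}

#' Add a reaction (and any new metabolites) to a network
#'
#' @param net a `metabolic_network`.
#' @param id new reaction id; must not collide with an existing one.
#' @param equation equation string (see [parse_reaction_equation()]).
#' @param lower_bound,upper_bound flux bounds; defaults follow the equation's
#'   reversibility arrow.
#' @param name human-readable reaction name.
#' @param metabolite_meta optional named list of `list(name=, formula=,
#'   compartment=)` entries for metabolites not yet in the network.
#' @return the extended network.
#' @export
add_reaction <- function(net, id, equation, lower_bound = NULL,
                         upper_bound = 1000, name = id,
                         metabolite_meta = list()) {
  if (id %in% net$rxns$id) stop(sprintf("reaction id '%s' already present", id))
  eq <- parse_reaction_equation(equation)
  if (is.null(lower_bound)) lower_bound <- if (eq$reversible) -1000 else 0
  new_mets <- setdiff(names(eq$stoichiometry), net$mets$id)
  for (m in new_mets) {
    meta <- metabolite_meta[[m]] %||% list()
    net$mets <- rbind(net$mets, data.frame(
      id = m, name = meta$name %||% m, formula = meta$formula %||% "",
      compartment = meta$compartment %||%
        (if (grepl("_e$", m)) "e" else "c"),
      stringsAsFactors = FALSE))
  }
  S <- net$S
  if (length(new_mets) > 0) {
    pad <- Matrix::Matrix(0, nrow = length(new_mets), ncol = ncol(S),
                          dimnames = list(new_mets, colnames(S)), sparse = TRUE)
    S <- rbind(S, pad)
  }
  newcol <- Matrix::Matrix(0, nrow = nrow(S), ncol = 1,
                           dimnames = list(rownames(S), id), sparse = TRUE)
  newcol[names(eq$stoichiometry), 1] <- eq$stoichiometry
  net$S <- cbind(S, newcol)
  net$rxns <- rbind(net$rxns, data.frame(
    id = id, name = name, lower_bound = lower_bound,
    upper_bound = upper_bound, objective = FALSE, stringsAsFactors = FALSE))
  validate_network(net)
}

#' Remove reactions (and orphaned metabolites) from a network
#' @param net a `metabolic_network`.
#' @param ids reaction ids to drop.
#' @param drop_orphans drop metabolites no longer used by any reaction.
#' @return the reduced network.
#' @export
remove_reactions <- function(net, ids, drop_orphans = TRUE) {
  missing <- setdiff(ids, net$rxns$id)
  if (length(missing) > 0) {
    stop(sprintf("unknown reaction(s): %s", paste(missing, collapse = ", ")))
  }
  keep <- !(net$rxns$id %in% ids)
  net$rxns <- net$rxns[keep, , drop = FALSE]
  net$S <- net$S[, keep, drop = FALSE]
  if (drop_orphans) {
    used <- Matrix::rowSums(net$S != 0) > 0
    net$mets <- net$mets[used, , drop = FALSE]
    net$S <- net$S[used, , drop = FALSE]
  }
  rownames(net$rxns) <- NULL
  rownames(net$mets) <- NULL
  validate_network(net)
}

#' Carbon atoms in a chemical formula
#' @param formula a Hill-style formula such as `"C4H10O"`.
#' @return integer carbon count (0 for empty formulas).
#' @export
carbon_count <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(0L)
  m <- regmatches(formula, regexec("C([0-9]*)(?![a-z])", formula, perl = TRUE))[[1]]
  if (length(m) == 0 || !nzchar(m[1])) return(0L)
  if (!nzchar(m[2])) 1L else as.integer(m[2])
}
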