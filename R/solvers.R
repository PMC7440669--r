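#' Flux balance analysis
#'
#' Maximises the network objective subject to steady-state mass balance
#' `S v = 0` and the flux bounds.
#'
#' @param net a `metabolic_network` with an objective reaction.
#' @return a `flux_distribution`: list with `fluxes` (named numeric),
#'   `objective_value`, `objective_id`, `status`, `variant`, `condition`
#'   and `solver` settings.
#' @export
optimize_fba <- function(net) {
  obj_id <- objective_id(net)
  if (length(obj_id) != 1) stop("network needs exactly one objective reaction")
  cvec <- as.numeric(net$rxns$id == obj_id)
  res <- solve_lp(net$S, net$rxns$lower_bound, net$rxns$upper_bound, cvec, "max")
  if (res$status != "optimal") {
    stop(sprintf("FBA on '%s' is %s", net$annotation$variant %||% "?", res$status))
  }
  new_flux_distribution(net, res$primal, res$objective, obj_id, "FBA")
}

new_flux_distribution <- function(net, fluxes, objective_value, obj_id, method) {
  structure(list(variant = net$annotation$variant %||% NA_character_,
                 condition = net$annotation$condition %||% NA_character_,
                 method = method,
                 objective_id = obj_id,
                 objective_value = objective_value,
                 fluxes = fluxes,
                 solver = lp_solver_info()),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("flux_distribution (%s) '%s'/%s: %s = %.6g, %d reactions\n",
              x$method, x$variant, x$condition, x$objective_id,
              x$objective_value, length(x$fluxes)))
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage optimisation: the objective is fixed at its FBA optimum, then
#' the total absolute flux is minimised over an irreversible split of every
#' reaction.  The returned distribution carries the stage-one objective
#' value and the minimal total flux (`total_flux`).
#'
#' @param net a `metabolic_network`.
#' @return a `flux_distribution` with an extra `total_flux` element.
#' @export
optimize_pfba <- function(net) {
  fba <- optimize_fba(net)
  obj_id <- fba$objective_id
  n <- n_reactions(net)
  # split v = p - m with p, m >= 0
  S2 <- cbind(net$S, -net$S)
  colnames(S2) <- c(paste0(net$rxns$id, "..f"), paste0(net$rxns$id, "..r"))
  lb2 <- c(pmax(net$rxns$lower_bound, 0), pmax(-net$rxns$upper_bound, 0))
  ub2 <- c(pmax(net$rxns$upper_bound, 0), pmax(-net$rxns$lower_bound, 0))
  cfix <- c(as.numeric(net$rxns$id == obj_id), -as.numeric(net$rxns$id == obj_id))
  res <- solve_lp(S2, lb2, ub2, rep(1, 2 * n), "min",
                  extra = list(list(coef = cfix, dir = "=",
                                    rhs = fba$objective_value)))
  if (res$status != "optimal") {
    stop(sprintf("pFBA stage 2 on '%s' is %s",
                 net$annotation$variant %||% "?", res$status))
  }
  v <- res$primal[seq_len(n)] - res$primal[n + seq_len(n)]
  names(v) <- net$rxns$id
  fd <- new_flux_distribution(net, v, fba$objective_value, obj_id, "pFBA")
  fd$total_flux <- res$objective
  fd
}

#' Flux variability analysis
#'
#' For each reaction, minimises and maximises its flux subject to the
#' network objective being held at `fraction_of_optimum` times its FBA
#' optimum.
#'
#' @param net a `metabolic_network`.
#' @param fraction_of_optimum fraction in (0, 1]; default 1.
#' @param reactions reaction ids to scan (default: all).
#' @return a `flux_range_set`: data frame with columns `reaction`,
#'   `min`, `max`, plus attributes `provenance` and `fraction_of_optimum`.
#' @export
flux_variability <- function(net, fraction_of_optimum = 1.0, reactions = NULL) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  fba <- optimize_fba(net)
  if (is.null(reactions)) reactions <- net$rxns$id
  missing <- setdiff(reactions, net$rxns$id)
  if (length(missing) > 0) {
    stop("unknown reaction(s): ", paste(missing, collapse = ", "))
  }
  cvec <- as.numeric(net$rxns$id == fba$objective_id)
  fix <- list(coef = cvec, dir = ">=",
              rhs = fraction_of_optimum * fba$objective_value)
  lo <- hi <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    ck <- as.numeric(net$rxns$id == reactions[k])
    rmin <- solve_lp(net$S, net$rxns$lower_bound, net$rxns$upper_bound,
                     ck, "min", extra = list(fix))
    rmax <- solve_lp(net$S, net$rxns$lower_bound, net$rxns$upper_bound,
                     ck, "max", extra = list(fix))
    if (rmin$status != "optimal" || rmax$status != "optimal") {
      stop(sprintf("FVA subproblem for '%s' is not optimal", reactions[k]))
    }
    lo[k] <- rmin$objective; hi[k] <- rmax$objective
  }
  flux_range_set(reactions, lo, hi, provenance = "FVA",
                 fraction_of_optimum = fraction_of_optimum)
}

#' Construct a flux range set
#' @param reaction reaction ids.
#' @param min,max flux range endpoints.
#' @param provenance `"FVA"`, `"MOMA-scan"` or `"MFA"`.
#' @param fraction_of_optimum recorded for FVA ranges.
#' @return a `flux_range_set` data frame.
#' @export
flux_range_set <- function(reaction, min, max, provenance = "FVA",
                           fraction_of_optimum = NA_real_) {
  if (any(min > max + 1e-9)) stop("flux range with min above max")
  out <- data.frame(reaction = reaction, min = min, max = max,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  class(out) <- c("flux_range_set", "data.frame")
  out
}

#' Count reactions with non-degenerate flux ranges
#' @param ranges a `flux_range_set`.
#' @param tol degeneracy threshold in mmol gDW^-1 hr^-1 (default 1e-6).
#' @return integer count of reactions with `max - min > tol`.
#' @export
count_variable_reactions <- function(ranges, tol = 1e-6) {
  sum(abs(ranges$max - ranges$min) > tol)
}

#' Minimisation of metabolic adjustment (MOMA)
#'
#' Finds the feasible flux vector of minimal Euclidean distance to a
#' reference distribution after forcing the knocked-out reaction to zero.
#' The quadratic program is solved with the Goldfarb-Idnani dual method.
#'
#' @param net a `metabolic_network`.
#' @param reference a `flux_distribution` (or named flux vector) covering
#'   every reaction of `net`.
#' @param knockout reaction id whose bounds are set to zero; `NULL` solves
#'   the plain projection.
#' @return a `flux_distribution` with `distance` (Euclidean) added; the
#'   `objective_value` is the flux of the reference objective reaction.
#' @export
moma_knockout <- function(net, reference, knockout = NULL) {
  ref <- if (inherits(reference, "flux_distribution")) reference$fluxes else reference
  if (!all(net$rxns$id %in% names(ref))) {
    stop("reference distribution does not cover all reactions of the network")
  }
  ref <- ref[net$rxns$id]
  if (!is.null(knockout)) {
    if (!knockout %in% net$rxns$id) stop(sprintf("unknown reaction '%s'", knockout))
    net <- set_bounds(net, knockout, lower = 0, upper = 0)
  }
  n <- n_reactions(net)
  Sd <- as.matrix(net$S)
  # conserved-moiety pools make rows of S linearly dependent; keep an
  # independent subset for the equality constraints (the rest are implied)
  dec <- qr(t(Sd))
  Sd <- Sd[dec$pivot[seq_len(dec$rank)], , drop = FALSE]
  Amat <- cbind(t(Sd), diag(n), -diag(n))
  bvec <- c(rep(0, nrow(Sd)), net$rxns$lower_bound, -net$rxns$upper_bound)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(2, n), dvec = 2 * ref, Amat = Amat,
                       bvec = bvec, meq = nrow(Sd)),
    error = function(e) {
      stop(sprintf("MOMA%s is infeasible: %s",
                   if (is.null(knockout)) "" else sprintf(" with knockout '%s'", knockout),
                   conditionMessage(e)))
    })
  v <- sol$solution
  names(v) <- net$rxns$id
  obj_id <- objective_id(net)
  fd <- new_flux_distribution(net, v,
                              if (length(obj_id)) v[[obj_id]] else NA_real_,
                              if (length(obj_id)) obj_id else NA_character_,
                              "MOMA")
  fd$distance <- sqrt(sum((v - ref)^2))
  fd$knockout <- knockout
  fd
}

#' Loopless solution mode (delegated)
#'
#' Thermodynamically-infeasible-loop removal is delegated to an external
#' backend registered via `options(cobaflux.loopless_backend = <function>)`.
#' No backend ships with the package; when none is registered the function
#' warns and falls back to a standard parsimonious FBA solution, in which
#' internal co-factor cycles may persist.
#'
#' @param net a `metabolic_network`.
#' @return a `flux_distribution`; `method` records whether the loopless
#'   backend or the pFBA fallback produced it.
#' @export
loopless_mode <- function(net) {
  backend <- getOption("cobaflux.loopless_backend", NULL)
  if (is.function(backend)) {
    fd <- backend(net)
    fd$method <- "loopless"
    return(fd)
  }
  warning("no loopless backend registered; falling back to standard pFBA ",
          "(co-factor cycles may persist)")
  fd <- optimize_pfba(net)
  fd$method <- "pFBA (loopless fallback)"
  fd
}

#' Maximum mass-balance residual of a flux distribution
#' @param net the `metabolic_network` the fluxes belong to.
#' @param fd a `flux_distribution` or named flux vector.
#' @return `max |S v|` over internal metabolites.
#' @export
mass_balance_residual <- function(net, fd) {
  v <- if (inherits(fd, "flux_distribution")) fd$fluxes else fd
  max(abs(as.numeric(net$S %*% v[net$rxns$id])))
}

#' Export a flux distribution as a tab-separated table
#' @param fd a `flux_distribution`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_flux_table <- function(fd, file) {
  utils::write.table(
    data.frame(reaction = names(fd$fluxes), flux = unname(fd$fluxes)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export a flux range set as a tab-separated table
#' @param ranges a `flux_range_set`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_range_table <- function(ranges, file) {
  utils::write.table(as.data.frame(ranges), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
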