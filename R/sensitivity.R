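#' Rewrite the terminal aldehyde-reductase stoichiometry
#'
#' Replaces the terminal butyraldehyde -> butanol step with the
#' generalised form
#' `butyraldehyde + X NADH + X H+ + Y ADP + Y Pi -> butanol + X NAD + Y ATP`:
#' positive `X`/`Y` make the step release the co-factor, negative values add
#' demand (species move across the reaction arrow), and zero removes the
#' co-factor from the step entirely.  The native reaction corresponds to
#' `X = 1, Y = 0`.
#'
#' @param net an engineered `metabolic_network` whose annotation names a
#'   `terminal_reaction`.
#' @param X NADH coefficient (surplus positive).
#' @param Y ATP coefficient (surplus positive).
#' @return the modified network.
#' @export
modify_terminal_stoichiometry <- function(net, X, Y) {
  rid <- net$annotation$terminal_reaction
  if (is.null(rid)) stop("network has no terminal aldehyde-reductase annotation")
  if (!rid %in% net$rxns$id) stop(sprintf("terminal reaction '%s' absent", rid))
  st <- reaction_stoichiometry(net, rid)
  carbon <- st[!names(st) %in% c("nadh_c", "nad_c", "h_c", "atp_c", "adp_c", "pi_c", "h2o_c")]
  if (!all(c("btal_c", "btoh_c") %in% names(carbon))) {
    stop("terminal reaction does not interconvert butyraldehyde and butanol")
  }
  new_st <- c(carbon,
              c(nadh_c = -X, h_c = -X, nad_c = X,
                adp_c = -Y, pi_c = -Y, atp_c = Y))
  new_st <- new_st[new_st != 0]
  net$S[, rid] <- 0
  net$S[names(new_st), rid] <- new_st
  net
}

#' Co-factor stoichiometry landscape
#'
#' Sweeps the NADH (`X`) and ATP (`Y`) coefficients of the terminal
#' reductase step over a grid, re-optimising the target sink with
#' parsimonious FBA at every grid point and recording carbon yield and
#' biomass flux.  Infeasible cells are recorded with zero yield and
#' status `"infeasible"`.
#'
#' @param net an engineered (typically curated) `metabolic_network` with
#'   medium applied.
#' @param xs grid of NADH coefficients (default -10..10, step 1).
#' @param ys grid of ATP coefficients (default -10..10, step 1).
#' @param biomass_reaction id used for the biomass readout.
#' @return a `landscape_grid` data frame with columns `X`, `Y`, `yield`,
#'   `biomass`, `status`.
#' @export
build_landscape <- function(net, xs = seq(-10, 10), ys = seq(-10, 10),
                            biomass_reaction = "Biomass_Ecoli_core") {
  cells <- expand.grid(X = xs, Y = ys, KEEP.OUT.ATTRS = FALSE)
  yield <- biomass <- numeric(nrow(cells))
  status <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    m <- modify_terminal_stoichiometry(net, cells$X[i], cells$Y[i])
    sol <- tryCatch(optimize_pfba(m), error = function(e) NULL)
    if (is.null(sol)) {
      yield[i] <- 0; biomass[i] <- NA_real_; status[i] <- "infeasible"
    } else {
      yield[i] <- carbon_yield(m, sol)
      biomass[i] <- zero_na(sol$fluxes[biomass_reaction])
      status[i] <- "optimal"
    }
  }
  out <- data.frame(X = cells$X, Y = cells$Y, yield = yield,
                    biomass = biomass, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "variant") <- net$annotation$variant
  attr(out, "condition") <- net$annotation$condition
  class(out) <- c("landscape_grid", "data.frame")
  out
}
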