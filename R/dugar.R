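#' Parse a CHO(N) chemical formula
#' @param formula Hill-style formula, e.g. `"C4H10O"`.
#' @return named numeric vector of element counts.
#' @export
parse_chemical_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) stop("empty chemical formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula, perl = TRUE)[[1]]
  starts <- as.integer(m); lens <- attr(m, "match.length")
  if (starts[1] == -1 || sum(lens) != nchar(formula)) {
    stop(sprintf("cannot parse chemical formula '%s'", formula))
  }
  out <- numeric(0)
  for (k in seq_along(starts)) {
    tok <- substr(formula, starts[k], starts[k] + lens[k] - 1)
    el <- sub("[0-9.]*$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    out[el] <- zero_na(out[el]) + if (nzchar(cnt)) as.numeric(cnt) else 1
  }
  out
}

#' Degree of reductance of a CHO compound
#'
#' Available electrons per molecule, `4C + H - 2O` (nitrogen, when present,
#' contributes -3 per atom under the ammonia convention).
#'
#' @param formula chemical formula.
#' @return numeric degree of reductance.
#' @export
degree_of_reductance <- function(formula) {
  el <- parse_chemical_formula(formula)
  4 * zero_na(el["C"]) + zero_na(el["H"]) - 2 * zero_na(el["O"]) -
    3 * zero_na(el["N"])
}

atomic_masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                   P = 30.974, S = 32.06)

#' Molecular weight of a formula (g/mol)
#' @param formula chemical formula.
#' @return numeric molecular weight.
#' @export
molecular_weight <- function(formula) {
  el <- parse_chemical_formula(formula)
  known <- intersect(names(el), names(atomic_masses))
  if (length(known) < length(el)) {
    stop("formula contains elements without tabulated masses: ",
         paste(setdiff(names(el), known), collapse = ", "))
  }
  sum(el[known] * atomic_masses[known])
}

GLUCOSE_FORMULA <- "C6H12O6"

#' Energetic maximum yield of a product from glucose
#'
#' `Y^E` is the ratio of substrate to product degrees of reductance in
#' mol product per mol glucose; `Y^Ea` converts it to a mass yield via the
#' molecular weights.
#'
#' @param product_formula CHO formula of the product.
#' @return named numeric `c(YE=, YEa=)`.
#' @export
max_yield <- function(product_formula) {
  gp <- degree_of_reductance(product_formula)
  if (gp <= 0) stop("product has non-positive degree of reductance")
  ye <- degree_of_reductance(GLUCOSE_FORMULA) / gp
  c(YE = ye,
    YEa = ye * molecular_weight(product_formula) / molecular_weight(GLUCOSE_FORMULA))
}

#' Normalised pathway coefficients for the analytic yield framework
#'
#' Computes the coefficients a (NADPH demand), b (product), c (ATP
#' release), d (NADH release) and e (CO2 release) per carbon-mol of
#' glucose for a pathway running glucose -> product.  Respiro-fermentative
#' catabolism of one glucose to two acetyl-CoA contributes 2 ATP, 4 NADH
#' and 2 CO2 before the introduced reactions; the pathway sums are read
#' from the definition's reaction list.
#'
#' @param pd a `pathway_definition`.
#' @param glycolysis premise contributions per mol glucose.
#' @return a `pathway_coefficients` list with elements `a`, `b`, `c`, `d`,
#'   `e` (per C-mol glucose) and the product formula.
#' @export
pathway_coefficients <- function(pd, glycolysis = c(atp = 2, nadh = 4, co2 = 2)) {
  sums <- c(atp_c = 0, nadh_c = 0, nadph_c = 0, co2_c = 0)
  for (r in pd$reactions) {
    st <- parse_reaction_equation(r$equation)$stoichiometry
    for (m in names(sums)) sums[m] <- sums[m] + zero_na(st[m])
  }
  cn <- carbon_count(pd$target_formula)
  if (cn <= 0) stop("target formula lacks carbon")
  structure(list(
    a = -sums[["nadph_c"]] / 6,
    b = cn / 6,
    c = (glycolysis[["atp"]] + sums[["atp_c"]]) / 6,
    d = (glycolysis[["nadh"]] + sums[["nadh_c"]]) / 6,
    e = (glycolysis[["co2"]] + sums[["co2_c"]]) / 6,
    product_formula = pd$target_formula,
    pathway = pd$name
  ), class = "pathway_coefficients")
}

#' Pathway yield
#'
#' Relative pathway yield after accounting for substrate diverted to NADPH
#' supply (oxidative PPP, 2 NADPH per C-mol) and, when the net ATP balance
#' is negative, to respiratory ATP supply (4.82 ATP per C-mol).  Expressed
#' as a fraction of the energetic maximum, as in the source framework's
#' yield table.
#'
#' @param coeffs a `pathway_coefficients` object.
#' @return numeric `Y^P` in (0, 1].
#' @export
pathway_yield <- function(coeffs) {
  denom <- 1 + coeffs$a / 2 + if (coeffs$c < 0) -coeffs$c / 4.82 else 0
  if (denom <= 0) stop("non-positive yield denominator")
  1 / denom
}

#' Glycerol-adjusted pathway yield
#'
#' Surplus NADH is drained into a glycerol sink consuming 1/3 ATP and
#' 1/3 NADH per C-mol glycerol; the ATP consumed by the sink (and any
#' pre-existing ATP deficit) is supplied respiratorily at 4.82 ATP per
#' C-mol substrate.
#'
#' @param coeffs a `pathway_coefficients` object.
#' @return numeric `Y^P,G`, a fraction of the energetic maximum.
#' @export
glycerol_adjusted_yield <- function(coeffs) {
  d_pos <- max(coeffs$d, 0)
  atp_deficit <- max(d_pos - coeffs$c, 0)
  denom <- 1 + coeffs$a / 2 + 3 * d_pos + atp_deficit / 4.82
  if (denom <= 0) stop("non-positive yield denominator")
  1 / denom
}

#' Biomass-energetics parameters of the yield framework
#'
#' @param epsilon carbon fraction lost as CO2 during biomass synthesis
#'   (dimensionless, > 0.05 so that biomass formation releases NADH under
#'   the fixed biomass degree of reductance).
#' @param alpha ATP demand per C-mol biomass (mol ATP / C-mol).
#' @param kappa biomass degree of reductance (fixed at 4.2).
#' @param po_atp respiratory ATP equivalent per C-mol substrate (fixed at
#'   4.82).
#' @return a `dugar_parameters` list, including the derived NADH release
#'   `x = (4 (1 + epsilon) - kappa) / 2` per C-mol biomass.
#' @export
dugar_parameters <- function(epsilon, alpha, kappa = 4.2, po_atp = 4.82) {
  stopifnot(epsilon > 0, alpha > 0)
  x <- (4 * (1 + epsilon) - kappa) / 2
  if (x < 0) stop("epsilon too small: biomass synthesis would consume NADH")
  structure(list(epsilon = epsilon, alpha = alpha, kappa = kappa,
                 po_atp = po_atp, x = x), class = "dugar_parameters")
}

#' Biomass-adjusted pathway yield and efficiency
#'
#' Any ATP surplus remaining after the glycerol adjustment is diverted to
#' biomass formation.  Per C-mol of substrate entering the biomass branch,
#' `1/(1+epsilon)` C-mol biomass are formed, consuming
#' `alpha/(1+epsilon)` ATP and releasing `x/(1+epsilon)` NADH, which in
#' turn requires additional glycerol sink capacity.  The efficiency is
#' `eta = Y^P,G,X / Y^E`.
#'
#' @param coeffs a `pathway_coefficients` object.
#' @param params a [dugar_parameters()] object (`epsilon` and `alpha` are
#'   not printed in the source material and must be chosen by the user).
#' @param YE energetic maximum yield of the product.
#' @return named numeric `c(YPGX=, eta=)`.
#' @export
biomass_adjusted_yield <- function(coeffs, params, YE) {
  stopifnot(inherits(params, "dugar_parameters"))
  d_pos <- max(coeffs$d, 0)
  surplus <- max(coeffs$c - d_pos, 0)
  A <- params$alpha / (1 + params$epsilon)
  Xr <- params$x / (1 + params$epsilon)
  v5 <- if (surplus > 0) surplus / (A + Xr) else 0
  denom <- 1 + coeffs$a / 2 + 3 * d_pos + max(d_pos - coeffs$c, 0) / params$po_atp +
    v5 + 3 * Xr * v5
  ypgx <- 1 / denom
  c(YPGX = ypgx, eta = ypgx / YE)
}

#' Full analytic yield chain for one pathway
#'
#' @param pd a `pathway_definition`.
#' @param params optional [dugar_parameters()]; when `NULL` the
#'   biomass-adjusted stage is reported as `NA`.
#' @return one-row data frame with `pathway`, `YE`, `YEa`, `YP`, `YPG`,
#'   `YPGX`, `eta`.
#' @export
yield_chain <- function(pd, params = NULL) {
  co <- pathway_coefficients(pd)
  my <- max_yield(pd$target_formula)
  yp <- pathway_yield(co)
  ypg <- glycerol_adjusted_yield(co)
  if (!is.null(params)) {
    bx <- biomass_adjusted_yield(co, params, my[["YE"]])
    ypgx <- bx[["YPGX"]]; eta <- bx[["eta"]]
  } else {
    ypgx <- NA_real_; eta <- NA_real_
  }
  data.frame(pathway = pd$name, YE = my[["YE"]], YEa = my[["YEa"]],
             YP = yp, YPG = ypg, YPGX = ypgx, eta = eta,
             stringsAsFactors = FALSE)
}

#' Analytic yield table for all pathway definitions
#'
#' @param definitions list from [load_pathway_definitions()].
#' @param params optional [dugar_parameters()].
#' @return data frame with one row per pathway (the shape of the source
#'   framework's yield table).
#' @export
dugar_table <- function(definitions = load_pathway_definitions(),
                        params = NULL) {
  do.call(rbind, lapply(definitions, yield_chain, params = params))
}
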