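#' Toy network fixture with analytically known balance profile
#'
#' Builds a small (<= 15 reaction) artificial network with a
#' glycolysis-like catabolic reaction generating ATP and NADH, a target
#' pathway consuming both, a biomass drain, a maintenance reaction and a
#' planted phosphorylation/dephosphorylation futile pair, together with a
#' hand-set, mass-balanced flux vector whose category totals are known in
#' closed form.  Used throughout the test-suite as constructed ground
#' truth for the balance assessment and the cycle detector.
#'
#' @param cycle_flux flux through the planted PHOS/DEPHOS futile pair; the
#'   maintenance reaction absorbs correspondingly less ATP.
#' @return list with `network`, `fluxes` (named vector, mass-balanced),
#'   `expected` (per-co-factor category totals), `rules` (category rules
#'   matching the toy ids) and `candidates` (curation candidate table for
#'   the planted pair).
#' @export
toy_network_fixture <- function(cycle_flux = 0) {
  stopifnot(cycle_flux >= 0, cycle_flux <= 6)
  mets <- data.frame(
    id = c("sub_c", "prd0_c", "prd0p_c", "prd_c", "prd_e",
           "atp_c", "adp_c", "pi_c", "nadh_c", "nad_c"),
    name = c("substrate", "precursor", "phospho-precursor", "product",
             "product (external)", "ATP", "ADP", "phosphate", "NADH", "NAD"),
    formula = c("C6H12O6", "C3H4O3", "C3H5O6P", "C3H6O3", "C3H6O3",
                "", "", "", "", ""),
    compartment = c(rep("c", 4), "e", rep("c", 5)),
    stringsAsFactors = FALSE)
  eq <- c(
    SRC    = "-> sub_c",
    CAT    = "sub_c + 2 adp_c + 2 pi_c + 2 nad_c -> prd0_c + 2 atp_c + 2 nadh_c",
    TGT    = "prd0_c + atp_c + nadh_c -> prd_c + adp_c + pi_c + nad_c",
    TGTt   = "prd_c -> prd_e",
    PRD_sink = "prd_e ->",
    BIO    = "prd0_c + 3 atp_c + nadh_c -> 3 adp_c + 3 pi_c + nad_c",
    ATPM   = "atp_c -> adp_c + pi_c",
    OXI    = "nadh_c -> nad_c",
    PHOS   = "prd0_c + atp_c -> prd0p_c + adp_c",
    DEPHOS = "prd0p_c -> prd0_c + pi_c")
  rxns <- data.frame(id = names(eq), name = names(eq),
                     lower_bound = 0, upper_bound = 1000,
                     objective = names(eq) == "PRD_sink",
                     stringsAsFactors = FALSE)
  rxns$upper_bound[rxns$id == "SRC"] <- 10
  st <- lapply(eq, function(e) parse_reaction_equation(e)$stoichiometry)
  net <- metabolic_network(mets, rxns, st,
                           annotation = list(model = "toy", variant = "toy",
                                             pathway_reactions = c("TGT", "TGTt", "PRD_sink"),
                                             target_metabolite = "prd_e",
                                             target_formula = "C3H6O3"))
  fx <- c(SRC = 10, CAT = 10, TGT = 8, TGTt = 8, PRD_sink = 8, BIO = 2,
          ATPM = 6 - cycle_flux, OXI = 10,
          PHOS = cycle_flux, DEPHOS = cycle_flux)
  rules <- structure(list(biomass = "BIO", atp_burn = "ATPM",
                          atp_overflow = character(0),
                          nadph_co2 = character(0),
                          nadph_fermentation = character(0),
                          ppp = character(0)),
                     class = "category_rules")
  expected <- list(
    ATP = list(production = 20, biomass = -6, target = -8,
               waste = -(6 - cycle_flux), maintenance = -cycle_flux),
    `NAD(P)H` = list(production = 20, biomass = -2, target = -8,
                     waste = 0, maintenance = -10))
  candidates <- data.frame(cap = "DEPHOS", partner = "PHOS",
                           cofactor = "ATP", note = "planted pair",
                           stringsAsFactors = FALSE)
  list(network = net, fluxes = fx, expected = expected, rules = rules,
       candidates = candidates)
}

#' Synthetic knockout flux dataset in the 13C-MFA table shape
#'
#' Emits a reaction-by-strain matrix shaped like the published
#' knockout-panel flux table: two wild-type replicate columns, one column
#' per knockout strain, an isozyme family (pfkA/pfkB) that the formatter
#' must average into the single PFK reaction, a glucose-uptake row for
#' normalisation, and designated "plastic" rows (wide spread across
#' strains) and "rigid" rows (spread about `rigid_width`).
#'
#' @param seed integer seed; the same seed yields an identical dataset.
#' @param n_knockouts number of knockout strain columns (default 6).
#' @param rigid_width flux spread of the rigid reactions (default 1.3).
#' @param plastic_width flux spread of the plastic reactions (default 8).
#' @return list with `dataset` (a raw `flux_dataset`), `mapping` (dataset
#'   row -> model reaction id table) and the `plastic`/`rigid` id sets.
#' @export
simulate_flux_dataset <- function(seed = 1, n_knockouts = 6,
                                  rigid_width = 1.3, plastic_width = 8) {
  set.seed(seed)
  plastic <- c("PFK", "GAPD", "PGK", "PYK", "PGI")
  rigid <- c("ME1", "ME2", "PPCK", "PPC", "MDH")
  other <- c("PDH", "CS", "ICDHyr", "AKGDH", "FUM")
  base <- c(PFK = 7.5, GAPD = 16, PGK = -16, PYK = 2, PGI = 8,
            ME1 = 0.6, ME2 = 0.6, PPCK = 0.6, PPC = 2.5, MDH = 5,
            PDH = 9, CS = 6, ICDHyr = 6, AKGDH = 4.5, FUM = 4.5)
  width <- c(stats::setNames(rep(plastic_width, length(plastic)), plastic),
             stats::setNames(rep(rigid_width, length(rigid)), rigid),
             stats::setNames(rep(3, length(other)), other))
  strains <- paste0("ko", seq_len(n_knockouts))
  model_rows <- names(base)
  mat <- sapply(c("WT_1", "WT_2", strains), function(s) {
    wob <- if (grepl("^WT", s)) 0.02 else 1
    base + wob * width[model_rows] * stats::runif(length(base), -0.5, 0.5)
  })
  rownames(mat) <- model_rows
  # expand PFK into the pfkA/pfkB isozyme family (values average to PFK)
  delta <- stats::runif(ncol(mat), 0, 2)
  pfkA <- mat["PFK", ] + delta
  pfkB <- mat["PFK", ] - delta
  mat <- rbind(mat[setdiff(model_rows, "PFK"), , drop = FALSE],
               pfkA = pfkA, pfkB = pfkB)
  # glucose uptake varies per culture; measured fluxes scale with it
  glc <- 10 * stats::runif(ncol(mat), 0.8, 1.2)
  mat <- sweep(mat, 2, glc / 10, `*`)
  mat <- rbind(mat, GLC_uptake = glc)
  mapping <- data.frame(
    dataset = c(setdiff(model_rows, "PFK"), "pfkA", "pfkB", "GLC_uptake"),
    model = c(setdiff(model_rows, "PFK"), "PFK", "PFK", "GLC_uptake"),
    sign = 1, stringsAsFactors = FALSE)
  mapping$sign[mapping$dataset == "PGK"] <- -1  # measured in the phosphorylating direction
  list(dataset = flux_dataset(mat, glucose_row = "GLC_uptake"),
       mapping = mapping, plastic = plastic, rigid = rigid)
}
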