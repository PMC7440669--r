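#' Co-factor specifications
#'
#' A co-factor specification names the pool metabolites whose stoichiometric
#' coefficients define the co-factor flux score of a reaction.  By default
#' NADH and NADPH are pooled into a single NAD(P)H score, reflecting the
#' assumption that the two carriers are interchangeable for balance
#' accounting; `pooled = FALSE` tracks them separately.
#'
#' @param pooled pool NADH and NADPH into one score (default TRUE).
#' @return named list of `cofactor_spec` objects.
#' @export
cofactor_specs <- function(pooled = TRUE) {
  mk <- function(name, members) {
    structure(list(name = name, members = members), class = "cofactor_spec")
  }
  if (pooled) {
    list(ATP = mk("ATP", "atp_c"),
         `NAD(P)H` = mk("NAD(P)H", c("nadh_c", "nadph_c")))
  } else {
    list(ATP = mk("ATP", "atp_c"),
         NADH = mk("NADH", "nadh_c"),
         NADPH = mk("NADPH", "nadph_c"))
  }
}

#' Co-factor flux score of one reaction
#'
#' The score is the summed stoichiometric coefficient of the co-factor's
#' member metabolites in the reaction multiplied by the reaction flux:
#' positive scores are co-factor production, negative scores consumption.
#'
#' @param net a `metabolic_network`.
#' @param reaction reaction id.
#' @param flux flux value in mmol gDW^-1 hr^-1.
#' @param cofactor a `cofactor_spec`.
#' @return numeric score.
#' @export
cofactor_flux_score <- function(net, reaction, flux, cofactor) {
  st <- reaction_stoichiometry(net, reaction)
  coef <- sum(st[names(st) %in% cofactor$members])
  coef * flux
}

#' Co-factor flux scores for all reactions
#' @param net a `metabolic_network`.
#' @param fluxes a `flux_distribution` or named flux vector.
#' @param cofactor a `cofactor_spec`.
#' @return named numeric vector of scores.
#' @export
cofactor_scores <- function(net, fluxes, cofactor) {
  v <- if (inherits(fluxes, "flux_distribution")) fluxes$fluxes else fluxes
  present <- intersect(cofactor$members, net$mets$id)
  if (length(present) == 0) return(stats::setNames(numeric(n_reactions(net)), net$rxns$id))
  coef <- Matrix::colSums(net$S[present, , drop = FALSE])
  stats::setNames(as.numeric(coef) * as.numeric(v[net$rxns$id]), net$rxns$id)
}

#' Category rules for the co-factor balance assessment
#'
#' Loads the reaction-id lists that drive category assignment: the biomass
#' reaction, the ATP-hydrolysing and acetate-overflow waste rules, the
#' CO2-coupled NAD(P)H producers and the fermentative NAD(P)H consumers.
#' Target reactions are supplied per network from its pathway annotation.
#'
#' @param path YAML rule file; defaults to the copy shipped with the
#'   package, which reproduces the published category membership.
#' @return a `category_rules` object.
#' @export
category_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cba_categories.yml", package = "cobaflux")
  }
  cfg <- yaml::read_yaml(path)
  structure(list(
    biomass = unlist(cfg$biomass),
    atp_burn = unlist(cfg$atp$burn),
    atp_overflow = unlist(cfg$atp$overflow),
    nadph_co2 = unlist(cfg$nadph_pool$co2_coupled),
    nadph_fermentation = unlist(cfg$nadph_pool$fermentation),
    ppp = unlist(cfg$ppp_dehydrogenases)
  ), class = "category_rules")
}

#' Classify one reaction's co-factor score into a balance category
#'
#' Deterministic assignment: target pathway reactions always map to
#' `target`; the biomass reaction to `biomass`; the waste rules capture
#' ATP-hydrolysing reactions (negative ATP score), acetate-coupled ATP
#' production (positive ATP score), CO2-coupled NAD(P)H production
#' (positive score) and fermentative NAD(P)H consumption (negative score).
#' Every other producer is `production` and every other consumer
#' `maintenance`.
#'
#' @param reaction reaction id.
#' @param cofactor a `cofactor_spec`.
#' @param score the reaction's co-factor flux score.
#' @param rules a `category_rules` object.
#' @param target_reactions ids of the variant's introduced reactions.
#' @return one of `"target"`, `"biomass"`, `"waste"`, `"production"`,
#'   `"maintenance"`, or `"none"` for a zero score.
#' @export
classify_reaction <- function(reaction, cofactor, score, rules,
                              target_reactions = character(0)) {
  if (abs(score) < 1e-12) return("none")
  if (reaction %in% target_reactions) return("target")
  if (reaction %in% rules$biomass) return("biomass")
  if (cofactor$name == "ATP") {
    if (reaction %in% rules$atp_burn && score < 0) return("waste")
    if (reaction %in% rules$atp_overflow && score > 0) return("waste")
  } else {
    if (reaction %in% rules$nadph_co2 && score > 0) return("waste")
    if (reaction %in% rules$nadph_fermentation && score < 0) return("waste")
  }
  if (score > 0) "production" else "maintenance"
}

#' Assemble a co-factor balance profile
#'
#' For each co-factor, computes the total production (sum of positive
#' scores over non-target reactions) and the net biomass, target, waste and
#' maintenance category totals of a mass-balanced flux distribution.
#' Because every co-factor metabolite is internal, the signed scores sum to
#' zero in any steady-state solution (`closure`).
#'
#' @param net a `metabolic_network`.
#' @param fluxes a `flux_distribution` or named flux vector.
#' @param rules a `category_rules` object (default package rules).
#' @param cofactors list from [cofactor_specs()].
#' @return a `cofactor_profile`: list with per-co-factor `totals`
#'   (production and net category values), `fractions` (category /
#'   production), per-reaction `scores` table and `closure` residuals.
#' @export
assemble_profile <- function(net, fluxes, rules = category_rules(),
                             cofactors = cofactor_specs()) {
  target <- net$annotation$pathway_reactions %||% character(0)
  known <- c(rules$biomass, rules$atp_burn, rules$atp_overflow,
             rules$nadph_co2, rules$nadph_fermentation)
  unknown <- setdiff(known, net$rxns$id)
  if (length(unknown) > 0) {
    warning("category rules reference absent reaction(s), skipped: ",
            paste(unknown, collapse = ", "))
  }
  res <- list(); scores_tab <- list(); closure <- numeric(0)
  for (cf in cofactors) {
    sc <- cofactor_scores(net, fluxes, cf)
    cat_of <- vapply(names(sc), function(r) {
      classify_reaction(r, cf, sc[[r]], rules, target)
    }, character(1))
    production <- sum(sc[sc > 0 & cat_of != "target"])
    nets <- vapply(c("biomass", "target", "waste", "maintenance"),
                   function(k) sum(sc[cat_of == k]), numeric(1))
    fr <- if (production > 1e-12) nets / production else nets * NA_real_
    res[[cf$name]] <- list(production = production,
                           biomass = nets[["biomass"]],
                           target = nets[["target"]],
                           waste = nets[["waste"]],
                           maintenance = nets[["maintenance"]],
                           fractions = fr)
    closure[cf$name] <- sum(sc)
    keep <- abs(sc) > 1e-12
    if (any(keep)) {
      scores_tab[[cf$name]] <- data.frame(
        cofactor = cf$name, reaction = names(sc)[keep],
        score = unname(sc[keep]), category = unname(cat_of[keep]),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(variant = net$annotation$variant %||% NA_character_,
                 condition = net$annotation$condition %||% NA_character_,
                 totals = res,
                 scores = do.call(rbind, c(scores_tab, list(make.row.names = FALSE))),
                 closure = closure),
            class = "cofactor_profile")
}

#' @export
print.cofactor_profile <- function(x, ...) {
  cat(sprintf("cofactor_profile '%s'/%s\n", x$variant, x$condition))
  for (cf in names(x$totals)) {
    t <- x$totals[[cf]]
    cat(sprintf("  %-8s production %8.3f | biomass %8.3f target %8.3f waste %8.3f maintenance %8.3f\n",
                cf, t$production, t$biomass, t$target, t$waste, t$maintenance))
  }
  invisible(x)
}

#' Co-factor closure residuals of a profile
#' @param profile a `cofactor_profile`.
#' @return named numeric vector: signed sum of all scores per co-factor
#'   (zero for any mass-balanced solution).
#' @export
cba_closure <- function(profile) profile$closure

#' Waste fraction of ATP production through hydrolysis reactions
#'
#' Fraction of the total positive ATP flux scores consumed by the
#' ATP-hydrolysing maintenance/recycling reactions (`ATPM`, `ADK1`).
#'
#' @param net a `metabolic_network`.
#' @param fluxes a `flux_distribution` or named flux vector.
#' @param burn reaction ids counted as hydrolysis (default `ATPM`, `ADK1`).
#' @return percentage of total ATP production.
#' @export
atp_burn_fraction <- function(net, fluxes, burn = c("ATPM", "ADK1")) {
  sc <- cofactor_scores(net, fluxes, cofactor_specs()$ATP)
  prod <- sum(sc[sc > 0])
  if (prod < 1e-12) stop("no ATP production in solution")
  burned <- -sum(pmin(sc[intersect(burn, names(sc))], 0))
  100 * burned / prod
}

#' Pentose-phosphate share of NAD(P)H production
#'
#' Positive pooled NAD(P)H flux scores of the oxidative PPP dehydrogenases
#' divided by the total positive NAD(P)H scores of the solution.
#'
#' @param net a `metabolic_network`.
#' @param fluxes a `flux_distribution` or named flux vector.
#' @param rules a `category_rules` (supplies the dehydrogenase ids).
#' @return percentage of total NAD(P)H production.
#' @export
ppp_nadph_share <- function(net, fluxes, rules = category_rules()) {
  sc <- cofactor_scores(net, fluxes, cofactor_specs()$`NAD(P)H`)
  prod <- sum(sc[sc > 0])
  if (prod < 1e-12) stop("no NAD(P)H production in solution")
  ppp <- sum(pmax(sc[intersect(rules$ppp, names(sc))], 0))
  100 * ppp / prod
}

#' Carbon yield of the target product
#'
#' `100 * (carbon atoms of target) * (sink flux) / (6 * |glucose uptake|)`.
#'
#' @param net a `metabolic_network` with target annotation (or explicit
#'   arguments).
#' @param fluxes a `flux_distribution` or named flux vector.
#' @param sink_reaction target sink id; defaults to the network objective.
#' @param target_formula formula of the target; defaults to the annotation.
#' @param glucose_exchange id of the glucose exchange reaction.
#' @return percentage of glucose carbon influx recovered in the target.
#' @export
carbon_yield <- function(net, fluxes, sink_reaction = NULL,
                         target_formula = NULL,
                         glucose_exchange = "EX_glc__D_e") {
  v <- if (inherits(fluxes, "flux_distribution")) fluxes$fluxes else fluxes
  if (is.null(sink_reaction)) sink_reaction <- objective_id(net)
  if (is.null(target_formula)) target_formula <- net$annotation$target_formula
  if (is.null(target_formula)) stop("target formula unknown")
  uptake <- abs(v[[glucose_exchange]])
  if (uptake < 1e-9) stop("glucose uptake flux is zero; carbon yield undefined")
  100 * carbon_count(target_formula) * v[[sink_reaction]] / (6 * uptake)
}

#' Export a co-factor profile as a tab-separated table
#' @param profile a `cofactor_profile`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_profile_table <- function(profile, file) {
  rows <- do.call(rbind, lapply(names(profile$totals), function(cf) {
    t <- profile$totals[[cf]]
    data.frame(cofactor = cf,
               category = c("production", "biomass", "target", "waste", "maintenance"),
               net_flux = c(t$production, t$biomass, t$target, t$waste, t$maintenance),
               fraction = c(1, t$fractions),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
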