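test_that("co-factor flux scores follow stoichiometry times flux", {
  net <- core_model()
  atp <- cofactor_specs()$ATP
  # ATPM consumes one ATP per unit flux
  expect_equal(cofactor_flux_score(net, "ATPM", 7.6, atp), -7.6)
  expect_equal(cofactor_flux_score(net, "ATPM", -7.6, atp), 7.6)
  # a reaction without pool members scores zero
  expect_equal(cofactor_flux_score(net, "ENO", 12, atp), 0)
  # linearity
  expect_equal(cofactor_flux_score(net, "PGK", 3, atp),
               3 * cofactor_flux_score(net, "PGK", 1, atp))
})

test_that("category assignment follows the published rules", {
  rules <- category_rules()
  nadph <- cofactor_specs()$`NAD(P)H`
  atp <- cofactor_specs()$ATP
  expect_identical(classify_reaction("PDH", nadph, 5, rules), "waste")
  expect_identical(classify_reaction("GND", nadph, 2, rules), "waste")
  expect_identical(classify_reaction("ADK1", atp, -3, rules), "waste")
  expect_identical(classify_reaction("ATPM", atp, -7.6, rules), "waste")
  expect_identical(classify_reaction("Biomass_Ecoli_core", atp, -10, rules), "biomass")
  expect_identical(classify_reaction("CAR", atp, -9, rules,
                                     target_reactions = "CAR"), "target")
  expect_identical(classify_reaction("GAPD", nadph, 16, rules), "production")
  expect_identical(classify_reaction("HEXX", atp, -1, rules), "maintenance")
})

test_that("toy fixture profile equals the hand-computed category totals", {
  for (cyc in c(0, 4)) {
    fix <- toy_network_fixture(cycle_flux = cyc)
    expect_lt(mass_balance_residual(fix$network, fix$fluxes), 1e-12)
    prof <- assemble_profile(fix$network, fix$fluxes, rules = fix$rules)
    for (cf in names(fix$expected)) {
      exp <- fix$expected[[cf]]
      got <- prof$totals[[cf]]
      for (k in names(exp)) {
        expect_equal(got[[k]], exp[[k]], tolerance = 1e-12,
                     label = sprintf("%s %s (cycle %g)", cf, k, cyc))
      }
    }
    expect_true(all(abs(cba_closure(prof)) < 1e-9))
  }
})

test_that("co-factor closure holds on optimised solutions of all variants", {
  for (v in c("WT", variant_names())) {
    prof <- assemble_profile(variant_model(v), variant_pfba(v))
    expect_true(all(abs(cba_closure(prof)) < 1e-6), info = v)
  }
})

test_that("profiles scale linearly with a uniform flux rescaling", {
  fix <- toy_network_fixture()
  p1 <- assemble_profile(fix$network, fix$fluxes, rules = fix$rules)
  p2 <- assemble_profile(fix$network, fix$fluxes * 0.5, rules = fix$rules)
  expect_equal(p2$totals$ATP$production, 0.5 * p1$totals$ATP$production)
  expect_equal(p2$totals$ATP$waste, 0.5 * p1$totals$ATP$waste)
})

test_that("carbon yield arithmetic matches the four-carbon/six-carbon ratio", {
  net <- variant_model("BuOH-0")
  v <- variant_pfba("BuOH-0")$fluxes
  mock <- v; mock[["BTOH_sink"]] <- 10; mock[["EX_glc__D_e"]] <- -10
  expect_equal(carbon_yield(net, mock), 400 / 6, tolerance = 1e-9)
  mock[["BTOH_sink"]] <- 5
  expect_equal(carbon_yield(net, mock), 200 / 6, tolerance = 1e-9)
  mock[["BTOH_sink"]] <- 0
  expect_equal(carbon_yield(net, mock), 0)
  mock[["EX_glc__D_e"]] <- 0
  expect_error(carbon_yield(net, mock), "uptake flux is zero")
})

test_that("split accounting exposes the NADPH pool separately", {
  specs <- cofactor_specs(pooled = FALSE)
  expect_setequal(names(specs), c("ATP", "NADH", "NADPH"))
  net <- variant_model("tpcBuOH")
  sol <- variant_pfba("tpcBuOH")
  sc <- cofactor_scores(net, sol, specs$NADPH)
  expect_lt(sc[["CAR"]], 0)  # the reductase consumes NADPH
})
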