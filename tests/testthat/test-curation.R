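test_that("maintenance capping is bounded, idempotent and can switch off", {
  net <- variant_model("BuOH-1")
  capped <- cap_atpm(net)
  expect_equal(unname(reaction_bounds(capped, "ATPM")), c(7.6, 7.6))
  expect_equal(reaction_bounds(cap_atpm(capped), "ATPM"),
               reaction_bounds(capped, "ATPM"))
  off <- cap_atpm(net, 0)
  expect_equal(unname(reaction_bounds(off, "ATPM")), c(0, 0))
})

test_that("a distribution compared with itself shows no cycles", {
  wt <- wt_reference()
  expect_equal(nrow(detect_futile_cycles(wt, wt)), 0)
})

test_that("a planted phosphorylation cycle is detected exactly once", {
  fix <- toy_network_fixture(cycle_flux = 5)
  ref <- toy_network_fixture(cycle_flux = 0)
  cyc <- detect_futile_cycles(fix$fluxes, ref$fluxes, fix$candidates)
  expect_equal(nrow(cyc), 1)
  expect_identical(cyc$cap, "DEPHOS")
  expect_identical(cyc$partner, "PHOS")
  # below the high-flux threshold nothing is reported
  quiet <- toy_network_fixture(cycle_flux = 0.5)
  expect_equal(nrow(detect_futile_cycles(quiet$fluxes, ref$fluxes,
                                         fix$candidates)), 0)
})

test_that("curation converges, caps only shrink yield, and the final scan is empty", {
  wt <- wt_reference()
  for (v in c("BuOH-0", "BuOH-1", "CROT")) {
    net <- variant_model(v)
    uncurated_yield <- carbon_yield(net, variant_pfba(v))
    res <- curate_model(net, wt)
    expect_true(res$converged, info = v)
    expect_lte(carbon_yield(res$network, res$solution), uncurated_yield + 1e-6)
    expect_equal(nrow(detect_futile_cycles(res$solution, wt)), 0, info = v)
    # every applied cap equals the wild-type flux magnitude
    applied <- res$log[res$log$status == "applied", ]
    wt_mag <- vapply(applied$reaction, function(r) {
      x <- wt$fluxes[r]
      if (length(x) == 0 || is.na(x)) 0 else abs(unname(x))
    }, numeric(1))
    expect_equal(applied$new_bound, unname(wt_mag), tolerance = 1e-9)
  }
})

test_that("curating the wild type against itself changes nothing", {
  wt <- wt_reference()
  res <- curate_model(variant_model("WT"), wt, atpm_limit = NULL)
  expect_equal(nrow(res$log), 0)
  expect_true(res$converged)
  expect_equal(res$solution$objective_value, wt$objective_value, tolerance = 1e-8)
})

test_that("curated aerobic butanol models divert surplus energy to biomass", {
  wt <- wt_reference()
  res <- curate_model(variant_model("BuOH-1"), wt)
  expect_gt(res$solution$fluxes[["Biomass_Ecoli_core"]], 1e-6)
  expect_gt(res$solution$fluxes[["BTOH_sink"]], 1e-6)
  y <- carbon_yield(res$network, res$solution)
  expect_gt(y, 60); expect_lt(y, 66.67)
})

test_that("curated anaerobic CAR-route models balance by fermentation alone", {
  wt <- wt_reference("anaerobic")
  for (v in c("tpcBuOH", "BuOH-2", "fasBuOH")) {
    res <- curate_model(variant_model(v, "anaerobic"), wt)
    expect_true(res$converged, info = v)
    expect_lt(abs(res$solution$fluxes[["Biomass_Ecoli_core"]]), 1e-6)
    expect_gt(res$solution$fluxes[["BTOH_sink"]], 1e-6)
  }
})
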