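test_that("wild-type FBA grows aerobically and starves without glucose", {
  sol <- optimize_fba(variant_model("WT"))
  expect_gt(sol$objective_value, 0)
  starved <- set_bounds(variant_model("WT"), "EX_glc__D_e", lower = 0)
  # maintenance demand cannot be met without carbon
  expect_error(optimize_fba(starved), "infeasible")
  relaxed <- set_bounds(cap_atpm(starved, 0), "ATPM", lower = 0)
  expect_lt(optimize_fba(relaxed)$objective_value, 1e-9)
})

test_that("pFBA preserves the FBA optimum and minimises total flux", {
  for (v in c("WT", "BuOH-0", "tpcBuOH")) {
    fba <- optimize_fba(variant_model(v))
    pf <- variant_pfba(v)
    expect_equal(pf$objective_value, fba$objective_value, tolerance = 1e-8, info = v)
    expect_lte(pf$total_flux, sum(abs(fba$fluxes)) + 1e-6)
    expect_equal(pf$total_flux, sum(abs(pf$fluxes)), tolerance = 1e-6)
  }
})

test_that("pFBA is reproducible to solver precision", {
  a <- optimize_pfba(variant_model("BuOH-1"))
  b <- optimize_pfba(variant_model("BuOH-1"))
  expect_equal(a$objective_value, b$objective_value, tolerance = 1e-9)
  expect_equal(a$total_flux, b$total_flux, tolerance = 1e-9)
})

test_that("every returned distribution is mass balanced within 1e-6", {
  for (v in c("WT", "BuOH-0", "BuOH-1", "fasBuOH")) {
    expect_lt(mass_balance_residual(variant_model(v), variant_pfba(v)), 1e-6)
  }
  ana <- optimize_pfba(variant_model("BuOH-2", "anaerobic"))
  expect_lt(mass_balance_residual(variant_model("BuOH-2", "anaerobic"), ana), 1e-6)
})

test_that("fluxes respect reaction bounds", {
  net <- variant_model("BuOH-1")
  v <- variant_pfba("BuOH-1")$fluxes[net$rxns$id]
  expect_true(all(v >= net$rxns$lower_bound - 1e-6))
  expect_true(all(v <= net$rxns$upper_bound + 1e-6))
})

test_that("butanol production cannot exceed the electron-balance ceiling", {
  # independent oracle: available electrons bound the product flux;
  # glucose gives 24 electrons/mol at uptake 10, butanol carries 24
  electrons_in <- 10 * degree_of_reductance("C6H12O6")
  ceiling <- electrons_in / degree_of_reductance("C4H10O")
  sol <- variant_pfba("BuOH-0")
  expect_lte(sol$objective_value, ceiling + 1e-6)
  # the ATP-neutral redox-balanced route attains it
  expect_equal(sol$objective_value, ceiling, tolerance = 1e-6)
})

test_that("FVA ranges contain the pFBA flux and widen as the fraction drops", {
  net <- variant_model("BuOH-1")
  sub <- c("ATPM", "PFK", "FBP", "PDH", "GND", "BTOH_sink")
  r100 <- flux_variability(net, 1.0, reactions = sub)
  r95 <- flux_variability(net, 0.95, reactions = sub)
  pf <- variant_pfba("BuOH-1")$fluxes[sub]
  expect_true(all(r100$min - 1e-6 <= pf & pf <= r100$max + 1e-6))
  expect_true(all(r95$min <= r100$min + 1e-6))
  expect_true(all(r95$max >= r100$max - 1e-6))
  expect_error(flux_variability(net, 0), "fraction_of_optimum > 0")
})

test_that("loopless mode without a backend falls back to pFBA with a warning", {
  expect_warning(fd <- loopless_mode(variant_model("WT")), "no loopless backend")
  expect_equal(fd$objective_value, variant_pfba("WT")$objective_value,
               tolerance = 1e-8)
})
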