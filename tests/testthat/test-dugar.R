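test_that("degree of reductance and maximum yields match closed form", {
  expect_equal(degree_of_reductance("C6H12O6"), 24)
  expect_equal(degree_of_reductance("C4H10O"), 24)    # butanol
  expect_equal(degree_of_reductance("C4H6O2"), 18)    # crotonic acid
  expect_equal(degree_of_reductance("C4H8O2"), 20)    # butyric acid
  expect_equal(degree_of_reductance("C4H8O"), 22)     # butyraldehyde
  # published yield table, columns YE / YEa, to three decimals
  expect_equal(unname(max_yield("C4H10O")), c(1.000, 0.411), tolerance = 2e-3)
  expect_equal(unname(max_yield("C4H6O2")), c(1.333, 0.637), tolerance = 2e-3)
  expect_equal(unname(max_yield("C4H8O2")), c(1.200, 0.587), tolerance = 2e-3)
  expect_equal(unname(max_yield("C4H8O")), c(1.091, 0.437), tolerance = 2e-3)
  expect_equal(unname(max_yield("C6H12O6")), c(1, 1), tolerance = 1e-12)
  expect_error(max_yield("CO2"), "non-positive degree of reductance")
})

test_that("normalised pathway coefficients follow the glycolytic premise", {
  defs <- pathway_defs()
  # oracle: book-keeping per C-mol glucose -- glycolysis to 2 acetyl-CoA
  # gives +2 ATP, +4 NADH, +2 CO2; the pathway sums add on top
  co <- pathway_coefficients(defs[["BuOH-0"]])
  expect_equal(co$a, 0)
  expect_equal(co$b, 4 / 6)
  expect_equal(co$c, 2 / 6)
  expect_equal(co$d, 0)
  expect_equal(co$e, 2 / 6)
  co1 <- pathway_coefficients(defs[["tpcBuOH"]])
  expect_equal(co1$a, 1 / 6)   # one NADPH at the acid reductase
  expect_equal(co1$c, 1 / 6)
  co2 <- pathway_coefficients(defs[["fasBuOH"]])
  expect_equal(co2$a, 2 / 6)   # FAS reduction plus acid reductase
  expect_equal(co2$c, 0)
})

test_that("pathway yields reproduce the published table column", {
  defs <- pathway_defs()
  yp <- vapply(defs, function(d) pathway_yield(pathway_coefficients(d)),
               numeric(1))
  expect_equal(unname(yp[c("BuOH-0", "BuOH-1")]), c(1, 1), tolerance = 5e-4)
  expect_equal(unname(yp[["tpcBuOH"]]), 0.923, tolerance = 5e-4)
  expect_equal(unname(yp[["BuOH-2"]]), 0.923, tolerance = 5e-4)
  expect_equal(unname(yp[["fasBuOH"]]), 0.857, tolerance = 5e-4)
  expect_equal(unname(yp[c("CROT", "BUTYR", "BUTAL")]), c(1, 1, 1),
               tolerance = 5e-4)
})

test_that("glycerol-adjusted yields for the NADH-surplus precursor routes", {
  defs <- pathway_defs()
  ypg <- vapply(defs, function(d) glycerol_adjusted_yield(pathway_coefficients(d)),
                numeric(1))
  # routes without NADH surplus are unchanged
  expect_equal(unname(ypg[c("BuOH-0", "BuOH-1")]), c(1, 1), tolerance = 5e-4)
  # electron-sink penalty for the precursor routes
  expect_equal(unname(ypg[["BUTAL"]]), 0.667, tolerance = 5e-4)
  expect_equal(unname(ypg[["BUTYR"]]), 0.500, tolerance = 5e-4)
  expect_equal(unname(ypg[["CROT"]]), 0.395, tolerance = 2e-3)
})

test_that("the yield chain is monotone for every pathway", {
  params <- dugar_parameters(epsilon = 0.3, alpha = 2.3)
  tab <- dugar_table(pathway_defs(), params)
  expect_true(all(tab$YP <= 1 + 1e-12))
  expect_true(all(tab$YPG <= tab$YP + 1e-12))
  expect_true(all(tab$YPGX <= tab$YPG + 1e-12))
  expect_true(all(tab$eta >= 0 & tab$eta <= 1))
  expect_equal(tab$eta, tab$YPGX / tab$YE, tolerance = 1e-12)
})

test_that("smaller ATP excess is penalised less in the biomass stage", {
  params <- dugar_parameters(epsilon = 0.3, alpha = 2.3)
  tab <- dugar_table(pathway_defs(), params)
  # the malonyl-CoA-primed butanol route retains a higher efficiency than
  # the ATP-neutral route, and ranks first among the butanol producers
  butanol <- c("BuOH-0", "BuOH-1", "tpcBuOH", "BuOH-2", "fasBuOH")
  expect_gt(tab["BuOH-1", "eta"], tab["BuOH-0", "eta"])
  expect_identical(butanol[which.max(tab[butanol, "eta"])], "BuOH-1")
})

test_that("the biomass diversion is monotone in the energetics parameter", {
  defs <- pathway_defs()
  co <- pathway_coefficients(defs[["BuOH-0"]])
  ye <- max_yield("C4H10O")[["YE"]]
  # direct evaluation over an epsilon grid: larger epsilon means more
  # substrate burned per unit biomass, hence lower adjusted yield
  grid <- seq(0.1, 0.6, by = 0.05)
  vals <- vapply(grid, function(e) {
    biomass_adjusted_yield(co, dugar_parameters(e, alpha = 2.3), ye)[["YPGX"]]
  }, numeric(1))
  expect_true(all(diff(vals) < 1e-12))
  # zero ATP excess leaves the glycerol stage untouched
  co0 <- co; co0$c <- 0
  bx <- biomass_adjusted_yield(co0, dugar_parameters(0.3, 2.3), ye)
  expect_equal(bx[["YPGX"]], glycerol_adjusted_yield(co0), tolerance = 1e-12)
})
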