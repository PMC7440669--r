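test_that("formatting averages isozyme families and wild-type replicates", {
  raw <- flux_dataset(rbind(pfkA = c(WT_1 = 5, WT_2 = 5, ko1 = 5),
                            pfkB = c(1, 1, 1),
                            GLC_uptake = c(10, 10, 10)),
                      glucose_row = "GLC_uptake")
  mapping <- data.frame(dataset = c("pfkA", "pfkB"), model = "PFK", sign = 1)
  ds <- format_flux_dataset(raw, core_model(), mapping)
  expect_true(ds$formatted)
  expect_equal(unname(ds$values["PFK", ]), c(3, 3))
  expect_identical(colnames(ds$values), c("WT", "ko1"))
})

test_that("the reference-shaped synthetic dataset keeps 15 reactions", {
  sim <- simulate_flux_dataset(seed = 7)
  ds <- format_flux_dataset(sim$dataset, core_model(), sim$mapping)
  rg <- extract_ranges(ds)
  expect_equal(nrow(rg), 15)
  # formatting is idempotent
  expect_identical(format_flux_dataset(ds, core_model(), sim$mapping), ds)
  # normalisation: glucose row equals the model uptake in every column
  expect_true(all(abs(abs(ds$values["GLC_uptake", ]) - 10) < 1e-9))
  # same seed regenerates the identical dataset
  sim2 <- simulate_flux_dataset(seed = 7)
  expect_identical(sim$dataset$values, sim2$dataset$values)
})

test_that("ranges are min/max across strains; rigid rows stay narrow", {
  ds <- flux_dataset(rbind(PGI = c(WT_1 = 3, ko1 = 5, ko2 = 4),
                           PYK = c(2, 2, 2),
                           GLC_uptake = c(10, 10, 10)),
                     glucose_row = "GLC_uptake", formatted = TRUE)
  rg <- extract_ranges(ds)
  expect_equal(rg$min[rg$reaction == "PGI"], 3)
  expect_equal(rg$max[rg$reaction == "PGI"], 5)
  expect_equal(rg$max[rg$reaction == "PYK"] - rg$min[rg$reaction == "PYK"], 0)
  sim <- simulate_flux_dataset(seed = 3, rigid_width = 1.3)
  fds <- format_flux_dataset(sim$dataset, core_model(), sim$mapping)
  frg <- extract_ranges(fds)
  widths <- frg$max - frg$min
  names(widths) <- frg$reaction
  expect_true(all(widths[sim$rigid] <= 1.3 + 1e-9))
  expect_true(mean(widths[sim$plastic]) > mean(widths[sim$rigid]))
})

test_that("applying ranges replaces bounds and flags infeasible sets", {
  net <- variant_model("WT")
  expect_identical(apply_ranges(net, flux_range_set(character(0), numeric(0),
                                                    numeric(0)))$rxns, net$rxns)
  rg <- flux_range_set("PYK", 5, 5)
  con <- apply_ranges(net, rg)
  expect_equal(unname(reaction_bounds(con, "PYK")), c(5, 5))
  bad <- flux_range_set("EX_glc__D_e", 0, 0)  # no carbon uptake
  expect_error(apply_ranges(net, bad), "infeasible")
})

test_that("MOMA-scan ranges contain the wild-type reference flux", {
  net <- variant_model("WT")
  ref <- wt_reference()
  kos <- c("PGI", "GND", "PPC")
  rg <- moma_range_scan(net, kos, measured = c("PFK", "PYK", "GAPD"),
                        reference = ref)
  for (i in seq_len(nrow(rg))) {
    f <- ref$fluxes[[rg$reaction[i]]]
    expect_gte(f, rg$min[i] - 1e-6)
    expect_lte(f, rg$max[i] + 1e-6)
  }
  empty <- moma_range_scan(net, character(0), measured = c("PFK", "PYK"),
                           reference = ref)
  expect_true(all(empty$max - empty$min < 1e-9))
})

test_that("range comparison reports widths and overlaps", {
  a <- flux_range_set(c("r1", "r2"), c(0, 1), c(10, 2))
  b <- flux_range_set(c("r1", "r2"), c(2, 1), c(3, 2))
  cmp <- compare_ranges(a, b)
  expect_identical(cmp$wider, c("a", "equal"))
  expect_equal(cmp$overlap_min[1], 2)
  expect_equal(cmp$overlap_max[1], 3)
  expect_error(compare_ranges(a, flux_range_set("zz", 0, 1)), "share no reaction")
  # a range set compared with itself is all-equal with zero width difference
  self <- compare_ranges(a, a)
  expect_true(all(self$wider == "equal"))
})
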