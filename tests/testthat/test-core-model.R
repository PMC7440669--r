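test_that("bundled wild-type core network has the expected shape", {
  net <- core_model()
  expect_equal(n_reactions(net), 77)
  expect_equal(n_metabolites(net), 63)
  expect_identical(objective_id(net), "Biomass_Ecoli_core")
  expect_equal(unname(reaction_bounds(net, "ATPM")[["lower"]]), 7.6)
  # fatty-acid synthesis and butanol reactions absent
  expect_false(any(c("ACCOAC", "BTOH_sink", "MCOATA", "AtoB") %in% reaction_ids(net)))
})

test_that("network tables round-trip without loss", {
  net <- core_model()
  rf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  write_network_tables(net, rf, mf)
  back <- read_network_tables(rf, mf)
  expect_equal(n_reactions(back), n_reactions(net))
  expect_equal(as.matrix(back$S[metabolite_ids(net), reaction_ids(net)]),
               as.matrix(net$S), tolerance = 1e-12)
  expect_equal(back$rxns$lower_bound, net$rxns$lower_bound)
})

test_that("reading a reaction table with missing bounds is rejected", {
  rf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  write_network_tables(core_model(), rf, mf)
  tab <- read.delim(rf)
  tab$lower_bound[3] <- NA
  write.table(tab, rf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_network_tables(rf, mf), "missing flux bounds")
})

test_that("medium presets set exchange bounds and are idempotent", {
  net <- core_model()
  aer <- apply_medium(net, aerobic_medium())
  expect_equal(unname(reaction_bounds(aer, "EX_glc__D_e")[["lower"]]), -10)
  expect_equal(unname(reaction_bounds(aer, "EX_o2_e")[["lower"]]), -10)
  ana <- apply_medium(net, anaerobic_medium())
  expect_equal(unname(reaction_bounds(ana, "EX_o2_e")[["lower"]]), 0)
  twice <- apply_medium(aer, aerobic_medium())
  expect_equal(twice$rxns, aer$rxns)
  expect_error(apply_medium(net, medium_condition(other = c(EX_xyz_e = -5))),
               "absent from network")
})

test_that("engineered variants match the published catalogue shape", {
  defs <- pathway_defs()
  expect_length(defs, 8)
  for (v in names(defs)) {
    net <- variant_model(v)
    expect_equal(n_reactions(net), defs[[v]]$expected_reactions, info = v)
    expect_equal(n_metabolites(net), defs[[v]]$expected_metabolites, info = v)
    expect_identical(objective_id(net), defs[[v]]$objective, info = v)
    chk <- check_pathway_coefficients(defs[[v]])
    expect_true(chk$consistent, info = v)
  }
  expect_identical(pathway_defs()[["CROT"]]$objective, "CROAC_sink")
})

test_that("declared co-factor coefficients follow the catalogue pattern", {
  defs <- pathway_defs()
  atp <- vapply(defs, function(d) d$atp, numeric(1))
  pool <- vapply(defs, function(d) d$nadh + d$nadph, numeric(1))
  expect_equal(unname(atp), c(0, -1, -1, -2, -2, 0, 0, 0))
  expect_equal(unname(pool), c(-4, -4, -4, -4, -4, -1, -2, -3))
})

test_that("adding a pathway is purely additive", {
  defs <- pathway_defs()
  net <- add_pathway(core_model(), defs[["BuOH-0"]])
  undone <- remove_reactions(net, net$annotation$pathway_reactions)
  expect_equal(n_reactions(undone), n_reactions(core_model()))
  expect_identical(sort(metabolite_ids(undone)), sort(metabolite_ids(core_model())))
  expect_error(add_pathway(net, defs[["BuOH-0"]]), "already present")
})

test_that("build_catalog returns all nine models", {
  cat9 <- build_catalog(core = core_model(), definitions = pathway_defs())
  expect_length(cat9, 9)
  expect_identical(names(cat9)[1], "WT")
  expect_identical(objective_id(cat9[["BuOH-2"]]), "BTOH_sink")
})
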