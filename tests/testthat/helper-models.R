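# Shared model objects, built once per test run.  Everything is generated
# in code from the bundled core model and pathway definitions.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

core_model <- function() memo("core", load_core_model())

pathway_defs <- function() memo("defs", load_pathway_definitions())

variant_model <- function(name, condition = "aerobic") {
  memo(paste(name, condition), {
    med <- if (condition == "aerobic") aerobic_medium() else anaerobic_medium()
    if (name == "WT") apply_medium(core_model(), med)
    else apply_medium(add_pathway(core_model(), pathway_defs()[[name]]), med)
  })
}

variant_pfba <- function(name, condition = "aerobic") {
  memo(paste("pfba", name, condition), optimize_pfba(variant_model(name, condition)))
}

wt_reference <- function(condition = "aerobic") variant_pfba("WT", condition)

variant_names <- function() names(pathway_defs())
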