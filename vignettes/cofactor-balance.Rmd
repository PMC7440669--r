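---
title: "Co-factor balance assessment of engineered production pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-factor balance assessment of engineered production pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobaflux)
```

## The problem

When a synthetic production pathway is introduced into a microbial host it
does not only re-route carbon: it changes the production and consumption of
the central energy and electron carriers, ATP and NAD(P)H.  A pathway that
demands more redox than catabolism supplies forces the host to burn carbon
for electrons; a pathway that leaves an ATP surplus forces the host to
dissipate energy through maintenance reactions, futile cycles or biomass
formation.  Either way the co-factor economy, not the carbon backbone,
often decides how much of the substrate ends up in the product.

`cobaflux` quantifies this co-factor economy for a family of eight
*E. coli* butanol and butanol-precursor producer models built on the core
stoichiometric network, using standard constraint-based techniques (FBA,
parsimonious FBA, FVA, MOMA) plus three analyses built on top of them:

1. a **co-factor balance assessment** that partitions every ATP and
   NAD(P)H flux into production, biomass, target, waste and maintenance;
2. an **iterative futile-cycle curation** that removes the unrealistic
   co-factor-spilling cycles linear programming likes to exploit; and
3. an analytic **pathway-yield chain** (after Dugar and Stephanopoulos)
   that predicts yields from pathway stoichiometry alone, for comparison
   with the network-wide FBA view.

## The model catalogue

The wild-type base is the published *E. coli* core network restricted to
growth on minimal glucose medium (77 reactions, 63 metabolites).  The
restriction removes the uptake routes for seven alternative substrates and
the lactate/acetaldehyde secretion routes; all central carbon metabolism,
overflow acetate, ethanol and formate fermentation, respiration and the
biomass reaction are untouched.  Eight engineered variants add a
CoA-dependent (or, in one case, ACP-dependent) route from acetyl-CoA to
butanol, butyraldehyde, butyrate or crotonate, together with a transport
and an irreversible sink reaction whose flux is the production objective:

```{r catalog}
defs <- load_pathway_definitions()
core <- load_core_model()
data.frame(
  variant = names(defs),
  reactions = vapply(defs, function(d) d$expected_reactions, numeric(1)),
  ATP = vapply(defs, function(d) d$atp, numeric(1)),
  `NAD(P)H` = vapply(defs, function(d) d$nadh + d$nadph, numeric(1)),
  check.names = FALSE)
```

The declared ATP and NAD(P)H coefficients are the summed stoichiometric
coefficients of the introduced reactions from acetyl-CoA to the target;
`check_pathway_coefficients()` verifies the reaction list against them.

Two modelling choices deserve emphasis because they are load-bearing:

* **Maintenance.** The non-growth-associated maintenance reaction `ATPM`
  (ATP → ADP + Pi) is treated as an observable, not a fixed demand: its
  lower bound is the classical 7.6 mmol gDW⁻¹ hr⁻¹ measured on glucose
  minimal medium, and its upper bound is free until curation caps it.
* **Proton bookkeeping.** The core network has no generic proton antiport,
  so where the introduced reactions place H⁺ changes the energy balance.
  We write protons where the ionised species chemistry dictates:
  thioester hydrolysis releases the carboxylate proton, the carboxylic
  acid reductase consumes it again together with its NADPH partner
  proton, and acetyl-CoA carboxylase consumes the proton released on
  bicarbonate formation.  Writing the carboxylase module fully
  charge-balanced instead (two H⁺ released per malonyl-CoA) makes the
  NphT7 route's optimum proton-limited and suppresses its solution-space
  flexibility entirely — a qualitatively wrong model of the published
  behaviour.

## Optimisation layer

All linear programs are delegated to the GLPK simplex solver through its
command-line interface; quadratic programs (MOMA) use the Goldfarb-Idnani
dual method.  `optimize_pfba()` is the canonical two-stage parsimonious
FBA: the objective is fixed at its FBA optimum and the total absolute flux
is minimised over an irreversible split.  Because the stoichiometric
matrix carries five conserved moiety pools (AxP, NAD(H), NADP(H), CoA,
quinone), its rows are linearly dependent; the MOMA solver keeps a
QR-selected independent subset for its equality constraints.

```{r pfba}
wt <- apply_medium(core, aerobic_medium())
sol <- optimize_pfba(wt)
c(growth = sol$objective_value, ATPM = sol$fluxes[["ATPM"]],
  total_flux = sol$total_flux)
```

## The co-factor balance assessment

For a co-factor with member metabolites $M$ (ATP, or the pooled
NADH+NADPH), the **co-factor flux score** of reaction $j$ is
$\mathrm{CFS}_j = \big(\sum_{i \in M} S_{ij}\big)\, v_j$: positive scores
are production, negative scores consumption.  Because the co-factor
metabolites are internal, $\sum_j \mathrm{CFS}_j = 0$ for every
mass-balanced solution — the *closure* invariant that every profile is
checked against.

Scores are partitioned by reaction identity: the variant's introduced
reactions are **target**; the biomass reaction is **biomass**; the
ATP-hydrolysing reactions (`ATPM`, `ADK1`), acetate-coupled ATP formation
(`ACKr`), the CO₂-releasing NAD(P)H producers (`GND`, `PDH`, `AKGDH`,
`ICDHyr`) and the fermentative NAD(P)H consumers are **waste**; every
other producer is **production** and every other consumer
**maintenance**.  Mixed-sign categories report their net.  The rule lists
ship as an editable YAML file because category membership is a judgement
about biological role, not derivable from stoichiometry.

```{r cba}
b1 <- apply_medium(add_pathway(core, defs[["BuOH-1"]]), aerobic_medium())
s1 <- optimize_pfba(b1)
assemble_profile(b1, s1)
carbon_yield(b1, s1)
```

NADH and NADPH are pooled by default (the transhydrogenases make them
interchangeable at some proton-motive cost); `cofactor_specs(pooled =
FALSE)` tracks them separately, which the pentose-phosphate diagnostics
(`ppp_nadph_share()`) use to attribute NADPH supply.

## Futile-cycle curation

Unconstrained optima burn surplus ATP freely: the maintenance flux rises
up to about 25 mmol gDW⁻¹ hr⁻¹ across the catalogue, and once `ATPM` is
capped the surplus reappears in antagonistic reaction pairs
(fructose-bisphosphatase against phosphofructokinase, PEP carboxykinase
against PEP carboxylase, the transhydrogenase pair, the malic-enzyme
bypass of pyruvate kinase, transport proton leaks).  `curate_model()`
reproduces the manual "whack-a-mole" procedure deterministically:

1. cap `ATPM` at the wild-type maintenance level (7.6);
2. re-optimise with pFBA and compare the solution against the
   biomass-optimal wild-type reference;
3. cap the candidate cycle member with the largest flux excess over its
   wild-type magnitude (ties broken lexicographically) to that magnitude
   — zero when the wild type does not use the reaction;
4. repeat until no candidate exceeds the high-flux threshold
   (1 mmol gDW⁻¹ hr⁻¹ by default; the threshold is a package choice, the
   source material gives only "high-flux").

The capped member of each pair is the one inactive (or low-flux) in the
wild type.  For the canonical ATP cycles this coincides with the
non-ATP-consuming partner; for PEP carboxykinase it does not, and we
follow the wild-type-inactivity rule because capping the wild-type-active
partner (pyruvate kinase, PEP carboxylase) would cripple glycolysis
itself rather than the cycle.  Medium proton uptake is deliberately *not*
a candidate: the producer pathways are net cytosolic proton consumers, so
proton influx at the optimum is the medium acting as a buffer, not a
dissipation loop.

```{r curate}
wt_ref <- optimize_pfba(wt)
cur <- curate_model(b1, wt_ref)
cur$log[, c("iteration", "reaction", "partner", "new_bound", "excess")]
c(yield = carbon_yield(cur$network, cur$solution),
  biomass = cur$solution$fluxes[["Biomass_Ecoli_core"]])
```

After curation the surplus energy has nowhere left to go but the biomass
equation: the curated butanol producers grow while producing, at a small
yield cost.  The procedure is order-sensitive in principle (each cap
changes the next solution); the default largest-first and an
all-at-once batch policy converge to the same fixed point on this model
family, which is the behaviour we freeze in the tests.

## The analytic yield chain

For comparison, `dugar_table()` evaluates the stoichiometry-only yield
framework.  Coefficients per carbon-mol of glucose — $a$ (NADPH demand),
$b$ (product), $c$ (ATP release), $d$ (NADH release), $e$ (CO₂) — are
formed from the glycolytic premise (2 ATP, 4 NADH, 2 CO₂ per glucose
catabolised to two acetyl-CoA) plus the pathway sums.  The chain is

* $Y^E = \gamma_S/\gamma_P$ (degrees of reductance, $\gamma = 4C+H-2O$),
  the energetic maximum in mol product per mol glucose, and its mass
  form $Y^{Ea}$;
* $Y^P = 1/(1 + a/2 - c/4.82\,[c<0])$: substrate diverted to NADPH
  (oxidative PPP, 2 NADPH per C-mol) and, when the ATP balance is
  negative, to respiratory ATP (4.82 ATP per C-mol);
* $Y^{P,G}$: surplus NADH drained into a glycerol sink (⅓ ATP and ⅓ NADH
  per C-mol glycerol);
* $Y^{P,G,X}$: remaining ATP surplus diverted to biomass formation, with
  biomass degree of reductance fixed at 4.2 and two user parameters —
  $\varepsilon$ (CO₂ loss per C-mol biomass) and $\alpha$ (ATP per C-mol
  biomass) — that the source material does not print, which is why
  `dugar_parameters()` has no defaults and the absolute $Y^{P,G,X}$ and
  $\eta$ values are treated as parameter-dependent.  The *ordering* of
  pathways is stable across the parameter family: the chain is linear in
  the ATP surplus, so a smaller surplus is always penalised less.

$Y^P$ through $Y^{P,G,X}$ are expressed as fractions of the energetic
maximum (the convention of the framework's published yield table, where
the crotonate row has $Y^E = 1.333$ but $Y^P = 1.000$), and
$\eta = Y^{P,G,X}/Y^E$.

```{r dugar}
dugar_table(defs, dugar_parameters(epsilon = 0.3, alpha = 2.3))
```

Both the analytic chain and the curated FBA models rank the
NphT7-primed AdhE2 route (BuOH-1) as the most efficient butanol
producer: it is ATP-consuming enough to leave little surplus to divert,
but not so consuming that AMP recycling drags the network.

## Experimental flux ranges and MOMA ranges

The `flux_dataset` tools ingest a reaction-by-knockout-strain flux matrix
(the shape of published ¹³C-MFA panels): isozyme families are averaged
into their single model reaction, wild-type replicates are averaged,
every strain is rescaled to the model's glucose uptake, and the
min/max across strains becomes a per-reaction flux range that
`apply_ranges()` imposes as bounds.  `moma_range_scan()` builds the
*in silico* analogue by knocking out each panel reaction with MOMA
against the wild-type reference.  `simulate_flux_dataset()` generates
seeded synthetic panels with designated plastic and rigid rows so the
whole path is testable without the proprietary dataset; when a real
table is supplied, the same functions apply.  The generator emulates the
shape and normalisation quirks of such panels (replicates, isozymes,
culture-scale variation) but not their correlated measurement error, so
passing tests demonstrate the plumbing and the range logic, not
agreement with any particular laboratory dataset.

## Co-factor stoichiometry landscapes

`build_landscape()` rewrites the terminal aldehyde-reductase step as
butyraldehyde + X NADH + X H⁺ + Y ADP + Y Pi → butanol + X NAD + Y ATP
and re-optimises over a grid (default −10…+10 in steps of 1, i.e. 441
parsimonious FBAs, a few seconds with the GLPK backend).  Negative
coefficients move the species across the arrow; X = 1, Y = 0 recovers
the native reaction exactly, which is asserted as the native-point
consistency invariant.  On the curated butanol models the landscape
forms a plateau at the stoichiometric ceiling of 66.67 % carbon yield
where moderate ATP demand on the terminal step (Y < 0) soaks up the
energy surplus while a mild redox surplus (X ≤ 0) feeds respiration —
the same conclusion the balance profiles reach, found by a different
route.

## Numerical choices and limitations

* Solver: GLPK simplex with its default (10⁻⁹-scale) tolerances; every
  result records the backend and tolerances.  Mass-balance residuals of
  returned solutions are below 10⁻⁶ by test.
* Degenerate-range threshold for FVA counting: 10⁻⁶ mmol gDW⁻¹ hr⁻¹.
* The FVA variability count for the flexible butanol models includes six
  transport/internal loop reactions (formate and succinate transport
  pairs, the fumarate-reductase loop) that carry no co-factor; counts
  restricted to co-factor-carrying reactions are smaller.  Both views are
  available (`count_variable_reactions()` on a filtered range set).
* The wild type's "single solution" rigidity holds at the
  glucose-limited optimum; capping oxygen at 10 makes the wild-type
  optimum O₂-limited and opens genuine overflow-metabolism alternative
  optima.
* In this reconstruction the thioesterase/CAR butanol models satisfy
  their NADPH demand partly through the membrane transhydrogenase
  (whose pooled NAD(P)H score is zero), so the oxidative-PPP share of
  NAD(P)H production for the AtoB-primed CAR route is smaller than for
  its NphT7-primed and ACP-dependent siblings; the published account of
  that one route implies a PPP-dominant optimum that is linear-program
  suboptimal here.  Alternate-optimum sensitivity of flux-composition
  diagnostics is intrinsic to FBA and worth keeping in mind whenever a
  share statistic, rather than an objective value, is compared.
* Curated aerobic models grow only when the pathway leaves an energy
  surplus; the ATP-neutral-or-deficient CAR routes stay at zero biomass
  here.  Anaerobically, those three models balance through fermentation
  product release alone, with no biomass — a structure the tests assert.
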