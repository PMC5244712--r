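---
title: "Constraint-based modeling of the diazotroph/photoautotroph division of labor"
author: "TrichoFBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of the diazotroph/photoautotroph division of labor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrichoFBA)
```

# The biological problem

*Trichodesmium erythraeum* is a filamentous marine cyanobacterium that
fixes both carbon and nitrogen during the day, in the same trichome, by
differentiating into two cell types that share one genome: carbon-fixing
photoautotrophs (PA) and nitrogen-fixing diazotrophs (DZ).  The
diazotrophs switch photosystem II off (it produces oxygen, which poisons
nitrogenase), live off glycogen supplied by their neighbors, and leak a
substantial share of the ammonium they fix back to the community and the
surrounding ocean.  TrichoFBA implements the constraint-based analysis
of this division of labor: cell-type-specific flux balance analysis
(FBA), flux variability analysis (FVA), maintenance-energy calibration,
gene/reaction essentiality, and a two-phenotype population dynamic FBA
(dFBA) in which cells differentiate between the two states in proportion
to metabolite shortage.

# Steady-state machinery

## FBA and the solver

Each submodel is the linear program
$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\;\; lb \le v \le ub,$$
with $S$ the stoichiometric matrix (metabolites x reactions), $v$ in
mmol gDW$^{-1}$ h$^{-1}$, and $c$ selecting the biomass reaction (whose
flux is the specific growth rate in h$^{-1}$, because the reaction is
normalized to produce one gram dry weight).  The package ships its own
two-phase bounded-variable primal simplex (`solveLP()`).  Bland's rule
is used for both entering and leaving variables, which guarantees
termination on the heavily degenerate vertices typical of metabolic
networks; feasibility and optimality tolerances default to $10^{-9}$.
Flux bounds use the field's $\pm 1000$ sentinel and are stored
literally, never converted to infinity, so model files round-trip
unchanged.  The solver is validated in the test suite against an
independent oracle that exhaustively enumerates the basic solutions of
small programs.

Genome-scale models are underdetermined, so a single FBA optimum is one
of many.  All flux-level statements in the package are therefore made
through FVA envelopes (`runFVA()`, default fraction-of-optimum 1.0, the
"same solution" setting, exposed as a parameter), never through one
solution's values.

## Cell-type constraint sets

`cellTypeConstraints()` carries the published physiology as defaults:

| parameter | diazotroph | photoautotroph | units |
|---|---|---|---|
| carbon uptake | 0.927 (glycogen) | 0.927 (CO2, pinned) | mmol C gDW$^{-1}$ h$^{-1}$ |
| nitrogenase flux | 0.132 (pinned) | 0 | mmol gDW$^{-1}$ h$^{-1}$ |
| photosystem II | 0 | free | mmol gDW$^{-1}$ h$^{-1}$ |
| photon budget | 80 | 80 | uE, shared by PSI + PSII |
| maintenance ATP | 67.2 | 64.3 | mmol ATP gDW$^{-1}$ h$^{-1}$ |

Two printed values for the fixed nitrogenase flux circulate (0.132 and
0.206); the package defaults to 0.132, which matches the physiological
source, and exposes the alternative through the constructor.  The
diazotroph's carbon constraint is applied as an uptake *cap*
(lb = $-$0.927/6 on the glycogen exchange, six carbons per
glucose-equivalent unit) rather than an equality, because in the
dynamic setting the uptake is additionally limited by what the partners
actually supply; the photoautotroph's CO2 constraint is an equality.
The photon budget is modeled as a single photon exchange capped at 80,
from which PSI and PSII both draw, implementing the coupled
"80 $-$ h$\nu$" rows as a joint cap.  Maintenance is a *lower* bound on
the ATP-hydrolysis reaction (ATP + H2O $\to$ ADP + H$^+$ + Pi), the
standard non-growth-associated maintenance semantics.

`unconstrainedVariant()` produces the nutrient-unlimited variant used
for the independent optima and for the dFBA: the partner-supplied
substrate (glycogen or ammonium) opens fully and the pinned
carbon/nitrogenase rates become inequality bounds.  Only the
maintenance demand remains binding, as in the published calibration.

## Maintenance calibration and essentiality

`calibrateMaintenance()` bisects the maintenance lower bound until
predicted growth matches a measured rate to $10^{-6}$ h$^{-1}$ (growth
is monotone non-increasing in the maintenance demand, and piecewise
linear, so bisection is exact up to the tolerance).
`essentiality()` deletes genes through the boolean
gene-protein-reaction rules (AND = complex requirement, OR = isozymes)
or pins reactions to zero, re-optimizing growth per knockout.  The
published work states no classification threshold; the package calls a
knockout *essential* below $10^{-6}$ h$^{-1}$ and *growth-reducing*
below 99% of wild type, both configurable.

# The biomass equation

`buildMacromoleculeReactions()` turns monomer profiles into one
condensation reaction per macromolecule (protein, carbohydrate, DNA,
RNA, lipid, pigments, cyanophycin, soluble pool), releasing one water
per condensation bond, so each polymer unit's molar mass is the
profile-weighted monomer mass minus the condensation water.
Cyanophycin is polymerized arginine:aspartate at 1:1.  Lipids combine
the four subclasses (SQDG, MGDG, DGDG, PGP) with a single fatty-acid
chain-length distribution applied to every subclass.
`compositionToCoefficients()` converts measured mass fractions
(g/g DW) into biomass coefficients (mmol/g DW) by dividing by the molar
masses, after subtracting subset assays from their parents
(phycoerythrin and cyanophycin from protein; phycocyanin and
chlorophyll from lipid) so nothing is double counted.  The
nitrogen-grown composition is the default reference; the nitrate column
is selectable.  Printed compositions do not total exactly 1 g/g; the
package reproduces them verbatim by default and offers a
normalize-to-1 switch.  Because the printed totals are ambiguous about
subset rows, `compositionTotals()` reports both sums and asserts
neither.  `assembleBiomassReaction()` adds the growth-associated
maintenance (GAM) ATP hydrolysis, 544 mmol ATP per g DW by default.

The amino-acid and fatty-acid profiles shipped under `inst/extdata`
are **synthetic stand-ins** (plausible cyanobacterial values); the
measured profiles were not printed in the source publication.  The mass
fractions and biomass coefficients in
`inst/extdata/biomass_composition.tsv` are the published values.

# The reduced two-cell-type network

`makeToyModel()` generates a fully balanced 20-reaction model that
compresses the division of labor into its essential economy:

* photon exchange (80 uE budget) feeding PSI (2 photons per ATP) and
  PSII (2 photons per NADPH, releasing O2);
* a lumped Calvin cycle (6 CO2 + 18 ATP + 12 NADPH per glucose);
* glycogen polymerization/degradation on a six-carbon
  glucose-equivalent currency, with the total photoautotroph cost of
  one glycogen unit defaulting to 64 ATP-equivalents;
* nitrogenase (N2 + 16 ATP + 3 NADPH $\to$ 2 NH4$^+$, i.e. 8 ATP per
  N), respiration (30 ATP per glucose) and an oxidative
  pentose-phosphate route for NADPH;
* transporters and exchanges for glycogen and ammonium, and a lumped
  biomass drain with 45.8% carbon by mass and a molar C:N of 6.6 (the
  marine Redfield value).

Every reaction is elementally and charge balanced by construction, and
the generator's output passes the dead-end and closed-exchange
futile-cycle screens cleanly, which makes the toy a sound end-to-end
fixture for each pipeline stage.

Two generator defaults deserve justification.  First, the maintenance
demands default to 32 (PA) and 36 (DZ) mmol ATP gDW$^{-1}$ h$^{-1}$
rather than the published 64.3/67.2: those values were calibrated
against the full 971-reaction network's energy economy, while the toy's
lumped photosystems deliver at most ~40 ATP h$^{-1}$ from the 80 uE
budget, so the published demands would be infeasible there.  The chosen
values put the toy's growth rates in the organism's physiological range
(0.01-0.04 h$^{-1}$).  Second, the glycogen *importer* is capped at the
measured uptake rate (0.927/6 glucose-equivalents gDW$^{-1}$ h$^{-1}$):
without a finite per-cell import capacity the relaxed diazotroph could
run at the $\pm 1000$ sentinel and a vanishing diazotroph fraction
could feed the whole trichome, which is not a property of real cells.

## The equilibrium oracle

`analyticEquilibrium()` is the package's independent reference for the
population calculation: a brute-force scan over the diazotroph fraction
$f$ that solves, at each grid point, one joint linear program -- both
submodels at steady state under relaxed bounds, glycogen supply equal
to demand, ammonium supply at least demand, maximizing total specific
biomass production $(1-f)\,\mu^{PA} + f\,\mu^{DZ}$.  No per-type
balanced-growth constraint is imposed, because the differentiation
allocation redistributes the increment freely between the types.  The
scan runs a coarse grid (0.01) and refines around the optimum to the
$10^{-4}$ reference resolution, far below the 2-point agreement band
used in the tests.  With default parameters the optimum sits at
$f^{*} \approx 0.19$ -- a photoautotroph-majority trichome, like the
organism's observed 10-20% diazotroph share.

# The population dynamic FBA

`simulatePopulation()` advances a batch reactor in 1 h steps (the
published step), photoautotroph first, diazotroph second:

1. **PA step.**  The photoautotroph must replace the glycogen the
   diazotrophs drew last step, scaled by the predictive factor
   $(\mu^{DZ}\Delta t + 1)$ and the biomass ratio $X^{DZ}/X^{PA}$.  The
   step maximizes glycogen export up to that requirement, pins the
   achieved supply, then maximizes growth.  Supplying best-effort
   rather than failing outright matters: a hard failure would kill the
   equal-parts inoculum that demonstrably converges; an unmet
   requirement instead surfaces as a glycogen deficiency in the
   allocation stage.
2. **DZ step.**  Glycogen uptake is capped by the carbon the
   photoautotrophs fixed, $|v| \le |v_{CO2}^{PA}|/(6 f_{DZ})$, and by
   what the medium plus this step's supply hold.  The step then mirrors
   the PA: it maximizes ammonium export up to the community's
   predictively scaled demand and grows with what remains.  This
   realizes the bi-objective coupling (photoautotroph growth and
   diazotroph ammonium provisioning) and is what makes ammonium leak:
   the diazotroph over-fixes on behalf of the community rather than
   fixing only its own need.
3. **Batch update.**  $X_f' = X_0 e^{\mu \Delta t}$ per type.
4. **Differentiation allocation.**  For each cross-fed metabolite in
   shortage, the allocation coefficient
   $\alpha = (C^T_{prod} + C^T_{cons})/C^T_{cons}$ (signed totals,
   clamped to $[0,1]$) draws $\alpha\,\sigma^{\gamma}\,\Delta X'^{\gamma}$
   from the deficiency-generating consumers and deals it to the
   producers by their portion coefficients $\sigma$.  Shortage is
   judged against *demand* -- the uptake the cells would choose were
   the medium replete -- not against availability-capped uptake;
   otherwise a starving population would never register as deficient
   and the signal would be self-fulfilling.  If nothing is deficient,
   the entire diazotroph increment is allocated to photoautotroph
   production.  Allocation redistributes only the current increment (a
   type can lose at most what it gained this period), conserves total
   biomass exactly, and never creates a cell type from zero biomass.
5. **Medium update.**  Exact bookkeeping of produced minus consumed
   amounts; any grace-period overdraft is recorded as borrowing.

During the first three steps (the grace period) uptake is not limited
by medium stocks -- the cells may borrow from a seed cache, which
defaults to one step of inoculum consumption at unconstrained growth.
A step is flagged failing when the population gains essentially no
biomass or consumes a cross-fed currency it does not itself produce;
after `grace` consecutive failing steps the population is declared dead
at the next step, so an all-photoautotroph, all-diazotroph or
zero-energy population terminates after exactly grace + 1 steps.

`computeMetrics()` reports the per-step growth rate
$\mu_t = \ln(\Sigma X_t / \Sigma X_{t-1})/\Delta t$, the total growth
rate $\mu_T = \ln(\Sigma X_f / \Sigma X_0)/\Delta t_{total}$, the
fraction of fixed nitrogen released
$Y_{N \to Env} = \Delta C_{NH_4^+}/C_{NH_4^+,prod}$, and the
equilibrium composition as the mean fraction over the final tenth of
the run.  Dead populations report zero release.

## Observed behavior on the reduced network

From any inoculum with up to ~50% diazotrophs the simulation converges
to $f_{DZ} = 0.167$ and holds it exactly; the oracle's argmax is 0.186.
The ~0.02 offset is the steady-state error of a proportional
controller: the allocation inflow that holds the composition against
dilution requires a standing (small) shortage signal, so the population
hovers just below the zero-shortage fraction.  The equilibrium growth
rate equals the oracle's curve at the realized fraction, and the oracle
optimum bounds the simulated rate from above.  Strongly
diazotroph-dominated inocula ($f_0 \gtrsim 0.55$) instead reach a
distinct suboptimal state in which the few photoautotrophs are
permanently saturated by the supply requirement -- the same
phenomenology as the published bimodal growth distribution, where
diazotroph-dominated inocula grow suboptimally and photoautotroph-pure
ones die.

`runEnsemble()` repeats the simulation from randomized inocula (both
biomasses drawn uniformly, the fraction arising as their ratio, per the
published randomization) under one seeded generator, and
`nitrogenSourceScenario()` re-runs the simulation with a chosen
nitrogen source in excess.  For the reduced network the meaningful
scenarios are dinitrogen (baseline) and replete ammonium, which lifts
growth above the baseline because photoautotrophs stop depending on
diazotroph provisioning; richer sources (urea, amino acids) require the
genome-scale network's metabolism and a grafted transporter
(`addDiffusionTransporter()`, ATP-dependent for urea-style active
transport).

# Problem sizes and run times

The test suite and the acceptance script are sized for a single CPU:
the reference dFBA runs use the full 400 h horizon at 1 h steps
(~1600 linear programs each, a few seconds per run with warm starts);
the equilibrium oracle refines to the $10^{-4}$ grid only around its
coarse optimum; ensembles in the shipped scripts use 24 iterations at a
200 h horizon, which is enough to exhibit the viable/nonviable split
and the release-fraction clustering without hour-scale runtimes.

# What the toy network does and does not show

Passing the reduced-network suite demonstrates that the machinery --
solver, constraint application, calibration, the coupling and
allocation algorithm, metrics -- is internally consistent and matches
an independent brute-force reference.  It does not certify the
genome-scale predictions (essentiality counts, FVA panels, the 0.154
equilibrium or the ~40% nitrogen release): those depend on the full
971-reaction reconstruction, whose converted tables can be placed under
`tests/testthat/fixtures/trichodesmium/` to activate the genome-scale
acceptance test.  The toy's equilibrium (~17% diazotrophs) and growth
rates land in the organism's observed range by construction of its
energy economy, not by fitting.

# Known limitations

* The dFBA equilibrium carries the proportional-allocation offset
  described above; an integral-type allocation would remove it but is
  not what the published algorithm does.
* The sequential PA-then-DZ coupling means metabolites are not
  synthesized simultaneously; the grace-period cache exists precisely
  to bridge the resulting start-up artifact.
* No diffusion limits, light attenuation, O2 inhibition kinetics of
  nitrogenase, predation, or multi-species interactions are modeled.
* The simplex is dense and single-threaded: right for the toy network
  and adequate for occasional genome-scale solves, not for
  genome-scale ensembles.
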