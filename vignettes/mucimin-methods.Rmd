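---
title: "Methods: constraint-based medium design and growth phenotype analysis for Akkermansia muciniphila"
author: "mucimin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based medium design and growth phenotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucimin)
```

## The scientific problem

*Akkermansia muciniphila* is a mucin-degrading gut symbiont whose genome
lacks GlmS, the glutamine–fructose-6-phosphate transaminase
(EC 2.6.1.16) that every peptidoglycan-forming bacterium otherwise uses
to aminate fructose-6-phosphate (Fru6P) to glucosamine-6-phosphate
(GlcN6P). Its only candidate enzyme for that node, a NagB homologue,
works essentially in the deaminating direction (GlcN6P → Fru6P + NH4).
The consequence is a concrete, testable prediction: growth requires an
exogenous amino sugar — N-acetylglucosamine (GlcNAc) or
N-acetylgalactosamine (GalNAc), both abundant in mucin glycans — plus
L-threonine, and a defined minimal medium can be designed around that
requirement. This package implements the computational side of that
story end to end: a constraint-based modeling engine with the media
conventions used for the genome-scale model, the v1→v2 model curation
(removing the wrongly gap-filled GlmS reaction), and the analysis of the
accompanying experiments (growth rates from OD600 curves, acetate:
propionate ratios from fermentation series, NagB Michaelis–Menten
kinetics). Seeded synthetic-data generators stand in for the wet-lab
inputs so every stage is verifiable.

## Flux balance analysis

A metabolic model is a stoichiometric matrix $S$ (metabolites ×
reactions) with per-reaction flux bounds. At steady state, production of
every internal metabolite equals consumption, $S v = 0$, and flux
balance analysis (FBA) maximizes an objective (biomass synthesis) over
the resulting polytope:

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\;\; l \le v \le u.$$

Exchange reactions touch a single metabolite; uptake is negative flux,
secretion positive. All bounds and objective values are in arbitrary
units (a.u.).

The LP core is a dense two-phase primal simplex with Bland's
anti-cycling rule, operating on the bound-shifted standard form
$x = v - l \ge 0$. Feasibility and pivot tolerances are $10^{-9}$;
reported equalities in tests use $10^{-6}$. Ties among optimal vertices
are not resolved: the flux *vector* is one optimal vertex and only the
objective value and FVA ranges are contracts. Flux variability analysis
(FVA) pins the objective from below at `fraction × optimum − 1e-9` (the
slack avoids spurious infeasibility at a degenerate vertex) and
minimizes/maximizes each reaction in turn. Unbounded problems cannot
arise because all bounds are required finite. The solver is validated
against an independent implementation (scipy's HiGHS-based `linprog`)
on randomized networks in the test suite; thermodynamically infeasible
loops are reported by FVA, not removed.

## Media as exchange bounds

A medium recipe is translated into bounds in a fixed order: every
exchange is first closed for uptake (`lb = 0`) and opened for secretion
(`ub = 1000`); then non-limiting components (water, phosphate, trace
ions, ammonium) get `lb = -1000`; capped components get `lb = -bound`
(L-threonine is supplemented at a maximal uptake of 1 a.u.); and sugars
share a total budget equally — mixtures are equimolar. The default
budget of 10 a.u. is the top of the 0–10 a.u. uptake range scanned in
the simulations; the printed growing-prediction values (0.09–0.13 a.u.)
do not state the bound that produced them, so the budget-10 convention
is declared once here and used for every recomputation. The growth
yes/no threshold is $10^{-6}$ a.u. — growing predictions sit two to
three orders of magnitude above it, so the call is insensitive to the
exact value.

A medium component whose metabolite has no exchange reaction is a
structured "no route" outcome inside `growth_table()` (recorded as
no-growth with a note) rather than a bare error, because that situation
carries biological meaning: glucosamine (GlcN) has no annotated
transporter, and its absence is the sole reason the model predicts no
growth on GlcN media — adding a hypothetical transporter restores
growth.

## The amino-sugar core fixture

`make_toy_model("amino_sugar_core")` builds a ~30-reaction network
reproducing the qualitative physiology: the GlcNAc shortcut
(uptake/phosphorylation to GlcNAc6P), deacetylase and
N-acetyltransferase connecting GlcNAc6P and GlcN6P, the deaminating-only
NagB, lumped glycolysis producing acetyl-CoA/ATP/NADH, an ATP-yielding
acetate branch and an NADH-reoxidizing propionate branch, UDP-GlcNAc
synthesis with the reversible UDP-GlcNAc ↔ UDP-GalNAc 4-epimerase, and a
biomass reaction consuming UDP-GlcNAc, threonine and ATP. Design choices
that were genuinely open:

* **UDP-GlcNAc synthesis is reversible.** With an irreversible
  synthesis step, GalNAc (entering via the UDP route) could reach the
  biomass precursor but never glycolysis, so the model would neither
  grow on GalNAc nor produce SCFA from it — contradicting the observed
  phenotype. The reverse direction stands in for the catabolic route
  from the UDP node.
* **The v1-like GlmS flag keeps the paper-form stoichiometry**
  (Fru6P + glutamine → GlcN6P + glutamate) and adds a glutamine
  synthetase (glutamate + NH4 + ATP → glutamine) so the amino donor is
  recycled and nitrogen enters as ammonium; the bundled media therefore
  carry ammonium as non-limiting.
* **Coefficients are fixture constants**, chosen so that on pure GlcNAc
  the redox coupling forces acetate:propionate = 2:1 (deacetylation
  contributes extra acetate), dropping toward ~1.3:1 when glucose covers
  half the sugar budget — mirroring the measured 1.5–2:1 on amino
  sugars and ~1:1 on the mixture. The a.u. growth values of the toy are
  not comparable to the deposited genome-scale model's printed values;
  only the yes/no pattern and orderings are.

The bundled six media (glucose+GlcN, GlcN, GlcNAc, GlcNAc+glucose,
GalNAc, glucose) ship as JSON data, with the CP-medium trace components
mapped to inert exchanges.

## Growth-rate estimation

The specific growth rate is the slope of $\ln(\mathrm{OD600})$ versus
time in exponential phase. The window is selected automatically: after
blank subtraction, points at or below the detection floor (OD 0.01, to
avoid taking logs of near-zero noise) and after the OD maximum are
excluded; every 5-point window is fitted by OLS and the *steepest*
window with $R^2 \ge 0.98$ and a fitted log-rise of at least 0.3 is
taken. Two alternatives were rejected on synthetic validation:
maximal-*length* $R^2$-gated windows are biased 20–30% low on
logistic-capped curves, because long high-signal windows retain
$R^2 \ge 0.98$ well into saturation; and dropping the rise requirement
lets noise-aligned short windows fake growth on near-flat curves (on 5
points, $R^2 \ge 0.98$ is equivalent to $|t| \ge 12$ whatever the
effect size, so a pure significance gate cannot help). When no window
qualifies — growth too slow to rise 35% within a window — the slope
over the whole curve (without peak truncation, which would bias a noisy
flat curve upward) is kept only if significantly positive (one-sided
$p < 0.01$); otherwise the replicate is an explicit no-growth result.
Replicates are fitted separately and pooled as mean ± across-replicate
SD. All gates (`r2_min`, `window_points`, `floor_od`, `min_rise`) are
exposed as arguments.

On triplicate synthetic curves (sampling every 2 h over 60 h, initial
OD 0.02, cap 0.5, 3% CV multiplicative noise) the estimator recovers
generating rates of 0.122, 0.056, 0.084 and 0.005 h⁻¹ with relative
bias between −5% and +3%, and flags zero-rate curves as no-growth; the
test suite verifies this over 200 seeded simulations per condition.

## SCFA ratios and consumption rates

Acetate and propionate production are measured endpoint-to-endpoint
(final − initial, floored at zero), matching how ratios like 1.5:1–2:1
are stated; production below an HPLC-scale quantification floor of
0.05 mM counts as none, so a substrate that is degraded without SCFA
production yields a distinct undefined-ratio result rather than a
noise-driven quotient. Consumption rates are OLS slopes over the
depletion phase (until the first sample below 5% of the initial
concentration); two sugars are declared equally consumed when the 95%
confidence intervals of their slopes overlap.

## Enzyme kinetics

Km and Vmax are estimated per replicate by unweighted ordinary least
squares on the double-reciprocal (Lineweaver–Burk) plot,
$1/v = (K_m/V_{max})(1/[S]) + 1/V_{max}$, and pooled as mean ± SE
across replicates — so the pooled estimate is comparable to a reported
mean ± spread over n = 2–3 assays. Unweighted regression on reciprocals
is statistically fragile (low-concentration points dominate), which is
exactly why a nonlinear Michaelis–Menten fit (Levenberg–Marquardt) is
provided as a cross-check; on noiseless data both agree with the
generating parameters to $10^{-9}$ relative, and across seeded
simulations the double-reciprocal Km is verifiably more variable.
Replicates with a non-positive reciprocal intercept, non-convergent
optimizer, or $R^2 < 0.5$ against the Michaelis–Menten form are flagged
invalid. Two-substrate assays fix the co-substrate at a saturating
concentration (≥5× its own Km). The activator comparison is a Welch
t-test on replicate-level Km values; the "no influence" conclusion is
$p > 0.05$. The comparison is concentration-agnostic — the activator
level is a label, not a model input — which also sidesteps the
ambiguity between 0.25 mM and 25 in the reported activator condition.
The glutamine-dependent amination assay is represented as a one-sided
test of rates against the no-enzyme blank: no activity means
indistinguishable from blank.

## Synthetic data

Generators are pure functions of (parameters, seed): the global RNG
state is saved and restored, and a fixed seed reproduces output bit for
bit. OD600 curves are logistic-capped exponentials with multiplicative
log-normal noise (unit mean, stated CV); initial-rate assays use the
same noise family (positivity-preserving); fermentation series decay
sugars linearly, accumulate acids by fixed yield stoichiometry, and add
additive Gaussian noise floored at zero. Defaults follow the study
conditions: 3% CV for OD600 (three biological replicates), 5% CV for
assay rates (triplicates, 8 concentrations log-spaced over
0.1×–10× Km), sugars supplied to a 25 mM scale.

What the generators do *not* emulate: lag phases, death phases,
transcriptional adaptation between sugars, instrument drift, or any
kinetic (ODE) behavior of the genome-scale model. Passing recovery
tests therefore demonstrates estimator correctness under the stated
noise model, not robustness to every artifact of real curves.

## Problem sizes and runtime choices

The test suite validates the solver on 100 random networks (≤12
reactions) against an independent LP implementation; parameter-recovery
properties use 200 seeded simulations per condition and the activator
null uses 1000 seeds — sizes at which Monte-Carlo error is well below
the asserted tolerances while the whole suite runs in well under a
minute per property.

## Repository shape

The package is organised as an analysis workflow: all computation lives
in the package functions (`R/`), with thin numbered drivers under
`analysis/` that narrate each stage and write tables under `results/`,
and `run_pipeline()` orchestrating the full reproduction with a single
seed and a provenance block. There is no shell CLI beyond `Rscript`
invocations of those drivers; the functions and scripts are the
interface.

## Known limitations

* Gene–protein–reaction rules, elemental balancing and gap-filling are
  out of scope; curation is explicit, replayable edits.
* The quantitative growth values (0.09/0.13 a.u.) and the 5:4
  acetate:propionate prediction belong to the deposited genome-scale
  model (BioModels MODEL1710040000); the corresponding check runs only
  when that model file is supplied locally under `models/`, and the
  bundled core reproduces the qualitative pattern only.
* FBA flux vectors are representative optimal vertices; downstream
  comparisons use FVA midpoints at the fixed optimum with a 10%
  relative-difference rule for higher/lower/similar calls.
* The simplex core is dense; it is sized for models up to a few
  thousand reactions, not for community-scale models.
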