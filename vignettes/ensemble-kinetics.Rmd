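---
title: "Ensemble kinetic modelling of metabolic networks with kinens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble kinetic modelling of metabolic networks with kinens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinens)
```

## The problem

Constraint-based (stoichiometric) models predict flux distributions from
mass balance and an optimality assumption, but they are blind to enzyme
levels, metabolite concentrations and substrate-level regulation, which
is why strain designs derived from them often fail.  Kinetic models
carry exactly that information, but their parameters are mostly
unmeasured.  `kinens` implements the ensemble-modelling (EM) answer to
this: build not one kinetic model but a population of them, all exactly
consistent with one reference (wild-type) steady state, and then let
mutant flux data decide which parameterizations survive, using a genetic
algorithm (GA) that recombines per-reaction parameter blocks.

## Model formalism

**Elementary decomposition.** Every enzyme-catalysed reaction is
decomposed into an ordered sequential catalytic cycle of elementary
mass-action steps: one binding step per substrate molecule in declared
stoichiometric order (a coefficient of 2 becomes two sequential binding
steps), one central conversion step, one release step per product
molecule (declared order).  Cofactors bind like any substrate.
Substrate-level regulations become extra elementary steps:
competitive inhibitors bind the free enzyme as a dead-end complex,
uncompetitive inhibitors the fully substrate-bound complex, mixed
inhibition adds both, and an activator becomes an obligatory first
ligand that is released again at the end of the cycle, so catalysis
cannot start from the free enzyme.  Exchange reactions and uncatalysed
drains (the biomass reaction) are kept as single lumped mass-action
steps.  Each enzyme pool (one per isozyme per reaction) contributes one
structural conservation law: every step has exactly one enzyme form on
each side, so pool totals are invariants of the dynamics, not
constraints that must be imposed.

**Scaling and anchoring.** All metabolite concentrations are normalized
by their wild-type values, so the reference state is the all-ones
vector; fluxes are normalized to the uptake basis (uptake = 100).  The
free parameters of one model are, per elementary step, a reversibility
$R \in [0, 1)$ — the ratio of backward to forward elementary rate at the
reference state — and, per enzyme pool, a vector of enzyme-form
fractions on the probability simplex.  Given the reference net flux $V$
of a reaction, each of its steps carries forward flux $V/(1-R)$ and
backward flux $VR/(1-R)$; dividing by the reference activities
(metabolites at 1, enzyme forms at their sampled fractions) yields the
elementary rate constants.  By construction the reference state is an
*exact* fixed point of every sampled model — the test suite asserts a
residual below $10^{-9}$ across 100 random models.

**The reference state** is built in three LP phases from wild-type
measurements: (1) biomass maximization with the measurements imposed as
1-s.d. ranges, (2) flux variability at the fixed biomass optimum for all
unmeasured reactions, (3) one biomass-optimal vector inside those
ranges.  Phase 3 is tie-broken by minimizing the L1 norm, a
reproducibility choice the source procedure leaves open ("a feasible
flux distribution").  A coupling analysis (`biomass_coupled_reactions`)
identifies reactions whose flux-to-biomass ratio is stoichiometrically
fixed; a biomass measurement then resolves these fluxes, which is how
flux data are augmented beyond central metabolism.

## Parameter estimation

The objective is the CV-scaled average relative deviation

$$z = \frac{1}{M}\sum_{m=1}^{M} \frac{1}{N_m} \sum_{j}
\frac{1}{CV_j}\,\frac{|v_j - v_j^{exp}|}{\max(|v_j^{exp}|,\ \epsilon)},$$

so reactions with tighter confidence intervals contribute more.  Mutant
measurements without their own s.d. inherit the wild-type CV of the same
reaction.  $\epsilon$ floors near-zero measured fluxes at $10^{-3}$ of
the uptake basis.  Steady states that do not converge contribute a fixed
penalty of $10^6$.

**Stage 1** fits the elementary parameters against knockout data under
the reference condition.  A knockout fixes the enzyme's normalized pool
at zero.  Deleting one isozyme zeroes its pool and leaves the remaining
total enzyme of that reaction as a fitted gene $\tau \in [0,1]$
(survivors share it in proportion to their sampled reference shares; the
isozyme shares themselves are Dirichlet(1)-sampled and sum to one at
reference).  The GA uses tournament selection, elitism, per-reaction
block recombination (a reaction's reversibilities, fractions, shares and
anchored constants travel together, so every offspring is anchored
without re-computation) and mutation by block resampling.  Defaults
(P = 256, G = 60, tournament 4, crossover 0.9, per-reaction mutation
0.05, elitism 1) are desk-scale choices exposed in `ga_config()`.

**Stage 2** freezes the stage-1 parameters (the apparent $K_m$) and
fits only total enzyme levels — equivalently $v_{max}$ — per non-reference
condition, each in $[0, 10]$ (zero = deletion, ten-fold overexpression),
over a deliberately small whitelist of enzymes to avoid
overparameterization.

**Cross-validation** (`cross_validate`) refits with folds of one or two
data sets removed and reports the held-out strains' prediction deviation
from the full-data fit.

## Michaelis–Menten back-conversion

`elementary_to_mm` clamps one substrate over a log grid with
co-substrates, products and regulators at reference levels, solves the
enzyme-form quasi-steady state, and reads $v_{max}$ (plateau, refined
far into saturation), apparent $K_m$ (half-saturation, root-refined) and
$k_{cat} = v_{max}/e_{tot}$.  These agree with King–Altman closed forms
to $10^{-6}$ relative on uni-uni mechanisms.  Normalized constants are
converted to absolute mM ranges by interval multiplication with the
wild-type concentration range; agreement with "measured" ranges is a
closed-interval overlap, with measured ranges formed as mean ± 1 sample
s.d. (≥ 2 reported values) or ± 10% (single value).

## Strain evaluation

Product yield is the product-formation flux divided by the uptake flux
(mol/mol).  Designed strains map knockouts to zeroed pools; reported
up-/downregulations rarely carry fold changes and are treated as boxes
($[1,10]$ and $[0.1,1]$), resolved by maximizing product flux over a
4-point log grid per enzyme (≤ 3 jointly) with Nelder–Mead refinement —
a stated selection rule where the source leaves the choice open.  The
stoichiometric comparators FBA (max biomass), MOMA (closest flux vector
to the wild type) and max-yield share the same genotype semantics but
see knockouts only.  `compare_yields` computes Pearson correlation,
the within-20% count and grouped mean relative errors.

## The synthetic world

No real-organism data ships with the package.  `make_toy_network`
provides three presets — `linear-8`, `branched-14` (the workhorse:
uptake, backbone, two secreted products, a biomass branch pair, a cycled
NAD(H) pair, an isozyme pair on the branch-point reaction, one
competitive product inhibition) and `core-24` (adds ATP/ADP, oxygen,
a second route, activation and uncompetitive regulation, fractional
biomass coefficients).  `toy_ground_truth` derives the reference state
from preset "chemostat" measurements (~3% s.d.) and samples a
ground-truth parameterization under the given seed;
`ground_truth_datasets` simulates mutant panels and adds multiplicative
Gaussian noise with a stated CV (default 0.1, emulating how fluxomic
uncertainty is reported), attaching that CV to each reaction.

What a green test establishes: that the estimation machinery can recover
a model *from the model class that generated the data*.  It does not
establish identifiability on real fluxomes, where the mechanism
templates are approximations, noise is not multiplicative-Gaussian, and
uptake kinetics are clamped rather than predicted.  Two behaviors of the
stated world are worth knowing: with uptake clamped at the basis value,
knockouts of backbone enzymes often have *no* steady state (influx
exceeds the crippled network's capacity; concentrations diverge) — these
genotypes are flagged lethal by the generator and penalized in fits, as
in the EM tradition of rejecting inconsistent models; and the held-out
prediction error of the *generating* model on CV-0.1 data is ~8% by
construction, so the 10% recovery criterion is intentionally tight.
Because the GA has no early-stopping or regularization, it can push the
training objective below the generating model's own value on the same
noisy data — at that point it is fitting noise, and held-out deviation
rises with further generations; the acceptance suite records this as a
failing recovery criterion rather than masking it.

## Numerical choices

* Reversibilities are sampled on $[0, 1-10^{-6}]$; the cap avoids the
  $1/(1-R)$ blow-up at equilibrium.
* Enzyme fractions: symmetric Dirichlet(1).  Occasional tiny fractions
  produce very stiff models; these either converge under the implicit
  solver or are penalized — they are not resampled, to keep the sampling
  distribution honest.
* Steps with zero reference flux (latent pathway branches, dead-end
  regulatory steps) are anchored as equilibria with a sampled exchange
  magnitude $s \cdot \mathrm{basis}$, $s \sim U(0.01, 1)$, preserving
  the fixed point exactly.
* Steady states: pseudo-transient continuation (implicit Euler with a
  step that grows as the residual falls, becoming Newton), tolerance
  $10^{-9}$ on $\|\dot C\|_\infty$, analytic Jacobian, divergence
  cut-off at $10^9$ times reference, iteration cap 120 (the 99th
  percentile of converged solves is ~40).  Non-convergence is a model
  property (penalty), not an error.
* LPs run on an in-package two-phase bounded-variable simplex (the only
  LP routine available in the target environment proved unreliable on
  rank-deficient flux systems); every analysis built on it is tested
  against brute-force vertex enumeration.  MOMA uses the dual active-set
  QP solver with an LP variability presolve to remove the degeneracy
  knockouts create.
* The reference-state LP phases add a whisker of slack (≤ $10^{-7}$
  relative, only on numerical failure) when re-imposing values that are
  themselves LP optima.

## Known limitations

Binding order is the declared stoichiometric order (random-order and
ping-pong mechanisms are not implemented); transcriptional regulation is
out of scope; substrate uptake is an input, not a prediction; yields of
designs with more than three bounded interventions are resolved only
approximately; and apparent constants extracted with regulators at
reference levels approximate, not equal, what in vitro tables report.
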