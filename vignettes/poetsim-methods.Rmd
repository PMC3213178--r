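---
title: "Ensemble modeling of insulin-induced translation initiation: models, estimation and interrogation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble modeling of insulin-induced translation initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(poetsim)
```

# The modeling problem

Insulin signals reach the translation machinery through a cascade —
receptor activation, the IRS-1 adaptor, PI3K-generated PIP3 opposed by
PTEN, Akt, inhibition of the TSC1/2 GAP, Rheb-GTP activation of mTORC1,
S6K1, and phosphorylation of 4E-BP1 that liberates eIF4E for cap-dependent
assembly of the 80S ribosome. Which of these components actually *control*
initiation, basally and under insulin, is not obvious from the wiring
alone. poetsim treats the question the way ensemble modeling does: encode
the wiring as a mass-action kinetic model, estimate not one parameter set
but a *population* of sets consistent with heterogeneous training data,
and then interrogate that population with sensitivity and knockdown
analyses so that conclusions are claims about the network, not about one
arbitrary parameterization.

# The model class

A network is a list of species and irreversible mass-action reactions.
With stoichiometric matrix $S$ (species $\times$ reactions) the dynamics
are

$$\frac{dx}{dt} = S\, r(x, k), \qquad
  r_j(x, k) = k_j \prod_{s \in \mathrm{reactants}(j)} x_s^{\sigma_{sj}},$$

where the kinetic exponent is the reactant stoichiometric coefficient
(also for coefficients above one — a literal mass-action reading).
Reversible reactions are split into independent forward and reverse
irreversible steps before simulation, so every rate constant is a separate
unknown. The unknown-parameter vector is the concatenation of rate
constants and initial conditions, in network order. Compartments are
treated as unit volume: the SBML subset we read does not carry reliable
volume semantics, and rescaling rates by volumes we cannot verify would
corrupt the rate law. Rates, the Jacobian $\partial(Sr)/\partial x$ and
the parameter-derivative matrix $\partial(Sr)/\partial k$ are evaluated
analytically in compiled code; integration uses `deSolve::lsoda` (stiff,
with the analytical Jacobian), relative/absolute tolerances $10^{-6}$ /
$10^{-9}$ by default.

Simulated experiments are *protocols*: optional structural perturbations
(species knockdowns, zeroed rate constants standing in for small-molecule
inhibitors such as wortmannin or rapamycin), pre-equilibration to steady
state, then a stimulus issued by *adding* ligand to the steady state —
the ligand is subsequently consumed by mass action, not clamped, because
ligand depletion is part of the model. Steady state is detected by
integrating over windows of length $\Delta t$ (default 1 min,
configurable; only detection granularity depends on it) until the norm of
the state change between successive window endpoints falls below
$\varepsilon = 0.001$; the norm is Euclidean by default (a max-norm
option exists), and the choice is recorded with the result. Knockdowns
remove the node from the stoichiometric matrix — every reaction touching
the species is deleted and its initial condition zeroed — rather than
merely zeroing the species, so synthesis reactions cannot regenerate it.

# Scoring against immunoblot-style data

Training data are band intensities in arbitrary units, so the model is
trained on *shape*, not scale: measurement and simulated readout (the sum
of the species mapped to a blot band) are min-max scaled independently to
$[0,1]$ within each objective, then compared by the sum of squared
differences over the objective's time points, or across condition bars
for single-time comparisons. A constant series maps to all zeros (flat
basal controls are legitimate data, not errors). The simulation is
interpolated linearly to the measurement times; solver output is dense
enough that the interpolation choice is inconsequential. Scaled error is
invariant to positive affine transforms of either side — that is the
point of the scaling, and it is what lets data from different cell lines
and exposure settings coexist in one training set. The flip side, which
matters for interpretation below, is that parameter *scale* is only
weakly identified: many parameter directions move simulated curves
without changing their shapes.

# POETs: multiobjective annealed ensemble estimation

Candidates are scored on all training objectives simultaneously. A
candidate's fitness is its Fonseca–Fleming Pareto rank — the number of
archived error vectors that dominate it (rank 0 = nondominated) — and it
is accepted with probability $\exp(-\mathrm{rank}/T)$. Accepted
candidates join the archive; ranks are updated incrementally so stored
ranks always equal a from-scratch dominance count. The temperature is
discretized into 10 quanta walked from $T_0$ (default 10) to $T_f$
(default 0.1); we space the quanta geometrically, since a fixed 0.9
cooling ratio cannot connect those two endpoints in ten steps, and we
advance the quantum with both the iteration count and an epoch counter
incremented per 100 accepted members. New candidates come from
multiplicative perturbation — each parameter times a uniform factor in
$[1-m, 1+m]$, $m = 0.25$ by default, initial conditions included unless
frozen — and a local pattern search (coordinate-wise multiply/divide
polling that accepts only improvements and shrinks its step on failure)
is interleaved every 10 acceptances on one randomly chosen objective. All
of these constants are explicit `poets_config()` keys and are stored with
every archive.

Two properties of this scheme at desk scale are worth knowing. First,
with ~20 objectives dominance is rare, so most members are rank 0 and the
annealing pressure is weak; the search behaves largely as a constrained
random walk plus pattern-search pull. Second, the uniform multiplicative
factor has negative mean in log space, so long accepted chains drift
downward in parameter magnitude. Both effects are properties of the
algorithm itself, and both are the reason the sub-ensemble *selection*
step matters.

Cross-validation is leave-three-out: 24 objectives partition into eight
folds of 21 training and 3 validation objectives; each fold runs an
independent POETs instance and validation errors are computed post hoc.
The sub-ensemble used for interrogation is drawn per fold from the rank-0
members: candidates are first restricted to the lowest-error fraction
(error-norm quantile 0.15 by default) and then chosen greedy-randomly to
minimize mean pairwise Pearson correlation of log-transformed
rate-constant profiles, with the Euclidean error norm as a tie-breaking
term. Correlation is computed on log constants because the parameters
span decades; untransformed correlation would be dominated by the largest
ones. The achieved mean pairwise correlation is reported (0.5-0.7 on
the synthetic study, where the per-parameter coefficients of variation of
the selected members are of order one — the data constrain shapes, not
scales).

# Sensitivity analysis and fragility ranking

First-order sensitivities $s_j = \partial x/\partial k_j$ solve
$\dot s_j = J s_j + b_j$ with $s_j(0) = 0$, integrated alongside the
states from the stimulated state, with $J$ and $b_j$ evaluated
analytically. Raw sensitivities are made dimensionless as log
sensitivities $(k_j / x_i)\, s_{ij}$, the concentration guarded by
$\max(x_i, 10^{-6})$ to tolerate zero concentrations, and time-averaged
with the trapezoid rule over a window (full horizon, or an early window
such as 0–5 min to isolate transient control). Per-member matrices are
assembled into a parameters $\times$ (members $\cdot$ species) array and
decomposed by SVD. Within each singular vector of the largest $k$
singular values (default: the vectors capturing 95% of spectral energy;
no canonical count exists), indices with coefficient
magnitude above a threshold are marked, and a species' or reaction's
score is the fraction of the $k$ vectors in which it occurs; the ranking
is deterministic given the array, invariant to member order, and each
species score carries a standard error across members. Reaction-axis
scores are additionally mapped to species by giving each species the
maximum score over reactions it participates in (a convention, recorded
as such).

The absolute threshold 0.001 is the right default at the scale the
procedure was designed for (hundreds of species, unit-norm vectors with
thousands of entries). On a ~30-species toy, however, nearly every
*involved* coefficient of a unit-norm vector exceeds 0.001, and every
score saturates at 1 — the instrument stops discriminating. For
toy-scale work the package therefore offers a relative mode,
$|c| > \theta \cdot \max|c|$ within each vector (we use $\theta = 0.05$
in the tests), which restores the intended reading — "this index
contributes materially to this principal direction" — at small dimension.
The exported score is the raw fraction, with no further
normalization.

# Robustness analysis by knockdown screening

The robustness coefficient of a perturbation is the ratio of the
trapezoid-integrated marker concentration (default marker: the assembled
80S proxy) in the perturbed versus nominal simulation over the protocol
horizon: $>1$ increased, $=1$ untouched, $<1$ decreased. The screen
crosses ensemble members $\times$ knockdown targets $\times$ conditions,
flags failed cells rather than aborting, aggregates by the member
*median* (robust to the qualitatively different subpopulations that
ensembles genuinely contain), and classifies each target as increase
($m > 1+\delta$), none ($|m-1| \le \delta$), moderate decrease, or severe
decrease ($m \le c_{sev}$, closed boundary). The cutoffs
$\delta = 0.1$ and $c_{sev} = 0.25$ are package conventions — the
four-way scheme is inherited, the numeric cutoffs are not recoverable —
and they are printed in every report header. Subpopulation reports expose
raw counts at several fold-change cutoffs (above 1, below 1, at least
two-fold either way) rather than hardcoding a significance threshold, and
a convergence report re-derives categories over nested member subsets
(50/100/200/all) and flags targets whose category flips.

# The synthetic study system

`build_toy_insulin_network()` is a 29-species, 34-reaction reduction of
the insulin initiation pathway with every motif the analyses exercise:
ligand consumption, basal PI3K tone, PTEN opposition, dual Akt activation
(PIP3 and mTORC2), TSC1/2 inhibition, Rheb cycling whose GTP loading
drains a finite GTP pool with synthesis and degradation, mTORC1- and
mTORC2-driven 4E-BP1 phosphorylation, tight eIF4E sequestration, and 80S
assembly consuming GTP (second order in GTP, so GTP availability is a
genuine axis of control). Rate constants were hand-tuned once to place
the model in the regime the biology describes and then frozen; tests
never regenerate them. In that regime the frozen truth reproduces the
qualitative switch structure: PTEN knockdown raises basal initiation;
PI3K knockdown under insulin lowers initiation to roughly 60% without
abolishing it; Rheb knockdown lowers initiation nominally, but in the
`strong_rheb_gtp` variant (Rheb-GTP association raised so cycling starves
the GTP pool) the same knockdown *raises* initiation by releasing GTP —
the bottleneck-relief mechanism behind paradoxical knockdown responses;
and removing the S6K1 to IRS-1 feedback raises the sensitivity scores of
the PI3K axis.

Training objectives emulate a literature-compiled immunoblot
training table structurally: 20
time-course objectives (four phospho/assembly readouts under five
conditions, seven time points over 100 min) plus 4 condition-bar
objectives (each readout across all six conditions at 60 min), 24 in
all. Raw values are simulated readouts times lognormal noise with
coefficient of variation 0.10 — a typical densitometry quantitation
error; the noise model is multiplicative because blot intensities are.
What the generator does *not* emulate: antibody saturation and blot
nonlinearity, between-lab systematic shifts beyond affine ones, missing
time points, or cell-line-specific wiring differences. Passing the
recovery tests therefore shows the estimation and interrogation machinery
is sound, not that real immunoblot panels of this size identify real
networks.

`random_network()` supplies seeded random mass-action networks (optionally
closed, i.e. count-conserving) for property tests: derivative oracles,
non-negativity, mass conservation, and integrator cross-checks.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline at
desk scale: two of the eight cross-validation folds, 600 POETs
iterations per fold, 50 sub-ensemble members per fold, 10 random control
sets, and 20-member knockdown screens. These sizes are the package's
choices for a single-workstation study; all are configuration keys and
scale up unchanged. Other numerical conventions: trajectories are
clipped to zero only on output (tiny negative excursions within solver
tolerance; the raw minimum is retained as an attribute); the sensitivity
system is integrated by lsoda on the augmented equations; SVD rank
requests beyond the matrix rank are clamped with a warning; a boundary
median exactly at $c_{sev}$ classifies as severe (documented tie-break);
and seeded runs are exactly reproducible, with the seed and a
configuration hash stored in every archive, ensemble file and manifest.

# Known limitations

Min-max training leaves parameter scale weakly identified, so ensembles
constrain shapes and relative orderings, not rate constants individually
— the per-parameter coefficients of variation near one are a feature of
the problem, not a failure of the search. The annealing fitness loses
selectivity as objective count grows (dominance becomes rare), which the
low-error restriction in sub-ensemble selection compensates. Sensitivity
conclusions are first-order and local, sampled over an uncorrelated
member family rather than globally. The SBML reader deliberately covers
only the pure mass-action subset and errors on anything else. Delay,
stochastic and spatial formulations are out of scope, as are
dose-response partial knockdowns and double-knockdown combinatorics.
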