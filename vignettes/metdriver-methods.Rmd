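---
title: "Models and methods behind metdriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metdriver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metdriver)
```

`metdriver` implements a two-step discovery pipeline for metabolic
tumor-suppressor candidates: a genomic screen followed by a
constraint-based metabolic transformation search. This vignette explains
the underlying models, every tunable parameter that matters, the
numerical conventions, and what the synthetic benchmarks do and do not
demonstrate.

## The constraint-based model

A metabolic network with $m$ metabolites and $n$ reactions is
represented by its stoichiometric matrix $S \in \mathbb{R}^{m\times n}$.
A *feasible steady-state flux distribution* is any $v$ with

$$ S\,v = 0, \qquad v_{\min} \le v \le v_{\max}. $$

Exchange reactions are written as "metabolite $\rightarrow$", so
negative flux is uptake and positive flux secretion; a growth medium is
a set of uptake/secretion bounds on exchanges, with every exchange the
medium does not mention closed to uptake. Gene–protein–reaction (GPR)
rules are Boolean AND/OR expressions; a knockout turns its gene FALSE
and blocks (bounds $(0,0)$) every reaction whose rule evaluates FALSE.
Expression is propagated to reactions by the usual algebra — min over
AND branches, max over OR branches.

Two deliberate conventions:

* **Finite bounds.** Unbounded reactions in external files are capped at
  $\pm 1000$ flux units at load time, so every optimisation runs over a
  bounded polytope and "unbounded objective" cannot arise.
* **Unique FBA representative.** LP optima are usually degenerate.
  After the optimum $f^\*$ is found, the returned flux vector is the
  *minimum-Euclidean-norm* point of the optimal face. Because that
  projection is strictly convex its solution is unique, which makes
  every downstream computation reproducible without reference to solver
  internals. (An $\ell_1$ secondary stage was considered and rejected:
  it is itself an LP and can remain degenerate.)

### How the optimisation layer works

All computations reduce to linear programs over the flux polytope or to
strictly convex quadratic programs (projections). The QP primitive is
the dual active-set method of `quadprog`; variables pinned by
$lb_i = ub_i$ are eliminated before the solve, and feasibility probes
retry from several targets because a dual active-set start far from a
degenerate region can fail spuriously. LPs are solved *through* the QP
primitive: feasibility of $\{S v = 0,\; bounds,\; c^\top v \ge \theta\}$
is decided by a projection, and bisection on $\theta$ brackets the
optimum to a relative tolerance of $10^{-8}$. On models with tens of
reactions the ~40 probes per LP are cheap, and the scheme inherits the
numerical robustness of the QP code. Every flux vector returned by any
function passes a shared validator
($\|S v\|_\infty \le 10^{-6}$, bounds within $10^{-6}$).

The two mixed-integer problems (iMAT, the transformation search) are
solved by depth-first branch-and-bound over their binary indicators.
Nodes are pruned by (a) infeasibility of the partial assignment and
(b) an admissible bound: the relaxation objective can only get worse as
more constraints are forced, so `bound = alpha * (k + remaining) -
(1 - alpha) * relaxed_stay_term` dominates every completion. Search
order and tie-breaks are fixed, so results are deterministic.

## Context-specific states

**GIMME** minimises $\sum_r w_r |v_r|$ with $w_r = \max(0, t - e_r)$
over reactions whose GPR-mapped expression $e_r$ falls below a threshold
$t$, subject to the objective keeping at least a fraction of its
optimum. Absolute values are linearised by flux splitting
($v = v^+ - v^-$). Defaults: $t$ = 25th percentile of the profile
(configurable as an absolute value), objective fraction 0.9. Both are
conventions from the GIMME literature; the method's sources do not fix
them. A context in which the objective optimum is zero is rejected —
there is no functionality to protect.

**iMAT** discretises reactions into high/low/moderate (gene calls at
mean $\pm$ 0.5 sd of the profile, mapped through the GPR) and maximises
the number of satisfied calls: a high reaction should carry
$|v| \ge \varepsilon_{act}$ (default 1) in either direction, a low
reaction should carry none. The returned flux is the minimal-norm point
of the best region, and the agreement score is exact (verified against
exhaustive enumeration in the test suite).

**Sampling.** The flux polytope is explored by hit-and-run in the null
space of $S$, restricted to non-fixed coordinates. Directions are drawn
in a space scaled by each reaction's *effective* flux range (computed by
per-reaction LPs), not its declared bounds — otherwise dimensions whose
reachable range is far narrower than their box (context bands,
obligatory fluxes) throttle the step size and the walk mixes poorly.
The chain starts from the projection of the range midpoints, uses
burn-in 100 and thinning 5, and is seeded; identical seeds give
identical draws. No claim of exact uniformity is made — the sampler is a
reproducible explorer of the constrained space, which is what the
downstream rank-sum comparisons need.

**Context restriction.** Downstream analyses restrict a model to an
expression context by confining each below-threshold (GIMME) or
low-called (iMAT) reaction to a band of $|v^{ctx}_r| + 0.1$ around its
inferred context flux. This is a linearisation of "lowly expressed
reactions stay lowly active" that keeps the sampled region a box-bounded
polytope.

## The transformation search

Given matched source (healthy) and target (tumor) expression, reactions
are partitioned by the expression change:

* with replicates: two-sided rank-sum per gene, BH-corrected at 0.05,
  direction by median difference;
* with single paired profiles: $|\log_2 \mathrm{FC}| \ge 1$, with a
  moderating pseudo-count of 0.5 so near-silent genes do not produce
  spurious infinite fold changes.

Up-called genes push their reactions into $R_F$ (required flux
increase), down-called into $R_B$; conflicting calls on one reaction —
e.g. one isozyme up, the other down — leave it in $R_S$.

For a candidate knockout the search maximises

$$ \alpha \sum_{i \in R_F \cup R_B} b_i \;-\; (1-\alpha)
   \sum_{i \in R_S} (v_i - v^{ref}_i)^2 $$

over the knocked-out polytope, where $b_i = 1$ forces
$v_i \ge v^{ref}_i + \varepsilon$ (for $R_F$) or
$v_i \le v^{ref}_i - \varepsilon$ (for $R_B$). Defaults:
$\varepsilon = 0.1$ flux units, $\alpha = 0.66$ — conventions, flagged
as such. The stay-term QP carries a tiny ridge ($10^{-6}$) on the
non-$R_S$ coordinates so it remains strictly convex; the ridge is
subtracted from the node bound before pruning, so optimality is not
affected beyond that slack.

Scoring is deliberately a *second* step: the integer objective cannot
distinguish a barely-$\varepsilon$ change from genuine rewiring, so the
success sets are re-derived from the achieved fluxes and the
transformation score

$$ TS = \frac{\sum_{R_{success}} |\Delta v| -
              \sum_{R_{unsuccess}} |\Delta v|}
             {\sum_{R_S} |\Delta v|} $$

is computed from $v^{res}$. Degenerate-denominator policy: below
$10^{-9}$ the denominator is replaced by $10^{-9}$ and the score capped
at $\pm 10^9$; if the numerator is also below $10^{-9}$ the score is 0,
so a null perturbation scores exactly 0. A Euclidean variant (squared
differences) is exercised in the tests and places the implanted driver
in the same top-20% bucket. Knockouts that make the model infeasible
receive $TS = -10^9$ and rank last. Rankings sort by TS with
lexicographic tie-breaks and always include the control.

**OTS aggregation.** Per pair $j$, $I_{ij} = 1$ iff candidate $i$
*strictly* beats the control (ties are failures), and $P_j$ is the
fraction of candidates beating the control. $OTS(i) = \sum_j I_{ij}(1 -
P_j)$: pairs in which few candidates score weigh more. $P$ must be a
fraction for $1 - P$ to stay in $[0,1]$; a raw count — the other reading
of the source description — would make the weight negative, so the
fraction is implemented. The candidate universe per pair is all model
genes with at least one reaction, keeping $P$ comparable across pairs.
Genes inherit the maximum over their reactions' scores; datasets are
summed with absent genes contributing 0.

## The genomic screen

* Rank-sum screens use the normal approximation with continuity
  correction (`exact = FALSE`) — the standard choice for genome-scale
  screens where ties are ubiquitous — and BH correction (the
  copy-number step's Q-values imply an FDR-style correction).
* Kaplan–Meier ΔAUC integrates both survival step functions to a common
  horizon, by default the smaller of the two bins' last observed times
  so neither curve is extrapolated; an explicit `horizon` argument is
  available when a fixed follow-up window is wanted. The median split
  assigns ties at the median to the low bin (deterministic); a
  top-vs-bottom-quartile mode is also provided.
* Quantile normalization replaces each sample's values rank-wise by a
  sorted reference distribution (ties receive the average of the tied
  reference values); the reference defaults to the per-gene mean across
  samples and is idempotent by construction.

## MOMA-based phenotype analyses

MOMA predicts the post-perturbation state as the Euclidean projection
of a reference flux onto the perturbed region; infeasibility is an
error, never a "large distance". In the knockdown/overexpression
comparison, the biomass floor (80% of the optimum, modeling
proliferating cells) constrains only the *sampled wild-type states*;
the MOMA projections after the perturbation are free to lose biomass —
a strong knockout legitimately drops below the floor, and forcing it
would misreport such knockouts as infeasible. Overexpression is
simulated by raising the gene's reaction lower bounds to 80% of their
flux-variability maximum, the maximum being taken within the
biomass-constrained wild-type region.

In the stage-specific analysis both the per-sample states and the
advanced-stage target are inferred on the *knocked-out* model — the
question is how close each sample's post-knockout state comes to the
advanced-stage state, so the comparison must live on the same network.
Each sample's state is the mean of sampled points in its knocked-out
context region (with the same proliferation floor), and its distance to
the target is the squared Euclidean adjustment between the two states.

The binomial benchmark statistic is provided in both point-mass and
upper-tail form; the two differ by about 12% at 13 successes of 19
trials with rate 0.2, and both are exposed so users can choose the
reading they need.

## Synthetic data: what it shows and what it does not

`make_toy_model()` builds a branched network — glucose uptake,
glycolysis, an efficient oxidative route (gene `gDRV`) versus
fermentative branches that secrete lactate, a biomass sink, and inert
side modules. The driver implant rests on one structural idea: the
oxidative reaction carries an *obligatory minimum flux* just under the
full pyruvate supply, so epsilon-scale rerouting into the fermentative
branches is infeasible for the unperturbed model, and only the driver's
knockout can light them up. This is exactly the situation the
transformation search is designed to detect, and it gives the benchmark
a true positive with known mechanism, surrounded by negative controls
(isozyme pairs whose single knockouts are buffered, genes on
freely-varying or permanently blocked reactions, and lethal knockouts).

Expression is emulated as GPR-propagated absolute flux plus Gaussian
noise (sd 0.2 expression units by default, against signal separations of
5–20 units), with the knocked-down driver pinned at a floor of 0.05 —
chosen so the state-inference engines can in principle invert the map.
Cohorts implant a −3 sd expression shift, a single-copy loss in 60% of
tumors and a hazard ratio of 2 for low driver expression, with
exponential survival times, uniform censoring over a 2500-day horizon
and a baseline median survival of 1000 days; tumor/normal counts default
to 272/42, the scale of the motivating cohort.

Passing these benchmarks shows the machinery is correct and the
implanted signal recoverable. It does **not** show performance on real
tumor cohorts: the toys have no batch effects, no correlated
covariates, no isoform structure, no CN segmentation, and networks of
~14 reactions rather than thousands. Headline numbers tied to
genome-scale models and real cohorts (candidate-table contents,
pathway-level p-values on real data) are out of reach at this scale and
are not asserted anywhere.

## Problem sizes and runtime

The test-suite and acceptance computations use toy networks of 13–18
reactions, 1 matched pair per seeded dataset (20 seeds for recovery
rates), cohorts of 30–100 tumors and 2,000 null genes for screen
calibration, and 40–100 sampled flux states per arm — sizes at which
the exhaustive oracles (vertex enumeration for FBA, full enumeration of
activation patterns and success subsets for the integer programs)
remain computable, so every optimiser is checked against an independent
ground truth rather than against itself.

## Known limitations

* The MIQP/MILP branch-and-bound targets tens of integer variables; a
  genome-scale model with thousands of called reactions would need a
  commercial MIP solver behind the same interfaces.
* The hit-and-run sampler is a reproducible explorer, not a certified
  uniform sampler; inferences drawn from it are rank-based
  comparisons, which are robust to its residual autocorrelation.
* The SBML reader covers Level 3 + FBC v2 as produced by this package
  and by common COBRA exports; exotic SBML constructs (species
  references with non-constant stoichiometry, multiple objectives) are
  out of scope.
* No thermodynamic/loopless constraints, no gap-filling, no
  overexpression-search variant of the transformation algorithm —
  identifying genes whose *overexpression* transforms remains open.
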