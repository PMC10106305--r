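---
title: "Methods: causal discovery and effect estimation for longitudinal clinical outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal discovery and effect estimation for longitudinal clinical outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalpaths)
```

## The problem

Given a subject-by-variable table of clinical measures taken at treatment
entry (baseline) and at follow-up (here, six months), we want to know which
variables plausibly *cause* later social and occupational functioning, not
merely predict it. `causalpaths` answers this with a hybrid causal-discovery
search that outputs a partial ancestral graph (PAG), followed by a linear SEM
fit that attaches effect sizes to the discovered structure, resampling-based
stability checks, and pathway/cycle reports.

## Model and assumptions

The data model throughout is linear-Gaussian and recursive: each variable is
a linear function of its direct causes plus independent Gaussian noise, with
possible unmeasured common causes. The search assumes:

* **Causal Markov + faithfulness.** Conditional independences in the
  population are exactly those implied by d-separation in the generating
  graph. Faithfulness can fail numerically when multiple paths nearly cancel;
  see *Limitations*.
* **No selection bias.** Sampling does not condition on effects; accordingly
  the selection-bias orientation rules (R5–R7) are omitted and undirected
  selection marks are not produced.
* **Acyclicity within a timepoint.** Synchronous causal cycles cannot be
  represented; cross-timepoint feedback is reported instead via the rolled
  cycle view (A causes B at baseline, B causes A over the follow-up window).
* **Temporal tiers.** Follow-up variables cannot cause baseline variables,
  and explicitly listed variables (e.g. age) cannot be caused at all. Tier
  knowledge contributes arrowheads: a forbidden cause X of Y receives an
  arrowhead at X's end of the X–Y edge (X is not an ancestor of Y). It never
  contributes tails, because a tail would additionally rule out latent
  confounding, which temporal order alone cannot.

## The two-stage search

**Stage 1 — greedy equivalence search.** `fges_search()` searches CPDAG
space with a forward phase of single-edge insertions and a backward phase of
deletions, using the standard validity conditions (clique and blocked
semidirected-path tests for inserts, clique tests for deletes). The score is
the decomposable penalised Gaussian likelihood

\[ S(y \mid pa) = -n \log \hat\sigma^2_{y|pa} - c\,(|pa|+1)\log n, \]

with penalty discount \(c\) (default 1). Constant terms are dropped — they
cancel in every score difference the search consults. After each operator the
graph is re-completed: a consistent DAG extension is computed (Dor–Tarsi),
v-structures are re-oriented, and the Meek rules plus knowledge-forced
orientations are closed to fixpoint. Ties between candidate operators are
broken toward the lexicographically smallest (source, target) pair in input
column order, making the search deterministic.

**Stage 2 — latent-admitting refinement.** `gfci()` takes the stage-1
adjacencies and prunes them with Fisher-Z conditional-independence tests:
conditioning sets are drawn from the adjacency sets of both endpoints in
increasing size, then from each endpoint's Possible-D-Sep set. The first
independence found (p-value above `alpha`) removes the edge and records the
separating set. The pruned skeleton is re-oriented from scratch: every
endpoint reset to a circle; unshielded colliders oriented from recorded
separating sets (falling back to stage-1 colliders for pairs that were never
adjacent after stage 1); background-knowledge arrowheads; then FCI rules
R1–R4 and R8–R10 to fixpoint. Orientation conflicts — possible in finite
samples — keep the first-applied mark and are logged on the result's
`conflicts` attribute.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.01 | Fisher-Z significance level for stage-2 pruning (the reference configuration for this analysis family). |
| `penalty_discount` | 1 | Multiplier \(c\) on the BIC complexity penalty; larger values yield sparser stage-1 graphs. |
| `max_cond_size` | unlimited | Cap on conditioning-set size during adjacency pruning. Unlimited is affordable at desk scale (tens of variables); a cap trades completeness for speed. |
| `pdsep_max` | unlimited | Same cap for the Possible-D-Sep stage. |

Both defaults are the conventional settings for Gaussian clinical data of a
few hundred subjects; `alpha` trades false adjacency removals (too large)
against false retentions (too small).

## Effect-size estimation

`pag_to_sem()` maps the PAG to a linear SEM: fully directed edges become free
regression paths; every edge with a circle endpoint, and bidirected edges,
become free covariances between the two variables' disturbances — a possible
latent common cause licenses covariation but no direction, so no directional
claim is estimated for such edges. Every variable receives a free residual
variance. `fit_sem()` minimises the ML discrepancy

\[ F(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S\,\Sigma(\theta)^{-1}) - \log|S| - p \]

with \(\Sigma(\theta) = (I-B)^{-1}\Psi(I-B)^{-\top}\), by BFGS with an
analytic gradient; start values are equation-wise OLS estimates and sample
variances; convergence is declared at a relative change of \(10^{-9}\) in
\(F\) (at most 10,000 iterations). The test statistic is \(\chi^2 = (n-1)F\)
(Wishart convention; the convention only rescales \(\chi^2\) by \((n-1)/n\)
and every reported index is computed under the same one). Mean structure is
omitted — only the covariance matrix enters. Standard errors come from the
numerically differentiated Hessian of \(F\) scaled by \(2/(n-1)\);
standardized estimates use model-implied variances.

Fit indices follow the usual definitions:
CFI \(= 1 - \max(\chi^2_m - df_m, 0)/\max(\chi^2_b - df_b,\ \chi^2_m - df_m,\ 0)\)
against the independence baseline, and
RMSEA \(= \sqrt{\max(\chi^2_m - df_m, 0)/(df_m\,(n-1))}\), reported as 0 with
a saturation flag when \(df_m = 0\). `compare_nested()` performs the
likelihood-ratio difference test and refuses non-nested inputs.

A consequence worth knowing: when many edges are circle-marked, the
SEM models only *pairwise* disturbance covariances, so covariation that the
true structure transmits along chains (e.g. between two baseline composites
linked only through a third) is unmodelled and absolute fit indices can be
mediocre even though the PAG is correct. The coefficient-recovery experiments
therefore fit the fully directed generating structure, where a correctly
specified model attains CFI ≥ 0.99 and RMSEA ≤ 0.01 at large n.

## The synthetic-data generator

`simulation_spec()` defines a linear-Gaussian recursive system (nodes with
latent flags and timepoint tags, coefficient-weighted edges, per-node noise
SDs); `simulate()` samples it in topological order. Noise streams are keyed
by sorted node name so the joint distribution is invariant to declaration
order, and identical `(spec, seed)` yield identical data.

`build_published_model()` hard-codes the nine-variable functional-outcome
system with the reported raw effect sizes as coefficients: NegSx_BL → SaC_BL
(−0.27), SaC_BL → Mot_BL (0.77), Mot_BL → SF_BL (1.5), Mot_BL → OF_BL (0.96),
SF_BL → SF_6M (0.6), OF_BL → OF_6M (0.36), SF_6M → Mot_6M (0.21), Mot_6M →
OF_6M (0.92), Mot_6M → SaC_6M (0.24). Where the source's pathway narrative
and its rolled-graph annotation disagree slightly (0.77 vs 0.76, 1.5 vs 1.4,
0.21 vs 0.22), the pathway values are used, once, throughout. Disturbances
are unit-variance Gaussians: residual variances and raw variable scales are
not published, and every recovery experiment in this package is invariant to
that choice because the generating coefficients are refit on the simulated
scale. `random_model()` draws benchmark DAGs (uniform random order, edge
probability `expected_degree/(p−1)`, coefficients uniform on ±[0.3, 1],
optional latents with at least two observed children).

What the generator deliberately does **not** emulate: non-Gaussian or
heavy-tailed clinical score distributions, floor/ceiling effects and
discreteness of rating scales, missingness mechanisms, measurement error, or
synchronous feedback. Passing recovery tests on this generator therefore
demonstrates correctness of the algorithms under their stated assumptions,
not robustness of the scientific conclusions to violations of those
assumptions in real cohort data.

## Preprocessing conventions

Composite variables are aggregated across their source items *before* any
transform. Motivation and socio-affective composites use the **sum** of their
scale items (the usual subscale-construction convention when item sets are
fixed); the cognition composite uses the **mean** of the six domain z-scores,
which is how that composite is defined. Skewed duration variables use the
natural log (the base is a labelling choice; it rescales coefficients but not
test decisions). Binary covariates are passed through as 0/1 codes and enter
the Gaussian machinery as continuous columns — a single-pipeline convention
for mixed clinical tables. Filtering is strictly complete-case
(`complete_case_filter()`), with the excluded count reported; no imputation.

## Stability analysis

`resample_stability()` re-runs the entire discovery pipeline on jackknifed
(⌊frac·n⌋ rows without replacement, default frac = 0.9, floor rounding) or
bootstrapped (n rows with replacement) datasets and tallies per-feature
agreement with the reference PAG: adjacency presence, adjacency absence, and
endpoint-exact orientation. "Confirmed" is reported both strictly (both
endpoint marks equal) and leniently (adjacency only), because a single edge
can be stable in presence while its marks fluctuate. Per-replicate seeds are
derived from the master seed by counter, so results are independent of
execution order; replicate failures are excluded from the denominator and
counted. Both per-edge and per-feature aggregate summaries are emitted.

## Numerical choices and degenerate inputs

* Scores and tests run on sufficient statistics (covariance, n), so large-n
  analyses cost no more than small-n once the covariance is computed.
* A zero residual variance marks a local score degenerate (−∞); the search
  never selects such a move. Singular covariance sub-matrices make a CI test
  uninformative: the pruning step skips the removal rather than guessing.
* Duplicated or collinear columns, empty tables and constant columns are
  rejected with typed errors before the search starts.
* Edge-list text I/O round-trips PAGs losslessly; GraphML and DOT are
  export-only views with endpoint marks as attributes.

## Design choices that were genuinely open

* **Score constant convention.** Only score *differences* drive the search,
  so the per-parameter count `(|pa|+1)` and the dropped constants are one of
  several equivalent conventions; the chosen one preserves all differences.
* **Collider fallback.** For unshielded triples whose endpoints were never
  adjacent after stage 1, no separating set is recorded; the stage-1
  pattern's colliders are trusted instead of re-running a test search. This
  matches the hybrid algorithm's published design and keeps stage 2
  deterministic.
* **Conflict policy.** First-applied orientation wins and the conflict is
  logged; at the sample sizes studied, conflicts are rare and inspection of
  the log is preferable to silent overwriting.
* **Pathway semantics.** Reported causal pathways traverse only fully
  directed edges. Paths through circle-marked edges are enumerated separately
  as possible-causal and never merged, since a circle withholds exactly the
  ancestral claim a causal path asserts.
* **Rolled-cycle pairing.** Baseline/follow-up variable pairs are declared
  explicitly in the config rather than inferred from name suffixes, because
  naming conventions differ across instruments and cohorts.

## Problem sizes used by the test suite

The suite exercises: coefficient recovery and structure recovery at
n = 100,000 on the nine-variable published system; greedy-vs-exhaustive
oracle agreement on 200 random 3–4-node systems at n = 5,000; latent-pair
orientation over 100 replicates at n = 100,000; Fisher-Z calibration over
1,000 replicates at n = 500; and jackknife stability with 100 replicates at
n = 276 (the motivating study's cohort size), scaled from the 1,000
replicates a full analysis would use. These sizes keep each property
statistically decisive while the whole suite remains a desk-scale run.

## Limitations

* **Near-unfaithful systems.** With random ±[0.3, 1] coefficients, a
  substantial fraction of benchmark draws contain path cancellations whose
  population partial correlations fall below the detection limit of the
  Fisher-Z test at n = 100,000 (|r| ≈ 0.008 at α = 0.01). On such systems a
  true edge can be pruned or a stage-1 misorientation can survive, and *no*
  method based on the same tests could do better. The soundness property
  test screens benchmark systems for detectability through the implied
  covariance before asserting orientation correctness; real-data analyses
  have no such guarantee.
* **Orientation completeness.** The rule set (colliders, R1–R4, R8–R10) is
  sound; without the selection-bias rules the output is not guaranteed to be
  arrow-complete in every exotic configuration. In practice the circle marks
  that remain are the honest statement of what the data do not determine.
* **Gaussian likelihood throughout.** Heavily skewed or discrete variables
  are transformed or passed through; rank-based or mixed-likelihood tests are
  out of scope.
* **Single-shot model selection.** The SEM is fit to the single discovered
  PAG; model-averaging across the resampled graphs is deliberately not done
  (the stability report is the intended uncertainty summary).
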