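---
title: "Methods: mixed-type symptom-biomarker networks in bridgenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-type symptom-biomarker networks in bridgenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bridgenet)
```

bridgenet estimates and stress-tests regularized partial-correlation
networks over the kind of mixed clinical data collected in psychiatric
emergency settings: ordinal symptom ratings (24 HAMD items scored 0-4),
binary suicidality self-reports (current suicidal ideation, plan, attempt),
and continuous stress-axis biomarkers (ACTH in pg/ml, cortisol-type
measures in nmol/L). This vignette documents the statistical model behind
each stage, the tunable parameters and their defaults, the numerical
choices, and what the synthetic validation cohort does and does not show
about real data.

## The measurement and dependence model

All variables are modelled as manifestations of a latent multivariate
Gaussian $Z \sim N(0, \Sigma)$. Ordinal items arise by discretising a
latent dimension at increasing thresholds $\tau_1 < \dots < \tau_K$;
binary items are the one-threshold special case; biomarkers are strictly
increasing transforms (lognormal) of their latent coordinate. Conditional
dependence lives in the precision matrix $\Theta = \Sigma^{-1}$: the edge
weight between nodes $i$ and $j$ is the partial correlation

$$\omega_{ij} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\,\Theta_{jj}}},$$

zero exactly when the two variables are conditionally independent given
the rest. This latent-Gaussian view is what justifies feeding polychoric
correlations into a Gaussian graphical model (GGM).

## Stage 1: mixed-type correlations

`mixed_cor()` dispatches pairwise by variable type:

* ordinal x ordinal (and anything involving a binary variable, treated as
  a 2-category ordinal): two-step **polychoric** correlation. Thresholds
  are set to inverse-normal CDF values of the cumulative marginal
  proportions; $\rho$ then maximises the bivariate-normal contingency
  likelihood by bounded one-dimensional optimisation on
  $(-0.999, 0.999)$ with tolerance $10^{-6}$. The 2x2 case is the
  tetrachoric correlation, by the same code path.
* ordinal x continuous: two-step **polyserial** (continuous variable
  standardised, conditional ordinal likelihood maximised over $\rho$).
* continuous x continuous: Pearson.

Two-step rather than joint-ML estimation is the standard choice at
cohort-scale $n$; the threshold estimates are consistent and the
conditional optimisation is fast and stable. Bivariate-normal rectangle
probabilities are computed from a 64-point Gauss-Legendre quadrature of
the single-integral CDF representation (absolute error well under
$10^{-8}$ across the usable $\rho$ range; cells are floored at
$10^{-12}$ before logging). Biomarkers enter untransformed by default;
`rank_transform = TRUE` replaces continuous columns by normal scores
(a nonparanormal-style pre-transform) for users worried about marginal
non-normality — results in this package's own validation are insensitive
to the switch because the generator's biomarkers are exactly lognormal.

Pairwise polychoric matrices need not be jointly positive semi-definite.
`nearest_psd()` clips eigenvalues at a floor ($10^{-6}$), reconstructs,
rescales to unit diagonal, and iterates that clip-and-rescale to a fixed
point; it leaves PSD inputs untouched.

Complete-case analysis is used throughout: the resampling and permutation
machinery re-estimates the network thousands of times, which is
incompatible with multiple imputation, so rows with any missing analysis
variable are dropped (and counted) at load time.

## Stage 2: EBIC graphical lasso

`glasso_fit()` maximises the penalised Gaussian log-likelihood

$$\log\det\Theta - \operatorname{tr}(S\Theta)
  - \sum_{i \ne j} \lambda_{ij} |\Theta_{ij}|$$

by block coordinate descent (the diagonal is never penalised), declaring
convergence when the duality gap
$|\operatorname{tr}(S\Theta) + \lambda\lVert\Theta\rVert_{1,\text{off}} - p|$
drops below `tol` (default $10^{-4}$). At $\lambda = 0$ the solver
reproduces matrix inversion; at
$\lambda \ge \max_{i<j}|S_{ij}|$ the solution is exactly diagonal — both
ends are asserted in the test suite.

`ebic_glasso()` fits a logarithmic path of 100 penalties from
$\lambda_{\max}$ down to $0.01\,\lambda_{\max}$ (warm-started) and picks
the model minimising the Extended Bayesian Information Criterion

$$\mathrm{EBIC}_\gamma = -2\,\ell + E \log n + 4 E \gamma \log p,
\qquad \ell = \tfrac{n}{2}\left(\log\det\Theta -
\operatorname{tr}(S\Theta)\right),$$

with $E$ the number of non-zero off-diagonal pairs and $\gamma = 0.5$ by
default (the conservative community standard). Ties break toward the
larger penalty. $n$ is the number of rows used for the correlation
matrix, with no pairwise-$n$ correction.

**Decoupled refits.** Scoring the *penalised* fits couples selection to
shrinkage: to keep strong edges close to their unpenalised size the path
must descend far enough that small spurious edges slip in, and in our
calibration runs (10-node chain, true partials 0.3, $n = 2000$) the
selected model carried 2-7 tiny extra edges. bridgenet therefore scores
each distinct support found on the path by refitting the GGM with that
support fixed and no shrinkage (the constrained MLE, obtained from the
same solver via an effectively infinite off-support penalty) and computes
the EBIC on the refit. This decoupled selection recovers the chain with
at most one spurious edge in every calibration seed, and the reported
weights are the refit's unshrunken partial correlations. Set
`refit = FALSE` for the plain path-EBIC behaviour.

## Stage 3: centrality, bridges, flow

For a weighted network $W$ with communities $c(\cdot)$:

* **strength** $\sum_j |w_{ij}|$ and one-step **expected influence (EI)**
  $\sum_j w_{ij}$. On all-positive networks the two coincide; EI is the
  headline index because it keeps the sign information. The one-step
  form (direct edges only) is used.
* **bridge EI** $\sum_{j : c(j) \neq c(i)} w_{ij}$: the signed weight a
  node sends outside its own community — the quantity that identifies
  symptoms or biomarkers linking the depression, suicidality and
  biomarker communities.
* **betweenness** on distances $d_{ij} = 1/|w_{ij}|$ over non-zero
  edges (the convention of the reference network-psychometrics tooling;
  stronger associations are shorter). Ties in path length share credit
  fractionally, which removes any dependence on enumeration order;
  disconnected pairs contribute nothing.
* **predictive betweenness** for a focal node (ACTH by default): for
  each other node $v$, the fractional count of shortest paths anchored at
  the focal node that pass through $v$. Shortest-path machinery is
  delegated to igraph; a brute-force path-enumeration oracle in the test
  suite checks both measures exactly on all networks up to 7 nodes.
* `flow_edges()` gives the focal node's direct neighbours ordered by
  absolute weight, plus the indirectly-reachable and unreachable sets —
  the tabular content of a flow diagram.

Centrality tables carry raw and z-scored columns; z-scoring is for
display and never feeds back into computation.

## Stage 4: bootstrap accuracy and stability

`bootstrap_network()` resamples rows with replacement and re-runs the
entire pipeline (correlations, EBIC glasso, centralities) per replicate;
edge weights get 2.5/97.5% quantile intervals, and
`edge_difference_test()` declares two edges different when the bootstrap
interval of their difference excludes zero. Replicates whose estimation
fails are dropped and counted rather than imputed, so instability stays
visible.

`case_dropping()` implements the case-dropping subset bootstrap: at each
drop proportion $q$ it retains $\lceil (1-q) n\rceil$ rows without
replacement and correlates subset centralities with the full-sample ones.
The **CS-coefficient** is the largest $q$ — the grid runs to 0.75 —
such that at every proportion up to $q$ at least 95% of subsamples
correlate at least 0.7 with the full sample. The 0.7/0.95 convention is
fixed as the ecosystem standard. The contiguous ("at every proportion up
to $q$") reading is deliberate: it makes the statistic monotone in both
tuning constants, which is also property-tested. Published reports
sometimes attach a confidence interval to the CS-coefficient; no standard
construction exists, so bridgenet reports the per-proportion pass rates
(`tidy()` on the result) and leaves interval summaries to the reader.

`bootstrap_predictive_betweenness()` summarises the focal-node measure
across replicates (point value, median, 2.5/97.5% quantiles per node) and
can reuse the replicate networks of an existing `bootstrap_network()`
run, which is how `run_study()` avoids paying for the bootstrap twice.

Every bootstrap routine draws one sub-seed per replicate up front from
its master seed, so results are bit-reproducible and independent of
execution order (parallel schedulers included, though the shipped code is
serial).

## Stage 5: permutation network comparison

`nct()` compares the networks of two subgroups (gender in the reference
design). Group labels are permuted over the pooled rows with group sizes
preserved; both networks are re-estimated per permutation. Two global
statistics are computed: **M**, the maximum absolute edge-weight
difference (structure invariance), and **S**, the absolute difference in
global strength $\sum_{i<j} |w_{ij}|$. The naming follows the reference
test's convention; because published prose occasionally attaches the
labels the other way round, both statistics are always reported side by
side. P-values use the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$, so they
are never zero at finite permutations. Per-edge permutation tests run on
every edge non-zero in at least one observed network, Holm-adjusted by
default. Pooled rows keep their input order, so with equal group sizes
the p-values are exactly invariant to swapping the labels.

## The synthetic cohort generator

Because the motivating study deposits no participant-level data, the
package ships a generator whose defaults emulate the study's structure,
and all end-to-end validation runs against it:

* `make_ground_truth()` builds a precision matrix with a requested sparse
  partial-correlation support. Positive-definiteness is enforced by a
  diagonal shift $\delta$, doubled from $10^{-3}$ until the smallest
  eigenvalue exceeds $10^{-6}$ — simple and reproducible; the shift
  slightly attenuates requested weights but never changes the support.
* `generate_cohort()` samples latents from the implied Gaussian and maps
  them to observables: a latent-Gaussian copula, i.e. exactly the
  mechanism the polychoric model assumes, which is what makes parameter
  recovery a well-posed test rather than a robustness claim.
* `study_truth()`/`simulate_study_cohort()` fix the defaults to the
  study conditions: $n = 898$; 24 ordinal HAMD items (shared thresholds
  0.25, 1.10, 1.90, 2.60, putting the mean HAMD-24 total near 13.9);
  binary thresholds from the reported prevalences 31.2%, 30.4%, 30.62%;
  lognormal biomarkers matching the reported means/SDs (ACTH 31.84/28.77
  pg/ml, Cort 16.68/11.41 nmol/L — lognormality itself is an assumption,
  the study reports no distributional form); a gender column at 41%
  male, matching the reported composition; and designated edges mirroring
  the qualitative findings (insomnia items as the strongest depressive
  edge, suicide attempt-plan as the strongest suicidality edge, Cort as
  the leading bridge and strongest ACTH neighbour, HAMD3 tied to SI). The
  ground truth includes HAMD3 as a 29th node so that the default network
  after the HAMD3 exclusion has 28 nodes while the inclusion total still
  uses all 24 items.

What passing tests on this cohort show: the estimators recover the
structure they assume, at the study's scale, under the documented seeds.
What they do not show: robustness to non-Gaussian latent dependence,
informative missingness, longitudinal carry-over, item-content semantics,
or assay noise — none of which the generator models.

## The orchestrated study run

`run_study()` chains load/simulate, the HAMD-24 $\ge 8$ inclusion rule
(computed over all 24 items; the HAMD3 exclusion applies only to network
nodes), node selection, correlations, EBIC glasso, centralities,
strongest edges, the ACTH flow view, the bootstrap pair, case-dropping
with CS, and the optional gender comparison. A single master seed is
expanded (via one `sample.int` draw per stage) into per-stage seeds that
are recorded in the report, so any stage can be reproduced in isolation
and two runs under one master seed serialise to byte-identical JSON.

Default replicate counts follow the reference analysis ($B = 1000$
bootstrap iterations, 1000 permutations, 50 subsamples per drop
proportion). The shipped test suite and the acceptance script scale these
down (e.g. $B = 200$, 25 subsamples per proportion, 100 permutations, or
less in pure determinism checks) — sizes chosen so the full validation
runs comfortably on a laptop core while leaving every qualitative
conclusion unchanged; the counts are recorded in each result object.

## Numerical choices and degenerate inputs

* Optimisation bound $|\rho| \le 0.999$: self-correlations and
  empty-cell-dominated tables estimate at the bound and set an
  `at_bound` flag instead of failing.
* A single-category ordinal column, a zero-variance continuous column, a
  missing community label, an unknown focal node, or a grouping column
  without exactly two levels each fail fast with the offending column or
  node named.
* Case-dropping proportions whose subsets would leave $n \le p$ are
  skipped with a warning rather than estimated.
* Edge rankings break absolute-weight ties by the lexicographic node
  pair, making exports deterministic.
* Wald binomial intervals are the default for prevalence because they
  reproduce the published intervals exactly at $n = 898$ (truncated to
  $[0, 1]$, reported in percent to two decimals); Wilson intervals are
  available via `method = "wilson"`.

## Known limitations

* The mixed GGM treats discretised and transformed variables through one
  latent correlation matrix; type-specific conditional models (mixed
  graphical models) are out of scope.
* Polychoric estimation here has no FIML/missing-data variant.
* The NCT implementation covers structure, global strength and per-edge
  invariance for two groups; centrality-invariance subtests, paired
  designs and $>2$ groups are not implemented.
* CS-coefficients are reported on the fixed 0.05-0.75 grid; a value of
  0.75 means "stable up to the largest tested proportion", not an
  extrapolation beyond it.
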