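---
title: "Building a common IRT metric for physical-function PROMs: models, decisions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a common IRT metric for physical-function PROMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Physical function is routinely measured with different patient-reported
outcome measures (PROMs) in different registries and trials.  Summed scores
from different questionnaires are not comparable: the same patient obtains
different totals depending on how hard the items happen to be.  `promlink`
implements the full workflow for putting the items of many PROMs on one
latent scale so that scores estimated from *any* calibrated subset of items
are directly comparable: assumption checks, concurrent item calibration
across linked datasets, linking of externally calibrated instruments,
standardized scoring, and validation that scores from different instruments
agree.

Because registry data of this kind cannot be redistributed, the package
ships a synthetic-data generator (`sim_spec()`, `generate_link_design()`,
`generate_bank()`, `simulate_responses()`) that reproduces the *structure*
of a multi-registry calibration study, and every stage of the pipeline is
exercised against it.

## The measurement model

Item responses are ordered categories $x \in \{0, \dots, m_j\}$.  The
generalized partial credit model (GPCM) gives

$$P(X_j = k \mid \theta) =
  \frac{\exp \sum_{v=1}^{k} a_j (\theta - b_{jv})}
       {\sum_{c=0}^{m_j} \exp \sum_{v=1}^{c} a_j (\theta - b_{jv})},$$

with discrimination $a_j > 0$ and step difficulties $b_{j1}, \dots,
b_{jm_j}$ (not necessarily ordered; steps are stored in step order and never
silently sorted).  The partial credit model (PCM) is the constraint
$a_j = 1$ for all items.  `gpcm_probs()`, `expected_score()`,
`item_information()` and `scale_characteristic()` are the core primitives;
`invert_scc()` turns a scale characteristic curve into a summed-score
crosswalk.

## Concurrent calibration

All datasets are stacked into one persons-by-items matrix with items not
administered in a person's dataset set missing (`concurrent_calibrate()`).
Identification comes from anchor items shared between datasets; the
package verifies that the dataset/item graph is connected and refuses to
calibrate otherwise.  Estimation is marginal maximum likelihood by EM over
a quadrature grid, with a separate normal latent distribution per dataset.
The reference dataset (the first) is fixed at $N(0, 1)$; the remaining
means and SDs are re-estimated each cycle.

Numerical choices (the source material is silent on all of them):

* **Grid**: 61 equally spaced nodes on $[-8, 8]$ — wide enough to cover
  every realistic group distribution; both are configurable
  (`calib_opts()`, `quad_grid()`).
* **M-step**: per-item maximization of the expected complete-data
  likelihood with analytic gradients (`L-BFGS-B` on $\log a$ and $b$),
  with box bounds $a \in [0.05, 5]$, $b \in [-10, 10]$.  The bounds keep
  quasi-deterministic items from running away and are far outside any
  plausible estimate.
* **Convergence**: absolute log-likelihood change below `tol` (default
  `1e-5`, 500 cycles maximum).  The EM log-likelihood is checked to be
  nondecreasing every cycle; replicated simulation tests use `tol = 1e-3`,
  which leaves parameter error entirely dominated by sampling noise.
* **Group SDs** are floored at 0.05 to prevent degenerate collapse.

`compare_models()` performs the PCM-vs-GPCM likelihood-ratio test and AIC
comparison; the identity $\Delta_{AIC} = LR - 2\,df$ is asserted in the
tests.

## Item fit and DIF screening

`lm_dif_test()` and `item_fit_lm()` implement a score-type
observed-versus-expected contrast.  For each item, each person's expected
item score and its variance are computed under the posterior given the
*rest* of the response pattern (the item's own response is removed).  This
matters: with the item left in, its response contaminates its own
expectation and the statistic is wildly anti-conservative — in our null
simulations every item came out "significant".  With the rest-pattern form
the null behaves as intended.

Cells are groups crossed with EAP bins (DIF: person groups, 4 bins within
each; item fit: 4 equal-count rest-EAP intervals).  The statistic is
$\sum_{cells} (O - E)^2 / V$ with a $\chi^2$ reference on cells $-$ 1
degrees of freedom.  The effect size `ES_DIF` is the size-weighted mean
absolute observed$-$expected gap in the most deviant group, divided by the
item's score range.  An item is flagged only when the test is significant
*and* `ES_DIF` exceeds 0.05 — pure significance flags essentially
everything at registry sample sizes.

Flagged items get group-specific parameters via
`assign_group_parameters()`: the focal group's responses are split into a
virtual item, the model is refit, and the estimates are folded back as
subgroup overrides, which also removes the item from the focal group's
anchor set.

**A calibration fact worth knowing**: in a concurrent calibration the
pooled item estimate absorbs part of any DIF.  With a 50/50 focal/reference
split, half of an injected 0.5-logit shift disappears into the pooled
estimate and `ES_DIF` lands near 0.035 — below the screen.  The package's
DIF validation world therefore uses a minority focal registry (1000 focal
vs 3000 pooled reference persons), the situation in which DIF screening is
actually informative (and the one that occurs in practice, where a single
registry deviates from the pool).  There, power at $\delta = 0.5$ is
$\approx$ 0.9 with a false-flag rate of essentially zero.

## Local dependence

`q3_matrix()` computes Yen's Q3: residuals $x_{ij} - T_j(\hat\theta_i)$
(EAP point estimates) correlated across items over pairwise-complete
persons, flagging $|Q3| > 0.25$ ($0.25^2 = 6.25\%$ shared residual
variance).  No bias correction is applied; note that raw Q3 has a known
negative bias of roughly $-1/(J-1)$ under local independence, so the 0.25
cutoff is conservative for short tests.

The testlet validation world deserves a comment.  Local dependence is
injected as $\theta_{\mathrm{eff}} = \theta + \gamma u$ with a shared
$u \sim N(0,1)$ per testlet.  For moderate items (4 categories,
$a \approx 1$), $\gamma = 0.8$ produces within-testlet Q3 of only
$\approx 0.09$ — the weak item transmits little of the testlet factor, and
no sample size changes that.  Near-duplicate physical-function items (the
kind that actually produce LD flags: walking distances, stairs) are highly
discriminating; PROMIS physical-function discriminations commonly run
2-4.  The LD world therefore uses 5-category items with
$a \sim \mathrm{lognormal}(\log 2, 0.2)$, where $\gamma = 0.8$ yields
within-testlet Q3 of 0.45-0.55 and a null pair flag rate of zero.

## Linking an external instrument

`stocking_lord()` finds $(A, B)$ minimizing the weighted squared distance
between the target scale characteristic curve of the common items and the
transformed source curve ($a^* = a/A$, $b^* = A b + B$), integrating over
the reference-population density on the grid (weights configurable),
optimized from a $3 \times 3$ multistart.  `apply_transform()` applies the
coefficients to a whole bank, subgroup overrides included.  The invariance
$SCC(\theta; \mathrm{bank}) = SCC(A\theta + B; \mathrm{transformed})$
holds to machine precision and is asserted.

In noisy validation (two independent calibrations of $n = 1000$ samples,
10 common items), the recovered coefficients have RMSE $\approx 0.06$
around the generating $(A, B)$.  A per-replicate $\pm 0.1$ guarantee is not
achievable at that $n$ — the shift estimate alone inherits
$\sigma/\sqrt{n} \approx 0.04$ from the source sample mean — so the
package's acceptance test asserts RMSE $\le 0.1$ over 20 replicates.

## The standardized metric

EAP scores (`eap_score()`, `eap_scores()`) use a standard-normal prior by
default.  The reporting metric is $S = 10(\theta - \theta_0)$: 10 points
per logit, with origin $\theta_0$ placed where every instrument's expected
*mean* item score has essentially reached its floor
(`locate_metric_origin()`).  An exactly zero expected score is attained
only asymptotically, so the origin uses a tolerance of 0.01 score units —
the largest grid value at which the worst instrument's mean expected item
score is still below it.  The origin is a bank attribute frozen at
calibration time (`set_metric_origin()`); crosswalk tables
(`crosswalk_table()`) carry summed score, $\theta$, and standardized score.
For very flat instruments ($a \approx 0.5$) the 0.01 floor may be
unattainable on $[-8, 8]$; the origin then falls back to the grid floor
with a warning.

## Reliability and congruence

* `marginal_reliability()`: $\mathrm{var}(\hat\theta) /
  (\mathrm{var}(\hat\theta) + \overline{se^2})$.
* `conditional_reliability()`: $CR(\theta) = I(\theta)/(I(\theta)+1)$,
  with the standardized-metric range where $CR > 0.70$.
* `glb_reliability()`: greatest lower bound approximated by iterated
  factor-analytic communality substitution on the covariance diagonal —
  not the exact SDP-based GLB, but it reproduces $\alpha$ exactly for
  parallel items and dominates $\alpha$ in simulation, which is the
  property that matters for its use as a summed-score reliability floor.
* `score_correlations()`: observed-vs-EAP correlations per scale, and
  between-scale summed correlations with shared items excluded from the
  larger member of any overlapping pair (any overlap triggers exclusion; a
  correction formula for *fully nested* short forms is not implemented —
  such cells are labelled `nested` and left blank).
* `congruence_report()`: per-instrument standardized EAP means/SDs and
  0-100 rescaled summed scores, all pairwise *paired* t-tests (the same
  persons answer all instruments) with Bonferroni divisor equal to the
  number of pairs per scoring method, and paired Cohen's $d$ (mean
  difference over the SD of differences — the denominator matching the
  paired test).  On a well-linked metric the IRT-score $|d|$ stays below
  0.20 even when disjoint item difficulty ranges push the summed-score
  $|d|$ far above 0.50; the acceptance tests reproduce exactly this
  dissociation.

## Dimensionality and monotonicity screens

`mixed_correlation_matrix()` estimates polychoric (two-step ML with normal
thresholds; empty cells get a 0.5 continuity correction), polyserial, or
Pearson correlations depending on whether each item has more than 10
response options (items beyond 10 options are treated as continuous).  The
bivariate normal CDF uses fixed-order Gauss-Legendre quadrature with an
interval split around the inner transition for strong correlations.
Non-convergent cells fall back to Pearson with a log entry.

`hierarchical_omega_ecv()` extracts (default) 3 factors by maximum
likelihood (`factanal`; minres fallback), rotates with promax, fits one
second-order factor to the factor correlations, and applies the
Schmid-Leiman orthogonalization.  It reports
$\omega_h = (\sum g_i)^2 / \mathbf{1}' R \mathbf{1}$ and
$ECV = \sum g_i^2 \big/ (\sum g_i^2 + \sum \lambda_{group}^2)$, with
per-group-factor ECVs.  The screening rule is $\omega_h \ge 0.70$ *and*
$ECV \ge 0.60$.  Degenerate structures are handled explicitly: factors
with sum-of-squares loadings below 0.1 are dropped and the solution
re-extracted (a truly unidimensional matrix then yields $ECV = 1$ rather
than noise factors), and with orthogonal factors the general factor is
null, so the negative control gives $ECV = 0$ — failing the cutoff, as it
should.  This EFA-based screen deliberately replaces a weighted-least-
squares confirmatory factor analysis with CFI/TLI/RMSEA, which would
require an external estimator; the omega/ECV rule is the screen that
drives the unidimensionality decision here.

`monotonicity_curves()` smooths each item's score against its rest score
(Nadaraya-Watson, Gaussian kernel) and flags any smooth that decreases by
more than 0.05 score units.  Two implementation details depart from the
naive recipe, both for false-alarm control on *cleanly monotone* data:
the bandwidth is twice Silverman's rule (the density rule-of-thumb
undersmooths a regression curve; at $n = 2000$ it leaves noise wiggles of
the same order as the tolerance), and the smooth is evaluated only over
the central 99% of the rest-score distribution (boundary estimates rest on
a handful of persons).  With these choices the false-flag rate on
simulated GPCM data is zero across seeds while reversed-coded items are
always caught.

## What the generator does and does not emulate

`sim_spec()` defaults describe a plausible multi-registry study: six
registries of 1000 respondents each administering two to four of six
instruments (one global anchor), eight 4-category items per instrument,
lognormal discriminations ($e^{N(0, 0.25^2)}$), item locations uniform on
$[-2, 2]$ logits, registry latent means between $-0.4$ and $0.8$ and SDs
between 0.8 and 1.2.  Optional ingredients: uniform DIF on chosen items
(shifted steps in a focal registry), testlet factors, MCAR missingness on
top of the by-design missingness, and sparse extreme categories (handled
by `collapse_sparse_categories()`, which merges categories with fewer than
20 responses toward the scale interior).

Not emulated: nonuniform DIF (discrimination shifts), MNAR missingness,
longitudinal structure, multidimensionality beyond testlets, and real
response styles.  A green end-to-end test therefore establishes that the
*machinery* is correct under the model's own assumptions — not that any
particular real dataset satisfies them; the diagnostic modules exist
precisely to check those assumptions on real data.

## Known limitations

* Standard errors for item parameters are not computed (`se_table` is
  `NULL`); parameter uncertainty must come from replication.
* The exact (SDP) greatest lower bound and Levy's nested-short-form
  correlation correction are not implemented.
* Run configurations are JSON only.
* Q3 is reported raw, without small-test bias correction.
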