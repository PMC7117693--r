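---
title: "Detecting differential item functioning in a binary deprivation questionnaire"
author: "epicesdif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential item functioning in a binary deprivation questionnaire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

EPICES is a French questionnaire that measures *precariousness* — socio-economic
instability short of poverty — with 11 binary yes/no items, combined into a
weighted sum score on a 0–100 scale (cut-offs 30.17 and 48.5 categorise
respondents as precarious). When such a score is compared across populations
(geographical areas, genders, age bands), the comparison is only valid if each
item works the same way in every group. An item that is systematically easier
or less discriminating in one group at the *same* underlying deprivation level
exhibits **differential item functioning (DIF)** — the classic example being
home-ownership, which signals a different level of deprivation in rural and
urban settings. DIF must be carefully separated from **impact**, a true
between-group difference in the latent trait distribution, which is not a
defect of the instrument.

This package implements the full analysis workflow for this question: an item
response theory (IRT) measurement model, condition checks, a
regression-based DIF screen with effect-size grading, an assessment of the
practical consequences of detected DIF, and classical companions (Cronbach's
alpha, a rotated multiple correspondence analysis). Because the motivating
cohort's individual-level data are not publicly deposited, the package ships a
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes, so every stage is testable end to end.

## The measurement model

Binary items under the graded response model reduce to the two-parameter
logistic (2PL):

$$P(y_{ij} = 1 \mid \theta_i) = \operatorname{logistic}\{a_j(\theta_i - b_j)\},$$

where $\theta_i$ is respondent $i$'s latent trait, $b_j$ is item $j$'s
*difficulty* (the trait level at which a "yes" has probability one half) and
$a_j > 0$ its *slope* or discriminating capacity. The latent trait is oriented
so that **higher $\theta$ means lower precariousness**; consequently the
score–trait correlations reported later are negative by construction. Items 1
(meeting a social worker) and 5 (financial difficulties) are worded so that
"yes" indicates *higher* precariousness; they are reversed before any
model-based analysis (`reverse_items()`), while descriptive endorsement tables
deliberately keep the raw coding.

`fit_grm()` estimates $(a_j, b_j)$ by marginal maximum likelihood: an EM
algorithm with Gauss–Hermite quadrature (49 nodes by default) under a fixed
Normal(0, 1) latent prior, which is the identification constraint. The M-step
is a weighted logistic regression of expected node-level response counts on
the node locations. The marginal log-likelihood is tracked and must be
non-decreasing; convergence is declared when it changes by less than `tol`
(default $10^{-4}$), and non-convergence is flagged, never silent. Slopes are
bounded to $[0.05, 10]$ and difficulties to $[-6, 6]$ to stabilise
near-degenerate items; an activation of these bounds is recorded on the item
(in practice it occurs only for pathological items such as a near-duplicate of
another item). `eap_scores()` returns the posterior mean (EAP) and SD of
$\theta$ per respondent on a 101-node grid. The estimation machinery is not
prescribed by the analysis design it follows — EM with fixed-prior quadrature
is simply the standard choice and was validated against dense-grid integration
(agreement to $10^{-4}$).

## Condition checks

Three IRT conditions are screened by `irt_diagnostics()`:

* **Item fit**: infit and outfit mean squares of the standardized residuals
  $z_{ij} = (y_{ij} - P_{ij})/\sqrt{P_{ij}(1 - P_{ij})}$ evaluated at the EAP
  estimates, with the conventional 0.7–1.3 acceptance band. Because residuals
  are computed at *estimated* (shrunken) trait values, mean squares sit
  slightly below 1 on well-fitting data — the statistics are conservative in
  the misfit direction, and strongly over-discriminating items can dip below
  the band's lower edge without indicating a modelling problem.
* **Unidimensionality**: eigenvalues of the residual correlation matrix. Pure
  noise gives eigenvalues near 1; the configurable verdict (first eigenvalue
  below twice the second, by default) codifies the qualitative "no dominant
  residual component" judgement.
* **Local independence**: Spearman correlations between residual columns,
  flagged at $|r| \ge 0.4$ (the level conventionally called strong),
  optionally per group. For each flagged pair the later-indexed item is
  recommended for removal — the rule that, applied to the questionnaire's
  near-duplicate final pair ("could someone give you shelter" / "could someone
  give material assistance"), drops item 11 and keeps item 10. After removal
  the diagnostics are re-run; the maximum off-diagonal residual correlation
  must decrease.

## The DIF screen

`detect_dif()` implements the hybrid (ordinal) logistic regression procedure:
the IRT-based EAP score is the conditioning variable in three nested logistic
models per item and group pair —

* M1 (no DIF): $\operatorname{logit} P(y=1) = \beta_0 + \beta_1\hat\theta$
* M2 (uniform DIF): adds a group main effect
* M3 (non-uniform DIF): adds the $\hat\theta\times$group interaction.

With binary items the ordinal logistic reduces to binary logistic regression;
the interface is written so ordinal items can slot in later. Likelihood-ratio
tests at $\alpha = 0.01$ judge significance and McFadden pseudo-$R^2$
differences grade magnitude: below 0.035 *negligible*, from 0.035 up to 0.07
*moderate*, 0.07 and above *important* (boundary values land in the higher
band; values within $10^{-6}$ of a boundary are logged). Classification is
sequential: non-uniform DIF when the M3-vs-M2 test is significant (magnitude
from its $\Delta R^2$), else uniform when M2-vs-M1 is significant, else no
DIF with magnitude *not assessed*.

Two deliberate design choices:

* **The screening flag is the 2-df total test (M3 vs M1) at $\alpha$.** A
  union of the two sequential 1-df tests would have a false-positive rate of
  roughly $2\alpha$ per item under no DIF; the total test keeps the screen at
  its nominal level, which is the property the validity simulations verify.
  The sequential tests still drive the reported uniform/non-uniform
  classification, exactly as the publication-style output table presents them.
* **Purification defaults on**: after an initial pass, the trait is
  re-estimated from the currently unflagged (anchor) items and the screen is
  repeated until the flag set stabilises (at most `max_purify_iter` rounds).
  Both behaviours are exposed because the upstream methodology literature uses
  purification while individual applications often do not state it.

Multi-group covariates are analysed pairwise (e.g. the three area pairs), not
omnibus. Groups enter with treatment coding and the alphabetically first level
as reference; likelihood-ratio statistics and $\Delta R^2$ are invariant to
that choice, and to the orientation of $\hat\theta$ (both asserted in tests).
Quasi-perfect separation is detected via coefficient size and flagged
`unstable` rather than silently reported.

## Impact of DIF on the score

`theta_dif_aware()` re-estimates the trait letting DIF-flagged items carry
group-specific parameters in an anchored multi-group model: anchor items share
parameters and identify a common scale, the reference group's latent
distribution is fixed at Normal(0, 1), and the other groups' means and SDs are
estimated (standard anchor linking; the quadrature grid is fixed and equally
spaced so node locations do not move as group distributions update). Items
with *moderate or important* DIF are freed by default; a switch frees every
LRT-significant item instead. With no flagged items the procedure reduces
exactly to the single-group fit. `correlation_report()` then gives the three
Pearson correlations — sum score vs naive trait, sum score vs DIF-aware trait,
naive vs aware — that summarise whether detected DIF actually distorts
measurement. On the study-shaped cohort the naive and DIF-aware estimates
correlate above 0.99, echoing the motivating finding that the detected DIFs,
though real, do not upend the score.

## Classical companions

`cronbach_alpha()` uses the standard variance decomposition on
direction-aligned codes. `chi2_endorsement()` compares raw endorsement across
groups per item (Pearson chi-square, no continuity correction by default, at
$\alpha = 0.05$) for the descriptive table. `mca_fit()` performs
correspondence analysis of the complete disjunctive table (each item
contributing a yes and a no category); for complete binary data the total
inertia is exactly 1 and eigenvalue conservation is asserted to $10^{-8}$.
`rotate_mca()` applies a varimax rotation to the retained block (4 dimensions
by default, a scree-plot choice) of *weighted category loadings* — principal
coordinates scaled by the square root of the category mass, so that squared
column sums are the dimension variances. This is the natural representation
for a varimax-type rotation of MCA: the rotated block's total variance is
preserved to $10^{-8}$ and contributions remain normalised per dimension.
Item-level contributions aggregate an item's two categories (the aggregation
is not uniquely defined in the literature; the sum is the natural choice and
is what the contribution tables report, with entries below 0.2 blanked for
display only). Benzécri-adjusted inertia percentages are available behind a
flag; unadjusted percentages are the default.

## The synthetic cohort

`india_like_preset()` encodes the study conditions: three unbalanced area
groups of 496, 289 and 768 respondents (1,553 in total), 11 binary items, and
a generative 2PL process (logistic link without the 1.7 scaling constant,
matching the downstream logistic framework). Its components:

* **Difficulties** are calibrated by quadrature so that the DIF-free marginal
  yes-rates reproduce the published whole-sample endorsement percentages
  (9%–94% across items); this calibration is deterministic (root-finding, no
  simulation).
* **Slopes** are not identified by the endorsement margins and had to be set
  by judgement. Two published anchors pull in opposite directions: the
  observed Cronbach's alpha (0.54 on 10 items) implies low discrimination,
  while the strong published score–latent correlation (magnitude 0.84)
  implies an empirical reliability near 0.85. The preset uses slopes between
  1.0 and 2.2, matching the latter, because the real data's depressed alpha
  reflects multidimensional structure (the published MCA finds four
  subdimensions) that a unidimensional generator deliberately does not
  emulate. The preset's alpha (≈0.75) is therefore higher than the published
  one — a known, documented divergence, not a calibration error.
* **DIF** defaults mirror the headline area findings: a uniform difficulty
  shift for health insurance and financial difficulties in the French Guiana
  group and a halved slope for the social-worker item in the West Indies
  group. **Impact** defaults shift the area latent means (0.3 / −0.5 / −0.1),
  so the pipeline's ability to distinguish impact from DIF is exercised by
  default.
* **The near-duplicate pair**: item 11 copies item 10's answer with
  probability 0.93 and takes the opposite answer otherwise, so the pair's
  same-answer proportion equals 0.93 exactly — the published statistic for
  the two support items. (A variant that redraws the partner from its own
  response function cannot reproduce that statistic, because redrawing also
  produces agreement by chance; the copy-or-flip construction is used
  instead, and requires `copy_prob` ≥ 0.5.) Local dependence is thus
  simulated by response copying rather than a second latent factor — simpler,
  and it directly reproduces the observable quantity.

Generation is seed-deterministic (identical configurations give identical
cohorts). What the generator does **not** emulate: genuine
multidimensionality beyond the single dependent pair, missing-data
mechanisms, polytomous variants, and survey weighting. Passing tests
therefore demonstrate the pipeline's behaviour under its own assumptions, not
robustness to violations of them.

## Validity properties and the simulation studies

The package's central claims are verified by replicated simulation
(`dif_type1_study()`, `dif_power_study()`), at problem sizes chosen to give
tight binomial intervals while keeping a full run in minutes on one core:

* **Level**: 200 DIF-free two-group cohorts (300 per group, 10 items) give a
  per-item flag rate inside the exact central 95% binomial interval around
  $\alpha = 0.01$.
* **Impact robustness**: the same design with a 1-SD latent mean shift and no
  DIF. Here the method shows a *mild* true inflation (about 0.015–0.02 at
  nominal 0.01 across base seeds): EAP scores shrink toward the pooled mean,
  so at a fixed estimated trait the two groups differ slightly in their true
  trait, and a residual group signal leaks into the regression. This is an
  inherent short-test limitation of regression-based DIF methods, grows with
  impact and shrinks with test length. Conditioning on group-specific
  (multi-group) EAP estimates was evaluated and rejected: it embeds group
  membership in the conditioning score and inflates the rate by an order of
  magnitude. The honest statement is that at 10 items and 1 SD of impact the
  screen is approximately, not exactly, level-$\alpha$.
* **Power and classification**: a 1-logit difficulty offset on one item is
  detected through the uniform (M2-vs-M1) test and classified uniform in
  essentially all of 100 replicates at 500 per group; a doubled slope is
  detected through the non-uniform (M3-vs-M2) test and classified non-uniform
  in the large majority.
* **Parameter recovery**: at the study size (1,553 respondents, 10 items) the
  fitted slopes and difficulties recover the generating values with RMSE
  well under 0.25 (pre-registered from an 8-seed pilot whose worst observed
  RMSEs were 0.15 and 0.16), and the EAP estimates correlate with the true
  trait at about 0.85.

## Numerical choices and degenerate inputs

Probabilities are clamped at $10^{-12}$ (likelihood) and $10^{-10}$
(residuals) before logs; pattern likelihoods are computed with a row-max
shift. Constant items are refused by name in `fit_grm()` and `mca_fit()`;
zero-variance inputs are errors in `cronbach_alpha()` and
`correlation_report()`; an all-flagged item set (no anchors) is an error in
the multi-group fit; fewer than two groups, unknown covariates and
out-of-range item indices are errors at the point of entry. The EPICES item
weights are *not* shipped — they belong to the original validation
publication — so scoring uses a clearly-labelled equal-weight placeholder
(100/11 per item) unless a YAML configuration supplies the real ones; all
internal analyses use the placeholder.

## Known limitations

* The impact scenario's mild type-I inflation, discussed above.
* Fit statistics at EAP estimates are conservative; no bias-corrected (Q3)
  residual correlations or bootstrap intervals are provided.
* The binary-only GRM: polytomous categories are not implemented (the
  interfaces do not preclude them).
* No Monte-Carlo calibration of $\Delta R^2$ thresholds; the fixed 0.035/0.07
  bands are used as published.
* Synthetic validation only: no individual-level study data are distributed,
  so all empirical statements in this vignette are about the synthetic
  conditions the tests and the acceptance script actually compute.
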