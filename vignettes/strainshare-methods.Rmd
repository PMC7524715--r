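---
title: "Methods: models, parameters and design choices in strainshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in strainshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainshare)
```

`strainshare` implements the statistical backbone of a randomized,
double-blind, four-arm fermented-milk trial: Test or Control product at 1 or
3 bottles/day for four weeks, with visits at baseline (D0), during
consumption (D14, D28) and after washout (D56). This vignette documents the
models, their assumptions, the tunable parameters, and the choices made where
the design was genuinely open. Everything quantitative stated here is
computed by the package's test suite or by `scripts/acceptance.R`; nothing is
quoted from external analyses.

## Safety statistics

For binary safety endpoints (subjects with at least one adverse event), the
relative risk between Test and Control arms is reported with its 95%
confidence interval on the log scale (the Katz normal approximation):

$$\exp\!\left(\log\widehat{RR} \pm z_{0.975}
\sqrt{\tfrac{1-p_1}{n_1 p_1} + \tfrac{1-p_2}{n_2 p_2}}\right).$$

Among the candidate "normal approximation" constructions, only the log-scale
interval reproduces the published safety table's intervals from its printed
counts (e.g. 0.84 with CI 0.47–1.52 from 11/25 vs 12/23), which is why the
package treats it as the reference method; the plain-scale Wald interval
does not reproduce them. When either arm has zero events the ratio is
reported as undefined ("NA"), matching clinical-table convention, rather
than continuity-corrected. One published row (follow-up gastrointestinal
events at 3 bottles/day, printed lower bound 0.09) does not agree with the
Katz recomputation from its own printed counts (0.28); the suite asserts
this as a recorded mismatch rather than forcing agreement — we believe the
printed bound is a typographical error.

For quantitative endpoints, Cohen's *d* is the between-arm difference of
mean change from baseline divided by the pooled *baseline* standard
deviation, with |d| strictly above 0.5 flagged. Note the strictness: d =
0.5 exactly is not flagged.

## Rank tests

All group comparisons are two-sided and nonparametric. Mann–Whitney uses the
exact permutation distribution when both groups have at most eight
observations and no ties, otherwise the normal approximation with mid-rank
tie correction and continuity correction — the continuity correction is kept
on because the trial's arms are small (21–25 subjects). Kruskal–Wallis uses
the tie-corrected H statistic against a chi-square reference. Spearman's rho
is the Pearson correlation of mid-ranks with a t-approximation p value.
Multiplicity is controlled by Benjamini–Hochberg throughout. The choice of
exact-vs-approximate crossover and the continuity correction are ours; the
trial report does not state them.

## Strain tracking

Strain-specific qPCR levels (log10 gene copies/g feces) are summarized as
median and interquartile range, with quartiles by linear interpolation
between order statistics (the common scientific-software default; no rule is
stated in the trial report). Nondetects are left-censored at the limit of
detection and imputed at the LOD, which ties them at the floor: a rank test
only needs nondetects ordered below every detected value, and the suite
verifies that this imputation gives the same U statistic as any other
below-detection coding. Dose comparisons (Test 1 vs Test 3) are run per
strain and visit with BH adjustment across the whole family of tests
performed — the family definition is ours.

## Diversity

Alpha diversity is computed at genus level on per-sample relative
abundances; because the trial report does not name its metrics, the package
computes observed richness, Shannon entropy (nats) and Simpson (1 − Σp²) and
reports all three. Beta diversity offers Bray–Curtis, Jensen–Shannon
divergence (natural log, divergence not its square root), and unweighted and
weighted (normalized) UniFrac on a rooted newick tree. UniFrac is computed
by a single postorder accumulation of branch-subtended abundances and is
tested against a brute-force per-branch oracle to 1e-12.

Group screening uses Kruskal–Wallis. For beta diversity the test needs a
scalar per sample; we use each sample's median distance to all other
samples. This construction is an interpretation (the trial report applies
Kruskal–Wallis to beta diversity without stating the summary) and is flagged
as such in the output metadata.

The confirmation analysis uses centered log-ratio transformed abundances
(pseudocount of 1 count, mirroring the contribution module's pseudocount)
followed by centered PCA via singular value decomposition, with a
Mann–Whitney test per axis, BH-adjusted across axes.

## The longitudinal screen (ZIBR)

Relative abundances of a genus over subjects and visits are modeled in two
parts, each with a subject random intercept:

- presence: $\mathrm{logit}\,P(y_{ij} > 0) = x_{ij}^\top\alpha + b_i$,
  $b_i \sim N(0, \sigma_b^2)$, over all observations;
- abundance: $y_{ij} \mid y_{ij}>0 \sim \mathrm{Beta}(\mu_{ij}\phi,
  (1-\mu_{ij})\phi)$ with $\mathrm{logit}\,\mu_{ij} = x_{ij}^\top\gamma + d_i$,
  $d_i \sim N(0, \sigma_d^2)$, over the nonzero observations.

The parts are fit independently (conditional independence of the two random
intercepts), each by maximum likelihood with adaptive Gauss–Hermite
quadrature: the integrand is recentered at each subject's posterior mode
(found by a vectorized Newton iteration) and scaled by the local curvature,
with 10 nodes by default. Doubling the order changes converged
log-likelihoods by less than 1e-3, which is the basis for the default. The
optimizer is `nlminb` from a small set of starts (fixed-effect fits for the
coefficients, two spreads for the variance), with a restart polish; nested
fits warm-start from each other so a likelihood-ratio comparison never
straddles two local branches. The suite cross-checks the logistic part
against `lme4::glmer` (adaptive quadrature, agreeing to ~1e-3) and the beta
part against `glmmTMB` (Laplace; our quadrature attains at least its
likelihood), and the fixed-effect reduction against a directly optimized
beta regression to 1e-4.

Covariates encode the trial design: `consumption` is 1 for Test-arm samples
at D14/D28, and `dose` is bottles/day times that indicator, so the dose
coefficient is a per-bottle effect during consumption. Tests are joint
likelihood-ratio tests dropping a covariate from both parts (df = 2; df = 1
when a genus has no zeros and the presence part is skipped). Genera nonzero
in fewer than 10% of samples are excluded and reported. FDR families are
consumption tests across genera and dose tests across genera, separately;
classification at adjusted p < 0.05 yields consumption-only, dose-only,
both, or none. Whether the original analysis pooled Control arms or
contrasted per dose is unstated; the design matrix here includes all four
arms in one model, and the covariate coding is configurable through
`zibr_design()`.

Calibration, verified by the acceptance suite at the study scale (45
subjects, 4 visits): the joint test's type-I error at nominal 0.05 stays
within Monte-Carlo bounds over 200 null genera, and a planted consumption
effect of 1.0 on the beta-mean logit is recovered with small bias and
near-nominal 95% CI coverage over 100 replicates.

## Functional contribution

Gene counts are aggregated per KEGG ortholog (KO), once over all genes and
once over product-strain genes only. Because both "relative abundances"
share the whole-metagenome denominator, the contribution of the product
strains to KO *k* in a sample reduces to the pseudocounted count ratio
$(c^{\text{product}}_k + 1) / (c^{\text{total}}_k + 1) \in (0, 1]$. The
alternative reading (normalizing the strain-only profile within itself) is
unbounded and cannot produce "contribution up to 90%" semantics, so it was
rejected. The pseudocount is applied to both counts before the ratio; the
summarized score is the mean over a designated sample set (all samples by
default; typically Test-arm consumption samples in a real run). Both
placements are interpretations of an underspecified recipe and are
configurable.

The minimal-contribution baseline uses universal single-copy marker KOs:
carried once by every genome, their contribution estimates the strains'
abundance share alone. The default summary is the median of marker scores
(robust); `max` is available as the conservative option. The contributive
set is every KO *strictly* above the baseline — KOs exactly at it, including
markers, are excluded.

## Co-abundance network

MSP abundances are CLR-transformed (pseudocount 1) and a sparse network is
estimated by Meinshausen–Bühlmann neighborhood selection: a lasso per node
over a decreasing penalty grid, rather than a graphical lasso — the
neighborhood variant is the common default of sparse inverse-covariance
microbiome tools and is directly checkable against synthetic precision
graphs. The penalty is chosen by StARS: 20 random subsamples of 80% of
samples, edge-selection frequencies per penalty, mean edge instability
2θ(1−θ), monotonized from the sparse end by a running maximum, and the
densest graph whose monotonized instability stays ≤ 0.05 is kept. (A literal
"largest penalty with instability below threshold" rule would always return
the empty graph, since instability vanishes at the sparse end; the
monotonized rule is the standard resolution.) Edges are symmetrized by the
OR rule; the sign is the sign of the mean of the two directed coefficients —
both conventions are ours, as the source method leaves them open.

Geodesic distances from the product-species nodes are unweighted hop counts
(breadth-first), with unreachable nodes reported as infinite and excluded —
and counted — in the association step. The association between distance and
shared contributive-KO count is Spearman's rho with its t-approximation p,
computed over resident nodes at finite distance, optionally restricted to
positive-only or negative-only edges before the distance computation. The
published rho of −0.12 requires the original sequence data and is not
desk-reproducible; the suite instead verifies sign and significance on
constructed fixtures and null behavior on shuffled counts.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes with known ground
truth. Defaults mirror the trial design: four arms of 24 subjects, four
visits, 50 genera, multinomial counts at 10^5 (16S) and 10^6 (metagenome)
depth — fixed library sizes standing in for sequencing depth without
modeling reads. Planted genus effects (consumption 1.0 on the beta-mean
logit, 0.4 per bottle for dose, 1.0 on presence log-odds; 3 consumption-only,
3 dose-only and 6 both-responsive genera, matching the screen's reported
pattern) apply only at consumption visits; the presence-part effect follows
each taxon's response class (dose-responsive taxa shift in proportion to
bottles/day) so the two response types are identifiable. The multinomial
draw includes a background component (`genus_other`) absorbing the residual
community mass, with the modeled genera centered on ~30% of the community:
without that headroom, closure (renormalization to the simplex) would leak
the planted effects into every null genus and no screen could classify
correctly on the relative-abundance scale. The per-taxon baseline spread
(SD 0.6 on the logit) and beta precision (200) keep conditional abundances
away from the extreme left tail so that observed zeros come from the
presence part rather than from count discretization;
real genus profiles are more overdispersed than this, so passing tests
demonstrate correctness of the machinery, not robustness to every real-data
pathology.

The synthetic metagenome gives every genome the 31 markers exactly once;
product strains additionally carry a planted product-exclusive KO set (150
of 500 KOs by default), and all other KOs are resident-only. Under the
median baseline the 15 markers above their own median are unavoidably
"contributive"; with the default planted-set size this floor contributes at
most ~0.09 to the false-discovery proportion of the discovery set, which is
the regime the acceptance checks probe. Real strain repertoires also share
non-marker KOs with residents at intermediate prevalence; the generator
omits that gray zone deliberately, so contribution-recovery results bound
the clean-signal case.

MSP abundances are logistic-normal: latent Gaussians with a configured
sparse precision matrix (off-diagonals are negated partial correlations;
the diagonal is inflated to strict dominance, guaranteeing positive
definiteness), exponentiated, normalized and sampled to counts. Per-sample
library sizes are fixed; the trial's observed mean 16S depth is of the same
order, but the generators are not calibrated to its per-sample variation.

Determinism: every generator derives a private substream from the master
seed by stable hashing of the generator's name, and restores the caller's
RNG state, so outputs are bit-identical for identical (config, seed) and
independent across generators.

## Problem sizes used by the shipped checks

The demo pipeline (`demo_run_config()`) runs 12 subjects/arm, 30 genera, 300
KOs, 20 MSPs and 200 network samples and completes in about half a minute;
the calibration studies use the study scale of 45 subjects for ZIBR (200
null and 100 effect replicates in the test suite; 100 and 50 in the
acceptance script), 20 metagenome replicates at strain share 0.05 and
library 10^6, and networks of 20–30 nodes at 500 samples. These sizes were
chosen so each check has enough Monte-Carlo resolution for the bands it
asserts.

## Known limitations

- The two-part model fits its parts independently; correlated random
  intercepts across parts, random slopes, and one-inflation are out of scope.
- The beta-diversity group test's per-sample summary (median inter-sample
  distance) is one of several defensible constructions.
- Contribution scoring assumes correct gene-to-strain attribution; read
  misassignment between close relatives is not modeled.
- StARS parameters are package-default reconstructions (20 subsamples, 80%
  size, threshold 0.05), configurable but not tuned per dataset.
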