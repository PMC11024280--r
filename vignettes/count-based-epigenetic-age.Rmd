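---
title: "Count-based maximum-likelihood estimation of epigenetic age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-based maximum-likelihood estimation of epigenetic age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methage)
```

## The model

Bisulfite sequencing reads out DNA methylation as counts: at a CpG site
covered by $n$ reads, $x$ reads report a (methylated) cytosine and
$n - x$ a (converted, unmethylated) thymine. Each read is a Bernoulli
trial with success probability equal to the site's methylation level, so

$$\Pr(x \mid n, p) = \binom{n}{x} p^x (1-p)^{n-x}.$$

Many CpGs drift in methylation with age, rapidly early in life and more
slowly later, so the trajectory $p_j(a)$ of site $j$ at age $a$ is in
general nonlinear. `methage` estimates these trajectories from a
training cohort and then inverts them: given one subject's counts
$\{(x_j, n_j)\}$ at a set of reference sites, the log-likelihood of
candidate age $a$ is

$$\ell(a) = \sum_j \log \binom{n_j}{x_j}
  + x_j \log p_j(a) + (n_j - x_j)\log\!\big(1 - p_j(a)\big),$$

evaluated on a discrete grid of ages (1–100 years in 1-year steps by
default), and the grid argmax is reported as the epigenetic age. The
log-sum replaces the product of per-site probabilities so the
computation cannot underflow. Under a flat prior over the grid this
maximum-likelihood age is also the posterior mode; `tidy()` on a
profile exposes the normalised posterior for plotting.

Working on counts rather than methylation fractions has two
consequences that drive the whole design. First, a site observed at
200x pulls the likelihood harder than a site observed at 5x, exactly in
proportion to its evidence. Second, a site with *no* reads simply
contributes nothing: missing data is skipped, never imputed as fraction
zero — the failure mode that breaks weighted-sum clocks on sparse data
(`predict_age_fraction(missing = "zero")` implements that failure mode
as a deliberately naive baseline for comparison).

## Training: per-site reference curves

`construct_reference()` fits, for every site of a cohort count matrix,
the trend of per-sample methylation fraction $x/n$ against chronological
age, using LOWESS — locally weighted linear regression with tricube
weights. We use a nonparametric smoother precisely so that no
functional form is imposed on the methylation–age relationship.
Each site is scored by the Spearman rank correlation of fraction with
age (robust to monotone nonlinearity), sites are ranked by $|\rho|$,
and predictions use the top-ranked sites.

The tunable parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.7 | LOWESS neighbourhood fraction: each local fit uses the nearest $\lceil \tau N\rceil$ points. Smaller values track sharper bends but overfit; 0.7 follows the smoothness that visual inspection of strongly age-associated CpGs supports. |
| `n_sites` | 8 | site budget at prediction; a handful of strongly ranked CpGs carries most of the signal, and small budgets keep the estimator interpretable |
| `grid` | 1–100 yr, step 1 | candidate ages; `grid_min` may be set to 0 for cohorts with neonates |
| `eps` | 1e-6 | reference curves are clipped to $[\epsilon, 1-\epsilon]$ so $\ell(a)$ is finite even when a trend touches 0 or 1 |
| `min_site_coverage` | 5 | a sample enters a site's trend fit only if it covers the site at least this deeply, so shallow cells do not add noise fractions to training |
| `min_coverage` / `min_sample_fraction` | 5 / 0.8 | matrix assembly keeps sites covered ≥ 5x in ≥ 80% of samples; both can be dialled to 1 and 0 for sparse data |

Numerical choices that matter and are otherwise invisible:

* **LOWESS.** Window of the $\lceil \tau N\rceil$ nearest points,
  tricube kernel $(1 - (d/d_{\max})^3)^3$, weighted least squares per
  target point, followed by 3 bisquare robustifying iterations (the
  canonical choice; it guards the trend against occasional aberrant
  fractions from low-coverage cells). When the local design degenerates
  (zero weighted spread in $x$) the fit falls back to the weighted
  mean. The implementation is checked against an independent
  brute-force loop that builds the weight vector and solves the 2×2
  normal equations point by point, to 1e-8.
* **Grid evaluation.** Fitted values are linearly interpolated at grid
  ages inside the training age range and extrapolated as constants
  outside it, then clipped. Constant extrapolation is deliberately
  conservative: beyond the oldest training subject the likelihood goes
  flat rather than following an invented slope.
* **Ranking ties** are broken by site key (chromosome, position), and
  grid argmax ties resolve to the youngest age, so training and
  prediction are bit-for-bit deterministic.
* **Linear reference** (`trend_kind = "linear"`) replaces the LOWESS
  curve with an ordinary least-squares line per site, inside the same
  binomial likelihood — the linear-trend baseline that the comparison
  harness contrasts with the nonparametric reference.
* **Prediction intersects first, truncates second**: the requested site
  budget is filled from the highest-ranked sites *the sample actually
  covers*, so a sample missing some top sites still uses `n_sites`
  informative sites rather than fewer.
* Sites are matched by exact (chromosome, position); opposite-strand
  records of one CpG are not collapsed. This is conservative, testable,
  and avoids an assumption the call formats do not guarantee.

## Uncertainty

`estimate_uncertainty()` runs a parametric bootstrap: the subject's age
is estimated, then 100 synthetic subjects are simulated at that age —
per site, $x^* \sim \mathrm{Binomial}(n, p_j(\hat a))$ with the
subject's real coverage $n$ — and re-estimated; the 25th/75th
percentiles of the re-estimates (linear interpolation between order
statistics, `quantile` type 7) are the reported IQR bounds. Simulating
from the reference trend at the point estimate (rather than from the
subject's observed fractions) matches the model being inverted;
`sim_from = "observed"` covers the other reading. Each sample derives
its own RNG substream from the master seed and its ID, so batch results
do not depend on processing order.

## What the synthetic cohorts emulate

`generate_cohort()` produces the statistical structure the estimator
assumes: signal CpGs follow saturating-exponential trajectories
$m_0 + A(1 - e^{-ra})$ (amplitude $A \sim U(0.3, 0.6)$, rate
$r \sim U(0.02, 0.08)\,\mathrm{yr}^{-1}$, baseline near one boundary
moving toward the middle, either direction) — change that is fast in
childhood and decelerates with age; noise CpGs sit at an
age-independent level drawn from $U(0.05, 0.95)$; per-subject biological
scatter is Gaussian jitter (sd 0.03 by default) on the probability
scale before binomial sampling. The standard study conditions used
throughout the tests and the acceptance script are 300 subjects, ages
uniform on 1–90, 30 signal + 30 noise sites, fixed 100x coverage. An
optional beta-binomial mode (`overdispersion`) generates overdispersed
counts as a stress test while the estimator itself stays binomial.

`downsample_counts()` emulates resequencing at lower depth by
multivariate-hypergeometric thinning: the target number of reads is
drawn without replacement from the pooled per-site
methylated/unmethylated read population, so per-site $x \le n$ is
preserved and sites can genuinely drop to zero coverage (becoming
missing, not fraction-0).

What the generator does **not** emulate: read-level bisulfite
conversion error, alignment artefacts, strand structure, linked CpGs
covered by one read, cell-type composition shifts, or real trend
shapes beyond the four families above. Passing recovery tests on these
cohorts therefore demonstrates that the estimator inverts the model it
assumes — not that real cohorts meet that model.

## Evaluation harness

`kfold_cross_validate()` partitions samples into seeded folds (sizes
differing by at most one, keyed to sorted sample IDs so input order is
irrelevant) and — crucially — refits the reference *including the
Spearman site ranking* inside every fold. Selecting sites on the full
cohort and then cross-validating only the curve fits would leak the
test ages into site selection; refitting per fold is the only
leakage-free reading, at the cost of some variance in which sites each
fold uses. Reports carry per-sample predictions (`tidy()`), summary
metrics (`glance()`: coefficient of determination $1 - SS_{res}/SS_{tot}$
as primary, squared Pearson correlation alongside, MAE), and a
residual-bias analysis: a LOWESS fit (tau 0.9, a deliberately stiff
smoother for a diagnostic curve) of residual versus true age plus the
Spearman correlation of residuals with age. Residuals are
predicted − true, so positive values read as age acceleration.

The simulation-study sizes used by the test suite were chosen once:
the standard cohort above for end-to-end recovery and downsampling; 10
replicate cohorts of 150 subjects with 20 signal + 20 noise sites under
5-fold CV for the LOWESS-versus-linear residual-bias contrast; interval
calibration at 20x coverage (where the 50% interval spans several grid
steps and its coverage is measurable) and interval concentration at
1000x.

## Known limitations

* The binomial likelihood ignores overdispersion; real bulk data with
  cell-composition heterogeneity will be overdispersed, making
  likelihood profiles overconfident and bootstrap intervals too narrow.
  A beta-binomial likelihood is the natural extension.
* The age grid is discrete; estimates are reported at 1-year
  resolution and ties resolve young. Off-grid optimisation is out of
  scope.
* Constant extrapolation means subjects older than the oldest training
  subject produce flat likelihood tails; ages beyond the training range
  are effectively censored at it.
* Very sparse samples (a handful of reads) carry little information per
  read at realistically shallow trend slopes; the estimator degrades
  gracefully but no estimator can beat the Fisher information of a few
  Bernoulli trials.
* Site selection by marginal $|\rho|$ ignores redundancy between
  correlated CpGs; a budget of $N$ correlated sites is worth less than
  $N$ independent ones.
```
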