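---
title: "Predicting bacterial growth in fresh juice from electronic sensor arrays"
author: "GrowthSense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bacterial growth in fresh juice from electronic sensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GrowthSense)
```

## The problem

Freshly squeezed fruit juice spoils under cold storage as its total
viable bacterial count (TVC, reported as Log10 CFU/mL) rises; a common
regulatory limit treats juice as unsafe once the count reaches
5 Log CFU/mL. Plate counting is the reference measurement but takes
days per sample. Electronic noses (arrays of cross-sensitive gas
sensors) and electronic tongues (potentiometric taste sensors) respond
within minutes to the volatile and taste changes that microbial
metabolism causes, so a calibrated sensor channel — or a fused summary
of both arrays — can stand in for the plate count when fitting a
predictive growth model.

GrowthSense implements that workflow end to end: primary growth-model
fitting, sensor-channel screening, array fusion, shelf-life inversion,
and a seeded generator that emulates the cold-storage study design the
package targets (strawberry juice at 4 °C, sampled every 12 h for
7 days, 20 replicate samples per time, a 10-channel E-nose and a
9-channel E-tongue).

## The four primary models

All four classical primary models share the parameters `n0` (initial
level), `nMax` (asymptote), `muMax` (maximum specific rate, h^-1) and
`lag` (lag time, h). We implement the canonical explicit forms:

* **Modified Gompertz** (Zwietering):
  \(N(t) = N_0 + \Delta \exp\{-\exp[\mu_{max} e / |\Delta| (\lambda - t) + 1]\}\),
  \(\Delta = N_{max} - N_0\).
* **Logistic** (four-parameter):
  \(N(t) = N_0 + \Delta / (1 + e^{\mu_{max}(\lambda - t)})\).
* **Huang**:
  \(B(t) = t + \tfrac14 \ln\frac{1 + e^{-4(t - \lambda)}}{1 + e^{4\lambda}}\),
  \(N(t) = N_0 + N_{max} - \ln[e^{N_0} + (e^{N_{max}} - e^{N_0}) e^{-\mu_{max} B(t)}]\).
* **Baranyi–Roberts** (explicit form, \(h_0 = \mu_{max}\lambda\)):
  \(A(t) = t + \frac{1}{\mu_{max}} \ln(e^{-\mu_{max} t} + e^{-h_0} - e^{-\mu_{max} t - h_0})\),
  \(N(t) = N_0 + \mu_{max} A(t) - \ln[1 + (e^{\mu_{max} A(t)} - 1) e^{-(N_{max}-N_0)}]\).

Three numerical choices matter:

* **Declining curves.** Gas-sensor responses fall as bacteria grow, so
  `nMax < n0` is legal and all four forms must stay monotone towards
  `nMax`. The logistic, Huang and Baranyi forms already are; the
  Gompertz slope factor uses \(|\Delta|\) rather than \(\Delta\),
  which is identical to the usual form for growth and is the unique
  sign choice that keeps the sigmoid monotone for decline. This avoids
  asking callers to negate their data.
* **Log-space evaluation.** Products \(\mu_{max} t\) reach several
  hundred on long grids; every exponential that can overflow is
  evaluated through `log1p`-style identities, and the Huang response is
  algebraically rewritten as
  \(N_{max} - \mathrm{log1p}[(e^{\Delta} - 1)e^{-\mu_{max}B(t)}]\)
  so that `N(0) = n0` holds exactly in floating point.
* **The Gompertz constant.** The slope factor's "2.718" that often
  appears in print is Euler's \(e\), and is implemented as such.

```{r curves}
p <- growthParams(3.996, 5.337, 0.064, 97.85)   # plate-count Baranyi row
evaluateCurve("baranyi", p, seq(0, 168, 12))
shelfLifeTime("baranyi", p, 5)   # hours to reach 5 Log CFU/mL
```

Shelf life is the smallest `t` with `N(t)` equal to a threshold,
located by bisection on the monotone curve. Thresholds at or beyond
the start return 0; thresholds at or past the asymptote return `NA`
(the asymptote is never attained). The bisection tolerance is 1e-9
relative in time, comfortably below the 1e-6 level agreement the
round-trip tests check.

## Fitting and the adjusted metrics

Fits minimise the residual sum of squares by bounded
Levenberg–Marquardt (via `minpack.lm`), restarted from one data-driven
heuristic start (levels from the series endpoints, rate from the
steepest finite-difference slope, lag from the slope location) plus
seeded Latin-hypercube draws over the bounds (`nRestarts = 32` by
default; the best restart wins, and a fixed seed makes the whole fit
bit-reproducible). Default bounds keep `muMax` in (1e-4, 1] per hour,
`lag` within the observation window, and the two levels within the
observed range extended by one full span on either side — slow curves
can end an entire span short of their asymptote, so anything tighter
would clip legitimate optima (the packaged plate-count Huang row is an
example).

Reported metrics use the degrees-of-freedom-adjusted forms with `n`
observations and `p = 4` parameters:

\[ RMSE = \sqrt{\frac{\sum (y_i - \hat y_i)^2}{n - p}}, \qquad
   R^2 = 1 - \frac{n-1}{n-p}
   \frac{\sum (y_i - \hat y_i)^2}{\sum (y_i - \bar y)^2}. \]

For replicate panels the fitting target is the per-time mean, not the
pooled replicates: the published training RMSEs (~0.37 response units)
match mean-level scatter, while replicate-level scatter would be two
to three times larger. Validation (`fitWithValidation`) fits the
training-split means and then evaluates the *same* trained curve on
the held-out means without refitting, also at `p = 4`, since the same
four parameters generated both predictions. The reported correlation
`r` compares the fitted curve, evaluated on the sampling grid, with
the observed plate-count log means — the package's reference series
for "does this sensor track the bacteria".

## Screening sensor channels

Raw replicates are rarely published; per-time mean ± sd with `n` is.
One-way ANOVA is therefore reconstructed exactly from summaries
(`SS_between = sum n_i (m_i - grand)^2`,
`SS_within = sum (n_i - 1) sd_i^2`), which a property test verifies
against `stats::aov` on raw replicates to 1e-10.

Duncan's multiple range test then assigns homogeneous-subset letters:
means are sorted in decreasing order, and an ordered pair spanning `k`
means is separated when its difference reaches
\(q^*(\alpha_k, k, df_w)\sqrt{MSE/n_h}\), with the Duncan protection
level \(\alpha_k = 1 - (1-\alpha)^{k-1}\), `q*` the studentized-range
quantile and `n_h` the harmonic mean group size. Letters come from the
standard sweep over maximal non-separated stretches, the largest mean
lettered "a". A channel's *discrimination count* — how many distinct
letters its display needs — is the screening workhorse: a channel that
distinguishes many storage times carries kinetic information.

One honest caveat: letter displays recomputed from rounded published
summaries can differ by one subset from the original software's output
on the raw data, because borderline pairs sit within the rounding of
the published SDs. The packaged E-nose table therefore retains the
original letter column alongside the means and SDs, and
`discriminationCount` accepts either a recomputed grouping or a
published letter column.

Channel selection (`rankSensors`) orders channels by discrimination
count, then by absolute Pearson correlation with the plate-count
series (two-sided t-test stars: `*` p < 0.05, `**` p < 0.01), then by
absolute first-component loading from a centered (unscaled) PCA of the
mean-response matrix — unscaled because raw gas-sensor responses live
on a common conductance-ratio scale where variance itself is signal.
Taste channels are screened by correlation alone, mirroring how taste
panels are reported.

## Fusing the two arrays

The fused analysis z-standardises the per-time mean matrix (15 × 19
here) before PCA — the arrays' scales are incommensurate, and an
unscaled decomposition would be dominated by the widest-swinging gas
channel. Components are retained up to 90% cumulative variance by
default, and each component's sign is oriented so its score series
falls with storage time, matching the spoilage convention and making
the downstream negation reproducible. The per-time composite is the
variance-fraction-weighted sum of retained scores,

\[ \mathrm{Score}_t = \sum_{j \le k} f_j \, s_{tj}, \]

and `orientForFitting` negates it into a growth-like increasing series
("inverse" here means sign negation, not reciprocal — reciprocals of
near-zero mid-storage scores would explode). Fitting the four models
to that negated composite is the fusion endpoint; on the packaged
score table the Baranyi model ranks first with adjusted R² ≈ 0.956.

## The synthetic generator

Because no raw study data are published, the generator reproduces the
design statistically so every stage is testable:

* latent growth: the packaged plate-count Baranyi parameters
  (n0 3.996, nMax 5.337, muMax 0.064 h^-1, lag 97.85 h) on the 0–168 h
  grid; replicate counts add Gaussian noise of 0.1 Log CFU/mL;
* E-nose channels: affine transforms of the latent curve calibrated
  from the packaged summary table (slope maps the latent span onto the
  channel's observed span — negative for falling responses — and the
  noise is the channel's median published sd);
* taste channels: slopes set so the per-time-mean correlation with the
  latent curve matches the published taste–count correlations
  (sweetness +0.77, umami −0.58, ...), at a common replicate noise of
  2 taste units; additionally each taste channel loads on one of three
  deterministic drift factors, orthogonalised against the latent curve
  and sized at four times the mean-level noise variance. The drift
  emulates the structured between-session variation of potentiometric
  tongues; without it the fused decomposition would need ~11
  components for 90% variance, where the emulated study's structure
  concentrates it in 4 (the generated panels retain 4 at the default
  threshold, with a PC1 share near 61%);
* 20 replicates per time, replicates 1–15 forming the training split;
  all randomness flows from one integer seed through per-channel
  sub-streams, so panels are bit-reproducible and adding a channel
  never perturbs the others.

What the generator does *not* emulate: residual between-channel
covariance beyond the shared latent and drift factors (none is
published), non-Gaussian replicate noise, sensor saturation, or any
temperature dependence. Passing tests on synthetic data therefore
demonstrate that the pipeline's inference machinery is correct under
the study's declared statistical structure, not that any particular
juice or instrument behaves this way. A note on the emulated design
itself: the study protocol records sweetness five times per sample but
twenty repetitions per storage time; the generator uses a uniform 20
replicates for every channel.

## Problem sizes and determinism

The defaults everywhere are the study's own sizes: 15 time points, 20
replicates, 19 sensor channels. Tests and examples that fit many
series use 8 optimizer restarts (the heuristic start almost always
wins; the restarts guard against the occasional local optimum), and
the property checks use 200 simulated studies for parameter recovery
and a 20^4 brute-force parameter lattice as the optimizer's
independence oracle. Pipelines, fits and panels are deterministic
given (config, seed); reports embed the seed and a configuration hash.

## Known limitations

* Published tables are rounded; quantities recomputed from them
  (Duncan letter counts, composite scores) can sit one rounding step
  from the originals, as flagged above.
* The optimizer is a bounded multi-start local method. The dominance
  tests (grid oracle, SSE at the generating truth) bound its quality,
  but published parameter sets that were themselves local optima will
  not be reproduced — the fits here can be strictly better than
  numbers reported from weaker optimizations of the same data.
* Shelf-life inversion is only meaningful for sources in Log CFU/mL;
  sensor-unit fits report `NA` rather than implying a unit conversion
  the data cannot support.
* Secondary modelling (temperature dependence), stochastic growth,
  death phases and confidence intervals on parameters are out of
  scope.
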