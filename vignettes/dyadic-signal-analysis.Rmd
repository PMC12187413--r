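---
title: "Models and design choices in dyadsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in dyadsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsignal)
```

`dyadsignal` analyses multi-component signalling in staged male–male
contests of a colour-changing agamid lizard. Each trial pairs two
size-matched males (a dyad); both members are measured, so no observation
is independent of its partner's. The package covers the five stages of
that analysis — colour quantification, trait assembly, univariate
comparisons, composite-trait inference, and opponent matching — plus a
synthetic-study generator that makes every stage testable against known
ground truth. This vignette documents the models, the tunable parameters,
and the design decisions taken where the methodology left genuine
choices.

## The receptor-noise-limited colour model

Skin colours are quantified as chromatic contrast in just-noticeable
differences (JND) between a displayed colour and a spectrally flat 40%
grey reference, under a receptor-noise-limited (RNL) model of the
receiver's eye.

The quantum catch of receptor class $i$ for a stimulus with reflectance
$R(\lambda)$ under illuminant $I(\lambda)$ is

$$q_i = \int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, d\lambda,$$

with $S_i$ the receptor's spectral sensitivity. All spectra are treated
as piecewise-linear in wavelength; `quantum_catches()` integrates the
product *exactly* for that model with two-point Gauss–Legendre quadrature
on each segment of the union grid (the integrand is a cubic per segment).
This removes quadrature error as a concern: agreement with a 10×-finer
trapezoid evaluation of the same interpolants is at the $10^{-7}$ level,
against a requirement of $10^{-6}$.

Receptor coding is logarithmic (Weber–Fechner), $f_i = \ln q_i$, and
discriminability is limited by per-channel noise

$$e_i = \frac{\nu}{\sqrt{\eta_i / \max_j \eta_j}},$$

where $\eta$ are relative cone abundances and $\nu$ the Weber fraction of
the most abundant channel. This scaling makes $\nu$ interpretable whether
or not the abundances are normalised: the most abundant channel carries
exactly $\nu$. The study system's cone ratios are
$\mathrm{lw}:\mathrm{mw}:\mathrm{sw} = 0.06:0.08:0.15$, so the default
assigns $\nu$ to sw. The Weber fraction itself is not reported for this
system; the package default is $\nu = 0.05$, the value most RNL
applications adopt, and it is exposed everywhere since every contrast
scales exactly as $1/\nu$.

For two stimuli with $\Delta f_i = f_i^a - f_i^b$, the trichromatic
contrast is

$$\Delta S^2 = \frac{e_1^2(\Delta f_3-\Delta f_2)^2 +
e_2^2(\Delta f_3-\Delta f_1)^2 + e_3^2(\Delta f_1-\Delta f_2)^2}
{(e_1e_2)^2+(e_1e_3)^2+(e_2e_3)^2},$$

implemented for any $n \ge 2$ channels via the general pairwise opponent
form. `rnl_coordinates()` provides the dual construction — log catches
whitened by $1/e_i$ and projected orthogonally to the achromatic
direction — whose Euclidean distances equal $\Delta S$; the two routes
are verified against each other to $10^{-9}$ relative tolerance in the
test suite. Channel count is open in principle (a UV or double-cone
channel can be added by passing four abundances and sensitivities); the
default is the trichromatic set actually reported for this system.

Two further rendering choices: the 40% grey is a flat spectrum at
reflectance 0.40 (the natural reading of "40% grey", matching the natural
substrate range it was chosen to span), and the default illuminant is an
analytic 6500 K blackbody normalised to peak 1 — a daylight-like SPD
computed from Planck's law rather than a transcribed standard table. Any
measured illuminant can be supplied as a `spectrum`. No von Kries
adaptation is applied by default: contrasts against a grey under a single
illuminant are invariant to it in the log model. The per-trial trait is
the *maximum* contrast over an individual's 6–10 images
(`max_series_contrast()`), ties broken at the earliest image.

## Trait assembly and exclusions

The analysis matrix has five traits per individual: headbob and shudder
counts (the two display behaviours common enough to analyse), total UV
patch area (left + right flank), and the maximum dorsal and lateral
chromatic contrasts. Exclusion rules are applied in a fixed order with a
full audit log: interaction-induced testosterone above 2000 ng/ml
(assay-implausible values; configurable cutoff), an input flag for
atypical shudder displays (no numeric rule exists, and inventing one
would misrepresent a judgement made by eye), and — at the PCA stage only
— listwise deletion of individuals missing any trait. Univariate stages
keep those rows and use pairwise-complete data, so each test retains the
largest defensible sample.

## Univariate stage

Every trait is gated through a Shapiro–Wilk test at $\alpha = 0.05$ (the
conventional level; the gate level is configurable) and then compared
with Welch's *t* (parametric, unpaired), paired *t*, Wilcoxon rank-sum,
or Wilcoxon signed-rank accordingly, all two-tailed. Ties and
zero-differences follow the standard conventions (midranks, zeros
dropped, continuity-corrected normal approximation beyond the exact
range). Identical paired samples return the null-centred statistic with
$p = 1$ rather than an error, so degenerate simulated data cannot crash
a pipeline run.

## Composite traits and the dyad-aware bootstrap

The five traits are condensed by PCA on the **correlation** matrix.
Scaling is deliberate: the traits mix counts, mm² and JND, and an
unscaled PCA would be dominated by UV area's units. Bartlett's test of
sphericity, $\chi^2 = -(n-1-(2p+5)/6)\ln\det R$ on $p(p-1)/2$ df, is
computed alongside as the usual pre-condition check. Eigenvector signs
are fixed by flipping each column so its largest-magnitude entry is
positive.

Because both dyad members are measured, rows are not independent. The
package handles this the way the study design implies: a bootstrap that
keeps exactly one uniformly chosen member of each pair per iteration
(pure subsampling, no replacement — "subsampling" is the stated scheme;
a with-replacement variant would be a different estimator), refits the
PCA, and collects loadings over 100 iterations (default), reporting
percentile 95% intervals. Two indeterminacies would corrupt those
intervals if ignored: eigenvector sign, and component *order* (at
subsample size $n \approx 23$ the behaviour and colour eigenvalues are
close enough to swap ranks). Each bootstrap fit is therefore aligned to
the full-data reference by matching components on largest absolute dot
product and then sign-flipping to positive agreement. Subsamples with a
singular correlation matrix are redrawn, capped at ten times the
iteration count.

Hormone–signal models are ordinary least squares of a PC score on
interaction-induced testosterone and corticosterone (ng/ml) and
snout–vent length (mm), all untransformed — the published coefficient
magnitudes (~10⁻³–10⁻⁴) only arise on raw units. Designs with condition
number above $10^{10}$ are rejected as collinear. The same one-per-pair
bootstrap yields percentile intervals per coefficient.

## Opponent matching

Whether opponents match each other's signal intensity is tested by
permutation. The statistic is the mean within-pair absolute difference —
absolute, because dyad members are unordered, making a signed difference
meaningless. The null re-pairs all individuals as uniform random perfect
matchings (shuffle, pair consecutive; the true pairing is *not* excluded,
since excluding it biases the null), and

$$p = \frac{1 + \#\{d_{\mathrm{null}} \le d_{\mathrm{obs}}\}}{n_{\mathrm{perm}} + 1},$$

a lower-tail test with the add-one correction so $p$ is never zero.
Lower-tail is the scientifically meaningful direction — matching means
*smaller* differences than random — and a two-sided option exists. An
alternative null that permutes one column of the pair table is provided
(`null = "column"`); the uniform-matching null is the default as the more
complete randomisation. Site structure is ignored when re-pairing, as
the original analysis re-paired across the whole sample. Default
$n_{\mathrm{perm}} = 1000$.

## The synthetic-study generator

The generator exists so every downstream stage can be verified against
planted truth. Its defaults *are* the study conditions: 23 size-matched
dyads (SVL 112–137 mm, within-pair gap ≤ 3 mm), 9 single-lizard controls
that display no headbobs or shudders, lognormal hormones (testosterone
median 300 ng/ml, corticosterone median 40 ng/ml induced vs 15 baseline
— corticosterone rises in response to the trial, testosterone does not),
and planted exclusion counts configurable up to the study's 3/2/6
pattern (defaults to none, so the statistical criteria run on intact
pairs).

Each trait has a unit-variance latent that decomposes into four shares:

* a **pair share** equal to the trait's intraclass correlation (ICC) —
  the generator's knob for opponent matching (defaults: headbob 0.5,
  shudder 0.5, dorsal 0.5, lateral 0, UV 0.2, i.e. matching present for
  behaviours and dorsal colour, absent for lateral colour);
* a **block factor**: behaviours + UV share one individual-level factor,
  the two colours another (variance 0.22 and 0.08), representing
  behavioural reactivity and colour expressiveness;
* a **hormone share** with the planted signs: standardized testosterone
  +0.4 on the behaviour+UV block, −0.4 on colour; corticosterone −0.5 on
  colour, 0 on behaviour. (UV receives the behavioural testosterone
  loading: UV patch size tracks behavioural intensity, and its composite
  is the testosterone-positive one.)
* a free residual absorbing the remainder.

Partitioning the variance this way — rather than adding hormone effects
on top of a unit-variance latent — keeps the configured ICC equal to the
trait's *actual* intraclass correlation: hormone effects are
individual-level and must come out of the individual share, or they
would silently dilute the matching signal they coexist with.

Two structural points deserve emphasis:

1. **Count traits carry their ICC on the count scale.** Headbobs and
   shudders are Poisson with log link (medians 35 and 20 per trial,
   slope 0.5, optional gamma overdispersion). Poisson noise and the exp
   link attenuate any latent correlation, so the latent pair share is
   calibrated analytically — inverting the lognormal–Poisson moment map
   — such that the *emitted count* has the configured ICC. The
   configured quantity is the one the analysis sees; an uncalibrated
   latent ICC would overstate the matching actually present in the data.

2. **Pair components are correlated within a block** (`pair_cor`,
   default 0.5): a pair that escalates does so across its displays, so
   the headbob, shudder and UV pair components share a pair-level
   "contest intensity" factor, and likewise the colour block. This
   couples traits at the pair level without changing any trait's
   marginal ICC, and it is what lets a 46-individual sample resolve the
   behaviour+UV block from the colour block the way the real data do.

Continuous traits are affine (dorsal JND $= 5.5 + 1.6x$, lateral
$= 6.5 + 1.8x$, floored at 0.1) or lognormal (UV area, median 80 mm²,
split ~evenly between flanks) maps of their latents; controls' colour
latents are shifted by −0.9 sd (no opponent, weaker display). These
scales are order-of-magnitude choices for a ~12 cm rock agama, exposed
in `study_config()`, not empirical claims.

What the generator does *not* emulate: temporal escalation within a
contest (only end-of-trial aggregates exist downstream, so shared
pair-level variance is the minimal sufficient structure), winner/loser
asymmetries, site effects, and any pair-level correlation of hormones
(hormone effects are strictly individual-level, which is what makes the
type-I calibration of the matching test meaningful at ICC 0). Passing
tests on synthetic data therefore demonstrate that the *machinery*
recovers planted structure of this form — not that real contests lack
richer dynamics.

## Numerical and reproducibility choices

* Integration: exact for piecewise-linear spectra (two-point
  Gauss–Legendre per union-grid segment); union grid refined to ≤ 1 nm.
* PCA via `eigen()` on the correlation matrix; degenerate inputs
  (singular correlation) carry `bartlett = NULL` rather than failing the
  whole fit.
* Percentile bootstrap intervals, 95%, 100 iterations — interval type
  and count as in the original analysis; percentile is the natural
  choice when the resampled quantity (a loading) is bounded.
* All randomised stages take explicit seeds; `run_all()` derives
  per-stage seeds from the master seed through a labelled hash
  (`derive_seed()`), so adding a stage never shifts another stage's
  draws, and a standalone stage call with the derived seed reproduces
  the pipeline's result bit for bit.
* Simulation sizes in the test suite (e.g. 200 replicates for the
  qualitative-recovery checks, 1000 for the type-I calibration of the
  matching test, 100-replicate batches for power monotonicity) are
  chosen to keep Monte-Carlo error well inside the asserted margins
  while the whole suite stays comfortably runnable on a laptop.

## Known limitations

* The exact grey rendering is an assumption (flat 0.40 reflectance); a
  measured grey-card spectrum can be substituted but none is shipped.
* Whether the receiver's eye model should include a UV cone is
  unresolved for this system; the package supports $n$ channels but
  defaults to the three reported cone classes.
* The regression treats PC scores as data, ignoring their estimation
  uncertainty; the one-per-pair bootstrap propagates pair
  non-independence but not score uncertainty.
* With 23 pairs, percentile intervals from 100 bootstrap refits are
  themselves noisy; loadings near zero can yield intervals that cross
  zero in a minority of replicates even when the population loading is
  nonzero.
* The atypical-shudder exclusion is an input flag; studies without such
  annotations simply leave it `FALSE`.
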