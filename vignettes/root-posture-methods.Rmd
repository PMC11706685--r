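---
title: "Methods: quantifying root posture and local curvature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying root posture and local curvature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootposture)
```

## The measurement problem

A seedling root grown on a vertical agar plate traces a curve in the plane
of the medium. Mutants affected in gravitropism or in organ straightening
produce wavy roots, and different lesions produce different *kinds* of
waviness: some roots wander in large, gentle arcs, others stay near the
vertical overall but kink sharply. Endpoint-based summaries — root length
$L$, the horizontal and vertical growth indices $HGI = L_x/L$ and
$VGI = L_y/L$, and the straightness index $SI = L_c/L$ — are cheap and
robust but blind to everything between base and tip: two roots with equal
$SI$ can differ grossly in local bending. The curvature index $CI(s)$, a
per-point estimate of $|d\theta/ds|$ along the centerline, recovers that
local information. This package implements both layers plus the
nonparametric statistics used to compare genotypes or treatments.

## From digitized dots to a curvature profile

**Input.** An ordered polyline, base (root–hypocotyl junction) first, in cm
after an explicit scale conversion. The internal frame is y-up with gravity
$(0, -1)$, so image-convention exports (y growing downward) are flipped at
read time and "downward" is one sign convention everywhere. Consecutive
duplicate dots — an occasional artefact of manual clicking — are collapsed
with a warning.

**Resampling.** The trace is parameterized by cumulative chord length and
each coordinate is fitted with a cubic smoothing spline whose penalty is
chosen by generalized cross-validation (`stats::smooth.spline`). The fit is
evaluated on a dense grid (10× the target density), its arc length is
accumulated, and the curve is re-evaluated at uniform arc-length targets:
$\mathrm{round}(L \cdot \text{density}) + 1$ points at the default
1,000 dots cm⁻¹.

The choice of a *smoothing* rather than an *interpolating* spline is the
one place this implementation deliberately departs from the most literal
reading of the protocol, and it matters. Manually placed dots carry
positional error; an interpolating spline passes through every dot and so
converts jitter of SD $\sigma$ at dot spacing $h$ into spurious curvature
of order $\sigma (2\pi/2h)^2$ — tens of cm⁻¹ for realistic values
($\sigma = 0.002$ cm, $h \approx 0.01$ cm), an order of magnitude above the
true signal, and the downstream 0.01 cm moving average cannot remove it
because curvature is unsigned. With GCV the penalty adapts to the data:
noise-free traces are reproduced essentially exactly (a noiseless circle
yields mean CI within numerical precision of $1/r$; an already-uniform
curve is reproduced to better than $10^{-4}$ cm pointwise), while noisy
traces are denoised before differentiation, which is what the original
two-stage tracing workflow (spline fitting in the image tool, then
re-interpolation) achieved in practice. `resample_spline(smoothing =
"none")` restores pure interpolation; traces with fewer than 8 points
always interpolate. One known cost: the data-driven penalty is not exactly
equivariant under rotations (the two coordinates are smoothed
independently), so rigid motions change CI values by a relative
$\sim 10^{-4}$; the interpolating path is exactly equivariant and is the
one used when that property is needed.

**Curvature.** For interior point $i$,
$$\kappa_i = \frac{\Delta\theta_i}{\bar s_i}, \qquad
\bar s_i = \tfrac12\left(\lVert p_i - p_{i-1}\rVert +
\lVert p_{i+1} - p_i\rVert\right),$$
with $\Delta\theta_i$ the unsigned angle between successive chords
(radians, via `atan2` of cross and dot products, so collinear points give
exactly 0). The mean-chord denominator makes $\kappa$ converge to
$|d\theta/ds|$; the alternative $p_{i-1} \to p_{i+1}$ distance
(`denominator = "endpoint_chord"`) differs only at $O(h^2)$ and is exposed
for comparison. Angles in radians make a circle of radius $r$ read exactly
$1/r$ cm⁻¹, which is what gives the 50 cm⁻¹ exceedance threshold its
geometric meaning (a bend tighter than 0.02 cm radius of curvature).
Curvature is unsigned because the trait of interest is bend sharpness, not
handedness. Endpoints copy their neighbour's value and are always trimmed
at defaults.

**Smoothing and trimming.** The raw profile is averaged over an inclusive
arc-length window of ±0.005 cm (11 points at default density; windows
truncate at the ends), then the first and last 20 dots are marked invalid —
the spline is least constrained near the manually chosen first and last
dots. The order is fixed: resample → raw curvature → moving average → trim
→ summarize. Whether trimming should precede the moving average is not
determined by the protocol text; trimming last discards exactly the points
whose windows were truncated, which is the more conservative reading.

**Per-root summaries.** The mean CI uses a symmetric trimmed mean dropping
$\lfloor n \cdot 0.005 \rfloor$ values from each extreme (4 points per side
for the canonical ~961 valid points; a plain mean below 200 points), which
guards against isolated spikes surviving the moving average. The threshold
count uses strict exceedance (CI > 50 cm⁻¹). Compartment means over
$[0, 0.5)$, $[0.5, 1.0)$ and $[1.0, \infty)$ cm from the base are plain
(untrimmed) means — trimming is a whole-root procedure — and empty
compartments are reported as missing, never zero. The curvature-versus-
distance group smoother defaults to LOESS (span 0.3) with a penalized
spline (`mgcv::gam`) as an option; the published analysis used a GAM
smoother whose basis and penalty are unspecified, so the smoother family is
configurable and recorded in the output rather than fixed.

## Tip angles

The gravitropic readout is the angle between the root tip and the
horizontal: 0° horizontal, +90° parallel to gravity, values in
$(-180°, 180°]$. Manual protractor measurements have no defined tip
segment; the reproducible surrogate is the secant from the point at arc
length $L - w$ to the tip, with $w$ (`tip_window_cm`, default 0.05 cm)
exposed because the effective manual window is unknown. Summaries use
20°-wide classes anchored at 0° and arithmetic mean ± sample SD, which is
appropriate while angles stay far from the ±180° wrap (they do in these
assays — typical groups sit between 40° and 100°); a circular-statistics
option (`circular = TRUE`) is available for data that straddle the wrap.

## Group statistics

All comparisons are rank-based: posture indices are bounded, skewed and
outlier-prone, so normal-theory ANOVA is not appropriate.

- **Kruskal–Wallis** (tie-corrected, χ² reference) is the omnibus test;
  the degenerate all-identical case returns $H = 0$, $p = 1$.
- **Steel–Dwass** handles all-pairs post hoc comparison: each pair is
  midranked separately, the standardized Wilcoxon-type statistic with tie
  correction is referred to the studentized-range distribution with $k$
  means and infinite df (the asymptotic variant). At $k = 2$ this reduces
  exactly to the two-sided normal-approximation Wilcoxon test, a reduction
  the test suite checks to $10^{-6}$, and the adjusted $p$ is never smaller
  than the unadjusted pairwise $p$.
- **Brunner–Munzel** tests the relative effect
  $\hat p = P(X < Y) + \tfrac12 P(X = Y)$ with a Satterthwaite-type $t$
  approximation — robust to unequal variances, the right default for
  planned two-sample contrasts, with `correction_family_size` implementing
  the Bonferroni ledger for a planned family (e.g. $0.05/9 \approx 0.0056$
  for a family of nine omnibus tests). If both samples are internally
  constant the variance estimate degenerates; the all-equal case returns
  $p = 1$ with a flag.
- **Compact letters** come from the insert-and-absorb algorithm: groups
  share a letter *iff* their pairwise $p \ge \alpha$ (default 0.05),
  verified exhaustively in tests.

Statistic implementations are cross-checked in the test suite against the
brute-force rank formulas and against frozen reference values from an
independent implementation.

## The synthetic generator and what passing tests mean

Synthetic roots grow along gravity with lateral displacement
$x(t) = \sum_i A_i \sin(2\pi t/\lambda_i + \phi)$, so curvature
$\kappa = |x''|/(1 + x'^2)^{3/2}$ is available in closed form and arc
length and arc-weighted mean $|\kappa|$ come from adaptive quadrature
(relative tolerance $10^{-10}$, pieces split at the kinks of $|x''|$). The
named archetypes encode the phenotype contrast of interest: `gradual_wave`
($A = 0.05$ cm, $\lambda = 0.5$ cm, peak $\kappa \approx 7.9$ cm⁻¹),
`sharp_wave` ($A = 0.02$ cm, $\lambda = 0.15$ cm, peak
$\kappa \approx 35$ cm⁻¹), their superposition (`mixed`), and `straight`.
The digitizer emulates manual marking: 100–450 dots approximately uniform
in arc length with ±30% spacing jitter and isotropic Gaussian positional
error (default SD 0.002 cm — no empirical estimate of manual clicking
error exists, so this is a characterized free parameter, not a fitted one).
All stochastic steps are seeded and reproducible.

`contrast_cohort()` constructs the decisive geometry: a `sharp` group that
is the `gradual` sinusoid scaled by 1/4 in both amplitude and wavelength
($A = 0.1, \lambda = 0.5$ versus $A = 0.025, \lambda = 0.125$ cm over
2 cm). Equal slope amplitude plus integer period counts make the analytic
arc length — hence SI — identical for any phase, while curvature scales
exactly 4× and the sharp peaks (~63 cm⁻¹) cross the 50 cm⁻¹ threshold the
gradual group (~16 cm⁻¹) never reaches. Each root additionally receives a
per-root amplitude factor (CV 0.15, truncated to [0.5, 1.5], identically
distributed in both groups): real plants vary, and without between-plant
spread a two-sample test at $n = 30$ would flag even the ~0.005
frequency-dependent bias difference in *estimated* SI as significant, which
would say something about the estimator, not the phenotype.

Validated behaviour at the study's conditions: noiseless 450-dot
digitization recovers SI within 0.5% and mean CI within 5% for every
archetype; at 250 dots with 0.002 cm jitter, mean CI stays within 15% of
truth across 50 seeded replicates (typically 3–11%); the contrast cohorts
separate at $p < 0.01$ (Brunner–Munzel) in `ci_mean` and `n_exceed` while
SI does not differ ($p > 0.05$).

What the generator does *not* emulate: root thickness and the ambiguity of
choosing a centerline inside it, correlated (non-isotropic) clicking error,
image distortion, roots leaving the medium plane, and any growth dynamics.
Passing recovery tests therefore demonstrates correctness of the geometry
and statistics pipeline on idealized traces, not robustness to every
artefact of real scans.

## Numerical choices and degenerate inputs

- Arc-length inversion uses a 10× dense parameter grid with monotone linear
  interpolation; output spacing is uniform by construction and `arc_pos`
  ends exactly at $L$.
- Moving-average windows are inclusive with a relative tolerance of
  $10^{-9}$ on the window edge, so a half-window of exactly 5 dot spacings
  yields the intended 11-point window despite floating-point accumulation.
- `half_window_cm = 0` and `n_trim = 0` are exact identities.
- Traces shorter than $2 \cdot n\_trim$ resampled dots, or shorter than the
  tip window, raise errors naming the root; batch runs skip such roots with
  a logged reason instead of aborting.
- Zero-length segments are collapsed at construction; a trace degenerating
  to fewer than 3 distinct points is rejected.
- Known bias: the pipeline's mean CI carries a small positive bias
  (~1.6% on the gradual archetype, independent of dot count) from the
  unsigned-curvature moving average; digitization noise adds more (see
  above). Error *grows* with jitter at fixed dot count, but does not
  monotonically shrink with dot count at fixed jitter — denser noisy dots
  raise the noise-to-spacing ratio and the GCV fit follows more of the
  noise. Dot count matters where resolution is limiting (the 0.15 cm
  wavelength archetype at 100 dots is visibly under-sampled).

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on synthetic
data generated at run time: single roots of 1–3 cm at 1,000 dots cm⁻¹,
cohorts of up to 30 roots per group at 450 digitized dots, and 50-replicate
recovery experiments — sizes chosen to exercise every code path at the
protocol's canonical density while keeping a full run in the order of
seconds to a couple of minutes.

## Limitations

Strictly 2D; curvature is unsigned (no handedness or wave-count
statistics); the Steel–Dwass implementation is asymptotic only (no exact
permutation variant, so very small groups rely on the large-sample
approximation); the tip-angle surrogate depends on `tip_window_cm` near
sharply hooked tips; and the GCV resampler assumes uncorrelated positional
noise — systematically biased tracing (e.g. always cutting corners) is
indistinguishable from signal.
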