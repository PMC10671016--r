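---
title: "Methods: simulating and analysing CMOS dopamine-sensor recordings"
author: "cmosdff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing CMOS dopamine-sensor recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmosdff)
```

This vignette is the package's account of its science: what the synthetic
session generator models and deliberately does not, how the ΔF/F₀ and ROI
analyses are defined down to their tie-breaks and boundary conventions, and
why the statistical layer behaves the way it does at n = 3 animals.

## 1. The measurement being emulated

An implantable needle-type CMOS sensor (40 × 90 px at 7.5 µm pitch — a
300 µm × 675 µm field; `sensor_geometry()`) images dLight fluorescence in
the nucleus accumbens. Fluorescence intensity is proportional to local
extracellular dopamine. An animal is recorded before a subcutaneous
injection (morphine, cocaine, or saline), then followed for hours; the drug
response is quantified per pixel as ΔF/F₀ % = (F − F₀)/F₀ × 100 against a
pre-injection baseline.

Because the original recordings are not publicly deposited, every analysis
here runs against `simulate_session()`, which produces stacks with known
ground truth. The generator's model for pixel (r, c) at time t (minutes
from injection) is

```
I(r, c, t) = B(r, c) · bleach(t) · (1 + C(r, c) · k(t)) + ε
```

* `B(r, c)` — baseline illumination: `baseline_mean` (default 1000 counts)
  with a 10% linear gradient along rows (`illumination_gradient`),
  reflecting excitation LEDs at the top and bottom of the needle.
* `C(r, c)` — coupling map: a sum of Gaussian release-site footprints
  (`n_sites = 6`, σ ~ U(1.5, 3) px ≈ 11–22 µm structures at the 7.5 µm
  pitch, gain ~ U(0.75, 1.25)) plus a diffuse `background_coupling = 0.3`
  seen by every pixel (neuropil fluorescence). Sites are placed uniformly
  at random from the session seed.
* `k(t)` — the drug kinetic transient (below).
* `ε` — Gaussian read noise (`read_noise_sd = 5` counts) plus a
  signal-proportional term with variance `shot_noise_gain · I` (default
  0.1). These are independent Gaussians, so they are drawn as a single
  Gaussian at the combined standard deviation; negative counts are clipped
  at zero (never triggered at default levels).

Sessions are deterministic in their seed: identical `simulation_params()`
give bit-identical stacks, and the caller's RNG state is untouched.

### The kinetic transient

No closed-form kinetics are published for these recordings; the generator
uses the simplest form that reproduces the described trends. For t > 0,

```
k(t) = A · B(t) − U · S(t)
B(t) = (exp(−t/τ_d) − exp(−t/τ_r)) / B_max      (Bateman, unit max)
S(t) = 1 / (1 + exp(−(t − t_u)/s_u))            (logistic undershoot)
```

and k(t) = 0 for t ≤ 0. The Bateman peak is at
`τ_r τ_d/(τ_d − τ_r) · ln(τ_d/τ_r)` (`bateman_peak_time()`).

| class | A | τ_r (min) | τ_d (min) | U | t_u (min) | s_u (min) |
|---|---|---|---|---|---|---|
| morphine_like | 0.10 | 18 | 90 | 0.015 | 150 | 20 |
| cocaine_like | 0.12 | 8 | 50 | 0.04 | 130 | 8 |
| saline | 0 | — | — | 0 | — | — |

Morphine-like defaults peak at 36.2 min (inside the expected 30–60 min
window; the 15-min-binned peak lands in the (30, 45] bin), rise and decay
slowly, and drift slightly below baseline late — the GABA-disinhibition
phenotype. Cocaine-like defaults peak at 17.5 min (window 15–45 min; binned
peak (15, 30]), rise fast, and step markedly below baseline around 130 min
— the reuptake-block "comedown". Saline is identically zero.

A rectangular handling dip of depth `artifact_depth = 0.02` spans the first
`artifact_duration = 5` minutes *after* injection, matching where the dip
is visible in interval images (the first post-injection 5-min frame). An
early design placed the dip symmetrically around t = 0; its pre-injection
half then leaked into the baseline window, biased F₀ for every pixel by
the same systematic, and made the saline control spuriously significant at
every time point — the post-injection placement keeps the baseline clean
and confines the saline group's only detectable effect to the dip bin
itself. At the generator's noise level that dip *is* statistically
detectable (unlike in real recordings, where animal-to-animal variability
swamps it); a saline run therefore typically stars the 15-min bin and
nothing else.

### What the generator does not model

Optics and PSF, photon-transfer-curve realism, fixed-pattern noise, motion
artifacts beyond the injection dip, and hardware behaviour are all out of
scope. Passing tests on synthetic sessions show the *analysis* is correct
and recovers planted structure at realistic signal-to-noise; they cannot
certify performance against real sensor artifacts.

## 2. ΔF/F₀ processing conventions

* **Baseline window.** F₀ defaults to the per-pixel mean over the 15
  minutes immediately before injection (`compute_f0(rec, c(-15, 0))`),
  matching the analysis span of the recordings; the full acclimation
  period is not simulated. The window is half-open `[start, end)` over
  frame-centre timestamps.
* **Invalid pixels.** Pixels with non-positive baseline are flagged and
  excluded from every downstream average (division by ~0 would make ΔF/F₀
  unbounded); they are never clipped or imputed.
* **Timestamps.** A duration of D minutes at r frames/s yields
  `floor(D·60·r)` frames with centres at `−pre_min + (k + 0.5)/(60·r)`.
  All downstream operations are frame-rate-agnostic.
* **Interval binning.** Intervals tile time as `((k−1)·w, k·w]` anchored
  at the injection and mirrored before it, labelled by their *end* time —
  "the 30-min mark" is the average over (15, 30]. The pre-injection
  control is the (−15, 0] bin, labelled `pre`. A bin is kept only if the
  recording covers it up to at most half a frame period of slack, so
  partial leading/trailing bins are dropped but a bin exactly tiled by
  frames counts as complete.
* **Exactness.** ΔF/F₀ is computed as `100·(F − F₀)/F₀` with the
  multiplication before the division, so exact inputs give exact percent
  values; ΔF/F₀ is invariant under any global gain on the raw counts.
* **Detrending.** No photobleaching correction is applied by default (the
  generator's default has no bleaching either; `bleaching_tau` exists to
  study it).

## 3. ROI detection

The detector formalises "analyse every frame with adaptive binarization and
morphological transformations" as:

1. **Adaptive binarization** (`binarize_frame()`): pixel active iff its
   ΔF/F₀ value exceeds the mean of its `block_size` × `block_size`
   neighbourhood by more than `offset`. Defaults: block 11 px, offset 1.0
   percentage point (thresholding ΔF/F₀ rather than raw counts gives the
   offset physical units). The local mean uses an integral image over
   edge-replicated padding — exact arithmetic, no FFT roundoff — and
   invalid pixels are replaced by the frame's valid mean before averaging
   so they do not bias their neighbours' thresholds (they can never be
   active themselves).
2. **Morphological cleaning** (`morph_clean()`): opening then closing with
   diamond (cross-shaped) elements of radius 1. Neighbours falling outside
   the frame are ignored — with a symmetric element this makes erosion and
   dilation adjoint on the frame, so opening/closing are idempotent and
   anti-extensive/extensive, properties the test suite asserts.
3. **Occupancy mapping**: the fraction of analysed (post-injection) frames
   in which each pixel was active, thresholded at `occupancy_min = 0.05`.
   Because occupancy is a fraction, the rule is invariant to the simulated
   frame rate. Opening removes almost all single-frame noise speckle, so
   background occupancy sits near zero while genuine sites (active
   whenever the transient clears the offset) score far above 0.05.
4. **Components and filtering**: connected components at 8-connectivity,
   area-filtered to [6 px, quarter-frame]; ids run from 1 in raster order
   of centroids (row, then column), deterministically.

Every step has an exhaustive from-definition oracle in the test suite, and
the full detector is asserted to match that oracle *exactly* on ≤ 12 × 12
stacks — this pins down edge handling, tie behaviour and connectivity, not
just typical-case agreement. On 20 seeded default-noise sessions, ≥ 80% of
planted sites must be recovered with ≤ 2 px centroid error with ≤ 20%
spurious detections.

Profile metrics of an interval trace take the earliest maximal
post-injection bin on ties; half-rise is the first bin reaching half the
peak; the baseline crossing is the first post-peak bin ≤ 0 (possibly none);
the undershoot minimum is the post-peak minimum.

## 4. Group statistics at n = 3

`rm_anova()` computes the standard subject × time decomposition from first
principles — SS_subject = k·Σᵢ(x̄ᵢ. − x̄)², SS_time = n·Σⱼ(x̄.ⱼ − x̄)²,
SS_error by subtraction — with F = MS_time/MS_error on (k−1), (n−1)(k−1)
degrees of freedom. An independent `aov(y ~ time + Error(subject))` fit is
the cross-check in the tests, never the implementation. If SS_error is
numerically zero the fit is flagged degenerate (p reported at the
machine-epsilon bound, or 1 when the time effect is also zero); missing
cells are an error, never imputed.

Post-hoc comparisons are paired t tests of each bin against the `pre`
control with Holm adjustment (`*` adjusted p < 0.05, `**` < 0.01). Holm
was chosen because it controls the family-wise error rate without any
sphericity assumption and matches the versus-control star pattern of the
group figures; Bonferroni and unadjusted are available. No
Greenhouse–Geisser correction is applied: with n = 3 the sphericity
estimate is far too unstable to help, which is a documented limitation of
the design, not of the implementation.

**Power at n = 3 deserves a caveat.** A paired t at 2 degrees of freedom
needs |t| ≈ 18 to clear a Holm-adjusted 0.05 across 15 bins. If the
between-animal spread of the response amplitude is 10% of its mean, the
non-centrality is only √3/0.1 ≈ 17, and the adjusted-p power is bounded
near P(χ²₂ < 2) ≈ 0.63 — no pipeline can do better, because the t
statistic is amplitude-free. The test suite therefore asserts raw-p power
≥ 95% under a planted 10% amplitude spread, and adjusted-p power ≥ 95%
under the generator's own between-animal variability (site-placement
geometry gives a 2–3% coefficient of variation at full sensor size), which
is the regime the three-animal groups actually occupy. The saline null is
simulated with the handling dip disabled (a dip is a real effect, not a
null), and the omnibus type-I error at α = 0.05 is required to sit in
[0.02, 0.09] over 200 simulated triplets.

## 5. Storage and determinism

Sessions are stored as multi-page TIFF (one page per frame, 32-bit samples)
with the frames divided by a power-of-two full scale recorded in the JSON
sidecar; round-trip error is below 2⁻³² of full scale — orders of magnitude
under one count of sensor noise, but not bit-exact, which the I/O tests
acknowledge with an explicit tolerance. The sidecar carries geometry,
frame rate, injection time, the uniform frame-centre timestamp policy, the
seed and (for synthetic sessions) the ground truth. `run_pipeline()`
validates its whole configuration before any computation, writes every
table/JSON/figure with an MD5 manifest, and is byte-deterministic in its
CSV/JSON outputs for a fixed configuration.

## 6. Problem sizes used by the tests

The default study condition — 40 × 90 px, 15 min pre to 225 min post at
one frame per 5 s (2880 frames), three animals per drug — is used for the
end-to-end checks (peak windows, post-hoc significance). Property-style
Monte Carlo runs scale the geometry or frame rate down (10–14 px frames at
1 frame per 20–60 s) so that hundreds of simulated triplets stay cheap:
the statistical properties under test (type-I error, power, family-wise
marking rate) depend on the distribution of the binned group table, not on
the pixel count, and the chosen sizes keep those distributions in the same
regime while the full-size acceptance runs cover the study condition
itself.
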