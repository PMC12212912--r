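---
title: "Quantifying Raynaud's attacks from hand photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Raynaud's attacks from hand photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(raynaudbd)
library(dplyr)
```

## The measurement problem

Raynaud's phenomenon (RP) is episodic vasospasm of the digits, defined
clinically by its skin colour change — pallor, cyanosis, then reactive
hyperaemia. Outcome assessment in RP trials still leans on subjective
patient-reported scores (the daily Raynaud's Condition Score, or a
per-attack 0–10 severity rating), and different patients use such scales
very differently: some anchor near the top, others minimise. A
smartphone photograph taken during an attack carries an objective record
of the colour change, if it can be reduced to a number.

This package implements that reduction:

1. The hand outline is obtained, either from an externally fitted
   landmark file (the faithful path for real photographs, where a
   statistical shape model produces the border) or, for images with a
   near-uniform background such as the bundled synthetic fixtures, from
   the package's own chroma-distance segmentation.
2. Twenty-five regions of interest (ROIs) are laid out: three per
   non-thumb digit (distal, middle, proximal thirds of the digit's
   vertical extent, inset from the border) over eight digits of the two
   hands photographed together, plus one dorsal reference ROI — the back
   of the hand is typically spared by vasospasm, so it provides a
   within-image baseline of the patient's normal skin at that moment,
   cancelling slower confounders such as tanning and ambient light.
3. ROI pixels are converted from sRGB to CIE L\*a\*b\* (IEC 61966-2-1
   decoding, D65 white, 2° observer). L\* is lightness; a\* and b\* are
   the green–red and blue–yellow hue axes.
4. Each digit ROI's colour distribution is compared with the dorsal
   reference by the Bhattacharyya distance. For histograms with bin
   masses $p_i$ and $q_i$, the Bhattacharyya coefficient is
   $BC = \sum_i \sqrt{p_i q_i} \in [0, 1]$ and $BD = -\ln BC$: zero for
   identical distributions, growing without bound as they separate.
5. BD is averaged over the 24 digit ROIs of an image, and over the
   images of an attack, giving one *mean BD per attack*.
6. Attacks are delimited either by timestamp chaining (two or more
   images whose consecutive gaps are at most 30 minutes) or by
   app-recorded attack-end times, and the per-attack mean BD is related
   to the reported severity by Pearson correlation, a two-factor ANOVA,
   and Tukey multiple comparisons.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| Channel subset | `ab` | The hue plane captures the red↔blue/white shifts that define RP while being insensitive to overall lightness; a full `lab` mode exists, and every results table records which was used. |
| Histogram binning | width 2, fixed edges over $[-60, 60]$ in a\*, b\* | Distributions are comparable only on shared edges; 2 units ≈ a just-noticeable colour step. Out-of-range values land in the edge bins. |
| Smoothing $\varepsilon$ | $10^{-9}$ on the union support | Prevents spuriously zero coefficients from isolated empty bins. |
| BD cap | 50 | Exactly disjoint supports would give $BD = \infty$; the sentinel keeps episode means finite and the record is flagged. |
| Episode window | 30 min | An attack is "two or more images within a sliding 30-minute window", read as transitive chaining: consecutive gaps ≤ 30 min (a gap of exactly 30 joins). Chaining is brute-force checkable against union-find over all pairs. |
| App-mode grace | 5 min | The closing photograph may follow the recorded attack end by a moment. |
| ROI inset | 20% of local digit width | Keeps ROIs clear of border mixing pixels. |
| Minimum ROI size | 50 px | Smaller ROIs are flagged degenerate and excluded from means. |

The estimator is the histogram BD by default; a Gaussian
(moment-matched) mode provides the closed form
$BD = \tfrac18 d^\top \bar\Sigma^{-1} d + \tfrac12 \ln
\left(\det\bar\Sigma / \sqrt{\det\Sigma_1 \det\Sigma_2}\right)$, which
doubles as an independent oracle: on $10^5$ samples the histogram
estimate agrees with the closed form to within a few percent when the
bin width is matched to the distribution scale (about half the smallest
standard deviation — coarser bins bias the discretised distance low).

Colour conversion is implemented from the standard constants rather than
delegated, because the package's whole contract runs through it; it is
verified against reference values from an independent implementation of
the CIE formulas to 0.1 units.

## The synthetic study

No patient photographs ship with the package, so a generator
(`generate_dataset()`) renders the entire data layout an imaging app
would produce: per-patient folders of date-stamped subfolders holding
JPEG images (quality 95, EXIF `DateTimeOriginal` set) plus plain-text
attack and daily questionnaire records, and a ground-truth table.

The rendered scene is deliberately stylised — two flat-background hands
with rectangular, round-tipped digits — because the pipeline's contract
is colour statistics over masks, not shape realism. The study
conditions, chosen once as a plausible imaging scenario and then left
alone:

* **Base skin colour** sRGB (200, 160, 140), a light skin tone
  reflecting the study population this method was developed in.
* **Vasospastic shift**: each attack shifts all digits by a magnitude
  $m$ along $(-0.8, -0.6)$ in the (a\*, b\*) plane — less red, more blue.
  Episode magnitudes sweep a deterministic, evenly spaced ladder over
  2–14 units per patient (10 episodes). A designed sweep, rather than
  uniform random draws, keeps parameter-recovery questions well posed:
  random draws can place two episodes arbitrarily close together, where
  no estimator could rank them. The analysis pipeline never sees the ladder.
* **Pixel noise** sd 3 L\*a\*b\* units per channel. Lightness noise is
  per-pixel; chroma noise is generated at 2×2-pixel blocks, the chroma
  resolution of a 4:2:0 JPEG — finer chroma variation would not survive
  the camera's own encoder, so rendering it would misstate what the
  analysis can ever see.
* **Severity reporting**: `clip(round(0.65 m + offset + N(0, 0.5)), 0, 10)`
  with a per-patient offset drawn from $\{-2, \dots, 2\}$ — the
  subjective-scale behaviour (some patients always score high, others
  minimise) that motivates including patient as a factor in the ANOVA.
* **Timing**: 3–5 images per episode, 2–8 minutes apart; two episodes
  per day four hours apart, so within-episode gaps sit far below the
  30-minute window and between-episode gaps far above it.

What the fixtures do *not* emulate: illumination geometry and shadows,
camera-to-camera colour response, motion blur, partial hands, varied
skin tones, and anatomical shape. Passing tests therefore demonstrate
the correctness of the measurement chain on its own terms — mask-based
colour statistics, grouping, inference — not robustness to real-world
photography, which in the intended workflow is handled upstream
(photography instructions, quality review via the exclusion list, and
externally fitted landmarks).

`simulate_episode_bd()` is the generator's statistical layer: it draws
per-episode mean BD and severity directly, without rendering, and is
used where many replicate datasets are needed (e.g. 500 simulations for
the type-I error of the severity test).

## Numerical and design choices

* **Sliding window semantics.** Transitive chaining with a ≤ boundary
  was chosen as the simplest reading of the window definition; it is
  order-invariant, idempotent, and checkable by brute force.
* **Estimator edge cases.** Exactly disjoint histogram supports report
  $BC = 0$ with the capped sentinel and a flag; a singular pooled
  covariance in the Gaussian mode is ridge-regularised and logged.
  Degenerate ROIs (below 50 px) never enter means; an image with no
  usable ROI, or an episode with no usable image, is dropped with a
  warning rather than silently imputed.
* **ANOVA.** `mean_bd ~ patient + severity`, both categorical, no
  interaction, Type II sums of squares (severity counts per patient are
  naturally unbalanced). Patient enters as a fixed factor — the simplest
  model that absorbs subjective scale use; a mixed model is out of
  scope. Severity is categorical because the per-level comparisons are
  the target display. If severity is constant within every patient the
  factors are confounded and the fit refuses by name.
* **Tukey display.** Per-level adjusted means carry comparison
  half-widths $q^* \, \mathrm{se}_i / \sqrt2$ (with $q^*$ the
  studentised-range quantile scaled for pairwise differences), so
  non-overlap of two intervals coincides with Tukey significance under
  equal standard errors and approximates it otherwise. Levels with one
  observation are kept, flagged, with accordingly wide intervals.
* **Timestamps** are timezone-naive local times (EXIF carries no zone;
  episodes span minutes), pinned to UTC internally so arithmetic is
  DST-free. Ties are broken path-lexicographically for determinism.
* **Reference ROI placement** when both hands are detected: the dorsum
  of the hand with the larger segmented area.

## A worked run

A small end-to-end pass (one patient, two episodes; the package default
is five patients × ten episodes):

```{r, eval = FALSE}
root <- file.path(tempdir(), "demo")
g <- generate_dataset(root, n_patients = 1, episodes_per_patient = 2,
                      seed = 42)
res <- analyze_folder(root, rp_config())
res$episodes
```

On the full default conditions the pipeline recovers all 50 generated
episodes, ranks per-attack mean BD identically to the true shift ladder
within every patient, and the severity factor of the ANOVA is
overwhelmingly significant while 500 null simulations reject at the
nominal 5% rate — these are exactly the quantities recomputed by
`scripts/acceptance.R`.

```{r, eval = FALSE}
fit <- bd_anova(res$episodes)
glance(fit)
autoplot(tukey_hsd(fit))   # adjusted level means with comparison intervals
```

## Known limitations

* The fallback segmentation expects a near-uniform background; real
  photographs need landmark sidecars from an external shape model.
* Thumbs are excluded by construction (eight digits, three ROIs each);
  nail regions are not separated out.
* BD is a distance: it reports the *magnitude* of colour change, not
  its direction (pallor vs hyperaemia look alike to it).
* The capped sentinel bounds, but does not remove, the influence of
  disjoint-support records on means; capped records are flagged so
  downstream users can filter.
* Mixed-effects and ordinal-severity models, palmar views, and
  camera-specific colour profiling are deliberately out of scope.
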