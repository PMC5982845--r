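---
title: "Contactless cardiorespiratory monitoring from thermal video: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless cardiorespiratory monitoring from thermal video: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermovitals)
```

## The measurement problem

Heart rate (HR) and respiratory rate (RR) are routinely measured with
sensors glued or strapped to the body. A calibrated thermal camera can
recover both without contact, from two physically independent signals:

* **Respiration.** Air drawn through the nostrils is at room temperature;
  exhaled air is near core temperature. The skin just below the nose
  therefore cools during inspiration and warms during expiration, by a few
  tenths of a kelvin — well above the noise floor of a research-grade camera
  (noise-equivalent temperature difference, NETD, around 0.025 K).
* **Heart rate.** Every systole ejects blood through the carotid arteries
  and the aortic arch into the head, and the recoil moves the head — head
  ballistocardiography (BCG). The motion is vertical, periodic at the
  cardiac frequency, and *sub-pixel* at typical camera geometry, so it must
  be recovered by sub-pixel feature tracking rather than by any visible
  displacement.

`thermovitals` implements both estimation branches, the agreement
statistics used to validate them against contact references, and a
synthetic scene generator that renders thermal videos with known ground
truth so that every stage is testable without access to clinical
recordings.

## Respiratory branch

The nose region of interest (ROI) is supplied by the user and tracked
across the video by normalized cross-correlation of the first frame's
template within a ±20 px neighbourhood of the previous position
(integer-pixel precision is sufficient because the waveform is an average
over tens of pixels). Inside the tracked ROI, a centred sub-rectangle of
half the area — the region of measurement (ROM) — is averaged per frame:

$$\bar s(t) = \frac{1}{mn} \sum_{i=0}^{m-1} \sum_{j=0}^{n-1} s(i,j,t),$$

giving the respiratory waveform at the frame rate. It is band-passed with
a second-order zero-phase Butterworth filter, 3 dB corners at 0.1 and
0.85 Hz (6–51 breaths/min).

Breath-to-breath intervals are then estimated at stride-spaced window
centres. For every candidate lag $m$ in
$[\lceil f_s/0.85\rceil, \lfloor f_s/0.1\rfloor]$ samples, an adaptive
window $w[v]$, $v \in [-m, m]$, around the current centre feeds three
estimators:

* autocorrelation $E_{AC}[m] = \frac{1}{m}\sum_{v=0}^{m} w[v]\,w[v-m]$,
* the reciprocal average magnitude difference
  $E_{AMDF}[m] = \left(\frac{1}{m}\sum_{v=0}^{m} |w[v]-w[v-m]|\right)^{-1}$
  (guarded by $\varepsilon = 10^{-12}$ so a perfectly periodic window maps
  to a finite maximum), and
* maximum amplitude pairs
  $E_{MAP}[m] = \max_{v\in\{0..m\}} (w[v]+w[v-m])$, an indirect peak-pair
  detector.

Each estimator is converted to a probability mass over the lag grid by
shifting to non-negative values and normalizing to unit sum, and the three
masses are fused as a Bayesian product,

$$P(m \mid E_{AC}, E_{AMDF}, E_{MAP}) \propto
  P(m \mid E_{AC})\, P(m \mid E_{AMDF})\, P(m \mid E_{MAP}),$$

renormalized. The reported interval is the posterior argmax and the rate is
$RR = 60 f_s / \hat m$ breaths/min.

**Sub-harmonic disambiguation.** A signal with period $T$ is also
$2T$-periodic, so all three estimators score high at integer multiples of
the true interval; for a near-stationary breathing pattern the posterior
carries near-equal peaks at $T$ and $2T$ and the argmax alone can fall an
octave low. As in pitch estimation, the reported interval is therefore the
smallest integer sub-multiple of the argmax whose local posterior mass
(within ±3 lags) reaches half the argmax mass
(`subharmonic_theta = 0.5` in `rr_config()`; set to 0 to disable). At true
rates whose half-interval corresponds to an anti-correlated lag this check
never fires, because the posterior has no mass there.

## Heart-rate branch

1. **Preprocessing** (every thermogram): thresholds from a multilevel Otsu
   search (exhaustive maximization of between-class variance over a 256-bin
   histogram; two classes by default, since skin is reliably warmer than
   the room), head mask = pixels above the top threshold, cleaned by
   largest-connected-component and hole filling; then a linear contrast
   stretch of the in-mask gray levels between their 1st and 99th
   percentiles, with the background set to 0. Re-thresholding each frame
   makes the branch invariant to slow global temperature drift. The stretch
   percentiles are computed over the mask eroded by a 7 px disc: boundary
   pixels are sub-pixel blends of skin and background whose in-and-out
   flicker would otherwise wobble the mapping from frame to frame and leak
   into the tracked motion.
2. **Feature selection** (first frame only): Shi–Tomasi cornerness
   $R = \min(\lambda_1, \lambda_2)$ of the Sobel structure tensor summed
   over a 5 px window, restricted to a user-chosen lower-face ROI with the
   mouth rectangle excluded (lip motion is not cardiac); the strongest
   corners are kept greedily with a 5 px minimum separation, at most 100.
3. **Tracking**: frame-to-frame pyramidal Lucas–Kanade with sub-pixel
   output (3 levels, 21 px patches, 30 iterations, 0.01 px convergence).
   The residual is affine-intensity-compensated (both patches zero-meaned
   and contrast-equalized) so the per-frame contrast renormalization cannot
   bias the motion estimate, and the Gauss–Newton step uses the symmetric
   (ESM-style) average of template and image gradients, which cancels the
   first-order interpolation bias of one-sided Lucas–Kanade and keeps the
   recovered sub-pixel amplitude within a few percent of truth. Points
   whose patch leaves the frame or whose residual diverges are invalid from
   that frame on; there is no re-acquisition.
4. **Pruning**: each point's maximum inter-frame displacement is compared
   with the 95th percentile of these maxima pooled over points; strict
   exceedance drops the point (never below 10 survivors). Pooling keeps the
   threshold defined when tracks have different valid lengths.
5. **Per window** (256 samples, stride 50 at 50 fps): each vertical
   trajectory is band-passed at 0.65–5 Hz (the wide band keeps cardiac
   harmonics, which sharpen the periodicity score), the 15% of columns with
   the largest L2 norms are excluded (gross motions dominate the
   covariance), and PCA is computed on the rest. The first six components
   are scored by the peak-to-total ratio — the fraction of spectral power
   within ±0.05 Hz of the dominant frequency and of its first harmonic —
   and the most periodic component wins. Its dominant frequency, restricted
   to 0.65–2 Hz (39–120 beats/min resting range), is the heart rate;
   estimates outside that plausibility band are dropped, and every kept
   estimate carries its periodicity ratio so that unconfident output is
   visible downstream.

### Numerical choices

* **Zero-phase filtering.** The branches compare signals across channels
  and windows; single-pass IIR filtering would skew their relative phase,
  so the filter runs forward and backward (corner gain 0.5 instead of
  $1/\sqrt 2$). The input is demeaned first — the pass band rejects DC
  anyway, and demeaning eliminates the DC step transient entirely — and
  edges are padded by odd reflection over three impulse-response time
  constants ($3 f_s / 2\pi f_{lo}$ samples).
* **Spectral readout.** A 256-sample window at 50 fps has a raw bin width
  of ~0.2 Hz ≈ 12 beats/min, far coarser than the bpm-level agreement the
  method achieves, so windows are Hann-tapered, zero-padded to 4096
  samples, and the peak is refined by three-point parabolic interpolation —
  applied only at strict local maxima so that exact ties resolve to the
  lower frequency. A noiseless tone anywhere in the search band is then
  located to better than half a padded bin (~0.006 Hz).
* **Peak-to-total ratio scale.** With a 256-sample Hann window the main
  spectral lobe of a pure tone is ±0.39 Hz wide, so the ±0.05 Hz bands
  capture only about a third of a clean tone's power. The ratio is
  meaningful *comparatively* — a periodic component scores several times
  higher than broadband noise — and the component selection uses it only
  that way; its absolute value should not be read as a quality percentage.
* **Power vs amplitude.** "Spectral density" is ambiguous; squared
  amplitude is used, which weights the concentrated peak more strongly and
  separates periodic from broadband components more sharply.
* **Ties.** Component-selection ties go to the lower component index;
  lag-posterior ties to the smaller lag; L2-exclusion ties drop the higher
  column index. All are arbitrary but fixed, keeping reruns bit-identical.
* **Degenerate inputs** raise typed conditions (`tv_config_error`,
  `tv_degenerate_error`, `tv_segmentation_error`, `tv_tracking_error`, …)
  rather than returning silent numbers; the pipeline wrappers add the
  failing stage name.

## The synthetic scene generator

`generate_scene()` renders the study conditions the pipelines target: a
~34 °C elliptical head over a 22.3 °C background at 50 fps, with

* a frozen facial speckle field (0.8 K SD, smoothed) that gives the tracker
  corners — thermal faces have muted texture compared to visible light, and
  tracking must work on that reduced contrast;
* rigid vertical head motion
  $\delta(t) = A\sin(2\pi f_{HR} t) + \text{drift}$, rendered by bilinear
  sub-pixel resampling of the static template. The default $A = 0.3$ px is
  a deliberate test choice (no measured pixel amplitude is available for
  head BCG), small enough that the tracker is exercised genuinely below
  one pixel;
* an additive nostril term $-a\,w(f_{RR} t)$, cold during inspiration,
  either sinusoidal or with an asymmetric fast-inspiration/slow-recovery
  waveform, because the interval estimators must not depend on a
  sinusoidal shape;
* i.i.d. Gaussian sensor noise of 0.025 K SD, matching the stated NETD of a
  cooled research camera.

What the generator deliberately does **not** model: radiative physics and
emissivity, airflow convection patterns, facial expression and swallowing,
occlusions, camera vibration, and realistic head shape. Passing the
recovery tests therefore demonstrates that the algorithm chain is
implemented correctly and reaches its accuracy under ideal-but-noisy
conditions; it does not by itself establish clinical performance, which
the bundled per-subject pilot tables summarize from real recordings.

## Problem sizes used in the tests

Unit tests run on 32–96 px scenes of 4–30 s so the suite stays fast; the
acceptance checks run the full study conditions, 128 × 128 px at 50 fps
for 60 s, over heart rates {50, 70, 90, 110} beats/min and respiratory
rates {9, 15, 21} breaths/min with both waveforms. These sizes are the
package's reference configuration for reproducing its accuracy figures.

## Known limitations

* ROIs are user-supplied, as in the underlying protocol; there is no
  automatic face or nose detection.
* Lost feature points are never re-acquired, so long recordings with a
  large posture change degrade to the pruned survivor set.
* One rate is read per analysis window; the package does not attempt
  beat-to-beat HR variability.
* The ROI tracker is integer-pixel and template-based; large rotations or
  scale changes of the face will break the correlation and raise a
  tracking error rather than degrade silently.
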