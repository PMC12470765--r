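---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science behind each pipeline: the models and
their assumptions, the tunable parameters with their defaults and
rationale, the numerical conventions, and what the synthetic-data
generators do and do not emulate.

## Ratiometric Ca²⁺ trace analysis

### Signal model

A cameleon-type FRET sensor converts a cytosolic Ca²⁺ rise into an
increase of acceptor emission (F535) and a simultaneous decrease of donor
emission (F480). Writing the summed transient modulation as $s(t)$, the
package models the two channels as

$$F_{535}(t) = F_{535}^0\, e^{-\beta t}\,(1 + s(t))\,(1+\varepsilon_1),
\qquad
F_{480}(t) = F_{480}^0\, e^{-\beta t}\,(1 - s(t))\,(1+\varepsilon_2),$$

with shared photobleaching $\beta$ and independent multiplicative white
noise $\varepsilon_i \sim N(0, \sigma_\text{noise}^2)$. The analysis
works on the ratio $R = F_{535}/F_{480}$, in which every shared
multiplicative factor — bleaching, excitation fluctuations — cancels
exactly. This symmetric $\pm s$ coupling is the simplest model producing
mirror-image channel changes; real sensors have unequal dynamic ranges in
the two channels, which changes amplitudes but not the sign structure the
detector relies on.

Same-sign artifacts (focus drift, motion) are modelled as events that move
*both* channels in the same direction but with unequal per-channel gains
(defaults 1.0 for F535, 0.6 for F480, emulating the two emission paths
responding differently to defocus). The unequal gains matter: an artifact
scaling both channels identically would cancel in the ratio and be
invisible; with unequal gains it produces a ratio excursion that the
detector sees and the mirror criterion must reject.

### Transient kernel

No closed form is standard for spontaneous vulva-muscle transients, so the
generator uses the usual Ca²⁺ phenomenology, a normalized double
exponential

$$s(t) = A\,\frac{e^{-(t-t_0)/\tau_d} - e^{-(t-t_0)/\tau_r}}{\max(\cdot)},
\qquad \tau_r < \tau_d,$$

whose peak modulation is exactly $A$, plus a triangular kernel whose
metrics have closed forms for exact tests. Defaults ($A = 0.1$,
$\tau_r = 1$ s, $\tau_d = 5$ s, 1% channel noise) give transients about
15 times the per-frame ratio noise — comfortably detectable, as
spontaneous muscle transients are in practice. The amplitude/duration
*distributions* of real recordings are unknown to us; the defaults are
plausible placeholders, not calibrated to any real data set, so recovery
results quantify algorithm performance under these conditions only.

### Detection pipeline and its parameters

`analyze_recording()` chains ratio → smoothing → baseline → candidate
detection → mirror filter → per-peak measurement. All parameters live in
`analysis_config()`:

| parameter | default | role and rationale |
|---|---|---|
| `smooth_s` | 2 s | centered moving average on the ratio (5 frames at 2.5 Hz). A single-frame noise spike has prominence up to ~6 σ and would otherwise pass a 4 σ threshold; averaging suppresses it while widening a multi-second transient only slightly. |
| `baseline_window_s` | 60 s | sliding window for the resting-ratio percentile; long against transients (~15 s footprint), short against slow drift. |
| `baseline_prob` | 0.1 | low percentile, insensitive to transients occupying < 50% of a window. The noise-induced offset of a percentile below the resting mean, $q_p\,\sigma$, is known analytically and added back, so the baseline is unbiased; for a noise-free trace the correction is exactly zero. |
| `k` | 4 | prominence threshold in units of the *raw* per-frame noise SD $\hat\sigma = 1.4826\,\mathrm{median}|\Delta R|/\sqrt 2$ (robust: sparse transients contribute few large differences). Smoothed noise prominence stays well below $4\hat\sigma$, so pure noise yields no candidates while any event a few times the noise floor passes. |
| `mirror_threshold` | −0.5 | maximum channel correlation for acceptance; a genuine mirror event correlates strongly negatively, artifacts positively, so the acceptance band is wide on both sides. |
| `eps` | 0.1 | a peak starts/ends where the excess ratio re-enters `eps` × height; defines "base to peak" operationally since "base" has no unique definition on a noisy trace. |
| `min_sep_s` | 2 s | minimum apex separation; closer events merge at the inter-peak trough. |

The mirror score is the Pearson correlation of the two linearly detrended
channels over the candidate interval, computed on lightly smoothed
channels (same width as the ratio smoothing). Frame noise is uncorrelated
between channels and only dilutes the correlation of a true event toward
zero; smoothing makes the score measure the event waveform. A sign check
(acceptor up *and* donor down at the apex relative to the interval edges)
accompanies the correlation, so a same-sign artifact can never be
accepted regardless of amplitude. Mirror validation is applied per peak,
not once per record: a record can contain both genuine transients and
artifacts, and per-peak validation keeps the former.

Peak metrics follow the classical definitions: height as percent ratio
change from base to peak, total width and width at half-height (crossings
linearly interpolated between frames, ties at the apex broken to the
earliest frame), rise time $t_\text{apex}-t_\text{start}$, decay time
$t_\text{end}-t_\text{apex}$, and the derived quotients rise rate =
height / time-to-peak and decay rate = height / decay time, which satisfy
rate × time = height identically by construction. Peaks truncated by the
record edges are discarded and counted separately. The time base is taken
from the time column and is not assumed uniform.

Group summaries are offered both pooled over peaks and averaged per
recording first; the two differ in their SEM (peaks within a worm are not
independent), so both are reported rather than choosing silently.

### Ground-truth oracle

`transient_oracle_metrics()` computes each kernel's reference metrics by
brute force on a dense grid (default 1/2500 s, 1000 × finer than the
frame interval) of the noise-free ratio, using the same
`eps`-boundary and half-height definitions. Oracle and pipeline share the
*definition* of the measurand but no code path: the oracle never sees
sampled, noisy data, and the pipeline never sees the dense grid.

## Mitochondrial linearity

Lines run parallel to the declared longitudinal axis by default (the
quantity of interest is continuity along the muscle axis); a fully random
orientation mode exists for sensitivity checks. Sampling is
nearest-pixel at unit spacing — the binarization rule (0 → 0, non-zero →
1) implies integer intensity reads, so no interpolation is used. Scores
are integer sums, 0–200.

Morphology uses 8-connected components. Aspect ratios come from the
moment-equivalent ellipse with the continuous pixel model (central second
moments plus the 1/12 unit-pixel term), under which an axis-aligned
$L \times W$ rectangle scores exactly $L/W$. The mask frame is treated as
one cell unless a cell mask is supplied.

The generator paints sarcomere rows of $20 \times 4$ px units on a lattice
whose bands tile the image height, so a fully populated, unjittered mask
covers every row-aligned line completely. Disorganization has two knobs:
independent unit deletion with probability `gap_prob` (expected line
coverage $(1-g)\,\ell/(\ell+\text{gap})$) and transverse jitter, which
moves bands off the sampled row and lowers coverage below that
expectation. Deletion draws precede jitter draws so the deleted set grows
monotonically with `gap_prob` at fixed seed. Note that line coverages
sampled from a *single* mask estimate that mask's realized coverage, not
the generator expectation; validation against the closed form therefore
draws many independent masks (100 masks × 100 independent rows per
gap-probability value, 10⁴ lines per rung of a 10-value ladder).

## ThT aggregate quantification

Z-stacks are reduced by maximum-intensity projection before any
thresholding. The worm body is the largest 8-connected supra-threshold
component with internal holes filled; aggregates are 8-connected
supra-threshold components inside the body with area ≥ `min_size`
(holes inside ROIs are not filled). The published workflow's manual ROI
review is replaced by the `min_size` filter for reproducibility; the
batch driver enforces one threshold per batch and refuses per-image
thresholds unless explicitly overridden. The area fraction
$\sum_i |\text{ROI}_i| / |\text{worm}|$ is invariant under joint intensity
rescaling of image and thresholds.

The generator paints an elliptical body (background 10, body 60,
aggregate 200 a.u.; Gaussian noise default 2 a.u.) with circular
aggregates wholly inside the body; truth is direct pixel counting on the
noise-free label image, overlapping disks counted once. Validation uses
20 seeded images with 5 aggregates of 4–7 px radius. Real ThT images
differ in ways the generator does not emulate: graded dye uptake, off-body
fluorescence, out-of-focus light and irregular body outlines; passing
recovery tests therefore demonstrates correctness of the measurement
chain, not robustness to acquisition pathology.

## Group statistics

Normality is tested per group with the Lilliefors-corrected
Kolmogorov–Smirnov test (plain KS with estimated parameters is
anti-conservative). Two groups: two-tailed unpaired Student's *t*-test;
three or more: one-way ANOVA with Tukey HSD. Stars at
0.05/0.01/0.001/0.0001 are a pure function of p. When any group fails
normality the parametric result is still reported, alongside a clearly
labelled rank-based sensitivity test (Wilcoxon rank-sum or
Kruskal–Wallis) — transparency instead of a silent test switch. The
two-group path holds its nominal 5% type-I error, checked over 2000 null
replicates.

## Problem sizes and determinism

Validation runs use 50 simulated 900-s recordings at 2.5 Hz for parameter
recovery, 10⁵ Monte-Carlo lines for the linearity ladder, 20 aggregate
images, and 2000 null replicates for the type-I error — sizes at which
Monte-Carlo error is small against every tolerance tested. Every
generator is a pure function of its parameters including the seed; the
batch pipeline logs package version, seed and parameters, and reruns are
byte-identical.

## Known limitations

- Transient amplitude/duration defaults are not calibrated to real vulva
  muscle data; absolute recovery numbers hold for these conditions.
- No Ca²⁺ concentration calibration from YC2.1 ratios, and no
  motion correction — input is assumed to be a stable ROI trace.
- Mitochondrial segmentation itself is accepted as input (a fixed or Otsu
  threshold is provided only as a fallback); the linearity score
  quantifies the mask it is given.
- The per-cell unit count normalizes to the mask frame unless a genuine
  cell outline is supplied.
- No optics (PSF) or 3-D simulation; images are 2-D and noise is
  Gaussian.
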