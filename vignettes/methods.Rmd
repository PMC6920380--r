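---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquant)
```

This vignette documents the models behind each analysis stage, the
parameters that matter (with units and defaults), what the synthetic
data emulate — and do not — and the numerical choices made where the
design was genuinely open.

## Stain quantification

### Optical model

Brightfield stains obey Beer-Lambert absorption: with incident white
intensity $I_0$ per channel, a pixel's optical density is
$OD_c = -\log_{10}(I_c / I_{0,c})$, and stains mix *additively* in OD
space. A pixel's OD vector is therefore
$\mathrm{od} = c_{\mathrm{hema}} H + c_{\mathrm{dab}} D$, where $H$ and
$D$ are unit-norm OD direction vectors. Colour deconvolution inverts
this 3×3 system per pixel. The package uses the standard H-DAB basis
(hematoxylin ≈ (0.650, 0.704, 0.286), DAB ≈ (0.269, 0.568, 0.778)) with
the normalised cross product as the residual channel; no stain-vector
estimation from data is attempted (`stain_matrix()` accepts custom
vectors where a lab has calibrated its own).

Intensities are floored at $\varepsilon = 1$ intensity unit before the
logarithm, so $OD$ stays finite at $I = 0$; white balance estimates
$I_0$ per channel as the 99th percentile of that channel (robust to a
small fraction of specular or saturated pixels) and rescales it to 255.
The estimator relies on the image containing bare glass; a tissue-filled
frame would need an explicit `white_point`. Note a bias worth knowing
about: with additive OD noise *and* 8-bit clamping, upper-percentile
estimation is exact only when the true white point sits at the clamp
(the usual case after camera exposure is set against glass); for
unclamped sources, pass the known `white_point` instead.

### Grayscale and threshold

The DAB concentration channel is mapped to an analysis grayscale by the
affine, order-reversing map $g = g_{\max} - (g_{\max}/od_{\max}) \cdot
c_{\mathrm{dab}}$ with $od_{\max} = 2$ and $g_{\max} = 255$, so strongly
stained pixels are dark. The map is deliberately not clipped, which
keeps it exactly invertible; values below 0 simply remain "very dark".
The alternative of taking a luminance grayscale of the raw RGB was
rejected: it mixes hematoxylin into the TH signal, whereas the
DAB-channel map isolates the chromogen the threshold is meant to find.

The threshold for a region on a section pools the ipsilateral and
contralateral ROI pixels and takes
$T = \mathrm{mean} - 0.5\,\mathrm{SD}$ (sample SD, $n-1$ denominator —
consistent with the SEM/t-test conventions used downstream). Pooling
both hemispheres into one threshold is what makes the ipsi/contra
comparison fair; computing $T$ per section per region absorbs the
time-sensitive nature of DAB colour development. "Below the threshold"
is implemented strictly ($g < T$); boundary pixels are excluded.

### Aggregation

Per mouse and region, the per-section area fractions are averaged per
hemisphere (unweighted), and the DAB area ratio is the ratio of the two
means — *ratio of means*, not mean of per-section ratios, which is more
stable when contralateral fractions are small. When ROI sizes differ
between sections, mean-of-fractions and pooled-pixel fractions differ;
the unweighted mean treats each section as one biological observation,
matching one-point-per-mouse plotting.

ROIs are supplied as integer label masks with a JSON legend (atlas-based
manual segmentation is upstream of this package). Pixel-center
coordinates, row-major, no sub-pixel geometry.

## Cavitation dose metrics

Each pulse is transformed with an FFT into a one-sided spectrum whose
squared magnitudes sum to the signal's mean square (interior bins carry
the conjugate half's energy, i.e. are scaled by $\sqrt{2}$). A band dose
is the root-sum-of-squares of magnitudes over the band's bins. Under
this normalisation:

* a sinusoid of amplitude $A$ on a bin contributes exactly $A/\sqrt 2$
  (its RMS) to any window containing its bin;
* ideal band-limited white noise of pre-filter SD $\sigma$ contributes
  its analytic in-band RMS $\sigma\sqrt{W/(f_s/2)}$ for total bandwidth
  $W$ (`noise_band_rms()`);
* the full-band dose equals the time-domain RMS (Parseval), which the
  tests verify to 0.5%.

A per-bin root-*mean*-square was rejected because it would make a
tone's dose depend on the window width and the noise dose
non-analytic; root-sum-of-squares is the unique scaling with the three
properties above.

The band plan at $f_0 = 1.5$ MHz over 3–9 MHz places harmonic windows
at {3, 4.5, 6, 7.5, 9} MHz and ultraharmonic windows at {3.75, 5.25,
6.75, 8.25} MHz, each extending ±150 kHz (10% of $f_0$; the half-width
must stay below $f_0/4$ so the two window families remain disjoint).
Window membership is half-open on the upper edge — bins with
$c - \Delta f \le f < c + \Delta f$ — and windows are clipped at the
band edges, so a harmonic sitting exactly on the 9 MHz edge loses its
upper half-window (a sub-1% effect in the default configuration). ICD
is computed over the band minus all windows; because ICD excludes the
windows by definition, its reference value for band-limited noise is
the analytic RMS over that *support*, not over the full band.

The default spectral window is rectangular: simulated and typical
recorded pulses are steady-state within the analysis gate, where
rectangular windows give the sharpest tone concentration. A Hann
option exists for pulses with transients; it is normalised by its RMS
so broadband levels are preserved, at the cost of smearing tone energy
into neighbouring bins.

Per-sonication aggregation is the mean over pulses, so the normalised
dose (with microbubbles ÷ without) is insensitive to pulse count;
normalisation fails loudly, naming the metric, if a baseline aggregate
is zero.

## Rotation counting

Headings are unwrapped by mapping successive differences into
$(-180°, 180°]$ and accumulating. A clockwise turn (CW = decreasing
heading in image coordinates; the `cw_sign` flag flips this for mirrored
camera mounts) is registered by an accumulator each time the cumulative
angle moves a further 360° below its running reference, the reference
stepping by 360° per completed turn in either direction. Partial turns
never count. CCW turns are counted by running the same clockwise
accumulator on the time-reversed trace. This makes the two directions
exactly symmetric — reversing any trace swaps CW and CCW — which a
single shared-reference pass does not guarantee for mixed-direction
traces (the completed-turn phase offsets the reversed threshold
lattice). On monotone or well-separated turn sequences the two
formulations agree. Counts are invariant to time rescaling and to
adding a constant to all headings. An analysis window (half-open, in
seconds) trims acclimation periods before counting; the conventional
session is 10 min acclimation followed by 40 min of scoring.

The Grubbs screen is the standard two-sided single-outlier test:
$G = \max_i |x_i - \bar x| / s$ against
$G_{\mathrm{crit}} = \frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with $t$
the upper $\alpha/(2n)$ Student quantile on $n-2$ df. It is single-pass
(at most one value removed), which matches the screening use case; the
p-value is the Bonferroni-style tail bound obtained by inverting $G$
back to $t$, capped at 1.

## Group statistics

Within each group, a two-tailed paired t compares ipsilateral and
contralateral means; across groups, a one-way ANOVA on the area ratios
is followed by pairwise comparisons using the ANOVA's pooled
within-group variance ($t = (\bar x_a - \bar x_b)/\sqrt{MS_W(1/n_a +
1/n_b)}$, $df = N - k$), corrected with the Holm-Sidak step-down
adjustment $1 - (1-p_{(i)})^{m-i+1}$ with enforced monotonicity. All
three group pairs are corrected by default (configurable where a study
pre-registers fewer). No correction is applied to the within-group
paired tests, which answer separate questions. Degenerate inputs (zero
variance) return flagged result objects rather than raising, so batch
analyses of many regions complete and report which tests were
undefined.

Percent-injected-per-gram values are *truncated*, not rounded, to one
decimal (29.05 µg/g of a 400 µg dose → 7.2625 → 7.2 %/g), matching the
convention of biodistribution tables; a flag disables truncation.

## Synthetic data: what it emulates, and what it does not

`gen_histology()` draws TH+ pixels as a spatially random subset of each
ROI at the requested fraction — the simplest model with *exact*
area-fraction ground truth — places tissue (hematoxylin background, OD
0.3) only inside ROIs with bare glass elsewhere, applies the
Beer-Lambert forward model with optional Gaussian OD noise, and
quantizes to 8 bits (a float mode disables quantization for 1e-6
round-trip tests). It does not emulate morphological clustering of TH+
neurons, uneven illumination, stain colocalisation gradients, section
artifacts, or counterstains. Passing recovery tests therefore shows the
*algorithmic* chain (balance → OD → deconvolution → threshold → ratio)
is correct, not that real tissue meets its assumptions; OD levels are
free parameters, not calibrated to any particular scanner or staining
batch. With the default DAB amplitude (OD 1.0) and noise SD 0.05, the
TH+/background separation on the analysis grayscale is about 12 noise
SDs, comfortably beyond the ≥ 4 SD regime in which fraction recovery
within ±0.02 is claimed.

`gen_pcd()` sums harmonic and ultraharmonic tones (zero phase), a
Gaussian broadband component ideally band-limited to 3–9 MHz by FFT
masking, and wideband sensor noise, at 50 MS/s for 0.2 ms (10,000
samples, placing every default tone exactly on a bin). Ground truth
stores each component's analytic RMS. It does not model bubble
dynamics, frequency-dependent attenuation, or transducer response.

`gen_rotation()` builds a piecewise-linear cumulative angle completing
the requested CW then CCW turns, overshooting each block by 135° so
that completed turns are robust to heading jitter, which is Gaussian
clamped at 4.5 SD (capped below 90°). Configurations whose planned
per-sample step could combine with jitter to exceed the 180° unwrap
limit are rejected, as are jitter SDs ≥ 22.5°. Within those bounds,
count recovery is exact by construction, and the tests sweep 50 seeded
configurations to confirm it.

`gen_group_study()` simulates the study design at the *measurement*
level: latent contralateral fraction per mouse
$\mu \sim N(0.25, 0.03)$, ipsilateral fraction $e \cdot \mu$ with the
group's effect ratio $e$, and independent $N(0, 0.01)$ section noise,
for 3 groups × 7 mice × 6 sections. The defaults encode the design this
package targets — a treated group at $e = 1.2$ against two control
groups at $e = 1$ — and are used unchanged by the acceptance checks: at
these settings the treated group's paired test rejects decisively while
controls do not, and over 200 null replicates the ANOVA's type-I rate
stays within binomial error of $\alpha = 0.05$.

## Numerical and interface conventions

Problem sizes in the tests and the acceptance script — 160×120-pixel
sections with 2,000-pixel ROIs, 10,000-sample pulses, 5 Hz traces of a
few minutes, 20-seed stain sweeps and 200-replicate null sweeps — are
the package's chosen verification scale: large enough that every
tolerance is dominated by the method rather than by discreteness, and
small enough to run routinely. Intervals are half-open `[lo, hi)`
throughout (spectral windows, analysis windows); images are row-major
with origin top-left; CSVs are comma-separated with mandatory headers
and '.' decimals; every pipeline output carries a provenance JSON
(package version, parameters, MD5 of inputs, seed), and all generators
are bit-reproducible under a fixed seed.

Known limitations: no atlas registration or manual ROI tooling; no
stain-vector estimation; no cell-level stereology (area fraction only);
PCD metrics assume a calibrated, linear receive chain and report
relative (not absolute pressure) doses; rotation counting consumes
exported heading traces, not video.
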