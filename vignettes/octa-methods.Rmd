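---
title: "Models, parameters and design choices in octawalsh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in octawalsh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octawalsh)
```

## The reconstruction model

An SD-OCT interferogram at one lateral position is modelled as

$$ I_n(x, k) = S(k)\,\Big[\mathrm{DC} + \sum_j a_j \cos(2 k z_j + \varphi_{j,n})\Big] + \varepsilon, $$

with $S(k)$ a Gaussian source envelope and one complex scatterer per depth
bin.  Reconstruction is the standard chain: background subtraction,
linear interpolation onto a uniform wavenumber grid (the identity on
phantoms, kept as a pipeline hook), spectral windowing, FFT, and retention
of the positive-frequency half (depth bins $1 \dots n_k/2$, DC excluded).
There is no zero padding, so FFT bin and depth bin coincide — convenient
for exact unit tests.

Two numerical choices deserve a note:

* **Background estimation.**  The background of a B-scan position is the
  fast-axis mean of the *repeat-averaged* spectra.  A per-repeat
  background contains the repeat-varying vessel fringes and, once
  subtracted, injects decorrelation into every static A-line of the
  B-scan; estimating it on the repeat average keeps it strictly static
  (physically it approximates the reference-arm spectrum).  We measured a
  roughly threefold reduction of the static flow floor from this choice.
* **Bulk-phase compensation.**  The full phase-registration algorithms
  used on clinical data are replaced by a documented simplified step: per
  repeat pair and A-line, the amplitude-weighted mean phase difference
  $\arg \sum_z E_{n+1} \bar E_n$ is removed.  Phantoms contain no bulk
  motion, so this stand-in only needs to be exact on global phase offsets
  (it is) and harmless otherwise.

## Walsh windows and their smoothing

Walsh functions are evaluated through their Gray code at half-sample
positions $x = (j + 0.5)/N$, so no sample ever falls on a jump and
orthogonality holds exactly on the grid.  Each jump is replaced by an
arctangent ramp $\pm (2/\pi)\arctan(\beta (x - p_m)/(\alpha N))$ inside a
transition region of half-width $\alpha N$; the $(2/\pi)$ normalisation
keeps the ramp inside $(-1, 1)$.  As printed, the ramp leaves a
discontinuity of $1 - (2/\pi)\arctan\beta \approx 0.295$ at the region
edges for $\beta = 2$; we implement this literal form by default and offer
`continuous = TRUE`, which rescales the ramp so the edges meet $\pm 1$.

The transition half-width is a *physical* quantity: a fixed fraction
$\alpha$ of the spectral length corresponds to very different widths on a
2048-pixel clinical spectrometer and on the 256-sample phantom spectra
used here.  The window functions default to $\alpha = 0.01$; the pipeline
configuration uses $\alpha = 0.08$ for its $n_k = 256$ phantoms, which
reproduces the same transition width in samples ($\approx 20$) as
$\alpha = 0.01$ at $N \approx 2048$.  Smoothing measurably reduces the
out-of-lobe energy of the axial point-spread function at every order and
length tested (`psf_report()`), though the dominant Walsh harmonics — the
square-wave overtones that displace a reflector's energy by one to two
bins per sequency — are a property of the family itself, not of the
jumps, and remain.

The SSADA baseline uses $M = 11$ unit-peak Gaussian windows.  Their FWHM
is 0.15 of the sampled band: the physical specification is 15 nm windows
on a source whose 40 nm FWHM occupies 40 % of the sampled band, hence
$15/40 \times 0.4 = 0.15$.

## The flow statistics

Four methods operate on the same reconstructed amplitudes:

* **ISCA** (the proposed method's statistic):
  $\frac{1}{N-1}\frac1N \sum_n \frac{|A_{n+1}-A_n|}{A_{n+1}A_n} \sum_n A_n$,
  computed per split and averaged over the smoothed Walsh windows of
  orders 1–3.  The denominator product is guarded by
  $\varepsilon = 10^{-12}\max(A)^2$.  Note the statistic is
  *scale-invariant*: the amplitude product cancels both the difference
  and the summed amplitude.  It is also heavy-tailed wherever amplitudes
  are small — a property inherited by any normalised decorrelation
  measure, and the reason the Otsu histograms below are clipped.
* **SSADA**: $1 - \langle A_n A_{n+1} / \tfrac12(A_n^2+A_{n+1}^2)\rangle$
  over splits and repeat pairs, bounded in $[0, 1]$.
* **OMAG-A / OMAG-C**: mean absolute amplitude/complex differences, the
  canonical forms (the source material does not print them).

## Layer-mask Otsu enhancement

The segmented retina (outermost surfaces) provides the mask; Otsu's
threshold is computed from in-mask voxels on a 256-bin histogram whose
top edge is the 0.99 quantile of the in-mask values — with a min–max
histogram, a handful of ratio-statistic outliers compresses every other
voxel into a few bins.  Values below the threshold, and everything
outside the retina, are zeroed before mean en face projection.  The
default scope is one threshold per volume (`scope = "volume"`); per-B-scan
thresholding is available and matches the description of enhancing
individual B-scans, but on vessel-free B-scans it splits the noise
distribution itself, which is rarely what one wants.

Quality metrics are evaluated on display-normalised images (percentile
stretch, black point at the in-image median, white point at the 99.5th
percentile, clipped to $[0,1]$) — the scale on which 8-bit clinical
angiograms are compared, and the scale that makes an equal-weight fused
mask across methods meaningful.

## The phantoms

**Spectral phantom** (`make_spectral_phantom()`): a 64×64 lateral raster,
4 repeats, 256 spectral samples; three retinal layers between depth
fractions 0.20 and 0.56 with reflectivities (1.0, 0.65, 0.8); a
perifoveal vessel ring with six radial branches mid-IR and a sparse
capillary grid mid-MR, tubes of radius ≈ 2 px; Gaussian source envelope
with FWHM 40 % of the band; additive detector noise (σ = 0.1).  Static
tissue carries *partially developed* speckle (complex texture of relative
amplitude 0.35): fully developed Rayleigh speckle would create arbitrarily
dark static voxels whose ratio statistics are indistinguishable from
flow.  In-vessel voxels carry fully developed speckle re-mixed between
repeats as $\sqrt{1-d}\,E_{\text{static}} + \sqrt{d}\,E_{\text{fresh}}$
with $d$ = `decorrelation` × a per-vessel flow-speed factor drawn from
[0.65, 1] — the textbook model of flow-induced speckle decorrelation,
chosen over pure phase jitter because phase jitter of grid-aligned
scatterers decorrelates amplitudes only weakly and indirectly.  The
decorrelation scale is a free parameter, not calibrated to a red-blood-cell
velocity: the source material gives no quantitative flow-speed model.

**En face phantom** (`make_enface_phantom()`): a 3 mm field at 0.0125 mm
pitch (240 px); an elliptical FAZ (semi-axes drawn from the normative
0.2–0.38 mm range in the batch tests) sealed by a thin capillary ring
whose inner edge *is* the ground-truth ellipse; a jittered capillary mesh
whose enclosed pockets are far smaller than the FAZ; optical blur of
σ = 0.6 px; multiplicative Gamma(36) speckle (the speckle contrast of a
heavily averaged angiogram) over a 0.06 background.  Two geometry choices
were driven by measured failure modes: a *thick* solid arcade band leaks —
adaptive local-mean binarisation makes large uniform bright regions
porous — and the drawn capillary fill is kept near 50 %, where the local
mean crosses the blurred vessel edge at its half maximum and the
binarised vessel width is unbiased.

What the phantoms deliberately do **not** model: eye motion and bulk
tissue motion, dispersion mismatch, birefringence, vignetting, or a
quantitative velocity-to-decorrelation calibration.  Passing phantom tests
therefore demonstrates correctness of the algorithms and of their
interplay, not clinical image quality.

## Quantification choices

* LFD is computed on the binarised vessel map (white-pixel counts), with
  one centred window per scale (mass-dimension form), scales
  $2w+1, w = 2..6$, and the regression slope clamped to $[0, 2]$ — counts
  are bounded by $s^2$, but a least-squares slope over a subset of scales
  can exceed the planar dimension near thick-vessel edges.
* The LFD vessel map is restricted to binarised white pixels.  The bare
  thresholded map is a ≈ w-pixel dilation of the binary map (every pixel
  within the largest window of a white pixel gets a positive slope), which
  would erode the FAZ by several pixels; restricted, the LFD acts purely
  as a noise filter — isolated white pixels have slope 0 and are dropped.
* FAZ extraction: opening (disk radius 1 at this pitch; radius 2 destroys
  capillary-width mesh lines), inversion, largest 8-connected component
  within the central half of the field (the periphery is avascular too and
  would otherwise win), and a final radius-2 opening of the extracted mask
  that removes hairline protrusions into inter-capillary gaps.
* Perimeter: marching squares with linear interpolation on a σ = 1.5 px
  Gaussian-smoothed mask.  Hard-mask contours overestimate a digital
  disc's circumference by ≈ 6 % (circularity 0.89 for a true circle); the
  smoothed sub-pixel contour is accurate to a few tenths of a percent.
* Circularity uses the isoperimetric form $4\pi S/P^2$ (the printed form
  $4\pi S/P$ is dimensionally inconsistent with its stated $[0,1]$ range),
  clipped at 1.
* Quadrants: boundaries on the ±45° diagonals, diagonal pixels assigned to
  the horizontal (T/N) quadrants, exclusion radius 0.5 mm, laterality
  (T left / N right) configurable per eye.
* ICC is the two-way random-effects, absolute-agreement, single-measure
  form ICC(A,1); Cohen's d defaults to the pooled-SD scale with the paired
  $d_z$ form available.

## Problem sizes and determinism

The test-suite and the acceptance script run entirely on generated data:
spectral phantoms of 64×64×4×256 samples (about 4 million points each, a
few seconds per reconstruction pass on one CPU) and en face phantoms of
240×240 px.  Batch studies use ten fixed seeds.  All randomness flows
through a single seed per phantom; identical configuration and seed give
bit-identical volumes, reports and files.

## Known limitations

* The enhancement and algorithm-comparison studies inherit a structural
  tension: the same static-voxel flow floor that must stay low for the
  flow statistic to classify voxels well (AUC ≥ 0.95) is the noise that
  the Otsu enhancement exists to remove, and the acquisition artefacts
  that penalise the baseline algorithms on clinical data (bulk motion,
  phase noise) are deliberately outside the phantom's scope.  On
  motion-free phantoms the bounded SSADA statistic and the clean OMAG
  differences are intrinsically smooth, so directional comparisons
  against them measure the phantom regime as much as the algorithms.
* The gradient-fallback layer segmentation assumes layers of distinct
  mean intensity and flat-ish topology; it is a stand-in for a proper
  segmentation model and is exercised on vessel-free phantoms.
* FAZ quantification on the 64 px spectral-phantom field is approximate
  (the FAZ spans only ≈ 18 px there); quantitative FAZ validation uses
  the 240 px en face phantoms.
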