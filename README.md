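# octawalsh

Split-spectrum OCT angiography (OCTA) reconstruction with smoothed Walsh
windows, and a fully automated pipeline for the clinical indicators that
ophthalmologists read off en face angiograms: foveal avascular zone (FAZ)
morphology and quadrant vessel density.

## The problem and the method

OCTA derives blood-flow contrast from repeated B-scans acquired at the same
slow-axis position: moving red blood cells decorrelate the speckle pattern
between repeats while static tissue does not.  Classical split-spectrum
methods (SSADA) divide the source spectrum into narrow Gaussian bands to
suppress axial-motion noise, at the price of axial resolution — each band
discards most of the spectrum.  This package implements an alternative
family of spectral splits built from **Walsh functions**, the ±1-valued
orthogonal family on [0, 1) generated from Gray-code products of square
waves:

    Walsh(n, x) = prod_{i=0..3} sign[ sin(2^{i+1} pi x) ]^{g_i},
    g = n XOR (n >> 1)

Every Walsh window spans the *entire* spectrum, so each split retains the
full signal energy and axial resolution.  Because the raw ±1 jumps cause
spectral leakage after the FFT, each jump p_m is smoothed by an arctangent
ramp inside a transition region of half-width αN:

    w(x) = ± (2/π) · arctan( β (x − p_m) / (αN) ),   |x − p_m| < αN

Flow is computed per split with the improved speckle-contrast statistic

    I_flow = 1/(N−1) · 1/N · Σ_n |A_{n+1} − A_n| / (A_{n+1} A_n) · Σ_n A_n

over the N = 4 repeats and averaged over the smoothed Walsh windows of
orders 1–3.  Retinal layer boundaries (ground truth on phantoms, or a
gradient fallback) isolate the retina; Otsu's threshold computed inside
that mask truncates residual noise in every flow B-scan before mean en
face projection.  Baselines for comparison — SSADA with an 11-window
Gaussian bank, amplitude OMAG, complex OMAG — share the same preprocessing
and projection.

On the quantification side, vessels are segmented by adaptive binarisation
refined with a per-pixel **local fractal dimension** (slope of log
box-count versus log window size, w = 2..6); the FAZ is the largest
avascular component in the central field after morphological opening and
inversion, reported as area, perimeter (sub-pixel marching-squares contour)
and circularity 4πS/P²; vessel density is the vessel-pixel fraction of
each peri-foveal quadrant (T/S/N/I).  The evaluation suite implements
vessel connectivity, contrast and SNR on a fused skeleton mask, the
largest-connected-component ratio, Dice with false positive/negative
rates, ICC(A,1), and paired t / Cohen's d statistics.

Because no public raw data exist for this modality, the package ships a
**synthetic SD-OCT phantom generator** (spectral volumes with layered
retina, decorrelating vessel networks and exact ground truth, plus en face
angiogram phantoms with known FAZ ellipses and quadrant fills) so every
stage is testable end to end.

## Worked example

```r
library(octawalsh)

# quantify a synthetic en face angiogram with a known FAZ
ph <- make_enface_phantom(seed = 3)
q  <- quantify_angiogram(ph$angiogram)
q$faz
#> <faz_report> area 0.2259 mm^2, perimeter 1.6970 mm, circularity 0.9859
ph$truth$faz_area_mm2   # 0.2262  (generating ellipse)
#> [1] 0.2261947
q$vd
#> <vd_report> vessel density (%): T=54.60, S=52.05, N=52.27, I=54.41 (excl. r=0.50 mm)
```

The estimated FAZ area differs from the generating ellipse by 0.1 %, the
circularity by 0.004, and every quadrant density is within one percentage
point of the drawn capillary fill — the package's automated pipeline
recovers the phantom's ground truth to clinical precision.

The full reconstruction pipeline runs from raw interferograms:

```r
res <- octa_run(octa_config(seed = 7, out_dir = "run01"))
res$quality$IR$enhanced
cmp <- octa_compare(octa_config(seed = 1))   # ours vs SSADA / OMAG-A / OMAG-C
```

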