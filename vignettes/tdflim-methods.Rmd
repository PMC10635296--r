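---
title: "Lifetime-based receptor quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime-based receptor quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A pulsed laser excites a fluorescent probe; a gated intensified camera
records the decaying emission through a sequence of gates of width $w$
(500 ps) stepped by $\Delta t$ (200 ps), about 30 gates per cycle. The
counts collected in a gate opening at time $t$ are the integral of the
instantaneous decay over $[t, t+w]$. For a decay
$U(s) = a_0 + \sum_k a_k e^{-s/\tau_k}$ this integral is

$$N(t) = a_0 w + \sum_k a_k\,\tau_k\bigl(1 - e^{-w/\tau_k}\bigr)\,e^{-t/\tau_k},$$

i.e. each exponential keeps its decay rate and only its amplitude picks up
a $t$-independent gate factor. Two consequences drive the package design:

* **Lifetimes are gate-robust.** A single-exponential tail fit returns
  the same $\tau$ whether the data are point samples or gate integrals
  (`fit_single_exp` is tested for exactly this invariance).
* **Amplitudes must be de-gated.** The dual-basis fit uses the
  gate-integrated regressors $\tau_k(1-e^{-w/\tau_k})e^{-t/\tau_k}$ (and
  $w$ for the offset) so that recovered amplitudes live in the same
  parameterisation as the generator's decay specification; noise-free
  recovery is then exact to solver tolerance rather than off by a
  basis-dependent factor.

An optional Gaussian instrument response of width $\sigma$ is supported
analytically (exponentially modified Gaussian integrated per gate); tail
fits are then required to start at least $3\sigma$ after the peak, since
the analysis tail-fits rather than deconvolves.

## Single-exponential tail fitting

Per pixel, the decay window runs from one gate after the peak to the last
gate above a background floor $\hat a_0 + 3\sqrt{\hat a_0}$, with
$\hat a_0$ estimated from the final three gates; windows shorter than four
gates mark the pixel unfittable (`NaN`). The fit itself is weighted
nonlinear least squares of $a_0 w + a\,g_\tau(t)$ by variable projection:
the two amplitudes are profiled out linearly and $\tau$ is optimised on a
bounded interval (0.05–10 ns) by Brent's method, initialised from the
log-linear slope of background-subtracted counts. Weights are
$1/\max(N, 1)$, the usual Poisson approximation. All of these are
configurable; the window rule and the weighting are design choices the
upstream description leaves open, and both are recorded in the run
manifest.

## Dual-basis unmixing and the amplitude ratio

With basis lifetimes fixed at the measured tumour ($\tau_T$, e.g. 0.8 ns
in vivo, 0.85 ns in situ) and normal-tissue ($\tau_{NS}$, 0.7 / 0.60 ns)
values, $U(t) = a_0 + a_T e^{-t/\tau_T} + a_{NS} e^{-t/\tau_{NS}}$ is
linear in its amplitudes. The solver constrains $a_T, a_{NS} \ge 0$
(physical amplitudes) by an exact active-set over the two amplitudes; an
unconstrained mode exists for comparison. Bases closer than 0.02 ns are
rejected as ill-conditioned. Amplitudes are divided by camera exposure;
the ratio $a_T/a_{NS}$ is additionally invariant to every multiplicative
factor common to both components — gain, illumination, uptake scale —
which is precisely why it is the cross-subject metric. The ratio map is
`NaN` where $a_{NS}$ falls below $10^{-6}$ of its map maximum.

A photon-budget caveat: separating lifetimes 0.1 ns apart is
photon-hungry. At peak counts of a few hundred per gate the per-pixel
amplitude estimates are strongly correlated and the non-negativity
constraint induces visible bias; at a few thousand counts (the level a
gated ICCD actually collects, and the generator default) ROI-mean ratios
are essentially unbiased. This is worth remembering when adapting the
tools to dimmer data.

## Asymptotic time-domain tomography

When the probe lies deeper than a few mm, planar imaging saturates and
per-pair decay amplitudes from a transmission geometry are inverted
tomographically. Because the probe lifetimes (0.6–0.85 ns) exceed the
intrinsic light-diffusion timescale (~0.2–0.3 ns), the late-time decay
amplitude of each source–detector pair is linear in the per-voxel yield:

$$a_T(r_s, r_d) = \int_\Omega W(r_s, r_d, r')\, \eta_T(r')\, dr'.$$

`tdflim` builds $W$ as a Born product of continuous-wave
diffusion-approximation Green's functions
$G(d) = e^{-\mu_{eff} d} / (4\pi D d)$ at excitation and emission
(identical optics by default: $\mu_a = 0.03\,\mathrm{mm^{-1}}$,
$\mu_s' = 1.0\,\mathrm{mm^{-1}}$, $n = 1.37$ — typical NIR tissue
values), with slab boundaries handled by extrapolated-boundary image
sources (5 image pairs) and sources/detectors sunk one transport mean
free path into the medium. The Jacobian provider is an interface: a Monte
Carlo backend can replace the diffusion kernel without touching the
inversion. The default geometry is a 4×4 source grid at 5 mm pitch on the
dorsal face and a 6×7 detector patch (2 mm pitch) opposite each source —
16 × 42 = 672 pairs.

### Inversion: why the regulariser is sensitivity-weighted

The inversion solves
$\min_\eta \|W\eta - a\|^2 + \lambda \|S\eta\|^2$ with
$\lambda = \lambda_{rel} \cdot$ (largest eigenvalue of the preconditioned
normal operator), solved exactly in measurement space. The original
design called for an identity regulariser ($S = I$) with post-hoc
clipping of negative yields. That default proved wrong in a way worth
recording: Born sensitivities are orders of magnitude larger in voxels
adjacent to the measurement surfaces, so the identity-penalised
minimum-norm solution explains any data with a thin sheet of yield at the
detector face — on an 18.6 mm slab with an inclusion at 6.3 mm depth the
identity solution reconstructs the blob at 1.5 mm (Dice 0 against truth).
The package therefore defaults to the field-standard depth/sensitivity
compensation $S = \mathrm{diag}\,\sqrt{\mathrm{diag}(W^\top W)}$ (L2
column norms); `regularizer = "identity"` remains available, as does a
projected-gradient non-negative mode (`nonneg = "project"`) alongside the
default post-solve clipping.

### Known limitation: residual depth bias at heavy regularisation

At $\lambda_{rel} = 10^{-2}$ the sensitivity-weighted reconstruction of
the 6.3 mm-deep inclusion places the yield-weighted centroid of the
top-80% mask at ≈ 4.5 mm — about 1.8 mm toward the (densely sampled)
detector plane — while overlapping the true inclusion well (Dice ≈ 0.55).
The bias is a property of heavy Tikhonov smoothing in diffuse
tomography, not of a particular implementation choice: it is unchanged
under detector pitch 2–4 mm, source/detector placement conventions,
surface-margin exclusion, row normalisation and the projected
non-negative solver, and it shrinks to well under a voxel at
$\lambda_{rel} = 10^{-3}$–$10^{-4}$ (5.5–6.5 mm recovered). The
acceptance suite pins $\lambda_{rel} = 10^{-2}$ and therefore asserts the
depth criterion honestly red; no parameter was adjusted toward the
reference after measurement.

### Yield metrics

Thresholding keeps voxels at or above 80% of the volume maximum (an
alternative percentile semantics — drop the lowest 20% of positive
voxels — is selectable but is a poor localiser and is not the default).
The normalised expression metric is the mean specific yield over the
tumour mask divided by the mean of the top-80% nonspecific yield
restricted to the same mask; it is invariant to global source power and
exposure. Note one asymmetry inherited from the procedure definition: for
non-uniform fields the numerator is an unthresholded mask mean while the
denominator is thresholded, so proportional but non-uniform
$\eta_T = c\,\eta_{NS}$ gives a ratio below $c$; only uniform fields give
exactly $c$. Tumour depth is the Euclidean distance from the
yield-weighted centroid voxel of the kept mask to the requested surface
(ventral by default). The intensity comparator sums each pair's trace
over all gates and inverts with the same Jacobian and regularisation,
which reproduces the qualitative behaviour that motivates the lifetime
approach: the intensity volume is contaminated by nonspecific background
and its thresholded mask is systematically at least as large as the
specific-yield mask.

## Microscopy: FLIM versus immunohistochemistry

Brightfield IHC images are separated into hematoxylin and DAB optical
densities by Beer–Lambert colour deconvolution: per-pixel OD
$= -\log_{10}(I/I_0)$ unmixed with the pseudo-inverse of the standard
H-DAB stain matrix (hematoxylin ≈ (0.650, 0.704, 0.286), DAB ≈ (0.269,
0.568, 0.779), unit-normalised), negative densities clipped. The
DAB-positivity threshold defaults to 0.15 OD and is deliberately exposed
as configuration — the original toolchain's exact criterion is not
recoverable. Registered image pairs are tiled into exact 100×100 px ROIs
(trailing remainders dropped); tiles with under 10% tissue (Otsu rule on
the intensity channel) are excluded. Per ROI the package reports mean
intensity, mean lifetime within 0.3–1.6 ns, % DAB-positive area, and the
clinical category — negative < 1%, moderate [1, 50), high ≥ 50, closing
the printed 49→50% gap half-open so the mapping is monotone and
exhaustive. Cell-scale expression uses the positive-area fraction: pixels
with lifetime in [0.6, 0.7] ns (inclusive) per nucleus, with nuclei
counted from the DAPI channel by Otsu threshold + connected components +
a 20 px minimum-area filter. A watershed split of touching nuclei is not
implemented; the generator keeps nucleus overlap low enough (centre
separation ≥ 2.2 radii) that counts stay within ±10% of truth, which is
the regime the counter is specified for.

## Statistics

Pearson correlations are reported both as plain $r^2$ and as
$\mathrm{sign}(r)\,r^2$: expression reports are conventionally printed on
an $r^2$ scale, and the signed variant keeps anti-correlations visible
(an observed near-zero negative correlation is representable as −0.02
rather than 0.0004). Whether a published $r^2$ is the signed variant or
an adjusted $R^2$ is generally not recoverable from the number alone, so
both are exposed and neither is guessed. The Mann–Whitney U test uses
exact enumeration of the null distribution (Gaussian-binomial recurrence,
equivalent to enumerating all orderings) when $n_1+n_2 \le 16$ without
ties, otherwise the normal approximation with tie correction and
continuity correction; two-tailed p-values throughout.

## What the synthetic generators do and do not establish

All generators are pure functions of `(config, seed)`.

* **Wide-field cohorts** emulate a six-subject experiment: specific
  amplitude proportional to a known expression score; nonspecific
  amplitude with 15% subject-to-subject coefficient of variation;
  exposure uniform on 0.1–1 s; and a log-normal uptake/system gain
  (sdlog 0.5). The gain magnitude is calibrated to the in vivo situation
  the method targets, where uncontrolled inter-animal factors decorrelate
  raw intensity from expression almost completely — that calibration is
  part of the stated world, fixed before the mechanism tests and not
  revisited. A green mechanism test establishes that *given* nuisance
  variation of this magnitude, the amplitude ratio is the more faithful
  metric; it does not measure real inter-animal variability.
* **Tomography phantoms** use an inverse-crime design (data generated by
  the same Jacobian used for inversion), which isolates the inversion's
  intrinsic behaviour from forward-model error. Green tests therefore say
  nothing about diffusion-versus-Monte-Carlo model mismatch on real
  tissue.
* **Microscopy slides** are generated pre-registered with Gaussian
  per-region lifetimes (tumour 1.04 ± 0.04, muscle 0.75 ± 0.02, vessels
  0.49 ± 0.03, adipose 0.79 ± 0.05 ns, truncated to (0, 10) ns) and
  deliberately overlapping per-region intensities. Real slides add
  registration error, stain variability and autofluorescence, all out of
  scope.

## Numerical choices and degenerate inputs

* Lifetime bounds (0.05, 10) ns; basis-separation guard 0.02 ns.
* Distances in the diffusion kernel are capped at one voxel radius.
* Tiles smaller than one full 100×100 block are dropped, never padded.
* Masked or unfittable pixels are `NaN` and excluded from every ROI
  statistic.
* All-zero volumes, empty ROIs, constant expression vectors and singular
  stain matrices raise errors rather than propagating silently.
* Units: times ns, lengths mm, counts photons, exposure seconds.
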