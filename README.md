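# tdflim

Quantifying receptor expression in vivo with time-domain (TD) fluorescence
imaging. Targeted antibody–dye probes accumulate both specifically (on the
receptor) and nonspecifically (everywhere else), and raw fluorescence
intensity — which depends on exposure, gain, illumination, uptake and
tissue optics — cannot separate the two or be compared across subjects.
The fluorescence lifetime (FLT) can: receptor-bound probe decays with a
distinctly longer lifetime than nonspecifically retained probe, and a
lifetime is an absolute quantity in nanoseconds.

`tdflim` implements the full analysis chain for gated time-domain data:

- **Lifetime fitting** — per-pixel single-exponential tail fits of gated
  image stacks `U(t) = a0 + a·e^{-t/τ}` (gate-integral model for a gated
  intensified camera; 500 ps gates / 200 ps steps / 30 gates by default).
- **Dual-basis unmixing** — linear decomposition of each decay into two
  fixed-lifetime components, `U(t) = a0 + aT e^{-t/τT} + aNS e^{-t/τNS}`,
  giving target-specific (`aT`) and nonspecific (`aNS`) amplitude maps.
  The ratio `aT/aNS` cancels every multiplicative nuisance factor and is
  the cross-subject expression metric.
- **Asymptotic TD tomography** — for deep tumours: per-pair decay
  amplitudes `a_T(r_s, r_d) = ∫ W(r_s, r_d, r′) η_T(r′) dr′` inverted with
  sensitivity-weighted Tikhonov regularisation on a slab geometry
  (diffusion-approximation Born Jacobian, extrapolated-boundary Green's
  functions, 16 sources × 42 detectors = 672 pairs), yielding specific /
  nonspecific / intensity yield volumes and the normalised ratio
  `η_T/η_NS`.
- **Microscopy-scale FLIM ↔ IHC** — colour deconvolution of DAB /
  hematoxylin brightfield images (Beer–Lambert, standard H-DAB stain
  vectors), 100×100 px ROI tiling with tissue filtering, per-ROI mean FLT
  (0.3–1.6 ns window), % positive area and clinical expression categories
  (<1%, 1–49%, ≥50%).
- **Statistics** — signed Pearson r², exact-enumeration Mann–Whitney U
  (two-tailed), NaN-aware ROI statistics.
- **Synthetic generators** — seeded phantoms with known ground truth for
  every stage (wide-field cohorts, slab tomography phantoms, registered
  FLIM + IHC slides), so the entire pipeline is testable offline.

## Worked example

```r
library(tdflim)

# 1. simulate a surface-tumour acquisition (48x48 px, Poisson noise)
sim   <- generate_widefield_phantom(widefield_config(), seed = 11)
stack <- sim$stack

# 2. intensity mask (20% rule) and per-pixel lifetime map
mask <- intensity_mask(stack)
fl   <- flt_map(stack, mask)

# 3. dual-basis unmixing at the in vivo basis (0.8 / 0.7 ns)
db <- dual_basis_maps(stack, tauT = 0.8, tauNS = 0.7, mask = mask)

tum <- sim$phantom$label_map == 2
nrm <- sim$phantom$label_map == 1
roi_stats(fl$tau, tum)$mean        # tumour FLT
roi_stats(db$ratio_map, tum)$mean  # tumour aT/aNS

# 4. six-subject cohort: ratio tracks expression, intensity does not
coh <- generate_widefield_cohort(6, seed = 11)
rep <- cohort_report(coh, metrics = c("intensity", "ratio"))
```

Output of the above:

```
tumour FLT 0.757 ns, normal FLT 0.696 ns
tumour aT/aNS 1.30 (truth 1.33), normal aT/aNS 0.046
signed r2 vs expression: intensity 0.49, aT/aNS 0.83
```

The tumour pixels mix a 0.8 ns specific and a 0.7 ns nonspecific
component, so their single-exponential lifetime (0.757 ns) falls between
the two and above the pure-nonspecific normal tissue (0.696 ns). The
unmixed amplitude ratio recovers the generating specific/nonspecific
ratio (1.33) almost exactly, is near zero where there is no specific
uptake, and across a cohort with subject-varying uptake/gain it stays
tightly linked to true expression while raw intensity decorrelates.

## Pipeline / CLI

`run_pipeline(run_config(...))` drives staged runs (`simulate`, `fit`,
`quant`, `tomo`, `micro`, `report`) writing plain-text artifacts (CSV
images/stacks/traces with JSON sidecars) and a `manifest.json` with
checksums, seed and every threshold. A thin command-line wrapper lives at
`inst/cli/flt`:

```sh
Rscript inst/cli/flt report --seed 4 --out demo_out/
```

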