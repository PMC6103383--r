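# dectk

Dual-energy micro-CT (DECT) on a conventional gantry-based preclinical
scanner, as a desk-scale R toolkit.

Most laboratory micro-CT scanners image at a single tube potential at a
time. Contrast-perfused vasculature and cortical bone then overlap in CT
value and cannot be separated by thresholding. DECT solves this by scanning
twice with two differently shaped x-ray spectra — here a 70-kVp beam
hardened by an erbium filter and a 90-kVp beam hardened by copper, bracketing
the Er K-edge at 57.5 keV of an erbium-based vascular contrast agent — and
decomposing each voxel into soft-tissue, bone and vessel volume fractions.
`dectk` implements the computational side of that workflow for
physicists and imaging scientists who want to design such protocols or test
decomposition pipelines without scanner time:

* **Spectral modeling** — a tungsten-anode bremsstrahlung model (Kramers
  thick-target with Thomson–Whiddington anode self-filtration and W
  K-characteristic lines) on 1-keV bins, with Beer–Lambert filtration from
  packaged mass-attenuation tables (H, C, O, F, Al, Cu, Er, W, water, PTFE,
  polycarbonate; K/L-edge-aware log-log interpolation).
* **Filter design** — solve filter thicknesses for a target flux reduction,
  convert foil-equivalent thicknesses into nanopowder mass loadings for
  resin-cast annular filters, and compute half-value layers (direct
  bisection or step-wedge slope fit).
* **Fiducial co-registration** — PTFE bead detection (26-connected
  components, intensity-weighted centroids), mutual-nearest-neighbour
  matching, closed-form least-squares rigid fitting (SVD with reflection
  correction), and sub-voxel trilinear resampling.
* **Three-material decomposition** — per-voxel solution of

  ```
  | L_st  L_bone  L_ves |   | f_st  |   | L |
  | H_st  H_bone  H_ves | x | f_bone| = | H |
  |  1      1       1   |   | f_ves |   | 1 |
  ```

  from six pure-material calibration values, on the 0–10000
  volume-fraction scale, plus iterative six-value calibration and
  ROI-based misclassification tables.
* **Digital phantom** — a hindlimb-like dual-energy phantom generator
  (160 × 160 × 200 voxels at 100 µm) with ground-truth fractions, beads,
  Gaussian noise and known misalignment, so the whole pipeline is testable
  end to end.

## Worked example

```r
library(dectk)

## design the high-energy filter: Cu thickness for 30% transmission at 90 kVp
t_cu <- solve_thickness(filter_design_request(90, "Cu", 0.30))
round(as.numeric(t_cu) * 1000)       # 586 um of Cu
s90 <- simulate_spectrum(90)
hvl(s90)                             # 6.36 mm Al
hvl(apply_filter(s90, filter_layer("Cu", as.numeric(t_cu))))  # 9.27 mm Al

## simulate a noisy, misaligned acquisition and run the full pipeline
mis <- rigid_about(c(7.95, 7.95, 9.95),             # about the phantom center
                   euler_rotation(c(1, -1, 1.5)), c(0.3, -0.2, 0.2))
cfg <- run_config(phantom = phantom_spec(noise_sigma = 60, seed = 1,
                                         misalignment = mis))
report <- run_pipeline(cfg)
report
#> <run_report>
#>   registered: TRUE (FRE 0.007062 mm, 10 markers)
#>   basis condition number: 4234
#>   misclassification (%):
#>              known
#> decomposed    soft_tissue  bone vessel
#>   soft_tissue       99.99 -0.20  -0.29
#>   bone               0.03 99.90   0.00
#>   vessel            -0.02  0.29 100.30
```

The fiducial registration error (FRE, root-mean-square residual over the
ten matched beads) is well under a tenth of a voxel. The misclassification
table reports, for a region known to be pure (columns), how the decomposed
volumes (rows) classify it: diagonals near 100% mean essentially every
voxel landed in the right material map despite the ±60 HU noise and the
deliberate starting misalignment. Entries slightly outside [0, 100] are
normal for the unclamped solver, whose zero-mean noise is preserved rather
than clipped.

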