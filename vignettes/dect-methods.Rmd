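---
title: "Methods: spectral shaping, co-registration and three-material decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral shaping, co-registration and three-material decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A conventional preclinical micro-CT scanner images at one tube potential at a
time. An erbium-based vascular contrast agent and cortical bone then overlap
in CT value, so vessels cannot be segmented from bone by thresholding alone.
Dual-energy CT (DECT) resolves the ambiguity by acquiring two sequential
scans with differently shaped spectra — a 70-kVp beam filtered with erbium
and a 90-kVp beam filtered with copper, bracketing erbium's K-edge at
57.5 keV — and solving a small linear system per voxel for soft-tissue, bone
and vessel volume fractions. `dectk` implements each computational stage of
that workflow and validates the chain end-to-end on a digital phantom.

# X-ray spectrum model

The tube is modeled as a tungsten thick target. Bremsstrahlung production
follows a Kramers law evaluated layer by layer inside the anode: an electron
of landing energy $T_0$ (keV) penetrates to mass depth
$\rho x = (T_0^2 - T^2)/C$ (Thomson–Whiddington), and photons of energy $E$
created at that depth escape through a tungsten path $\rho x / \sin\theta$,
where $\theta$ is the take-off angle. The fluence in each 1-keV bin is

$$\Phi(E) \;\propto\; \frac{1}{E}\int_E^{T_0}
   \exp\!\left(-\frac{\mu_W(E)}{\sin\theta}\,\frac{T_0^2-T^2}{C}\right)\,dT .$$

Tungsten K-characteristic lines (57.98, 59.32, 67.24, 69.07 keV; relative
strengths 57.6 : 100 : 33 : 8.9) are added for tube potentials above the
K-shell threshold (69.525 keV) with total intensity proportional to
$(T_0/69.5 - 1)^{1.63}$.

Tunable model parameters, all exposed through `tube_model()`:

| parameter | default | units | role |
|---|---|---|---|
| `target_angle_deg` | 15 | degrees | anode take-off angle; sets self-filtration path |
| `tw_constant` | 1.6e6 | keV^2 cm^2/g | Thomson–Whiddington electron penetration constant |
| `k_fraction` | 0.06 | — | K-line photons as a fraction of continuum photons at 100 kVp |
| `window_mm_al` | 1.0 | mm Al | tube exit-window equivalent filtration |

The Thomson–Whiddington constant and the characteristic fraction were fixed
at representative literature values for tungsten in the diagnostic range and
then held; the model was cross-checked against the four measured aluminium
half-value layers of the target scanner protocol (70/90 kVp with and without
the custom filters), which it reproduces to within a few percent. Source
distances and the target angle are carried in the spectrum provenance; heel
effect, scatter and detector blur are out of scope.

"Unfiltered" in this package means the tube output (anode plus exit window)
with no scanner filtration. The scanner's inherent stack — 1.6 mm Al plus
2 cm Lexan (`scanner_inherent_filtration()`) — is applied by default by
`simulate_spectrum()` and is the baseline all filter-design transmissions
refer to. The mean energy of the unfiltered 90-kVp tube output is ~42 keV;
behind the scanner stack the beam hardens to ~48 keV, which is why the
"unfiltered spectrum" figure of ~42.7 keV can only describe the tube output.

## Flux weighting

Two flux conventions coexist in practice. Photon counting
(`weighting = "photons"`) sums fluence; detected-energy weighting
(`weighting = "detected"`) sums $E\,\Phi(E)$, which is what an
energy-integrating flat-panel detector registers. All transmission-type
quantities (`beam_transmission()`, `hvl()`, `solve_thickness()`,
`step_wedge_counts()`) default to detected-energy weighting: with photon
counting, no physically plausible continuum reproduces the protocol's solved
Cu thickness, its measured flux reduction, or any of the four measured HVLs,
while detected-energy weighting reproduces all of them — the measured HVLs
being the deciding, independent evidence. Mean energy always uses photon
weighting (the convention of spectral simulation tools). The option is a
parameter, not a hidden constant, so either convention can be requested.

## Numerical choices

Spectra live on 1-keV bins from 1 keV to the tube potential; tube potentials
are accepted from 30 to 140 kVp in 0.5-kVp steps. All thickness solving
(HVL, filter design) uses bisection to 0.1 µm. The slope-fit HVL regresses
$\ln(I/I_0)$ on absorber thickness — for a polychromatic beam this
linearises a convex curve, so it equals the direct root only for
monoenergetic beams; the step-wedge simulator exists to exercise exactly
this analysis.

# Attenuation data

Mass attenuation tables for H, C, O, F, Al, Cu, Er, W, water, PTFE and
polycarbonate are packaged as CSV + JSON sidecar (density, edges,
provenance). They are computed, not transcribed: photoabsorption from
Cromer–Liberman $f''$ ($\sigma = 2 r_e \lambda f''$), incoherent scattering
as $Z$ times the Klein–Nishina cross section, and coherent scattering as an
empirical $a\,Z^{2.92}/E^{1.95}$ term fitted so totals match standard
reference tabulations — to about 1% for $Z \le 29$ and water over
20–150 keV, and about 4% for W. Erbium has no independent anchor available
offline; its below-K-edge values carry an estimated 5–10% uncertainty, which
propagates directly into the solved Er filter thickness. The generator
script is committed under `data-raw/` for provenance.

Grids are log-spaced with doublet rows 1 eV either side of each absorption
edge. Interpolation is log-log and segment-wise between edges, so an
interpolated value never averages across a discontinuity; a query exactly at
an edge returns the above-edge branch. The erbium K edge is placed at
57.5 keV, the value used throughout the protocol. Queries outside the
3–150 keV grid clamp to the end values (relevant only for bins that any
filtration extinguishes anyway).

# Filter design

`solve_thickness()` bisects the filter thickness until the filtered beam
transmits the requested fraction of the inherent-filtered beam's flux, and
returns the achieved transmission alongside. The annular filter geometry
(`annular_filter_geometry()`, default 8.2 cm OD × 6.4 cm H × 0.3 cm wall)
crosses the beam twice, so `passes = 2` by default and the filter is
equivalent to a pre-object filter of path `passes × wall`. `mass_loading()`
converts a foil-equivalent thickness into compound powder mass for a resin
cast under two explicit assumptions, echoed in its report: the element alone
carries the attenuation (the oxide's oxygen is neglected, consistent with
K-edge-dominated design) and the powder disperses uniformly through the
stated resin volume. The formula is deliberately transparent —
$m = t_{eq}\rho_{foil}/(w_{el} L)\times V$ — because published casting
recipes are not always reproducible from stated geometry alone, and a
formula the user can audit is worth more than a matched constant.

# The digital phantom

`phantom_spec()` describes a hindlimb-like object on a 160 × 160 × 200 grid
of 100-µm isotropic voxels (16 × 16 × 20 mm, a few-second build): a
soft-tissue cylinder holding a cortical-bone tube with marrow, two
contrast-filled vessels and a bone-mimicking calibrator rod; water and air
vials in the surrounding air-equivalent holder; and ten 1.6-mm PTFE beads on
a peripheral ring at staggered heights (minimum spacing 4 mm, non-coplanar).
Partial volume is modeled by 3 × 3 × 3 sub-voxel supersampling at material
boundaries; interior voxels are pure. Rendering is the decomposition model
run forward: each voxel's HU is the fraction-weighted sum of the six
calibration values plus fixed auxiliary values (water 0, air −1000, PTFE
+1000 — a free parameter, chosen distinct from every calibration value so
threshold detection cannot confuse beads with tissue; calibrator = bone).
The scanner's "±60 HU" noise is modeled as additive Gaussian with
$\sigma = 60$ HU, independent between the two energy scans (they are
sequential acquisitions); misalignment is a proper rigid transform applied
to the high-energy volume, defaulting to rotations about the phantom center
(the effective bed/gantry axis).

What the phantom does *not* emulate: cone-beam reconstruction artifacts,
scatter, beam-hardening-induced cupping, detector blur, ring artifacts, or
tissue heterogeneity. Passing tests therefore demonstrate the correctness of
the algorithms under the stated forward model, not robustness to every
physical nuisance of a real scanner.

# Fiducial co-registration

Bead detection thresholds at the soft-tissue/PTFE midpoint (518 HU), labels
26-connected components, keeps components of 700–4000 voxels (a 1.6-mm bead
is ~2100; vessels, rods and bone tubes fall outside), and computes
intensity-weighted centroids using the HU excess over threshold — the
weighting that makes centroids sub-voxel accurate. Correspondence uses
mutual nearest neighbours after centering both clouds, valid because
misalignments (≲1 mm) are small against the 4-mm minimum bead spacing; the
protocol minimum of eight markers is enforced (hard floor three, the rigid
minimum). The transform is the closed-form least-squares solution via SVD of
the cross-covariance with the reflection corrected to $\det R = +1$;
near-coplanar bead layouts are exactly the case where the unconstrained
optimum can be a reflection, hence the staggered bead heights in the phantom
and the correction in the solver. Resampling is trilinear with out-of-field
fill at −1000 HU. Conventions: world coordinates in mm, a voxel's world
position is its center, R arrays are 1-based.

# Three-material decomposition

With six calibration values $(L, H)$ for soft tissue, bone and vessel, each
voxel solves

$$\begin{pmatrix} L_{st} & L_{b} & L_{v}\\ H_{st} & H_{b} & H_{v}\\
1 & 1 & 1\end{pmatrix}\! \begin{pmatrix} f_{st}\\ f_{b}\\ f_{v}\end{pmatrix}
= \begin{pmatrix} L\\ H\\ 1\end{pmatrix},$$

scaled to 0–10000. The matrix is factorised once and reused across voxels.
The default output is unclamped: fractions may leave $[0, 10000]$ under
noise but always sum to exactly 10000, preserving the protocol's
bookkeeping; `clamp = TRUE` clips to the physical range and therefore breaks
the sum property (a message says so). The basis condition number is computed
on construction and capped (default $10^6$); the poorer spectral separation
of an unfiltered acquisition shows up directly as a larger condition number.

## Iterative six-value calibration

The exact objective of the original iterative six-value selection is not
specified anywhere we could consult, so the package implements a declared
interpretation rather than a guess presented as ground truth: initialise at
the calibration-ROI means, then coordinate-descend each of the six values
(step halving from 50 HU to 0.5 HU) on the total off-diagonal mass of the
misclassification table over separate evaluation ROIs, stopping at relative
improvement $<10^{-4}$ or 200 sweeps. The full objective trace is returned
so alternative schemes can be compared against it. On noiseless data the ROI
means are already the exact fixed point and the objective starts at zero.

## Misclassification accounting and the clamping question

A misclassification table transposes known-pure ROIs (0.5-mm cubes snapped
to whole voxels, 125 voxels each) through the three decomposed volumes,
expresses ROI means as percentages and normalises each known-component
column to 100%. Whether fraction maps should be clamped before ROI
averaging is genuinely open; the package treats the two choices as answering
different questions. Unclamped maps keep zero-mean noise zero-mean, so ROI
means measure *bias* — misregistration, miscalibration — and this is the
default and the right analog of the published accuracy tables. But precisely
because unclamped averaging cancels noise, it cannot see noise
*amplification*: a worse-conditioned basis inflates the per-voxel fraction
variance without moving ROI means. Clamped maps convert that variance into a
measurable bias (clipped tails), so basis-conditioning comparisons are run
with clamping applied identically to both arms. Every comparison in the
tests uses one metric for both of its arms.

# Problem sizes and determinism

The full-size phantom (5.12M voxels) is used for the conservation,
inversion, registration-recovery (20 seeded misalignment draws) and
misclassification (10 seeded replicates) properties; geometric unit tests
use a 12-mm-tall variant of the same layout for speed. Every stochastic
element — phantom noise, misalignment draws, Poisson wedge counts — is
seeded explicitly, and the pipeline report records every seed and parameter
needed to regenerate it.

# Known limitations

* The erbium attenuation table is computed, not measured; its below-edge
  uncertainty (est. 5–10%) propagates into the solved Er thickness.
* The spectrum model is semi-empirical; its constants were chosen from
  literature ranges and validated against four measured HVLs, not fitted to
  a measured spectrum.
* The phantom's forward model is linear in the calibration values; real
  reconstructions add beam-hardening and scatter biases the decomposition
  inherits silently.
* Fully automatic bead detection replaces the original operator-seeded
  centroid procedure; equivalence with an operator-in-the-loop workflow is
  untested by construction.
* Only rigid misregistration is modeled or corrected; deformable motion is
  out of scope.
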