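---
title: "Designing multi-phase tACS montages: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-phase tACS montages: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the forward model and its assumptions, the phasor optimization, the
evaluation metrics, the synthetic generators used for validation, and
the numerical and design choices that were genuinely open.

## 1. Forward model

Scalp-applied currents at tACS frequencies (tens of Hz) satisfy the
quasi-static approximation: capacitive and inductive effects in tissue
are negligible, so at every instant the potential obeys the
electrostatic Laplace equation $\nabla\cdot(\sigma\nabla V)=0$ with
isotropic conductivities per tissue. The package discretizes this with
linear (P1) tetrahedral finite elements. Assembly is exact for P1:
element stiffness $\sigma_e V_e\, G^\top G$ with $G$ the constant
barycentric gradients; the assembled matrix is symmetric positive
semidefinite with constants in its null space (each row sums to zero,
which the tests check to 1e-10 relative).

One **pair solve** fixes $V=1$ V on the distal face of the active
electrode and $V=0$ on one return (sparse Cholesky on the reduced
system), then rescales so the delivered current is exactly 1 mA. The
delivered current is read from the stiffness reaction forces at the
constrained nodes, which is variationally consistent for P1 elements;
surface flux integration of $J\cdot\hat n$ is retained only as a
cross-check, because the piecewise-constant current density carries a
few-percent quadrature error at practical resolutions (the in/out flux
*balance* is much tighter, ~0.1%). The reaction-force balance itself is
conserved to ~1e-11.

The **lead field** stacks, per return electrode, the component of
$\mathbf E=-\nabla V$ normal to the cortical surface (the quantity the
optimizer targets, since radial fields are the ones commonly assumed to
polarize pyramidal populations). All 60 solves share one factorization
of the active-grounded matrix; each return's Dirichlet set is imposed by
a small Lagrange/Schur correction, algebraically identical to solving
each reduced system separately. Columns are signed so that column $r$ is
the field when return $r$ injects +1 mA and the active electrode
returns it; with that orientation, superposition
$\text{field}=\sum_k x_k\,\text{col}_k$ with active current
$-\sum_k x_k$ agrees with a direct multi-electrode Neumann solve to
~1e-5 relative L2 (tested at 1%).

**Validation oracle.** For a homogeneous conducting sphere with two
surface point electrodes, the interior potential has the Legendre series
$V=\frac{I}{4\pi\sigma R}\sum_n \frac{2n+1}{n}\left(\frac rR\right)^n
[P_n(\cos\gamma_A)-P_n(\cos\gamma_B)]$, which on the surface sums in
closed form to $f(\gamma)=1/\sin(\gamma/2)-2-\log(\sin(\gamma/2)
(1+\sin(\gamma/2)))$. The FEM solution on an ~97k-tet sphere matches
this oracle within ~1.7% relative L2 (evaluated more than 30° away from
the electrode caps, where the point-source idealization is valid), and
the discrepancy falls monotonically under mesh refinement.

## 2. Phantom head model

Individual MRI meshes are not generally shareable, so the default
geometry is a **layered-sphere phantom**: concentric shells at 92, 88,
83 and 80 mm (scalp, skull, CSF, brain), adult-head proportions. The
mesh is structured — an icosphere triangulation replicated on radial
node shells, prisms split into tetrahedra with globally consistent
diagonals — so every tissue interface lies exactly at its nominal
radius, shell volumes land within a fraction of a percent of the
analytic values, and the construction is fully deterministic (the `seed`
argument exists for interface stability only). Thin layers are always
resolved because interfaces carry their own node shells, regardless of
the target edge length.

Conductivities (S/m): scalp 0.25, skull 0.015, CSF 1.79, grey matter
0.276, white matter 0.126, sponge electrode 5.21. The phantom uses a
single `brain` compartment at the grey-matter value: the optimization
only consumes the field *on* the cortical boundary, while the full
six-entry table remains available for external meshes read from Gmsh
MSH v2.2.

Electrodes are disc sponges (radius 5 mm, height 25 mm) placed by a
geometrically generated 61-channel 10-10 layout: footprints are the
scalp boundary triangles whose summed area best matches the disc area
(so a curved cap, not a planar disc — recorded in each electrode's
metadata), extruded outward along the local surface normals. ROIs are
geodesic caps: all cortical elements whose centroid direction lies
within a given angular radius of a center direction — a transparent
stand-in for manual segmentation of, e.g., the intraparietal sulcus.

## 3. Phasor optimization

At a fixed carrier the desired field on each ROI is a phasor
$A\angle\phi$; the reference ROI carries $\phi=0$ and a positive $\phi$
on another ROI means the reference leads it, i.e.
$\text{lead}(X\ \text{over}\ Y)=\text{wrap}(\phi_Y-\phi_X)$. This
convention reproduces all the inter-regional phase-difference arithmetic
it is tested against. The default amplitude is $A=0.3$ V/m, a value in
the range typically considered sufficient to modulate ongoing
oscillations.

Because the electrostatic map is linear and real, the carrier frequency
and time drop out of the least-squares problem entirely (frequency is
montage metadata only), and the complex problem splits *exactly* into
two real ones. The solver is a rank-revealing SVD — never the explicit
normal-equation inverse of the closed form — with singular values below
1e-10 of the largest truncated when no ridge is requested; an optional
Tikhonov ridge is available but defaults to 0, since the 61-channel
phantom systems are well conditioned. The normal-equation residual is
verified below 1e-8 relative.

**Safety limits.** The literature states limits (2 mA per return, 4 mA
active) without a mechanism. The package applies one uniform scale
$s=\min(1,\ 2/\max_r|x_r|,\ 4/|x_\text{act}|)$ because uniform scaling
preserves every phase and the relative amplitude distribution exactly
(linearity) — the tests verify the synthesized phase map moves by less
than 1e-9 degrees. A constrained-least-squares variant would trade
amplitude pattern against the limits and is left as an extension point.
After scaling, the active current is recomputed as the negated sum of
the scaled returns so the Kirchhoff identity stays bitwise exact.

## 4. Evaluation metrics

Per ROI: $E^\text{ROI}_\max$ is the peak amplitude of the
normal-component phasor; the **half-maximum area** contains the ROI
elements with amplitude $\ge \tfrac12 E^\text{ROI}_\max$ (ROI-local by
definition, never cortex-wide); the **median phase** is taken over that
set. "Median" is not well defined on a circle, so the package uses the
circular median: the observed angle minimizing the summed absolute
circular deviations, ties broken toward the smallest wrapped angle. It
is robust, exact, reduces to the ordinary median for concentrated
samples of odd size (the ROI phase distributions here are tightly
concentrated), and handles wraparound correctly — a cluster near 180°
yields a median near 180°, not a spurious sign flip. An area-weighted
variant is exposed (`area_weighted = TRUE`) since it is unclear whether
element areas should weight the median; unweighted is the default.
Amplitude maps are the modulus of the *normal-component* phasor — the
optimized quantity; full vector-magnitude maps would require storing all
three field components and are out of scope for the metrics module.

Percent phase error uses division by the desired delay,
$|\text{wrap}(\text{ach}-\text{des})|/|\text{des}|\cdot 100$, the form
that regenerates the reference percent values from their phase
differences; for a synchronization target (desired 0) the relative
error is defined as 0 only when the absolute error is below a tolerance
(default 1e-6 degrees) and flagged NA otherwise.

Angles live in $(-180°, 180°]$ throughout, with exactly $-180°$ mapped
to $+180°$; `lead_angle` is antisymmetric except at that branch point.

## 5. Stimulation protocol

`phase_to_time()` is the exact identity
$(\phi/360)\cdot(1000/f)$ ms — 90° at 80 Hz is 3.125 ms. Waveforms are
$\text{env}(t)\,|x_k|\cos(2\pi f t+\phi_k)$ with linear 30 s ramps
(durations are stated in the source protocol, the ramp *shape* is not;
linear is the simplest monotone choice), default 10 kHz sampling
(125 samples per 80 Hz cycle), and a 20 kΩ impedance-abort threshold
carried as metadata only — no hardware control. Since the phasors sum
to zero, the instantaneous cross-channel sum vanishes at every sample
to ~1e-13 mA.

## 6. Behavioral indices and the session simulator

The lateralized change-detection session is fixed by design: 120 trials
in 6 blocks of 20, loads 4/5/6 with two blocks each, 10 left / 10 right
hemifield trials per block, 5 match / 5 mismatch per hemifield.

The printed index definitions leave three details open, each implemented
with a documented default and a configurable alternative:

* **K = load × (accuracy − miss rate)**: accuracy is
  (hits + correct rejections)/all cell trials and the default miss rate
  is misses/all cell trials (`miss_denominator = "all"`); the
  alternative normalizes misses by match trials only. The Cowan form
  K = load × (hit rate − FA rate) is available via `k_form = "cowan"`.
* **d′ = Φ⁻¹(hit) − Φ⁻¹(FA)** needs an extreme-rate correction to stay
  finite; the default replaces 0 by 1/(2N) and 1 by 1−1/(2N), with the
  log-linear (+0.5) correction as an alternative.
* **Omissions** count as errors through the proportion denominators and
  are reported separately, never silently dropped.

The weighted d′ is mean(load · d′ per load); LI = (M_R − M_L)/(M_R +
M_L); the median split assigns at-median subjects to the high group;
`bh_fdr()` is the Benjamini–Hochberg step-up (via `p.adjust`,
cross-checked in the tests against a hand-rolled step-up).

The **simulator** draws from the equal-variance Gaussian
signal-detection model: match-trial evidence $\mathcal N(d',1)$,
mismatch $\mathcal N(0,1)$, "same" response when evidence exceeds
$d'/2+c$, optional lapses replaced by coin flips. It emulates exactly
the design's counts and the SDT generative assumptions — it does *not*
emulate learning or fatigue across blocks, load-dependent d′ profiles,
reaction times, or inter-subject variance structure, so passing
recovery tests demonstrates correctness of the index pipeline, not
realism of human data. Recovery checks: pooled d′ estimates are
unbiased within Monte-Carlo error over a 3×3 d′-by-criterion grid
(~5,000 trials per cell), a generating d′ of 1.5 is recovered within
±0.1 from ~10,000 trials, and with a strong generating asymmetry
(d′ 2.0 vs 0.5) the sign of the d′-based LI matches the asymmetry in
≥99% of single-session replicates.

## 7. Problem sizes and numerics

The validation suite uses: a half-scale coarse phantom (edge 6 mm,
8 electrodes) for unit-level FEM properties; an ~97k-tet homogeneous
sphere (edge 10 mm) for the analytic-oracle comparison with a
three-level refinement study (edges 18/12/8 mm); and the full-scale
study phantom — 92/88/83/80 mm at 8 mm target edge, ~177k tets, ~32k
nodes, 61 electrodes — for the end-to-end 90° bilateral-parietal
recovery, which completes in well under a minute on one core. These
sizes were chosen as the coarsest meshes at which each geometric and
analytic check is comfortably inside its tolerance; everything scales
to finer meshes through the same code paths. The solver is a sparse
direct Cholesky factorization throughout: on the mesh sizes this package
targets (up to a few hundred thousand nodes) it is faster and more
robust than an iterative solve, needs no tolerance tuning, and one
factorization serves all sixty return electrodes; meshes in the
million-node range would call for preconditioned conjugate gradients,
which is a deliberate non-goal here.

Degenerate inputs are rejected loudly: non-monotone radii, absurd edge
lengths, zero-area electrode discs on empty caps, overlapping
footprints or ROIs, missing conductivities (named per label), singular
tets (named per index), all-zero ROI fields (undefined-phase flag
rather than a crash), zero LI denominators (NA with a warning).

## 8. Known limitations

* The phantom is spherical: no gyrification, no skull holes, no
  anisotropy. Phase *patterns* transfer better than amplitudes across
  geometries, but absolute amplitudes on the phantom should not be read
  as cortical dose predictions.
* The electrode model is a conductive sponge with an equipotential
  distal face; contact impedance (complete electrode model) is not
  implemented.
* The lead field fixes one active electrode (default Fpz); a
  common-ground reformulation is out of scope.
* Focality- or energy-constrained optimization variants (LCMV-style)
  are not provided; the single least-squares objective is the point.
* The behavioral module deliberately stops at tidy per-subject index
  tables; repeated-measures ANOVAs and nonparametric group tests are
  routine statistics best done in the user's preferred framework.
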