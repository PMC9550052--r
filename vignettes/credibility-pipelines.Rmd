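---
title: "Credibility pipelines for virtual cohorts of cardiac electrophysiology models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Credibility pipelines for virtual cohorts of cardiac electrophysiology models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`cardiocred` implements two credibility-assessment pipelines for
patient-specific cardiac electrophysiology (EP) models deployed as a
*virtual cohort*:

1. **Study 1 — multi-patient mesh convergence.** How much does spatial
   discretization error vary *across patients*? Each patient's anatomy is
   meshed at nested resolutions, paced once apically, and the errors of two
   quantities of interest — the normalized apex-to-base activation time and
   a pseudo-ECG — are computed against the finest mesh, then summarized as
   across-patient coefficients of variation (COV).
2. **Study 2 — input-uncertainty robustness.** Is the cohort-level
   conclusion *"high repolarization gradient volume (HRGV) is larger when
   pacing close to scar than far from it"* robust to errors in a
   personalized input (border-zone extent) and a non-personalized input
   (tissue conductivity)? The pipeline perturbs both inputs and runs a
   battery of statistical scenarios: systematic bias, worst-case
   combination, Monte-Carlo sampling over discrete variant assignments, and
   continuous normal conduction-velocity sampling with interpolation.

Everything runs on a seeded *synthetic* cohort of slab anatomies so that
every geometric label has a closed-form ground truth; user-supplied
tetrahedral meshes in the same labeled format are accepted by every stage.

Units throughout: lengths in cm, time in ms, voltage in mV, conductivity in
mS/cm, conduction velocity (CV) in cm/s.

# The tissue model

Electrical propagation follows the anisotropic monodomain reaction-diffusion
equation

$$\chi C_m \, \partial_t V_m = \nabla\cdot(\sigma \nabla V_m) + \chi I_{ion},
\qquad
\sigma = \sigma_f\, \mathbf{f}\mathbf{f}^T + \sigma_c (I - \mathbf{f}\mathbf{f}^T),$$

with per-element fiber direction $\mathbf{f}$, fiber and cross-fiber
conductivities $\sigma_f, \sigma_c$, surface-to-volume ratio $\chi$ and
membrane capacitance $C_m$. Border-zone (BZ) elements scale $\sigma$ by
`bz_conductivity_scale`; scar elements carry zero conductivity and no
reaction (non-excitable), so scar-interior nodes provably stay at rest.

**Cell model.** The membrane kinetics are the two-variable
Mitchell–Schaeffer model in normalized units, mapped to physical voltage by
$V = V_{rest} + A\,u$ with $V_{rest} = -85$ mV and $A = 120$ mV, so the
$-70$ mV repolarization criterion and $-20$ mV activation criterion are
meaningful. A full ionic model at fine resolution costs orders of magnitude
more compute while the two studies' logic depends only on the
activation/repolarization structure, which this surrogate reproduces; the
cell interface (`cell_model()`) is pluggable.

**Discretization.** Linear (P1) tetrahedral finite elements with lumped
mass; operator splitting with an explicit reaction substep (exact
exponential update for the recovery gate) and a backward-Euler diffusion
solve reusing one sparse Cholesky factorization. The diffusion step is
unconditionally stable, so coarse desk-scale meshes run reliably; the
explicit reaction bounds `dt` (default 0.1 ms, comfortable for the default
$\tau_{in} = 0.3$ ms). Fixed `dt` across a mesh family: study 1 probes
*spatial* refinement only.

**Conductivity calibration.** `measure_planar_cv()` measures the planar
wavefront speed on a homogeneous fiber-aligned slab by least-squares
regression of activation time on distance over the 25–75% probe window
(excluding stimulus and boundary artifacts), and
`tune_conductivity_to_cv()` exploits the monodomain square-root
CV–conductivity law as its update rule, preserving the anisotropy ratio
exactly. Study 2 calibrates at the *study resolution* (mesh-specific
calibration, the standard practice when a fixed mesh is used throughout) to
a baseline CV of 66 cm/s, a typical human myocardial fiber-direction value.
Only the relative factors (80%/120%, SD = 10% of the mean) enter the
robustness logic.

# The synthetic cohort

`draw_cohort_specs()` draws per-patient geometry from uniform ranges under
one master seed (which spawns per-patient seeds, so the entire cohort is
reproducible from a single integer):

* slab 3.2 × 1.6 × 0.3 cm — a ventricular wall segment; the transmural
  coordinate is the z-depth;
* spherical scar core, radius U(0.30, 0.38) cm, centered mid-wall so the
  scar is transmural, as post-infarct LV scars typically are;
* BZ shell of width U(0.10, 0.16) cm around the scar — population mean
  ≈ 1.2 mm, matching reported image-derived cohort averages;
* rule-based fibers: in-plane unit vectors rotating linearly with
  normalized transmural depth from −60° (endo) to +60° (epi);
* meshes from a structured hex grid split 6 tets/hex (Kuhn decomposition —
  conforming without parity bookkeeping); the grid spacing is
  `target_edge_length / 1.2821` so the *mean* edge length lands on target.

Pacing sites are selected by `select_pacing_sites()` as the excitable-tissue
node whose Euclidean distance to the triangulated scar boundary best matches
the prescribed distance (ties to the lowest node index). Study 2 uses
0.2 cm (near, the literature's value) and 2.0 cm (far) — the published far
distance of 4.5 cm does not fit a desk-scale slab, and only the near-far
*contrast* matters to the statistics.

What the generator does *not* emulate: real LV chamber geometry and wall
curvature, image-derived scar/BZ morphology (interdigitation, channels),
sheet anisotropy, torso-dependent electrode placement, and rate-dependent
restitution (a single paced beat from rest). Passing tests therefore
demonstrate the *pipeline's* correctness and the reproducibility of its
statistical logic on a cohort with a known built-in effect — not fidelity
to any individual patient.

# Quantities of interest

* **Activation map**: first upward crossing of −20 mV, linearly
  interpolated between output samples (crossing times are first-order
  independent of the 1 ms output interval). dV/dt-max detection is
  deliberately avoided — it is fragile at coarse sampling.
* **Repolarization map**: first return below −70 mV after activation.
* **Normalized activation time**: activation at the node nearest a fixed
  basal probe point divided by its distance to the pacing node (ms/cm) —
  removes heart-size differences.
* **Pseudo-ECG**: infinite-volume-conductor lead
  $\phi(\mathbf{e}) = -\sum_K v_K\, (\sigma\nabla V_m)\cdot\nabla(1/r)$
  with single centroid quadrature and per-element constant $\nabla V_m$
  (exact for P1). The lead constant is 1: downstream error metrics are
  invariant to it. The default electrode sits 4 cm from the domain centroid
  along +x ("V1-like"); no torso model is attempted.
* **Repolarization gradient**: per-element $\lvert\nabla T_{rep}\rvert$
  from the P1 interpolant — exact for nodal data linear in space, which is
  what the unit tests exploit.
* **HRGV**: total volume of healthy/BZ elements whose centroid lies within
  1 cm of the scar boundary surface and whose repolarization gradient
  exceeds 30 ms/cm (alternate threshold 25 ms/cm). Distances are Euclidean
  to the triangulated scar boundary, evaluated at element centroids — the
  same convention as every other distance in the package.

# Discretization-error metrics (study 1)

* $E_x = \lVert\phi_X - \phi_H\rVert_\infty / \lVert\phi_H\rVert_\infty$ —
  scaled infinity-norm ECG error against the finest mesh.
* ECG lag: the integer-sample shift maximizing the zero-padded,
  un-normalized cross-correlation; ties break toward the smallest absolute
  shift, then toward the negative shift (documented for bit-exact
  reproducibility).
* Activation error: absolute difference of normalized activation times
  (signed differences are retained in an auxiliary column).
* COV = sample SD / mean across patients, per resolution and metric;
  a zero mean (typical for the integer-valued lag) yields `NA` — undefined,
  not zero.

The finest mesh is ground truth and never appears as an error row. The
probe and pacing locations are fixed *physical* points mapped to the nearest
node on each mesh, making the cross-resolution correspondence
mesh-independent.

# Input perturbations (study 2)

BZ extent is perturbed by pure label reassignment (no remeshing), mirroring
segmentation error: `contract_bz()` relabels BZ elements within 0.5 mm of
the BZ-healthy interface as healthy; `expand_bz()` relabels healthy elements
within 1 mm of the BZ∪scar boundary as BZ. Scar is never altered (pacing
locations are defined relative to scar). Distances are centroid-to-interface
Euclidean. By construction the variants nest:
contracted ⊆ original ⊆ expanded, with an identical scar set.

Conductivity variants retune $\sigma_f$ to 80% and 120% of the baseline CV
with the anisotropy ratio preserved exactly, each verified by re-measuring
the planar CV to within 2%.

# The robustness battery

With $K$ patients and HRGV panels (near/far × 3 variants):

* **Systematic bias**: one-sided paired t-test (near > far) using a single
  variant for all patients.
* **Worst case**: per-patient max over variants of near-HRGV against min of
  far-HRGV. This combination is not jointly attainable and — because the
  paired t statistic is not monotone in per-patient differences (the
  variance can grow) — its significance does not *formally* bound all
  assignments; the report records this caveat rather than repairing the
  argument.
* **Monte-Carlo assignment sampling**: each sample assigns one variant per
  patient uniformly and independently, the same variant feeding both pacing
  sites of a patient (one representation per patient per sample); the
  fraction of samples significant at α = 0.01 is reported. For $K\le 6$
  cohorts the exhaustive fraction over all $3^K$ assignments is available
  as an oracle (`exhaustive_fraction_significant()`).
* **Normal-CV interpolation sampling**: per sample and patient an
  independent CV ~ N(66, 6.6²) cm/s is drawn, clamped to the simulated CV
  range (extrapolating beyond the simulated physics is unsupported), and
  near/far HRGV are piecewise-linearly interpolated at the drawn CV.

Zero-variance difference vectors are degenerate for the t statistic;
the package's convention is p = 0 / 1 / 0.5 for all-positive / all-negative
/ all-zero differences, with an explicit flag. Constructed fixtures hit this
case; real panels essentially never do.

All sampling is chunked, vectorized and reproducible bitwise from
`(panel, seed, n_samples)`. Desk default `n_samples = 1e4`; the full-scale
$10^6$ is a flag away.

# Design notes on the built-in near-vs-far effect

Study 2's cohort must *contain* the effect whose robustness is being
tested. In slab geometry, which pacing site accumulates the larger
super-threshold gradient volume is governed by the alignment of two
gradients across the BZ: the activation-time gradient (direction of wave
travel) and the APD gradient (BZ-healthy difference). With a strongly
prolonged BZ APD, the aligned halo forms on the *far*-pacing approach side
and the contrast reverses. The frozen defaults therefore combine:

* strong BZ conduction slowing (`bz_conductivity_scale = 0.1`, BZ CV ≈ 26%
  of healthy — within the range reported for surviving infarct border
  zones), which makes near-scar pacing generate wrap-around activation-time
  shear along the BZ circumference; and
* BZ membrane remodeling with `tau_close` × 1.2 and `tau_in` × 1.5. The
  longer `tau_close` alone would prolong APD, but the reduced excitability
  dominates and the emergent cellular APD is ~7% *shorter* in BZ —
  consistent with experimental healed-infarct epicardial border zones
  (shortened APD, slowed upstroke).

With these conditions the near-vs-far contrast is positive for every
patient across independent cohort draws, which is what the acceptance run
measures end to end. The healthy-tissue activation gradient
(1/CV ≈ 15–23 ms/cm across fiber angles with anisotropy ratio
$\sigma_f/\sigma_c = 2.25$) sits below the 30 ms/cm HRGV threshold, as it
does at the calibrated CV in full-scale studies — so HRGV measures
scar-related gradients rather than background propagation.

# Problem sizes and numerical defaults

The packaged studies are intentionally desk-scale: study 1 uses 3 patients
on 1.6 × 0.8 × 0.3 cm slabs at target edge lengths 0.2 / 0.1 / 0.05 cm with
a 100 ms window (the convergence QOIs are complete once activation is);
study 2 uses 5 patients at 0.1 cm with a 320 ms window covering full
repolarization, 10 simulations per patient (3 BZ variants × 2 sites, plus
low/high conductivity × 2 sites). `dt = 0.1` ms, output every 1 ms.
Both complete in minutes on one core; all sizes are arguments, so larger
cohorts, finer meshes or $10^6$-sample batteries are configuration changes,
not code changes.

# Known limitations

* Slab anatomies cannot reproduce anatomically specific findings (e.g.
  which real patient is an outlier); they validate machinery and logic.
* The worst-case test's "covers all assignments" interpretation is
  heuristic (see above); the Monte-Carlo scenario is the load-bearing one.
* Scar handling (zero conductivity, no reaction) is one of several
  reasonable treatments of non-excitable tissue; alternatives (e.g.
  passive conduction in scar) would change HRGV near the scar boundary.
* BZ electrophysiology parameters are declared package defaults, not
  values from any specific patient cohort; provenance is recorded in the
  study manifests.
* The pseudo-ECG is a far-field proxy; no torso conductor or 12-lead
  reconstruction is attempted.
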