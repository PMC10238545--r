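---
title: "Solving a sparsely populated excited state: models, restraints and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solving a sparsely populated excited state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(exstate)
```

This vignette is the package's account of its science: the models it
fits, the restraint energies it minimizes, the defaults it chose where
the design was genuinely open, and what its synthetic benchmarks do and
do not demonstrate about real data.

## 1. Two-site exchange and CPMG dispersion

The exchange model is A ⇌ B with forward rate $k_1 = p_B k_{ex}$ and
reverse rate $k_{-1} = p_A k_{ex}$, populations $p_A + p_B = 1$
($p_B \le 0.5$ by convention), shift difference $\Delta\omega$ and
intrinsic relaxation rates $R_{2A}, R_{2B}$. During a constant-time
CPMG element of length $T_{CP}$ (20 ms throughout, matching the
experiment emulated) with refocusing frequency $\nu_{CPMG}$, the
transverse magnetization evolves under the $2\times 2$ complex
Bloch–McConnell matrix

$$A = \begin{pmatrix}-(R_{2A}+k_1) & k_{-1}\\ k_1 &
-(R_{2B}+k_{-1}) + i\Delta\omega\end{pmatrix},$$

interrupted by $180^\circ$ pulses that conjugate the coherence. One
$(\tau\!-\!180\!-\!2\tau\!-\!180\!-\!\tau)$ block has propagator
$M = E(\tau)\,\overline{E(2\tau)}\,E(\tau)$ with $E(t) = e^{At}$ and
$\tau = T_{CP}/(4n)$, where the echo-block count $n = T_{CP}\nu_{CPMG}$
must be a positive integer (values within 0.01 of an integer are
rounded with a warning; others are rejected).
`r2eff_exact()` diagonalizes $E$ and $M$ in closed form (all
eigen-quantities of a $2\times2$ matrix are explicit) and computes

$$R_{2,\mathrm{eff}} = -\tfrac{1}{T_{CP}}
\ln\bigl|\mathbf{1}^{T} M^{\,n} p_0\bigr|, \qquad p_0 = (p_A, p_B)^T .$$

This is the exact all-timescale solution of the Carver–Richards
family, valid for unequal intrinsic rates. `r2eff_numeric()` is its
independent oracle: stepwise pulse-by-pulse propagation using a
scaling-and-squaring series exponential; the test suite additionally
cross-checks it against an ODE integration. Two details the exact
solution exposes: in deep slow exchange ($k_{ex} \ll \Delta\omega$) the
profile genuinely oscillates with $\nu_{CPMG}$, so monotonicity is
asserted only for $k_{ex} \gtrsim \Delta\omega$; and for unequal
$R_{2A} \ne R_{2B}$ at $\Delta\omega = 0$ the observed rate differs
from the population average by an exchange-narrowing term of order
$(\Delta R_2)^2/k_{ex}$.

$\Delta\omega$ is stored in ppm and converted with the nucleus Larmor
frequency derived from the stated $^1$H field via fixed gyromagnetic
ratios. Its sign is not identifiable from CPMG data, so fits constrain
$\Delta\omega \ge 0$.

## 2. Dispersion fitting

`fit_dispersion()` minimizes the error-weighted $\chi^2$ against the
exact model. Replicate $\nu_{CPMG}$ points (100/400/1000 Hz are
acquired twice) enter individually, never averaged; their spread can
supply the per-point error (`sigma_from_replicates()`, pooled over the
replicated frequencies of a profile).

* *Single temperature*: $(k_{ex}, p_B)$ shared across residues,
  per-residue $\Delta\omega$ and $R_{2,0}$.
* *Multi-temperature*: $k_1(T)$ and $k_{-1}(T)$ each follow an
  Arrhenius law, parameterized for conditioning as (rate at the 298.15
  K reference, $E_a$) with the prefactor derived; populations at each
  temperature follow from the rates; each residue's $\Delta\omega$ is
  temperature-independent; intrinsic $R_{2,0}$ is free per residue and
  temperature.

Both modes start from an extensive grid search ($k_{ex}$: 20
log-spaced points in 100–6000 s$^{-1}$; $p_B$: 10 points in 0.01–0.5;
$\Delta\omega$: 10 points in 0.1–5 ppm) and finish with bounded
quasi-Newton (L-BFGS-B) descent — a monotone descent honoring the
accelerated-gradient contract without copying a specific algorithm.
Two implementation choices matter for robustness: the intrinsic
$R_{2,0}$ offsets enter the model linearly and are profiled out in
closed form at every objective evaluation (halving the parameter count
and removing the slowest directions), and parameters are rescaled so
the optimizer sees comparable curvatures.

Uncertainties follow the multi-start convention: `estimate_errors()`
restarts the local descent from 100 random points inside the grid
ranges and reports the standard deviation over the 10 lowest-$\chi^2$
refits. Exchange is only reported where the dispersion amplitude
$R_{2,\mathrm{eff}}(\nu_{\min}) - R_{2,\mathrm{eff}}(\nu_{\max})$
strictly exceeds twice the median point error (`detect_dispersion()`;
a profile exactly at threshold is *not* detected).

## 3. Lineshapes and populations

`lineshape_1d()` evaluates the n-site McConnell spectrum
$I(\omega) = \mathrm{Re}[\mathbf{1}^T(i(\omega I - \Omega) + R_2 -
K)^{-1}p]$ with a $10^{-3}$ s$^{-1}$ linewidth floor; the kinetic
matrix must satisfy detailed balance. In slow exchange the integrated
component areas report the populations; `fit_lorentzian_pair()`
quantifies them, and `populations_from_peaks()` is the trivial
minor/(major+minor) ratio. The temperature series generator shows the
expected phenomenology: a single averaged line at 35 °C splitting into
resolved major/minor peaks near 2–7 °C as the Arrhenius-coupled rates
slow, with the cold-temperature minor fraction (about 26% under the
default truth) exceeding the 15% seen by CPMG at 25 °C because the
forward and reverse activation energies differ.

## 4. RDCs and alignment tensors

Couplings are modeled as $D = D_{\max}\, v^{T} S v$ with $S$ the
traceless symmetric Saupe tensor expressed in Hz on the N–H scale;
type-specific constants are computed from gyromagnetic ratios and
effective bond lengths (N–H 1.041 Å, C$^\alpha$–H$^\alpha$ 1.117 Å,
N–C′ 1.329 Å, H$^N$–C′ 2.085 Å), giving scale factors 1, −2.01, 0.121,
−0.309 relative to N–H. Missing protons are built by ideal geometry
(amide H on the external C$^\alpha$–N–C′ bisector at 1.02 Å;
H$^\alpha$ by tetrahedral completion at 1.09 Å); prolines carry no
N–H, glycines no C$^\alpha$–H$^\alpha$. N–C′ couples N(i) to the
preceding carbonyl.

`svd_fit_tensor()` solves the five Saupe components from the
$1/\sigma$-weighted direction-cosine design matrix by SVD (rank 5
required). Conventions: eigenvalues ordered
$|S_{zz}| \ge |S_{yy}| \ge |S_{xx}|$, magnitude $D_a = S_{zz}/2$,
rhombicity $R = \tfrac{2}{3}(S_{xx}-S_{yy})/S_{zz} \in [0, 2/3]$.
Quality factors (on the N–H-normalized scale):
$\mathrm{rmsd} = \sqrt{\langle(\mathrm{obs}-\mathrm{calc})^2\rangle}$,
$Q = \mathrm{rmsd}/\sqrt{\langle \mathrm{obs}^2\rangle}$, and
$R = \mathrm{rmsd}/\sqrt{2D_a^2(4+3R_h^2)/5}$, whose denominator is
the rms coupling of an isotropic bond-vector distribution; computed on
a held-out set it is the cross-validated R-free.

### Tensor-magnitude ("sparsity") correction

An RDC set fitted against an imperfect reference structure suffers
regression dilution: angular errors in the bond vectors enter the
design matrix and bias the fitted magnitude low, typically by about
10%, while rhombicity and orientation are much less affected. The
effect is strongest when the set samples orientations sparsely and
anisotropically, because missing near-axis vectors leave the $S_{zz}$
direction poorly conditioned. `correct_tensor_magnitude()` implements
the grid remedy: per-set SVD fits, then a common scale factor
(1.00–1.20, step 0.01) applied to all magnitudes in one medium with
orientation and rhombicity fixed, selecting the scale that minimizes
the summed R factor over the medium's coupling types (the scaled
magnitude enters the R-factor denominator, which is what drives the
optimum above 1 exactly when the residual power exceeds the
measurement noise). A warning reports a grid that is still descending
at its upper edge. On densely sampled data fit against the true
structure the selected scale is 1.00; the package's benchmark for the
corrective direction uses orientationally anisotropic subsets
(`anisotropic_rdc_subset()`, $|\cos\theta| < 0.75$ to the tensor axis)
fitted against a reference perturbed by 0.08 Å coordinate noise
(`perturb_structure()`), conditions under which the SVD magnitude is
biased low by 5–10% and the corrected magnitude lands closer to the
truth, with scales in the 7–12% range.

## 5. Two-state ensemble refinement

`refine_two_state()` solves for the minor conformer of an N = 2
ensemble whose major member is fixed (bit-identical) to the ground
structure, by restrained Cartesian minimization of the heavy backbone
atoms (N, C$^\alpha$, C′, O, C$^\beta$) with analytic gradients
(L-BFGS-B, 600 iterations by default). The energy is

$$E = \sum_{\mathrm{sets}} k_{rdc} \sum_i
\Bigl(\tfrac{D^{obs}_i - (1-w)D^{g}_i - w\,D^{m}_i(X)}{\sigma_i}\Bigr)^2
+ E_{\mathrm{geom}} + E_{\mathrm{cap}} + E_{\mathrm{dihe}},$$

with $w$ the minor population. Three design decisions proved decisive
and are worth recording:

* **Rigid analytic RDC vectors.** The proton-borne vectors (N–H,
  C$^\alpha$–H$^\alpha$, H$^N$–C′) are differentiable functions of the
  heavy atoms through the ideal-geometry construction, with gradients
  chained through the unit-vector projections. Treating protons as
  free restrained particles instead lets the minimizer rotate
  individual bond vectors at negligible geometric cost to chase
  measurement noise, which destroys cross-validation transfer (0/4
  held-out sets improved in that configuration, 3/4 with rigid
  vectors). Rigidity restores the property that fitting an RDC can
  only reorient local backbone — the same reason torsion-space
  refinement engines behave well.
* **Local geometry plus fold preservation.** $E_{\mathrm{geom}}$ is an
  elastic network on the ground-state geometry: bonded pairs (k =
  200·$k_{geom}$), 1-3 pairs (50·$k_{geom}$), 1-4 pairs
  (20·$k_{geom}$), with $k_{geom} = 20$, plus weak long-range
  C$^\alpha$–C$^\alpha$ contact springs (reference distance < 9 Å,
  sequence separation ≥ 3, k = 2). The contacts are essential: without
  tertiary packing terms a backbone hinges freely at loops, and
  lever-arm motions of distant segments swamp the genuine signal.
* **No overfitting.** $k_{rdc} = 0.3$ together with start-coordinate
  noise of 0.25 Å and averaging the predictions of the $n_{keep}$
  lowest-energy runs keeps the in-sample fit near, not below, the
  measurement error — the "within but not tighter than experimental
  error" rule. `calibrate_rdc_weight()` automates the choice by
  bisection on the N–H fit rmsd band when data conditions differ.

$E_{\mathrm{cap}}$ is a flat-bottom penalty (k = 50) on atomic
departures beyond 3 Å from the start, the stated excursion limit.
$E_{\mathrm{dihe}}$ consumes generic flat-bottom $\varphi/\psi$
restraints (target, halfwidth; k = 30 rad$^{-2}$) — the role
chemical-shift-derived dihedral predictions play on real data; the
synthetic benchmarks derive them from the true minor structure with a
5° halfwidth (`dihedral_restraints_from()`). Residues without RDCs
(the exchange-broadened switch regions) are restrained by geometry
only. Each of the `n_runs` starts perturbs the mobile atoms with
seeded Gaussian noise; runs are sorted by energy and the `n_keep`
lowest form the reporting ensemble.

`crossval_rfree()` repeats the refinement with one (medium, type) set
excluded from *every* energy term and scores that set against the
kept-run-averaged ensemble prediction (R-free), alongside the
ground-only R. `population_grid_search()` runs the cross-validation
over minor fractions (default 0.1–0.5, step 0.1) and selects the
fraction minimizing the summed R-free; the dihedral energy per
fraction is reported as a secondary diagnostic. Selecting by dihedral
energy and selecting by R-free agree on the synthetic benchmark within
one grid step; R-free is the default because it is the quantity the
cross-validation already computes. "No
identifiable optimum" is declared when the grid is flat within
`flat_tol` (2% relative) *or* when no fraction beats the one-state
fit — the signature of ground-state-only data.

## 6. The synthetic truth: what it emulates, and what it does not

`synthetic_truth()` fixes the study conditions:

* a 166-residue idealized mixed α/β backbone (G-domain-like secondary
  structure layout, all-alanine), built from ideal internal
  coordinates;
* a minor conformer displaced in two segments (residues 105–118 and
  125–140, strand/helix analogues): each segment is *tilted* about an
  axis perpendicular to its principal axis — so bond vectors genuinely
  reorient, the feature RDCs detect — slightly translated, blended
  over 4 flanking residues, and relaxed under the elastic network
  until bond-class distances are within 1% of ideal; the maximum
  atomic displacement request is 2.8 Å (realized ≈ 2.2 Å after
  relaxation), under the 3 Å refinement cap;
* minor weight 0.30 for RDC averaging;
* two alignment media with seeded non-collinear tensors
  ($D_a$ = −13 Hz, $R_h$ = 0.30; +8.5 Hz, 0.55), four coupling types,
  switch-region residues removed (exchange broadening), 92%
  completeness, noise 0.5/1.0/0.2/0.2 Hz for
  NH/C$^\alpha$H$^\alpha$/NC′/H$^N$C′;
* exchange probes at the Ile positions 21, 24, 36, 55, 100, 139, 142
  with $\Delta\omega$ 0.6–2.4 ppm, $p_B$(25 °C) = 0.15 and
  $k_{ex}$(25 °C) = 1000 s$^{-1}$ via $E_a$ = 40 (forward) and 60
  (reverse) kJ/mol — so the minor state grows to ~26% on cooling to
  2 °C, reproducing the apparent tension between CPMG- and
  lineshape-derived populations as pure temperature dependence;
* dispersion noise 0.3 s$^{-1}$ with the 100/400/1000 Hz points
  duplicated, at 20/25/30 °C.

Every generator is a pure function of (parameters, seed).

What the generator does *not* emulate: side chains beyond C$^\beta$
and real packing (contacts are springs, not physics); anisotropic
tumbling and field-dependent relaxation; multi-state or μs-timescale
exchange layered on the two-state process (the real system's elevated
multi-temperature $\chi^2$ hints at exactly that); medium-induced
structural perturbations; and assignment ambiguity. Passing benchmarks
therefore demonstrates the correctness and internal consistency of the
estimators under the stated noise model — not that two states suffice
for any particular real protein, which is precisely what the R-free
cross-validation must decide anew on real data.

## 7. Numerical choices and problem sizes

* Closed-form $2\times2$ eigen-decompositions throughout the CPMG
  kernel, with a degenerate-eigenvalue branch; the numerical oracle
  uses a 24-term scaling-and-squaring series.
* Superposition by SVD (Kabsch) with a proper-rotation constraint; a
  required reflection warns of chirality mismatch. Backbone is
  N/C$^\alpha$/C′/O, configurable to C$^\alpha$-only. Ensemble means
  are computed by two rounds of mutual superposition onto the running
  mean.
* Ties and boundaries: dispersion detection uses a strict inequality;
  the echo count tolerates 0.01 of rounding; eigenvalue ordering is by
  absolute value with determinant-positive eigenvector frames.
* Seeds are explicit arguments everywhere; stage seeds in the pipeline
  derive from the master seed by fixed offsets; reports serialize with
  fixed precision so identical configurations reproduce byte-identical
  JSON.
* Benchmark problem sizes: the full 166-residue conditions are used for
  the acceptance suite (grid search and cross-validation with 8 starts
  per refit, keeping 4; the reporting ensemble with 20 starts, keeping
  10); unit tests exercise 40–60-residue instances of the same
  generators. The refinement's 10-best-of-100 convention remains the
  default of `refinement_config()` for production use.

## 8. Known limitations

* The refinement is a minimizer, not a sampler: the kept-run spread
  underestimates true conformational uncertainty and depends on the
  start noise.
* The R-free improvements that validate a two-state model are small
  (a few percent of the R factor), as in the real experiment; their
  detection needs several RDC sets of good precision, and the
  C$^\alpha$–H$^\alpha$ sets transfer less cleanly than N–H.
* The tensor-magnitude correction compensates dilution bias on
  average; on any single sparse set it can overshoot.
* The population grid is only as identifiable as the nonlinearity of
  the orientation response allows; fractions neighboring the optimum
  (±0.1) are often within noise, which is why the optimum is reported
  with its full diagnostic table.
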