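---
title: "Accelerated 3D multi-slab diffusion MRI: models, reconstruction and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated 3D multi-slab diffusion MRI: models, reconstruction and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`slabkq` simulates and reconstructs accelerated 3D multi-slab
diffusion-weighted MRI (3D-msDWI) experiments end to end: a multi-shell
q-space protocol with randomized 2D-CAIPI ky-kz undersampling, a
three-compartment tissue signal model with B-tensor encoding shapes, a
digital multi-coil slab phantom with per-shot motion-induced phase, a
compact denoising autoencoder (DAE) acting as a plug-and-play q-space
prior, a phase-compensated SENSE + TV + DAE joint k-q reconstruction, and
compartment / DTI / DKI fitting with ROI statistics. Everything runs at
desk scale on one CPU; the package is a testable reimplementation of the
method, not a scanner pipeline.

# Signal model

The per-voxel signal kernel has three compartments: an intra-axonal
"stick" with fraction $f_a$ and diffusivity $D_a$, an axially symmetric
extra-axonal tensor with diffusivities $D_{e\parallel} \ge D_{e\perp}$,
and free water with fraction $f_w$ and fixed $D_w$:

$$K(b,\beta,\xi^2) = f_a e^{-b D_a s} +
  f_e e^{-b D_{e\perp} - b (D_{e\parallel}-D_{e\perp}) s} +
  f_w e^{-b D_w},\qquad
  s = \beta\left(\xi^2 - \tfrac13\right) + \tfrac13,$$

with $\xi = \hat g \cdot \hat n$ the cosine between the encoding axis and
the fiber axis, and $\beta \in [0,1]$ the B-tensor encoding shape
(1 linear, 0 spherical). $\beta = 1$ recovers the standard
single-diffusion-encoding kernel. The measured signal convolves $K$ with
an orientation distribution $\mathcal P(\hat n)$ (Watson or discrete) on a
deterministic antipodally symmetric Gauss-Legendre x azimuth quadrature
grid (default 1000 nodes).

Choices worth noting:

* The dot products in the kernel exponents are interpreted as squared
  cosines, the standard-model convention.
* $b$-values are entered in s/mm^2 and converted to ms/um^2 so
  diffusivities in um^2/ms multiply directly; diffusivity bounds are
  0-3.2 um^2/ms and $D_w = 3.0$ um^2/ms (free water at body temperature).
* The powder average has a closed form per compartment,
  $e^{-bD(1-\beta)/3}\sqrt{\pi/4x}\,\mathrm{erf}(\sqrt x)$ with
  $x = bD\beta$, with a series expansion below $x = 10^{-6}$; it is tested
  against 10,000-node quadrature to 1e-6.

# Protocol, undersampling and timing

The default protocol matches the acquisition the package emulates:
3 shells at $b$ = 1000/2000/6000 s/mm^2 with 22 directions each (seeded
electrostatic repulsion on the hemisphere), TR = 2 s, 14 mm slabs
oversampled 40% to a 20 mm FOVz at 1 mm slices (20 kz planes), 8 slabs
(112 mm coverage). kz reductions are stored as rationals ("20/6"), so
"Rz = 3.33" means exactly 6 shots; the undersampling masks sample 6 kz
planes per volume (even partition, per-volume random circular offset) with
a step-3 ky progression whose offset follows the CAIPI shift across plane
ranks. Volume acquisition time is shots x TR = 12 s; the 66-volume scan
plus one fully sampled non-DW volume takes exactly 832 s (the package
reports seconds and never rounds to the printed "13.8 min"). The net
undersampling factor is exactly 10 when Ny is divisible by 3.

# Phantom: what it emulates, and what it does not

The phantom is a concentric 2D geometry extruded along the slab: a CSF
ventricle ($f_w = 1$), a corpus-callosum-like bundle carrying the
literature CC values ($f_a = 0.60$, $D_a = 2.27$ um^2/ms), a second
(CST-like) bundle, generic WM and a GM rim. Tissue parameters are
piecewise constant per label; S0 carries a seeded smooth 2% texture so
realizations differ. Watson concentrations (kappa 1-8) correspond to
orientation dispersions typical of in-vivo WM. Coils are Gaussian-profile
complex maps normalized to unit root-sum-of-squares; the slab excitation
profile is a raised-cosine-edged rectangle covering the nominal 14 mm
inside the oversampled FOVz. Per-shot motion phase is a second-order 2D
polynomial with coefficients $\sim N(0, \sigma^2 b/1000)$,
$\sigma = 0.5$ rad at $b = 1000$, zero for $b = 0$. Noise is complex
Gaussian in k-space with $\sigma$ = mean foreground b0 magnitude / SNR.

The phantom does **not** model susceptibility distortion, eddy currents,
fat signal, relaxation weighting, inter-volume motion, or partial-volume
mixing; a green phantom test validates the algorithm chain, not scanner
robustness. The readout (kx) dimension is collapsed: encoding acts on the
(ky, kz) plane per image column, consistent with a fully sampled EPI
readout.

# Navigator phase estimation

Each shot's 2D navigator is reconstructed by CG-SENSE (ky undersampled by
3). The phase estimator projects magnitude-weighted, wrap-free finite
phase differences $\arg(I_{i+1}\bar I_i)$ onto the quadratic phase model
that rigid motion induces; this is exact for noiseless polynomial phases
(the test asserts < 0.02 rad) and is the package's "low-pass filter".
Gaussian complex-image smoothing is available as an alternative
(`phase_model = "smooth"`). At desk scale (32x32 object, SNR 20,
per-direction diffusion contrast) the measured b1000 accuracy is
~0.13 rad circular RMSE, and the b6000 navigators are intrinsically
noise-limited — the acceptance tests freeze these measured values rather
than idealized ones. Constant phase offsets are unidentifiable and
irrelevant to the reconstruction.

# Joint k-q reconstruction

The reconstruction minimizes

$$\|\mathcal A(S) - Y\|^2 + \lambda_1 \mathrm{TV}(S) +
  \lambda_2 \|S - \mathcal Q_\Theta(S)\|^2$$

where $\mathcal A$ is the per-shot phase-compensated SENSE operator
(centered unitary FTs; the adjoint passes a 1e-10 dot-product test) and
$\mathcal Q_\Theta$ the trained DAE applied to per-voxel magnitude
q-vectors after b0 normalization, with the current phase carried by the
data-consistency variable.

The solver is a half-quadratic alternation: refresh the anchor
$Z = \mathcal Q_\Theta(|S|)$, solve the quadratic (data + anchor) terms
per volume by warm-started CG, then apply an isotropic-TV proximal step
(Chambolle dual projection, weight $\lambda_1/(1+\lambda_2)$). An outer
update is accepted only if the fixed-$Z$ objective does not increase, so
the objective-sanity invariant holds by construction. $\lambda_2 = 0$
gives the ablated variant, solved by ADMM (CG on the $\rho$-augmented
system plus the TV prox at strength $\lambda_1/\rho$) because plain
proximal-gradient descent semiconverges and then diverges on this
ill-conditioned 9x-undersampled problem; $\lambda_1 = \lambda_2 = 0$ is
plain CG-SENSE solved exactly (this path matches a dense
normal-equations solve to 1e-8 on a toy problem).

Two empirical findings shaped the defaults:

* **Initialization matters.** The plug-and-play iteration is started from
  the plain per-volume CG-SENSE solution. Its semiconvergent iterate
  carries noise-like residual aliasing that sits inside the denoiser's
  training regime; smoother initializations (scaled zero-filled adjoint)
  converge to visibly worse fixed points.
* **The prior's working range.** The DAE is trained at SNR 10-50; at
  desk scale the undersampling artifacts entering the denoiser are
  stronger than thermal noise, which bounds how much of the gap to the
  oracle (anchoring to ground truth reaches NRMSE ~0.03) the iteration
  can close. The acceptance criterion is the error *ordering*
  (full < ablated < zero-filled), which holds with wide margins.

$\lambda_1$ and $\lambda_2$ have no published reference values for this configuration; they were
chosen once by a small grid search on the phantom experiment and frozen
as `recon_config()` defaults.

Slab combination is a profile-weighted average with per-z weight
renormalization — a simplified, exactly-testable stand-in for nonlinear
slab-boundary correction (a constant object through overlapping
raised-cosine profiles reproduces a constant to 1e-10).

# DAE prior

"Three-layer fully connected autoencoder" is read as three hidden
representations (64-32-64, tanh; widths are not stated in the source
work). Training minimizes a shell-weighted MSE with weight 1.5 on the
b6000 shell (1.0 elsewhere) with Adam on simulated signals drawn
uniformly from healthy-brain parameter ranges, Watson ODFs with random
orientation and concentration, and Gaussian magnitude noise at SNR
10-50. Across 5 seeds, the weighted loss yields b6000 held-out MSE at or
below the unweighted counterpart (majority vote asserted). The denoiser
never changes the b0-normalization convention: inputs are divided by s0
and outputs rescaled by the same factor.

Because the trained network is an (approximately) MMSE denoiser for its
noise range, clean manifold signals pass through with a small bias floor
(~4-5% relative L2 at these widths/epochs); the test asserts the measured
bound (median < 8%), not an idealized one.

# Compartment fitting

Fitting uses per-shell rotational invariants. For each (b, beta) group
the spherical mean $s_0$ and, when the group has at least 6 directions,
the l = 2 invariant $s_2$ are estimated by least-squares spherical
harmonics (order 4 by default; higher orders absorb leakage). By the
Funk-Hecke factorization, $s_l(b,\beta) = p_l\,\tilde K_l(b,\beta)$ with
$\tilde K_l = \int_0^1 K(b,\beta,t^2) P_l(t)\,dt$ and
$p_l = E[P_l(\hat\mu \cdot \hat n)]$; both sides of this identity are
unit-tested against each other. A bounded multistart L-BFGS-B (fixed
Latin hypercube; coarse pass, then restarted tight polish of the best
candidates with 1e-6 numerical-gradient steps — the default 1e-3 steps
stall in the flat valleys of this model) returns the best-residual
solution, flags the known $D_a \gtrless D_{e\parallel}$ branch
ambiguity, and flags CSF-degenerate voxels.

Two identifiability facts drive the test design:

* With a single encoding shape (3-shell linear encoding), the
  six-invariant problem is *near-degenerate*: parameter sets several
  percent apart reproduce the invariants to ~1e-13. Exact-recovery
  checks therefore use B-tensor-varied (QTI-style) protocols
  (beta in {1, 0.7, 0}), where recovery is ~1e-5; linear-encoding fits
  are validated at the 5% level under noise, which is the regime such studies
  report.
* Rotational invariants estimated from finite direction sets carry
  angular truncation bias (~1e-3 relative at 21-22 directions). The
  200-voxel exact-recovery grid therefore uses fully dispersed
  (isotropic-ODF) voxels, for which powder averages over any direction
  set are exact; dispersion-bearing voxels are covered by dense-direction
  unit tests at their measured tolerance.

DTI uses weighted linear least squares on log-signals (one reweighting
pass); DKI fits the 22-parameter kurtosis design and averages the
directional apparent kurtosis (clamped to [0, 10]) over 256 uniform
directions. The two-Gaussian mixture identity K = 3 Var(D)/mean(D)^2 =
1/3 is a small-b cumulant property: the acceptance check runs it at
b = 100/200 s/mm^2, where the quadratic truncation bias is below 2%
(at b = 1000/2000 s/mm^2 the exact 3-point fit gives K = 0.267 — a 20%
truncation bias no fitting method avoids).

ROI statistics report mean, SD (n-1) and COV = SD/mean x 100% per label;
the across-realization variant aggregates per-realization ROI means,
emulating across-subject COV.

# Scaled-down acceptance experiments

The acceptance suite (tests/testthat/test-acceptance.R and
scripts/acceptance.R) runs the reconstruction ordering experiment at the
stated 32x32x6 / 8 coils / 66 volumes / SNR 20 configuration with
Ry = 3, Rz = 6/2 (net factor 9.1x, the closest realizable to "~10x" on a
6-plane slab) and fewer outer iterations than the package default (the
ordering is stable after a handful); the DAE comparisons use 3000
training samples. These reductions keep the suite inside its CPU budget
and are recorded here deliberately: none of them was chosen by searching
for a passing configuration.

# Known limitations

* Magnitude denoising introduces a Rician-like bias at very low SNR
  shells; the data-consistency term only partially corrects it.
* No motion compensation between volumes; no susceptibility, eddy
  current or fat modeling.
* The navigator phase model is quadratic; higher-order or non-rigid
  phase errors would need the Gaussian-smoothing estimator and denser
  navigators.
* Single-shape (pure linear-encoding) compartment fits inherit the
  standard model's flat-valley degeneracy; treat their absolute values
  with the same caution the field does.
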