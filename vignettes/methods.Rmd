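---
title: "Motion-resolved multiparametric cardiac mapping with mtsms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-resolved multiparametric cardiac mapping with mtsms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative myocardial T1 and T2 mapping conventionally requires one
breath-hold per slice per parameter, with ECG triggering to freeze cardiac
motion. `mtsms` implements a continuous-acquisition alternative: three
short-axis slices are excited simultaneously (multiband factor 3), k-space
is sampled continuously along golden-angle radial lines while a T2prep-IR
preparation cycle modulates the contrast, and cardiac phase, respiratory
phase, T1 recovery and preparation weighting are all resolved retrospectively
from the data themselves. The package provides both the *instrument* (a
dynamic digital phantom and an exact forward model, so every stage can be
validated against known ground truth) and the *method* (self-gating,
low-rank tensor reconstruction, and two-step parameter fitting).

## Signal model

Each recovery period starts with a preparation: a T2-sensitizing module of
duration $\tau$ followed by an inversion, with a signed efficiency $B$
($B=-1$ is a perfect inversion; $\tau = 0$ is a plain inversion). A spoiled
FLASH train with flip angle $\alpha_k$ then reads out the recovery. With
$E_1 = e^{-TR/T_1}$ and a B1+ transmit scale $\beta$, the signal at
excitation $n$ of period $k$ is

$$ s(n) = A\,\frac{1-E_1}{1-E_1\cos\beta\alpha_k}
 \left[1 + \left(B\,Q_k e^{-\tau/T_2} - 1\right)
 (E_1\cos\beta\alpha_k)^n\right]\sin\beta\alpha_k,
 \qquad
 Q_k = \frac{1-E_1\cos\beta\alpha_k}{1-E_1\cos\beta\alpha_{k-1}}. $$

$Q_k$ carries the steady state of the previous period's flip angle into the
current preparation; alternating two flip angles (3 and 10 degrees by
default) across periods makes the pair of recovery curves jointly sensitive
to $\beta$, which is what makes the T1/T2 estimates B1+-robust. Five
preparation durations (0, 30, 40, 50, 60 ms) interleaved with the two flip
angles give a cycle of 10 distinct (preparation, flip) combinations.

Two evaluation paths exist: the closed form above (`signal_curve`) and a
per-TR Bloch recursion (`bloch_oracle`). The closed form *assumes* the
magnetization entering each preparation sits at the previous period's FLASH
steady state. A strictly continuous recursion does not satisfy this for long
T1 (at T1 = 3000 ms, $(E_1\cos\beta\alpha)^N \approx 0.2$ after a 2.5 s
period), so `bloch_oracle` applies the same per-period steady-state reset by
default (`steady_prep = TRUE`), in which case the two paths agree to machine
precision - this equivalence is a package invariant tested over randomized
tissue parameters. `steady_prep = FALSE` exposes the continuous recursion
for studying the size of the steady-state approximation itself. The
simulator uses the closed form, so simulation and fitting share one
consistent model; TE decay is not modelled (TE is ~1.6 ms, far below any T2
of interest).

## Dictionary and relaxation subspaces

`build_dictionary` evaluates the closed form over 21 log-spaced T1 values in
[100, 3000] ms, 21 log-spaced T2 in [10, 3000] ms, 7 B1+ scales in [0, 1.5],
and 7 preparation efficiencies (21,609 atoms). Efficiencies span [-1, -0.7]:
the sign encodes the inversion, and adiabatic inversions in practice stay
within ~30% of ideal. Rows are stored on a decimated excitation grid (every
8th excitation of the 714 per period; full resolution when a period has at
most 256 readouts). The recovery basis `u_t1` and the combination basis
`u_ta` are the leading left singular vectors of the corresponding dictionary
unfoldings. Because the basis is needed at arbitrary excitation indices when
placing imaging lines, `eval_u_t1` evaluates rows *exactly* through the SVD
relation (regenerating dictionary rows from the closed form and projecting),
rather than interpolating.

For subspace estimation a much coarser dictionary suffices (the span
converges quickly in grid density), so the reconstruction presets use
reduced grids (11 x 11 x 5 x 4 in the desk-scale preset) while parameter
*matching* keeps the fit grids; both are configurable.

## Digital phantom and forward model

The generator is a three-slice short-axis left ventricle: a myocardial
annulus (T1/T2 = 1200/42 ms) around a blood pool (1900/250 ms) with a liver
block (800/34 ms) whose edge provides the respiratory navigator structure.
Defaults are chosen to be realistic at 3 T for a healthy subject. Cardiac
contraction scales the endocardial radius by 25% at peak systole with a
smooth asymmetric waveform; respiration translates the whole frame rigidly
along the readout direction of the training lines with an asymmetric
waveform (long expiratory plateau), optionally drifting by +-10% in period
and amplitude over the scan. Eight loop-like complex coil maps (RSS
normalized to 1) and a smooth quantized B1+ map (0.85-1.15) complete the
object.

The forward model is exact: per readout line, the voxelwise signal at that
line's (combination, excitation, cardiac frame) is coil-weighted,
CAIPIRINHA phase-cycled per band (increments $-2\pi/3, 0, +2\pi/3$ for
apical/mid/basal, stepping once per imaging readout; training lines
unmodulated), summed across bands, transformed along the radial line, and
the respiratory translation applied as its exact k-space phase ramp.
Partial volume is handled by 3x3 supersampled area-weighted class
fractions. What the phantom does *not* emulate: through-plane motion, flow,
off-resonance, non-rigid deformation, and realistic anatomy - passing tests
therefore demonstrate correctness of the algorithm chain under its own
physics assumptions, not clinical performance.

## Non-uniform encoding

Radial sampling uses 2x readout oversampling (sample spacing 0.5 cycles/FOV,
symmetric through k = 0). Two transform paths are provided: an exact direct
non-uniform DFT (the reference), and a 1-D Kaiser-Bessel NUFFT along each
line (spread onto a 2x-oversampled grid with an 8-tap kernel, FFT,
deapodize; accuracy ~1e-7 relative). The NUFFT's adjoint is the exact
transpose of the same factorization, so the forward/adjoint pair satisfies
the adjointness identity to machine precision regardless of the
approximation error - a property the test suite checks for both paths.
Density-compensation (ramp) weights are used only for gridded previews,
coil estimation, and as a least-squares preconditioner, never inside the
adjoint pair.

Coil sensitivities are estimated by phase-cycle-resolved gridding (3-point
inverse DFT across the CAIPIRINHA steps separates the bands), smoothing, and
RSS normalization; in simulation the truth maps can be used directly
(flagged). SVD coil compression to 4 virtual coils (6 at full scale)
precedes reconstruction.

## Self-gating

Training lines (the repeated 0-degree projections, every other readout) are
the gating signal. The contrast weighting predicted by the relaxation
subspaces at each line's (combination, excitation) coordinate is regressed
out of the feature vectors; the residual carries motion. Its leading
principal components are filtered: below 0.7 Hz for respiration (k-means
into 6 bins, ordered along the dominant component) and in a 0.5-2.5 Hz
search band for the heart. Within the search band the dominant cardiac
frequency is located first and the analytic-signal phase is taken on the
isolated fundamental - the asymmetric contraction waveform carries strong
harmonics that corrupt the instantaneous phase if left in - then lightly
smoothed (150 ms boxcar on the unwrapped phase) and partitioned into 20
phase bins refined by k-means on the unit circle (k-means++ style restarts,
50 starts, seeded; ties resolved by lowest bin index).

Respiratory bin orientation uses the waveform's asymmetry: the expiratory
plateau makes the end-expiration extreme the denser one, so that extreme is
anchored at bin 0. The motion state used for parameter fitting is chosen by
*contrast coverage*, not by occupancy: at short scan lengths a preparation
combination occurs in only one or two recovery periods, each spanning well
under one respiratory cycle, so some (combination, respiratory-bin) pairs
are never sampled and their tensor cells are pure extrapolation. Fitting at
a bin missing a combination (notably the inversion-only low-flip one, which
anchors T1) was observed to fail badly while bins with complete coverage fit
to a few percent. `map_volume` therefore defaults to the respiratory bin
maximizing the minimum per-combination line count (ties toward
end-expiration), at the cardiac bin with least contraction (diastole).

## Low-rank tensor reconstruction

Training features (compressed to a rank-16 feature basis by a unitary PCA
rotation - nuclear-norm shrinkage of the feature mode acts identically in
the rotated coordinates and memory drops ~30x) are binned into the 5-way
sampled tensor indexed (feature, excitation grid, combination, cardiac bin,
respiratory bin); multiple lines per cell are averaged. Completion solves

$$ \min_D \|d - \Omega(D)\|_2^2
 + \lambda\left(\|D_{(1)}\|_* + \|D_{(4)}\|_* + \|D_{(5)}\|_*\right)
 + \lambda_c\|\Delta_c D_{(4)}\|_1 + \lambda_r\|\Delta_r D_{(5)}\|_1 $$

subject to the mode-2/3 unfoldings lying in the ranges of `u_t1`/`u_ta`, by
a proximal alternating scheme: data-consistency step, subspace projection,
singular-value thresholding of unfoldings 1/4/5, and 1-D total-variation
proxes along the bin dimensions (cyclic for cardiac phase, one-sided for
respiration; Chambolle-type dual iterations). Defaults:
$\lambda = 0.01\,\sigma_{\max}$ of the zero-filled mode-1 unfolding,
$\lambda_c = \lambda_r = 0.1\lambda$, geometric continuation (factor 0.7
every 10 iterations, floored at $10^{-3}\lambda_0$), backtracked step size
so every accepted step is non-increasing in the objective. A
rank-constrained polish follows (data replacement + truncated HOSVD +
subspace projection), with ranks either supplied (the pipeline passes its
configured reconstruction ranks) or detected from the singular spectra at a
5% relative threshold - the latter is appropriate for exactly low-rank
data, the former for real (approximately low-rank) data. The sampling mask
is defined per tensor *cell*: a training line observes a whole feature
fiber, and the solver enforces this contract.

Factors come from the truncated HOSVD of the completed tensor with modes
2/3 fixed to the dictionary bases; the temporal factor tensor
$\Phi = G \times_2 U_{T_1} \times_3 U_{\tau\alpha} \times_4 U_c \times_5 U_r$
is stored factored and queried lazily. Imaging lines inherit (cardiac,
respiratory) bins from their temporally nearest training line (at most one
TR away given the 1:1 interleave).

The spatial factor solves
$\min_{U_x}\|d-\Omega(\Phi\times_1 F S U_x)\|_2^2+\lambda_w\|WU_x\|_1$.
With $\lambda_w = 0$ (the default for the noiseless presets) conjugate
gradient is used on the normal equations. The temporal weight vectors are
first orthonormalized over the acquired lines (solving in rotated
coordinates and mapping the factor back): the raw weights carry the core
tensor's singular values, whose orders-of-magnitude spread otherwise makes
CG converge last in exactly the weak, T2-bearing contrast directions.
Directions whose relative presence in the acquired lines falls below
`sv_tol` (1%) are truncated rather than inverted. CG is stopped after a
modest number of iterations: unregularized CG is semiconvergent against
model mismatch (binning discretization), and the iteration count acts as
the implicit regularizer. Ramp (density-compensation) weighting of the residual is
available as an option; it speeds up k-space residual convergence but was
observed to degrade the parameter maps by accelerating that same
overfitting, so it is off by default. With $\lambda_w > 0$
FISTA-with-restart is used, with an orthogonal periodic Daubechies-4
wavelet (implemented in the package; 3 levels; soft thresholding applied
separately to real and imaginary parts) and a power-iteration Lipschitz
step. Initialization is the scaled adjoint of the data.

## Parameter fitting

At the fixed diastolic/end-expiratory state, each voxel's (excitation x
combination) curve is rendered from $U_x$ and $\Phi$. Curves are
phase-anchored on their late-excitation (steady-state) samples and fitted as
signed real values, since the signal model is real-valued. Step 1 matches
against the dictionary by maximum normalized inner product and refines
(T1', T2, beta, B) by Nelder-Mead with the amplitude profiled out linearly;
the step-1 T1' is discarded. Step 2 re-fits T1 on the low-flip-angle
combinations only (reduced Look-Locker perturbation), holding (beta, B, T2)
fixed, by a 1-D bounded search on log T1 in [100, 3000] ms with the
amplitude again profiled. Voxels whose curve RMS falls below 8% of the
maximum are not fitted.

## Statistics

`aha16_labels` implements the standard 16-segment division (6 x 60 degrees
basal and mid, 4 x 90 degrees apical, numbered counter-clockwise from the
anterior RV insertion). ICC is fixed to the two-way mixed-effects,
absolute-agreement, single-measure form; Bland-Altman uses 1.96 sample
standard deviations of the differences; scan-rescan CoV uses the two-point
standard deviation $|x_1-x_2|/\sqrt2$ with RMS aggregation over segments and
subjects; segment SNR is mean/sd within a segment and SNR efficiency divides
by the square root of the scan time in minutes. All are validated in the
test suite against independent closed-form or `aov()`-based oracles.

## Problem sizes and presets

The `"default"` preset mirrors the reference acquisition (160 matrix over a
270 mm FOV, 73 recovery periods of 2.5 s = 3 min of scan, 8 coils). The
`"tiny"` preset - used by the worked examples, the acceptance script and
the headline tests - is a desk-scale study chosen to exercise every stage
at interactive cost: 48 matrix, 16 periods (~40 s of simulated scan, 5,712
imaging + 5,712 training lines), noiseless, 4 virtual coils, feature rank
16, factor ranks (16, 6, 6, 6, 4), 10 CG iterations. At this scale the full
simulate/reconstruct/fit chain runs in a few minutes on one core and
recovers myocardial T1 within 5% and T2 within 10% (median) of the phantom
truth.

## Container and file formats

A scan lives in a single serialized container (RDS) holding the named
groups /schedule, /kspace (imaging + training with per-line metadata),
/coils, /truth, and after reconstruction /bins, /dictionary, /subspaces and
/factors; round-trips are bitwise. Parameter maps export as float32 NIfTI
(one file per parameter per slice) with a JSON sidecar; schedules and
statistics tables export as TSV/CSV. A thin command-line driver
(`inst/cli/mtsms.R`) exposes simulate / reconstruct / fit / evaluate over
YAML configurations.

## Known limitations

The headline limitation at desk scale is motion-resolved factor stability:
with 16-28 recovery periods the training tensor's (combination, cardiac,
respiratory) cells are sparsely and unevenly covered, the completion must
extrapolate the rest, and the rendered recovery curves at a fixed motion
state inherit realization-dependent distortion. On a static phantom the
full chain recovers myocardial T1 to ~2% and T2 to ~7%; on the moving
desk-scale phantom the recovered-map accuracy varies strongly with the
phantom realization (best observed ~3.5%/4.4%, worst far outside tolerance,
with the fitted preparation efficiency collapsing and T1/T2 pinning at the
search bounds). The reference acquisition length (73 periods) is designed
to provide that coverage; desk-scale results should therefore be read as
exercising the machinery, not as the method's accuracy. Rendering quality
also varies across motion bins - bins far from the data-dense states rely
more heavily on completion. The completion objective is nonconvex once the
rank-constrained polish is included; results depend mildly on the
regularization path. The phantom's rigid respiratory model makes
translation exactly invertible in k-space, which is kinder than real
through-plane and deformable motion. No arrhythmia rejection is
implemented, and multiband factors other than 3 are out of scope.
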