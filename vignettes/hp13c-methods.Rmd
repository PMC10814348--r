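---
title: "Models and methods behind hp13c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hp13c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hp13c)
```

# Scope

`hp13c` analyzes dynamic hyperpolarized [1-¹³C]pyruvate MRI of the brain: a
bolus of hyperpolarized pyruvate is injected, and a metabolite-selective EPI
readout samples pyruvate, lactate and bicarbonate volumes every 3 s for 60 s.
The biology of interest is the apparent first-order conversion of pyruvate to
lactate (k~PL~, the Warburg axis) and to bicarbonate (k~PB~, oxidative
decarboxylation). Because no public dataset accompanies this class of exam,
the package carries a fully seeded synthetic generator that reproduces the
statistical structure the downstream analysis assumes, and every analysis
stage is tested against that generator or an independent oracle.

This vignette documents the models, the numerical choices, and the places
where a design was genuinely open and we had to pick.

# The forward model

Magnetization in a voxel follows a linear two-site exchange system driven by
a pyruvate input $u(t)$:

$$\frac{dP}{dt} = -\Big(\tfrac{1}{T_{1P}} + k_{PL} + k_{PB}\Big)P + u(t),
\qquad
\frac{dL}{dt} = k_{PL}P - \tfrac{L}{T_{1L}},
\qquad
\frac{dB}{dt} = k_{PB}P - \tfrac{B}{T_{1B}}.$$

At every frame the sequence records $S_X = M_X \sin\alpha_X$ and costs the
longitudinal pool one RF factor $M_X \leftarrow M_X\cos\alpha_X$ per
metabolite, with the flip scheme $(\alpha_{Pyr},\alpha_{Lac},\alpha_{Bic}) =
(20^\circ, 30^\circ, 30^\circ)$. Multi-slice sub-timing is folded into this
single effective per-frame loss because the analysis operates at the 3-s
frame level.

`simulate_two_site()` propagates the system exactly between samples with the
closed-form matrix exponential of the (lower-triangular) generator, holding
the input piecewise-constant on a fine internal grid (0.05 s default). The
propagator is verified against a brute-force `Matrix::expm()` oracle to
1e-8 relative over random parameter draws, and against the conservation
limit $k_{PL}\int P\,dt = L(\infty)$ when relaxation and RF losses are
switched off.

**Parameter choices.** The arterial input is not observed at 3-s resolution,
so the generator uses a gamma-variate bolus
$u(t) \propto ((t-t_0)/\alpha\beta)^{\alpha} e^{\alpha-(t-t_0)/\beta}$ —
the standard unimodal rise/decay — with arrival $t_0 = 4$ s, shape 2.5 and
scale 4 s, placing the pyruvate magnetization peak near 17 s after
injection, typical of adult brain exams. $T_1$ values (pyruvate 30 s,
lactate 25 s, bicarbonate 25 s) are configurable model assumptions; they are rarely measured per subject. Tissue presets put NAWM
(normal-appearing white matter) at k~PL~ = 0.015 s⁻¹ and k~PB~ = 0.003 s⁻¹,
gray matter higher-perfusion/higher-conversion, and the tumor core strongly
Warburg-shifted (k~PL~ = 0.030, k~PB~ = 0.001 s⁻¹).

# The inputless kinetic fit

`fit_inputless()` estimates k~PL~ and k~PB~ without an arterial input
function: the measured flip-corrected pyruvate magnetization
$P_i = S_{P,i}/\sin\alpha_P$ drives discrete product updates

$$M_X(i{+}1) = M_X(i)\cos\alpha_X\,e^{-\Delta t/T_{1X}}
 + k_{PX}\, I_i,$$

and the two rates are fitted jointly by bounded least squares
(bounds [0, 1] s⁻¹, start 0.01 s⁻¹) on the predicted signals
$M_X\sin\alpha_X$. Rate errors are standard errors from the residual
variance and the Gauss–Newton curvature $J^\top J$, reported as a fraction
of the estimate; the ≤ 25% error filter (`threshold_errors()`) keeps the
boundary value.

Two numerical decisions matter here and were settled by experiment:

**The pyruvate integral $I_i$.** A plain trapezoid of the sampled pyruvate,
$\Delta t\,(P_i\cos\alpha_P + P_{i+1})/2$, ignores the product relaxation
inside the 3-s interval and biases both rates low by about
$1 - e^{-\Delta t/2T_{1X}} \approx 5.4\%$ under the default conditions. The
package default instead treats pyruvate as piecewise-linear between samples
and convolves it exactly with the $e^{-(t_{i+1}-\tau)/T_{1X}}$ kernel:
closed form, same inputs, and noiseless round-trip recovery within 0.3%.
The trapezoid remains available (`integral = "trapezoid"`) for comparison
with implementations that use it.

**The initial condition.** By default the product magnetization is assumed
zero at the first frame (`initial = "zero"`), matching the forward-model
convention of starting the exam before conversion has accumulated. The
alternative `initial = "observed"` seeds the products from their first
measured signals. The choice is consequential: the observed-signal variant
is almost perfectly invariant to how much of the pyruvate inflow was
captured (rates move < 0.2% across any simulated acquisition delay), while
the zero variant reproduces the delay sensitivity documented for this class
of analysis — rates overestimated once the rise is missed, errors growing
steeply below ~40% captured inflow. Since characterizing that sensitivity
is one purpose of the package (see the delay sweep), zero initialization is
the default and the robust variant is one argument away.

# Inflow percentage and the delay sweep

`percent_inflow()` implements
$\%\text{Inflow} = \dfrac{\mathrm{Pyr}_{max} - (\mathrm{Pyr}_0 -
\mathrm{Pyr}_{min})}{\mathrm{Pyr}_{max} - \mathrm{Pyr}_{min}} \times 100$,
with $\mathrm{Pyr}_{min}$ read at the last timepoint exactly as specified
(a robustness variant uses the median of the last two frames). Note the
algebra: the statistic is 100% only when the trace starts *and* ends at the
same baseline; a noiseless pre-arrival first frame with a non-zero tail
gives values above 100%, which is expected on synthetic data where the tail
has not decayed into a noise floor.

`simulate_delay_sweep()` emulates longer post-injection delays: natural
cubic splines interpolate the native traces, the sampling grid is shifted
in 0.1-s steps, and the traces are resampled at the native 3-s resolution.
The resampled grid keeps its first sample at the shifted origin and is
truncated to the measured support, so a shift of exactly $k$ frames equals
dropping the first $k$ frames — this anchors the continuous sweep to an
exactly-interpretable special case and is asserted in the tests.
$\mathrm{Pyr}_{min}$ is read at the final native timepoint, which is stable
across sub-frame shifts; at sub-frame resolution the sampled maximum still
wiggles by ~1% as the grid slides over the peak, so monotonicity of
%Inflow is exact over whole-frame shifts and approximate between them.

One documented negative result: with the equal product $T_1$ values used
here, the *delay-relative* inflation of k~PB~ is structurally identical to
k~PL~'s on noiseless traces, and with noise the ordering of the two ratios
is a coin flip (verified over 30 seeds; a shorter bicarbonate $T_1$ even
reverses it). The real fragility of k~PB~ — the reason it degrades first in
practice — is its low SNR, and that is what the package asserts: under
matched noise the relative RMSE of k~PB~ exceeds k~PL~'s, and its
fractional fit error is uniformly larger.

# Multichannel preprocessing

The chain is fixed as prewhiten → combine → phase → denoise, with AUC maps
last; the order relative to phasing is a free choice, and
this order keeps every step's assumptions simple (the denoiser sees
real-valued data with unit noise variance).

* **Noise covariance** is estimated from signal-free samples — pre-arrival
  frames when the acquisition starts before the bolus, otherwise a
  dedicated appended noise frame — and regularized to positive-definite by
  `eps * trace/n` on the diagonal when (e.g. with duplicated channels) the
  sample estimate is singular.
* **Prewhitening** multiplies the channel dimension by $L^{-1}$ from a
  (hand-written, complex) Cholesky factorization $\Sigma = LL^H$; base R's
  `chol()` is real-only. Post-hoc covariance of prewhitened noise is
  identity within Monte-Carlo tolerance.
* **Combination** uses per-voxel conjugate weights from the time-summed
  pyruvate signal, unit-normalized across channels — a matched filter on
  prewhitened data, applied identically to all metabolites. Time-summing
  (rather than a single peak frame) averages noise out of the weights.
* **Phasing** removes the zero-order phase at the pyruvate peak frame and
  keeps the real channel; first-order (frequency) phase is out of scope.
  The per-volume noise SD of the real channel is estimated here from the
  noise frames.
* **AUC maps** sum frames and threshold at SNR strictly > 5, with
  SNR = AUC/(noise_sd·√n) — the standard deviation of a sum of n
  independent frames. The SNR definition is a convention rather than a
  standard; this one is chosen for additivity and is configurable.

## HOSVD denoising

`hosvd_denoise()` factors the (slice, row, col, time, metabolite) tensor by
higher-order SVD and reconstructs from truncated mode factors. Full ranks
reproduce the input to 1e-10. The interesting question is the truncation
rule. A cumulative-energy scree (e.g. "keep 95% of mode energy") looks
innocuous but is degenerate on this data: pyruvate carries the
overwhelming majority of signal energy, so the scree truncates the *time*
and *metabolite* modes to rank 1 — every voxel is forced onto one shared
temporal profile, and all kinetic and hemispheric contrast vanishes (we
observed spatially constant k~PL~ maps and asymmetry scores collapsing to
zero on deliberately lateralized phantoms). The default rule is therefore a
noise-floor criterion: per mode, keep singular values above the
random-matrix noise edge $\sigma(\sqrt{m}+\sqrt{n})$ of the $m \times n$
unfolding, using the pipeline's own noise estimate. This keeps every mode
direction with signal above the noise level regardless of how energy is
distributed, and end-to-end NAWM rate recovery through the full pipeline is
then biased by only ~0.3%. Explicit per-mode ranks and the scree rule
remain available.

# Hemispheric asymmetry

`prepare_map()` applies the map preparation steps: 2× in-plane linear
interpolation, z-normalization over the analysis region, a symmetric brain
mask (brain ∩ mirrored brain), and exclusion of lesion/cavity masks
*together with their midline reflections* so pathology cannot contribute on
either side. The midline is the column-axis center of the brain's in-plane
bounding box on the interpolated grid; reflection is exact on the grid.

`local_asymmetry()` scores each point $p$ of one hemisphere by the minimum
Euclidean distance between feature vectors $[f_{patch}(p);\, w\,
f_{coord}(p)]$ over points $q$ of the other hemisphere, where the patch is
the 3×3 in-plane neighborhood of normalized values and coordinates are
expressed in the mirrored frame, so a perfect mirror pair has distance
exactly zero (left patches are read in mirrored column order for the same
reason). Points whose patch touches excluded or out-of-mask voxels are
skipped. The coordinate weight $w$ is "empirical" in the source algorithm
and never published; the package default is 1.0 in interpolated-voxel
units, it must be held fixed across any comparison, and it is a mandatory
logged config value in the pipeline. The minimum search is same-slice by
default (`cross_slice = TRUE` widens it; it can only lower the minima, at
the cost of an extra $w\cdot$slice coordinate). `global_asymmetry()` is the
arithmetic mean over both hemispheres, also reported per slice; $S = 0$
means perfect left–right correspondence.

The implementation is verified against an exhaustive per-pair brute-force
oracle on maps up to 8×8×2, and the vectorized distance recomputes the
argmin pair directly so mirror-identical data scores an exact zero rather
than accumulated floating error.

# Coverage and acquisition utilities

Prescriptions are oriented boxes (center, orthonormal rotation, extents);
`voxelize()` includes a voxel iff its center lies in the half-open box
(max faces excluded), making Dice deterministic across platforms, and the
default rasterization grid is 1 mm isotropic. `dice()` is
$2|A\cap B|/(|A|+|B|)$. `serial_coverage_harness()` compares an
anatomy-anchored prescription (which follows a simulated change of head
pose, up to a small registration jitter) with a scanner-axis-fixed one
under the same rotation; atlas anchoring wins by construction and the
harness quantifies by how much. `roi_fraction()` block-averages a fine
segmentation into the coarse ¹³C grid for the strict >30% NAWM rule (a
voxel at exactly 30% is excluded; the error filter's 25% boundary is
conversely retained — both follow the printed inequality symbols, as do
the QC gate's bounds, where only the volume is strict).

Frequency utilities implement the two referencing rules
(`f0 = f_urea + 270 Hz`; `f0 = 0.251491899 × f_water`), the phase-encode
voxel bandwidth `1/(matrix × echo-spacing)` (60.562 Hz at the default
protocol), the half-bandwidth pixel-shift flag, and a Gaussian passband
model of the spectral-spatial excitation parameterized by its 130 Hz FWHM —
a model of the pulse, not a measured profile, and replaceable by one.

# Synthetic data: what it does and does not emulate

The generator reproduces: gamma-variate bolus arrival; two-site conversion
at literature-scale rates with per-tissue contrast; the (20°, 30°, 30°)
flip scheme at 3 s × 20 frames; smooth complex coil profiles; correlated
circular complex Gaussian channel noise with signal-free frames for
covariance estimation; mirror-symmetric anatomy with nested NAWM/GM/lesion/
tumor ROIs and an optional lateralized k~PL~ perturbation. Default noise
puts NAWM AUC SNR near 200 for pyruvate, ~47 for lactate and ~9 for
bicarbonate — extensive k~PL~ coverage with marginal bicarbonate, as in
adult brain exams.

It does not emulate: vascular anatomy or a measurable arterial input;
perfusion heterogeneity within a tissue class; B₀ inhomogeneity, EPI
ghosting or k-space effects (image domain only); partial-volume mixing
beyond the voxel grid; or physiological variation between exams. Passing
tests therefore demonstrate correctness of the estimators under their own
model assumptions and realistic SNR, not robustness to every in-vivo
artifact.

Problem sizes are chosen so the full suite runs in well under a minute per
module: 16×16×8 (or 10×10×8) phantoms, 20-frame dynamics, 200-draw Monte
Carlo recovery, 10⁵-sample covariance checks.

# Reproducibility

Every stochastic step takes an explicit seed; `run_pipeline()` is
bit-reproducible for a fixed `pipeline_config()`, and
`scripts/acceptance.R --seed N --out file.json` recomputes the package's
headline numbers from scratch.
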