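---
title: "Methods: steady-state anisotropy imaging and assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state anisotropy imaging and assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisokit)
```

This vignette is the package's own account of its science: the measurement
model, the assay quantification, the forward simulator that stands in for
real data, and the numerical choices made where the conventions of the
field leave room.

## 1. The measurement model

A polarization-resolved microscope splits emission into components
parallel ($I_\parallel$) and perpendicular ($I_\perp$) to the excitation
polarization. For each pixel the steady-state anisotropy is

$$r = \frac{I_\parallel - G\,I_\perp}{I_\parallel + 2\,G\,I_\perp},$$

which is algebraically confined to $[-0.5, 1]$ and, under two-photon
excitation of a slowly rotating fluorophore, physically capped near 0.57.
Three instrument effects stand between raw counts and this formula.

**Detector offset.** Both channels carry an additive background.
`subtract_background()` removes a per-channel scalar or the mean of a
user-marked sensor-free region; pixels driven negative are clamped to zero
and flagged so that no later stage uses them.

**Channel imbalance (G factor).** The two detection paths have unequal
efficiency. With an isotropic, fast-rotating dye the true channel
intensities are equal, so the measured without-plate ratio is
$\rho_0 = G s$ — $G$ the instrumental gain ratio, $s$ any residual
sample/illumination asymmetry — while a half-wave plate that swaps the
polarization entering the two paths gives $\rho_1 = G/s$.
`estimate_g_factor()` returns the geometric mean
$\hat G = \sqrt{\rho_0 \rho_1}$, which cancels $s$ exactly under an ideal
plate. The two-image procedure is standard; the combining rule is this
package's choice, and a warning is raised when the two ratios disagree by
more than 5%, the signature of a non-ideal plate or non-isotropic sample.

**High-NA mixing.** A wide collection cone (half-angle
$\theta = \arcsin(\mathrm{NA}/n)$) tilts the polarization basis of
off-axis rays, mixing the true components into both channels. Integrating
dipole far-field radiation over the cone with the solid-angle weight
$\sin\psi$ gives the detected $x$-polarized intensity of a dipole
$(\mu_x^2, \mu_y^2, \mu_z^2)$ as
$K_b \mu_x^2 + K_c \mu_y^2 + K_a \mu_z^2$ with, for $c = \cos\theta$,

$$K_a = \tfrac{1}{3}(2 - 3c + c^3), \quad
  K_b = \tfrac{1}{4}(5 - 3c - c^2 - c^3), \quad
  K_c = \tfrac{1}{12}(1 - c)^3.$$

For an excitation-symmetric population the out-of-plane weight equals the
in-plane perpendicular weight, so the correction reduces to an invertible
$2\times2$ map on $(I_\parallel, I_\perp)$, normalized by $K_b$ so the
paraxial limit is the identity (`na_mixing_matrix()`,
`apply_na_correction()`). Two conventions were open and are fixed here:
the aperture integral uses the pure solid-angle weight (no aplanatic
apodization factor), and the correction is applied to as-detected channels
by conjugating the inverse mixing with the gain,
$D M^{-1} D^{-1}$ with $D = \mathrm{diag}(1, 1/G)$, because the gain
imbalance arises downstream of the objective. With that ordering the
processing chain inverts the forward model exactly, which the tests verify
to $10^{-9}$. The closed forms are validated against adaptive 2-D
quadrature of the same integrals; they are evaluated via
$d = 1 - c = 2\sin^2(\theta/2)$ because the raw polynomials cancel
catastrophically at small apertures.

**Thresholding.** Quantification keeps pixels whose total intensity
$t = I_\parallel + 2 G I_\perp$ lies inside a configured band, computed on
the combined intensity rather than per channel so a pixel is kept or
dropped in both channels jointly (a per-channel mask would bias $r$).
"Upper and lower fifth percentile of the range of intensity values" is
read literally as 5% of the min–max *range* (default), with the
5th/95th *quantile* interpretation available via
`threshold_mode = "percentile"`.

**Order of operations.** Background subtraction → NA correction →
threshold mask → anisotropy formula (with G inside it). The corrections
are linear, so this order is self-consistent; it is fixed here because
the conventions of the field specify only that corrections precede the
anisotropy calculation. Median filtering (`smooth_for_display()`) exists
for figures only and is never applied before quantification.

## 2. Assay quantification

The transient-oxidation assay runs 0–20 min with the oxidant present from
5 to 10 min (phase bounds 300/600/1200 s), imaged at 10-s intervals at a
fixed depth. Each frame is reduced to its mean anisotropy over valid
pixels (`build_trace()`); whole-islet z-stacks instead pool all valid
pixels from slices with at least 1000 of them (`aggregate_zstack()` —
thin top/bottom slices would otherwise dilute the mean). Traces may be
re-referenced to the 5-min point (`delta_trace()`), which changes no
metric: all four are differences or rates.

`fit_phases()` fits the baseline as a constant, the oxidation phase as
$r(t) = \mathrm{plateau} + A e^{-k_{ox}(t - t_1)}$ and the recovery as
$r(t) = \mathrm{plateau} - B e^{-k_{red}(t - t_2)}$, consistent with
first-order oxidation and re-reduction of the sensed pool. Fits use
Levenberg–Marquardt (`minpack.lm`) with rate starts spanning the phase
duration ($k_0 \in \{8, 2, 0.5, 0.1\}/\mathrm{span}$, best RSS wins),
amplitudes bounded at zero and rates in $[10^{-8}, 100]\ \mathrm{s^{-1}}$.

Metrics (`assay_metrics()`):

* boundary values $r(300)$, $r(600)$, $r(1200)$ are read from the phase
  fits at the boundary times, which is robust to single noisy samples; a
  flag restores literal single-sample differencing;
* half-lives are $\ln 2 / k$ of the fitted exponentials — the time to half
  the asymptotic amplitude, free of 10-s sampling quantization. A
  raw-sample variant (first linearly interpolated crossing of half the
  observed extreme change) is reported alongside in `$raw`, since the
  choice between fitted and raw readings is a genuine open point;
* a half-life is *undefined* (NA) when the amplitude realized inside the
  phase window, $A(1 - e^{-k\,\mathrm{span}})$, is below a noise floor
  defaulting to twice the baseline residual SD. The realized amplitude is
  used because a degenerate flat-phase fit can push $k \to 0$ with an
  arbitrary nominal $A$; the asymptotic amplitude is then meaningless
  while the realized one correctly reads zero.

Truncated recordings are supported (`fit_phases(require_all = FALSE)`,
used by the pipeline): phases with fewer than 3 samples are skipped and
their metrics reported undefined.

## 3. The forward simulator

The simulator exists so that every pipeline stage has ground truth. It
emulates, in order (`simulate_assay()`):

1. **Redox kinetics** (`simulate_kinetics()`): the reduced fraction is
   constant at `nadph_frac0` through the baseline, decays toward 0 with
   rate `k_ox` while the oxidant is present, and relaxes toward
   `equilibrium_frac` with rate `k_red` after washout; continuous at both
   boundaries. Defaults $k_{ox} = \ln 2/60\ \mathrm{s^{-1}}$ and
   $k_{red} = \ln 2/300\ \mathrm{s^{-1}}$ place the depletion and
   recovery half-lives at 60 s and 300 s — fast oxidant action, slower
   metabolic recovery. Saturation (Michaelis–Menten) kinetics are
   deliberately not modeled.
2. **Sensor transfer** (`dimer_fraction()`, `ensemble_anisotropy()`): a
   Hill response $f_d = x^h / (K_{1/2}^h + x^h)$ in the NADP⁺ level $x$
   (pool-fraction units), then intensity-weighted anisotropy additivity
   with dimers twice as bright (two fluorophores),
   $r = w_d r_{dimer} + (1 - w_d) r_{mono}$,
   $w_d = 2 f_d / (1 + f_d)$. Bounds default to $r_{mono} = 0.40$ and
   $r_{dimer} = 0.25$, plausible two-photon values under the 0.57
   ceiling. None of the binding constants are measured quantities; they
   are simulator choices and documented as such.
3. **Depth depolarization** (`apply_depth_scatter()`): a fraction
   $\alpha = 0.005\,\mathrm{\mu m^{-1}} \times \mathrm{depth}$ of detected
   photons is treated as fully scrambled, so $r_{obs} = (1 - \alpha) r$:
   absolute anisotropy declines with depth while the separation of two
   sensor states shrinks by exactly $(1 - \alpha)$. This is the simplest
   model with that qualitative signature; it is not a radiative-transfer
   treatment.
4. **Image formation** (`render_stack()`): an elliptical islet phantom
   with Voronoi cell territories and lognormal per-cell expression
   (`make_phantom()`, default $128 \times 128$ px, 40 cells,
   $\mathrm{sdlog} = 0.4$); expected counts
   $I_\parallel = S(1+2r)/3$, $I_\perp = S(1-r)/3$ with
   $S = 2\times10^4 \times \mathrm{expression}$; forward high-NA mixing at
   NA 1.3 / n 1.518; perpendicular-path efficiency $1/G$ with $G = 1.25$;
   +50 counts offset; Poisson sampling. Read noise is omitted
   (photon-counting detection); so are optical PSF blur and bleaching.

**Why $K_{1/2} = 40$ pool fractions.** The half-saturation default places
the sensor in its weak-saturation, linear-response regime: dimer fraction
— and hence anisotropy — is then approximately proportional to NADP⁺ over
the whole pool range, and the anisotropy trace inherits the pool's
first-order kinetics. This is required for self-consistency: observed
anisotropy responses in this assay are well described by single
exponentials, which cannot coexist with a strongly saturating transfer
(a half-saturation at half the pool would bend the depletion trace enough
to bias a fitted half-life by tens of percent and the recovery fit by far
more). The price is that the simulated assay spans only a few percent of
the full monomer–dimer dynamic range (drops of ~0.006 anisotropy units),
which is also why the default photon budget matters.

**Bit-reproducibility.** Every stochastic entry point takes a seed and
restores the caller's RNG state; identical seeds give identical stacks,
byte for byte, including through TIFF round trips for integer data.

**NADK-style pool expansion.** `pool_scale > 1` grows the total pool
first-order (rate `k_red`) during the recovery phase toward
`pool_scale`, keeping the trace continuous. With the half-saturation
fixed in absolute units, an expanded pool raises absolute NADP⁺ at the
same reduced fraction, producing the negative baseline-change signature
of stress-induced pool expansion. An instantaneous scale change would be
simpler but discontinuous; a static scale would cancel out of the
baseline change entirely.

## 4. What passing tests do and do not show

The test suite validates the pipeline against the simulator: exact formula
fidelity, exact inversion of the forward optics, G recovery to 1% under
Poisson noise at $10^4$ counts/pixel, half-life recovery with median
absolute relative error within 10% across 20 simulated embryos at the
default budget, insensitivity of depletion kinetics to a 10-fold recovery
rate change, flat locked-control traces, and the depth behavior of the
control pair. Problem sizes in the tests ($128\times128$ phantoms, 121
time points, 20 embryos; smaller phantoms where only arithmetic is at
stake) are the package's chosen study conditions.

Passing them shows the *pipeline* is correct for data generated by the
stated measurement model. It does not show that real tissue obeys the
scatter model, that a real sensor's transfer is linear, that detector
read noise is negligible on a given instrument, or anything about which
metabolic pathway drives recovery — those are properties of experiments,
not of this code.

## 5. Known limitations

* Anisotropy maps exported to TIFF are 32-bit float; round trips are exact
  to single precision only (integer acquisition data round-trip bit-exactly).
* The G estimator assumes an ideal half-wave plate; plate retardance error
  appears only as the with/without consistency warning.
* At the default $k_{red}$ the washout phase covers two half-lives, so the
  default simulated assay ends ~25% short of full re-equilibration; the
  fitted recovery plateau absorbs this, but the raw 20-minus-5-min
  baseline change does not read zero even for a fully recovering pool.
* No cell-level segmentation: quantification is per ROI/slice/stack.
* Statistical comparison across treatment groups (t tests, ANOVA, post
  hoc) is out of scope; the metrics tables are designed to feed standard
  routines directly.
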