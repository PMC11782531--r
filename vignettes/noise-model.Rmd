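---
title: "A working noise model for scintillation-coupled CCD detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A working noise model for scintillation-coupled CCD detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdnoise)
```

## The model

A scintillation-coupled CCD camera converts each incident beam electron
into a cascade of photons in a fluorescent layer, guides them through
fiber optics onto a CCD, and digitizes the collected charge per pixel.
`ccdnoise` models the counts $\xi_{i,j}$ of such a detector as

$$
\xi_{i,j} \approx
g\,\mathcal{X}[\bar g]_{i,j}\,\beta\,
\mathcal{P}\!\left[\frac{[\Omega_d \otimes \hat S_{el}]_{i,j}}{\beta}\right]
+ g_c\left(\mathcal{P}[\mu_{therm}]
+ \mathcal{N}[\bar\mu_{read},\,\sigma_{read}^2 + \sigma_{row,j}^2]\right),
$$

with a composite gain $g$ (counts per beam electron), a unit-mean
fixed-pattern gain map $\mathcal{X}[\bar g]$ (quantum-efficiency
variation), the detector point-spread function $\Omega_d$, dark current
accumulating as $\mu_{therm} = I_{dark}\,t_{acq}$, Gaussian read-out
noise, a per-row integer bias fluctuation ("row noise"), and a read-out
offset.  The four detector quadrants have independent ADCs and therefore
independent read/row/offset parameters.

Three ideas do most of the work:

1. **Scaled Poisson statistics.**  Multiplying a Poisson signal by a gain
   $g$ gives the super-Poisson distribution
   $\mathcal{P}_g[\hat S] = g\,\mathcal{P}[\hat S/g]$ with mean $\hat S$
   and variance $g\hat S$ (`dscaled_pois()`, `rscaled_pois()`).  For
   fractional $g$ the analytic expression is a density approximation; we
   evaluate it on the integer count grid and renormalize numerically,
   which is where the residual approximation error goes.  Sampling uses
   the defining construction `g * rpois(n, s/g)` exactly.
2. **Convolution smooths noise.**  Because hundreds of photons spread per
   electron, convolution with $\Omega_d$ correlates neighbouring pixels
   and *reduces* the per-pixel variance by
   $\beta_{conv} = [\Omega_d \otimes \Omega_d]_{0,0} = (\sum \rho_{m,n})^{-1}$
   (`beta_conv()`).  Within a single finite frame the sample variance is
   additionally biased by the correlation factor $\beta_{corr}$ of
   `beta_corr()`, which is 1 for white noise, 0 for total correlation and
   exactly 2 for total anti-correlation.
3. **The Wiener-Khinchin route to the PSF.**  The autocovariance of a flat
   noise image is the inverse FFT of its periodogram
   (`autocovariance_wk()`); normalized to the central element it yields
   the Pearson coefficients $\rho_{m,n}$, and the PSF follows as
   $\Omega = \mathcal{F}^{-1}[(\mathcal{F}[\rho])^{1/2}]$
   (`psf_from_pearson()`).

## Estimator conventions and numerical choices

* **Circular estimation.**  `autocovariance_wk()` is the periodogram
  (circular) estimator, so every synthetic-data oracle in the package
  uses circular convolution.  Lag fields are stored centred with odd
  dimensions $(2M-1)\times(2N-1)$; because the estimator is circular,
  lag $m$ and lag $m - M$ share one estimate and the stored field beyond
  half the frame duplicates mirrored structure.  Operations that fit or
  subtract long-range structure (`fit_beam_correlation()`,
  `detector_psf()`) therefore measure lag distance on the wrapped
  topology.  The estimator's exact identity - the distinct circular
  coefficients of one mean-subtracted frame sum to zero - leaks small
  negative entries into large lags.  This motivates the $K^+$ clipping
  (`clip_negative_field()`) used by `estimate_kref_autocov()` and
  `estimate_smoothed_gain()`; the clipping is applied only where those
  estimators specify it, never silently, and the dark-difference field is
  deliberately left signed because read-out noise carries genuine small
  anti-correlations.  The bias of the circular estimator against the
  unbiased lag estimator is documented here, not corrected.
* **PSF reconstruction.**  Negative Fourier magnitudes (estimator noise)
  are clipped to zero before the square root; the clipped spectral mass
  is recorded and more than 5% escalates to an error in strict mode.
* **Row rounding.**  Row-bias steps are integer-valued in the ADC, so
  `split_row_noise()` rounds per-quadrant row means to the nearest
  integer (ties away from zero).  At a row-mean standard error of about
  0.126 counts the mis-rounding probability per row is
  $\Phi(-0.5/0.126) \approx 3.6\times10^{-5}$.  The decomposition into
  row offsets plus residual is exact by construction.
* **Variance conventions.**  Sample variances carry the $MN/(MN-1)$
  factor; estimators report the $\beta_{corr}$-corrected "true" variance
  whenever a Pearson field is available.
* **Cosmic-ray removal** is a two-pass 5$\sigma$ clip (both sides, since
  subtracted darks carry negative spikes), with the flagged pixel and its
  3x3 neighbourhood replaced by the robust mean.  Two passes suffice at
  realistic contamination; the pass is not iterated to convergence.

## The calibration chain

The gain reference is built from $w$ summed flat/dark pairs
(`build_gain_reference()`); its relative uncertainty is

$$
k_{ref}^2 = \frac{\sum_w \beta g\,\hat S_{ref,c} + 2\sum_w \sigma_d^2}
{(\sum_w \hat S_{ref,c})^2},
$$

(`kref_theoretical()`), measured either from the SD of the difference of
two references (`estimate_kref_difference()`) or from difference-frame
autocovariances (`estimate_kref_autocov()`), which also yields the
reference's Pearson field.  Two scalings in these estimators deserve
emphasis because dimensional analysis, confirmed by parameter recovery,
fixes them uniquely: the autocovariance $k_{ref}$ estimator normalizes
by the *squared* total reference intensity, and the smoothed-gain
formula subtracts the reference field scaled by $\hat S_c^2$ (not
$\hat S_c$) - at reference conditions the $k^2 \hat S_c^2$
fixed-pattern term is ~365 counts$^2$ and any other scaling would bias
$\beta g$ by +3%.  With these conventions
`estimate_smoothed_gain()` recovers $\beta g$ within 2% at the package's
default simulation scale, and the autocovariance and
difference-of-references $k_{ref}$ routes agree to better than 3%.

Read-out and thermal noise separate by regressing single-frame variances
of dark pairs against exposure time (`regress_read_thermal()`): intercept
$2\sigma_{read}^2$, slope $2 g_c I_{dark}$, with row noise removed
first.  Inside the regression the row component is estimated from the
raw per-quadrant row means with the read/thermal contribution
subtracted, which is unbiased at any quadrant width; the integer-rounding
decomposition of `split_row_noise()` is kept as a separate operation
because rounding needs the row-mean standard error well below half a
count (hundreds of columns per quadrant), which small study-size frames
do not provide.  The regression assumes pure linearity in $t$; residual
diagnostics are reported rather than modelling any sub-second
departures.

## Non-linearity and the brighter-fatter effect

The charge well saturates on total accumulated charge, so the
linearization factor
$g_{lin}(\xi) = \xi / (\xi - x_1 - x_2\xi^2 - x_3\xi^3)$ consumes raw,
offset-inclusive counts and is anchored to exactly 1 at the mean signal
of the gain-reference frames (`g_lin()`).  `fit_nonlinearity()` finds
$(x_1, x_2, x_3, \beta g)$ by minimizing the squared departure of the
corrected flat-series variances from the photon-transfer model

$$
\sigma^2_{total} = (1+k^2)\,\beta_{BF}\,\beta g\,\hat S_c
 + k^2 \hat S_c^2 + 2\sigma_{d,corr}^2
$$

(`total_variance_model()`), re-applying the candidate correction to the
gain-reference frames themselves and recomputing $\hat S$, $k$ and
$\sigma_{d,corr}$ per iterate.  The minimizer is a derivative-free
simplex with multiple starts over scaled coefficient axes: the objective
re-runs a pipeline per iterate and gradients are unavailable.  Omitting
the $\beta_{BF}$ term measurably biases the recovered non-linearity,
which is asserted as a regression test.

The brighter-fatter effect is a signal-dependent PSF broadening from
charge diffusion.  `estimate_bf_curve()` tracks the reciprocal of the
nearest-neighbour Pearson coefficient sum against intensity (higher
coefficients are too noisy to include; the 8-neighbourhood is the
default, with the 4-neighbourhood exposed as an option since the exact
window is a matter of convention), normalized to 1 at the reference
intensity, and fits a Pade [4/5] approximation by damped linear least
squares.  `bf_psf_from_beta()` inverts a smoothing factor into a blur
kernel in the *column-summed spectrum domain*: a 2D isotropic reading
would place half of the migrating counts back into the central column,
and only the 1D channel-domain kernel reproduces both the first-order
off-centre mass $(1/\beta_{BF}-1)/2$ and the fitted width
$\sigma_{BF} \approx 0.27$ px at $\beta_{BF} = 0.995$ simultaneously.
The forward simulator, by contrast, cannot use the first-order relation
to choose its blur width: that relation holds for white noise, while the
simulated signal is already PSF-correlated, and on a smoothed signal the
same blur removes an order of magnitude more variance.  The simulator
therefore calibrates its count-conserving blur so that the realized
variance ratio
$\sum(\Omega_d \otimes \omega_{BF})^2 / \sum \Omega_d^2$ equals
$\beta_{BF}(S)$ — the quantity the photon-transfer model actually
multiplies — keeping forward model and estimators consistent.  `bre_linearity_check()` validates a
correction independently on mean-versus-exposure data with bracketed
repeat exposures cancelling beam-current drift.  Two practical notes on
that check: correcting raw (offset-inclusive) means leaves a small
procedural residual of order $0.1\%$ across the range, visible only when
the beam is unrealistically stable, and the bracket interpolation
assumes each exposure's effective beam level sits at its midpoint; the
package's validation series therefore include realistic per-frame
emission jitter, below which both effects disappear.

A precision caveat on the non-linearity fit itself: the joint
$(x_1, x_2, x_3, \beta g)$ minimization is strongly collinear over a
single-decade intensity range, so at the package's problem sizes the
fit pins down $\beta g$ (to about 1%) and the overall photon-transfer
shape, while the posterior on the individual polynomial coefficients
remains broad - tightening $x_2$ to the few-percent level requires
roughly two orders of magnitude more pixels than the desk-scale study
conditions provide (full-frame cameras and hundreds of intensities).
This is a property of the estimator's information content, not of the
implementation, and it is why the BRE check exists as an independent
validation route.

## Binning and EELS

Summing $H\times V$ pixels adds $2w-1$ Pearson coefficients per
direction (`bin_pearson()`); the binned variance multiplier
$\rho^{bin,*}_{0,0}$ propagates the smoothed gain as
$\beta_{H,V} = \beta_1\rho^{bin,*}_{0,0}/(HV)$ and the reference
uncertainty per `binned_kref()`.  Detector noise adds linearly over the
bin except for row noise, which is constant along rows and adds
quadratically in $H$ (`predict_binned_variance()`).  Two readings of the
signal distribution factor $\alpha$ circulate: the literal
$\sum (S/\Sigma S)^2$ (which is $1/(HV)$ for flat signal) and the
bin-size-normalized variant (1 for flat signal).  Closing the variance
model against Monte-Carlo simulation shows the normalized variant is the
one consistent with the binned $k_{ref}$, which already carries the
$1/(HV)$ scaling; `alpha_factor()` exposes both and the prediction
functions take $\alpha$ explicitly.  The EELS model
(`eels_model()`, `eels_variance_model()`) is the $H=1$ special case with
$V$ rows summed per spectral channel, per-channel $\alpha$ from the
vertical ZLP profile, and per-side detector noise summed over the
quadrant pair each channel crosses; the EELS band geometry is
configurable and defaults to a centre band spanning all four quadrants.

## The simulator and what it does (not) emulate

`simulate_frame()` runs the forward chain: Poisson beam electrons,
detector-PSF blur of the *realized* field, fixed-pattern gain, optional
count-conserving brighter-fatter blur, Poisson dark counts, polynomial
distortion of the accumulated charge-well counts (applied before read-out
noise and offset, since saturation is a charge effect and ADC noise is
downstream), and per-quadrant read/row/offset noise.  Row offsets are
drawn as integer-rounded Gaussians - the bias steps are integers in real
hardware, and rounding-based recovery requires integer ground truth - so
the realized offset SD of the 0.6-count nominal parameter is about
0.665 counts and recovery tests compare against the realized SD recorded
in the frame metadata.

Beam correlation deserves a note.  Writing the correlated beam as a
mixture of two *independent* Poisson components cannot reproduce the
$2p(1-p)\,\Omega_{TEM}^*$ cross term that the correlation analysis
measures; the term requires shared randomness between the local and
spread components.  The simulator therefore adds a zero-mean Gaussian
random field with autocovariance
$2p(1-p)\,\mu_{el}\,\Omega_{TEM}^*(r)$ on top of the Poisson field - the
exact correlation structure the estimators target, with unchanged mean,
reducing to pure Poisson statistics at $p = 0$.  `estimate_p()` inverts
the fitted broad amplitude through $A = 2p(1-p)h$ with $h$ the measured
core coefficient sum; this convention is documented and exposed rather
than asserted as unique, and it is validated by forward-inverse recovery
at $p = 0.01$.

One master seed expands deterministically into per-frame, per-stage
streams (`derive_seed()`), so any single frame is reproducible in
isolation, and row bias is drawn independently per read-out.

What the simulator does *not* emulate: electron-trajectory or
optical-photon transport in the scintillator, delayed phosphorescence,
charge-transfer inefficiency beyond the low-signal brighter-fatter
anomaly, position-dependent (non-stationary) covariance, or per-pixel
non-linearity maps (the correction is global by assumption).  Passing
recovery tests on simulated frames therefore demonstrates the internal
consistency of model and estimators, not that a given physical detector
obeys the model; on real data the calibration chain should be validated
with the BRE check and the residual diagnostics the estimators report.

## Default study conditions and problem sizes

The default `detector_model()` emulates a 2k-class TEM camera at desk
scale: 256x256 pixels (2x2 quadrants), Gaussian PSF of FWHM 2.0 px,
smoothed gain $\beta g = 1.55$ counts/electron (the composite gain is
derived from that target and the PSF's $\beta_{conv}$), read noise
4.0 counts, nominal row noise 0.6 counts, offset 252 counts, dark current
1.2 counts/s, fixed-pattern SD 6.7%, and a reference acquisition of 30
flat/dark pairs at about 7050 counts and 0.85 s.  Recovery suites run on
128x128 or 256x256 frames with tens of frames per condition; these sizes
put Monte-Carlo standard errors comfortably below the tolerances being
asserted while keeping the full suite fast on a single core.  The
non-linearity fit uses a 14-point intensity ladder to 45k counts with
three frames per intensity, which is the smallest design we found that
identifies $x_2$ to the asserted accuracy alongside the co-fitted
$x_1, x_3, \beta g$.

## Worked example

```{r, eval = FALSE}
det  <- detector_model()                      # default detector
beam <- flat_beam(det, s_c = 7050, t_acq = 0.85)
stk  <- simulate_flat_stack(det, beam, 30, 30, t_acq = 0.85, seed = 1)
ref  <- build_gain_reference(stk$signal, stk$dark)
ref$k_ref                                     # ~0.0027 at these conditions

sig <- lapply(1:8, function(k) simulate_frame(det, beam, 0.85, 1000 + k))
drk <- lapply(1:10, function(k) simulate_dark(det, 0.85, 2000 + k))
sg  <- estimate_smoothed_gain(Map(dark_subtract, sig, drk[1:8]), ref,
                              list(dark_subtract(drk[[9]], drk[[10]])))
sg$beta_g                                     # recovers beta*g = 1.55 within 2%
```

## Known limitations

* The composite gain cannot be decomposed into fluorescence, fiber and
  CCD layer gains from count data alone; the model exposes only `g` and
  `g_c`.
* Estimated Pearson fields inherit the circular estimator's zero-sum
  bias; all downstream corrections ($K^+$, wrapped-lag fitting) mitigate
  but do not remove it.
* `k_lin`, the residual linearization uncertainty, is defined
  operationally as the binning-independent offset between
  regression-derived and Pearson-reconstructed $k^2$ and is not estimated
  by `fit_nonlinearity()` itself.
* The EELS model is validated against simulated spectra only; real EEL
  spectra add energy drift and jitter that are out of scope here.
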