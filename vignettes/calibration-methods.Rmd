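---
title: "Calibrating multichromatic visual stimulators: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating multichromatic visual stimulators: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimcal)
```

# The problem

LED-based projection stimulators for vision research in mice or zebrafish
must be calibrated in units the photoreceptors care about: the
photoisomerisation rate (P\*/photoreceptor/s) each LED evokes in each opsin
type. `stimcal` implements the complete computational chain from raw
spectrometer readings to those rates, and the downstream design steps that
depend on them — opsin-isolating (silent substitution) stimuli,
gamma-correction lookup tables, spatial-resolution and blanking/aliasing
quantification, and trial-based response statistics for two-photon calcium
recordings.

# Opsin sensitivity templates

Photoreceptor spectral sensitivities are generated from the Govardovskii
et al. (2000) vitamin-A1 pigment template: a main alpha band whose shape is
parameterised by the peak wavelength $\lambda_{max}$, plus a Gaussian
short-wavelength beta band. The beta band matters in practice: it is why a
UV LED cross-activates the mouse M-opsin at all. Curves are
peak-normalised to 1. For UV-shifted pigments ($\lambda_{max}$ near
360 nm) the beta band merges into the alpha band and can pull the discrete
maximum one grid step short of $\lambda_{max}$; we normalise by the global
maximum so the curve invariant (max = 1) always holds, and the value at
$\lambda_{max}$ stays within $10^{-3}$ of 1.

The template coefficients are data (`a1_template_coefficients()`), not
code, so another nomogram family with the same parameterisation can be
swapped in. Default peak wavelengths are literature values — mouse S = 360,
M = 508, rod = 498 nm; zebrafish UV = 365, S = 416, M = 480, L = 570,
rod = 501 nm — and every one of them is overridable
(`species_preset(..., lambda_max_overrides = )`).

# From counts to photoisomerisation rates

The conversion chain is a sequence of per-wavelength operations, each of
which advances an explicit `stage` tag so that units can never silently
mix:

1. counts $\to$ electrical power (nW): divide by the integration time
   $\Delta t$ and multiply by the spectrometer calibration factor
   ($\mu$J/count) and $10^3$;
2. power $\to$ energy flux (eV/s): multiply by $a = 6.242\cdot10^{18}$
   eV/J and $10^{-9}$;
3. energy flux $\to$ photon flux (photons/s): divide by the photon energy
   $Q(\lambda) = c\,h/(\lambda\cdot 10^{-9})$ with
   $c = 299{,}792{,}458$ m/s and $h = 4.135667\cdot10^{-15}$ eV·s;
4. photon flux $\to$ flux density (photons/s/$\mu$m$^2$): divide by the
   stimulus area (a 1000-$\mu$m spot has area $\pi\cdot500^2 \approx
   7.854\cdot10^5\ \mu$m$^2$);
5. flux density $\to$ rate: multiply by the outer-segment collection area
   ($A_{collect} = 0.2\ \mu$m$^2$ for cones) and sum over the wavelength
   grid weighted by the effective activation
   $S_{act}(\lambda) = S_{opsin}(\lambda)\,S_{LED}(\lambda)$.

Two deliberate numerical choices:

* **The summation is a bare sum, not an integral.** The final rate has no
  grid-step factor, so its value depends on the grid resolution. All
  curves therefore live on a fixed default grid of 300–720 nm at 1-nm
  steps (`default_grid()`); comparable numbers require that grid.
* **The weighting switch.** Taken literally, weighting the
  spectrally-resolved flux density (which already carries the LED
  spectrum) by $S_{act} = S_{opsin}\cdot S_{LED}$ counts the LED spectral
  shape twice. Because published calibrations may have done either,
  `photoisomerisation_rate()` exposes `weighting = "as_printed"`
  (the product form, default) and `"opsin_only"` ($S_{opsin}$ alone).
  For narrow-band LEDs the two differ by only a few percent, and every
  qualitative statement in the test suite is required to hold under both.

The scalar *effective activation* reported alongside the rates is defined
as $\sum S_{act} / \sum S_{LED}$ — the LED-weighted mean opsin
sensitivity. For a narrow-band LED it reduces to the opsin sensitivity at
the LED peak. This is a declared convention: it is one natural scalar
summary of the product curve, chosen because of that limit behaviour.

```{r}
leds <- list(
  UV    = synth_led_spectrum(led_model("UV", 387, 11, c(381.5, 392.5), 100)),
  green = synth_led_spectrum(led_model("green", 576, 10, c(571, 581), 100)))
build_activation_matrix(leds, species_preset("mouse")$cone_opsins)
```

# Denoising spectrometer reads

Low-intensity measurements (especially UV) are shot-noise limited. Repeated
reads are averaged first (`average_reads()`), then a four-parameter
Gaussian (amplitude, centre, width, non-negative baseline) is fitted and
evaluated on the grid (`denoise_gaussian()`), with negative fitted values
clipped to zero. The baseline term is included because real spectrometers
have dark offsets; it is reported with the fit so a user can verify it is
small. The fit is by Levenberg–Marquardt least squares with moment-based
starting values; flat or all-zero spectra are rejected rather than fitted.

# Silent substitution

The cross-activation ratio
$S_{crossact} = R_{iso}(\text{cross LED}, \text{opsin}) /
R_{iso}(\text{reference LED}, \text{opsin})$ scales the counterphase
stimulus: for the dichromatic case $I_G = I - I_{UV}\cdot S_{crossact}$.
With the published mouse M-opsin rates (19.5 and 3.8 $\cdot10^3$ P\*/cone/s
for green and UV) this gives $S_{crossact} = 0.195$ and a green amplitude
of 0.805 for a unit stimulus.

The general case (`substitution_solve()`) solves
$R_{iso}^\top w = t$ for per-LED weights $w$ given a desired per-opsin
modulation vector $t$, by QR. With more LEDs than opsins a basic solution
is returned (free weights set to zero); a rank-deficient matrix with an
inconsistent target is an error that reports the per-opsin residuals.
Out-of-gamut weights are flagged, never silently clipped — a stimulus
that cannot be displayed should fail loudly at design time.

# Gamma correction

Measured intensity series (pixel value 0–254 in steps of 2, rate per
level) are fitted with the four-parameter sigmoid
$y = K_0 + K_1/(1+\exp(-(x-K_2)/K_3))$, initialised at
$K_0=\min y$, $K_1=\mathrm{range}(y)$, $K_2$ = half-range crossing,
$K_3=\mathrm{range}(x)/10$. The 256-entry LUT then maps each desired
linear level to the drive value whose fitted intensity matches it, via the
analytic inverse of the sigmoid. A `raw` mode inverts the measured curve
directly by monotone piecewise-linear interpolation; it is the right
choice when the response is not sigmoid-shaped (e.g. a power-law test
curve), and is what the LUT linearisation check uses. Entries are rounded
to the 8-bit drive domain, forced non-decreasing, with endpoints 0 and
255; the quantisation bounds the residual non-linearity at roughly
$\gamma/255$ of range (about 0.9% for $\gamma = 2.2$).

The LUT linearises in whatever unit the intensity series carries
(photoisomerisation rate in the intended workflow); the unit is recorded
in the LUT file metadata, not assumed.

# Spatial resolution

`synth_checkerboard()` renders a binary checkerboard at a given checker
size and sampling pitch and convolves it with a Gaussian of standard
deviation `blur_sigma` (in µm) to emulate optical blur; a per-channel
sigma emulates chromatic defocus. The pattern is padded by the blur
support before convolution and cropped afterwards, so no wrap-around seam
artefacts appear at the image border (with an odd number of checkers per
axis, a circular convolution would see a parity flip there).

Edge sharpness follows the measurement convention: the profile is
rescaled to [0, 1], the position axis is optionally rescaled so the
half-maximum width of the bright checker equals 1 (making different
checker sizes comparable), and the sigmoid above is fitted to the rising
segment between the preceding trough and following peak; $1/K_3$ is the
sharpness. Transitions are located by 50% threshold crossing. Two
degenerate cases are handled explicitly: an instantaneous step (completed
within one sample) cannot constrain $K_3$, so the sharpness is capped at
$2/\Delta x$ and flagged; and because the residual surface has a
step-like local optimum at tiny $K_3$, the fit is run from several $K_3$
starting values and the best residual kept. Both the normalised-axis
sharpness (primary) and the per-µm value are reported, since the
measurement convention does not pin down which axis the published values
used.

`pixel_footprint(feature, scale)` is deliberately in pixels-per-µm: a
5-µm checker at a 1.9 × 0.9 px/µm device scale covers 9.5 × 4.5 device
pixels (note that scan scales are often quoted inverted, as µm/pixel —
pass `1/scale` then).

# Blanking and aliasing

In a scanning two-photon microscope the stimulator LEDs are gated on only
during the scan-line retrace (default 20% of a 1–2 ms line) to separate
stimulation from fluorescence detection. The line clock and the 60-Hz
display frame clock are free-running, so the gated output can beat. The
simulation models an ideal gate (zero rise/fall), a sample-and-hold
stimulus that changes only at frame boundaries, and a photoreceptor
integration stage as a 100-ms box filter (about the integration time of
mouse cones). The modulation depth (max − min)/mean of the smoothed trace
over its central region quantifies the perceived ripple. When the box
width is an exact multiple of the line period the ripple vanishes; the
default simulation sample rate (100 kHz) is chosen so typical line
periods are an integer number of samples and the gate is exactly
periodic. The box filter is a cumulative-sum moving average (O(n),
independent of box width).

# Response statistics

Calcium traces are preprocessed either as FRET ratios
($\Delta R/R$ with $R = F_A/F_D$, baseline $R_0$ = mean ratio over a
caller-specified pre-stimulus window, default the first second — the
baseline definition is a package convention) resampled to 500 Hz, or by
zero-phase high-pass filtering above 0.1 Hz (second-order Butterworth,
forward–backward so detrending does not shift response timing) followed
by z-normalisation over the 1–6 s interval.

Trials are cut at the stimulus markers with a per-ROI sub-frame offset
(scan-line index × line period), keeping alignment within ~2 ms. The
quality index is
$$Q_i = \frac{\mathrm{Var}_t[\langle C\rangle_r]}{\langle\mathrm{Var}_t[C]\rangle_r},$$
1 for perfectly repeatable responses and $\approx 1/R$ for pure noise;
variances use the population convention (the ratio is unchanged under the
sample convention for equal lengths). The default acceptance threshold
$Q_i > 0.3$ is a flag, not a hard filter. Spectral contrast uses the power
(squared DFT magnitude; an amplitude option exists — the sign of SC is
unaffected, the magnitude is) at the bin nearest the 1-Hz fundamental of
the trial-averaged trace, with no windowing — trials are required to span
an integer number of stimulus cycles instead.

The synthetic trial generator (`synth_trials()`) produces sinusoidal
responses whose amplitudes encode a true spectral contrast
($A_G^2 \propto 1+SC$, $A_B^2 \propto 1-SC$) plus i.i.d. Gaussian noise
tuned so the expected $Q_i$ hits a target, via
$Q_i \approx (\sigma_s^2 + \sigma_n^2/R)/(\sigma_s^2+\sigma_n^2)$ with
$\sigma_s^2$ the mean sinusoid variance across the two channels. It is
deterministic under a fixed seed.

# What the synthetic generators do and do not show

The generators emulate the *structure* of real calibration data — band-pass
LED spectra (Gaussian emission hard-clipped by an interference filter),
Poisson shot noise on spectrometer counts, Gaussian optical blur on
checkerboards, sinusoid-plus-Gaussian-noise trial matrices. They do not
emulate LED spectral drift with temperature or drive current, filter
leakage outside the passband, non-Gaussian point-spread functions,
photoreceptor adaptation, or correlated (shared across trials) noise.
Passing tests therefore demonstrate that the computational chain is
correct and self-consistent, not that any particular hardware meets its
specification; published rate values (e.g. the mouse matrix used in the
worked examples) depend on the authors' measured spectra and are used
here as *inputs*, not as quantities this package could re-derive from
first principles.

Problem sizes used in the shipped checks were chosen to exercise each
property at comfortable statistical resolution: trial matrices up to
5000 × 10 samples for the $Q_i$ noise floor, 300-pixel checkerboard
images across checker sizes 2–100 µm, and 1–2 s gating simulations at
100 kHz (with a 1-MHz brute-force cross-check).

# Known limitations

* The rate sum's grid dependence (above) is inherent to the bare-sum
  definition; treat rates computed on other grids as incomparable.
* The effective-activation scalar is one convention among several; only
  the product curve itself is convention-free.
* `substitution_solve()` returns a basic (not minimum-norm) solution in
  the underdetermined case.
* The edge-sharpness cap for instantaneous steps makes the sharpness
  scale with the sampling density in that regime — it is a flag, not a
  measurement.
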