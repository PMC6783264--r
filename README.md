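# stimcal

Spectral and temporal calibration of multichromatic visual stimulators.

Vision researchers working with mice, zebrafish or other non-human species
build their own LED-based projection stimulators, because consumer displays
cannot drive UV-shifted photoreceptors or more than three chromatic
channels. Such a stimulator is only as good as its calibration. `stimcal`
implements the computational side of that calibration for people running
these rigs:

* **photometry** — convert spectrometer readings (counts vs wavelength)
  into per-photoreceptor photoisomerisation rates
  (P\*/photoreceptor/s), via pigment-template sensitivity curves
  (Govardovskii A1 nomogram, species presets for mouse and zebrafish);
* **stimulus design** — quantify cross-activation between LED/opsin
  pairs, compute opsin-isolating *silent substitution* stimuli (scalar
  dichromatic rule and a general linear solver), and build
  gamma-correction lookup tables from measured intensity series;
* **spatial and temporal characterisation** — contrast and
  edge-sharpness (sigmoid rise, 1/K3) analysis of projected
  checkerboards, pixel-footprint arithmetic, and simulation of LED
  gating by the scan-retrace "blanking" signal with perceived-ripple
  estimates after photoreceptor integration;
* **response statistics** — ΔR/R and z-normalised trace preprocessing,
  marker-aligned trial matrices, the repeatability quality index
  Qi = Var_t[mean_r C] / mean_r[Var_t C], and the spectral contrast
  SC = (P_G − P_B)/(P_G + P_B) from response power at the stimulus
  fundamental.

Every module ships a synthetic generator (band-pass LED spectra, blurred
checkerboards, noisy sinusoid-driven trial matrices), so the entire
pipeline can be exercised and tested without hardware.

## The core quantity

For each LED × opsin pair, the photoisomerisation rate is

    R_iso = sum_lambda  P_E(lambda) * A_collect * S_act(lambda)

where `P_E` is the photon flux density (photons/s/µm²) derived from the
measured spectrum through power (nW) → energy flux (eV/s) → photon flux →
flux density, `A_collect = 0.2 µm²` is the cone outer-segment collection
area, and `S_act = S_opsin * S_LED` is the effective activation
(peak-normalised opsin and LED spectra) on a fixed 300–720 nm, 1-nm grid.
The cross-activation ratio of these rates scales the counterphase arm of a
silent-substitution stimulus: `I_G = I − I_UV * S_crossact`.

## Worked example

Cross-activation of the mouse M-opsin from a measured calibration (rates
in P\*/cone/s), and the silent-substitution stimulus that cancels it:

```r
library(stimcal)

am <- activation_matrix(rbind(green = c(S = 0,      M = 19.5e3),
                              UV    = c(S = 19.2e3, M = 3.8e3)))
cross_activation(am, "M", reference_led = "green", cross_led = "UV")
#> <cross_activation> M: UV/green = 0.1949

silent_substitution_dichromatic(1, 1, 0.195)
#> [1] 0.805

substitution_solve(am, c(S = 1, M = 0))
#> <substitution_stimulus>
#>   weights: green=-1.015e-05, UV=5.208e-05
#>   max |residual|: 5.8e-18; feasible: TRUE
```

The UV LED activates M-opsin at 19.5% of the green drive (the opsin's
short-wavelength beta band), so an S-isolating stimulus runs green in
counterphase at that ratio — the general solver recovers exactly the
scalar rule. From modelled band-pass LEDs instead of measured rates:

```r
leds <- list(
  UV    = synth_led_spectrum(led_model("UV", 387, 11, c(381.5, 392.5), 100)),
  green = synth_led_spectrum(led_model("green", 576, 10, c(571, 581), 100)))
build_activation_matrix(leds, species_preset("mouse")$cone_opsins)
#> <activation_matrix> (P*/photoreceptor/s; rows = LEDs)
#>               S      M
#> UV    1.990e+05  79610
#> green 9.751e-04 110800
#> effective activation (fraction):
#>              S     M
#> UV    5.36e-01 0.214
#> green 1.89e-09 0.214
```

The green LED is invisible to the S-opsin (ratio ~1e-9) while the UV LED
drives both — the qualitative pattern that motivates silent substitution.

A thin command-line front end over these functions is installed at
`inst/cli/stimcal.R` (subcommands `synth`, `calibrate`, `lut`,
`substitute`, `spatial`, `timing`, `response`).

See `vignettes/calibration-methods.Rmd` for the models, parameter
conventions and numerical choices.

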