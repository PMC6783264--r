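#' Physical constants used in the photoisomerisation chain
#'
#' Speed of light `c` (m/s), Planck's constant `h` (eV s) and the J-to-eV
#' conversion factor `a`.
#'
#' @return Named list `c`, `h`, `a`.
#' @export
physical_constants <- function() {
  list(c = 299792458, h = 4.135667e-15, a = 6.242e18)
}

#' Stimulus geometry
#'
#' @param spot_diameter Diameter of a circular stimulus spot, um. The
#'   stimulus area is then `pi * (d/2)^2`.
#' @param area Stimulus area in um^2, overriding `spot_diameter`.
#' @return Object of class `stimulus_geometry` with field `a_stim` (um^2).
#' @examples
#' stimulus_geometry(spot_diameter = 1000)$a_stim  # pi * 500^2
#' @export
stimulus_geometry <- function(spot_diameter = NULL, area = NULL) {
  if (is.null(area)) {
    if (is.null(spot_diameter) || spot_diameter <= 0)
      stop("need a positive spot_diameter or area", call. = FALSE)
    area <- pi * (spot_diameter / 2)^2
  }
  if (area <= 0) stop("stimulus area must be positive", call. = FALSE)
  structure(list(spot_diameter = spot_diameter, a_stim = area),
            class = "stimulus_geometry")
}

#' Photoreceptor light-collection optics
#'
#' @param a_collect Outer-segment light collection area, um^2; default 0.2
#'   for cone outer segments.
#' @return Object of class `receptor_optics`.
#' @export
receptor_optics <- function(a_collect = 0.2) {
  if (a_collect <= 0) stop("a_collect must be positive", call. = FALSE)
  structure(list(a_collect = a_collect), class = "receptor_optics")
}

#' Convert electrical power to energy flux
#'
#' `P_eflux(lambda) = P_el(lambda) * a * 1e-9` (nW to eV/s).
#'
#' @param m A [spectral_measurement()] at stage `power_nW`.
#' @param constants See [physical_constants()].
#' @return The measurement at stage `energy_flux_eV_per_s`.
#' @export
power_to_energy_flux <- function(m, constants = physical_constants()) {
  assert_stage(m, "power_nW", "power_to_energy_flux")
  spectral_measurement(m$wavelengths, m$values * constants$a * 1e-9,
                       stage = "energy_flux_eV_per_s",
                       integration_time = m$integration_time,
                       n_reads = m$n_reads, name = m$name)
}

#' Photon energy at a wavelength
#'
#' `P_Q = c * h / (lambda * 1e-9)` in eV, with lambda in nm.
#'
#' @param lambda Wavelength(s), nm, positive.
#' @param constants See [physical_constants()].
#' @return Photon energy in eV.
#' @examples
#' photon_energy(500)  # ~2.4797 eV
#' @export
photon_energy <- function(lambda, constants = physical_constants()) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("photon_energy: lambda must be positive", call. = FALSE)
  constants$c * constants$h / (lambda * 1e-9)
}

#' Convert energy flux to photon flux
#'
#' `P_Phi(lambda) = P_eflux(lambda) / P_Q(lambda)` (photons/s).
#'
#' @param m A [spectral_measurement()] at stage `energy_flux_eV_per_s`.
#' @param constants See [physical_constants()].
#' @return The measurement at stage `photon_flux_per_s`.
#' @export
energy_to_photon_flux <- function(m, constants = physical_constants()) {
  assert_stage(m, "energy_flux_eV_per_s", "energy_to_photon_flux")
  spectral_measurement(m$wavelengths,
                       m$values / photon_energy(m$wavelengths, constants),
                       stage = "photon_flux_per_s",
                       integration_time = m$integration_time,
                       n_reads = m$n_reads, name = m$name)
}

#' Convert photon flux to photon flux density
#'
#' `P_E(lambda) = P_Phi(lambda) / A_stim` (photons/s/um^2).
#'
#' @param m A [spectral_measurement()] at stage `photon_flux_per_s`.
#' @param geom A [stimulus_geometry()].
#' @return The measurement at stage `flux_density_per_s_per_um2`.
#' @export
flux_density <- function(m, geom) {
  assert_stage(m, "photon_flux_per_s", "flux_density")
  stopifnot(inherits(geom, "stimulus_geometry"))
  spectral_measurement(m$wavelengths, m$values / geom$a_stim,
                       stage = "flux_density_per_s_per_um2",
                       integration_time = m$integration_time,
                       n_reads = m$n_reads, name = m$name)
}

#' Run the full power-to-flux-density chain
#'
#' Convenience composition of [power_to_energy_flux()],
#' [energy_to_photon_flux()] and [flux_density()].
#'
#' @param m A [spectral_measurement()] at stage `power_nW`.
#' @param geom A [stimulus_geometry()].
#' @param constants See [physical_constants()].
#' @return The measurement at stage `flux_density_per_s_per_um2`.
#' @export
power_to_flux_density <- function(m, geom, constants = physical_constants()) {
  flux_density(energy_to_photon_flux(power_to_energy_flux(m, constants),
                                     constants), geom)
}

#' Effective activation of an opsin by an LED
#'
#' Computes the product curve `S_act(lambda) = S_opsin(lambda) *
#' S_led(lambda)` with the LED spectrum peak-normalised, and a scalar
#' summary `sum(S_act) / sum(S_led)` — the LED-weighted mean opsin
#' sensitivity, which for a narrow-band LED reduces to the opsin sensitivity
#' at the LED peak. Curves are resampled to the opsin's grid.
#'
#' @param opsin A [sensitivity_curve()].
#' @param led A [spectral_measurement()] (any stage; only the spectral shape
#'   is used).
#' @return List with `curve` (a [sensitivity_curve()] holding `S_act`) and
#'   `fraction` (scalar in \[0, 1\]).
#' @export
effective_activation <- function(opsin, led) {
  stopifnot(inherits(opsin, "sensitivity_curve"),
            inherits(led, "spectral_measurement"))
  grid <- opsin$wavelengths
  s_led <- resample_curve(led$wavelengths, led$values, grid)
  if (max(s_led) <= 0) {
    warning("effective_activation: LED has no power on the opsin grid")
    return(list(curve = sensitivity_curve(grid, rep(0, length(grid))),
                fraction = 0))
  }
  s_led <- s_led / max(s_led)
  s_act <- opsin$sensitivity * s_led
  frac <- sum(s_act) / sum(s_led)
  curve <- sensitivity_curve(grid, s_act,
                             name = paste(opsin$name %||% "opsin", "x",
                                          led$name %||% "led"))
  list(curve = curve, fraction = frac)
}

#' Photoisomerisation rate for one LED/opsin pair
#'
#' Photon flux per receptor is `R_ph(lambda) = P_E(lambda) * A_collect`; the
#' rate is the plain sum over the wavelength grid
#' `R_iso = sum(R_ph(lambda) * S_act(lambda))` in P*/photoreceptor/s. The
#' `weighting` switch selects what stands in for `S_act`: `"as_printed"`
#' weights by the product of opsin sensitivity and peak-normalised LED
#' spectrum (which double-counts the LED spectral shape, since `P_E` already
#' carries it), `"opsin_only"` weights by the opsin sensitivity alone. The
#' sum has no grid-step factor, so rates are grid-step dependent; use the
#' 1-nm [default_grid()] for comparable numbers.
#'
#' @param flux A [spectral_measurement()] at stage
#'   `flux_density_per_s_per_um2`.
#' @param opsin A [sensitivity_curve()] on the same grid.
#' @param optics A [receptor_optics()].
#' @param weighting `"as_printed"` or `"opsin_only"`.
#' @return Rate in P*/photoreceptor/s (scalar).
#' @export
photoisomerisation_rate <- function(flux, opsin, optics = receptor_optics(),
                                    weighting = c("as_printed", "opsin_only")) {
  assert_stage(flux, "flux_density_per_s_per_um2", "photoisomerisation_rate")
  stopifnot(inherits(opsin, "sensitivity_curve"),
            inherits(optics, "receptor_optics"))
  weighting <- match.arg(weighting)
  if (length(flux$wavelengths) != length(opsin$wavelengths) ||
      any(flux$wavelengths != opsin$wavelengths))
    stop("photoisomerisation_rate: flux and opsin grids differ",
         call. = FALSE)
  r_ph <- flux$values * optics$a_collect
  s_act <- if (weighting == "as_printed") {
    mx <- max(flux$values)
    if (mx > 0) opsin$sensitivity * flux$values / mx else flux$values
  } else {
    opsin$sensitivity
  }
  sum(r_ph * s_act)
}

#' Activation matrix over LEDs and opsins
#'
#' Runs the conversion chain for every LED and accumulates
#' photoisomerisation rates (`r_iso`, LED x opsin, P*/photoreceptor/s) and
#' effective-activation fractions.
#'
#' @param leds Named list of [spectral_measurement()] at stage `power_nW`
#'   (e.g. from [synth_led_spectrum()] or [counts_to_power()]).
#' @param opsins Named list of [sensitivity_curve()] on a common grid, e.g.
#'   `species_preset("mouse")$cone_opsins`.
#' @param geom A [stimulus_geometry()].
#' @param optics A [receptor_optics()].
#' @param weighting Passed to [photoisomerisation_rate()].
#' @param constants See [physical_constants()].
#' @return Object of class `activation_matrix` with matrices `r_iso` and
#'   `effective_activation` (rows = LEDs, columns = opsins).
#' @export
build_activation_matrix <- function(leds, opsins,
                                    geom = stimulus_geometry(1000),
                                    optics = receptor_optics(),
                                    weighting = c("as_printed", "opsin_only"),
                                    constants = physical_constants()) {
  weighting <- match.arg(weighting)
  if (length(leds) < 1L || length(opsins) < 1L)
    stop("need at least one LED and one opsin", call. = FALSE)
  led_names <- names(leds)
  if (is.null(led_names))
    led_names <- vapply(leds, function(l) l$name %||% "?", "")
  opsin_names <- names(opsins)
  if (is.null(opsin_names))
    opsin_names <- vapply(opsins, function(o) o$name %||% "?", "")
  grid <- opsins[[1]]$wavelengths
  r_iso <- matrix(NA_real_, length(leds), length(opsins),
                  dimnames = list(led_names, opsin_names))
  eff <- r_iso
  for (i in seq_along(leds)) {
    led <- leds[[i]]
    assert_stage(led, "power_nW", "build_activation_matrix")
    led_g <- spectral_measurement(
      grid, resample_curve(led$wavelengths, led$values, grid),
      stage = "power_nW", integration_time = led$integration_time,
      n_reads = led$n_reads, name = led$name)
    flux <- power_to_flux_density(led_g, geom, constants)
    for (j in seq_along(opsins)) {
      r_iso[i, j] <- photoisomerisation_rate(flux, opsins[[j]], optics,
                                             weighting)
      eff[i, j] <- effective_activation(opsins[[j]], led_g)$fraction
    }
  }
  structure(list(led_names = led_names, opsin_names = opsin_names,
                 r_iso = r_iso, effective_activation = eff,
                 weighting = weighting),
            class = "activation_matrix")
}

#' Construct an activation matrix from known rates
#'
#' For worked examples where photoisomerisation rates are given directly
#' (e.g. from a published calibration) rather than computed from spectra.
#'
#' @param r_iso Numeric matrix, rows = LEDs, columns = opsins, with dimnames.
#' @param effective_activation Optional matching matrix of fractions.
#' @return An `activation_matrix`.
#' @examples
#' m <- activation_matrix(rbind(green = c(S = 0,    M = 19.5e3),
#'                              UV    = c(S = 19.2e3, M = 3.8e3)))
#' cross_activation(m, "M", reference_led = "green", cross_led = "UV")
#' @export
activation_matrix <- function(r_iso, effective_activation = NULL) {
  r_iso <- as.matrix(r_iso)
  if (is.null(rownames(r_iso)) || is.null(colnames(r_iso)))
    stop("r_iso needs LED row names and opsin column names", call. = FALSE)
  if (any(r_iso < 0)) stop("r_iso must be non-negative", call. = FALSE)
  structure(list(led_names = rownames(r_iso), opsin_names = colnames(r_iso),
                 r_iso = r_iso, effective_activation = effective_activation,
                 weighting = NA_character_),
            class = "activation_matrix")
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat("<activation_matrix> (P*/photoreceptor/s; rows = LEDs)\n")
  print(signif(x$r_iso, 4))
  if (!is.null(x$effective_activation)) {
    cat("effective activation (fraction):\n")
    print(signif(x$effective_activation, 3))
  }
  invisible(x)
}

#' Cross-activation of an opsin by an off-target LED
#'
#' The ratio of photoisomerisation rates `r_iso(cross_led, opsin) /
#' r_iso(reference_led, opsin)`, used to scale counterphase stimuli in
#' silent substitution.
#'
#' @param matrix An `activation_matrix`.
#' @param opsin Target opsin name.
#' @param reference_led LED that primarily drives the opsin.
#' @param cross_led LED whose unwanted drive is quantified.
#' @return Object of class `cross_activation` with field `s_cross_act`.
#' @export
cross_activation <- function(matrix, opsin, reference_led, cross_led) {
  stopifnot(inherits(matrix, "activation_matrix"))
  r <- matrix$r_iso
  for (nm in c(reference_led, cross_led))
    if (!nm %in% rownames(r))
      stop("unknown LED: ", nm, call. = FALSE)
  if (!opsin %in% colnames(r)) stop("unknown opsin: ", opsin, call. = FALSE)
  ref <- r[reference_led, opsin]
  if (ref <= 0)
    stop("cross_activation: reference activation is zero", call. = FALSE)
  structure(list(target_opsin = opsin, reference_led = reference_led,
                 cross_led = cross_led,
                 s_cross_act = r[cross_led, opsin] / ref),
            class = "cross_activation")
}

#' @export
print.cross_activation <- function(x, ...) {
  cat(sprintf("<cross_activation> %s: %s/%s = %.4g\n", x$target_opsin,
              x$cross_led, x$reference_led, x$s_cross_act))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
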