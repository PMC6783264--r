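#' Default A1 visual-pigment template coefficients
#'
#' Coefficient set of the Govardovskii et al. (2000) vitamin-A1 pigment
#' template. The alpha band is
#' \deqn{S_\alpha(\lambda) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda} and the peak-position-dependent
#' \eqn{a = a_0 + a_1 \exp(-(\lambda_{max}-300)^2 / a_2)}. The beta band is a
#' Gaussian \eqn{S_\beta(\lambda) = A_\beta \exp(-((\lambda - \lambda_{m\beta})
#' / b_\beta)^2)} with \eqn{\lambda_{m\beta} = \beta_0 + \beta_1
#' \lambda_{max}} and \eqn{b_\beta = \beta_2 + \beta_3 \lambda_{max}}.
#'
#' The coefficients are returned as a plain named list so an alternative
#' template family with the same parameterisation can be swapped in via the
#' `coefficients` argument of [template_sensitivity()].
#'
#' @return Named list of template coefficients.
#' @export
a1_template_coefficients <- function() {
  list(
    A = 69.7, B = 28, C = -14.9, D = 0.674,
    b = 0.922, c = 1.104,
    a0 = 0.8795, a1 = 0.0459, a2 = 11940,
    A_beta = 0.26,
    beta0 = 189, beta1 = 0.315,   # beta-band peak position vs lambda_max
    beta2 = -40.5, beta3 = 0.195  # beta-band bandwidth vs lambda_max
  )
}

#' Construct a spectral sensitivity curve
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param sensitivity Relative sensitivity values (unitless, peak 1).
#' @param name Optional opsin label.
#' @param lambda_max Optional nominal peak wavelength (nm).
#' @return An object of class `sensitivity_curve`.
#' @export
sensitivity_curve <- function(wavelengths, sensitivity, name = NULL,
                              lambda_max = NULL) {
  wavelengths <- as.numeric(wavelengths)
  sensitivity <- as.numeric(sensitivity)
  if (length(wavelengths) == 0L)
    stop("empty wavelength grid", call. = FALSE)
  if (length(wavelengths) != length(sensitivity))
    stop("wavelengths and sensitivity must have the same length", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(sensitivity)) || any(sensitivity < 0))
    stop("sensitivity must be finite and non-negative", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, sensitivity = sensitivity,
         name = name, lambda_max = lambda_max),
    class = "sensitivity_curve"
  )
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat("<sensitivity_curve>",
      if (!is.null(x$name)) paste0(" ", x$name) else "", "\n", sep = "")
  cat(sprintf("  grid: %g-%g nm (%d points)\n",
              min(x$wavelengths), max(x$wavelengths), length(x$wavelengths)))
  if (!is.null(x$lambda_max))
    cat(sprintf("  lambda_max: %g nm\n", x$lambda_max))
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  graphics::plot(x$wavelengths, x$sensitivity, type = "l",
                 xlab = "wavelength (nm)", ylab = "relative sensitivity",
                 main = x$name, ...)
  invisible(x)
}

#' Pigment-template spectral sensitivity from lambda_max
#'
#' Evaluates an A1 visual-pigment nomogram template (alpha band plus optional
#' short-wavelength beta band) at the given peak wavelength and peak-normalises
#' the result so the maximum on the grid equals 1.
#'
#' @param lambda_max Peak wavelength of the pigment alpha band, nm; must lie
#'   in \[300, 650\].
#' @param grid Strictly increasing wavelength grid in nm within \[300, 800\].
#'   Defaults to 300-720 nm at 1-nm steps, the grid used throughout the
#'   calibration chain.
#' @param include_beta_band Include the Gaussian beta band? The beta band adds
#'   short-wavelength sensitivity (e.g. UV cross-activation of an M pigment).
#' @param coefficients Template coefficient list, see
#'   [a1_template_coefficients()].
#' @param name Optional label stored on the curve.
#' @return A [sensitivity_curve()].
#' @examples
#' s <- template_sensitivity(508)
#' s$wavelengths[which.max(s$sensitivity)]
#' @export
template_sensitivity <- function(lambda_max, grid = default_grid(),
                                 include_beta_band = TRUE,
                                 coefficients = a1_template_coefficients(),
                                 name = NULL) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      !is.finite(lambda_max) || lambda_max < 300 || lambda_max > 650)
    stop("lambda_max must be a single value in [300, 650] nm", call. = FALSE)
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty wavelength grid", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  if (min(grid) < 300 || max(grid) > 800)
    stop("grid must lie within [300, 800] nm", call. = FALSE)
  k <- coefficients

  x <- lambda_max / grid
  a <- k$a0 + k$a1 * exp(-(lambda_max - 300)^2 / k$a2)
  alpha <- 1 / (exp(k$A * (a - x)) + exp(k$B * (k$b - x)) +
                  exp(k$C * (k$c - x)) + k$D)
  s <- alpha
  if (include_beta_band) {
    lm_beta <- k$beta0 + k$beta1 * lambda_max
    b_beta <- k$beta2 + k$beta3 * lambda_max
    s <- s + k$A_beta * exp(-((grid - lm_beta) / b_beta)^2)
  }
  s <- s / max(s)
  sensitivity_curve(grid, s, name = name, lambda_max = lambda_max)
}

#' Default wavelength grid
#'
#' 300-720 nm at 1-nm steps. All curves and spectra are resampled to this
#' grid before the photoisomerisation sum, which is a plain (unit-step)
#' Riemann sum; rates computed on other grid steps are not comparable.
#'
#' @param step Grid step in nm.
#' @return Numeric wavelength vector.
#' @export
default_grid <- function(step = 1) seq(300, 720, by = step)

# built-in lambda_max defaults (nm); literature values, overridable
.species_table <- list(
  mouse = list(
    cones = c(S = 360, M = 508),
    rod = c(rod = 498)
  ),
  zebrafish = list(
    cones = c(UV = 365, S = 416, M = 480, L = 570),
    rod = c(rod = 501)
  )
)

#' Species opsin presets
#'
#' Returns the full set of cone-opsin and rod sensitivity curves for a
#' supported species, generated from the pigment template. Default peak
#' wavelengths: mouse S = 360, M = 508, rod = 498 nm; zebrafish UV = 365,
#' S = 416, M = 480, L = 570, rod = 501 nm. All defaults can be overridden.
#'
#' @param species `"mouse"` or `"zebrafish"`.
#' @param grid Wavelength grid (nm), see [default_grid()].
#' @param lambda_max_overrides Named numeric vector overriding individual
#'   opsin peak wavelengths, e.g. `c(M = 511)`.
#' @param include_beta_band Include the beta band in every template.
#' @return A list of class `species_preset` with elements `species`,
#'   `cone_opsins` (named list of [sensitivity_curve()]) and `rod_opsin`.
#' @examples
#' p <- species_preset("mouse")
#' names(p$cone_opsins)
#' @export
species_preset <- function(species, grid = default_grid(),
                           lambda_max_overrides = NULL,
                           include_beta_band = TRUE) {
  if (!is.character(species) || length(species) != 1L ||
      !species %in% names(.species_table))
    stop(sprintf("unknown species '%s'; supported: %s",
                 as.character(species)[1],
                 paste(names(.species_table), collapse = ", ")),
         call. = FALSE)
  tab <- .species_table[[species]]
  lmax <- c(tab$cones, tab$rod)
  if (!is.null(lambda_max_overrides)) {
    bad <- setdiff(names(lambda_max_overrides), names(lmax))
    if (length(bad))
      stop("unknown opsin in overrides: ", paste(bad, collapse = ", "),
           call. = FALSE)
    lmax[names(lambda_max_overrides)] <- lambda_max_overrides
  }
  curves <- lapply(names(lmax), function(nm) {
    template_sensitivity(lmax[[nm]], grid = grid,
                         include_beta_band = include_beta_band, name = nm)
  })
  names(curves) <- names(lmax)
  structure(
    list(species = species,
         cone_opsins = curves[names(tab$cones)],
         rod_opsin = curves[[names(tab$rod)]]),
    class = "species_preset"
  )
}

#' @export
print.species_preset <- function(x, ...) {
  cat("<species_preset> ", x$species, "\n", sep = "")
  cat("  cones:", paste(sprintf("%s (%g nm)", names(x$cone_opsins),
                                vapply(x$cone_opsins, `[[`, 0, "lambda_max")),
                        collapse = ", "), "\n")
  cat(sprintf("  rod: %g nm\n", x$rod_opsin$lambda_max))
  invisible(x)
}

#' Read a species preset file
#'
#' Plain `key: value` text (YAML subset) with fields `species`, and one
#' `opsins:` block mapping opsin name to peak wavelength, plus optional
#' `rod:` name and `beta_band:` flag.
#'
#' @param path Path to the preset file.
#' @param grid Wavelength grid.
#' @return A `species_preset`.
#' @export
read_preset <- function(path, grid = default_grid()) {
  y <- yaml::read_yaml(path)
  if (is.null(y$species) || is.null(y$opsins))
    stop("preset file must define 'species' and 'opsins'", call. = FALSE)
  beta <- if (is.null(y$beta_band)) TRUE else isTRUE(y$beta_band)
  rod_name <- if (is.null(y$rod)) "rod" else y$rod
  lmax <- unlist(y$opsins)
  curves <- lapply(names(lmax), function(nm)
    template_sensitivity(lmax[[nm]], grid = grid,
                         include_beta_band = beta, name = nm))
  names(curves) <- names(lmax)
  cones <- curves[setdiff(names(curves), rod_name)]
  structure(
    list(species = y$species, cone_opsins = cones,
         rod_opsin = curves[[rod_name]]),
    class = "species_preset"
  )
}

#' Write a sensitivity curve as a two-column text table
#'
#' @param x A [sensitivity_curve()].
#' @param path Output path; tab-separated `wavelength_nm sensitivity` with a
#'   `#` comment header.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(x, path) {
  stopifnot(inherits(x, "sensitivity_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sensitivity curve%s",
                     if (!is.null(x$name)) paste0(": ", x$name) else ""), con)
  writeLines("wavelength_nm\tsensitivity", con)
  utils::write.table(
    data.frame(x$wavelengths, signif(x$sensitivity, 8)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# linear resample of a curve to a new grid; zero outside support
resample_curve <- function(wavelengths, values, grid) {
  out <- stats::approx(wavelengths, values, xout = grid, rule = 1)$y
  out[is.na(out)] <- 0
  out
}
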