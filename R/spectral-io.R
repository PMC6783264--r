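#' Spectral measurement container
#'
#' A wavelength-resolved measurement tagged with its processing stage. Stages
#' advance only through the conversion chain:
#' `counts` -> `power_nW` ([counts_to_power()]) -> `energy_flux_eV_per_s`
#' ([power_to_energy_flux()]) -> `photon_flux_per_s`
#' ([energy_to_photon_flux()]) -> `flux_density_per_s_per_um2`
#' ([flux_density()]).
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param values Per-wavelength quantity (non-negative).
#' @param stage One of `counts`, `counts_per_s`, `power_nW`,
#'   `energy_flux_eV_per_s`, `photon_flux_per_s`,
#'   `flux_density_per_s_per_um2`.
#' @param integration_time Spectrometer integration time, s.
#' @param n_reads Number of averaged reads.
#' @param name Optional label (e.g. LED name).
#' @return An object of class `spectral_measurement`.
#' @export
spectral_measurement <- function(wavelengths, values, stage = "counts",
                                 integration_time = 1, n_reads = 1,
                                 name = NULL) {
  stages <- c("counts", "counts_per_s", "power_nW", "energy_flux_eV_per_s",
              "photon_flux_per_s", "flux_density_per_s_per_um2")
  stage <- match.arg(stage, stages)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values must have the same length", call. = FALSE)
  if (length(wavelengths) == 0L) stop("empty spectrum", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, values = values, stage = stage,
         integration_time = integration_time, n_reads = n_reads, name = name),
    class = "spectral_measurement"
  )
}

#' @export
print.spectral_measurement <- function(x, ...) {
  cat("<spectral_measurement>",
      if (!is.null(x$name)) paste0(" ", x$name) else "", "\n", sep = "")
  cat(sprintf("  stage: %s\n  grid: %g-%g nm (%d points)\n",
              x$stage, min(x$wavelengths), max(x$wavelengths),
              length(x$wavelengths)))
  cat(sprintf("  integration: %g s x %d read(s)\n",
              x$integration_time, x$n_reads))
  invisible(x)
}

assert_stage <- function(m, expected, op) {
  if (!inherits(m, "spectral_measurement"))
    stop(op, ": input must be a spectral_measurement", call. = FALSE)
  if (!m$stage %in% expected)
    stop(sprintf("%s: expected stage %s but got '%s'", op,
                 paste(sQuote(expected), collapse = " or "), m$stage),
         call. = FALSE)
  invisible(m)
}

#' Read a two-column spectrum file
#'
#' Parses `wavelength, value` text tables. Comment lines start with `#`; the
#' first non-comment line may be a textual header; the separator is
#' auto-detected among comma, tab and whitespace.
#'
#' @param path Path to the file.
#' @param integration_time Integration time in s recorded on the result.
#' @param n_reads Number of reads averaged into the file.
#' @param stage Stage tag of the stored values (default `counts`).
#' @param name Optional label.
#' @return A [spectral_measurement()].
#' @export
read_spectrum <- function(path, integration_time = 1, n_reads = 1,
                          stage = "counts", name = NULL) {
  tab <- read_two_column(path)
  if (any(diff(tab$x) <= 0)) {
    i <- which(diff(tab$x) <= 0)[1]
    stop(sprintf("%s: wavelengths not strictly increasing at data row %d",
                 path, i + 1L), call. = FALSE)
  }
  spectral_measurement(tab$x, tab$y, stage = stage,
                       integration_time = integration_time,
                       n_reads = n_reads, name = name)
}

# shared two-column dialect parser: '#' comments, optional header line,
# separator among comma/tab/whitespace
read_two_column <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(path, ": no data lines", call. = FALSE)
  split_line <- function(l) {
    if (grepl(",", l)) strsplit(trimws(l), "\\s*,\\s*")[[1]]
    else strsplit(trimws(l), "[\t ]+")[[1]]
  }
  first <- suppressWarnings(as.numeric(split_line(lines[1])))
  start <- if (any(is.na(first))) 2L else 1L  # header line
  if (start > length(lines))
    stop(path, ": no numeric data", call. = FALSE)
  parsed <- lapply(seq(start, length(lines)), function(i) {
    v <- suppressWarnings(as.numeric(split_line(lines[i])))
    if (length(v) < 2L || any(is.na(v[1:2])))
      stop(sprintf("%s: non-numeric data at line %d", path, i), call. = FALSE)
    v[1:2]
  })
  m <- do.call(rbind, parsed)
  list(x = m[, 1], y = m[, 2])
}

#' Write a spectrum as a two-column text table
#'
#' Same dialect as [read_spectrum()] expects; metadata goes into `#` comments.
#'
#' @param m A [spectral_measurement()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(m, path) {
  stopifnot(inherits(m, "spectral_measurement"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# stage: %s", m$stage),
    sprintf("# integration_time_s: %g", m$integration_time),
    sprintf("# n_reads: %d", as.integer(m$n_reads)),
    "wavelength_nm\tvalue"), con)
  utils::write.table(data.frame(m$wavelengths, m$values), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average repeated spectrometer reads
#'
#' Reads are averaged sample-wise before any denoising, so shot noise is
#' reduced by \eqn{\sqrt{n}} ahead of the Gaussian fit.
#'
#' @param reads List of [spectral_measurement()] on identical grids and stage.
#' @return A single [spectral_measurement()] with `n_reads` set to the total.
#' @export
average_reads <- function(reads) {
  stopifnot(length(reads) >= 1L)
  w <- reads[[1]]$wavelengths
  for (r in reads) {
    assert_stage(r, reads[[1]]$stage, "average_reads")
    if (!isTRUE(all.equal(r$wavelengths, w)))
      stop("average_reads: grids differ", call. = FALSE)
  }
  vals <- rowMeans(vapply(reads, `[[`, numeric(length(w)), "values"))
  spectral_measurement(w, vals, stage = reads[[1]]$stage,
                       integration_time = reads[[1]]$integration_time,
                       n_reads = sum(vapply(reads, `[[`, 0, "n_reads")),
                       name = reads[[1]]$name)
}

#' Remove shot noise by fitting a Gaussian
#'
#' Fits `baseline + amp * exp(-(lambda - centre)^2 / (2 sigma^2))` to a
#' single-peaked spectrum by nonlinear least squares and returns the fitted
#' curve evaluated on the grid, with negative values clipped to zero. The
#' baseline term is constrained non-negative.
#'
#' @param m A [spectral_measurement()] at stage `counts` or `counts_per_s`.
#' @return The denoised measurement; fit parameters in attribute `fit`
#'   (`amp`, `centre`, `sigma`, `baseline`).
#' @export
denoise_gaussian <- function(m) {
  assert_stage(m, c("counts", "counts_per_s"), "denoise_gaussian")
  y <- m$values
  w <- m$wavelengths
  if (max(y) <= 0 || stats::sd(y) == 0)
    stop("denoise_gaussian: flat or empty spectrum, nothing to fit",
         call. = FALSE)
  i0 <- which.max(y)
  amp0 <- max(y) - min(y)
  centre0 <- w[i0]
  # moment-based width guess over the above-half-max region
  above <- which(y >= min(y) + amp0 / 2)
  sigma0 <- max(diff(range(w[above])) / 2.355, mean(diff(w)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ base + amp * exp(-(w - centre)^2 / (2 * sigma^2)),
      data = list(y = y, w = w),
      start = list(base = max(min(y), 0), amp = amp0,
                   centre = centre0, sigma = sigma0),
      lower = c(base = 0, amp = 0, centre = min(w), sigma = mean(diff(w)) / 10),
      upper = c(base = max(y), amp = Inf, centre = max(w),
                sigma = diff(range(w))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("denoise_gaussian: fit failed (", conditionMessage(e), ")",
           call. = FALSE))
  p <- as.list(stats::coef(fit))
  vals <- pmax(p$base + p$amp * exp(-(w - p$centre)^2 / (2 * p$sigma^2)), 0)
  out <- spectral_measurement(w, vals, stage = m$stage,
                              integration_time = m$integration_time,
                              n_reads = m$n_reads, name = m$name)
  attr(out, "fit") <- list(amp = p$amp, centre = p$centre, sigma = p$sigma,
                           baseline = p$base,
                           rss = sum(stats::resid(fit)^2))
  out
}

#' Spectrometer calibration table
#'
#' @param wavelengths Wavelength grid (nm).
#' @param factor Calibration factor, uJ/count, strictly positive.
#' @return Object of class `spectrometer_calibration`.
#' @export
spectrometer_calibration <- function(wavelengths, factor) {
  wavelengths <- as.numeric(wavelengths)
  factor <- as.numeric(factor)
  if (length(wavelengths) != length(factor))
    stop("wavelengths and factor must have the same length", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(factor)) || any(factor <= 0))
    stop("calibration factor must be positive everywhere", call. = FALSE)
  structure(list(wavelengths = wavelengths, factor = factor),
            class = "spectrometer_calibration")
}

#' Read a spectrometer calibration file
#'
#' Two-column text table (`wavelength_nm`, `uJ_per_count`), same dialect as
#' [read_spectrum()].
#'
#' @param path Path to the file.
#' @return A [spectrometer_calibration()].
#' @export
read_calibration <- function(path) {
  tab <- read_two_column(path)
  spectrometer_calibration(tab$x, tab$y)
}

#' Convert spectrometer counts to electrical power
#'
#' Counts are divided by the integration time and multiplied by the
#' per-wavelength calibration factor (uJ/count) and 10^3, yielding power in
#' nW: `P_el(lambda) = counts(lambda) / dt * S_cal(lambda) * 1e3`.
#' Calibration factors are linearly interpolated to the measurement grid;
#' extrapolation beyond the calibrated range is an error.
#'
#' @param m A [spectral_measurement()] at stage `counts`.
#' @param cal A [spectrometer_calibration()] covering `m`'s grid.
#' @return The measurement at stage `power_nW`.
#' @export
counts_to_power <- function(m, cal) {
  assert_stage(m, "counts", "counts_to_power")
  stopifnot(inherits(cal, "spectrometer_calibration"))
  if (min(m$wavelengths) < min(cal$wavelengths) ||
      max(m$wavelengths) > max(cal$wavelengths))
    stop("counts_to_power: calibration does not cover the measurement range",
         call. = FALSE)
  f <- stats::approx(cal$wavelengths, cal$factor, xout = m$wavelengths,
                     rule = 1)$y
  vals <- m$values / m$integration_time * f * 1e3
  spectral_measurement(m$wavelengths, vals, stage = "power_nW",
                       integration_time = m$integration_time,
                       n_reads = m$n_reads, name = m$name)
}

#' Band-pass-filtered LED model
#'
#' Describes an LED/interference-filter combination as a Gaussian emission
#' profile hard-clipped by the filter passband, e.g. the 576/10 green and
#' 387/11 UV combinations of a dichromatic mouse stimulator.
#'
#' @param name LED label.
#' @param peak Emission peak, nm.
#' @param fwhm Full width at half maximum of the emission Gaussian, nm.
#' @param passband Length-2 numeric, filter passband `(low, high)` in nm with
#'   `low < peak < high`.
#' @param peak_power Power at the emission peak, nW.
#' @return Object of class `led_model`.
#' @export
led_model <- function(name, peak, fwhm, passband, peak_power = 1) {
  stopifnot(length(passband) == 2L)
  if (!(passband[1] < peak && peak < passband[2]))
    stop("led_model: passband must bracket the peak", call. = FALSE)
  if (fwhm <= 0) stop("led_model: fwhm must be positive", call. = FALSE)
  structure(list(name = name, peak = peak, fwhm = fwhm,
                 passband = as.numeric(passband), peak_power = peak_power),
            class = "led_model")
}

#' Synthesise a band-pass LED spectrum
#'
#' Evaluates the [led_model()] Gaussian on the grid, clips it to zero outside
#' the filter passband and scales it so the maximum equals `peak_power`.
#' The result is tagged `power_nW`, ready for the photoisomerisation chain.
#'
#' @param led An [led_model()].
#' @param grid Wavelength grid (nm) covering the passband.
#' @return A [spectral_measurement()] at stage `power_nW`.
#' @examples
#' uv <- synth_led_spectrum(led_model("UV", 387, 11, c(381.5, 392.5), 100))
#' range(uv$wavelengths[uv$values > 0])
#' @export
synth_led_spectrum <- function(led, grid = default_grid()) {
  stopifnot(inherits(led, "led_model"))
  grid <- as.numeric(grid)
  if (min(grid) > led$passband[1] || max(grid) < led$passband[2])
    stop("synth_led_spectrum: grid does not cover the passband", call. = FALSE)
  sigma <- led$fwhm / (2 * sqrt(2 * log(2)))
  vals <- exp(-(grid - led$peak)^2 / (2 * sigma^2))
  vals[grid < led$passband[1] | grid > led$passband[2]] <- 0
  if (max(vals) > 0) vals <- vals / max(vals) * led$peak_power
  spectral_measurement(grid, vals, stage = "power_nW", name = led$name)
}
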