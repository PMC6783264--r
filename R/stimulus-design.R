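#' Measured LED intensity series
#'
#' Pairs display pixel values (8-bit domain) with the measured intensity
#' (typically the photoisomerisation rate) at each level.
#'
#' @param pixel_values Strictly increasing display levels in \[0, 255\].
#' @param r_iso Measured intensity per level, non-negative.
#' @param led_name LED label.
#' @return Object of class `intensity_series`.
#' @export
intensity_series <- function(pixel_values, r_iso, led_name = NULL) {
  pixel_values <- as.numeric(pixel_values)
  r_iso <- as.numeric(r_iso)
  if (length(pixel_values) != length(r_iso))
    stop("pixel_values and r_iso must have the same length", call. = FALSE)
  if (any(diff(pixel_values) <= 0))
    stop("pixel_values must be strictly increasing", call. = FALSE)
  if (any(pixel_values < 0 | pixel_values > 255))
    stop("pixel_values must lie in [0, 255]", call. = FALSE)
  if (any(!is.finite(r_iso)) || any(r_iso < 0))
    stop("r_iso must be finite and non-negative", call. = FALSE)
  structure(list(led_name = led_name, pixel_values = pixel_values,
                 r_iso = r_iso),
            class = "intensity_series")
}

#' Fit a sigmoid intensity curve
#'
#' Least-squares fit of `y = K0 + K1 / (1 + exp(-(x - K2) / K3))` through
#' the (pixel value, intensity) points. Initialisation: `K0 = min(y)`,
#' `K1 = range(y)`, `K2 = x` at half range, `K3 = range(x) / 10`, with
#' `K3 > 0` enforced. Monotone-decreasing data are rejected; near-linear
#' data fit with a large `K3` and a warning.
#'
#' @param series An [intensity_series()] with at least 8 points.
#' @return Object of class `gamma_fit` with fields `k0`, `k1`, `k2`, `k3`,
#'   `residual` (RMS) and the data range fitted.
#' @export
fit_intensity_curve <- function(series) {
  stopifnot(inherits(series, "intensity_series"))
  x <- series$pixel_values
  y <- series$r_iso
  if (length(x) < 8L)
    stop("fit_intensity_curve: need at least 8 points", call. = FALSE)
  if (stats::cor(x, y) < 0)
    stop("fit_intensity_curve: intensity decreases with pixel value; ",
         "rising sigmoid (K1 > 0) cannot fit", call. = FALSE)
  k0_0 <- min(y)
  k1_0 <- diff(range(y))
  k2_0 <- x[which.min(abs(y - (min(y) + k1_0 / 2)))]
  k3_0 <- diff(range(x)) / 10
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ k0 + k1 / (1 + exp(-(x - k2) / k3)),
      data = list(x = x, y = y),
      start = list(k0 = k0_0, k1 = k1_0, k2 = k2_0, k3 = k3_0),
      lower = c(k0 = -Inf, k1 = 0, k2 = -Inf, k3 = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(sprintf(
        "fit_intensity_curve: fit failed (%s); starts were K0=%g K1=%g K2=%g K3=%g",
        conditionMessage(e), k0_0, k1_0, k2_0, k3_0), call. = FALSE))
  p <- as.list(stats::coef(fit))
  if (p$k3 > 2 * diff(range(x)))
    warning("fit_intensity_curve: K3 much larger than the pixel range; ",
            "curve is near-linear and the sigmoid is weakly identified")
  structure(list(k0 = p$k0, k1 = p$k1, k2 = p$k2, k3 = p$k3,
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 x_range = range(x), led_name = series$led_name),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "<gamma_fit>%s K0=%.4g K1=%.4g K2=%.4g K3=%.4g (rms %.3g)\n",
    if (!is.null(x$led_name)) paste0(" ", x$led_name) else "",
    x$k0, x$k1, x$k2, x$k3, x$residual))
  invisible(x)
}

#' @export
predict.gamma_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) seq(object$x_range[1], object$x_range[2])
       else if (is.list(newdata)) newdata$x else newdata
  object$k0 + object$k1 / (1 + exp(-(x - object$k2) / object$k3))
}

#' Build a gamma-correction lookup table
#'
#' Computes the 256-entry display-value to drive-value table that
#' linearises an LED's intensity response: entry `v` is the drive level
#' whose intensity equals `min + (v/255) * (max - min)` of the measured
#' (or fitted) intensity range. Given a [fit_intensity_curve()] result the
#' sigmoid is inverted analytically; given an [intensity_series()] the
#' measured curve is inverted by monotone piecewise-linear interpolation
#' (the "raw" mode). Entries are rounded to the 8-bit drive domain and are
#' non-decreasing with endpoints 0 and 255.
#'
#' @param x A `gamma_fit` or an `intensity_series`.
#' @param ... Unused.
#' @return Object of class `lut` with integer `entries` (length 256,
#'   indexed by desired level 0-255).
#' @export
build_lut <- function(x, ...) UseMethod("build_lut")

#' @rdname build_lut
#' @export
build_lut.gamma_fit <- function(x, ...) {
  f0 <- predict(x, 0)
  f255 <- predict(x, 255)
  if (f255 <= f0)
    stop("build_lut: fitted curve is not increasing over [0, 255]",
         call. = FALSE)
  targets <- f0 + (0:255) / 255 * (f255 - f0)
  # analytic inverse of the sigmoid, clipped to the drive domain
  arg <- x$k1 / (targets - x$k0) - 1
  drive <- ifelse(arg > 0, x$k2 - x$k3 * log(arg), 255)
  drive <- pmin(pmax(drive, 0), 255)
  new_lut(drive, led_name = x$led_name,
          source = "sigmoid fit",
          fit = c(k0 = x$k0, k1 = x$k1, k2 = x$k2, k3 = x$k3))
}

#' @rdname build_lut
#' @export
build_lut.intensity_series <- function(x, ...) {
  px <- x$pixel_values
  y <- x$r_iso
  if (any(diff(y) < 0))
    stop("build_lut: measured curve is not monotone non-decreasing; ",
         "smooth or refit before inverting", call. = FALSE)
  if (max(y) <= min(y))
    stop("build_lut: constant intensity curve is not invertible",
         call. = FALSE)
  # collapse flat runs so approx() has a function to invert
  keep <- !duplicated(y)
  targets <- min(y) + (0:255) / 255 * (max(y) - min(y))
  drive <- stats::approx(y[keep], px[keep], xout = targets, rule = 2,
                         ties = "ordered")$y
  drive <- pmin(pmax(drive, 0), 255)
  new_lut(drive, led_name = x$led_name, source = "raw interpolation")
}

new_lut <- function(drive, led_name = NULL, source = "", fit = NULL) {
  entries <- as.integer(round(drive))
  entries <- cummax(entries)   # guard against rounding-induced inversions
  entries[1] <- 0L
  entries[256] <- 255L
  structure(list(entries = entries, led_name = led_name, source = source,
                 fit = fit),
            class = "lut")
}

#' @export
print.lut <- function(x, ...) {
  cat(sprintf("<lut>%s 256 entries (%s)\n",
              if (!is.null(x$led_name)) paste0(" ", x$led_name) else "",
              x$source))
  cat("  entries[c(1, 65, 129, 193, 256)]:",
      paste(x$entries[c(1, 65, 129, 193, 256)], collapse = " "), "\n")
  invisible(x)
}

#' Map desired levels through a LUT
#'
#' @param lut A [build_lut()] result.
#' @param levels Desired linear levels, 0-255.
#' @return Drive values, 0-255.
#' @export
lut_apply <- function(lut, levels) {
  stopifnot(inherits(lut, "lut"))
  if (any(levels < 0 | levels > 255))
    stop("levels must be in [0, 255]", call. = FALSE)
  lut$entries[round(levels) + 1L]
}

#' Write / read a LUT file
#'
#' Plain text, one `index,drive_value` line per entry, with `#` metadata
#' header lines (LED name, source, fit parameters).
#'
#' @param lut A `lut`.
#' @param path File path.
#' @return `path` (write) or a `lut` (read).
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "lut"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# led: %s", lut$led_name %||% "unknown"),
    sprintf("# source: %s", lut$source),
    if (!is.null(lut$fit))
      sprintf("# fit: %s", paste(sprintf("%s=%.6g", names(lut$fit), lut$fit),
                                 collapse = " "))), con)
  writeLines(sprintf("%d,%d", 0:255, lut$entries), con)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^#", lines)]
  dat <- lines[!grepl("^#", lines) & nzchar(lines)]
  m <- do.call(rbind, strsplit(dat, ","))
  entries <- as.integer(m[, 2])[order(as.integer(m[, 1]))]
  if (length(entries) != 256L)
    stop("read_lut: expected 256 entries, got ", length(entries),
         call. = FALSE)
  led <- sub("^# led: ", "", grep("^# led: ", meta, value = TRUE)[1])
  structure(list(entries = entries,
                 led_name = if (is.na(led)) NULL else led,
                 source = "file", fit = NULL),
            class = "lut")
}

#' Dichromatic silent-substitution amplitude
#'
#' Scales the counterphase (here: green) amplitude by the cross-activation
#' ratio so the off-target opsin sees constant excitation:
#' `I_G = I - I_UV * S_cross_act`.
#'
#' @param i Stimulus amplitude seen by the target opsin (linearised units).
#' @param i_uv Amplitude of the UV primary.
#' @param s_cross_act Cross-activation ratio (scalar >= 0 or a
#'   [cross_activation()] result).
#' @return The green amplitude `I_G`.
#' @examples
#' silent_substitution_dichromatic(1, 1, 0.195)  # 0.805
#' @export
silent_substitution_dichromatic <- function(i, i_uv, s_cross_act) {
  if (inherits(s_cross_act, "cross_activation"))
    s_cross_act <- s_cross_act$s_cross_act
  if (s_cross_act < 0)
    stop("s_cross_act must be non-negative", call. = FALSE)
  i - i_uv * s_cross_act
}

#' General opsin-isolating stimulus by linear solve
#'
#' Solves `t(R_iso) %*% w = target` for per-LED modulation weights `w`, in
#' the least-squares sense when there are more LEDs than opsins. Residual
#' modulation per opsin and feasibility against intensity bounds are
#' reported. A rank-deficient matrix with an inconsistent target is an
#' error.
#'
#' @param matrix An `activation_matrix` (or bare LED x opsin matrix with
#'   dimnames).
#' @param target Named numeric vector of desired per-opsin modulation (one
#'   entry per opsin column; unnamed vectors are matched by position).
#' @param bounds Length-2 displayable modulation range for feasibility
#'   checking (default `c(-1, 1)` in linearised contrast units).
#' @return Object of class `substitution_stimulus` with `weights` (per
#'   LED), `residual` (per opsin), `feasible` flag and `out_of_gamut` LED
#'   names.
#' @export
substitution_solve <- function(matrix, target, bounds = c(-1, 1)) {
  r <- if (inherits(matrix, "activation_matrix")) matrix$r_iso
       else as.matrix(matrix)
  n_led <- nrow(r)
  n_ops <- ncol(r)
  if (n_led < n_ops)
    stop("substitution_solve: need at least as many LEDs as opsins",
         call. = FALSE)
  if (!is.null(names(target)) && !is.null(colnames(r)))
    target <- target[colnames(r)]
  if (length(target) != n_ops)
    stop("target must have one entry per opsin", call. = FALSE)
  a <- t(r)                     # opsin x LED
  qr_a <- qr(a)
  if (qr_a$rank < n_led) {
    # rank-deficient: solvable only if target lies in the column space
    w_ls <- qr.coef(qr_a, target)
    w_ls[is.na(w_ls)] <- 0
    resid <- as.numeric(a %*% w_ls - target)
    if (max(abs(resid)) > 1e-8 * max(1, max(abs(target))))
      stop(sprintf(
        "substitution_solve: target unsatisfiable (rank %d < %d LEDs); per-opsin residuals: %s",
        qr_a$rank, n_led,
        paste(sprintf("%s=%.3g", colnames(r), resid), collapse = ", ")),
        call. = FALSE)
    w <- w_ls
  } else {
    w <- qr.coef(qr_a, target)
  }
  resid <- as.numeric(a %*% w - target)
  names(w) <- rownames(r)
  names(resid) <- colnames(r)
  oog <- names(w)[w < bounds[1] | w > bounds[2]]
  structure(list(weights = w, residual = resid,
                 feasible = length(oog) == 0L, out_of_gamut = oog,
                 target = target, bounds = bounds),
            class = "substitution_stimulus")
}

#' @export
print.substitution_stimulus <- function(x, ...) {
  cat("<substitution_stimulus>\n  weights:",
      paste(sprintf("%s=%.4g", names(x$weights), x$weights),
            collapse = ", "), "\n")
  cat(sprintf("  max |residual|: %.3g; feasible: %s\n",
              max(abs(x$residual)), x$feasible))
  if (length(x$out_of_gamut))
    cat("  out of gamut:", paste(x$out_of_gamut, collapse = ", "), "\n")
  invisible(x)
}
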