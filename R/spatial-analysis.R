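#' Synthetic blurred checkerboard image
#'
#' Renders a binary checkerboard at the given checker size and image pixel
#' pitch, then convolves it with a Gaussian of standard deviation
#' `blur_sigma` (in um) to emulate optical blur; a per-channel
#' `blur_sigma` stands in for chromatic defocus. Values stay in \[0, 1\].
#'
#' @param checker_size Checker edge length, um; must be >= `pitch`.
#' @param pitch Image sampling pitch, um per pixel.
#' @param blur_sigma Gaussian blur standard deviation, um (0 = no blur).
#' @param size Image size in pixels (square), default 256.
#' @param phase Offset of the checker pattern in um (applied to both axes).
#' @param channel Optional channel label carried in the result.
#' @return Object of class `checker_image` with fields `pixels` (matrix),
#'   `pixel_pitch`, `checker_size`, `blur_sigma`, `channel`.
#' @export
synth_checkerboard <- function(checker_size, pitch = 1, blur_sigma = 0,
                               size = 256, phase = 0, channel = NULL) {
  if (pitch <= 0) stop("pitch must be positive", call. = FALSE)
  if (checker_size < pitch)
    stop("checker_size below the sampling pitch would alias", call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  # pad by the blur support so the convolution sees the continued pattern
  # (no wrap seam), then crop back
  margin <- if (blur_sigma > 0) ceiling(4 * blur_sigma / pitch) else 0L
  n_pad <- size + 2L * margin
  pos <- (seq_len(n_pad) - 1L - margin) * pitch + phase
  ix <- floor(outer(pos, rep(1, n_pad)) / checker_size)
  iy <- floor(outer(rep(1, n_pad), pos) / checker_size)
  img <- (ix + iy) %% 2
  if (blur_sigma > 0) {
    img <- EBImage::gblur(img, sigma = blur_sigma / pitch)
    img <- pmin(pmax(img, 0), 1)
  }
  keep <- margin + seq_len(size)
  img <- img[keep, keep]
  structure(list(pixels = img, pixel_pitch = pitch,
                 checker_size = checker_size, blur_sigma = blur_sigma,
                 channel = channel),
            class = "checker_image")
}

#' Read a grayscale image as a checker_image
#'
#' Accepts 8- or 16-bit grayscale PNG or TIFF; intensities are scaled to
#' \[0, 1\].
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @param pitch um per image pixel.
#' @param checker_size Optional nominal checker size, um.
#' @param channel Optional channel label.
#' @return A `checker_image`.
#' @export
read_checker_image <- function(path, pitch, checker_size = NA,
                               channel = NULL) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- img[, , 1]   # drop extra channels
  structure(list(pixels = img, pixel_pitch = pitch,
                 checker_size = checker_size, blur_sigma = NA,
                 channel = channel),
            class = "checker_image")
}

#' Extract a 1-D intensity profile from an image
#'
#' @param img A `checker_image`.
#' @param index Row or column index (1-based).
#' @param axis `"row"` (profile along a row) or `"column"`.
#' @return Object of class `intensity_profile` with `position` (um) and
#'   `intensity`.
#' @export
extract_profile <- function(img, index, axis = c("row", "column")) {
  stopifnot(inherits(img, "checker_image"))
  axis <- match.arg(axis)
  d <- dim(img$pixels)
  n <- if (axis == "row") d[1] else d[2]
  if (index < 1 || index > n)
    stop(sprintf("index %d out of bounds [1, %d]", index, n), call. = FALSE)
  intensity <- if (axis == "row") img$pixels[index, ] else img$pixels[, index]
  intensity_profile((seq_along(intensity) - 1) * img$pixel_pitch,
                    as.numeric(intensity))
}

#' Construct an intensity profile
#'
#' @param position Strictly increasing positions, um.
#' @param intensity Intensities, arbitrary units.
#' @return Object of class `intensity_profile`.
#' @export
intensity_profile <- function(position, intensity) {
  position <- as.numeric(position)
  intensity <- as.numeric(intensity)
  if (length(position) != length(intensity))
    stop("position and intensity must have the same length", call. = FALSE)
  if (any(diff(position) <= 0))
    stop("position must be strictly increasing", call. = FALSE)
  structure(list(position = position, intensity = intensity),
            class = "intensity_profile")
}

#' Profile contrast
#'
#' `I_max - I_min` of an intensity profile.
#'
#' @param profile An [intensity_profile()] with at least 2 samples.
#' @return Scalar contrast.
#' @export
profile_contrast <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (length(profile$intensity) < 2L)
    stop("profile_contrast: need at least 2 samples", call. = FALSE)
  max(profile$intensity) - min(profile$intensity)
}

#' Edge sharpness from a sigmoid fit of the rising phase
#'
#' Quantifies the steepness of a dark-to-bright transition. The profile is
#' peak-normalised (rescaled to \[0, 1\]); when `normalise = TRUE` the
#' position axis is additionally rescaled so the half-maximum width of the
#' bright checker around the transition equals 1, making profiles of
#' different checker sizes comparable. A sigmoid
#' `y = K0 + K1 / (1 + exp(-(x - K2) / K3))` is then fitted to the rising
#' segment (preceding trough to following peak) and `1 / K3` is the
#' sharpness estimate.
#'
#' An effectively instantaneous step (transition completed within one
#' sample) cannot constrain `K3`; the sharpness is then capped at
#' `2 / min(dx)` on the working axis and flagged via `capped = TRUE`.
#'
#' @param profile An [intensity_profile()] containing at least one rising
#'   transition through half maximum.
#' @param normalise Rescale the position axis to unit half-maximum width
#'   (skipped, with a message in the result, when no falling crossing
#'   follows the rise).
#' @return Object of class `edge_fit` with `k0`, `k1`, `k2`, `k3`,
#'   `sharpness` (= 1/K3 on the working axis), `sharpness_um` (= 1/K3 per
#'   um on the raw axis), `capped`, `half_width` (um, or NA).
#' @export
edge_sharpness <- function(profile, normalise = TRUE) {
  stopifnot(inherits(profile, "intensity_profile"))
  x_raw <- profile$position
  y <- profile$intensity
  rng <- range(y)
  if (diff(rng) <= 0)
    stop("edge_sharpness: flat profile, no transition", call. = FALSE)
  yn <- (y - rng[1]) / diff(rng)

  rises <- which(yn[-length(yn)] < 0.5 & yn[-1] >= 0.5)
  if (length(rises) == 0L)
    stop("edge_sharpness: no rising transition through half maximum found",
         call. = FALSE)
  # use the rise nearest the profile centre to avoid boundary effects
  i <- rises[which.min(abs(rises - length(yn) / 2))]
  x_rise <- cross_pos(x_raw, yn, i)

  falls <- which(yn[-length(yn)] >= 0.5 & yn[-1] < 0.5)
  falls <- falls[falls > i]
  half_width <- if (length(falls)) cross_pos(x_raw, yn, falls[1]) - x_rise
                else NA_real_

  # fitting window: preceding trough to following peak
  lo <- i
  while (lo > 1 && yn[lo - 1] <= yn[lo]) lo <- lo - 1
  hi <- i + 1
  while (hi < length(yn) && yn[hi + 1] >= yn[hi]) hi <- hi + 1

  x <- if (normalise && is.finite(half_width) && half_width > 0)
         (x_raw - x_rise) / half_width
       else x_raw
  scale_per_um <- if (normalise && is.finite(half_width) && half_width > 0)
                    1 / half_width else 1

  xw <- x[lo:hi]
  yw <- yn[lo:hi]
  dx <- min(diff(xw))

  # instantaneous step: K3 unconstrained by the data
  jump <- max(abs(diff(yw)))
  if (jump > 0.8 || length(xw) < 5L) {
    cap <- 2 / dx
    return(new_edge_fit(min(yw), diff(range(yw)), xw[which.max(diff(yw))],
                        1 / cap, cap, TRUE, half_width, scale_per_um))
  }
  k0_0 <- min(yw); k1_0 <- diff(range(yw))
  k2_0 <- cross_pos(xw, yw, which(yw[-length(yw)] < 0.5 & yw[-1] >= 0.5)[1])
  if (!is.finite(k2_0)) k2_0 <- mean(range(xw))
  # a denormal-scale start breaks the relative-step numeric derivative
  if (abs(k2_0) < sqrt(.Machine$double.eps)) k2_0 <- 0
  k3_0 <- diff(range(xw)) / 10
  # multi-start in K3: the RSS surface has a flat step-like local optimum
  sig <- function(p) p[1] + p[2] / (1 + exp(-(xw - p[3]) / p[4]))
  best <- NULL
  for (k3_try in unique(c(k3_0, diff(range(xw)) / c(2, 50, 250)))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(k0 = k0_0, k1 = k1_0, k2 = k2_0, k3 = k3_try),
        fn = function(p) yw - sig(p),
        lower = c(-Inf, 0, min(xw), dx / 100),
        upper = c(Inf, Inf, max(xw), Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0L, 9L)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("edge_sharpness: sigmoid fit failed on all starts", call. = FALSE)
  p <- as.list(best$fit$par)
  capped <- p$k3 <= dx / 50
  sharp <- if (capped) 2 / dx else 1 / p$k3
  new_edge_fit(p$k0, p$k1, p$k2, p$k3, sharp, capped, half_width,
               scale_per_um)
}

new_edge_fit <- function(k0, k1, k2, k3, sharpness, capped,
                         half_width, scale_per_um) {
  # sharpness is per unit of the working axis; convert to per-um via the
  # half-width rescale factor
  structure(list(k0 = k0, k1 = k1, k2 = k2, k3 = k3,
                 sharpness = sharpness,
                 sharpness_um = sharpness * scale_per_um,
                 capped = capped, half_width = half_width),
            class = "edge_fit")
}

#' @export
print.edge_fit <- function(x, ...) {
  cat(sprintf("<edge_fit> 1/K3 = %.4g%s (K3 = %.4g, half width %.3g um)\n",
              x$sharpness, if (x$capped) " [capped]" else "",
              x$k3, x$half_width))
  invisible(x)
}

# linearly interpolated position of the 0.5 crossing between i and i+1
cross_pos <- function(x, yn, i) {
  x[i] + (0.5 - yn[i]) / (yn[i + 1] - yn[i]) * (x[i + 1] - x[i])
}

#' Pixel footprint of a stimulus feature
#'
#' Number of device or camera pixels covered per axis by a feature of the
#' given size: `footprint = feature_size * scale`. `scale` is in pixels
#' per um (note: stimulator scan scales are often quoted as um/pixel; pass
#' `1 / scale` in that case).
#'
#' @param feature_size Feature edge length, um (positive).
#' @param scale Pixels per um, per axis (scalar or length-2).
#' @return Pixels per axis, same length as `scale`.
#' @examples
#' pixel_footprint(5, c(1.9, 0.9))   # 9.5 x 4.5 device pixels
#' pixel_footprint(20, 1 / 1.4)      # ~14.3 camera pixels
#' @export
pixel_footprint <- function(feature_size, scale) {
  if (any(feature_size <= 0) || any(scale <= 0))
    stop("pixel_footprint: inputs must be positive", call. = FALSE)
  feature_size * scale
}
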