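#' FRET ratio trace (dR/R)
#'
#' Computes the acceptor/donor ratio `R = FA / FD`, baseline-normalises it
#' as `dR/R = (R - R0) / R0` with `R0` the mean ratio over a pre-stimulus
#' window, and resamples the result to a uniform output rate by linear
#' interpolation.
#'
#' @param time Sample times, s.
#' @param fa Acceptor fluorescence.
#' @param fd Donor fluorescence (positive; up to 1% non-positive samples
#'   are masked with a warning, more is an error).
#' @param out_rate Output sample rate, Hz (default 500).
#' @param baseline Length-2 window (s) over which `R0` is averaged;
#'   default the first second.
#' @return Object of class `ratio_trace` with `time` and `dr_over_r` on the
#'   uniform grid, plus `r0` and `sample_rate_out`.
#' @export
fret_ratio <- function(time, fa, fd, out_rate = 500, baseline = NULL) {
  if (length(time) != length(fa) || length(fa) != length(fd))
    stop("time, fa, fd must have the same length", call. = FALSE)
  bad <- !is.finite(fd) | fd <= 0
  if (any(bad)) {
    if (mean(bad) > 0.01)
      stop(sprintf("fret_ratio: %.1f%% of donor samples are non-positive",
                   100 * mean(bad)), call. = FALSE)
    warning(sprintf("fret_ratio: masking %d non-positive donor sample(s)",
                    sum(bad)))
    time <- time[!bad]; fa <- fa[!bad]; fd <- fd[!bad]
  }
  r <- fa / fd
  if (is.null(baseline)) baseline <- c(time[1], time[1] + 1)
  in_base <- time >= baseline[1] & time <= baseline[2]
  if (!any(in_base))
    stop("fret_ratio: baseline window contains no samples", call. = FALSE)
  r0 <- mean(r[in_base])
  if (r0 == 0) stop("fret_ratio: zero baseline ratio", call. = FALSE)
  drr <- (r - r0) / r0
  t_out <- seq(time[1], time[length(time)], by = 1 / out_rate)
  structure(list(time = t_out,
                 dr_over_r = stats::approx(time, drr, xout = t_out)$y,
                 r0 = r0, sample_rate_out = out_rate),
            class = "ratio_trace")
}

#' Detrend and z-normalise a trace
#'
#' High-pass filters the trace (zero-phase second-order Butterworth, so
#' detrending does not shift response timing) and z-scores it using the
#' mean and SD over a baseline interval.
#'
#' @param x Numeric trace (uniformly sampled).
#' @param sample_rate Sampling rate, Hz.
#' @param cutoff High-pass cutoff, Hz (default 0.1).
#' @param baseline_window Length-2 interval (s) used for the z-score;
#'   default `c(1, 6)`.
#' @return Numeric trace, filtered and z-scored; filter settings in
#'   attribute `filter`.
#' @export
znorm_detrend <- function(x, sample_rate, cutoff = 0.1,
                          baseline_window = c(1, 6)) {
  n <- length(x)
  if (n / sample_rate <= baseline_window[2])
    stop("znorm_detrend: trace shorter than the baseline window",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("znorm_detrend: constant trace cannot be normalised", call. = FALSE)
  bf <- signal::butter(2, cutoff / (sample_rate / 2), type = "high")
  xf <- signal::filtfilt(bf, x)
  t <- (seq_len(n) - 1) / sample_rate
  in_base <- t >= baseline_window[1] & t <= baseline_window[2]
  s <- stats::sd(xf[in_base])
  if (s == 0)
    stop("znorm_detrend: zero SD in the baseline window", call. = FALSE)
  out <- (xf - mean(xf[in_base])) / s
  attr(out, "filter") <- list(type = "butterworth high-pass, zero-phase",
                              order = 2, cutoff = cutoff)
  out
}

#' Trial matrix (time x repetitions)
#'
#' @param c Numeric T x R matrix, time samples by stimulus repetitions.
#' @param sample_rate Sampling rate, Hz.
#' @param stimulus_freq Fundamental stimulus frequency, Hz (default 1).
#' @return Object of class `trial_matrix`.
#' @export
trial_matrix <- function(c, sample_rate, stimulus_freq = 1) {
  c <- as.matrix(c)
  if (any(!is.finite(c)))
    stop("trial matrix must not contain NaN/Inf", call. = FALSE)
  structure(list(c = c, sample_rate = sample_rate,
                 stimulus_freq = stimulus_freq),
            class = "trial_matrix")
}

#' Segment a trace into stimulus-aligned trials
#'
#' Cuts a uniformly sampled trace at the stimulus synchronisation markers
#' and corrects each segment for the ROI's sub-frame acquisition offset
#' (`line_index * scan_line_period`): the ROI on scan line k of the frame
#' is imaged k line periods after the frame marker, so its time base is
#' shifted back by that amount, keeping alignment to within a couple of
#' milliseconds. Segments are resampled onto a common per-trial grid by
#' linear interpolation.
#'
#' @param x Numeric trace.
#' @param sample_rate Sampling rate of `x`, Hz.
#' @param marker_times Strictly increasing stimulus marker times, s (>= 2).
#' @param trial_duration Trial window, s; defaults to the median marker
#'   interval. Must not exceed the marker interval.
#' @param line_index ROI scan-line index within the frame (0-based).
#' @param scan_line_period Scan line period, ms.
#' @param stimulus_freq Stored on the result.
#' @return A [trial_matrix()].
#' @export
align_trials <- function(x, sample_rate, marker_times, trial_duration = NULL,
                         line_index = 0, scan_line_period = 2,
                         stimulus_freq = 1) {
  if (length(marker_times) < 2L)
    stop("align_trials: need at least 2 markers", call. = FALSE)
  if (any(diff(marker_times) <= 0))
    stop("align_trials: markers must be strictly increasing", call. = FALSE)
  if (is.null(trial_duration))
    trial_duration <- stats::median(diff(marker_times))
  if (trial_duration > min(diff(marker_times)) + 1e-9)
    stop("align_trials: marker interval shorter than the trial window",
         call. = FALSE)
  t <- (seq_along(x) - 1) / sample_rate
  offset <- line_index * scan_line_period / 1000
  n_t <- round(trial_duration * sample_rate)
  rel <- (seq_len(n_t) - 1) / sample_rate
  reps <- vapply(marker_times, function(m) {
    stats::approx(t, x, xout = m + offset + rel, rule = 2)$y
  }, numeric(n_t))
  trial_matrix(reps, sample_rate, stimulus_freq)
}

#' Response quality index
#'
#' Signal-to-noise ratio of a trial matrix: the variance over time of the
#' trial-averaged response divided by the average over trials of the
#' within-trial variance,
#' `Qi = Var_t[ mean_r C ] / mean_r[ Var_t C ]`. Qi is 1 for perfectly
#' repeatable responses and about `1/R` for pure noise over R repetitions.
#' Variances use the population convention (divide by T).
#'
#' @param m A [trial_matrix()] with at least 2 repetitions and 2 time
#'   samples.
#' @param threshold Pass/fail threshold on Qi (default 0.3).
#' @return Object of class `quality_result` with `qi` and `passes`.
#' @export
quality_index <- function(m, threshold = 0.3) {
  stopifnot(inherits(m, "trial_matrix"))
  c <- m$c
  if (ncol(c) < 2L || nrow(c) < 2L)
    stop("quality_index: need >= 2 repetitions and >= 2 time samples",
         call. = FALSE)
  var_pop <- function(v) mean((v - mean(v))^2)
  denom <- mean(apply(c, 2, var_pop))
  if (denom == 0)
    stop("quality_index: all trials constant, Qi undefined", call. = FALSE)
  qi <- var_pop(rowMeans(c)) / denom
  structure(list(qi = qi, passes = qi > threshold, threshold = threshold),
            class = "quality_result")
}

#' @export
print.quality_result <- function(x, ...) {
  cat(sprintf("<quality_result> Qi = %.3f (%s at threshold %g)\n", x$qi,
              if (x$passes) "pass" else "fail", x$threshold))
  invisible(x)
}

# power of the trial-averaged trace at the DFT bin nearest f0
power_at_fundamental <- function(m, f0, type = c("power", "amplitude")) {
  type <- match.arg(type)
  avg <- rowMeans(m$c)
  n <- length(avg)
  k <- round(f0 * n / m$sample_rate)      # 0-based bin index
  if (k < 1 || k > floor(n / 2))
    stop("fundamental frequency outside the resolvable range", call. = FALSE)
  amp <- Mod(stats::fft(avg)[k + 1]) / n
  if (type == "power") amp^2 else amp
}

#' Spectral contrast of responses to two chromatic stimuli
#'
#' Uses the power at the stimulus fundamental frequency of the
#' trial-averaged response to each chromatic stimulus as response strength
#' and forms the Michelson-style contrast
#' `SC = (P_G - P_B) / (P_G + P_B)`, ranging from -1 (UV-only response)
#' to +1 (green-only). Each trial matrix must span an integer number of
#' stimulus cycles (no windowing is applied).
#'
#' @param green_trials,uv_trials [trial_matrix()] objects for the green
#'   and UV stimulus phases.
#' @param f0 Fundamental frequency, Hz (default 1).
#' @param type `"power"` (squared magnitude, default) or `"amplitude"`.
#'   The sign of SC is unaffected by this choice; its magnitude is not.
#' @return Object of class `spectral_contrast_result` with `p_g`, `p_b`,
#'   `sc`.
#' @export
spectral_contrast <- function(green_trials, uv_trials, f0 = 1,
                              type = c("power", "amplitude")) {
  type <- match.arg(type)
  for (m in list(green_trials, uv_trials)) {
    stopifnot(inherits(m, "trial_matrix"))
    n_cyc <- f0 * nrow(m$c) / m$sample_rate
    if (abs(n_cyc - round(n_cyc)) > 1e-6)
      stop("spectral_contrast: trials must span an integer number of cycles",
           call. = FALSE)
  }
  p_g <- power_at_fundamental(green_trials, f0, type)
  p_b <- power_at_fundamental(uv_trials, f0, type)
  if (p_g + p_b == 0)
    stop("spectral_contrast: zero power in both channels, SC undefined",
         call. = FALSE)
  structure(list(p_g = p_g, p_b = p_b, sc = (p_g - p_b) / (p_g + p_b),
                 f0 = f0, type = type),
            class = "spectral_contrast_result")
}

#' @export
print.spectral_contrast_result <- function(x, ...) {
  cat(sprintf("<spectral_contrast> SC = %+.3f (P_G %.3g, P_B %.3g, %s)\n",
              x$sc, x$p_g, x$p_b, x$type))
  invisible(x)
}

#' Synthetic trial matrices with known ground truth
#'
#' Generates sinusoidal responses to a green and a UV stimulus phase with
#' amplitudes chosen so the true spectral contrast equals `sc_true`
#' (`A_G^2 proportional to 1 + sc`, `A_B^2 proportional to 1 - sc`), plus
#' i.i.d. Gaussian noise with variance tuned so the expected quality index
#' is `qi_target` via `Qi ~ (s^2 + n^2/R) / (s^2 + n^2)` where `s^2` is
#' the mean sinusoid variance across the two channels. Deterministic under
#' a fixed seed.
#'
#' @param sc_true True spectral contrast in \[-1, 1\].
#' @param qi_target Target quality index in `(1/R, 1]`; 1 means no noise.
#' @param R Number of repetitions (>= 2).
#' @param T_dur Trial duration, s.
#' @param f0 Stimulus frequency, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed.
#' @return List with `green_trials` and `uv_trials` ([trial_matrix()]),
#'   plus the generating `amplitudes` and `noise_sd`.
#' @export
synth_trials <- function(sc_true, qi_target = 0.8, R = 3, T_dur = 4,
                         f0 = 1, sample_rate = 500, seed = 1) {
  if (sc_true < -1 || sc_true > 1)
    stop("sc_true must lie in [-1, 1]", call. = FALSE)
  if (R < 2) stop("need R >= 2 repetitions", call. = FALSE)
  if (qi_target > 1)
    stop("qi_target > 1 is infeasible (noise variance would be negative)",
         call. = FALSE)
  if (qi_target <= 1 / R)
    stop(sprintf("qi_target must exceed 1/R = %.3g", 1 / R), call. = FALSE)
  a_g <- sqrt(1 + sc_true)
  a_b <- sqrt(1 - sc_true)
  sig_var <- (a_g^2 + a_b^2) / 4          # mean sinusoid variance (A^2/2)/2
  noise_sd <- if (qi_target >= 1) 0 else
    sqrt(sig_var * (1 - qi_target) / (qi_target - 1 / R))
  n_t <- round(T_dur * sample_rate)
  t <- (seq_len(n_t) - 1) / sample_rate
  set.seed(seed)
  mk <- function(a) {
    sig <- a * sin(2 * pi * f0 * t)
    trial_matrix(matrix(sig, n_t, R) +
                   matrix(stats::rnorm(n_t * R, sd = noise_sd), n_t, R),
                 sample_rate, f0)
  }
  list(green_trials = mk(a_g), uv_trials = mk(a_b),
       amplitudes = c(green = a_g, uv = a_b), noise_sd = noise_sd)
}
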