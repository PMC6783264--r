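#' Blanking/gating configuration
#'
#' Describes the interaction of the scan-line retrace gating with the
#' display frame rate. LEDs are on only during the final
#' `retrace_fraction` of each scan line; the displayed stimulus level is
#' sample-and-held at frame boundaries (the frame clock and the line clock
#' are free-running, which is what produces aliasing beats).
#'
#' @param line_period Scan line period, ms (1-2 ms typical).
#' @param retrace_fraction Fraction of the line spent in retrace (LED on),
#'   in (0, 1); default 0.2.
#' @param frame_rate Display frame rate, Hz; default 60.
#' @param duration Simulated duration, s.
#' @param sample_rate Simulation sample rate, Hz; must be at least 20x the
#'   line rate. Default 1e5.
#' @return Object of class `blanking_config`.
#' @export
blanking_config <- function(line_period = 1, retrace_fraction = 0.2,
                            frame_rate = 60, duration = 1,
                            sample_rate = 1e5) {
  if (retrace_fraction <= 0 || retrace_fraction >= 1)
    stop("retrace_fraction must be in (0, 1)", call. = FALSE)
  if (line_period <= 0 || frame_rate <= 0 || duration <= 0)
    stop("line_period, frame_rate, duration must be positive", call. = FALSE)
  line_rate <- 1000 / line_period
  if (sample_rate < 20 * line_rate)
    stop(sprintf(
      "sample_rate %g Hz too low for %g Hz lines (need >= 20x line rate)",
      sample_rate, line_rate), call. = FALSE)
  structure(list(line_period = line_period,
                 retrace_fraction = retrace_fraction,
                 frame_rate = frame_rate, duration = duration,
                 sample_rate = sample_rate),
            class = "blanking_config")
}

#' Simulate a retrace-gated LED trace
#'
#' The instantaneous LED output equals the stimulus level during each
#' retrace window (the last `retrace_fraction` of every line period) and 0
#' otherwise. The stimulus level is evaluated once per display frame
#' (sample-and-hold), modelling an unsynchronised 60-Hz display driving
#' LEDs gated at the (much faster) line rate. The gate itself is ideal
#' (zero rise/fall time).
#'
#' @param cfg A [blanking_config()].
#' @param stimulus_level Function of time (s) returning the requested
#'   level, or a single constant. Default constant 1.
#' @return Object of class `led_trace` with `time` (s), `intensity`, and
#'   the config.
#' @export
simulate_gated_led <- function(cfg, stimulus_level = 1) {
  stopifnot(inherits(cfg, "blanking_config"))
  if (is.numeric(stimulus_level) && length(stimulus_level) == 1L) {
    lvl <- stimulus_level
    stimulus_level <- function(t) rep(lvl, length(t))
  }
  n <- round(cfg$duration * cfg$sample_rate)
  k <- seq_len(n) - 1
  t <- k / cfg$sample_rate
  lp <- cfg$line_period / 1000                 # s
  spl <- lp * cfg$sample_rate                  # samples per line
  if (abs(spl - round(spl)) < 1e-9 * spl) {
    # integer samples per line: exact periodic gate, no float jitter at
    # the on/off boundaries
    phase <- (k %% round(spl)) / round(spl)
  } else {
    phase <- (t %% lp) / lp
  }
  # small epsilon so binary representation of (1 - fraction) does not drop
  # the boundary sample
  gate <- phase >= (1 - cfg$retrace_fraction) - 1e-9
  frame_t <- floor(t * cfg$frame_rate) / cfg$frame_rate
  level <- stimulus_level(frame_t)
  structure(list(time = t, intensity = ifelse(gate, level, 0), cfg = cfg),
            class = "led_trace")
}

#' Perceived brightness modulation after photoreceptor integration
#'
#' Box-smooths a gated LED trace (default box width 100 ms, roughly the
#' integration time of mouse cone photoreceptors) and computes the
#' modulation depth `(max - min) / mean` of the smoothed trace over its
#' central, edge-free region (one box width trimmed from each end).
#'
#' @param trace A [simulate_gated_led()] result; must span more than 3 box
#'   widths.
#' @param box_width Moving-average width, ms.
#' @return Object of class `modulation_result` with `time`, `smoothed`
#'   (central region), `modulation_depth`, `mean_level`.
#' @export
perceived_modulation <- function(trace, box_width = 100) {
  stopifnot(inherits(trace, "led_trace"))
  fs <- trace$cfg$sample_rate
  n_box <- max(1L, round(box_width / 1000 * fs))
  n <- length(trace$intensity)
  if (n <= 3L * n_box)
    stop("perceived_modulation: trace shorter than 3 box widths",
         call. = FALSE)
  sm <- moving_average(trace$intensity, n_box)
  keep <- seq(n_box + 1L, n - n_box)
  sm <- sm[keep]
  tt <- trace$time[keep]
  mean_level <- mean(sm)
  depth <- if (mean_level > 0) (max(sm) - min(sm)) / mean_level else 0
  structure(list(time = tt, smoothed = sm, modulation_depth = depth,
                 mean_level = mean_level, box_width = box_width),
            class = "modulation_result")
}

#' Centred moving average
#'
#' Cumulative-sum implementation (O(n) independent of window length).
#' Entries whose window would run past either end are NA.
#'
#' @param x Numeric vector.
#' @param n_box Window length in samples.
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, n_box) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- n_box %/% 2
  lo <- seq_len(n) - half            # window start index
  hi <- lo + n_box - 1L              # window end index
  out <- rep(NA_real_, n)
  ok <- lo >= 1L & hi <= n
  out[ok] <- (cs[hi[ok] + 1L] - cs[lo[ok]]) / n_box
  out
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf(
    "<modulation_result> depth %.3g, mean level %.4g (box %g ms)\n",
    x$modulation_depth, x$mean_level, x$box_width))
  invisible(x)
}
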