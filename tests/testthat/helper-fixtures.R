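# Shared fixtures for the calibration chain tests.

# band-pass LED models matching a dichromatic mouse stimulator
# (387/11 UV and 576/10 green LED/filter combinations)
mouse_leds <- function(peak_power = 100) {
  list(
    UV = synth_led_spectrum(
      led_model("UV", 387, 11, c(381.5, 392.5), peak_power)),
    green = synth_led_spectrum(
      led_model("green", 576, 10, c(571, 581), peak_power))
  )
}

# published-style mouse activation matrix (P*/cone/s): rows LED, cols opsin
mouse_riso_matrix <- function() {
  activation_matrix(rbind(green = c(S = 0,      M = 19.5e3),
                          UV    = c(S = 19.2e3, M = 3.8e3)))
}

# sigmoid used for gamma curves and edge profiles
sigmoid4 <- function(x, k0, k1, k2, k3) k0 + k1 / (1 + exp(-(x - k2) / k3))

# write lines to a temp file, return its path
write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
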