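# Build a raw 1024-point block from an explicit line list, with a known
# zero-order phase (radians) and frequency offset (ppm) baked into the FID.
# Mirrors the physics, not the package's synthesis entry point, so known
# corruptions can be planted and inverted independently.
make_block <- function(lines, phase = 0, shift_ppm = 0, noise_sd = 0,
                       edit_state = "Off", block_index = 1L,
                       f0 = 123.25, dwell = 1 / 1200, lb0 = 3,
                       lorentzian = FALSE, seed = NULL) {
  n <- 1024L
  t <- (seq_len(n) - 1) * dwell
  env <- if (lorentzian) exp(-pi * lb0 * t) else
    exp(-(pi * lb0 * t)^2 / (4 * log(2)))
  fid <- complex(real = rep(0, n))
  for (ln in lines) {
    fid <- fid + ln$amp * exp(2i * pi * (ln$ppm - 4.7) * f0 * t) * env
  }
  fid <- fid * exp(1i * (phase + 2 * pi * shift_ppm * f0 * t))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    fid <- fid + complex(real = rnorm(n, 0, noise_sd),
                         imaginary = rnorm(n, 0, noise_sd))
  }
  block_spectrum(gabasupp:::spectrum_from_fid(fid), f0, dwell,
                 edit_state = edit_state, block_index = block_index)
}

# full width at half maximum (Hz) of the real part around a peak
measure_fwhm_hz <- function(block, ppm_center, halfwin = 0.3) {
  sel <- block$ppm >= ppm_center - halfwin & block$ppm <= ppm_center + halfwin
  x <- rev(block$ppm[sel]); y <- rev(Re(block$values[sel]))
  pk <- which.max(y)
  half <- y[pk] / 2
  left <- which(y[seq_len(pk)] <= half)
  right <- pk - 1L + which(y[pk:length(y)] <= half)
  if (!length(left) || !length(right)) return(NA_real_)
  lo <- approx(y[c(max(left), max(left) + 1L)],
               x[c(max(left), max(left) + 1L)], xout = half)$y
  hi <- approx(y[c(min(right) - 1L, min(right))],
               x[c(min(right) - 1L, min(right))], xout = half)$y
  (hi - lo) * block$f0
}

# small normalized point table for suppression-module unit tests
toy_points <- function(df) {
  defaults <- data.frame(subject_id = "S1", eye_label = "DE",
                         ocular_config = "dichoptic", orientation = "iso",
                         t_rel = 2, c_rel = 5, baseline = 0.03,
                         raw_threshold = 0.06, raw_surround = 0.15,
                         stringsAsFactors = FALSE)
  out <- df
  for (nm in setdiff(names(defaults), names(df))) out[[nm]] <- defaults[[nm]]
  out
}
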