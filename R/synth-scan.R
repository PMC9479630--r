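#' Synthesize an edited MRS scan with a planted GABA:Cr ratio
#'
#' Builds paired On/Off block spectra (10-transient averages, 1024 complex
#' points each) containing a creatine singlet at 3.00 ppm (both editing
#' states), creatine-CH2 and NAA lines for realism, and an edited GABA
#' pseudo-doublet centered at 3.00 ppm present only in On-resonance blocks,
#' so that it survives in the On - Off difference spectrum. Line shapes are
#' Gaussian (3 Hz intrinsic width) so that the tails outside the integration
#' windows are negligible; the GABA amplitude is chosen so that the noiseless
#' difference-spectrum GABA area (2.85-3.15 ppm) divided by the summed-spectrum
#' creatine area (2.93-3.10 ppm) equals `true_gaba_cr`. Note the summed
#' spectrum carries creatine twice (On + Off) plus the edited GABA signal, and
#' the planted amplitude accounts for both.
#'
#' Each On/Off block pair shares a small random zero-order phase error and
#' frequency offset (scanner drift emulation); complex Gaussian noise is added
#' independently per block with amplitude set by `snr` (creatine peak height
#' divided by the per-point spectral noise SD). `snr = Inf` gives noiseless
#' spectra.
#'
#' @param true_gaba_cr planted GABA:Cr ratio (> 0, or 0 for a null metabolite).
#' @param snr amplitude signal-to-noise ratio of the creatine peak; `Inf`
#'   disables noise.
#' @param seed integer; identical seeds give bit-identical scans.
#' @param n_blocks number of blocks per editing state (default 16, i.e. 160
#'   transients per state in 10-transient averages).
#' @param phase_jitter_sd,shift_jitter_sd SD of the per-pair phase error
#'   (radians) and frequency offset (ppm).
#' @param f0 transmit frequency, MHz. @param dwell dwell time, seconds.
#' @param scan_id identifier stamped on all blocks.
#' @return an [edited_scan()] with `n_blocks` On and `n_blocks` Off raw blocks.
#' @export
synthesize_scan <- function(true_gaba_cr, snr = Inf, seed = 1L,
                            n_blocks = 16L,
                            phase_jitter_sd = 0.05, shift_jitter_sd = 0.003,
                            f0 = 123.25, dwell = 1 / 1200,
                            scan_id = "synthetic") {
  if (!is.numeric(true_gaba_cr) || true_gaba_cr < 0) {
    stop("true_gaba_cr must be >= 0")
  }
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  if (n_blocks < 3L) stop("need at least 3 blocks per editing state")

  n <- 1024L
  t <- (seq_len(n) - 1) * dwell
  lb0 <- 3                                   # intrinsic Gaussian linewidth, Hz
  env <- exp(-(pi * lb0 * t)^2 / (4 * log(2)))

  line <- function(ppm, amp) amp * exp(2i * pi * (ppm - 4.7) * f0 * t) * env
  # shared resonances (both editing states)
  shared <- line(3.00, 1.0) +                # creatine CH3 (the reference)
    line(3.92, 0.7) +                        # creatine CH2
    line(2.01, 1.4) +                        # NAA
    line(4.70, 0.3)                          # residual water
  # edited GABA pseudo-doublet, On state only. Amplitude g solves
  # g / (2*A_cr + g) = r  =>  g = 2 r A_cr / (1 - r), A_cr = 1.
  if (true_gaba_cr >= 1) stop("true_gaba_cr must be < 1")
  g <- 2 * true_gaba_cr / (1 - true_gaba_cr)
  gaba <- line(2.985, g / 2) + line(3.015, g / 2)

  fid_off <- shared
  fid_on <- shared + gaba

  # noise scale: creatine peak height in the raw Off spectrum
  spec_off <- spectrum_from_fid(fid_off)
  ax <- ppm_axis(n, f0, dwell)
  cr_h <- max(Mod(spec_off[ax >= 2.8 & ax <= 3.2]))
  sd_t <- if (is.finite(snr)) cr_h / (snr * sqrt(n)) else 0

  with_seed(seed, {
    mk <- function(state, fid, idx) {
      blocks <- vector("list", n_blocks)
      for (b in seq_len(n_blocks)) {
        jit <- jitters[[b]]
        fid_b <- fid * exp(1i * (jit$phase + 2 * pi * jit$shift * f0 * t))
        if (sd_t > 0) {
          fid_b <- fid_b + complex(real = stats::rnorm(n, 0, sd_t),
                                   imaginary = stats::rnorm(n, 0, sd_t))
        }
        blocks[[b]] <- block_spectrum(spectrum_from_fid(fid_b), f0, dwell,
                                      edit_state = state, scan_id = scan_id,
                                      block_index = b)
      }
      blocks
    }
    jitters <- lapply(seq_len(n_blocks), function(b) {
      list(phase = stats::rnorm(1, 0, phase_jitter_sd),
           shift = stats::rnorm(1, 0, shift_jitter_sd))
    })
    off <- mk("Off", fid_off)
    on <- mk("On", fid_on)
    edited_scan(on, off)
  })
}
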