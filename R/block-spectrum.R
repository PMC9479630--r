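#' Construct a block spectrum
#'
#' A block spectrum is the frequency-domain representation of one 10-transient
#' average from an edited MRS acquisition: complex amplitudes on a chemical
#' shift (ppm) axis that decreases from left to right (index 1 = highest ppm),
#' tagged with its editing state and acquisition metadata.
#'
#' @param values complex vector of spectral amplitudes, ordered by decreasing
#'   ppm.
#' @param f0 transmit frequency in MHz (sets the Hz-per-ppm scale).
#' @param dwell dwell time in seconds (sets the spectral width `1/dwell`).
#' @param edit_state `"On"` or `"Off"` editing pulse state.
#' @param scan_id,block_index identifiers linking the block to its scan and
#'   its position within the scan; On/Off blocks with equal `block_index`
#'   form a pair.
#' @param preprocessed has zero-padding/apodization been applied?
#' @param phase_applied,shift_applied cumulative phase (radians) and frequency
#'   (ppm) corrections already applied to the values.
#' @param center_ppm chemical shift at zero frequency offset (water, 4.7 ppm).
#' @return an object of class `block_spectrum`.
#' @export
block_spectrum <- function(values, f0, dwell, edit_state,
                           scan_id = "scan", block_index = 1L,
                           preprocessed = FALSE,
                           phase_applied = 0, shift_applied = 0,
                           center_ppm = 4.7) {
  n <- length(values)
  if (!n %in% c(1024L, 4096L)) {
    stop("block must have 1024 (raw) or 4096 (preprocessed) points, got ", n)
  }
  if (!edit_state %in% c("On", "Off")) {
    stop("edit_state must be \"On\" or \"Off\"")
  }
  structure(
    list(values = as.complex(values),
         ppm = ppm_axis(n, f0, dwell, center_ppm),
         f0 = f0, dwell = dwell,
         edit_state = edit_state,
         scan_id = scan_id, block_index = as.integer(block_index),
         preprocessed = isTRUE(preprocessed),
         phase_applied = phase_applied, shift_applied = shift_applied,
         center_ppm = center_ppm),
    class = "block_spectrum")
}

# ppm per point, strictly decreasing left -> right
ppm_axis <- function(n, f0, dwell, center_ppm = 4.7) {
  freq <- (seq_len(n) - 1 - n / 2) / (n * dwell)   # Hz, ascending
  rev(center_ppm + freq / f0)
}

# FFT conventions: a time-domain component exp(2i*pi*f*t) lands at +f.
# spectrum_from_fid returns complex values ordered by *decreasing* ppm.
spectrum_from_fid <- function(fid) {
  n <- length(fid)
  s <- stats::fft(fid)
  half <- n %/% 2L
  rev(c(s[(half + 1L):n], s[1:half]))  # ascending freq, then flipped to ppm order
}

fid_from_spectrum <- function(values) {
  n <- length(values)
  half <- n %/% 2L
  s_ord <- rev(values)                       # ascending frequency
  s <- c(s_ord[(half + 1L):n], s_ord[1:half])
  stats::fft(s, inverse = TRUE) / n
}

#' @export
print.block_spectrum <- function(x, ...) {
  cat(sprintf("<block_spectrum> %s block %d (%s), %d points, ppm %.2f..%.2f%s\n",
              x$scan_id, x$block_index, x$edit_state, length(x$values),
              max(x$ppm), min(x$ppm),
              if (x$preprocessed) ", preprocessed" else ""))
  invisible(x)
}

#' Construct an edited scan
#'
#' Bundles equal numbers of On- and Off-resonance block spectra with the
#' acquisition metadata of an edited (MEGA-PRESS style) scan.
#'
#' @param on_blocks,off_blocks lists of [block_spectrum()] objects.
#' @param meta named list; defaults follow the acquisition protocol
#'   (TR/TE = 1500/68 ms, editing pulses at 1.9 ppm On / 7.5 ppm Off).
#' @return an object of class `edited_scan`.
#' @export
edited_scan <- function(on_blocks, off_blocks, meta = list()) {
  if (length(on_blocks) != length(off_blocks)) {
    stop("unequal counts of On (", length(on_blocks), ") and Off (",
         length(off_blocks), ") blocks")
  }
  meta_def <- list(tr_ms = 1500, te_ms = 68,
                   edit_on_ppm = 1.9, edit_off_ppm = 7.5)
  meta <- utils::modifyList(meta_def, meta)
  structure(list(on = on_blocks, off = off_blocks, meta = meta),
            class = "edited_scan")
}

#' @export
print.edited_scan <- function(x, ...) {
  cat(sprintf("<edited_scan> %d On + %d Off blocks, TR/TE %g/%g ms\n",
              length(x$on), length(x$off), x$meta$tr_ms, x$meta$te_ms))
  invisible(x)
}
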