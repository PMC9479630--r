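cr_line <- list(list(ppm = 3.00, amp = 1))

test_that("rda bundle round-trips exactly and validates its inputs", {
  scan <- synthesize_scan(0.09, snr = 30, seed = 4, n_blocks = 16)
  dir <- withr::local_tempdir()
  write_rda_bundle(scan, dir)
  expect_length(Sys.glob(file.path(dir, "block_*.rda")), 32L)

  back <- read_rda_bundle(dir)
  expect_length(back$on, 16L)
  expect_length(back$off, 16L)
  expect_identical(back$off[[3]]$values, scan$off[[3]]$values)
  expect_identical(back$on[[16]]$values, scan$on[[16]]$values)
  expect_equal(back$off[[1]]$ppm, scan$off[[1]]$ppm)

  # a second write must reproduce the files byte for byte
  dir2 <- withr::local_tempdir()
  write_rda_bundle(back, dir2)
  f <- "block_Off_007.rda"
  expect_identical(readLines(file.path(dir2, f)),
                   readLines(file.path(dir, f)))

  # malformed inputs fail naming the problem
  bad <- file.path(dir, "block_Off_001.rda")
  lines <- readLines(bad)
  writeLines(lines[-length(lines)], bad)       # 1023 data lines
  expect_error(read_rda_bundle(dir), "point count")
  writeLines(lines[-grep("^EditState", lines)], bad)
  expect_error(read_rda_bundle(dir), "EditState")
})

test_that("preprocessing zero-pads, broadens, and preserves peak position", {
  b <- make_block(cr_line)
  p <- preprocess(b)
  expect_length(p$values, 4096L)
  expect_true(p$preprocessed)
  expect_error(preprocess(p), "already preprocessed")

  # linearity: zero in, zero out
  z <- block_spectrum(complex(real = rep(0, 1024)), 123.25, 1 / 1200, "Off")
  expect_equal(max(Mod(preprocess(z)$values)), 0)

  # a noiseless 4-Hz Lorentzian gains width from the 4-Hz Gaussian window
  # but stays centered: compare against direct linewidth measurement
  lor <- make_block(cr_line, lorentzian = TRUE, lb0 = 4)
  pl <- preprocess(lor)
  fw <- measure_fwhm_hz(pl, 3.00)
  expect_gt(fw, 4)
  expect_lt(fw, 10)
  pk <- pl$ppm[which.max(Re(pl$values))]
  expect_lt(abs(pk - 3.00), diff(range(pl$ppm)) / 4096 * 1.5)
})

test_that("creatine-referenced correction inverts a known corruption", {
  corrupted <- preprocess(make_block(cr_line, phase = 0.5, shift_ppm = 0.02))
  corr <- phase_and_frequency_correct(corrupted)
  expect_false(corr$uncorrectable)
  expect_lt(abs(corr$phase - 0.5), 0.05)
  # feature sits at 3.02; the correction must move it back by -0.02
  expect_lt(abs(corr$shift - (-0.02)), 0.005)

  fixed <- apply_pair_correction(corrupted, corr)
  clean <- preprocess(make_block(cr_line))
  i <- which(fixed$ppm >= 2.9 & fixed$ppm <= 3.1)
  expect_lt(max(Mod(fixed$values[i] - clean$values[i])) /
              max(Mod(clean$values[i])), 0.05)

  # an already-corrected block is a fixed point
  corr2 <- phase_and_frequency_correct(clean)
  expect_lt(abs(corr2$phase), 0.02)
  expect_lt(abs(corr2$shift), 0.002)

  # pure noise carries no creatine reference
  noise <- preprocess(make_block(list(), noise_sd = 1, seed = 9))
  expect_true(phase_and_frequency_correct(noise)$uncorrectable)
})

test_that("pair correction is identity at (0, 0) and guards pairing", {
  b <- preprocess(make_block(cr_line, block_index = 2L))
  ident <- apply_pair_correction(
    b, list(phase = 0, shift = 0, block_index = 2L))
  expect_equal(ident$values, b$values)
  expect_error(
    apply_pair_correction(b, list(phase = 0, shift = 0, block_index = 5L)),
    "unpaired")
})

test_that("QC tallies deviant bins and excludes only the corrupted block", {
  # identical blocks: zero spread, zero deviants, zero exclusions
  flat <- synthesize_scan(0.09, snr = Inf, seed = 1, n_blocks = 4,
                          phase_jitter_sd = 0, shift_jitter_sd = 0)
  qc0 <- qc_blocks(flat)
  expect_equal(sum(qc0$table$deviant_count), 0L)
  expect_equal(qc0$exclusion_fraction, 0)

  # plant a +10 SD artifact in 600 bins of one On block
  scan <- synthesize_scan(0.09, snr = 30, seed = 5, n_blocks = 8)
  scan2 <- lapply(scan$on, preprocess)
  scan2off <- lapply(scan$off, preprocess)
  mat <- vapply(scan2, function(b) Re(b$values), numeric(4096))
  sdv <- apply(mat, 1, sd)
  bins <- 301:900
  scan2[[3]]$values[bins] <- scan2[[3]]$values[bins] + 10 * mean(sdv)
  qc <- qc_blocks(edited_scan(scan2, scan2off), max_deviant = 410)
  excl <- qc$excluded
  expect_equal(nrow(excl), 1L)
  expect_equal(excl$state, "On")
  expect_equal(excl$block_index, scan2[[3]]$block_index)

  # exclusion-only contract: retained block values untouched by QC
  ds <- difference_and_sum(edited_scan(scan2, scan2off), qc)
  manual_on <- Reduce(`+`, lapply(scan2[-3], function(b) b$values)) / 7
  manual_off <- Reduce(`+`, lapply(scan2off, function(b) b$values)) / 8
  expect_equal(ds$diff$values, manual_on - manual_off)

  # planted corruption rate is recovered in the exclusion fraction
  expect_equal(qc$exclusion_fraction, 1 / 16)
})

test_that("difference/sum cancels shared lines and is linear", {
  blocks <- lapply(1:3, function(i) make_block(cr_line, block_index = i))
  same <- edited_scan(blocks, blocks)
  ds <- difference_and_sum(same)
  expect_equal(max(Mod(ds$diff$values)), 0)

  onb <- lapply(1:3, function(i) {
    make_block(c(cr_line, list(list(ppm = 3.015, amp = 0.1))),
               block_index = i, edit_state = "On")
  })
  ds2 <- difference_and_sum(edited_scan(onb, blocks))
  expect_gt(integrate_peak(ds2$diff, 2.85, 3.15), 0)

  doubled <- edited_scan(lapply(onb, function(b) { b$values <- 2 * b$values; b }),
                         lapply(blocks, function(b) { b$values <- 2 * b$values; b }))
  ds3 <- difference_and_sum(doubled)
  expect_equal(ds3$diff$values, 2 * ds2$diff$values)
  expect_equal(ds3$summed$values, 2 * ds2$summed$values)
})

test_that("peak integration matches the closed-form Gaussian area", {
  n <- 4096
  ppm <- gabasupp:::ppm_axis(n, 123.25, 1 / 1200)
  A <- 3; sig <- 0.02; mu <- 3.0
  spec <- list(values = complex(real = A * exp(-(ppm - mu)^2 / (2 * sig^2))),
               ppm = ppm)
  expect_equal(integrate_peak(spec, mu - 5 * sig, mu + 5 * sig),
               A * sig * sqrt(2 * pi), tolerance = 0.005)
  zero <- list(values = complex(real = rep(0, n)), ppm = ppm)
  expect_equal(integrate_peak(zero, 2.85, 3.15), 0)
  expect_error(integrate_peak(spec, 3.15, 2.85), "ppm_lo")
  expect_error(integrate_peak(spec, -2, 0), "outside")
})

test_that("planted GABA:Cr is recovered by the full chain", {
  # noiseless: within the 2% window-leakage bound
  sc <- synthesize_scan(0.09, snr = Inf, seed = 1, n_blocks = 4)
  est <- gaba_cr_ratio(sc)
  expect_lt(abs(est$gaba_cr - 0.09), 0.002)
  expect_equal(est$gaba_cr, est$gaba_area / est$cr_area)

  # null metabolite: difference-spectrum window area vanishes
  sc0 <- synthesize_scan(0, snr = Inf, seed = 1, n_blocks = 4)
  expect_lt(abs(gaba_cr_ratio(sc0)$gaba_cr), 1e-6)

  # determinism
  expect_identical(synthesize_scan(0.09, snr = 25, seed = 7, n_blocks = 4),
                   synthesize_scan(0.09, snr = 25, seed = 7, n_blocks = 4))

  # scale invariance of the ratio under global amplitude scaling
  sc2 <- sc
  sc2$on <- lapply(sc$on, function(b) { b$values <- 2 * b$values; b })
  sc2$off <- lapply(sc$off, function(b) { b$values <- 2 * b$values; b })
  expect_equal(gaba_cr_ratio(sc2)$gaba_cr, est$gaba_cr, tolerance = 1e-6)

  # monotonicity in the planted value (noiseless)
  ests <- vapply(c(0.03, 0.06, 0.09, 0.12), function(r) {
    gaba_cr_ratio(synthesize_scan(r, snr = Inf, seed = 2, n_blocks = 4))$gaba_cr
  }, 0)
  expect_true(all(diff(ests) > 0))

  expect_error(synthesize_scan(0.09, snr = -1), "snr")
  expect_error(synthesize_scan(-0.1), "true_gaba_cr")
})

test_that("noisy quantification is unbiased within 5% across scans and seeds", {
  means <- vapply(1:50, function(s) {
    mean(vapply(1:8, function(k) {
      sc <- synthesize_scan(0.09, snr = 20, seed = 1000 * s + k, n_blocks = 8)
      gaba_cr_ratio(sc)$gaba_cr
    }, 0))
  }, 0)
  expect_lt(abs(mean(means) - 0.09) / 0.09, 0.05)
})
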