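test_that("cohort generation is deterministic and validates its spec", {
  a <- generate_cohort(cohort_spec(n_pwa = 6, n_nsp = 5, seed = 5))
  b <- generate_cohort(cohort_spec(n_pwa = 6, n_nsp = 5, seed = 5))
  expect_identical(a, b)
  expect_false(identical(
    a, generate_cohort(cohort_spec(n_pwa = 6, n_nsp = 5, seed = 6))))

  expect_error(cohort_spec(n_pwa = 2), "n_pwa")
  expect_error(cohort_spec(rho_gaba_depth = -1.2), "rho_gaba_depth")
  expect_error(cohort_spec(gaba_sd = 0), "gaba_sd")
  expect_error(cohort_spec(snr_spectra = 0), "snr_spectra")
  w <- default_suppression_weights(); w$w[1] <- -0.1
  expect_error(cohort_spec(suppression_weights = w), "suppression_weights")
})

test_that("the Gaussian copula plants the requested rank correlation", {
  co <- generate_cohort(cohort_spec(n_pwa = 500, n_nsp = 3,
                                    rho_gaba_depth = -0.61, seed = 2))
  g <- co$truth$gaba$gaba_cr[seq_len(500)]
  d <- co$truth$depth$depth
  rho <- spearman_rho(g, d)
  expect_gt(rho, -0.71)
  expect_lt(rho, -0.51)

  co0 <- generate_cohort(cohort_spec(n_pwa = 500, n_nsp = 3,
                                     rho_gaba_depth = 0, seed = 3))
  expect_lt(abs(spearman_rho(co0$truth$gaba$gaba_cr[seq_len(500)],
                             co0$truth$depth$depth)), 0.15)
})

test_that("generated records satisfy the clinical invariants", {
  co <- generate_cohort(cohort_spec(n_pwa = 40, n_nsp = 20, seed = 9))
  rec <- co$records
  pwa <- rec[rec$group == "PWA", ]
  expect_true(all(pwa$acuity_nde_logmar > pwa$acuity_de_logmar))
  expect_true(all(depth_of_amblyopia(pwa) > 0))
  nsp <- rec[rec$group == "NSP", ]
  expect_true(all(abs(nsp$acuity_nde_logmar - nsp$acuity_de_logmar) < 0.3))
  bl <- co$truth$baselines
  expect_true(all(bl$threshold > 0 & bl$threshold < 1))
  # planted amblyopic-eye baseline elevation
  wide <- reshape(bl[, c("subject_id", "eye", "threshold")],
                  idvar = "subject_id", timevar = "eye", direction = "wide")
  expect_true(all(wide$threshold.NDE >= wide$threshold.DE))
})

test_that("the packaged clinical table matches its source values", {
  rec <- load_table1_fixture()
  expect_equal(nrow(rec), 16L)
  a1 <- rec[rec$subject_id == "A1", ]
  expect_equal(a1$acuity_nde_logmar, 0.418)
  expect_equal(a1$acuity_de_logmar, -0.097)
  expect_equal(depth_of_amblyopia(a1), 0.515)
  expect_equal(sum(rec$amb_type == "Aniso"), 12L)
  expect_setequal(rec$subject_id[rec$mrs_quality_flag], c("A5", "A10"))
  m2 <- rec[rec$subject_id == "M2", ]
  expect_equal(depth_of_amblyopia(m2), 1.261)
  expect_error(load_table1_fixture("/nonexistent/table.csv"), "not found")
})

test_that("synthesized scans have the protocol geometry", {
  sc <- synthesize_scan(0.09, snr = 40, seed = 1)
  expect_length(sc$on, 16L)
  expect_length(sc$off, 16L)
  expect_length(sc$off[[1]]$values, 1024L)
  expect_equal(sc$meta$tr_ms, 1500)
  expect_equal(sc$meta$edit_on_ppm, 1.9)
  expect_true(all(diff(sc$off[[1]]$ppm) < 0))    # ppm decreasing left->right
})

test_that("simulated sessions cover every cell with enough staircases", {
  co <- generate_cohort(cohort_spec(n_pwa = 3, n_nsp = 3, seed = 8,
                                    surround_contrasts = c(0.1, 0.4)))
  sim <- simulate_sessions(co)
  tr <- sim$trials
  key <- paste(tr$subject_id, tr$eye, tr$ocular_config, tr$orientation,
               ifelse(is.na(tr$surround_contrast), "none",
                      tr$surround_contrast))
  n_stair <- tapply(tr$staircase_id, key, function(s) length(unique(s)))
  expect_true(all(n_stair >= 4L))
  # 2 eyes x (baseline + 2 configs x 2 orientations x 2 contrasts) per subject
  expect_equal(length(n_stair), 6L * 2L * (1L + 8L))
  # baseline rows carry no surround fields
  expect_true(all(is.na(tr$surround_contrast[tr$ocular_config == "baseline"])))
  expect_true(all(tr$orientation[tr$ocular_config == "baseline"] == "none"))
  # determinism at fixed seed
  expect_identical(sim$trials, simulate_sessions(co)$trials)
  # generating thresholds equal baseline x multiplier
  cells <- sim$cells
  base <- cells[cells$ocular_config == "baseline", ]
  t0 <- setNames(base$alpha_true, paste(base$subject_id, base$eye))
  surr <- cells[cells$ocular_config != "baseline", ]
  w <- co$truth$weights
  grp <- co$records$group[match(surr$subject_id, co$records$subject_id)]
  wi <- mapply(function(g, e, cfg, o) {
    w$w[w$group == g & w$eye == e & w$ocular_config == cfg & w$orientation == o]
  }, grp, surr$eye_label, surr$ocular_config, surr$orientation)
  t0s <- t0[paste(surr$subject_id, surr$eye)]
  expect_equal(surr$alpha_true,
               unname(t0s * (1 + wi * surr$surround_contrast / t0s)))
  expect_true(all(surr$alpha_true >= t0s))       # suppression, not facilitation
})

test_that("a flat (weight-zero) cohort yields relative thresholds near 1", {
  w0 <- default_suppression_weights(); w0$w <- 0
  co <- generate_cohort(cohort_spec(n_pwa = 3, n_nsp = 3, seed = 12,
                                    suppression_weights = w0,
                                    surround_contrasts = c(0.1, 0.4)))
  sim <- simulate_sessions(co)
  # no suppression anywhere: the data-driven selection must refuse
  ana <- analyze_cohort(co$records, sim$trials, c_star = 5)
  expect_lt(abs(mean(ana$points$t_rel) - 1), 0.1)
  expect_lt(abs(median(ana$points$t_rel) - 1), 0.1)
})
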