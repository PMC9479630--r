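#' Cohort specification for the synthetic-data generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: group sizes
#' (matching the study: 16 persons with amblyopia, PWA, and 15 normally
#' sighted persons, NSP), the planted rank correlation between visual-cortical
#' GABA:Cr and depth of amblyopia, the GABA:Cr margin, acuity ranges, the
#' surround-suppression weight table, the psychometric observer, and spectral
#' SNR.
#'
#' @param n_pwa,n_nsp group sizes (each >= 3).
#' @param rho_gaba_depth target Spearman correlation in `[-1, 1]` between true
#'   GABA:Cr and depth of amblyopia among PWA (study estimate: -0.61).
#' @param gaba_mean,gaba_sd GABA:Cr margin (dimensionless; mean 0.09 with SD
#'   chosen to match a standard error of 0.001 at n = 14).
#' @param acuity_de_range uniform range (logMAR) of the dominant-eye acuity
#'   for PWA.
#' @param depth_meanlog,depth_sdlog log-normal margin of the depth of
#'   amblyopia (interocular logMAR difference); defaults reproduce the spread
#'   of the packaged clinical table (median ~0.48 logMAR).
#' @param nsp_acuity_sd SD of NSP acuities around 0 logMAR (both eyes, near
#'   zero interocular difference).
#' @param suppression_weights data frame mapping (group, eye, ocular_config,
#'   orientation) to the surround weight `w` in the multiplier
#'   `1 + w * C_rel`; defaults from [default_suppression_weights()].
#' @param baseline_de_meanlog,baseline_de_sdlog log-normal margin of the true
#'   dominant-eye baseline contrast discrimination threshold.
#' @param nde_baseline_slope amblyopic-eye baseline elevation per logMAR of
#'   depth: `T0_NDE = T0_DE * (1 + slope * depth)`.
#' @param observer_beta,observer_lapse Weibull observer parameters.
#' @param surround_contrasts Michelson contrasts of the tested surrounds
#'   (identical across conditions within a participant, as in the task
#'   design).
#' @param staircases_per_cell staircases per condition per surround contrast
#'   (>= 4).
#' @param snr_spectra amplitude SNR of synthetic spectra.
#' @param seed integer; identical seeds give bit-identical cohorts.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pwa = 16L, n_nsp = 15L,
                        rho_gaba_depth = -0.61,
                        gaba_mean = 0.09, gaba_sd = 0.004,
                        acuity_de_range = c(-0.20, 0.08),
                        depth_meanlog = log(0.48), depth_sdlog = 0.4,
                        nsp_acuity_sd = 0.03,
                        suppression_weights = default_suppression_weights(),
                        baseline_de_meanlog = log(0.03),
                        baseline_de_sdlog = 0.25,
                        nde_baseline_slope = 1.5,
                        observer_beta = 3, observer_lapse = 0.02,
                        surround_contrasts = c(0.08, 0.17, 0.40, 0.90),
                        staircases_per_cell = 4L,
                        snr_spectra = 60,
                        seed = 1L) {
  if (n_pwa < 3L) stop("invalid cohort spec: n_pwa must be >= 3")
  if (n_nsp < 3L) stop("invalid cohort spec: n_nsp must be >= 3")
  if (abs(rho_gaba_depth) > 1) {
    stop("invalid cohort spec: rho_gaba_depth must be in [-1, 1]")
  }
  if (gaba_sd <= 0) stop("invalid cohort spec: gaba_sd must be > 0")
  if (any(suppression_weights$w < 0)) {
    stop("invalid cohort spec: suppression_weights must be >= 0")
  }
  if (snr_spectra <= 0) stop("invalid cohort spec: snr_spectra must be > 0")
  if (staircases_per_cell < 4L) {
    stop("invalid cohort spec: staircases_per_cell must be >= 4")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Default surround-suppression weight table
#'
#' Condition-specific weights `w` of the multiplicative threshold-elevation
#' model `threshold = baseline * (1 + w * C_rel)`, where `C_rel` is the
#' surround contrast in units of the annulus-viewing eye's baseline
#' threshold. Defaults plant iso > cross orientation selectivity in every
#' cell, and for PWA a strongly asymmetric dichoptic pattern: the dominant
#' eye suppresses the amblyopic (non-dominant) eye far more than the reverse,
#' and the amblyopic eye also shows stronger monocular suppression.
#'
#' @param pwa_asymmetry set to `FALSE` to plant a symmetric (null) PWA
#'   pattern identical to NSP, for false-positive checks.
#' @return data frame with columns group, eye, ocular_config, orientation, w.
#' @export
default_suppression_weights <- function(pwa_asymmetry = TRUE) {
  g <- expand.grid(group = c("PWA", "NSP"), eye = c("DE", "NDE"),
                   ocular_config = c("monocular", "dichoptic"),
                   orientation = c("iso", "cross"),
                   stringsAsFactors = FALSE)
  w_nsp <- function(config, orient) {
    ifelse(config == "monocular",
           ifelse(orient == "iso", 0.20, 0.09),
           ifelse(orient == "iso", 0.12, 0.05))
  }
  w_pwa <- function(eye, config, orient) {
    ifelse(config == "dichoptic" & eye == "NDE",
           ifelse(orient == "iso", 0.35, 0.20),
    ifelse(config == "dichoptic" & eye == "DE",
           ifelse(orient == "iso", 0.08, 0.04),
    ifelse(eye == "NDE",                           # monocular
           ifelse(orient == "iso", 0.28, 0.13),
           ifelse(orient == "iso", 0.16, 0.07))))
  }
  g$w <- ifelse(g$group == "NSP" | !pwa_asymmetry,
                w_nsp(g$ocular_config, g$orientation),
                w_pwa(g$eye, g$ocular_config, g$orientation))
  g
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a clinical table and the latent quantities every downstream stage is
#' later asked to recover. Among PWA, true GABA:Cr and depth of amblyopia are
#' coupled through a Gaussian copula whose correlation is chosen (via the
#' `2 sin(pi rho / 6)` relation) so that the population Spearman correlation
#' equals `spec$rho_gaba_depth`; both margins are monotone transforms of the
#' latent normals, so the planted rank correlation survives the margins
#' exactly. NSP GABA:Cr is drawn independently and NSP acuities sit near 0
#' logMAR in both eyes.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `amb_cohort`: list with `records` (the clinical
#'   table: subject_id, group, age, sex, amb_type, amb_eye, acuity
#'   per eye, mrs_quality_flag) and `truth` (per-subject true GABA:Cr,
#'   per-eye true baseline thresholds with their physical-eye assignment,
#'   and the suppression weight table).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n_p <- spec$n_pwa; n_n <- spec$n_nsp
    r_lat <- 2 * sin(pi * spec$rho_gaba_depth / 6)

    z1 <- stats::rnorm(n_p)
    z2 <- r_lat * z1 + sqrt(1 - r_lat^2) * stats::rnorm(n_p)
    gaba_p <- pmax(spec$gaba_mean + spec$gaba_sd * z1, 0.01)
    depth <- stats::qlnorm(stats::pnorm(z2), spec$depth_meanlog,
                           spec$depth_sdlog)
    ac_de <- stats::runif(n_p, spec$acuity_de_range[1],
                          spec$acuity_de_range[2])
    amb_eye <- sample(c("OS", "OD"), n_p, replace = TRUE, prob = c(0.7, 0.3))
    pwa <- data.frame(
      subject_id = sprintf("P%02d", seq_len(n_p)), group = "PWA",
      age = sample(19:61, n_p, replace = TRUE),
      sex = sample(c("F", "M"), n_p, replace = TRUE),
      amb_type = sample(c("Aniso", "Mixed"), n_p, replace = TRUE,
                        prob = c(0.75, 0.25)),
      amb_eye = amb_eye,
      acuity_de_logmar = ac_de, acuity_nde_logmar = ac_de + depth,
      stereo_arcsec = NA_real_, mrs_quality_flag = FALSE)

    gaba_n <- pmax(spec$gaba_mean + spec$gaba_sd * stats::rnorm(n_n), 0.01)
    nsp <- data.frame(
      subject_id = sprintf("N%02d", seq_len(n_n)), group = "NSP",
      age = sample(19:61, n_n, replace = TRUE),
      sex = sample(c("F", "M"), n_n, replace = TRUE),
      amb_type = "none", amb_eye = "none",
      acuity_de_logmar = stats::rnorm(n_n, 0, spec$nsp_acuity_sd),
      acuity_nde_logmar = stats::rnorm(n_n, 0, spec$nsp_acuity_sd),
      stereo_arcsec = NA_real_, mrs_quality_flag = FALSE)
    records <- rbind(pwa, nsp)

    # true baseline thresholds per eye; for NSP the true NDE is the eye with
    # the (slightly) higher threshold, mirroring the operational definition
    t0_de <- stats::rlnorm(n_p + n_n, spec$baseline_de_meanlog,
                           spec$baseline_de_sdlog)
    elev <- c(1 + spec$nde_baseline_slope * depth,
              exp(abs(stats::rnorm(n_n, 0, 0.10))))
    t0_nde <- t0_de * elev
    nde_phys <- c(pwa$amb_eye, sample(c("OS", "OD"), n_n, replace = TRUE))
    baselines <- data.frame(
      subject_id = rep(records$subject_id, 2L),
      eye = rep(c("DE", "NDE"), each = n_p + n_n),
      eye_physical = c(ifelse(nde_phys == "OS", "OD", "OS"), nde_phys),
      threshold = c(t0_de, t0_nde))

    truth <- list(gaba = data.frame(subject_id = records$subject_id,
                                    gaba_cr = c(gaba_p, gaba_n)),
                  baselines = baselines,
                  weights = spec$suppression_weights,
                  depth = data.frame(subject_id = pwa$subject_id,
                                     depth = depth))
    structure(list(records = records, truth = truth, spec = spec),
              class = "amb_cohort")
  })
}

#' @export
print.amb_cohort <- function(x, ...) {
  cat(sprintf("<amb_cohort> %d PWA + %d NSP (seed %d), planted rho(GABA, depth) = %.2f\n",
              sum(x$records$group == "PWA"), sum(x$records$group == "NSP"),
              x$spec$seed, x$spec$rho_gaba_depth))
  invisible(x)
}

#' Load the packaged clinical table of persons with amblyopia
#'
#' Reads the packaged 16-row clinical fixture (subject id, age, sex,
#' amblyopia type, amblyopic eye, per-eye logMAR acuity, MRS quality flag;
#' two subjects carry `mrs_quality_flag = TRUE`, marking scans discarded for
#' head motion / inadequate correction).
#'
#' @param path override the packaged file (for testing).
#' @return data frame of 16 subject records.
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_pwa.csv", package = "gabasupp")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("clinical table fixture not found")
  }
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "amb_type", "amb_eye",
            "acuity_de_logmar", "acuity_nde_logmar", "mrs_quality_flag")
  if (!all(need %in% names(rec)) || nrow(rec) != 16L) {
    stop("clinical table fixture is corrupt")
  }
  if (any(rec$acuity_nde_logmar <= rec$acuity_de_logmar)) {
    stop("clinical table fixture is corrupt: amblyopic eye must be worse")
  }
  rec
}

#' Simulate psychophysical sessions for a cohort
#'
#' Plays a 4AFC Weibull observer through the full factorial design: for each
#' subject and eye, a no-surround baseline condition plus 2 (ocular
#' configuration) x 2 (surround orientation) conditions at each tested
#' surround contrast, with `spec$staircases_per_cell` staircases per cell.
#' The generating threshold of a surround cell is
#' `baseline * (1 + w * C / baseline)` with the condition's weight `w`;
#' baseline cells generate at the baseline threshold itself.
#'
#' @param cohort an `amb_cohort` from [generate_cohort()].
#' @param config a [staircase_config()]; the start increment of each
#'   staircase is 10x the generating threshold (capped at the ceiling).
#' @param subjects optional subset of subject ids to simulate.
#' @return object of class `session_sim`: `trials` (the trial log: subject_id,
#'   eye = physical eye code, ocular_config, orientation, surround_contrast,
#'   staircase_id, trial_index, increment, correct) and `cells` (per-cell
#'   generating thresholds, the recovery oracle).
#' @export
simulate_sessions <- function(cohort, config = staircase_config(),
                              subjects = NULL) {
  stopifnot(inherits(cohort, "amb_cohort"))
  spec <- cohort$spec
  recs <- cohort$records
  if (!is.null(subjects)) recs <- recs[recs$subject_id %in% subjects, ]
  bl <- cohort$truth$baselines
  wt <- cohort$truth$weights

  with_seed(spec$seed + 104729L, {
    acc <- vector("list", 0L)
    cells <- vector("list", 0L)
    for (i in seq_len(nrow(recs))) {
      rec <- recs[i, ]
      for (eye_lab in c("DE", "NDE")) {
        b <- bl[bl$subject_id == rec$subject_id & bl$eye == eye_lab, ]
        if (nrow(b) != 1L) {
          stop("ground truth is missing baseline for cell ",
               rec$subject_id, "/", eye_lab)
        }
        t0 <- b$threshold; eye_phys <- b$eye_physical
        grid <- rbind(
          data.frame(ocular_config = "baseline", orientation = "none",
                     surround_contrast = NA_real_),
          expand.grid(ocular_config = c("monocular", "dichoptic"),
                      orientation = c("iso", "cross"),
                      surround_contrast = spec$surround_contrasts,
                      stringsAsFactors = FALSE))
        for (j in seq_len(nrow(grid))) {
          cfg_row <- grid[j, ]
          if (cfg_row$ocular_config == "baseline") {
            alpha <- t0
          } else {
            w <- wt$w[wt$group == rec$group & wt$eye == eye_lab &
                        wt$ocular_config == cfg_row$ocular_config &
                        wt$orientation == cfg_row$orientation]
            if (length(w) != 1L) {
              stop("ground truth is missing suppression weight for cell ",
                   rec$subject_id, "/", eye_lab, "/", cfg_row$ocular_config,
                   "/", cfg_row$orientation)
            }
            alpha <- t0 * (1 + w * cfg_row$surround_contrast / t0)
          }
          cells[[length(cells) + 1L]] <- data.frame(
            subject_id = rec$subject_id, eye = eye_phys,
            eye_label = eye_lab, ocular_config = cfg_row$ocular_config,
            orientation = cfg_row$orientation,
            surround_contrast = cfg_row$surround_contrast,
            alpha_true = alpha)
          responder <- weibull_responder(alpha, spec$observer_beta,
                                         spec$observer_lapse)
          cfg <- config
          cfg$start_increment <- min(10 * alpha, config$ceiling)
          for (s in seq_len(spec$staircases_per_cell)) {
            run <- run_staircase(responder, cfg)
            nt <- run$outcome$n_trials
            acc[[length(acc) + 1L]] <- list(
              subject_id = rep(rec$subject_id, nt),
              eye = rep(eye_phys, nt),
              ocular_config = rep(cfg_row$ocular_config, nt),
              orientation = rep(cfg_row$orientation, nt),
              surround_contrast = rep(cfg_row$surround_contrast, nt),
              staircase_id = rep(sprintf("%s_%s_%s_%s_c%.3f_s%d",
                                         rec$subject_id, eye_phys,
                                         cfg_row$ocular_config,
                                         cfg_row$orientation,
                                         cfg_row$surround_contrast %|NA|% 0,
                                         s), nt),
              trial_index = seq_len(nt),
              increment = run$trials$increment,
              correct = run$trials$correct)
          }
        }
      }
    }
    trials <- data.frame(
      subject_id = unlist(lapply(acc, `[[`, "subject_id")),
      eye = unlist(lapply(acc, `[[`, "eye")),
      ocular_config = unlist(lapply(acc, `[[`, "ocular_config")),
      orientation = unlist(lapply(acc, `[[`, "orientation")),
      surround_contrast = unlist(lapply(acc, `[[`, "surround_contrast")),
      staircase_id = unlist(lapply(acc, `[[`, "staircase_id")),
      trial_index = unlist(lapply(acc, `[[`, "trial_index")),
      increment = unlist(lapply(acc, `[[`, "increment")),
      correct = unlist(lapply(acc, `[[`, "correct")))
    structure(list(trials = trials, cells = do.call(rbind, cells),
                   config = config),
              class = "session_sim")
  })
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Synthesize MRS scans for every cohort subject and quantify them
#'
#' Generates `scans_per_subject` edited scans per subject at the cohort's
#' spectral SNR, each planting the subject's true GABA:Cr, runs the full
#' quantification chain, and returns the per-subject table the downstream
#' correlation analyses consume.
#'
#' @param cohort an `amb_cohort`.
#' @param scans_per_subject scans averaged per subject (the protocol acquires
#'   several per voxel across visual stimulation conditions).
#' @param n_blocks blocks per editing state per scan (16 in the full
#'   protocol; smaller values trade fidelity for speed).
#' @param region label stamped on the output rows.
#' @return data frame: subject_id, region, gaba_cr, n_blocks_used,
#'   exclusion_fraction.
#' @export
quantify_cohort_mrs <- function(cohort, scans_per_subject = 4L,
                                n_blocks = 16L, region = "visual") {
  stopifnot(inherits(cohort, "amb_cohort"))
  tg <- cohort$truth$gaba
  rows <- lapply(seq_len(nrow(tg)), function(i) {
    ests <- lapply(seq_len(scans_per_subject), function(k) {
      sc <- synthesize_scan(tg$gaba_cr[i], snr = cohort$spec$snr_spectra,
                            seed = (cohort$spec$seed * 1009 + i * 37 + k) %%
                              2147483647,
                            n_blocks = n_blocks,
                            scan_id = paste0(tg$subject_id[i], "_", k))
      gaba_cr_ratio(sc)
    })
    vals <- vapply(ests, function(e) e$gaba_cr, 0)
    data.frame(subject_id = tg$subject_id[i], region = region,
               gaba_cr = mean(vals, na.rm = TRUE),
               n_blocks_used = mean(vapply(ests, function(e)
                 e$n_blocks_used, 0)),
               exclusion_fraction = mean(vapply(ests, function(e)
                 e$exclusion_fraction, 0)))
  })
  do.call(rbind, rows)
}
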