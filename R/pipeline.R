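#' Analyze a cohort's thresholds, clinical table, and MRS values
#'
#' The full behavioral analysis: replays the trial log through the staircase
#' rule, aggregates staircases into cell thresholds, assigns DE/NDE labels
#' (clinically for PWA, by measured baseline threshold for NSP),
#' baseline-normalizes thresholds and surround contrasts, selects (or takes)
#' the reference relative surround contrast, extracts one relative threshold
#' per subject-eye-condition, and computes interocular suppression ratios,
#' orientation-selectivity ratios, and depth of amblyopia, merged with
#' per-subject GABA:Cr values when provided.
#'
#' @param records clinical table (see [generate_cohort()] /
#'   [load_table1_fixture()]).
#' @param trials trial-log data frame (see [simulate_sessions()]).
#' @param mrs optional data frame with `subject_id` and `gaba_cr`.
#' @param config the [staircase_config()] used for data collection.
#' @param c_star `"auto"` to select the reference relative surround contrast
#'   from the data, or a numeric value (the robustness range of interest is
#'   2-10).
#' @return object of class `supp_analysis`: cell thresholds, normalized
#'   points, the reference-contrast selection audit, selected points,
#'   suppression and orientation-selectivity ratio tables, and a per-subject
#'   summary (depth of amblyopia, GABA:Cr).
#' @export
analyze_cohort <- function(records, trials, mrs = NULL,
                           config = staircase_config(), c_star = "auto") {
  stair <- fit_thresholds(trials, config)
  cells <- aggregate_cells(stair)

  # measured baselines per physical eye -> DE/NDE labels per subject
  base <- cells[cells$ocular_config == "baseline", ]
  labels <- list()
  for (sid in unique(cells$subject_id)) {
    rec <- records[records$subject_id == sid, ]
    if (nrow(rec) != 1L) stop("no clinical record for subject ", sid)
    bsub <- base[base$subject_id == sid, ]
    bt <- stats::setNames(bsub$threshold, bsub$eye)
    labels[[sid]] <- assign_eye_dominance(rec, bt)
  }
  cells$eye_label <- vapply(seq_len(nrow(cells)), function(i) {
    unname(labels[[cells$subject_id[i]]][[cells$eye[i]]])
  }, "")

  points <- normalize_points(cells)
  sel <- if (identical(c_star, "auto")) {
    select_reference_contrast(points)
  } else {
    structure(list(c_star = as.numeric(c_star), audit = NULL, reason = NULL),
              class = "cstar_selection")
  }
  if (is.na(sel$c_star)) {
    stop("no reference relative surround contrast could be selected: ",
         sel$reason)
  }
  selected <- nearest_points(points, sel$c_star)
  ratios <- suppression_ratio(selected)
  osss <- osss_ratio(selected)

  subjects <- records[records$subject_id %in% cells$subject_id,
                      c("subject_id", "group")]
  subjects$depth <- NA_real_
  is_pwa <- subjects$group == "PWA"
  subjects$depth[is_pwa] <-
    depth_of_amblyopia(records[match(subjects$subject_id[is_pwa],
                                     records$subject_id), ])
  if (!is.null(mrs)) {
    subjects$gaba_cr <- mrs$gaba_cr[match(subjects$subject_id,
                                          mrs$subject_id)]
  }
  selected$group <- subjects$group[match(selected$subject_id,
                                         subjects$subject_id)]
  structure(list(cells = cells, points = points, selection = sel,
                 selected = selected, ratios = ratios, osss = osss,
                 subjects = subjects, labels = labels, config = config),
            class = "supp_analysis")
}

#' @export
print.supp_analysis <- function(x, ...) {
  cat(sprintf("<supp_analysis> %d subjects, %d cells, reference C* = %.2f\n",
              nrow(x$subjects), nrow(x$cells), x$selection$c_star))
  cat(sprintf("  mean NDE:DE ratio (dichoptic): %.2f | mean iso:cross ratio: %.2f\n",
              mean(x$ratios$ratio[x$ratios$ocular_config == "dichoptic"]),
              mean(x$osss$ratio)))
  invisible(x)
}

#' Run the full synthetic study end to end
#'
#' Generates a cohort, synthesizes and quantifies edited MRS scans for every
#' subject, simulates psychophysical sessions, runs the suppression analysis,
#' and computes the headline inferential statistics: the permutation-tested
#' Spearman correlation between GABA:Cr and depth of amblyopia in PWA,
#' one-sample t-tests of the NDE:DE and iso:cross ratios against 1 per
#' condition and group, the interocular baseline threshold comparison, and
#' the omnibus factorial ANOVA.
#'
#' @param spec a [cohort_spec()].
#' @param scans_per_subject,n_blocks MRS simulation sizes (see
#'   [quantify_cohort_mrs()]).
#' @param n_perm permutation draws for correlation tests.
#' @param psychophysics_subjects optional subject-id subset for the
#'   behavioral arm (MRS is quantified for everyone).
#' @return object of class `study_result` with the cohort, MRS table,
#'   analysis, and `stats` list.
#' @export
run_study <- function(spec = cohort_spec(), scans_per_subject = 2L,
                      n_blocks = 8L, n_perm = 10000L,
                      psychophysics_subjects = NULL) {
  cohort <- generate_cohort(spec)
  mrs <- quantify_cohort_mrs(cohort, scans_per_subject = scans_per_subject,
                             n_blocks = n_blocks)
  sim <- simulate_sessions(cohort, subjects = psychophysics_subjects)
  ana <- analyze_cohort(cohort$records, sim$trials, mrs = mrs,
                        config = sim$config)

  pwa <- ana$subjects[ana$subjects$group == "PWA" &
                        !is.na(ana$subjects$gaba_cr), ]
  rho_depth <- if (nrow(pwa) >= 4L) {
    perm_test_rho(pwa$gaba_cr, pwa$depth, n_perm = n_perm,
                  seed = spec$seed + 7L)
  } else NULL

  ratio_tests <- lapply(split(ana$ratios,
                              list(ana$ratios$ocular_config,
                                   ana$ratios$orientation)), function(d) {
    d$group <- ana$subjects$group[match(d$subject_id,
                                        ana$subjects$subject_id)]
    lapply(split(d, d$group), function(g) {
      if (nrow(g) < 2L) return(NULL)
      c(list(mean_ratio = mean(g$ratio), n = nrow(g)),
        one_sample_t(g$ratio, 1))
    })
  })

  base <- ana$cells[ana$cells$ocular_config == "baseline", ]
  base_pwa <- base[ana$subjects$group[match(base$subject_id,
                                            ana$subjects$subject_id)] == "PWA", ]
  wide <- stats::reshape(base_pwa[, c("subject_id", "eye_label", "threshold")],
                         idvar = "subject_id", timevar = "eye_label",
                         direction = "wide")
  baseline_test <- if (nrow(wide) >= 3L && all(c("threshold.NDE",
                                                 "threshold.DE") %in% names(wide))) {
    ok <- stats::complete.cases(wide)
    c(one_sample_t(wide$threshold.NDE[ok] - wide$threshold.DE[ok], 0),
      cohens_d(wide$threshold.NDE[ok], wide$threshold.DE[ok]))
  } else NULL

  anova_tab <- omnibus_anova(ana$selected)

  structure(list(cohort = cohort, mrs = mrs, sessions = sim, analysis = ana,
                 stats = list(rho_gaba_depth = rho_depth,
                              ratio_tests = ratio_tests,
                              baseline_interocular = baseline_test,
                              anova = anova_tab)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  print(x$analysis)
  if (!is.null(x$stats$rho_gaba_depth)) {
    cat("GABA:Cr vs depth of amblyopia (PWA): ")
    print(x$stats$rho_gaba_depth)
  }
  invisible(x)
}
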