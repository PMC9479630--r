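#' Assign dominant / non-dominant eye labels
#'
#' For persons with amblyopia the amblyopic eye is the non-dominant eye (NDE)
#' and the fellow eye the dominant eye (DE), read from the clinical record.
#' For normally sighted persons the NDE is the eye with the higher baseline
#' (no-surround) contrast discrimination threshold; an exact tie is broken
#' deterministically in favour of the right eye as DE, with a warning.
#'
#' @param record one clinical record (a one-row data frame or list with
#'   `group` and `amb_eye`).
#' @param baseline_thresholds named numeric vector `c(OS = ..., OD = ...)` of
#'   measured baseline thresholds (required for NSP).
#' @return named character vector mapping physical eyes to labels, e.g.
#'   `c(OS = "NDE", OD = "DE")`.
#' @export
assign_eye_dominance <- function(record, baseline_thresholds = NULL) {
  if (record$group == "PWA") {
    if (!record$amb_eye %in% c("OS", "OD")) {
      stop("PWA record has no amblyopic-eye designation")
    }
    nde <- record$amb_eye
  } else {
    if (is.null(baseline_thresholds) ||
        !all(c("OS", "OD") %in% names(baseline_thresholds)) ||
        anyNA(baseline_thresholds[c("OS", "OD")])) {
      stop("NSP dominance assignment needs baseline thresholds for both eyes")
    }
    bt <- baseline_thresholds
    if (bt[["OS"]] == bt[["OD"]]) {
      warning("exact baseline-threshold tie; labeling right eye (OD) as DE")
      nde <- "OS"
    } else {
      nde <- if (bt[["OS"]] > bt[["OD"]]) "OS" else "OD"
    }
  }
  de <- setdiff(c("OS", "OD"), nde)
  stats::setNames(c("DE", "NDE"), c(de, nde))
}

#' Baseline-normalize cell thresholds
#'
#' Converts each surround cell threshold `T` measured at surround contrast
#' `C` into a relative threshold `T_rel = T / T0` and relative surround
#' contrast `C_rel = C / T0`, where `T0` is the baseline (no-surround)
#' threshold of the same subject and the same annulus-viewing eye. Dividing
#' both quantities by the same baseline removes interocular and
#' between-subject differences in intrinsic contrast discrimination;
#' baseline cells map to `T_rel = 1` by construction.
#'
#' @param cells cell-threshold table from [aggregate_cells()] with an
#'   `eye_label` column (`DE`/`NDE`); baseline rows
#'   (`ocular_config == "baseline"`) supply `T0`.
#' @return data frame of surround cells with `t_rel`, `c_rel`,
#'   `raw_threshold`, `raw_surround`; subject-eyes without a baseline are
#'   dropped with a message.
#' @export
normalize_points <- function(cells) {
  stopifnot(all(c("eye_label", "ocular_config", "threshold") %in% names(cells)))
  base <- cells[cells$ocular_config == "baseline", ]
  surr <- cells[cells$ocular_config != "baseline", ]
  key <- function(d) paste(d$subject_id, d$eye_label)
  t0 <- stats::setNames(base$threshold, key(base))
  t0_here <- t0[key(surr)]
  if (anyNA(t0_here)) {
    dropped <- unique(key(surr)[is.na(t0_here)])
    message("dropping subject-eyes without measured baseline: ",
            paste(dropped, collapse = ", "))
  }
  out <- surr[!is.na(t0_here), ]
  t0_here <- t0_here[!is.na(t0_here)]
  out$baseline <- as.numeric(t0_here)
  out$t_rel <- out$threshold / out$baseline
  out$c_rel <- out$surround_contrast / out$baseline
  out$raw_threshold <- out$threshold
  out$raw_surround <- out$surround_contrast
  rownames(out) <- NULL
  out
}

#' Select the reference relative surround contrast
#'
#' Finds the single relative surround contrast at which one threshold value
#' per (eye, configuration, orientation, subject) is extracted for all group
#' analyses. Over a log-spaced candidate grid, each candidate is scored by
#' the fraction of the eight conditions whose across-subject mean nearest-
#' point relative threshold exceeds 1 (the candidate reliably evokes
#' suppression); ties are broken by the between-eye bias, the absolute
#' difference in mean log relative surround contrast actually used for DE
#' vs. NDE data (the analysis must not systematically probe one eye at
#' higher relative contrasts), then by proximity to the pooled median log
#' relative contrast, then by the lower candidate. The full score surface is
#' returned for audit.
#'
#' @param points normalized point table from [normalize_points()].
#' @param grid candidate relative surround contrasts (default 40 log-spaced
#'   values in `[1, 20]`).
#' @return object of class `cstar_selection`: `c_star` (NA if no candidate
#'   evokes suppression in any condition) and `audit` (per-candidate score
#'   and bias).
#' @export
select_reference_contrast <- function(points,
                                      grid = exp(seq(log(1), log(20),
                                                     length.out = 40L))) {
  if (length(grid) == 0L) stop("empty candidate grid")
  score_one <- function(cand) {
    near <- nearest_points(points, cand)
    cond_means <- tapply(near$t_rel,
                         paste(near$eye_label, near$ocular_config,
                               near$orientation), mean)
    frac <- mean(cond_means > 1)
    bias <- abs(mean(log(near$c_rel[near$eye_label == "DE"])) -
                  mean(log(near$c_rel[near$eye_label == "NDE"])))
    c(frac, bias)
  }
  sc <- t(vapply(grid, score_one, c(0, 0)))
  audit <- data.frame(candidate = grid, score = sc[, 1], eye_bias = sc[, 2])
  best_score <- max(audit$score)
  if (best_score == 0) {
    return(structure(list(c_star = NA_real_, audit = audit,
                          reason = "no candidate evokes mean suppression > 1 in any condition"),
                     class = "cstar_selection"))
  }
  cand <- audit[audit$score >= best_score - 1e-9, ]
  med <- stats::median(log(points$c_rel))
  cand <- cand[order(round(cand$eye_bias, 9),
                     abs(log(cand$candidate) - med), cand$candidate), ]
  structure(list(c_star = cand$candidate[1], audit = audit, reason = NULL),
            class = "cstar_selection")
}

#' @export
print.cstar_selection <- function(x, ...) {
  if (is.na(x$c_star)) {
    cat("<cstar_selection> no selection:", x$reason, "\n")
  } else {
    cat(sprintf("<cstar_selection> reference relative surround contrast = %.2f (grid of %d)\n",
                x$c_star, nrow(x$audit)))
  }
  invisible(x)
}

# one row per (subject, eye, config, orientation): the point whose relative
# surround contrast is nearest the candidate in the log domain, ties to the
# lower contrast
nearest_points <- function(points, c_star) {
  key <- interaction(points$subject_id, points$eye_label,
                     points$ocular_config, points$orientation, drop = TRUE)
  sp <- split(points, key)
  out <- lapply(sp, function(d) {
    dist <- abs(log(d$c_rel) - log(c_star))
    d <- d[order(dist, d$c_rel), ]
    d[1L, ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract the condition value at the reference contrast
#'
#' For one subject-eye-condition cell, returns the relative threshold of the
#' point whose relative surround contrast is closest (in the log domain) to
#' the reference value; equidistant ties resolve to the lower contrast.
#'
#' @param points normalized points of one cell.
#' @param c_star reference relative surround contrast.
#' @return one-row data frame (the selected point), or `NULL` for an empty
#'   cell.
#' @export
extract_condition_value <- function(points, c_star) {
  if (nrow(points) == 0L) return(NULL)
  dist <- abs(log(points$c_rel) - log(c_star))
  points[order(dist, points$c_rel), ][1L, ]
}

#' Interocular (NDE:DE) suppression ratios
#'
#' For each subject, configuration, and orientation, the ratio of the
#' selected relative threshold when the annulus was viewed by the NDE to
#' that when it was viewed by the DE. Values above 1 mean the non-dominant
#' (amblyopic) eye is suppressed more strongly than it suppresses; the
#' normalization by per-eye baselines makes the ratio insensitive to
#' interocular differences in contrast discrimination.
#'
#' @param selected data frame of selected points (one per subject, eye,
#'   config, orientation) with columns `subject_id`, `eye_label`,
#'   `ocular_config`, `orientation`, `t_rel`.
#' @return data frame: subject_id, ocular_config, orientation, ratio.
#' @export
suppression_ratio <- function(selected) {
  key <- interaction(selected$subject_id, selected$ocular_config,
                     selected$orientation, drop = TRUE)
  sp <- split(selected, key)
  rows <- lapply(sp, function(d) {
    de <- d$t_rel[d$eye_label == "DE"]; nde <- d$t_rel[d$eye_label == "NDE"]
    if (length(de) != 1L || length(nde) != 1L) return(NULL)
    data.frame(subject_id = d$subject_id[1],
               ocular_config = d$ocular_config[1],
               orientation = d$orientation[1], ratio = nde / de)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Orientation-selective surround suppression (iso:cross) ratios
#'
#' For each subject, eye, and configuration, the ratio of the selected
#' relative threshold with an iso-oriented surround to that with a
#' cross-oriented surround; values above 1 replicate orientation-selective
#' surround suppression.
#'
#' @inheritParams suppression_ratio
#' @return data frame: subject_id, eye_label, ocular_config, ratio.
#' @export
osss_ratio <- function(selected) {
  key <- interaction(selected$subject_id, selected$eye_label,
                     selected$ocular_config, drop = TRUE)
  sp <- split(selected, key)
  rows <- lapply(sp, function(d) {
    iso <- d$t_rel[d$orientation == "iso"]
    cross <- d$t_rel[d$orientation == "cross"]
    if (length(iso) != 1L || length(cross) != 1L) return(NULL)
    data.frame(subject_id = d$subject_id[1], eye_label = d$eye_label[1],
               ocular_config = d$ocular_config[1], ratio = iso / cross)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Depth of amblyopia
#'
#' Interocular difference in visual acuity: non-dominant (amblyopic) eye
#' logMAR minus dominant (fellow) eye logMAR. Non-negative for persons with
#' amblyopia by definition of the labels.
#'
#' @param records clinical record(s) with `acuity_nde_logmar` and
#'   `acuity_de_logmar` columns.
#' @return numeric vector of depths (logMAR).
#' @export
depth_of_amblyopia <- function(records) {
  if (!all(c("acuity_nde_logmar", "acuity_de_logmar") %in% names(records))) {
    stop("records must have acuity_nde_logmar and acuity_de_logmar")
  }
  records$acuity_nde_logmar - records$acuity_de_logmar
}
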