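#' Spearman rank correlation
#'
#' Pearson correlation of midranks (ties receive their average rank).
#'
#' @param x,y paired numeric vectors, `n >= 3`, finite.
#' @return the rank correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutation test for a Spearman correlation
#'
#' Builds the null distribution of the rank correlation by shuffling `y`
#' against `x` (`n_perm` random shuffles, default 100,000) and reports the
#' two-tailed permutation p-value with the add-one correction
#' `p = (1 + #(|rho_perm| >= |rho_obs|)) / (1 + n_perm)`. With
#' `exact = TRUE` all `n!` pairings are enumerated instead (small `n` only)
#' and the p-value is the exact proportion.
#'
#' @param x,y paired numeric vectors, `n >= 4` (3 allowed when exact).
#' @param n_perm number of random shuffles.
#' @param seed integer seed; identical seeds give identical results.
#' @param exact enumerate all permutations instead of sampling.
#' @return object of class `perm_cor_test`: `rho`, `n`, `p`, `n_perm`,
#'   `seed`, `exact`.
#' @export
perm_test_rho <- function(x, y, n_perm = 1e5, seed = 1L, exact = FALSE) {
  n <- length(x)
  if (n < 3L || (!exact && n < 4L)) stop("too few pairs for a permutation test")
  rho_obs <- spearman_rho(x, y)
  rx <- rank(x, ties.method = "average"); ry <- rank(y, ties.method = "average")
  rx0 <- (rx - mean(rx)); rx0 <- rx0 / sqrt(sum(rx0^2))
  ry0 <- (ry - mean(ry))
  sy <- sqrt(sum(ry0^2))
  if (sy == 0 || !is.finite(rho_obs)) stop("degenerate input: no rank variance")
  ry0 <- ry0 / sy
  tol <- 1e-12
  if (exact) {
    pm <- all_perms(n)
    rhos <- as.vector(matrix(ry0[pm], nrow(pm)) %*% rx0)
    p <- mean(abs(rhos) >= abs(rho_obs) - tol)
    n_perm <- nrow(pm)
  } else {
    p <- with_seed(seed, {
      idx <- replicate(n_perm, sample.int(n))
      rhos <- colSums(matrix(ry0[idx], n) * rx0)
      (1 + sum(abs(rhos) >= abs(rho_obs) - tol)) / (1 + n_perm)
    })
  }
  structure(list(rho = rho_obs, n = n, p = p, n_perm = n_perm,
                 seed = if (exact) NA_integer_ else seed, exact = exact),
            class = "perm_cor_test")
}

#' @export
print.perm_cor_test <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d), permutation p = %.4g (%s)\n",
              x$rho, x$n, x$p,
              if (x$exact) sprintf("exact, %d perms", x$n_perm)
              else sprintf("%d shuffles", x$n_perm)))
  invisible(x)
}

#' Permutation test for an interocular correlation difference
#'
#' Tests whether a shared regressor (GABA:Cr) correlates differently with a
#' per-subject DE measure than with the paired NDE measure. The observed
#' statistic is `delta = rho(g, de) - rho(g, nde)`; the null distribution is
#' built by independently swapping each subject's DE/NDE values (under the
#' null of no eye difference the two labels are exchangeable within
#' subject), two-tailed with the add-one correction. `exact = TRUE`
#' enumerates all `2^n` swap patterns.
#'
#' @param g shared regressor (one value per subject).
#' @param de,nde paired per-subject measures for the two eyes.
#' @param n_perm number of random swap patterns.
#' @param seed integer seed. @param exact enumerate all swap patterns
#'   (n <= 20).
#' @return object of class `perm_delta_test`: `delta` (observed difference),
#'   `rho_de`, `rho_nde`, `p`, `n`, `n_perm`.
#' @export
perm_test_delta_rho_eyes <- function(g, de, nde, n_perm = 1e5, seed = 1L,
                                     exact = FALSE) {
  n <- length(g)
  stopifnot(length(de) == n, length(nde) == n)
  if (n < 3L) stop("too few subjects")
  rho_de <- spearman_rho(g, de); rho_nde <- spearman_rho(g, nde)
  delta_obs <- rho_de - rho_nde
  stat <- function(swap) {
    a <- ifelse(swap, nde, de); b <- ifelse(swap, de, nde)
    spearman_rho(g, a) - spearman_rho(g, b)
  }
  tol <- 1e-12
  if (exact) {
    if (n > 20L) stop("exact enumeration limited to n <= 20")
    pat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    deltas <- apply(pat, 1L, stat)
    p <- mean(abs(deltas) >= abs(delta_obs) - tol)
    n_perm <- nrow(pat)
  } else {
    p <- with_seed(seed, {
      deltas <- vapply(seq_len(n_perm),
                       function(i) stat(stats::runif(n) < 0.5), 0)
      (1 + sum(abs(deltas) >= abs(delta_obs) - tol)) / (1 + n_perm)
    })
  }
  structure(list(delta = delta_obs, rho_de = rho_de, rho_nde = rho_nde,
                 p = p, n = n, n_perm = n_perm, exact = exact),
            class = "perm_delta_test")
}

#' @export
print.perm_delta_test <- function(x, ...) {
  cat(sprintf("delta rho (DE - NDE) = %.3f (rho_DE = %.3f, rho_NDE = %.3f, n = %d), p = %.4g\n",
              x$delta, x$rho_de, x$rho_nde, x$n, x$p))
  invisible(x)
}

#' Regional specificity of a brain-behavior correlation
#'
#' Compares the correlation of a behavioral measure with GABA:Cr from the
#' visual-cortex voxel against the correlation with GABA:Cr from the
#' sensorimotor control voxel in the same subjects. The default
#' (`method = "bootstrap"`) resamples subjects with replacement, building the
#' bootstrap distribution of `delta = rho(visual, y) - rho(motor, y)`; the
#' two-tailed p-value is twice the smaller tail fraction of the distribution
#' relative to zero. `method = "label_perm"` instead swaps each subject's
#' region labels at random and compares `|delta|` to that permutation null.
#'
#' @param y behavioral measure, one value per subject.
#' @param gaba_visual,gaba_motor region-wise GABA:Cr per subject.
#' @param n_draws bootstrap/permutation draws.
#' @param seed integer seed.
#' @param method `"bootstrap"` (subject resampling, default) or
#'   `"label_perm"`.
#' @return object of class `region_spec_test`: `delta`, `rho_visual`,
#'   `rho_motor`, `p`, `n`, `method`.
#' @export
perm_test_region_specificity <- function(y, gaba_visual, gaba_motor,
                                         n_draws = 1e4, seed = 1L,
                                         method = c("bootstrap", "label_perm")) {
  method <- match.arg(method)
  n <- length(y)
  stopifnot(length(gaba_visual) == n, length(gaba_motor) == n)
  if (n < 4L) stop("too few subjects")
  rho_v <- spearman_rho(gaba_visual, y); rho_m <- spearman_rho(gaba_motor, y)
  delta_obs <- rho_v - rho_m
  safe_rho <- function(a, b) {
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) return(NA_real_)
    spearman_rho(a, b)
  }
  p <- with_seed(seed, {
    if (method == "bootstrap") {
      deltas <- vapply(seq_len(n_draws), function(i) {
        id <- sample.int(n, replace = TRUE)
        safe_rho(gaba_visual[id], y[id]) - safe_rho(gaba_motor[id], y[id])
      }, 0)
      deltas <- deltas[!is.na(deltas)]
      lo <- (1 + sum(deltas <= 0)) / (1 + length(deltas))
      hi <- (1 + sum(deltas >= 0)) / (1 + length(deltas))
      min(1, 2 * min(lo, hi))
    } else {
      tol <- 1e-12
      deltas <- vapply(seq_len(n_draws), function(i) {
        swap <- stats::runif(n) < 0.5
        gv <- ifelse(swap, gaba_motor, gaba_visual)
        gm <- ifelse(swap, gaba_visual, gaba_motor)
        spearman_rho(gv, y) - spearman_rho(gm, y)
      }, 0)
      (1 + sum(abs(deltas) >= abs(delta_obs) - tol)) / (1 + n_draws)
    }
  })
  structure(list(delta = delta_obs, rho_visual = rho_v, rho_motor = rho_m,
                 p = p, n = n, method = method, n_draws = n_draws),
            class = "region_spec_test")
}

#' @export
print.region_spec_test <- function(x, ...) {
  cat(sprintf("regional specificity: delta rho = %.3f (visual %.3f vs motor %.3f, n = %d), p = %.4g [%s]\n",
              x$delta, x$rho_visual, x$rho_motor, x$n, x$p, x$method))
  invisible(x)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))`, compared
#' to the standard normal for a two-tailed p-value.
#'
#' @param rho1,rho2 correlation coefficients (`|rho| < 1`).
#' @param n1,n2 sample sizes (each > 3).
#' @return object of class `fisher_z_result`: `z`, `p`, and the inputs.
#' @export
fisher_z_compare <- function(rho1, n1, rho2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("Fisher comparison requires n > 3 per sample")
  if (abs(rho1) >= 1 || abs(rho2) >= 1) stop("|rho| must be < 1")
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)),
                 rho1 = rho1, n1 = n1, rho2 = rho2, n2 = n2),
            class = "fisher_z_result")
}

#' @export
print.fisher_z_result <- function(x, ...) {
  cat(sprintf("Fisher r-to-z: z = %.3f, two-tailed p = %.3f (rho1 = %.2f n1 = %d; rho2 = %.2f n2 = %d)\n",
              x$z, x$p, x$rho1, x$n1, x$rho2, x$n2))
  invisible(x)
}

#' One- and two-sample t statistics and Cohen's d
#'
#' Thin wrappers over Student's t-test (two-tailed; the two-sample version is
#' the pooled equal-variance test) plus the pooled-SD standardized mean
#' difference.
#'
#' @param values,a,b numeric samples. @param mu0 null mean.
#' @return list with `t`, `df`, `p` (and `d` for `cohens_d`).
#' @export
one_sample_t <- function(values, mu0 = 0) {
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname one_sample_t
#' @export
two_sample_t <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname one_sample_t
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("pooled SD is zero; effect size undefined")
  list(d = (mean(a) - mean(b)) / sp)
}

#' Bootstrap confidence band for a linear fit
#'
#' Least-squares line with subject-resampling bootstrap: rows are resampled
#' with replacement `n_boot` times and the percentile 2.5/97.5 interval is
#' reported for the slope and for the fitted line at each evaluation point.
#'
#' @param x,y paired observations (`n >= 4`).
#' @param n_boot bootstrap draws. @param seed integer seed.
#' @param eval_points abscissae of the band (default 50 points spanning `x`).
#' @param level confidence level.
#' @return list: `intercept`, `slope`, `slope_ci`, and `band` (data frame
#'   with `x`, `lo`, `hi`).
#' @export
bootstrap_linear_ci <- function(x, y, n_boot = 2000L, seed = 1L,
                                eval_points = NULL, level = 0.95) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4L) stop("need at least 4 points")
  if (is.null(eval_points)) {
    eval_points <- seq(min(x), max(x), length.out = 50L)
  }
  fit <- stats::lm.fit(cbind(1, x), y)$coefficients
  a <- (1 - level) / 2
  with_seed(seed, {
    coefs <- matrix(NA_real_, n_boot, 2L)
    for (b in seq_len(n_boot)) {
      id <- sample.int(n, replace = TRUE)
      if (length(unique(x[id])) < 2L) next
      coefs[b, ] <- stats::lm.fit(cbind(1, x[id]), y[id])$coefficients
    }
    coefs <- coefs[!is.na(coefs[, 1L]), , drop = FALSE]
    preds <- coefs[, 1L] %o% rep(1, length(eval_points)) +
      coefs[, 2L] %o% eval_points
    list(intercept = unname(fit[1L]), slope = unname(fit[2L]),
         slope_ci = unname(stats::quantile(coefs[, 2L], c(a, 1 - a))),
         band = data.frame(x = eval_points,
                           lo = apply(preds, 2L, stats::quantile, a),
                           hi = apply(preds, 2L, stats::quantile, 1 - a)),
         n_boot_used = nrow(coefs))
  })
}

#' Omnibus factorial ANOVA on selected relative thresholds
#'
#' Fixed-effects factorial ANOVA of the selected relative threshold on
#' surround orientation, ocular configuration, eye, and group, reporting the
#' orientation main effect plus the full configuration x eye x group
#' factorial (Type-II sums of squares, robust to mild imbalance from missing
#' cells). The seven reported effects are the four main effects and the
#' configuration:eye, group:eye, and configuration:group:eye interactions.
#'
#' @param data long-format data frame with columns `t_rel` (or `response`),
#'   `orientation`, `ocular_config`, `eye_label`, `group`.
#' @param response name of the response column.
#' @return object of class `anova_table`: data frame with `effect`, `F`, `p`.
#' @export
omnibus_anova <- function(data, response = "t_rel") {
  need <- c(response, "orientation", "ocular_config", "eye_label", "group")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data.frame(y = data[[response]],
                  orientation = factor(data$orientation),
                  config = factor(data$ocular_config),
                  eye = factor(data$eye_label),
                  group = factor(data$group))
  effects <- c(orientation = "Orientation",
               config = "Ocular configuration",
               eye = "Eye", group = "Group",
               `config:eye` = "Ocular configuration x eye",
               `eye:group` = "Group x eye",
               `config:eye:group` = "Ocular configuration x group x eye")
  if (stats::var(d$y) == 0) {
    tab <- data.frame(effect = unname(effects), F = 0, p = 1)
    return(structure(tab, class = c("anova_table", "data.frame")))
  }
  m <- stats::lm(y ~ orientation + config * eye * group, data = d)
  a <- car::Anova(m, type = 2)
  rn <- rownames(a)
  norm_term <- function(t) paste(sort(strsplit(t, ":")[[1]]), collapse = ":")
  rn_norm <- vapply(rn, norm_term, "")
  rows <- lapply(names(effects), function(term) {
    i <- match(norm_term(term), rn_norm)
    Fv <- a[i, "F value"]; pv <- a[i, "Pr(>F)"]
    if (is.na(Fv) || a[i, "Sum Sq"] < 1e-12) { Fv <- 0; pv <- 1 }
    data.frame(effect = effects[[term]], F = Fv, p = pv)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Omnibus ANOVA (Type-II):\n")
  print.data.frame(data.frame(effect = x$effect, F = round(x$F, 2),
                              p = signif(x$p, 3)), row.names = FALSE)
  invisible(x)
}
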