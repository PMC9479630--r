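test_that("spearman_rho equals the midrank Pearson oracle, with and without ties", {
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 4, 6)
  midrank <- function(v) {
    vapply(v, function(a) mean(which(sort(v) == a)), 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y), oracle)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))

  expect_equal(spearman_rho(1:3, 1:3), 1)
  expect_equal(spearman_rho(1:3, 3:1), -1)
  # invariance under strictly monotone transforms
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
  expect_equal(spearman_rho(a, atan(b)), spearman_rho(a, b))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("permutation p-values agree with exhaustive enumeration", {
  x <- c(0.3, 1.2, 2.9); y <- c(2.1, 0.4, 1.5)
  res <- perm_test_rho(x, y, exact = TRUE)
  # independent oracle: walk all 6 pairings by hand
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  rhos <- vapply(perms, function(p) cor(x, y[p], method = "spearman"), 0)
  obs <- cor(x, y, method = "spearman")
  expect_equal(res$p, mean(abs(rhos) >= abs(obs) - 1e-12))
  expect_equal(res$n_perm, 6L)

  # sampled version converges to the exact value on a fixed tiny dataset
  x6 <- c(5, 1, 4, 2, 6, 3); y6 <- c(2, 1, 5, 3, 6, 4)
  ex <- perm_test_rho(x6, y6, exact = TRUE)
  sa <- perm_test_rho(x6, y6, n_perm = 20000, seed = 2)
  expect_lt(abs(sa$p - ex$p), 3 * sqrt(ex$p * (1 - ex$p) / 20000) + 1e-4)

  # determinism at fixed seed
  expect_identical(perm_test_rho(x6, y6, n_perm = 500, seed = 9),
                   perm_test_rho(x6, y6, n_perm = 500, seed = 9))
})

test_that("permutation test attains its nominal type-I error rate", {
  set.seed(31)
  n <- 12L
  hits <- vapply(seq_len(500), function(i) {
    x <- rnorm(n); y <- rnorm(n)
    perm_test_rho(x, y, n_perm = 2000, seed = i)$p <= 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("the interocular correlation-difference test is calibrated and powered", {
  # exact null: identical eyes give delta = 0 and p = 1
  set.seed(6)
  g <- rnorm(8); v <- rnorm(8)
  same <- perm_test_delta_rho_eyes(g, v, v, n_perm = 200, seed = 1)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  # n = 3: sampled swaps must match the 2^3 enumeration
  g3 <- c(1, 2, 3); de3 <- c(0.2, 1.4, 0.9); nde3 <- c(1.1, 0.3, 0.8)
  ex <- perm_test_delta_rho_eyes(g3, de3, nde3, exact = TRUE)
  pat <- expand.grid(c(FALSE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE))
  deltas <- apply(pat, 1, function(s) {
    a <- ifelse(s, nde3, de3); b <- ifelse(s, de3, nde3)
    cor(g3, a, method = "spearman") - cor(g3, b, method = "spearman")
  })
  obs <- cor(g3, de3, method = "spearman") - cor(g3, nde3, method = "spearman")
  expect_equal(ex$p, mean(abs(deltas) >= abs(obs) - 1e-12))

  # power on a planted opposite-sign coupling
  set.seed(77)
  hits <- vapply(seq_len(100), function(i) {
    n <- 100L
    g <- rnorm(n)
    de <- 0.6 * g + sqrt(1 - 0.36) * rnorm(n)
    nde <- -0.6 * g + sqrt(1 - 0.36) * rnorm(n)
    perm_test_delta_rho_eyes(g, de, nde, n_perm = 400, seed = i)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("regional specificity test behaves on null and planted data", {
  set.seed(13)
  n <- 40L
  y <- rnorm(n); gv <- rnorm(n)
  same <- perm_test_region_specificity(y, gv, gv, n_draws = 400, seed = 2)
  expect_equal(same$delta, 0)
  expect_gt(same$p, 0.9)

  y2 <- gv + 0.3 * rnorm(n)                    # visual-specific coupling
  gm <- rnorm(n)
  strong <- perm_test_region_specificity(y2, gv, gm, n_draws = 1000, seed = 3)
  expect_lt(strong$p, 0.05)
  lab <- perm_test_region_specificity(y2, gv, gm, n_draws = 1000, seed = 4,
                                      method = "label_perm")
  expect_lt(lab$p, 0.05)
  expect_identical(
    perm_test_region_specificity(y2, gv, gm, n_draws = 300, seed = 5),
    perm_test_region_specificity(y2, gv, gm, n_draws = 300, seed = 5))
})

test_that("Fisher r-to-z comparison matches the closed form and is antisymmetric", {
  # the arithmetic chain recomputed independently
  z_oracle <- (atanh(0.5) - atanh(0)) / sqrt(1 / 17 + 1 / 17)
  res <- fisher_z_compare(0.5, 20, 0.0, 20)
  expect_equal(res$z, z_oracle)
  expect_equal(res$p, 2 * pnorm(-abs(z_oracle)))

  eq <- fisher_z_compare(0.4, 15, 0.4, 22)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  a <- fisher_z_compare(-0.61, 14, 0.10, 11)
  b <- fisher_z_compare(0.10, 11, -0.61, 14)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  expect_error(fisher_z_compare(0.5, 3, 0.2, 10), "n > 3")
  expect_error(fisher_z_compare(1, 10, 0.2, 10), "rho")
})

test_that("t statistics and effect sizes reduce to their textbook values", {
  r <- one_sample_t(c(0.9, 1.0, 1.1), 1)
  expect_equal(r$t, 0)
  expect_equal(r$df, 2)
  s <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$t, 0)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  # means 0 vs 1 at pooled SD 1
  a <- c(-1, 0, 1); b <- c(0, 1, 2)
  expect_equal(cohens_d(a, b)$d, -1)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("bootstrap linear CI collapses on exact data and covers the slope", {
  x <- 1:10; y <- 2 * x
  ci <- bootstrap_linear_ci(x, y, n_boot = 200, seed = 1)
  expect_equal(ci$slope, 2)
  expect_equal(unname(ci$slope_ci), c(2, 2))
  expect_true(all(abs(ci$band$hi - ci$band$lo) < 1e-9))

  set.seed(23)
  cover <- vapply(seq_len(500), function(i) {
    x <- runif(20, 0, 4)
    y <- 1 + 1 * x + rnorm(20)
    ci <- bootstrap_linear_ci(x, y, n_boot = 400, seed = i)
    ci$slope_ci[1] <= 1 && 1 <= ci$slope_ci[2]
  }, TRUE)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
  expect_identical(bootstrap_linear_ci(x, y, n_boot = 100, seed = 3),
                   bootstrap_linear_ci(x, y, n_boot = 100, seed = 3))
})

test_that("the factorial ANOVA matches a closed-form balanced oracle", {
  # balanced 2x2x2x2 with 3 replicates and planted orientation + group:eye
  d <- expand.grid(orientation = c("iso", "cross"),
                   ocular_config = c("monocular", "dichoptic"),
                   eye_label = c("DE", "NDE"), group = c("PWA", "NSP"),
                   rep = 1:3, stringsAsFactors = FALSE)
  set.seed(8)
  d$t_rel <- 1 + 0.5 * (d$orientation == "iso") +
    0.4 * (d$group == "PWA") * (d$eye_label == "NDE") + rnorm(nrow(d), 0, 0.2)
  tab <- omnibus_anova(d)
  expect_equal(nrow(tab), 7L)

  # closed-form sums of squares for the balanced design
  N <- nrow(d); gm <- mean(d$t_rel)
  ss_between <- function(f) {
    m <- tapply(d$t_rel, f, mean); n <- tapply(d$t_rel, f, length)
    sum(n * (m - gm)^2)
  }
  ss_o <- ss_between(d$orientation)
  ss_c <- ss_between(d$ocular_config)
  ss_e <- ss_between(d$eye_label)
  ss_g <- ss_between(d$group)
  ss_ce <- ss_between(paste(d$ocular_config, d$eye_label)) - ss_c - ss_e
  ss_ge <- ss_between(paste(d$group, d$eye_label)) - ss_g - ss_e
  ss_cg <- ss_between(paste(d$ocular_config, d$group)) - ss_c - ss_g
  ss_ceg <- ss_between(paste(d$ocular_config, d$eye_label, d$group)) -
    ss_c - ss_e - ss_g - ss_ce - ss_ge - ss_cg
  fitted_ss <- ss_o + ss_c + ss_e + ss_g + ss_ce + ss_ge + ss_cg + ss_ceg
  ss_res <- sum((d$t_rel - gm)^2) - fitted_ss
  df_res <- N - 9L                     # 1 + 1*4 + 3 two-way + 1 three-way
  Fo <- function(ss) (ss / 1) / (ss_res / df_res)
  expect_equal(tab$F[tab$effect == "Orientation"], Fo(ss_o))
  expect_equal(tab$F[tab$effect == "Group x eye"], Fo(ss_ge))
  expect_equal(tab$F[tab$effect == "Ocular configuration x group x eye"],
               Fo(ss_ceg))

  # selectivity: only the planted effects are large
  expect_gt(tab$F[tab$effect == "Orientation"], 20)
  expect_gt(tab$F[tab$effect == "Group x eye"], 8)
  expect_lt(tab$F[tab$effect == "Ocular configuration"], 5)

  # degenerate input: all cells equal
  d0 <- d; d0$t_rel <- 1
  tab0 <- omnibus_anova(d0)
  expect_true(all(tab0$F == 0))
  expect_true(all(tab0$p == 1))
})
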