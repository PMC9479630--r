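#' Staircase configuration
#'
#' Parameters of the transformed up-down (2-up/1-down) adaptive staircase used
#' for the 4AFC contrast-increment task. With the defaults, two consecutive
#' correct responses lower the contrast increment by 0.125 log10 units and a
#' single error raises it by the same step, so the procedure converges near
#' the 70.7%-correct point of the psychometric function. A staircase
#' terminates after `stop_reversals` direction reversals and its threshold is
#' the geometric mean of the last `threshold_reversals` reversal increments.
#'
#' @param step step size in log10 units of Michelson contrast.
#' @param n_up number of consecutive correct responses required to decrease
#'   the increment. @param n_down number of consecutive incorrect responses
#'   required to increase it.
#' @param stop_reversals reversals at which the staircase terminates.
#' @param threshold_reversals terminal reversals averaged into the threshold.
#' @param start_increment initial contrast increment (Michelson).
#' @param max_trials safety cap; a staircase that has not reached
#'   `stop_reversals` by then is unconverged.
#' @param floor,ceiling contrast increment bounds; `ceiling` defaults to
#'   1 - pedestal with a 30% pedestal.
#' @param pin_trials consecutive trials pinned at `ceiling` after which the
#'   staircase is declared unmeasurable (the observer cannot do the task at
#'   any presentable contrast).
#' @return a validated list of class `staircase_config`.
#' @export
staircase_config <- function(step = 0.125, n_up = 2L, n_down = 1L,
                             stop_reversals = 12L, threshold_reversals = 6L,
                             start_increment = 0.3, max_trials = 400L,
                             floor = 1e-4, ceiling = 0.7, pin_trials = 10L) {
  if (step <= 0) stop("invalid staircase config: step must be positive")
  if (threshold_reversals > stop_reversals) {
    stop("invalid staircase config: threshold_reversals must be <= stop_reversals")
  }
  if (!(0 < floor && floor < start_increment && start_increment <= ceiling &&
        ceiling <= 1)) {
    stop("invalid staircase config: need 0 < floor < start_increment <= ceiling <= 1")
  }
  structure(list(step = step, n_up = as.integer(n_up),
                 n_down = as.integer(n_down),
                 stop_reversals = as.integer(stop_reversals),
                 threshold_reversals = as.integer(threshold_reversals),
                 start_increment = start_increment,
                 max_trials = as.integer(max_trials),
                 floor = floor, ceiling = ceiling,
                 pin_trials = as.integer(pin_trials)),
            class = "staircase_config")
}

# Core of the adaptive rule, shared by live runs and log replays.
# `respond(increment, trial)` returns TRUE/FALSE.
staircase_engine <- function(respond, config) {
  lvl <- log10(config$start_increment)
  lfloor <- log10(config$floor); lceil <- log10(config$ceiling)
  inc <- numeric(config$max_trials); corr <- logical(config$max_trials)
  reversals <- numeric(0)
  streak_c <- 0L; streak_i <- 0L; last_move <- 0L; pinned <- 0L
  unmeasurable <- FALSE
  n <- 0L
  for (t in seq_len(config$max_trials)) {
    x <- 10^lvl
    ans <- respond(x, t)
    if (is.na(ans)) break                    # responder failure: partial log
    n <- t; inc[t] <- x; corr[t] <- ans
    move <- 0L
    if (ans) {
      streak_c <- streak_c + 1L; streak_i <- 0L
      if (streak_c >= config$n_up) { move <- -1L; streak_c <- 0L }
    } else {
      streak_i <- streak_i + 1L; streak_c <- 0L
      if (streak_i >= config$n_down) { move <- +1L; streak_i <- 0L }
    }
    if (move != 0L) {
      if (last_move != 0L && move != last_move) reversals <- c(reversals, lvl)
      last_move <- move
      lvl <- min(max(lvl + move * config$step, lfloor), lceil)
    }
    if (x >= config$ceiling * (1 - 1e-12)) pinned <- pinned + 1L else pinned <- 0L
    if (pinned >= config$pin_trials) { unmeasurable <- TRUE; break }
    if (length(reversals) >= config$stop_reversals) break
  }
  converged <- length(reversals) >= config$stop_reversals
  structure(list(reversal_increments = 10^reversals,
                 reversal_log10 = reversals,
                 converged = converged, unmeasurable = unmeasurable,
                 n_trials = n,
                 increments = inc[seq_len(n)], correct = corr[seq_len(n)],
                 threshold = NA_real_),
            class = "staircase_outcome")
}

#' Run an adaptive staircase against a responder
#'
#' @param responder function mapping a contrast increment (Michelson) to a
#'   logical correct/incorrect response, e.g. [weibull_responder()].
#' @param config a [staircase_config()].
#' @param seed optional integer seed for stochastic responders.
#' @return list with `trials` (data frame of trial_index, increment, correct)
#'   and `outcome` (a `staircase_outcome` with the reversal list, convergence
#'   flag, and the estimated threshold when converged).
#' @export
run_staircase <- function(responder, config = staircase_config(),
                          seed = NULL) {
  stopifnot(inherits(config, "staircase_config"), is.function(responder))
  out <- with_seed(seed, {
    staircase_engine(function(x, t) {
      ans <- tryCatch(responder(x), error = function(e) NA)
      if (is.na(ans)) NA else isTRUE(ans)
    }, config)
  })
  out$threshold <- estimate_threshold(out, config)
  list(trials = data.frame(trial_index = seq_len(out$n_trials),
                           increment = out$increments,
                           correct = out$correct),
       outcome = out)
}

#' Replay a recorded trial log through the staircase rule
#'
#' Reconstructs reversals, convergence, and the threshold estimate from the
#' recorded response sequence of one staircase.
#'
#' @param correct logical vector of responses in trial order.
#' @param config the [staircase_config()] the staircase was run with.
#' @param start_increment the increment presented on the first trial (each
#'   staircase's starting level is part of its log; the level track is fully
#'   determined by the start and the response sequence).
#' @return a `staircase_outcome`.
#' @export
replay_staircase <- function(correct, config = staircase_config(),
                             start_increment = config$start_increment) {
  k <- length(correct)
  cfg <- config
  cfg$max_trials <- max(cfg$max_trials, k)
  cfg$start_increment <- start_increment
  cfg$ceiling <- max(cfg$ceiling, start_increment)
  out <- staircase_engine(function(x, t) if (t <= k) correct[t] else NA, cfg)
  out$threshold <- estimate_threshold(out, config)
  out
}

#' Threshold from a converged staircase
#'
#' The contrast discrimination threshold is the average of the last
#' `threshold_reversals` reversal increments, taken in the log10 domain and
#' exponentiated (a geometric mean, matching the multiplicative step rule).
#'
#' @param outcome a `staircase_outcome`.
#' @param config the matching [staircase_config()].
#' @return threshold in Michelson contrast, or `NA` (flagged) when the
#'   staircase did not converge.
#' @export
estimate_threshold <- function(outcome, config = staircase_config()) {
  if (!isTRUE(outcome$converged) ||
      length(outcome$reversal_log10) < config$threshold_reversals) {
    return(NA_real_)
  }
  last <- utils::tail(outcome$reversal_log10, config$threshold_reversals)
  10^mean(last)
}

#' @export
print.staircase_outcome <- function(x, ...) {
  cat(sprintf("<staircase_outcome> %d trials, %d reversals, %s%s\n",
              x$n_trials, length(x$reversal_increments),
              if (x$converged) sprintf("threshold = %.4f", x$threshold)
              else "unconverged",
              if (x$unmeasurable) " [unmeasurable: pinned at ceiling]" else ""))
  invisible(x)
}

#' @export
plot.staircase_outcome <- function(x, ...) {
  graphics::plot(seq_len(x$n_trials), x$increments, log = "y", type = "b",
                 pch = ifelse(x$correct, 19, 1),
                 xlab = "trial", ylab = "contrast increment (Michelson)", ...)
  if (x$converged) graphics::abline(h = x$threshold, lty = 2)
}

#' Aggregate staircase thresholds within one cell
#'
#' A cell is one (subject, eye, ocular configuration, orientation, surround
#' contrast) combination, measured with four (or more) staircases. The cell
#' threshold is the geometric mean of the converged staircases' thresholds;
#' cells with fewer than `min_converged` converged staircases are flagged
#' unstable, and cells with none are missing.
#'
#' @param thresholds numeric vector of per-staircase thresholds (NA for
#'   unconverged staircases).
#' @param min_converged stability criterion (default 4).
#' @return list with `threshold` (NA when no staircase converged),
#'   `n_converged`, and `unstable`.
#' @export
aggregate_cell <- function(thresholds, min_converged = 4L) {
  ok <- thresholds[!is.na(thresholds)]
  list(threshold = if (length(ok) == 0L) NA_real_ else geomean(ok),
       n_converged = length(ok),
       unstable = length(ok) < min_converged)
}

#' 4AFC Weibull observer
#'
#' Probability correct `p(x) = guess + (1 - guess - lapse) *
#' (1 - exp(-(x / alpha)^beta))` for a four-alternative forced choice task
#' (`guess = 0.25`). With `beta = 3` and `lapse = 0.02`, the 70.7%-correct
#' point tracked by the 2-up/1-down rule lies within half a percent of
#' `alpha`, so `alpha` is the cell's generating threshold.
#'
#' @param alpha threshold parameter (Michelson contrast increment).
#' @param beta psychometric slope. @param lapse lapse rate.
#' @param guess chance performance.
#' @return `weibull_responder` returns a function of the increment that draws
#'   a Bernoulli response; `weibull_p` returns the analytic probability.
#' @export
weibull_responder <- function(alpha, beta = 3, lapse = 0.02, guess = 0.25) {
  function(x) stats::runif(1) < weibull_p(x, alpha, beta, lapse, guess)
}

#' @rdname weibull_responder
#' @param x contrast increment(s).
#' @export
weibull_p <- function(x, alpha, beta = 3, lapse = 0.02, guess = 0.25) {
  guess + (1 - guess - lapse) * (1 - exp(-(x / alpha)^beta))
}

#' Increment at a given percent-correct level of the Weibull observer
#'
#' Inverse of [weibull_p()]; the 2-up/1-down convergence point is
#' `weibull_q(sqrt(0.5), ...)` (the level where p(correct)^2 = 1/2).
#'
#' @param p target probability correct.
#' @inheritParams weibull_responder
#' @export
weibull_q <- function(p, alpha, beta = 3, lapse = 0.02, guess = 0.25) {
  stopifnot(p > guess, p < 1 - lapse)
  alpha * (-log(1 - (p - guess) / (1 - guess - lapse)))^(1 / beta)
}

#' Fit thresholds for every staircase in a trial log
#'
#' Replays each staircase in a trial-log table through the adaptive rule and
#' returns one row per staircase with its reconstructed threshold.
#'
#' @param trials data frame with columns `subject_id`, `eye`, `ocular_config`,
#'   `orientation`, `surround_contrast`, `staircase_id`, `trial_index`,
#'   `increment`, `correct` (as produced by [simulate_sessions()]).
#' @param config the [staircase_config()] used to collect the data.
#' @return data frame, one row per staircase: cell key columns plus
#'   `threshold`, `converged`, `unmeasurable`, `n_trials`.
#' @export
fit_thresholds <- function(trials, config = staircase_config()) {
  need <- c("subject_id", "eye", "ocular_config", "orientation",
            "surround_contrast", "staircase_id", "trial_index", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial log is missing columns: ",
                         paste(miss, collapse = ", "))
  sp <- split(trials, trials$staircase_id)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$trial_index), ]
    out <- replay_staircase(d$correct, config,
                            start_increment = d$increment[1])
    data.frame(subject_id = d$subject_id[1], eye = d$eye[1],
               ocular_config = d$ocular_config[1],
               orientation = d$orientation[1],
               surround_contrast = d$surround_contrast[1],
               staircase_id = d$staircase_id[1],
               threshold = out$threshold, converged = out$converged,
               unmeasurable = out$unmeasurable, n_trials = out$n_trials)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Aggregate per-staircase thresholds into cell thresholds
#'
#' @param staircases output of [fit_thresholds()].
#' @param min_converged see [aggregate_cell()].
#' @return data frame with one row per cell (`subject_id`, `eye`,
#'   `ocular_config`, `orientation`, `surround_contrast`) and columns
#'   `threshold`, `n_converged`, `unstable`; cells where no staircase
#'   converged are dropped (missing data propagate downstream).
#' @export
aggregate_cells <- function(staircases, min_converged = 4L) {
  key <- paste(staircases$subject_id, staircases$eye,
               staircases$ocular_config, staircases$orientation,
               ifelse(is.na(staircases$surround_contrast), "none",
                      staircases$surround_contrast))
  sp <- split(staircases, key)
  rows <- lapply(sp, function(d) {
    agg <- aggregate_cell(d$threshold, min_converged)
    data.frame(subject_id = d$subject_id[1], eye = d$eye[1],
               ocular_config = d$ocular_config[1],
               orientation = d$orientation[1],
               surround_contrast = d$surround_contrast[1],
               threshold = agg$threshold, n_converged = agg$n_converged,
               unstable = agg$unstable)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[!is.na(res$threshold), ]
}
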