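#' Threshold-normalized training distance error
#'
#' Training navigation performance per trial: the excess distance traveled,
#' expressed as a percentage of the learning criterion threshold, which is
#' 120% of the shortest possible path. A trial meets criterion when the
#' traveled distance does not exceed the threshold.
#'
#' @param shortest shortest possible path length (> 0).
#' @param traveled distance actually traveled (>= 0).
#' @param threshold_factor criterion threshold as a multiple of the
#'   shortest path (default 1.2).
#' @return data.frame with columns `error_pct`
#'   (`100 * (traveled - shortest) / (threshold_factor * shortest)`) and
#'   `criterion_met` (`traveled <= threshold_factor * shortest`).
#' @examples
#' training_normalized_error(10, 12)   # 16.67, criterion met (boundary)
#' training_normalized_error(10, 24)   # 116.67, criterion failed
#' @export
training_normalized_error <- function(shortest, traveled,
                                      threshold_factor = 1.2) {
  if (any(!is.finite(shortest)) || any(shortest <= 0))
    stop_invalid("shortest path length must be positive and finite")
  if (any(!is.finite(traveled)) || any(traveled < 0))
    stop_invalid("traveled length must be non-negative and finite")
  if (threshold_factor <= 0) stop_invalid("threshold_factor must be positive")
  data.frame(
    error_pct = 100 * (traveled - shortest) / (threshold_factor * shortest),
    criterion_met = traveled <= threshold_factor * shortest
  )
}

#' Optimal-distance-normalized transfer error
#'
#' Transfer-task navigation error per trial: distance error divided by the
#' optimal (shortest) distance, `(traveled - shortest) / shortest`. Values
#' below zero are impossible in practice; they are permitted but warned
#' about.
#'
#' @inheritParams training_normalized_error
#' @return numeric vector of normalized errors.
#' @export
transfer_normalized_error <- function(shortest, traveled) {
  if (any(!is.finite(shortest)) || any(shortest <= 0))
    stop_invalid("shortest path length must be positive and finite")
  if (any(!is.finite(traveled)) || any(traveled < 0))
    stop_invalid("traveled length must be non-negative and finite")
  out <- (traveled - shortest) / shortest
  if (any(out < 0))
    warning("traveled distance below the optimal path on ", sum(out < 0),
            " trial(s)")
  out
}

#' Navigation transfer learning rate
#'
#' Contrasts early versus late performance over an ordered transfer session
#' of `2k` trials (default 20): `-(mean(first k) - mean(last k)) /
#' (mean(first k) + mean(last k))` on the normalized distance errors. With
#' errors declining over trials the value is negative; values near zero
#' indicate uniform (stable) performance across the session, and a
#' pre-to-post increase means the early trials are learned faster after
#' training.
#'
#' @param errors ordered per-trial normalized errors (length `2k`).
#' @param half_size `k`; defaults to half the trial count (10 of 20).
#' @return object of class `learning_rate`: list with `value`, `first_half`,
#'   `last_half`, `n_trials`, `task = "navigation"`.
#' @examples
#' navigation_learning_rate(c(rep(3, 10), rep(1, 10)))$value  # -0.5
#' @export
navigation_learning_rate <- function(errors, half_size = length(errors) %/% 2) {
  if (length(errors) != 2 * half_size || half_size < 1)
    stop_invalid("need exactly 2 * half_size trials (got %d, half_size %d)",
                 length(errors), half_size)
  if (any(!is.finite(errors))) stop_invalid("errors must be finite")
  m_first <- mean(errors[seq_len(half_size)])
  m_last <- mean(errors[seq.int(half_size + 1, 2 * half_size)])
  denom <- m_first + m_last
  if (denom == 0)
    stop_invalid("undefined learning rate: first and last half means sum to 0")
  structure(list(value = -(m_first - m_last) / denom,
                 first_half = m_first, last_half = m_last,
                 n_trials = 2L * as.integer(half_size),
                 task = "navigation"),
            class = "learning_rate")
}

#' Verbal memory transfer learning rate
#'
#' `(words correct on last trial - words correct on first trial) / number
#' of trials` over an ordered recall session (at most 5 trials in the
#' full design; recall can stop early when the whole list is recalled).
#'
#' @param n_correct ordered per-trial counts of correctly recalled words.
#' @return object of class `learning_rate` with `value`, `first`, `last`,
#'   `n_trials`, `task = "verbal"`.
#' @examples
#' verbal_learning_rate(c(6, 9, 12))$value  # (12 - 6) / 3 = 2
#' @export
verbal_learning_rate <- function(n_correct) {
  if (length(n_correct) < 1L) stop_invalid("need at least one trial")
  if (any(!is.finite(n_correct)) || any(n_correct < 0))
    stop_invalid("recall counts must be non-negative and finite")
  n <- length(n_correct)
  structure(list(value = (n_correct[n] - n_correct[1]) / n,
                 first = n_correct[1], last = n_correct[n],
                 n_trials = n, task = "verbal"),
            class = "learning_rate")
}

#' @export
print.learning_rate <- function(x, ...) {
  cat(sprintf("%s learning rate: %.4f (n = %d trials)\n",
              x$task, x$value, x$n_trials))
  invisible(x)
}

#' Training slope of daily maximum recall
#'
#' Ordinary least-squares slope of the maximum number of correctly recalled
#' words per day on the day index, computed within a window of days
#' (training analyses fit the first five and last five days separately).
#'
#' @param day integer day indices.
#' @param max_words daily maxima, same length.
#' @param window optional length-2 day range `c(from, to)` (inclusive).
#' @return list with `slope` (words/day), `intercept`, `t` and `p` of the
#'   slope against zero, and `n_days`.
#' @examples
#' training_slope(1:5, c(10, 12, 14, 16, 18))$slope  # 2
#' @export
training_slope <- function(day, max_words, window = NULL) {
  if (length(day) != length(max_words))
    stop_invalid("day and max_words lengths differ")
  if (!is.null(window)) {
    keep <- day >= window[1] & day <= window[2]
    day <- day[keep]; max_words <- max_words[keep]
  }
  if (length(unique(day)) < 2L)
    stop_invalid("need >= 2 distinct days in the window")
  fit <- stats::lm(max_words ~ day)
  # exact-fit inputs trip summary.lm's "essentially perfect fit" warning;
  # the slope and intercept are still exact
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       t = if (nrow(sm) > 1 && ncol(sm) >= 3) unname(sm[2, 3]) else NA_real_,
       p = if (nrow(sm) > 1 && ncol(sm) >= 4) unname(sm[2, 4]) else NA_real_,
       n_days = length(day))
}

#' Correlation with optional covariates and automatic method choice
#'
#' With `method = "auto"` both variables are Shapiro-Wilk tested at
#' alpha = 0.05; Pearson is used when neither rejects normality, Spearman
#' otherwise. Covariates are handled as a partial correlation: both
#' variables are residualized on the covariates by OLS and the residuals
#' correlated (ranks are residualized for Spearman); the t-based p-value
#' uses `df = n - 2 - n_covariates`.
#'
#' @param x,y numeric vectors of equal length (n >= 4, and at least
#'   `n_covariates + 3` observations beyond the intercept when partialling).
#' @param covariates optional numeric matrix/data.frame of covariate columns.
#' @param method `"auto"`, `"pearson"`, or `"spearman"`.
#' @return list with `r`, `p`, `n`, `df`, `method` (resolved).
#' @export
correlate <- function(x, y, covariates = NULL,
                      method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop_invalid("x and y lengths differ")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < max(4L, k + 3L)) stop_invalid("too few observations (n = %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("zero variance in x or y")
  if (method == "auto") {
    pw <- c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
    method <- if (any(pw < 0.05)) "spearman" else "pearson"
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    if (!is.null(covariates))
      covariates <- apply(as.matrix(covariates), 2, rank)
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    x <- stats::lm.fit(cbind(1, cv), x)$residuals
    y <- stats::lm.fit(cbind(1, cv), y)$residuals
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, n = n, df = df, method = method)
}

#' Fisher z-test comparing two independent correlations
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with the
#' p-value from the standard normal, one- or two-sided.
#'
#' @param r1,r2 correlations with `|r| < 1`.
#' @param n1,n2 sample sizes (> 3).
#' @param sided `"two"` or `"one"` (one-sided tests `r1 > r2`).
#' @return list with `Z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop_invalid("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop_invalid("need n > 3 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (sided == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
  list(Z = z, p = p)
}
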