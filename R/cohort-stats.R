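#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return the sample correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(x, y)
}

#' Percentile bootstrap confidence interval of a paired statistic
#'
#' Resamples rows (pairs) with replacement `n_boot` times and returns
#' the central `level` percentile interval of the statistic. Resamples
#' on which the statistic is undefined (e.g. zero variance for a
#' correlation) are redrawn, with a capped retry count.
#'
#' @param statistic function of `(x, y)` (or of `x` alone when `y` is
#'   NULL) returning a scalar.
#' @param x,y data vectors; rows are resampled jointly.
#' @param n_boot number of bootstrap resamples (the reference analysis
#'   uses 1e6; tests scale this down).
#' @param level coverage of the interval.
#' @param max_retries redraw cap per resample.
#' @return numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(statistic, x, y = NULL, n_boot = 1e6,
                         level = 0.95, max_retries = 100L) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (n_boot < 1000) stop("n_boot must be at least 1000")
  if (!is.null(y) && length(y) != n) stop("x and y must have equal length")
  eval_stat <- function(idx) {
    if (is.null(y)) statistic(x[idx]) else statistic(x[idx], y[idx])
  }
  draws <- vapply(seq_len(n_boot), function(b) {
    for (r in seq_len(max_retries)) {
      v <- tryCatch(eval_stat(sample.int(n, n, replace = TRUE)),
                    error = function(e) NA_real_)
      if (!is.na(v)) return(v)
    }
    stop("statistic undefined on ", max_retries, " consecutive resamples")
  }, numeric(1))
  alpha <- (1 - level) / 2
  unname(stats::quantile(draws, c(alpha, 1 - alpha)))
}

correlation_result <- function(x, y, n_boot, level = 0.95) {
  r <- pearson_r(x, y)
  ci <- bootstrap_ci(function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance")
    stats::cor(a, b)
  }, x, y, n_boot = n_boot, level = level)
  structure(list(r = r, ci_low = ci[1L], ci_high = ci[2L],
                 n_boot = as.integer(n_boot), n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.2f, 95%% CI [%.2f, %.2f] (n = %d, %d resamples)\n",
              x$r, x$ci_low, x$ci_high, x$n, x$n_boot))
  invisible(x)
}

#' Consistency of L between the first and the second selection
#'
#' Pearson correlation, with a percentile bootstrap CI, between the
#' per-participant MAP values of L fitted separately to the first and
#' to the second choice. A positive correlation is the signature of
#' stable individual differences in sensitivity to popularity.
#'
#' @param fits data.frame with columns `L_map_first` and `L_map_second`
#'   (e.g. from [fit_choices_cohort()]).
#' @param n_boot bootstrap resamples.
#' @return a `correlation_result`.
#' @export
first_second_consistency <- function(fits, n_boot = 1e6) {
  stopifnot(all(c("L_map_first", "L_map_second") %in% names(fits)))
  correlation_result(fits$L_map_first, fits$L_map_second, n_boot)
}

#' Correlations of fitted L with the five personality traits
#'
#' One Pearson correlation (with percentile bootstrap CI) per Big Five
#' trait between the participants' fitted sensitivity and their trait
#' scores. No multiple-comparison adjustment is applied; raw intervals
#' are reported.
#'
#' @param L_map numeric vector of per-participant fitted L (the joint
#'   two-selection fit).
#' @param personality data.frame with `participant_id` and the five
#'   trait columns `openness`, `conscientiousness`, `extraversion`,
#'   `agreeableness`, `neuroticism`.
#' @param n_boot bootstrap resamples.
#' @return named list of `correlation_result`, one per trait.
#' @export
trait_correlations <- function(L_map, personality, n_boot = 1e6) {
  traits <- c("openness", "conscientiousness", "extraversion",
              "agreeableness", "neuroticism")
  if (!all(traits %in% names(personality))) {
    stop("personality table must have columns ", paste(traits, collapse = ", "))
  }
  if (length(L_map) != nrow(personality)) {
    stop("L_map length must match the personality table")
  }
  stats::setNames(lapply(traits, function(tr) {
    correlation_result(L_map, personality[[tr]], n_boot)
  }), traits)
}
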