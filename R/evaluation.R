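# Validation statistics for screening algorithms: confusion-matrix
# diagnostics, stratified importance-sampling rate estimation, nonparametric
# bootstrap intervals, and predictive-value-adjusted prevalence.

#' Confusion counts from truth and prediction vectors
#'
#' @param truth,pred Logical vectors of equal length (manual truth labels
#'   and detector predictions).
#' @return A list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.logical(truth); pred <- as.logical(pred)
  stopifnot(!anyNA(truth), !anyNA(pred))
  list(tp = sum(truth & pred), fp = sum(!truth & pred),
       fn = sum(truth & !pred), tn = sum(!truth & !pred))
}

#' Diagnostic metrics of a screening algorithm
#'
#' Computes sensitivity (recall), specificity, positive and negative
#' predictive value, accuracy, the true and estimated prevalence, and the
#' error (absolute difference of the two prevalences). Ratios with a zero
#' denominator are returned as `NA` ("undefined"), never silently as zero.
#'
#' @param tp,fp,fn,tn Non-negative counts, or a list with those elements as
#'   the first argument.
#' @return A list of class `transcreen_metrics`.
#' @examples
#' diagnostic_metrics(tp = 9, fp = 1, fn = 1, tn = 89)
#' @export
diagnostic_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.list(tp)) {
    c0 <- tp
    tp <- c0$tp; fp <- c0$fp; fn <- c0$fn; tn <- c0$tn
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("diagnostic_metrics needs at least one observation")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  prevalence_true <- (tp + fn) / total
  prevalence_est <- (tp + fp) / total
  out <- list(
    tp = tp, fp = fp, fn = fn, tn = tn, total = total,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / total,
    prevalence_true = prevalence_true,
    prevalence_est = prevalence_est,
    error = abs(prevalence_true - prevalence_est)
  )
  class(out) <- "transcreen_metrics"
  out
}

#' @export
print.transcreen_metrics <- function(x, ...) {
  cat(sprintf("<diagnostics> n=%d  tp=%d fp=%d fn=%d tn=%d\n",
              x$total, x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.3f", v))
  cat(sprintf("  sensitivity %s  specificity %s  ppv %s  npv %s  accuracy %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
              fmt(x$accuracy)))
  cat(sprintf("  prevalence true %.3f / estimated %.3f  (error %.3f)\n",
              x$prevalence_true, x$prevalence_est, x$error))
  invisible(x)
}

#' Stratified importance-weighted positive rate
#'
#' Estimates the positive rate of a population that was sampled by strata,
#' oversampling informative strata: the estimated population positive count
#' is `sum(N_h / n_h * positives_h)` and the rate is that count divided by
#' `sum(N_h)`. Strata sampled exhaustively contribute their exact count.
#' This is how a rare error rate (e.g. false negatives of a detector) is
#' estimated from a handful of manually checked articles per stratum.
#'
#' @param design A data frame with columns `N_total` (population size of the
#'   stratum), `n_sampled`, `n_positive`, and optionally `label`.
#' @return A list with `rate`, `estimated_positives`, `N`, and `se` (the
#'   stratified standard error of the rate, with finite-population
#'   correction; strata with fewer than two sampled units contribute no
#'   variance).
#' @examples
#' weighted_rate(data.frame(N_total = c(90, 10), n_sampled = c(9, 10),
#'                          n_positive = c(0, 1)))
#' @export
weighted_rate <- function(design) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("N_total", "n_sampled", "n_positive") %in% names(design)))
  if ("label" %in% names(design) && anyDuplicated(design$label) > 0) {
    stop("stratum labels must be unique")
  }
  with(design, {
    stopifnot(all(n_positive >= 0), all(n_positive <= n_sampled),
              all(n_sampled <= N_total))
    if (any(n_sampled == 0 & N_total > 0)) {
      stop("every non-empty stratum needs at least one sampled article")
    }
  })
  live <- design[design$N_total > 0, , drop = FALSE]
  N <- sum(live$N_total)
  if (N == 0) return(list(rate = NA_real_, estimated_positives = 0, N = 0, se = NA_real_))
  est_pos <- sum(live$N_total / live$n_sampled * live$n_positive)
  p_h <- live$n_positive / live$n_sampled
  s2 <- ifelse(live$n_sampled >= 2,
               live$n_sampled / (live$n_sampled - 1) * p_h * (1 - p_h), 0)
  var_rate <- sum(live$N_total^2 * (1 - live$n_sampled / live$N_total) *
                    s2 / live$n_sampled) / N^2
  list(rate = est_pos / N, estimated_positives = est_pos, N = N,
       se = sqrt(var_rate))
}

#' Adjust an observed flag rate for detector error
#'
#' For an observed prevalence `p` and the detector's positive and negative
#' predictive values, the adjusted prevalence is
#' `p * PPV + (1 - p) * (1 - NPV)`: the expected proportion of truly
#' positive articles given the proportion flagged. When `PPV + NPV >= 1` the
#' result lies in `[1 - NPV, PPV]` and is monotone non-decreasing in `p`.
#'
#' @param p,ppv,npv Fractions in `[0, 1]` (vectorized).
#' @return Adjusted prevalence, same length as the longest argument.
#' @examples
#' adjusted_prevalence(0.5, ppv = 0.9, npv = 0.8) # 0.55
#' @export
adjusted_prevalence <- function(p, ppv, npv) {
  args <- cbind(p = p, ppv = ppv, npv = npv)
  if (anyNA(args) || any(args < 0) || any(args > 1)) {
    stop("p, ppv and npv must all lie in [0, 1]")
  }
  unname(args[, "p"] * args[, "ppv"] + (1 - args[, "p"]) * (1 - args[, "npv"]))
}

#' Nonparametric bootstrap confidence interval
#'
#' Resamples the data with replacement — independently within each stratum
#' when `strata` is given, so every sampling stage contributes its
#' variability — recomputes the statistic per iteration, and returns the
#' configured empirical quantiles (order-statistic quantiles, no
#' interpolation correction). Iterations where the statistic is undefined
#' (`NA`) are skipped and counted.
#'
#' @param sample_data A vector or data frame of observations.
#' @param statistic Function of a resampled copy of `sample_data` returning
#'   a single number.
#' @param iterations Number of bootstrap iterations.
#' @param lower_q,upper_q Interval quantiles, `0 < lower_q < upper_q < 1`.
#' @param seed Optional integer seed for reproducibility.
#' @param strata Optional vector (same length as the data) of stratum
#'   labels; resampling is stratified on it.
#' @return A list with `point` (statistic on the original data), `lower`,
#'   `upper`, `iterations`, and `n_skipped`.
#' @examples
#' bootstrap_ci(rbinom(50, 1, 0.3), mean, iterations = 200, seed = 1)
#' @export
bootstrap_ci <- function(sample_data, statistic, iterations = 5000,
                         lower_q = 0.025, upper_q = 0.975, seed = NULL,
                         strata = NULL) {
  if (!is.numeric(iterations) || iterations < 1) stop("iterations must be >= 1")
  stopifnot(lower_q > 0, upper_q < 1, lower_q < upper_q)
  n <- if (is.data.frame(sample_data)) nrow(sample_data) else length(sample_data)
  if (n == 0) stop("sample_data is empty")
  take <- function(x, idx) if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
  idx_groups <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)

  run <- function() {
    vapply(seq_len(iterations), function(b) {
      idx <- unlist(lapply(idx_groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      as.numeric(statistic(take(sample_data, idx)))
    }, numeric(1))
  }
  stats <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  skipped <- sum(is.na(stats))
  stats <- stats[!is.na(stats)]
  if (length(stats) == 0) stop("statistic was undefined in every iteration")
  qs <- stats::quantile(stats, c(lower_q, upper_q), type = 1, names = FALSE)
  list(point = as.numeric(statistic(sample_data)),
       lower = qs[1], upper = qs[2],
       iterations = as.integer(iterations), n_skipped = skipped)
}
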