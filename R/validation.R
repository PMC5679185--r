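#' Per-patient differences between measured and estimated GFR
#'
#' The convention throughout the package is `mgfr - egfr`, so a positive
#' bias means the model underestimates GFR.  The opposite sign can be
#' selected with `direction` for comparison with sources that report
#' `egfr - mgfr`.
#'
#' @param cohort cohort data frame; every record must have `mgfr`.
#' @param egfr numeric vector of estimated GFR aligned with the cohort rows.
#' @param direction `"mgfr_minus_egfr"` (default) or `"egfr_minus_mgfr"`.
#' @return Named numeric vector of differences (names are patient ids).
#' @export
gfr_differences <- function(cohort, egfr,
                            direction = c("mgfr_minus_egfr",
                                          "egfr_minus_mgfr")) {
  direction <- match.arg(direction)
  cohort <- check_cohort(cohort, require_mgfr = TRUE)
  if (!is.numeric(egfr) || length(egfr) != nrow(cohort))
    stop("`egfr` must be numeric with one entry per cohort record",
         call. = FALSE)
  if (any(!is.finite(egfr)))
    stop("`egfr` must be finite", call. = FALSE)
  d <- cohort$mgfr - egfr
  if (direction == "egfr_minus_mgfr") d <- -d
  names(d) <- cohort$id
  d
}

#' Bias, precision and P30 accuracy of a GFR estimate
#'
#' The three headline agreement metrics of GFR equation validation:
#' \describe{
#'   \item{bias}{the median of the per-patient differences
#'     (`median_bias`);}
#'   \item{precision}{the interquartile range Q3 − Q1 of the differences
#'     (`iqr_precision`), computed with linear interpolation of order
#'     statistics ([stats::quantile()] type 7);}
#'   \item{P30 accuracy}{the proportion of patients whose estimate lies
#'     within ±30\% of the measured value, boundary inclusive
#'     (`p30_accuracy`); `p30_hits` returns the underlying 0/1 vector.}
#' }
#'
#' @param d numeric vector of per-patient differences, e.g. from
#'   [gfr_differences()].
#' @return `median_bias` and `iqr_precision` return a single value in
#'   ml/min/1.73 m\eqn{^2}; `p30_accuracy` a proportion in `[0, 1]`;
#'   `p30_hits` an integer 0/1 vector.
#' @export
#' @examples
#' median_bias(c(-1, 0, 4))
#' iqr_precision(c(1, 2, 3, 4))
#' p30_accuracy(mgfr = c(100, 100), egfr = c(130, 130.1))
median_bias <- function(d) {
  if (length(d) < 1L || any(!is.finite(d)))
    stop("`d` must be a non-empty vector of finite differences",
         call. = FALSE)
  stats::median(d)
}

#' @rdname median_bias
#' @export
iqr_precision <- function(d) {
  if (length(d) < 2L || any(!is.finite(d)))
    stop("`d` must hold at least two finite differences", call. = FALSE)
  stats::IQR(d, type = 7)
}

#' @rdname median_bias
#' @param mgfr measured GFR (positive).
#' @param egfr estimated GFR, aligned with `mgfr`.
#' @export
p30_hits <- function(mgfr, egfr) {
  if (length(mgfr) != length(egfr))
    stop("`mgfr` and `egfr` must have equal length", call. = FALSE)
  if (any(!is.finite(mgfr)) || any(mgfr <= 0))
    stop("`mgfr` must be finite and positive", call. = FALSE)
  if (any(!is.finite(egfr)))
    stop("`egfr` must be finite", call. = FALSE)
  as.integer(abs(egfr - mgfr) <= 0.30 * mgfr)
}

#' @rdname median_bias
#' @export
p30_accuracy <- function(mgfr, egfr) {
  if (length(mgfr) < 1L)
    stop("at least one patient is required", call. = FALSE)
  mean(p30_hits(mgfr, egfr))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients with replacement `B` times, recomputes the statistic
#' on each resample, and returns the empirical `(1 - level)/2` and
#' `1 - (1 - level)/2` quantiles of the resampled statistics.
#'
#' @param x numeric vector (resampled element-wise) or data frame
#'   (resampled by row).
#' @param statistic function mapping a resample of `x` to a single number.
#' @param B number of bootstrap resamples (default 2000, minimum 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the interval is reproducible for a fixed seed.
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' bootstrap_ci(rnorm(50), median, B = 200, seed = 7)
bootstrap_ci <- function(x, statistic, B = 2000L, level = 0.95, seed = 1L) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n < 2L) stop("bootstrap needs at least two observations", call. = FALSE)
  if (B < 100L) stop("`B` must be at least 100", call. = FALSE)
  statistic <- match.fun(statistic)
  take <- if (is.data.frame(x)) function(i) x[i, , drop = FALSE]
          else function(i) x[i]
  set.seed(seed)
  stats <- vapply(seq_len(B), function(b) {
    statistic(take(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE, type = 7)
}

#' Paired significance tests against a benchmark model
#'
#' Three paired tests compare a candidate model with a benchmark on the
#' same patients:
#' \describe{
#'   \item{`compare_bias_wilcoxon`}{two-sided Wilcoxon signed rank test on
#'     the per-patient paired values `dA[i] - dB[i]`.  Zero paired
#'     differences are dropped (classic signed-rank convention); the exact
#'     null distribution is used for up to 25 non-zero pairs without ties
#'     in the absolute values, otherwise the normal approximation with tie
#'     correction and continuity correction.  If every paired difference
#'     is zero the p-value is 1.}
#'   \item{`compare_precision_bootstrap`}{paired percentile-bootstrap test
#'     of equal interquartile ranges: each of `B` draws resamples patient
#'     indices once and evaluates `IQR(dA*) - IQR(dB*)`; the achieved
#'     significance level is `2 * min(P(D* <= 0), P(D* >= 0))`, capped at
#'     1.}
#'   \item{`compare_accuracy_mcnemar`}{two-sided McNemar test on the
#'     paired P30 hit indicators, driven only by the discordant counts
#'     `b` (A hit, B miss) and `c` (A miss, B hit): exact binomial when
#'     `b + c < 25`, chi-square with continuity correction otherwise, and
#'     p = 1 when there are no discordant pairs.}
#' }
#'
#' @param dA,dB per-patient difference vectors for the two models, same
#'   patients in the same order (e.g. from [gfr_differences()]).
#' @return A two-sided p-value in `[0, 1]`.
#' @export
compare_bias_wilcoxon <- function(dA, dB) {
  if (length(dA) != length(dB))
    stop("`dA` and `dB` must pair the same patients", call. = FALSE)
  if (any(!is.finite(dA)) || any(!is.finite(dB)))
    stop("differences must be finite", call. = FALSE)
  z <- dA - dB
  z <- z[z != 0]
  n <- length(z)
  if (n == 0L) return(1)
  exact <- n <= 25L && !anyDuplicated(abs(z))
  suppressWarnings(
    stats::wilcox.test(z, mu = 0, exact = exact, correct = TRUE)$p.value
  )
}

#' @rdname compare_bias_wilcoxon
#' @param B number of bootstrap resamples (default 2000, minimum 100).
#' @param seed integer seed for the resampling.
#' @export
compare_precision_bootstrap <- function(dA, dB, B = 2000L, seed = 1L) {
  if (length(dA) != length(dB))
    stop("`dA` and `dB` must pair the same patients", call. = FALSE)
  n <- length(dA)
  if (n < 2L) stop("at least two pairs are required", call. = FALSE)
  if (B < 100L) stop("`B` must be at least 100", call. = FALSE)
  set.seed(seed)
  delta <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    stats::IQR(dA[i], type = 7) - stats::IQR(dB[i], type = 7)
  }, numeric(1))
  min(1, 2 * min(mean(delta <= 0), mean(delta >= 0)))
}

#' @rdname compare_bias_wilcoxon
#' @param hitsA,hitsB paired 0/1 vectors marking P30 success for the two
#'   models (see [p30_hits()]).
#' @export
compare_accuracy_mcnemar <- function(hitsA, hitsB) {
  if (length(hitsA) != length(hitsB))
    stop("`hitsA` and `hitsB` must pair the same patients", call. = FALSE)
  if (!all(hitsA %in% c(0, 1)) || !all(hitsB %in% c(0, 1)))
    stop("hit vectors must contain only 0 and 1", call. = FALSE)
  b <- sum(hitsA == 1 & hitsB == 0)
  cc <- sum(hitsA == 0 & hitsB == 1)
  if (b + cc == 0L) return(1)
  if (b + cc < 25L) return(stats::binom.test(b, b + cc, p = 0.5)$p.value)
  m <- matrix(c(sum(hitsA == 1 & hitsB == 1), cc,
                b, sum(hitsA == 0 & hitsB == 0)), nrow = 2L)
  stats::mcnemar.test(m, correct = TRUE)$p.value
}

## joint bootstrap of (bias, precision, accuracy) over one set of resamples
summary_ci <- function(d, hits, B, level, seed) {
  n <- length(d)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = B, ncol = 3L)
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    draws[b, ] <- c(stats::median(d[i]), stats::IQR(d[i], type = 7),
                    mean(hits[i]))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  apply(draws, 2L, stats::quantile, probs = probs, names = FALSE, type = 7)
}

#' Performance summary of one model on one (sub)cohort
#'
#' Point estimates and percentile-bootstrap confidence intervals for the
#' three agreement metrics (see [median_bias()]).  The three intervals are
#' computed on one shared set of patient resamples.
#'
#' @param mgfr measured GFR (positive).
#' @param egfr estimated GFR, aligned with `mgfr`.
#' @param B bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param direction difference direction, see [gfr_differences()].
#' @return A one-row data frame with columns `n`, `bias`, `bias_lo`,
#'   `bias_hi`, `precision`, `precision_lo`, `precision_hi`, `accuracy`,
#'   `accuracy_lo`, `accuracy_hi`.  With fewer than two patients the
#'   spread and interval entries are `NA`.
#' @export
performance_summary <- function(mgfr, egfr, B = 2000L, level = 0.95,
                                seed = 1L,
                                direction = c("mgfr_minus_egfr",
                                              "egfr_minus_mgfr")) {
  direction <- match.arg(direction)
  out <- data.frame(n = length(mgfr), bias = NA_real_, bias_lo = NA_real_,
                    bias_hi = NA_real_, precision = NA_real_,
                    precision_lo = NA_real_, precision_hi = NA_real_,
                    accuracy = NA_real_, accuracy_lo = NA_real_,
                    accuracy_hi = NA_real_)
  if (length(mgfr) == 0L) return(out)
  d <- mgfr - egfr
  if (direction == "egfr_minus_mgfr") d <- -d
  hits <- p30_hits(mgfr, egfr)
  out$bias <- median_bias(d)
  out$accuracy <- mean(hits)
  if (length(d) >= 2L) {
    out$precision <- iqr_precision(d)
    ci <- summary_ci(d, hits, B, level, seed)
    out[, c("bias_lo", "bias_hi")] <- ci[, 1L]
    out[, c("precision_lo", "precision_hi")] <- ci[, 2L]
    out[, c("accuracy_lo", "accuracy_hi")] <- ci[, 3L]
  }
  out
}

## bin labels for a set of GFR cut points, half-open [lo, hi)
subgroup_labels <- function(breaks) {
  k <- length(breaks)
  c(paste0("<", breaks[1L]),
    if (k > 1L) paste0(breaks[-k], "-", breaks[-1L]),
    paste0(">=", breaks[k]))
}

assign_subgroup <- function(mgfr, breaks) {
  cut(mgfr, c(-Inf, breaks, Inf), right = FALSE,
      labels = subgroup_labels(breaks))
}

#' GFR-stratified performance summaries for a set of models
#'
#' Computes [performance_summary()] for each model on the whole cohort and
#' within measured-GFR subgroups.  Subgroups are half-open intervals
#' `[lo, hi)` on measured (not estimated) GFR, so with the default breaks
#' `c(30, 60)` a patient with mGFR 30 falls in `30-60` and one with mGFR
#' 60 in `>=60`.
#'
#' @param cohort cohort data frame; every record must have `mgfr`.
#' @param predictions named list of estimated-GFR vectors, one per model.
#' @param breaks increasing GFR cut points (default `c(30, 60)`).  The
#'   finer five-stage grid is `c(15, 30, 60, 90)`.
#' @param B,level,seed,direction see [performance_summary()].  Sub-seeds
#'   for each (model, subgroup) cell are derived from `seed` with
#'   [derive_seed()].
#' @return A data frame with one row per model and subgroup (including
#'   `"Overall"`), with the [performance_summary()] columns.  An empty
#'   subgroup yields `n = 0` and `NA` metrics.
#' @export
stratified_summary <- function(cohort, predictions, breaks = c(30, 60),
                               B = 2000L, level = 0.95, seed = 1L,
                               direction = c("mgfr_minus_egfr",
                                             "egfr_minus_mgfr")) {
  direction <- match.arg(direction)
  cohort <- check_cohort(cohort, require_mgfr = TRUE)
  stopifnot(is.list(predictions), length(predictions) >= 1L,
            !is.null(names(predictions)), all(nzchar(names(predictions))))
  if (any(!vapply(predictions, length, integer(1)) == nrow(cohort)))
    stop("every prediction vector must match the cohort size", call. = FALSE)
  if (any(diff(breaks) <= 0))
    stop("`breaks` must be strictly increasing", call. = FALSE)
  groups <- c("Overall", subgroup_labels(breaks))
  bin <- as.character(assign_subgroup(cohort$mgfr, breaks))
  rows <- list(); cell <- 0L
  for (model in names(predictions)) {
    for (g in groups) {
      cell <- cell + 1L
      idx <- if (g == "Overall") seq_len(nrow(cohort)) else which(bin == g)
      s <- performance_summary(cohort$mgfr[idx], predictions[[model]][idx],
                               B = B, level = level,
                               seed = derive_seed(seed, cell),
                               direction = direction)
      rows[[cell]] <- cbind(data.frame(model = model, subgroup = g,
                                       stringsAsFactors = FALSE), s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate models against a benchmark, overall and by GFR stratum
#'
#' The full validation report: per-model, per-subgroup
#' [performance_summary()] rows with bootstrap confidence intervals, and,
#' for every non-benchmark model, paired significance tests against the
#' benchmark (Wilcoxon signed rank for bias, paired bootstrap for IQR
#' precision, McNemar for P30 accuracy; see [compare_bias_wilcoxon()]).
#' Comparisons are flagged significant at p < 0.05; no multiplicity
#' adjustment is applied.
#'
#' @inheritParams stratified_summary
#' @param benchmark name of the benchmark model in `predictions`.
#' @return An object of class `"gfr_report"`: a list with elements
#'   `summaries` (data frame, see [stratified_summary()]), `comparisons`
#'   (data frame with `candidate`, `benchmark`, `subgroup`, `n`, `p_bias`,
#'   `p_precision`, `p_accuracy`, `significant_*` flags) and `meta`.
#' @export
evaluate_models <- function(cohort, predictions, benchmark = "regression",
                            breaks = c(30, 60), B = 2000L, level = 0.95,
                            seed = 1L,
                            direction = c("mgfr_minus_egfr",
                                          "egfr_minus_mgfr")) {
  direction <- match.arg(direction)
  cohort <- check_cohort(cohort, require_mgfr = TRUE)
  if (!benchmark %in% names(predictions))
    stop("benchmark '", benchmark, "' not found among the predictions",
         call. = FALSE)
  summaries <- stratified_summary(cohort, predictions, breaks = breaks,
                                  B = B, level = level, seed = seed,
                                  direction = direction)
  groups <- c("Overall", subgroup_labels(breaks))
  bin <- as.character(assign_subgroup(cohort$mgfr, breaks))
  d_bench <- gfr_differences(cohort, predictions[[benchmark]],
                             direction = direction)
  hits_bench <- p30_hits(cohort$mgfr, predictions[[benchmark]])
  rows <- list(); cell <- 0L
  for (model in setdiff(names(predictions), benchmark)) {
    d_cand <- gfr_differences(cohort, predictions[[model]],
                              direction = direction)
    hits_cand <- p30_hits(cohort$mgfr, predictions[[model]])
    for (g in groups) {
      cell <- cell + 1L
      idx <- if (g == "Overall") seq_len(nrow(cohort)) else which(bin == g)
      p_bias <- p_prec <- p_acc <- NA_real_
      if (length(idx) >= 2L) {
        p_bias <- compare_bias_wilcoxon(d_cand[idx], d_bench[idx])
        p_prec <- compare_precision_bootstrap(
          d_cand[idx], d_bench[idx], B = B,
          seed = derive_seed(seed, 100000L + cell))
        p_acc <- compare_accuracy_mcnemar(hits_cand[idx], hits_bench[idx])
      }
      rows[[cell]] <- data.frame(
        candidate = model, benchmark = benchmark, subgroup = g,
        n = length(idx), p_bias = p_bias, p_precision = p_prec,
        p_accuracy = p_acc,
        significant_bias = !is.na(p_bias) & p_bias < 0.05,
        significant_precision = !is.na(p_prec) & p_prec < 0.05,
        significant_accuracy = !is.na(p_acc) & p_acc < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate = character(0), benchmark = character(0),
               subgroup = character(0), n = integer(0),
               p_bias = numeric(0), p_precision = numeric(0),
               p_accuracy = numeric(0), significant_bias = logical(0),
               significant_precision = logical(0),
               significant_accuracy = logical(0))
  rownames(comparisons) <- NULL
  structure(list(summaries = summaries, comparisons = comparisons,
                 meta = list(benchmark = benchmark, breaks = breaks,
                             B = as.integer(B), level = level,
                             seed = as.integer(seed),
                             direction = direction,
                             n = nrow(cohort))),
            class = "gfr_report")
}

#' @export
print.gfr_report <- function(x, ...) {
  cat(render_report(x, format = "markdown"), sep = "\n")
  invisible(x)
}
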