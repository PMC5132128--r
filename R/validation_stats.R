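#' Concordance of a test call set against an orthogonal truth set
#'
#' Calls are keyed by (chrom, pos, ref, alt); truth-negative positions
#' (sites asserted wild-type by the orthogonal technology) are keyed by
#' (chrom, pos). True/false positives at truth-negative positions are
#' judged by position: any test call at a truth-negative position is a
#' false positive, a truth-negative position with no test call is a true
#' negative.
#'
#' @param test_calls,truth_calls data.frames with columns `chrom, pos,
#'   ref, alt`.
#' @param truth_negatives data.frame with columns `chrom, pos`, or `NULL`.
#' @return list of class `concordance_table` with counts `tp, fn, tn, fp`.
#' @export
build_concordance <- function(test_calls, truth_calls,
                              truth_negatives = NULL) {
  tk <- variant_key(test_calls$chrom, test_calls$pos, test_calls$ref,
                    test_calls$alt)
  uk <- variant_key(truth_calls$chrom, truth_calls$pos, truth_calls$ref,
                    truth_calls$alt)
  assert_that(!anyDuplicated(tk), "duplicate keys in test calls")
  assert_that(!anyDuplicated(uk), "duplicate keys in truth calls")
  tp <- sum(uk %in% tk)
  fn <- sum(!(uk %in% tk))
  tn <- fp <- 0L
  if (!is.null(truth_negatives) && nrow(truth_negatives) > 0) {
    nk <- paste(truth_negatives$chrom, truth_negatives$pos, sep = ":")
    assert_that(!anyDuplicated(nk), "duplicate truth-negative positions")
    test_pos <- paste(test_calls$chrom, test_calls$pos, sep = ":")
    fp <- sum(nk %in% test_pos)
    tn <- sum(!(nk %in% test_pos))
  }
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 tn = as.integer(tn), fp = as.integer(fp)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("concordance_table: TP %d, FN %d, TN %d, FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Binomial confidence interval
#'
#' Wilson score interval or exact Clopper-Pearson interval for a binomial
#' proportion, both clipped to `[0, 1]`. Clopper-Pearson bounds are
#' computed from the beta quantile form: `low = qbeta(a/2, x, n-x+1)`,
#' `high = qbeta(1-a/2, x+1, n-x)`, with `low = 0` at `x = 0` and
#' `high = 1` at `x = n`.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param method `"wilson"` or `"exact"`.
#' @param level confidence level in (0, 1).
#' @return numeric vector `c(low, high)`.
#' @export
binomial_ci <- function(x, n, method = c("wilson", "exact"), level = 0.95) {
  method <- match.arg(method)
  assert_that(n >= 1 && x >= 0 && x <= n, "need 0 <= x <= n, n >= 1")
  assert_that(level > 0 && level < 1, "level must be in (0, 1)")
  alpha <- 1 - level
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    out <- c(centre - half, centre + half)
  } else {
    low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    out <- c(low, high)
  }
  pmin(pmax(out, 0), 1)
}

proportion_estimate <- function(x, n, method, level, what) {
  assert_that(n >= 1, "%s undefined: no informative counts (n = 0)", what)
  ci <- binomial_ci(x, n, method, level)
  structure(list(x = as.integer(x), n = as.integer(n), estimate = x / n,
                 ci_low = ci[1], ci_high = ci[2], method = method,
                 level = level,
                 percent = round_half_up(100 * x / n, 1),
                 what = what),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%s: %d/%d = %s%% (%d%% CI %s-%s%%, %s)\n", x$what, x$x, x$n,
              percent1(x$estimate), round(100 * x$level),
              percent1(x$ci_low), percent1(x$ci_high), x$method))
  invisible(x)
}

#' Sensitivity with binomial confidence interval
#'
#' `tp / (tp + fn)` with Wilson or exact Clopper-Pearson interval;
#' the percentage is rendered to one decimal, half away from zero.
#'
#' @param tab a [build_concordance()] table (or any list with `tp`, `fn`).
#' @param method,level see [binomial_ci()].
#' @return a `proportion_estimate`.
#' @export
sensitivity <- function(tab, method = c("wilson", "exact"), level = 0.95) {
  proportion_estimate(tab$tp, tab$tp + tab$fn, match.arg(method), level,
                      "sensitivity")
}

#' Specificity with binomial confidence interval
#'
#' `tn / (tn + fp)`.
#'
#' @inheritParams sensitivity
#' @return a `proportion_estimate`.
#' @export
specificity <- function(tab, method = c("wilson", "exact"), level = 0.95) {
  proportion_estimate(tab$tn, tab$tn + tab$fp, match.arg(method), level,
                      "specificity")
}

#' Reproducibility across replicate call sets
#'
#' Fraction of variant keys observed in every replicate of their sample,
#' over keys observed in any replicate of that sample (pooled across
#' samples). 1.0 means every variant found once was found on every
#' repeat.
#'
#' @param replicate_sets list (one element per sample) of lists of
#'   character vectors of variant keys, each inner vector one replicate;
#'   every sample needs at least two replicates.
#' @return list with `fraction`, `n_concordant`, `n_union`.
#' @export
reproducibility <- function(replicate_sets) {
  n_conc <- 0L; n_union <- 0L
  for (reps in replicate_sets) {
    assert_that(length(reps) >= 2, "each sample needs >= 2 replicates")
    reps <- lapply(reps, unique)
    all_keys <- Reduce(union, reps)
    shared <- Reduce(intersect, reps)
    n_union <- n_union + length(all_keys)
    n_conc <- n_conc + length(shared)
  }
  list(fraction = if (n_union > 0) n_conc / n_union else NA_real_,
       n_concordant = n_conc, n_union = n_union)
}
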