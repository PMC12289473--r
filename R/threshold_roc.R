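#' ROC analysis of same-syndrome vs random distance samples
#'
#' Distances below the cutoff are called "same disorder", so sensitivity
#' at threshold `c` is the fraction of same-syndrome samples `<= c` and
#' specificity the fraction of random samples `> c`. Candidate thresholds
#' are the midpoints between consecutive distinct values of the pooled
#' samples, plus one sentinel below the minimum and one above the maximum,
#' which makes the inclusive `<=` rule unambiguous. AUC is the
#' Mann-Whitney rank statistic: the probability that a same-syndrome
#' sample lies below a random sample, ties counted half.
#'
#' @param same Numeric vector of same-syndrome distance samples.
#' @param random Numeric vector of random-null distance samples.
#' @return Object of class `roc_result` with fields `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `youden_threshold`,
#'   `youden_sensitivity`, `youden_specificity`.
#' @export
roc_from_samples <- function(same, random) {
  if (length(same) == 0L || length(random) == 0L) {
    stop("both sample vectors must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(same)) || any(!is.finite(random))) {
    stop("non-finite values in samples", call. = FALSE)
  }
  pooled <- sort(unique(c(same, random)))
  if (length(pooled) > 1L) {
    mids <- (pooled[-length(pooled)] + pooled[-1L]) / 2
  } else {
    mids <- numeric(0)
  }
  thresholds <- c(pooled[1L] - 1, mids, pooled[length(pooled)] + 1)
  sens <- vapply(thresholds, function(ct) mean(same <= ct), numeric(1))
  spec <- vapply(thresholds, function(ct) mean(random > ct), numeric(1))

  # rank statistic: U counts (same > random) pairs, ties half
  ns <- length(same); nr <- length(random)
  r <- rank(c(same, random))
  u_greater <- sum(r[seq_len(ns)]) - ns * (ns + 1) / 2
  auc <- 1 - u_greater / (ns * nr)

  res <- structure(
    list(thresholds = thresholds, sensitivity = sens, specificity = spec,
         auc = auc, youden_threshold = NA_real_,
         youden_sensitivity = NA_real_, youden_specificity = NA_real_),
    class = "roc_result"
  )
  y <- youden_threshold(res)
  res$youden_threshold <- y$threshold
  res$youden_sensitivity <- y$sensitivity
  res$youden_specificity <- y$specificity
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f; Youden c = %.3f (sensitivity %.3f, specificity %.3f)\n",
    x$auc, x$youden_threshold, x$youden_sensitivity, x$youden_specificity))
  invisible(x)
}

#' Youden-index optimal threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` over the ROC's candidate
#' thresholds; ties are broken toward the smallest threshold (for
#' indistinguishable distributions this returns the sentinel below all
#' data, with J = 0).
#'
#' @param roc A [roc_from_samples()] result.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  # smallest threshold among the maximizers; the tolerance absorbs
  # one-ulp differences between equal count ratios (e.g. 21/30 + 25/30
  # vs 23/30 + 23/30)
  best <- which(j >= max(j) - 1e-12)[1L]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       youden = j[best])
}

#' k-fold cross-validated threshold performance
#'
#' Same-syndrome and random samples are independently shuffled and dealt
#' into `k` folds (stratified, so every fold holds both classes). For
#' each fold the Youden threshold is fitted on the other `k - 1` folds
#' and evaluated on the held-out fold, giving out-of-fold sensitivity and
#' specificity.
#'
#' @inheritParams roc_from_samples
#' @param k Number of folds (default 5).
#' @param seed Optional integer seed for the fold shuffle.
#' @return Object of class `cv_report`: `k`, `per_fold` (data.frame with
#'   `fold`, `threshold`, `sensitivity`, `specificity`),
#'   `mean_sensitivity`, `mean_specificity`, `seed`.
#' @export
crossvalidate <- function(same, random, k = 5L, seed = NULL) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > min(length(same), length(random))) {
    stop(sprintf("k = %d exceeds the smaller sample size (%d)",
                 k, min(length(same), length(random))), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fold_of <- function(n) {
    rep_len(seq_len(k), n)[sample.int(n)]
  }
  fs <- fold_of(length(same))
  fr <- fold_of(length(random))
  per_fold <- do.call(rbind, lapply(seq_len(k), function(i) {
    fit <- roc_from_samples(same[fs != i], random[fr != i])
    ct <- fit$youden_threshold
    data.frame(fold = i, threshold = ct,
               sensitivity = mean(same[fs == i] <= ct),
               specificity = mean(random[fr == i] > ct))
  }))
  structure(
    list(k = k, per_fold = per_fold,
         mean_sensitivity = mean(per_fold$sensitivity),
         mean_specificity = mean(per_fold$specificity),
         seed = if (is.null(seed)) NA_integer_ else seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold CV: mean sensitivity %.3f, mean specificity %.3f\n",
    x$k, x$mean_sensitivity, x$mean_specificity))
  invisible(x)
}

#' Fraction of a distance distribution at or below a cutoff
#'
#' Applied to the test cohort's resampled distribution this is the
#' headline cohort-similarity statistic: the share of sub-cohort draws
#' classified as "same disorder" by the fitted threshold.
#'
#' @param values Non-empty numeric vector.
#' @param c Cutoff; values `<= c` count (inclusive, matching the
#'   sensitivity definition).
#' @return A scalar in `[0, 1]`.
#' @export
fraction_below <- function(values, c) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  mean(values <= c)
}

#' ROC curve plot
#'
#' @param x A [roc_from_samples()] result.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  fpr <- 1 - x$specificity
  ord <- order(fpr, x$sensitivity)
  graphics::plot(fpr[ord], x$sensitivity[ord], type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  graphics::points(1 - x$youden_specificity, x$youden_sensitivity,
                   pch = 19, col = "firebrick")
  invisible(x)
}
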