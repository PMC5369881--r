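## normalise labels: logical, 0/1, or PCa/BPH -> logical (TRUE = case)
as_case_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("PCa", "BPH")))
  labels == "PCa"
}

#' Empirical ROC curve
#'
#' Sweeps every distinct score value as a decision threshold (rule: call
#' positive when `score >= threshold`), plus `+Inf` / `-Inf` sentinels, so
#' the curve always contains the endpoints (sens 0, spec 1) and
#' (sens 1, spec 0).  Markers that indicate disease by *low* values are
#' handled by `orientation = "lower"`, which negates the scores before the
#' sweep.
#'
#' @param scores Numeric marker values.
#' @param labels Case/control labels: logical, 0/1, or `"PCa"`/`"BPH"`.
#' @param orientation `"higher"` (default) if larger scores indicate
#'   disease, `"lower"` otherwise.
#' @return An object of class `pcp_roc`: `thresholds` (on the internal,
#'   higher-is-positive scale), `sensitivity`, `specificity`, the true/
#'   false call counts `tp` and `tn`, `n_pos`, `n_neg`, `orientation`.
#' @export
roc_curve <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  y <- as_case_labels(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  if (!any(y) || all(y)) stop("both classes must be present")
  s <- if (orientation == "lower") -scores else scores
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  n_pos <- sum(y); n_neg <- sum(!y)
  ## tp[k] = #cases with s >= cuts[k]; counts via cumulative tabulation
  tp <- vapply(cuts, function(ct) sum(s[y] >= ct), 0L)
  fp <- vapply(cuts, function(ct) sum(s[!y] >= ct), 0L)
  structure(
    list(thresholds = cuts,
         sensitivity = tp / n_pos,
         specificity = (n_neg - fp) / n_neg,
         tp = tp, tn = n_neg - fp,
         n_pos = n_pos, n_neg = n_neg, orientation = orientation),
    class = "pcp_roc"
  )
}

#' @export
print.pcp_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, %d cases / %d controls (%s-is-positive), AUC %.3f\n",
              length(x$thresholds), x$n_pos, x$n_neg, x$orientation,
              auc_trapezoid(x)))
  invisible(x)
}

#' @export
plot.pcp_roc <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "Sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Area under the ROC curve
#'
#' `auc()` uses the Mann–Whitney form: the fraction of (case, control)
#' pairs in which the case outscores the control, ties counted one half.
#' `auc_trapezoid()` integrates a [roc_curve()] by the trapezoidal rule;
#' the two agree to numerical precision.
#'
#' @inheritParams roc_curve
#' @return Area in \[0, 1\].
#' @export
auc <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  y <- as_case_labels(labels)
  if (!any(y) || all(y)) stop("both classes must be present")
  s <- if (orientation == "lower") -scores else scores
  n_pos <- sum(y); n_neg <- sum(!y)
  r <- rank(s)                      # mid-ranks handle ties as 0.5
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @param roc A [roc_curve()] object.
#' @rdname auc
#' @export
auc_trapezoid <- function(roc) {
  stopifnot(inherits(roc, "pcp_roc"))
  fpr <- 1 - roc$specificity
  o <- order(fpr, roc$sensitivity)
  fpr <- fpr[o]; sens <- roc$sensitivity[o]
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

#' Bootstrap distribution and percentile CI for an AUC
#'
#' Resamples patients with replacement *within* each diagnosis class
#' (stratified bootstrap, so every resample keeps both classes), recomputes
#' the AUC on each of the `B` resamples, and reports the percentile
#' confidence interval.  Deterministic given `seed`.
#'
#' @inheritParams roc_curve
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `pcp_auc`: `point` estimate, `replicates`
#'   vector, `ci`, `B`, `seed`.
#' @export
bootstrap_auc <- function(scores, labels, orientation = c("higher", "lower"),
                          B = 1000, seed = 1, conf = 0.95) {
  orientation <- match.arg(orientation)
  stopifnot(B >= 100)
  y <- as_case_labels(labels)
  point <- auc(scores, y, orientation)
  set.seed(seed)
  pos <- which(y); neg <- which(!y)
  reps <- vapply(seq_len(B), function(i) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    auc(scores[idx], y[idx], orientation)
  }, 0)
  a <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(a, 1 - a)))
  structure(list(point = point, replicates = reps, ci = ci, B = B,
                 seed = seed, conf = conf),
            class = "pcp_auc")
}

#' @export
print.pcp_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f, %d%% percentile bootstrap CI [%.3f, %.3f] (B = %d)\n",
              x$point, round(100 * x$conf), x$ci[1], x$ci[2], x$B))
  invisible(x)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Both markers are scored on the same subjects; each bootstrap resample
#' (stratified within class) is applied to both markers simultaneously, so
#' the resampled AUC difference accounts for their correlation.  The
#' difference is `auc(marker_a) - auc(marker_b)` and is flagged
#' significant when the percentile CI excludes zero.
#'
#' @param marker_a,marker_b Numeric scores on identical subjects.
#' @param labels Case/control labels.
#' @param orientation_a,orientation_b Per-marker orientations.
#' @inheritParams bootstrap_auc
#' @return An object of class `pcp_auc_diff`: `delta`, `replicates`, `ci`,
#'   `significant`, `B`, `seed`.
#' @export
compare_aucs <- function(marker_a, marker_b, labels,
                         orientation_a = "higher", orientation_b = "higher",
                         B = 1000, seed = 1, conf = 0.95) {
  stopifnot(length(marker_a) == length(marker_b), B >= 100)
  y <- as_case_labels(labels)
  delta <- auc(marker_a, y, orientation_a) - auc(marker_b, y, orientation_b)
  set.seed(seed)
  pos <- which(y); neg <- which(!y)
  reps <- vapply(seq_len(B), function(i) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    auc(marker_a[idx], y[idx], orientation_a) -
      auc(marker_b[idx], y[idx], orientation_b)
  }, 0)
  a <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(a, 1 - a)))
  structure(list(delta = delta, replicates = reps, ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0, B = B, seed = seed,
                 conf = conf),
            class = "pcp_auc_diff")
}

#' @export
print.pcp_auc_diff <- function(x, ...) {
  cat(sprintf("AUC difference %.3f, %d%% CI [%.3f, %.3f]%s (B = %d)\n",
              x$delta, round(100 * x$conf), x$ci[1], x$ci[2],
              if (x$significant) " *" else "", x$B))
  invisible(x)
}
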