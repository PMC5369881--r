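## reported cut-off for ROC point i: midpoint between the threshold's score
## and the next lower distinct score (orientation mapped back to the
## original marker scale)
report_threshold <- function(roc, i) {
  cuts <- roc$thresholds
  thr <- if (!is.finite(cuts[i])) cuts[i]
  else if (i < length(cuts) && is.finite(cuts[i + 1]))
    (cuts[i] + cuts[i + 1]) / 2
  else cuts[i]
  if (roc$orientation == "lower") -thr else thr
}

operating_point <- function(roc, i, level) {
  structure(
    list(threshold = report_threshold(roc, i),
         sensitivity = roc$sensitivity[i],
         specificity = roc$specificity[i],
         level = level, orientation = roc$orientation),
    class = "pcp_operating_point"
  )
}

#' @export
print.pcp_operating_point <- function(x, ...) {
  cat(sprintf("%s: threshold %s (%s-is-positive), sensitivity %.1f%%, specificity %.1f%%\n",
              x$level, format(x$threshold, digits = 4), x$orientation,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Operating point meeting a sensitivity floor
#'
#' Selects the threshold achieving the *smallest attainable* sensitivity
#' `m / n_pos` that is at least `target` — the achieved sensitivity is an
#' exact count fraction, which is why a 0.90 floor yields 49/54 = 90.7%
#' with 54 positives and 44/48 = 91.7% with 48.  Threshold ties are
#' resolved toward higher specificity.
#'
#' @param roc A [roc_curve()].
#' @param target Required sensitivity, in (0, 1].
#' @return A `pcp_operating_point` (level `"high_sensitivity"`).
#' @export
point_at_sensitivity <- function(roc, target = 0.9) {
  stopifnot(inherits(roc, "pcp_roc"))
  if (target > 1 || target <= 0) stop("target must lie in (0, 1]")
  ok <- which(roc$sensitivity >= target - 1e-12)
  best_sens <- min(roc$sensitivity[ok])
  cand <- ok[roc$sensitivity[ok] == best_sens]
  i <- cand[which.max(roc$specificity[cand])]
  operating_point(roc, i, "high_sensitivity")
}

#' Operating point meeting a specificity floor
#'
#' Mirror of [point_at_sensitivity()]: smallest attainable specificity
#' `k / n_neg` that is at least `target`, reporting the sensitivity there;
#' ties resolved toward higher sensitivity.
#'
#' @inheritParams point_at_sensitivity
#' @return A `pcp_operating_point` (level `"high_specificity"`).
#' @export
point_at_specificity <- function(roc, target = 0.9) {
  stopifnot(inherits(roc, "pcp_roc"))
  if (target > 1 || target <= 0) stop("target must lie in (0, 1]")
  ok <- which(roc$specificity >= target - 1e-12)
  best_spec <- min(roc$specificity[ok])
  cand <- ok[roc$specificity[ok] == best_spec]
  i <- cand[which.max(roc$sensitivity[cand])]
  operating_point(roc, i, "high_specificity")
}

#' Best-balance (Youden) operating point
#'
#' Maximizes the Youden index J = sensitivity + specificity - 1 over all
#' thresholds; ties are broken toward higher sensitivity.
#'
#' @inheritParams point_at_sensitivity
#' @return A `pcp_operating_point` (level `"balanced"`).
#' @export
youden_point <- function(roc) {
  stopifnot(inherits(roc, "pcp_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  cand <- which(j == max(j))
  i <- cand[which.max(roc$sensitivity[cand])]
  operating_point(roc, i, "balanced")
}

#' Three-level operating-point table
#'
#' For every marker, reports the three clinically motivated operating
#' points: (I) high sensitivity (sensitivity floor `sens_target`),
#' (II) best balance of sensitivity and specificity (Youden), and
#' (III) high specificity (specificity floor `spec_target`).  Each marker
#' is swept with its own orientation (by default %fPSA is
#' lower-is-positive, all others higher-is-positive).
#'
#' @param markers Data frame of marker scores, one column per marker, all
#'   scored on the same subjects (e.g. [marker_scores()]).
#' @param labels Case/control labels.
#' @param sens_target,spec_target Floors for levels I and III (default
#'   0.90 each).
#' @param orientations Named character vector of per-marker orientations;
#'   defaults to [marker_orientations()] for known names, `"higher"`
#'   otherwise.
#' @return A `pcp_threshold_table` data frame: `marker`, `level`,
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
three_level_table <- function(markers, labels, sens_target = 0.9,
                              spec_target = 0.9, orientations = NULL) {
  markers <- as.data.frame(markers)
  rows <- list()
  for (mk in names(markers)) {
    ori <- if (!is.null(orientations) && mk %in% names(orientations))
      orientations[[mk]]
    else if (mk %in% names(marker_orientations()))
      marker_orientations()[[mk]]
    else "higher"
    roc <- roc_curve(markers[[mk]], labels, ori)
    pts <- list(point_at_sensitivity(roc, sens_target),
                youden_point(roc),
                point_at_specificity(roc, spec_target))
    for (p in pts)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, level = p$level, threshold = p$threshold,
        sensitivity = p$sensitivity, specificity = p$specificity)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(), level = character(),
               threshold = numeric(), sensitivity = numeric(),
               specificity = numeric())
  rownames(out) <- NULL
  class(out) <- c("pcp_threshold_table", "data.frame")
  out
}

#' @export
print.pcp_threshold_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$sensitivity <- sprintf("%.1f%%", 100 * y$sensitivity)
  y$specificity <- sprintf("%.1f%%", 100 * y$specificity)
  y$threshold <- signif(y$threshold, 4)
  print(y)
  invisible(x)
}
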