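#' Univariate logistic regression for one marker
#'
#' Maximum-likelihood logistic fit of the diagnosis on a single marker
#' (via [stats::glm()]).  Reports the slope, the odds ratio per unit of the
#' marker with its Wald 95% confidence interval `exp(slope +/- 1.96 SE)`,
#' the two-sided Wald p-value, and the fitted per-subject probabilities.
#' Complete or quasi-complete separation is flagged, not raised.
#'
#' @param marker Numeric marker values (length >= 10).
#' @param labels Case/control labels (logical, 0/1 or `"PCa"`/`"BPH"`).
#' @return An object of class `pcp_logit`: `intercept`, `slope`, `se`,
#'   `or`, `ci` (length 2), `p_value`, `fitted`, `separation`, `n`.
#' @export
univariate_logistic <- function(marker, labels) {
  y <- as_case_labels(labels)
  stopifnot(length(marker) == length(y))
  if (length(y) < 10) stop("at least 10 observations are required")
  if (!any(y) || all(y)) stop("both classes must be present")
  if (stats::var(marker) == 0) stop("marker is constant")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ marker, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  slope <- cf["marker", "Estimate"]
  se <- cf["marker", "Std. Error"]
  ## glm does not always warn under separation (e.g. a binary marker whose
  ## fitted probabilities stop short of numerical 0/1); a vanishing
  ## deviance is the giveaway
  if (fit$deviance < 1e-6) separation <- TRUE
  structure(
    list(intercept = cf["(Intercept)", "Estimate"], slope = slope, se = se,
         or = exp(slope), ci = exp(slope + c(-1, 1) * 1.96 * se),
         p_value = cf["marker", "Pr(>|z|)"],
         fitted = unname(stats::fitted(fit)), separation = separation,
         n = length(y)),
    class = "pcp_logit"
  )
}

#' @export
print.pcp_logit <- function(x, ...) {
  cat(sprintf("Univariate logistic fit (n = %d)%s\n", x$n,
              if (x$separation) "  [separation flagged]" else ""))
  cat(sprintf("  slope %.4f (SE %.4f), OR %.3f [%.3f, %.3f], p %s\n",
              x$slope, x$se, x$or, x$ci[1], x$ci[2],
              format_p(x$p_value)))
  invisible(x)
}

## display convention for small p-values
format_p <- function(p) {
  ifelse(p < 5e-4, "<0.001", sprintf("%.3f", p))
}

#' Hosmer–Lemeshow goodness-of-fit test
#'
#' Sorts subjects by fitted probability, splits them into `g` near-equal
#' risk groups (tied probabilities stay together, assigned to the lower
#' group), and compares observed with expected event counts:
#' \deqn{\chi^2 = \sum_g \frac{(O_g - E_g)^2}{n_g \bar\pi_g (1-\bar\pi_g)}}
#' referred to a chi-square distribution with `g - 2` degrees of freedom.
#' A group whose mean probability is 0 or 1 is merged with its neighbour
#' (recorded in the result).
#'
#' @param probabilities Fitted probabilities in (0, 1).
#' @param labels Case/control labels.
#' @param g Number of risk groups (default 10; `n >= g >= 3` required).
#' @return An object of class `pcp_hl`: `statistic`, `g` (effective group
#'   count), `df`, `p_value`, per-group table `groups` (n, observed,
#'   expected, mean probability), `merged` count.
#' @export
hosmer_lemeshow <- function(probabilities, labels, g = 10) {
  y <- as.integer(as_case_labels(labels))
  p <- probabilities
  stopifnot(length(p) == length(y), all(p > 0 & p < 1), g >= 3,
            length(y) >= g)
  o <- order(p)
  p <- p[o]; y <- y[o]
  n <- length(p)
  grp <- ceiling(seq_len(n) * g / n)
  for (i in 2:n) if (p[i] == p[i - 1]) grp[i] <- grp[i - 1]
  grp <- match(grp, sort(unique(grp)))  # re-index 1..g_eff

  agg <- function(grp) {
    k <- max(grp)
    data.frame(
      n = tabulate(grp, k),
      observed = vapply(seq_len(k), function(j) sum(y[grp == j]), 0L),
      expected = vapply(seq_len(k), function(j) sum(p[grp == j]), 0),
      pi_bar = vapply(seq_len(k), function(j) mean(p[grp == j]), 0)
    )
  }
  tab <- agg(grp)
  merged <- 0L
  ## merge degenerate groups (mean prob 0 or 1) into a neighbour
  while (any(tab$pi_bar %in% c(0, 1)) && max(grp) > 3) {
    j <- which(tab$pi_bar %in% c(0, 1))[1]
    nb <- if (j == 1) 2L else j - 1L
    grp[grp == j] <- nb
    grp <- match(grp, sort(unique(grp)))
    tab <- agg(grp)
    merged <- merged + 1L
  }
  g_eff <- nrow(tab)
  df <- g_eff - 2
  if (df < 1) stop("fewer than 3 usable risk groups")
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$n * tab$pi_bar * (1 - tab$pi_bar)))
  structure(
    list(statistic = stat, g = g_eff, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         groups = tab, merged = merged),
    class = "pcp_hl"
  )
}

#' @export
print.pcp_hl <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d df (g = %d%s), p = %s\n",
              x$statistic, x$df, x$g,
              if (x$merged) sprintf(", %d merged", x$merged) else "",
              format_p(x$p_value)))
  invisible(x)
}

#' Bootstrap distribution of Hosmer–Lemeshow p-values
#'
#' For each of `B` stratified (within-class) bootstrap resamples, refits
#' the univariate logistic model and computes the Hosmer–Lemeshow test on
#' the refitted probabilities; returns the p-value vector (for
#' histogramming the calibration behaviour).  Resamples that fail to fit
#' are excluded and counted.
#'
#' @inheritParams univariate_logistic
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @param g Hosmer–Lemeshow group count.
#' @return Numeric vector of p-values with attribute `"failed"`.
#' @export
bootstrap_hl <- function(marker, labels, B = 1000, seed = 1, g = 10) {
  stopifnot(B >= 1)
  y <- as_case_labels(labels)
  set.seed(seed)
  pos <- which(y); neg <- which(!y)
  out <- rep(NA_real_, B)
  for (i in seq_len(B)) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    out[i] <- tryCatch({
      fit <- univariate_logistic(marker[idx], y[idx])
      hosmer_lemeshow(fit$fitted, y[idx], g = g)$p_value
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(out))
  structure(out[!is.na(out)], failed = failed)
}
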