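## half-up rounding for percent display (matches clinical-table convention)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Published reference performance anchors
#'
#' The per-stratum AUCs and the operating sensitivities/specificities of
#' the source study, as printed: used as comparison anchors (e.g. the
#' specificity gap between PCP and tPSA at the high-sensitivity operating
#' point).  These are inputs, not recomputed quantities.
#'
#' @return A data frame with one row per stratum x marker and columns
#'   `stratum`, `marker`, `auc`, `sens_level_pct` (the achieved
#'   high-sensitivity level), `spec_at_sens_pct` (specificity at that
#'   sensitivity) and `sens_at_spec_pct` (sensitivity at ~90%/~91%
#'   specificity).
#' @export
reference_performance <- function() {
  data.frame(
    stratum = rep(c("[2,10)", "[10,20)"), each = 5),
    marker = rep(c("pcp", "tpsa", "fpsa", "pct_fpsa", "cpsa"), 2),
    auc = c(0.680, 0.588, 0.571, 0.675, 0.613,
            0.686, 0.603, 0.643, 0.679, 0.647),
    sens_level_pct = rep(c(90.7, 91.7), each = 5),
    spec_at_sens_pct = c(22.8, 11.1, 11.2, 17.4, 15.5,
                         29.3, 10.9, 10.2, 23.1, 18.4),
    sens_at_spec_pct = c(33.3, 22.2, 20.4, 29.6, 20.4,
                         27.1, 6.3, 22.9, 22.9, 8.3)
  )
}

#' Descriptive cohort table
#'
#' Group-wise descriptive statistics over the pooled cohort: patient
#' counts, mean age (Welch t-test between groups) and the medians of the
#' five markers (tPSA, fPSA, %fPSA, cPSA, PCP; Mann–Whitney rank-sum test
#' between groups).
#'
#' @param cohort A cohort data frame with both diagnosis groups present.
#' @return A `pcp_table1` data frame: `variable`, `pca`, `bph`, `p_value`;
#'   attributes `n` (named group sizes) and `prevalence_pct`.
#' @export
build_table1 <- function(cohort) {
  y <- as_case_labels(cohort$diagnosis)
  if (!any(y) || all(y)) stop("both diagnosis groups must be present")
  sc <- marker_scores(cohort)
  rows <- list(data.frame(
    variable = "age_mean",
    pca = mean(cohort$age[y]), bph = mean(cohort$age[!y]),
    p_value = stats::t.test(cohort$age[y], cohort$age[!y])$p.value))
  for (mk in names(sc)) {
    p <- stats::wilcox.test(sc[[mk]][y], sc[[mk]][!y], exact = FALSE)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      variable = paste0(mk, "_median"),
      pca = median(sc[[mk]][y]), bph = median(sc[[mk]][!y]), p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            n = c(PCa = sum(y), BPH = sum(!y)),
            prevalence_pct = round_half_up(100 * mean(y), 1),
            class = c("pcp_table1", "data.frame"))
}

#' @export
print.pcp_table1 <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("Descriptive table: %d PCa vs %d BPH (prevalence %.1f%%)\n",
              n["PCa"], n["BPH"], attr(x, "prevalence_pct")))
  y <- as.data.frame(x)
  y$pca <- signif(y$pca, 4); y$bph <- signif(y$bph, 4)
  y$p_value <- format_p(y$p_value)
  print(y)
  invisible(x)
}

#' Per-marker diagnostic evaluation table
#'
#' For each of the five markers: the univariate logistic fit (slope, odds
#' ratio with Wald 95% CI, p-value), the oriented AUC with its stratified
#' bootstrap percentile CI, and the Hosmer–Lemeshow test on the in-sample
#' fitted probabilities.  Bootstrap replicate vectors (AUC, and
#' Hosmer–Lemeshow p-values from refitted resamples) are attached for
#' histogramming.  Setting `B = 0` skips all bootstraps (CI columns `NA`).
#'
#' @param cohort A cohort data frame (typically one tPSA stratum).
#' @param B Bootstrap replicates (default 1000; 0 disables).
#' @param seed Integer seed; per-marker streams are derived from it.
#' @param g Hosmer–Lemeshow group count.
#' @param orientations Named per-marker orientations (default
#'   [marker_orientations()]).
#' @return A `pcp_eval` data frame with one row per marker and columns
#'   `marker`, `slope`, `or`, `ci_low`, `ci_high`, `p`, `separation`,
#'   `auc`, `auc_ci_low`, `auc_ci_high`, `hl_chi2`, `hl_p`; attribute
#'   `replicates` holds matrices `auc` and `hl_p` (B x markers).
#' @export
evaluate_markers <- function(cohort, B = 1000, seed = 1, g = 10,
                             orientations = marker_orientations()) {
  sc <- marker_scores(cohort)
  y <- as_case_labels(cohort$diagnosis)
  rows <- list()
  auc_reps <- list(); hl_reps <- list()
  for (k in seq_along(sc)) {
    mk <- names(sc)[k]
    ori <- orientations[[mk]]
    lg <- univariate_logistic(sc[[mk]], y)
    hl <- hosmer_lemeshow(lg$fitted, y, g = g)
    a <- auc(sc[[mk]], y, ori)
    if (B >= 100) {
      ba <- bootstrap_auc(sc[[mk]], y, ori, B = B, seed = seed + 100L * k)
      bh <- bootstrap_hl(sc[[mk]], y, B = B, seed = seed + 100L * k + 1L,
                         g = g)
      auc_reps[[mk]] <- ba$replicates
      hl_reps[[mk]] <- c(bh, rep(NA_real_, B - length(bh)))
      ci <- ba$ci
    } else ci <- c(NA_real_, NA_real_)
    rows[[k]] <- data.frame(
      marker = mk, slope = lg$slope, or = lg$or,
      ci_low = lg$ci[1], ci_high = lg$ci[2], p = lg$p_value,
      separation = lg$separation,
      auc = a, auc_ci_low = ci[1], auc_ci_high = ci[2],
      hl_chi2 = hl$statistic, hl_p = hl$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            replicates = list(auc = if (length(auc_reps))
              do.call(cbind, auc_reps) else NULL,
              hl_p = if (length(hl_reps)) do.call(cbind, hl_reps) else NULL),
            B = B, seed = seed,
            class = c("pcp_eval", "data.frame"))
}

#' @export
print.pcp_eval <- function(x, ...) {
  y <- as.data.frame(x)
  for (cc in intersect(c("slope", "or", "ci_low", "ci_high", "auc",
                         "auc_ci_low", "auc_ci_high", "hl_chi2"), names(y)))
    y[[cc]] <- signif(y[[cc]], 3)
  for (cc in intersect(c("p", "hl_p"), names(y)))
    y[[cc]] <- format_p(y[[cc]])
  print(y)
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: obtains a cohort (generating one when given a
#' [generator_config()]), builds the pooled descriptive table, fits and
#' canonicalizes the power-combination model with a bootstrap stability
#' report, then — per tPSA stratum — evaluates all five markers
#' (logistic/OR, AUC with bootstrap CI, Hosmer–Lemeshow) and builds the
#' three-level operating-point table.  When `out_dir` is given, writes the
#' cohort CSV, all tables as CSV (percentages to one decimal), bootstrap
#' replicate dumps, the fitted model spec JSON, a machine-readable
#' `summary.json` and a run manifest logging every seed, exclusion and
#' warning flag.  Fully deterministic given the configuration.
#'
#' @param config A `pcp_generator_config` or an existing cohort data
#'   frame.
#' @param out_dir Output directory (created if needed); `NULL` for no
#'   files.
#' @param B Bootstrap replicates (0 for point estimates only).
#' @param seed Master seed for all stochastic stages (defaults to the
#'   generator seed, or 1 for a supplied cohort).
#' @param g Hosmer–Lemeshow group count.
#' @param sens_target,spec_target Operating-point floors.
#' @param stability_B Resamples for the exponent stability report.
#' @return Invisibly, a list: `cohort`, `table1`, `fit`, `canonical_spec`,
#'   `stability`, and per-stratum `evaluation` and `thresholds`, plus the
#'   `manifest` log lines.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = NULL,
                         B = 1000, seed = NULL, g = 10,
                         sens_target = 0.9, spec_target = 0.9,
                         stability_B = 200) {
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  if (inherits(config, "pcp_generator_config")) {
    cohort <- generate_cohort(config)
    if (is.null(seed)) seed <- config$seed
    say("cohort generated from config (seed %d): %d records", config$seed,
        nrow(cohort))
  } else {
    cohort <- config
    if (is.null(seed)) seed <- 1L
    say("cohort supplied: %d records", nrow(cohort))
  }
  seed <- as.integer(seed) %% 2147480000L
  strata <- attr(cohort, "strata")
  if (is.null(strata)) strata <- list(c(2, 10), c(10, 20))

  table1 <- build_table1(cohort)
  say("table1 built: prevalence %.1f%%", attr(table1, "prevalence_pct"))

  fit <- suppressWarnings(fit_power_model(cohort))
  say("power model fitted: n_used %d, excluded %d%s", fit$n_used,
      fit$n_excluded, if (fit$separation) ", SEPARATION" else "")
  canon <- canonicalize_exponents(fit$spec)
  stab <- if (stability_B >= 1)
    exponent_stability(cohort, B = stability_B, seed = seed + 7L) else NULL
  if (!is.null(stab))
    say("stability: %d resamples (seed %d), canonical rate %.3f, %d failed",
        stab$B, seed + 7L, stab$canonical_rate, stab$failed)

  evaluation <- list(); thresholds <- list()
  for (s in seq_along(strata)) {
    lab <- sprintf("[%g,%g)", strata[[s]][1], strata[[s]][2])
    sub <- stratify(cohort, strata[[s]])
    ev <- evaluate_markers(sub, B = B, seed = seed + 1000L * s, g = g)
    th <- three_level_table(marker_scores(sub), sub$diagnosis,
                            sens_target, spec_target)
    evaluation[[lab]] <- ev
    thresholds[[lab]] <- th
    say("stratum %s: %d records, eval seed %d, B %d", lab, nrow(sub),
        seed + 1000L * s, B)
  }

  bundle <- list(cohort = cohort, table1 = table1, fit = fit,
                 canonical_spec = canon, stability = stab,
                 evaluation = evaluation, thresholds = thresholds,
                 manifest = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(out_dir, sprintf(...))
    write_cohort(cohort, fp("cohort.csv"))
    utils::write.csv(as.data.frame(table1), fp("table1.csv"),
                     row.names = FALSE)
    write_power_spec(canon, fp("power_spec.json"))
    if (!is.null(stab))
      utils::write.csv(as.data.frame(stab$draws), fp("stability_exponents.csv"),
                       row.names = FALSE)
    for (lab in names(evaluation)) {
      tag <- gsub("[^0-9]+", "_", lab)
      utils::write.csv(as.data.frame(evaluation[[lab]]),
                       fp("evaluation%s.csv", tag), row.names = FALSE)
      reps <- attr(evaluation[[lab]], "replicates")
      if (!is.null(reps$auc))
        utils::write.csv(as.data.frame(reps$auc),
                         fp("auc_replicates%s.csv", tag), row.names = FALSE)
      if (!is.null(reps$hl_p))
        utils::write.csv(as.data.frame(reps$hl_p),
                         fp("hl_p_replicates%s.csv", tag), row.names = FALSE)
      th <- as.data.frame(thresholds[[lab]])
      th$sensitivity_pct <- round_half_up(100 * th$sensitivity, 1)
      th$specificity_pct <- round_half_up(100 * th$specificity, 1)
      utils::write.csv(th[, c("marker", "level", "threshold",
                              "sensitivity_pct", "specificity_pct")],
                       fp("thresholds%s.csv", tag), row.names = FALSE)
    }
    summ <- list(
      n = nrow(cohort),
      n_pca = sum(cohort$diagnosis == "PCa"),
      prevalence_pct = attr(table1, "prevalence_pct"),
      canonical_spec = unclass(canon),
      auc = lapply(evaluation, function(ev)
        stats::setNames(as.list(round(ev$auc, 6)), ev$marker)),
      seed = seed, B = B
    )
    jsonlite::write_json(summ, fp("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(log, fp("manifest.txt"))
  }
  invisible(bundle)
}
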