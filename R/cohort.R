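#' Reference cohort structure and marker medians
#'
#' Group sizes per tPSA stratum and the group-wise marker medians of the
#' source cohort: 54 PCa / 579 BPH patients with tPSA in \[2, 10) ng/mL and
#' 48 PCa / 147 BPH with tPSA in \[10, 20) ng/mL; median tPSA 9.2 vs 5.5
#' ng/mL, cPSA 8.0 vs 4.4 ng/mL, fPSA 1.0 vs 1.0 ng/mL and %fPSA 0.13 vs
#' 0.19 (PCa vs BPH).
#'
#' @return `reference_counts()`: a 2 x 2 integer matrix (rows `PCa`, `BPH`;
#'   columns the two strata).  `reference_marker_medians()`: a data frame
#'   with one row per diagnosis group and columns `tpsa`, `fpsa`, `cpsa`,
#'   `pct_fpsa`.
#' @export
reference_counts <- function() {
  m <- matrix(c(54L, 579L, 48L, 147L), nrow = 2,
              dimnames = list(c("PCa", "BPH"), c("[2,10)", "[10,20)")))
  m
}

#' @rdname reference_counts
#' @export
reference_marker_medians <- function() {
  data.frame(
    diagnosis = c("PCa", "BPH"),
    tpsa      = c(9.2, 5.5),
    fpsa      = c(1.0, 1.0),
    cpsa      = c(8.0, 4.4),
    pct_fpsa  = c(0.13, 0.19),
    row.names = c("PCa", "BPH")
  )
}

#' Synthetic-cohort generator configuration
#'
#' Describes the sampling scheme of [generate_cohort()]: per-group tPSA is
#' drawn from a log-normal truncated to each stratum's bounds, the
#' free-to-total ratio r = %fPSA from a Beta distribution, and the two are
#' coupled through a Gaussian copula with per-group correlation `rho`
#' (negative by default: %fPSA falls as tPSA rises).  Then
#' `fpsa = r * tpsa` and `cpsa = (tpsa - fpsa)` up to a small multiplicative
#' additivity noise.  Age is Normal, truncated below, identical across
#' groups.
#'
#' The default parameter values are the ones produced by
#' [calibrate_generator()] run against [reference_marker_medians()], so that
#' a default cohort reproduces the reference group sizes and marker medians.
#'
#' @param counts Integer matrix of group sizes, rows `PCa`/`BPH`, one column
#'   per stratum.
#' @param strata List of half-open tPSA intervals `c(lower, upper)` in
#'   ng/mL, one per column of `counts`.
#' @param tpsa_meanlog,tpsa_sdlog Named (`PCa`, `BPH`) log-location and
#'   log-scale of the un-truncated tPSA log-normal.
#' @param pct_fpsa_mean,pct_fpsa_conc Named mean and concentration of the
#'   Beta distribution of %fPSA (shape1 = mean * conc,
#'   shape2 = (1 - mean) * conc).
#' @param copula_rho Named Gaussian-copula correlation between the tPSA and
#'   %fPSA draws, in (-1, 1).
#' @param additivity_noise Half-width of the uniform multiplicative noise on
#'   `cpsa = tpsa - fpsa`; must not exceed 0.05 so that
#'   `|fpsa + cpsa - tpsa| <= 0.05 * tpsa` always holds.
#' @param age_mean,age_sd,age_min Age distribution (years): Normal truncated
#'   at `age_min`.
#' @param seed Integer seed; mandatory, every draw is deterministic given it.
#' @return An object of class `pcp_generator_config`.
#' @export
generator_config <- function(counts = reference_counts(),
                             strata = list(c(2, 10), c(10, 20)),
                             tpsa_meanlog = c(PCa = 1.81820776, BPH = 1.58281286),
                             tpsa_sdlog = c(PCa = 0.6, BPH = 0.6),
                             pct_fpsa_mean = c(PCa = 0.13806664, BPH = 0.19679121),
                             pct_fpsa_conc = c(PCa = 30, BPH = 30),
                             copula_rho = c(PCa = -0.54238805, BPH = -0.24694192),
                             additivity_noise = 0.02,
                             age_mean = 71.6, age_sd = 7, age_min = 40,
                             seed = 20170324) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) rownames(counts) <- c("PCa", "BPH")
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (length(strata) != ncol(counts))
    stop("one stratum interval per column of counts is required")
  for (b in strata)
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1])
      stop("each stratum must be a positive half-open interval c(lower, upper)")
  for (g in c("PCa", "BPH")) {
    m <- pct_fpsa_mean[[g]]
    if (!is.finite(m) || m <= 0 || m >= 1)
      stop("pct_fpsa_mean must lie strictly inside (0, 1)")
    if (pct_fpsa_conc[[g]] <= 0) stop("pct_fpsa_conc must be positive")
    if (abs(copula_rho[[g]]) >= 1) stop("copula_rho must lie in (-1, 1)")
    if (tpsa_sdlog[[g]] <= 0) stop("tpsa_sdlog must be positive")
  }
  if (additivity_noise < 0 || additivity_noise > 0.05)
    stop("additivity_noise must lie in [0, 0.05]")
  if (is.null(seed) || !is.finite(seed)) stop("an integer seed is mandatory")
  structure(
    list(counts = counts, strata = strata,
         tpsa_meanlog = tpsa_meanlog, tpsa_sdlog = tpsa_sdlog,
         pct_fpsa_mean = pct_fpsa_mean, pct_fpsa_conc = pct_fpsa_conc,
         copula_rho = copula_rho, additivity_noise = additivity_noise,
         age_mean = age_mean, age_sd = age_sd, age_min = age_min,
         seed = as.integer(seed)),
    class = "pcp_generator_config"
  )
}

#' @export
print.pcp_generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat("  strata:", paste(vapply(x$strata, function(b)
    sprintf("[%g,%g)", b[1], b[2]), ""), collapse = " "), "ng/mL\n")
  cat("  counts:\n")
  print(x$counts)
  for (g in rownames(x$counts))
    cat(sprintf("  %s: tpsa ~ logN(%.4f, %.2f), %%fPSA ~ Beta(mean %.4f, conc %g), rho %.2f\n",
                g, x$tpsa_meanlog[[g]], x$tpsa_sdlog[[g]],
                x$pct_fpsa_mean[[g]], x$pct_fpsa_conc[[g]],
                x$copula_rho[[g]]))
  cat(sprintf("  additivity noise +/-%g, seed %d\n",
              x$additivity_noise, x$seed))
  invisible(x)
}

#' Write / read a generator configuration as JSON
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "pcp_generator_config"))
  x <- unclass(config)
  x$counts <- list(PCa = unname(x$counts["PCa", ]),
                   BPH = unname(x$counts["BPH", ]))
  for (fld in c("tpsa_meanlog", "tpsa_sdlog", "pct_fpsa_mean",
                "pct_fpsa_conc", "copula_rho"))
    x[[fld]] <- as.list(x[[fld]])   # keep the PCa/BPH names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- rbind(PCa = x$counts$PCa, BPH = x$counts$BPH)
  colnames(counts) <- NULL
  generator_config(
    counts = counts,
    strata = lapply(seq_len(nrow(x$strata)), function(i) unlist(x$strata[i, ])),
    tpsa_meanlog = unlist(x$tpsa_meanlog), tpsa_sdlog = unlist(x$tpsa_sdlog),
    pct_fpsa_mean = unlist(x$pct_fpsa_mean),
    pct_fpsa_conc = unlist(x$pct_fpsa_conc),
    copula_rho = unlist(x$copula_rho),
    additivity_noise = x$additivity_noise,
    age_mean = x$age_mean, age_sd = x$age_sd, age_min = x$age_min,
    seed = x$seed
  )
}

## inverse-CDF draw from logN(mu, sd) truncated to [lo, hi), via standard
## normal deviates z (copula-compatible)
trunc_lnorm_quantile <- function(z, lo, hi, mu, sd) {
  flo <- plnorm(lo, mu, sd)
  fhi <- plnorm(hi, mu, sd)
  if (fhi - flo < 1e-12)
    stop("configuration error: log-normal mass inside stratum bounds is ~0")
  qlnorm(flo + pnorm(z) * (fhi - flo), mu, sd)
}

## core sampler used by generate_cohort and calibrate_generator: one
## diagnosis group with fixed per-stratum counts; consumes pre-drawn
## standard-normal/uniform deviates so calibration can reuse draws
sample_group <- function(ns, strata, mu, sd, m, conc, rho, noise,
                         z1, eps, u) {
  n <- sum(ns)
  z2 <- rho * z1 + sqrt(1 - rho^2) * eps
  tpsa <- numeric(n)
  stratum <- rep(seq_along(ns), ns)
  for (s in seq_along(ns)) {
    i <- stratum == s
    if (!any(i)) next
    tpsa[i] <- trunc_lnorm_quantile(z1[i], strata[[s]][1], strata[[s]][2],
                                    mu, sd)
  }
  r <- qbeta(pnorm(z2), m * conc, (1 - m) * conc)
  fpsa <- r * tpsa
  cpsa <- (tpsa - fpsa) * (1 + u)
  data.frame(tpsa = tpsa, fpsa = fpsa, cpsa = cpsa)
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort with exactly the group-by-stratum sizes of the
#' configuration.  Every record satisfies the marker invariants
#' `0 < fpsa < tpsa`, `cpsa > 0` and `|fpsa + cpsa - tpsa| <= 0.05 * tpsa`,
#' and its tPSA lies inside its stratum's half-open bounds.  The draw is
#' fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `pcp_cohort`: a data frame with columns `id`, `age`,
#'   `diagnosis` (`PCa`/`BPH`), `tpsa`, `fpsa`, `cpsa`, and a `"strata"`
#'   attribute holding the stratum bounds.
#' @examples
#' coh <- generate_cohort(generator_config(seed = 1))
#' table(coh$diagnosis)
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "pcp_generator_config"))
  set.seed(config$seed)
  out <- list()
  for (s in seq_along(config$strata)) {
    for (g in c("PCa", "BPH")) {
      n <- config$counts[g, s]
      if (n == 0L) next
      z1 <- rnorm(n); eps <- rnorm(n)
      u <- runif(n, -config$additivity_noise, config$additivity_noise)
      d <- sample_group(n, config$strata[s],
                        config$tpsa_meanlog[[g]], config$tpsa_sdlog[[g]],
                        config$pct_fpsa_mean[[g]], config$pct_fpsa_conc[[g]],
                        config$copula_rho[[g]], config$additivity_noise,
                        z1, eps, u)
      age <- config$age_mean + config$age_sd * rnorm(n)
      while (any(bad <- age < config$age_min))
        age[bad] <- config$age_mean + config$age_sd * rnorm(sum(bad))
      d <- cbind(age = age, diagnosis = g, d)
      out[[length(out) + 1L]] <- d
    }
  }
  coh <- if (length(out)) do.call(rbind, out) else
    data.frame(age = numeric(), diagnosis = character(),
               tpsa = numeric(), fpsa = numeric(), cpsa = numeric())
  coh <- cbind(id = sprintf("P%05d", seq_len(nrow(coh))), coh)
  coh <- coh[, c("id", "age", "diagnosis", "tpsa", "fpsa", "cpsa")]
  rownames(coh) <- NULL
  structure(coh, strata = config$strata,
            class = c("pcp_cohort", "data.frame"))
}

#' @export
print.pcp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PSA cohort: %d patients (%d PCa, %d BPH)\n",
              nrow(x), sum(x$diagnosis == "PCa"), sum(x$diagnosis == "BPH")))
  str <- attr(x, "strata")
  if (!is.null(str))
    cat("  strata:", paste(vapply(str, function(b)
      sprintf("[%g,%g)", b[1], b[2]), ""), collapse = " "), "ng/mL\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Restrict a cohort to one tPSA stratum
#'
#' Keeps the records whose tPSA lies in the half-open interval
#' `[bounds[1], bounds[2])`, preserving their order.
#'
#' @param cohort A cohort data frame with a `tpsa` column.
#' @param bounds Numeric `c(lower, upper)` in ng/mL.
#' @return The filtered cohort (same class and attributes).
#' @export
stratify <- function(cohort, bounds) {
  stopifnot(length(bounds) == 2, bounds[2] > bounds[1])
  keep <- cohort$tpsa >= bounds[1] & cohort$tpsa < bounds[2]
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "strata") <- list(bounds)
  out
}

#' Calibrate the generator to target marker medians
#'
#' Finds a configuration under which the simulated group-wise medians of
#' tPSA, fPSA, cPSA and %fPSA match given targets.  The search is
#' coordinate-wise and deterministic given the seed:
#' \enumerate{
#'   \item the tPSA log-location is solved (per group) so that the pooled
#'     median of the stratum-truncated log-normal mixture equals the tPSA
#'     target (root-finding on the analytic CDF; no simulation);
#'   \item the Beta mean is solved so the %fPSA median equals its target
#'     (analytic Beta quantile);
#'   \item the copula correlation is solved by root-finding on the
#'     simulated fPSA median, reusing one fixed set of random deviates
#'     across evaluations (common random numbers), so the objective is
#'     smooth and the result reproducible.
#' }
#' The cPSA target is implied by additivity and used as a consistency
#' check.  Calibration fails with a diagnostic error if any achieved median
#' deviates from its target by more than 10 percent at `n_sim` per group.
#'
#' @param targets Data frame like [reference_marker_medians()]: one row per
#'   group (`PCa`, `BPH` in rownames or a `diagnosis` column) with columns
#'   `tpsa`, `fpsa`, `cpsa`, `pct_fpsa`.
#' @param config0 Starting [generator_config()]; supplies strata, counts,
#'   dispersion parameters and the seed.
#' @param n_sim Simulated patients per group used in step 3 and in the
#'   final verification (default 10000).
#' @return A calibrated `pcp_generator_config` with a `"calibration"`
#'   attribute holding the achieved medians and relative errors.
#' @export
calibrate_generator <- function(targets = reference_marker_medians(),
                                config0 = generator_config(),
                                n_sim = 10000) {
  stopifnot(inherits(config0, "pcp_generator_config"))
  if (!is.null(targets$diagnosis)) rownames(targets) <- targets$diagnosis
  need <- c("tpsa", "fpsa", "cpsa", "pct_fpsa")
  if (!all(need %in% names(targets)) ||
      !all(c("PCa", "BPH") %in% rownames(targets)))
    stop("targets must give tpsa, fpsa, cpsa and pct_fpsa for PCa and BPH")

  cfg <- config0
  strata <- cfg$strata
  lo <- min(vapply(strata, `[`, 0, 1)); hi <- max(vapply(strata, `[`, 0, 2))
  achieved <- list()

  for (g in c("PCa", "BPH")) {
    tg <- targets[g, ]
    if (tg$pct_fpsa >= 0.9)
      stop("degenerate %fPSA target: implies cpsa ~ 0, violating invariants")
    if (tg$pct_fpsa <= 0 || any(unlist(tg[need]) <= 0))
      stop("targets must be positive with pct_fpsa in (0, 0.9)")
    if (tg$tpsa <= lo || tg$tpsa >= hi)
      stop("tpsa target lies outside the stratum bounds")
    w <- cfg$counts[g, ] / sum(cfg$counts[g, ])
    sd <- cfg$tpsa_sdlog[[g]]

    ## step 1: pooled truncated-lognormal median == tpsa target
    pool_cdf <- function(mu) {
      tot <- 0
      for (s in seq_along(strata)) {
        flo <- plnorm(strata[[s]][1], mu, sd)
        fhi <- plnorm(strata[[s]][2], mu, sd)
        if (fhi - flo < 1e-14) {
          ## vanishing mass: truncated mass piles on the near boundary
          tot <- tot + w[s] * as.numeric(mu <= log(strata[[s]][1]))
          next
        }
        fx <- min(max(plnorm(tg$tpsa, mu, sd), flo), fhi)
        tot <- tot + w[s] * (fx - flo) / (fhi - flo)
      }
      tot - 0.5
    }
    mu <- uniroot(pool_cdf, c(log(lo) - 4, log(hi) + 4), tol = 1e-9)$root

    ## step 2: Beta median == %fPSA target
    conc <- cfg$pct_fpsa_conc[[g]]
    m <- uniroot(function(m) qbeta(0.5, m * conc, (1 - m) * conc) - tg$pct_fpsa,
                 c(1e-3, 0.899), tol = 1e-9)$root

    ## step 3: copula rho -> simulated fPSA median, common random numbers
    ns <- round(n_sim * w)
    set.seed(cfg$seed + match(g, c("PCa", "BPH")))
    z1 <- rnorm(sum(ns)); eps <- rnorm(sum(ns))
    u <- runif(sum(ns), -cfg$additivity_noise, cfg$additivity_noise)
    fmed <- function(rho) {
      d <- sample_group(ns, strata, mu, sd, m, conc, rho,
                        cfg$additivity_noise, z1, eps, u)
      median(d$fpsa) - tg$fpsa
    }
    f_lo <- fmed(-0.95); f_hi <- fmed(0.95)
    rho <- if (f_lo > 0) -0.95 else if (f_hi < 0) 0.95 else
      uniroot(fmed, c(-0.95, 0.95), f.lower = f_lo, f.upper = f_hi,
              tol = 1e-3, maxiter = 50)$root

    cfg$tpsa_meanlog[[g]] <- mu
    cfg$pct_fpsa_mean[[g]] <- m
    cfg$copula_rho[[g]] <- rho

    d <- sample_group(ns, strata, mu, sd, m, conc, rho,
                      cfg$additivity_noise, z1, eps, u)
    got <- c(tpsa = median(d$tpsa), fpsa = median(d$fpsa),
             cpsa = median(d$cpsa),
             pct_fpsa = median(d$fpsa / d$tpsa))
    rel <- abs(got - unlist(tg[need])) / unlist(tg[need])
    achieved[[g]] <- list(achieved = got, rel_error = rel)
    if (any(rel > 0.10))
      stop(sprintf(
        "calibration error (%s): achieved medians %s deviate > 10%% from targets",
        g, paste(sprintf("%s=%.3f", names(got), got), collapse = ", ")))
  }
  attr(cfg, "calibration") <- achieved
  cfg
}

#' Write a cohort to CSV
#'
#' Header `id,age,diagnosis,tpsa,fpsa,cpsa`, UTF-8, decimal point,
#' newline-terminated rows.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("id", "age", "diagnosis", "tpsa", "fpsa", "cpsa")
  utils::write.csv(as.data.frame(cohort)[, cols], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Reads `id,age,diagnosis,tpsa,fpsa,cpsa`.  A missing `cpsa` is filled in
#' as `tpsa - fpsa` ([derive_cpsa()]) and flagged in the logical
#' `cpsa_derived` column.  Rows violating the marker invariants
#' (`tpsa > 0`, `0 < fpsa < tpsa`, `cpsa > 0`,
#' `|fpsa + cpsa - tpsa| <= 0.05 tpsa`) are rejected with a line-numbered
#' message; the count is stored in the `"rejected"` attribute.  Structural
#' problems (bad header, non-numeric fields, unknown diagnosis label) are
#' errors naming the offending row.
#'
#' @param path CSV file path.
#' @return A `pcp_cohort` data frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("id", "age", "diagnosis", "tpsa", "fpsa", "cpsa")
  if (!identical(names(raw), need))
    stop("malformed header: expected ", paste(need, collapse = ","))
  n <- nrow(raw)
  num <- function(col) {
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric %s in row %d: '%s'", col, bad[1],
                   v[bad[1]]))
    out[v == ""] <- NA_real_
    out
  }
  age <- num("age"); tpsa <- num("tpsa"); fpsa <- num("fpsa")
  cpsa <- num("cpsa")
  dx <- trimws(raw$diagnosis)
  badlab <- which(!dx %in% c("PCa", "BPH"))
  if (length(badlab))
    stop(sprintf("unknown diagnosis label in row %d: '%s'",
                 badlab[1], dx[badlab[1]]))
  derived <- is.na(cpsa) & !is.na(tpsa) & !is.na(fpsa) & fpsa > 0 &
    fpsa < tpsa
  cpsa[derived] <- tpsa[derived] - fpsa[derived]
  ok <- !is.na(tpsa) & !is.na(fpsa) & !is.na(cpsa) &
    tpsa > 0 & fpsa > 0 & fpsa < tpsa & cpsa > 0 &
    abs(fpsa + cpsa - tpsa) <= 0.05 * tpsa
  for (i in which(!ok))
    message(sprintf("read_cohort: row %d rejected (marker invariants violated)", i))
  coh <- data.frame(id = raw$id, age = age, diagnosis = dx,
                    tpsa = tpsa, fpsa = fpsa, cpsa = cpsa,
                    cpsa_derived = derived)[ok, , drop = FALSE]
  rownames(coh) <- NULL
  structure(coh, rejected = sum(!ok),
            class = c("pcp_cohort", "data.frame"))
}

#' Compute the five marker scores for a cohort
#'
#' @param cohort A cohort data frame.
#' @return A data frame with columns `tpsa`, `fpsa`, `pct_fpsa`, `cpsa`,
#'   `pcp` (one row per patient).
#' @export
marker_scores <- function(cohort) {
  data.frame(
    tpsa = cohort$tpsa,
    fpsa = cohort$fpsa,
    pct_fpsa = compute_pct_fpsa(cohort$fpsa, cohort$tpsa),
    cpsa = cohort$cpsa,
    pcp = compute_pcp(cohort$tpsa, cohort$fpsa, cohort$cpsa)
  )
}

#' Default marker orientations
#'
#' Direction in which each marker indicates cancer: all markers are
#' higher-is-positive except %fPSA, which is lower in PCa.
#'
#' @return Named character vector over the five markers.
#' @export
marker_orientations <- function() {
  c(tpsa = "higher", fpsa = "higher", pct_fpsa = "lower",
    cpsa = "higher", pcp = "higher")
}
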