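#' Prostate cancer predictor (PCP) score
#'
#' Computes the multiplicative combination score
#' \deqn{PCP = \frac{tPSA}{fPSA} \sqrt{cPSA}}
#' from the three serum PSA measurements.  The score is dimensionless,
#' strictly increasing in `tpsa` and `cpsa` and strictly decreasing in
#' `fpsa`.
#'
#' @param tpsa Total PSA (ng/mL), strictly positive.
#' @param fpsa Free PSA (ng/mL), strictly positive.
#' @param cpsa Complexed PSA (ng/mL), non-negative.
#' @return Numeric vector of PCP scores.
#' @examples
#' compute_pcp(9, 1, 4)   # 18
#' @export
compute_pcp <- function(tpsa, fpsa, cpsa) {
  stopifnot(is.numeric(tpsa), is.numeric(fpsa), is.numeric(cpsa))
  if (any(tpsa <= 0)) stop("tpsa must be strictly positive")
  if (any(fpsa <= 0)) stop("fpsa must be strictly positive")
  if (any(cpsa < 0)) stop("cpsa must be non-negative")
  tpsa / fpsa * sqrt(cpsa)
}

#' Free-to-total PSA ratio (%fPSA)
#'
#' @param fpsa Free PSA (ng/mL), with `0 < fpsa < tpsa`.
#' @param tpsa Total PSA (ng/mL), strictly positive.
#' @return Ratio `fpsa / tpsa` in (0, 1).
#' @examples
#' compute_pct_fpsa(1, 4)  # 0.25
#' @export
compute_pct_fpsa <- function(fpsa, tpsa) {
  if (any(tpsa <= 0)) stop("tpsa must be strictly positive")
  if (any(fpsa <= 0)) stop("fpsa must be strictly positive")
  if (any(fpsa >= tpsa)) stop("fpsa must be strictly less than tpsa")
  fpsa / tpsa
}

#' Derive complexed PSA from total and free PSA
#'
#' Complexed plus free PSA is, to measurement accuracy, equal to total PSA,
#' so a missing cPSA value is recovered as `tpsa - fpsa`.
#'
#' @inheritParams compute_pct_fpsa
#' @return Derived cPSA (ng/mL).
#' @examples
#' derive_cpsa(5, 1)  # 4
#' @export
derive_cpsa <- function(tpsa, fpsa) {
  if (any(tpsa <= 0)) stop("tpsa must be strictly positive")
  if (any(fpsa <= 0)) stop("fpsa must be strictly positive")
  if (any(fpsa >= tpsa)) stop("fpsa must be strictly less than tpsa")
  tpsa - fpsa
}

#' Power-model specification
#'
#' A specification of the multiplicative power family
#' \deqn{f = \alpha \, X^{a} Y^{b} Z^{c}}
#' where X, Y, Z are tPSA, fPSA and cPSA.  The published PCP score is the
#' member with `alpha = 1` and exponents `(a, b, c) = (1, -1, 0.5)`.
#'
#' @param alpha Positive multiplicative coefficient.
#' @param a,b,c Finite exponents for tPSA, fPSA and cPSA.
#' @param canonical Logical; `TRUE` when the exponents have been scaled to
#'   `a = 1` and snapped to the interpretation grid
#'   (see [canonicalize_exponents()]).
#' @return An object of class `pcp_power_spec`.
#' @seealso [score_power_model()], [fit_power_model()]
#' @export
power_model_spec <- function(alpha = 1, a = 1, b = -1, c = 0.5,
                             canonical = FALSE) {
  stopifnot(length(alpha) == 1L, length(a) == 1L, length(b) == 1L,
            length(c) == 1L)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be a positive real")
  if (!all(is.finite(c(a, b, c)))) stop("exponents must be finite")
  structure(
    list(alpha = as.numeric(alpha), a = as.numeric(a), b = as.numeric(b),
         c = as.numeric(c), canonical = isTRUE(canonical)),
    class = "pcp_power_spec"
  )
}

#' @export
print.pcp_power_spec <- function(x, ...) {
  cat(sprintf("Power model: f = %.4g * tpsa^%.4g * fpsa^%.4g * cpsa^%.4g%s\n",
              x$alpha, x$a, x$b, x$c,
              if (x$canonical) "  [canonical]" else ""))
  invisible(x)
}

#' Score records under a power-model specification
#'
#' Evaluates `alpha * tpsa^a * fpsa^b * cpsa^c` for every record.  With the
#' canonical PCP specification `(alpha, a, b, c) = (1, 1, -1, 0.5)` this is
#' exactly [compute_pcp()].
#'
#' @param records A data frame with columns `tpsa`, `fpsa`, `cpsa`
#'   (e.g. a cohort from [generate_cohort()]).
#' @param spec A [power_model_spec()].
#' @return Numeric vector of scores.
#' @export
score_power_model <- function(records, spec = power_model_spec()) {
  stopifnot(inherits(spec, "pcp_power_spec"))
  stopifnot(all(c("tpsa", "fpsa", "cpsa") %in% names(records)))
  t <- records$tpsa; f <- records$fpsa; z <- records$cpsa
  if (any(t <= 0 & spec$a < 0)) stop("tpsa = 0 with negative exponent")
  if (any(f <= 0 & spec$b < 0)) stop("fpsa = 0 with negative exponent")
  if (any(z <= 0 & spec$c < 0)) stop("cpsa = 0 with negative exponent")
  ## canonical PCP evaluated through the ratio form so the two entry
  ## points agree to the last bit
  if (spec$alpha == 1 && spec$a == 1 && spec$b == -1 && spec$c == 0.5)
    return(t / f * sqrt(z))
  spec$alpha * t^spec$a * f^spec$b * z^spec$c
}

#' Write / read a power-model specification as JSON
#'
#' @param spec A [power_model_spec()].
#' @param path File path.
#' @return `read_power_spec` returns a `pcp_power_spec`;
#'   `write_power_spec` returns `path` invisibly.
#' @export
write_power_spec <- function(spec, path) {
  stopifnot(inherits(spec, "pcp_power_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_power_spec
#' @export
read_power_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  power_model_spec(x$alpha, x$a, x$b, x$c, canonical = isTRUE(x$canonical))
}
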