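# Prephenate-dehydratase quantitation: Beer-Lambert conversion of A320 to
# phenylpyruvate concentration, initial rates with the <20%-conversion filter
# and non-enzymatic blank subtraction, Michaelis-Menten fitting and
# propagated kcat/KM errors.

#' Assay configuration
#'
#' @param extinction_coefficient Molar extinction coefficient of the product
#'   at 320 nm (1/(M cm)); default 17500.
#' @param path_length Cuvette path length (cm).
#' @param max_conversion_fraction Maximum substrate conversion used for rate
#'   estimation (default 0.20).
#' @return An `assay_config`.
#' @export
assay_config <- function(extinction_coefficient = 17500, path_length = 1,
                         max_conversion_fraction = 0.20) {
  stopifnot(extinction_coefficient > 0, path_length > 0,
            max_conversion_fraction > 0, max_conversion_fraction < 1)
  structure(list(extinction_coefficient = extinction_coefficient,
                 path_length = path_length,
                 max_conversion_fraction = max_conversion_fraction),
            class = "assay_config")
}

#' Absorbance to product concentration (Beer-Lambert)
#'
#' @param a320 Absorbance at 320 nm (vectorized, non-negative).
#' @param config An [assay_config()].
#' @return Concentration in uM.
#' @export
absorbance_to_concentration <- function(a320, config = assay_config()) {
  if (any(a320 < 0)) stop("negative absorbance", call. = FALSE)
  a320 / (config$extinction_coefficient * config$path_length) * 1e6
}

#' Initial rate from a progress curve with conversion filtering
#'
#' Least-squares slope of product concentration vs. time over the points
#' below the conversion threshold; the non-enzymatic blank slope is
#' subtracted.
#'
#' @param time Time points (s).
#' @param product Product concentration (uM) at each time point.
#' @param substrate0 Initial substrate concentration (uM).
#' @param blank Either a blank progress curve (uM, same time grid) or a
#'   pre-computed blank slope (uM/s, single value); NULL for none.
#' @param config An [assay_config()].
#' @return List with `rate` (uM/s, blank-subtracted), `raw_slope`,
#'   `blank_slope` and the indices of `excluded` points.
#' @export
compute_rate <- function(time, product, substrate0, blank = NULL,
                         config = assay_config()) {
  stopifnot(length(time) == length(product), length(time) >= 2L,
            substrate0 > 0)
  keep <- product < config$max_conversion_fraction * substrate0
  if (sum(keep) < 2L)
    stop("fewer than two points below the conversion threshold; reduce enzyme or time",
         call. = FALSE)
  slope <- stats::coef(stats::lm(product[keep] ~ time[keep]))[[2]]
  blank_slope <- 0
  if (!is.null(blank)) {
    blank_slope <- if (length(blank) == 1L) blank else {
      stopifnot(length(blank) == length(time))
      bk <- blank < config$max_conversion_fraction * substrate0
      stats::coef(stats::lm(blank[bk] ~ time[bk]))[[2]]
    }
  }
  list(rate = slope - blank_slope, raw_slope = slope,
       blank_slope = blank_slope, excluded = which(!keep))
}

#' Rate series over substrate concentrations
#'
#' @param substrate Substrate concentrations (uM, positive).
#' @param rate Blank-subtracted rates (uM/s).
#' @param enzyme Enzyme concentration (uM, single value).
#' @return A `rate_series` data frame.
#' @export
rate_series <- function(substrate, rate, enzyme) {
  stopifnot(length(substrate) == length(rate), all(substrate > 0),
            all(is.finite(rate)), length(enzyme) == 1L, enzyme > 0)
  out <- data.frame(substrate = substrate, rate = rate, enzyme = enzyme)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Michaelis-Menten fit
#'
#' Unweighted nonlinear least squares of `v = kcat * E * S / (KM + S)`;
#' standard errors from the Jacobian-based covariance at the optimum.
#'
#' @param rates A [rate_series()] (S in uM, v in uM/s, E in uM), or a data
#'   frame with columns `substrate`, `rate`, `enzyme`.
#' @return An `mm_fit`: `KM` (uM), `kcat` (1/s), their standard errors, and
#'   the underlying `nls` fit.
#' @export
fit_mm <- function(rates) {
  stopifnot(all(c("substrate", "rate", "enzyme") %in% names(rates)))
  if (length(unique(rates$substrate)) < 4L)
    stop("need at least four substrate concentrations", call. = FALSE)
  E <- rates$enzyme[1]
  dat <- data.frame(S = rates$substrate, v = rates$rate)
  km0 <- stats::median(dat$S)
  kcat0 <- 1.2 * max(dat$v) / E
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * E * S / (KM + S), data = dat,
                      start = list(KM = km0, kcat = kcat0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("Michaelis-Menten fit failed (", conditionMessage(e),
           "); the data may not constrain KM", call. = FALSE))
  if (!fit$convInfo$isConv)
    stop("Michaelis-Menten fit did not converge", call. = FALSE)
  cf <- summary(fit)$coefficients
  KM <- cf["KM", "Estimate"]
  if (KM < min(dat$S) / 10 || KM > 10 * max(dat$S))
    warning("KM poorly constrained by the sampled substrate range",
            call. = FALSE)
  structure(list(KM = KM, KM_se = cf["KM", "Std. Error"],
                 kcat = cf["kcat", "Estimate"],
                 kcat_se = cf["kcat", "Std. Error"],
                 enzyme = E, fit = fit),
            class = "mm_fit")
}

#' Construct an `mm_fit` from published parameters
#'
#' For error-propagation arithmetic on tabulated KM/kcat values.
#'
#' @param KM,KM_se KM and its standard error (uM).
#' @param kcat,kcat_se kcat and its standard error (1/s).
#' @return An `mm_fit` (without an underlying nls object).
#' @export
mm_fit_values <- function(KM, KM_se, kcat, kcat_se) {
  stopifnot(KM > 0, kcat > 0, KM_se >= 0, kcat_se >= 0)
  structure(list(KM = KM, KM_se = KM_se, kcat = kcat, kcat_se = kcat_se,
                 enzyme = NA_real_, fit = NULL),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> KM = %.4g +/- %.2g uM, kcat = %.4g +/- %.2g 1/s\n",
              x$KM, x$KM_se, x$kcat, x$kcat_se))
  invisible(x)
}

#' Catalytic efficiency with propagated error
#'
#' `kcat/KM` in 1/(M s), with standard error propagated in quadrature from
#' the relative errors of kcat and KM.
#'
#' @param fit An `mm_fit`.
#' @return List with `value` and `se` (1/(M s)).
#' @export
efficiency <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  if (fit$KM <= 0) stop("KM must be positive", call. = FALSE)
  value <- fit$kcat / (fit$KM * 1e-6)
  se <- value * sqrt((fit$KM_se / fit$KM)^2 + (fit$kcat_se / fit$kcat)^2)
  list(value = value, se = se)
}
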