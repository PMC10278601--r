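## Cohort-level statistics: group comparisons, box-plot summaries, SNR-bias
## regression, and repeatability. These wrap the standard R implementations
## (t.test, lm, quantile) behind the interfaces the pipeline uses.

#' Two-sample Student's t-test
#'
#' Two-sided, pooled-variance by default ("Student's t-test"); Welch's
#' unequal-variance variant is available via \code{welch = TRUE}.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param welch use the Welch correction instead of pooled variance.
#' @return list with \code{t} and \code{p}.
#' @export
twoSampleT <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both groups have zero variance: t undefined")
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Box-plot summary with the 1.5 IQR outlier rule
#'
#' Quartiles use linear interpolation between order statistics
#' (\code{quantile} type 7). Outliers are points above P75 + 1.5 (P75 - P25)
#' or below P25 - 1.5 (P75 - P25); whiskers extend to the most extreme
#' non-outlier points.
#'
#' @param values numeric vector (length >= 1).
#' @return list with \code{p25}, \code{median}, \code{p75},
#'   \code{whiskerLo}, \code{whiskerHi}, \code{outliers}.
#' @export
boxplotSummary <- function(values) {
  stopifnot(length(values) >= 1)
  values <- values[is.finite(values)]
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  keep <- values[values >= lo & values <= hi]
  list(p25 = q[1], median = q[2], p75 = q[3],
       whiskerLo = min(keep), whiskerHi = max(keep), outliers = out)
}

#' Regression of HFL extension on SNR
#'
#' Ordinary least squares of the measured extension on the en-face SNR; a
#' significant positive slope indicates that low signal quality biases the
#' measured extension downward, so SNR must be considered when comparing
#' groups.
#'
#' @param records data.frame with columns \code{snr} and \code{extension}
#'   (or two numeric vectors via \code{snr}, \code{extension}).
#' @param snr,extension alternative vector interface.
#' @return list with \code{slope} (deg per SNR unit), \code{p} (two-sided),
#'   \code{intercept}.
#' @export
snrExtensionRegression <- function(records = NULL, snr = records$snr,
                                   extension = records$extension) {
  stopifnot(length(snr) == length(extension), length(snr) >= 3)
  if (stats::sd(snr) == 0) stop("constant SNR: slope undefined")
  fit <- stats::lm(extension ~ snr)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["snr", "Estimate"]),
       p = unname(sm["snr", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]))
}

#' Repeatability of the HFL extension
#'
#' Sample standard deviation of the measured extension across repeat
#' acquisitions of each subject, and their cohort mean. Subjects with fewer
#' than two repeats are skipped with a message.
#'
#' @param extensions list of numeric vectors (one per subject, one value per
#'   repeat), or a data.frame with columns \code{subject} and
#'   \code{extension}.
#' @return list with \code{perSubject} (named numeric of SDs) and
#'   \code{meanSd}.
#' @export
repeatability <- function(extensions) {
  if (is.data.frame(extensions))
    extensions <- split(extensions$extension, extensions$subject)
  sds <- vapply(extensions, function(v) {
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }, numeric(1))
  skipped <- sum(is.na(sds))
  if (skipped > 0)
    message(skipped, " subject(s) with fewer than 2 repeats skipped")
  list(perSubject = sds, meanSd = mean(sds, na.rm = TRUE))
}
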