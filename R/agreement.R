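# Validity and agreement of a GA measure against the ultrasound gold
# standard: Pearson correlation, Bland-Altman bias and limits of
# agreement, and preterm classification.

#' Bland-Altman agreement statistics
#'
#' Computes paired differences `d = x - y` (method under test minus
#' reference, so a positive mean difference means the method overestimates
#' the reference), their mean and sample SD, the limits of agreement
#' `mean +/- k * SD` (k = 2 by default, the conventional "mean difference
#' plus or minus two standard deviations"; use `k = 1.96` for exact normal
#' quantiles), a two-sided one-sample t-test of zero bias, and the Pearson
#' correlation of the pair. Pairs with any missing value are dropped.
#'
#' @param x numeric vector, method under test (e.g. calibrated GA, weeks).
#' @param y numeric vector, reference method (e.g. ultrasound GA).
#' @param k limits-of-agreement multiplier.
#' @return An object of class `agreement_stats`: `n_pairs`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `p_bias`, `pearson_rho`, and `plot_data`
#'   (a data.frame of per-pair difference and mean, for the classic
#'   difference-vs-mean plot).
#' @examples
#' ba <- bland_altman(c(38, 40, 41), c(38.5, 39.5, 41))
#' ba$loa_high
#' @export
bland_altman <- function(x, y, k = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  d <- x - y
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  if (sd_diff == 0) {
    if (mean_diff != 0) {
      warning("zero variance in differences with nonzero mean; p_bias set to 0",
              call. = FALSE)
      p_bias <- 0
    } else {
      p_bias <- 1
    }
  } else {
    p_bias <- stats::t.test(d, mu = 0)$p.value
  }
  rho <- if (stats::sd(x) > 0 && stats::sd(y) > 0) {
    stats::cor(x, y)
  } else {
    NA_real_
  }
  structure(
    list(
      n_pairs = length(d),
      mean_diff = mean_diff,
      sd_diff = sd_diff,
      loa_low = mean_diff - k * sd_diff,
      loa_high = mean_diff + k * sd_diff,
      p_bias = p_bias,
      pearson_rho = rho,
      k = k,
      plot_data = data.frame(difference = d, average = (x + y) / 2)
    ),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean diff %.2f (SD %.2f), LOA %.2f to %.2f, p(bias=0) = %.3g, rho = %.3f\n",
    x$n_pairs, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$p_bias,
    x$pearson_rho))
  invisible(x)
}

#' Pearson correlation between two GA measures
#'
#' Sample product-moment correlation over complete pairs; a value near 1
#' indicates high validity of the measure against the reference.
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Preterm classification rate
#'
#' Flags each non-missing GA strictly below the cutoff (preterm birth is
#' delivery at < 37 completed weeks) and returns the proportion preterm.
#'
#' @param ga numeric vector of GA in weeks (NAs dropped from the rate).
#' @param cutoff preterm threshold in weeks.
#' @return List with `rate` (proportion over non-missing values) and
#'   `flags` (integer 0/1 per input element, `NA` where `ga` is missing).
#' @export
preterm_rate <- function(ga, cutoff = 37) {
  if (all(is.na(ga))) stop("all GA values missing", call. = FALSE)
  flags <- ifelse(is.na(ga), NA_integer_, as.integer(ga < cutoff))
  list(rate = mean(flags, na.rm = TRUE), flags = flags)
}
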