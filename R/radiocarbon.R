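#' Uncalibrated radiocarbon date
#'
#' @param age uncalibrated years BP (> 0).
#' @param sigma one-sigma uncertainty in years (> 0).
#' @param label optional sample label.
#' @return a `RadiocarbonDate`.
#' @export
radiocarbon_date <- function(age, sigma, label = "") {
  if (age <= 0 || sigma <= 0) stop("age and sigma must be positive")
  structure(list(age = age, sigma = sigma, label = label),
            class = "RadiocarbonDate")
}

#' @export
print.RadiocarbonDate <- function(x, ...) {
  cat(sprintf("%s%s ± %s BP\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              format(x$age, big.mark = ","), format(x$sigma)), sep = "")
  invisible(x)
}

#' Combine replicate radiocarbon measurements of one sample
#'
#' The `arithmetic` method takes the mean age truncated toward zero with
#' sigma `round(sqrt(sum(sigma_i^2)) / n)` (half-up), i.e. the error of the
#' mean of independent measurements. The `inverse_variance` method is the
#' standard weighted mean with `sigma = (sum sigma_i^-2)^-1/2`; both report
#' the consistency statistic `T = sum(((x_i - mean) / sigma_i)^2)`, which is
#' approximately chi-squared with n-1 degrees of freedom when the
#' measurements agree.
#'
#' @param dates list of [radiocarbon_date()] (at least 2), or a `data.frame`
#'   with columns `age`, `sigma` (and optionally `label`).
#' @param method `"arithmetic"` (default) or `"inverse_variance"`.
#' @return a `RadiocarbonDate` with attributes `method` and `T_statistic`.
#' @export
combine_dates <- function(dates, method = c("arithmetic", "inverse_variance")) {
  method <- match.arg(method)
  if (is.data.frame(dates)) {
    ages <- dates$age; sigmas <- dates$sigma
  } else {
    ages <- vapply(dates, `[[`, 0, "age")
    sigmas <- vapply(dates, `[[`, 0, "sigma")
  }
  n <- length(ages)
  if (n < 2) stop("need at least 2 dates to combine")
  if (method == "arithmetic") {
    age <- trunc(mean(ages))
    sigma <- floor(sqrt(sum(sigmas^2)) / n + 0.5)  # half-up rounding
    mu <- mean(ages)
  } else {
    w <- 1 / sigmas^2
    mu <- sum(w * ages) / sum(w)
    age <- round(mu)
    sigma <- round(1 / sqrt(sum(w)))
  }
  Tstat <- sum(((ages - mu) / sigmas)^2)
  out <- radiocarbon_date(age, sigma, label = "combined")
  attr(out, "method") <- method
  attr(out, "T_statistic") <- Tstat
  out
}
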