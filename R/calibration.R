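#' Adaptive-threshold calibration
#'
#' The click-seeded segmenter thresholds the slice at an adaptive HU value
#' derived from the clicked pixel (`Start`). Two regressions, fitted
#' offline on marked nodules, drive the estimate:
#'
#' * a simple linear model `Avg = beta0 + beta1 * Start` predicting the
#'   mean HU of the nodule from the clicked pixel;
#' * a multiple linear model `Std = c0 + c_start * Start + c_avg * Avg`
#'   predicting the nodule's HU standard deviation.
#'
#' The threshold is then `Threshold = Avg - alpha * Std`, with `alpha`
#' weighting the spread term (default 2). Larger `alpha` lowers the
#' threshold and enlarges the grown region.
#'
#' Calibration samples are rows of a data frame with columns `start`,
#' `avg`, `std` (all in HU).
#'
#' @name threshold-calibration
NULL

#' Construct a threshold calibration
#'
#' @param beta0,beta1 coefficients of the mean model (HU intercept,
#'   unitless slope).
#' @param std_coeffs length-3 numeric `(intercept, coef_start, coef_avg)`
#'   of the spread model.
#' @param alpha non-negative weight on the predicted spread.
#' @return an object of class `threshold_calibration`.
#' @export
threshold_calibration <- function(beta0, beta1, std_coeffs, alpha = 2) {
  std_coeffs <- as.numeric(std_coeffs)
  stopifnot(length(std_coeffs) == 3)
  if (!all(is.finite(c(beta0, beta1, std_coeffs, alpha)))) {
    stop("all calibration coefficients must be finite", call. = FALSE)
  }
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  structure(
    list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
         std_coeffs = std_coeffs, alpha = as.numeric(alpha)),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> Avg = %.4g + %.4g * Start;\n", x$beta0, x$beta1))
  cat(sprintf("  Std = %.4g + %.4g * Start + %.4g * Avg; alpha = %g\n",
              x$std_coeffs[1], x$std_coeffs[2], x$std_coeffs[3], x$alpha))
  invisible(x)
}

#' Fit the mean model on calibration samples
#'
#' Ordinary least squares of the nodule mean HU on the clicked HU.
#'
#' @param samples data frame with columns `start` and `avg`.
#' @return named numeric `c(beta0, beta1)` with the fit attached as
#'   attribute `"fit"`.
#' @export
fit_mean_model <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("start", "avg") %in% names(samples)))
  if (nrow(samples) < 2 || length(unique(samples$start)) < 2) {
    stop("need at least two samples with distinct start values", call. = FALSE)
  }
  fit <- stats::lm(avg ~ start, data = samples)
  out <- stats::setNames(as.numeric(stats::coef(fit)), c("beta0", "beta1"))
  attr(out, "fit") <- fit
  out
}

#' Fit the spread model on calibration samples
#'
#' Ordinary least squares of the nodule HU standard deviation on
#' `(1, start, avg)`.
#'
#' @param samples data frame with columns `start`, `avg`, `std`.
#' @return named numeric `c(intercept, coef_start, coef_avg)` with the fit
#'   attached as attribute `"fit"`.
#' @export
fit_std_model <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("start", "avg", "std") %in% names(samples)))
  if (nrow(samples) < 3) stop("need at least three samples", call. = FALSE)
  X <- cbind(1, samples$start, samples$avg)
  if (qr(X)$rank < 3) {
    stop("rank-deficient calibration design: start and avg are collinear",
         call. = FALSE)
  }
  fit <- stats::lm(std ~ start + avg, data = samples)
  out <- stats::setNames(as.numeric(stats::coef(fit)),
                         c("intercept", "coef_start", "coef_avg"))
  attr(out, "fit") <- fit
  out
}

#' Fit a full calibration from samples
#'
#' Convenience wrapper chaining [fit_mean_model()] and [fit_std_model()].
#'
#' @inheritParams fit_std_model
#' @param alpha spread weight, default 2.
#' @return a [threshold_calibration()].
#' @export
fit_calibration <- function(samples, alpha = 2) {
  mm <- fit_mean_model(samples)
  sm <- fit_std_model(samples)
  cal <- threshold_calibration(mm[["beta0"]], mm[["beta1"]], sm, alpha = alpha)
  attr(cal, "mean_fit") <- attr(mm, "fit")
  attr(cal, "std_fit") <- attr(sm, "fit")
  cal
}

#' Shipped default calibration
#'
#' The mean model uses the published coefficients (-173.34, 0.71) and
#' `alpha = 2`. The spread model has no published coefficients, so the
#' default is fitted deterministically on the package's synthetic
#' calibration set (`make_calibration_set(200, seed = 20)`).
#'
#' @param alpha spread weight, default 2.
#' @return a [threshold_calibration()].
#' @examples
#' default_calibration()
#' @export
default_calibration <- function(alpha = 2) {
  sm <- fit_std_model(make_calibration_set(200, seed = 20L))
  threshold_calibration(-173.34, 0.71, sm, alpha = alpha)
}

#' Estimate the nodule mean HU from the clicked pixel
#'
#' @param start clicked HU value (vectorised).
#' @param calib a [threshold_calibration()].
#' @return estimated mean HU.
#' @export
estimate_avg <- function(start, calib) {
  stopifnot(inherits(calib, "threshold_calibration"))
  calib$beta0 + calib$beta1 * start
}

#' Estimate the nodule HU spread
#'
#' Linear combination of `(1, start, avg)`; negative predictions are
#' clamped to zero so the threshold never rises above the estimated mean.
#'
#' @param start clicked HU value.
#' @param avg estimated (or measured) nodule mean HU.
#' @param calib a [threshold_calibration()].
#' @return estimated standard deviation, >= 0.
#' @export
estimate_std <- function(start, avg, calib) {
  stopifnot(inherits(calib, "threshold_calibration"))
  p <- calib$std_coeffs[1] + calib$std_coeffs[2] * start + calib$std_coeffs[3] * avg
  pmax(p, 0)
}

#' Compute the adaptive threshold
#'
#' `Threshold = avg - alpha * std`.
#'
#' @param avg estimated mean HU.
#' @param std estimated spread, >= 0.
#' @param alpha spread weight.
#' @return threshold in HU.
#' @export
compute_threshold <- function(avg, std, alpha = 2) {
  if (any(std < 0)) stop("std must be non-negative", call. = FALSE)
  avg - alpha * std
}

# full chain: clicked HU -> threshold
threshold_from_click <- function(start_hu, calib, alpha = calib$alpha) {
  avg <- estimate_avg(start_hu, calib)
  std <- estimate_std(start_hu, avg, calib)
  compute_threshold(avg, std, alpha)
}

#' Read / write a calibration as JSON
#'
#' @param calib a [threshold_calibration()].
#' @param path file path.
#' @return `read_calibration()` returns a [threshold_calibration()];
#'   `write_calibration()` returns the path invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "threshold_calibration"))
  jsonlite::write_json(
    list(beta0 = calib$beta0, beta1 = calib$beta1,
         std_coeffs = calib$std_coeffs, alpha = calib$alpha),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_calibration(j$beta0, j$beta1, j$std_coeffs, alpha = j$alpha)
}
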