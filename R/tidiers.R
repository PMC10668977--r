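#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold calibration
#'
#' One row per coefficient of the two regressions.
#'
#' @param x a [threshold_calibration()].
#' @param ... unused.
#' @return tibble with `model`, `term`, `estimate`.
#' @method tidy threshold_calibration
#' @export
tidy.threshold_calibration <- function(x, ...) {
  tibble::tibble(
    model = c("mean", "mean", "std", "std", "std"),
    term = c("beta0", "beta1", "intercept", "coef_start", "coef_avg"),
    estimate = c(x$beta0, x$beta1, x$std_coeffs)
  )
}

#' @rdname tidy.threshold_calibration
#' @method glance threshold_calibration
#' @export
glance.threshold_calibration <- function(x, ...) {
  tibble::tibble(beta0 = x$beta0, beta1 = x$beta1, alpha = x$alpha)
}

#' Tidy a BEED ensemble
#'
#' One row per member with its subset size, cross-subset AUC and weight.
#'
#' @param x a `beed_model`.
#' @param ... unused.
#' @return tibble with `member`, `subset_size`, `auc`, `weight`.
#' @method tidy beed_model
#' @export
tidy.beed_model <- function(x, ...) {
  tibble::tibble(
    member = seq_along(x$members),
    subset_size = if (is.null(x$subsets)) NA_integer_ else
      lengths(x$subsets),
    auc = if (anyNA(x$aucs)) NA_real_ else x$aucs,
    weight = x$weights
  )
}

#' @rdname tidy.beed_model
#' @method glance beed_model
#' @export
glance.beed_model <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members), base_kind = x$base_kind,
    n_features = length(x$features), criterion = x$criterion,
    n_discarded = length(x$discarded %||% integer(0)), seed = x$seed
  )
}

#' Tidy a cross-validation result
#'
#' @param x a `beed_cv` from [run_cross_validation()].
#' @param ... unused.
#' @return `tidy()`: per-fold metrics; `glance()`: pooled metrics with
#'   the configuration.
#' @method tidy beed_cv
#' @export
tidy.beed_cv <- function(x, ...) x$per_fold

#' @rdname tidy.beed_cv
#' @method glance beed_cv
#' @export
glance.beed_cv <- function(x, ...) {
  dplyr::bind_cols(
    x$pooled,
    tibble::tibble(folds = x$config$folds, base_kind = x$config$base_kind)
  )
}

#' Tidy a recognition report
#'
#' @param x a `recognition_report` from [run_recognition()].
#' @param ... unused.
#' @return per-case tibble without the mask list column.
#' @method tidy recognition_report
#' @export
tidy.recognition_report <- function(x, ...) {
  dplyr::select(x$cases, -"segmentation")
}

#' @rdname tidy.recognition_report
#' @method glance recognition_report
#' @export
glance.recognition_report <- function(x, ...) {
  cc <- x$cases
  out <- tibble::tibble(
    n_cases = nrow(cc),
    n_tm = sum(cc$provenance == "TM", na.rm = TRUE),
    n_fallback = sum(cc$provenance == "FALLBACK", na.rm = TRUE),
    n_failed = sum(!is.na(cc$error))
  )
  if ("dice" %in% names(cc)) out$mean_dice <- mean(cc$dice, na.rm = TRUE)
  out
}
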