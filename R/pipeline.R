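#' End-to-end recognition and cross-validation
#'
#' `run_recognition()` walks a batch of cases through lung-constrained
#' click-seeded segmentation (with fallback), feature extraction and,
#' when a trained ensemble is supplied, invasiveness prediction.
#' `run_cross_validation()` evaluates the ensemble by stratified k-fold
#' cross-validation (stratification keeps every fold two-class at 160:30
#' imbalance).
#'
#' @name pipeline
NULL

#' Run the recognition pipeline on a batch of cases
#'
#' Each case is a list with elements `slice` (a [ct_slice()]) or `hu`
#' (numeric matrix), `lung` (logical mask), `click` (a [click_seed()]),
#' and optionally `truth` (logical mask) and `label` — the shape returned
#' by [make_phantom()]. A failing case is recorded with its error message
#' and the run continues.
#'
#' @param cases list of cases.
#' @param calib a [threshold_calibration()].
#' @param model optional `beed_model` for invasiveness prediction.
#' @param alpha spread weight; defaults to the calibration's.
#' @param provider fallback candidate provider, see
#'   [segment_with_fallback()].
#' @return an object of class `recognition_report`: `cases` (one tibble
#'   row per case, with the segmentation kept in the `segmentation` list
#'   column), `config`.
#' @export
run_recognition <- function(cases, calib, model = NULL,
                            alpha = calib$alpha, provider = NULL) {
  stopifnot(inherits(calib, "threshold_calibration"))
  rows <- purrr::imap(cases, function(case, i) {
    hu <- if (!is.null(case$hu)) case$hu else to_hounsfield(case$slice)
    res <- tryCatch({
      seg <- segment_with_fallback(hu, case$lung, case$click, calib,
                                   alpha = alpha, provider = provider)
      row <- tibble::tibble(
        case = i, error = NA_character_,
        provenance = seg$provenance, is_null = seg$is_null,
        threshold = seg$threshold %||% NA_real_,
        mask_area = mask_area(seg$mask),
        segmentation = list(seg)
      )
      if (!is.null(case$truth)) {
        row <- dplyr::bind_cols(row, mask_metrics(seg$mask, case$truth)[
          , c("dice", "precision", "recall", "f_measure")])
      }
      if (!is.null(model) && !seg$is_null) {
        fv <- extract_features(hu, seg$mask)
        pr <- stats::predict(model, fv)
        row$pred_score <- pr$.score
        row$pred_label <- pr$.label
        if (!is.null(case$label)) row$true_label <- as.integer(case$label)
      }
      row
    }, error = function(e) {
      tibble::tibble(case = i, error = conditionMessage(e),
                     provenance = NA_character_, is_null = NA,
                     threshold = NA_real_, mask_area = NA_integer_,
                     segmentation = list(NULL))
    })
    res
  })
  structure(
    list(cases = dplyr::bind_rows(rows),
         config = list(alpha = alpha, calib = calib,
                       model = !is.null(model))),
    class = "recognition_report"
  )
}

#' @export
print.recognition_report <- function(x, ...) {
  n <- nrow(x$cases)
  cat(sprintf("<recognition_report> %d case(s): %d TM, %d FALLBACK, %d failed\n",
              n, sum(x$cases$provenance == "TM", na.rm = TRUE),
              sum(x$cases$provenance == "FALLBACK", na.rm = TRUE),
              sum(!is.na(x$cases$error))))
  invisible(x)
}

#' Stratified k-fold cross-validation of a BEED ensemble
#'
#' @param table feature table with 0/1 `label` (and optional `id`).
#' @param folds number of folds (>= 2).
#' @param base_kind,feature_method,k,criterion passed to [train_beed()].
#' @param seed integer seed controlling fold assignment and training.
#' @return an object of class `beed_cv`: `per_fold` metrics tibble,
#'   `pooled` metrics (one row), `predictions`, `fold_assignment`.
#' @export
run_cross_validation <- function(table, folds = 5, base_kind = "RF",
                                 feature_method = "info_gain", k = NULL,
                                 criterion = 0.5, seed = 1L) {
  stopifnot(folds >= 2)
  table <- tibble::as_tibble(table)
  if (!"id" %in% names(table)) table$id <- seq_len(nrow(table))
  lab <- as_binary_label(table$label)
  idx <- withr::with_seed(seed,
    caret::createFolds(factor(lab), k = folds, list = TRUE))

  preds <- purrr::imap(idx, function(test_rows, fold_name) {
    train <- table[-test_rows, ]
    test <- table[test_rows, ]
    if (length(unique(train$label)) < 2 || length(unique(test$label)) < 2) {
      stop("a fold ended up single-class; use stratified folds >= class size",
           call. = FALSE)
    }
    fit <- train_beed(train, base_kind = base_kind,
                      feature_method = feature_method, k = k,
                      criterion = criterion, seed = seed)
    pr <- stats::predict(fit, test)
    tibble::tibble(fold = fold_name, id = test$id,
                   truth = as_binary_label(test$label),
                   score = pr$.score, estimate = pr$.label)
  })
  preds <- dplyr::bind_rows(preds)

  per_fold <- preds |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(~ confusion_metrics(.x$truth, .x$estimate, .x$score)) |>
    dplyr::ungroup()
  pooled <- confusion_metrics(preds$truth, preds$estimate, preds$score)

  structure(
    list(per_fold = per_fold, pooled = pooled, predictions = preds,
         config = list(folds = folds, base_kind = base_kind,
                       feature_method = feature_method, k = k,
                       criterion = criterion, seed = seed)),
    class = "beed_cv"
  )
}

#' @export
print.beed_cv <- function(x, ...) {
  cat(sprintf("<beed_cv> %d-fold, %s: accuracy %.3f, AUC %.3f, sens %.3f, spec %.3f\n",
              x$config$folds, x$config$base_kind,
              x$pooled$accuracy, x$pooled$auc,
              x$pooled$sensitivity, x$pooled$specificity))
  invisible(x)
}
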