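#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

hu_raster_df <- function(hu) {
  tibble::tibble(
    row = rep(seq_len(nrow(hu)), times = ncol(hu)),
    col = rep(seq_len(ncol(hu)), each = nrow(hu)),
    hu = as.vector(hu)
  )
}

#' Plot a segmentation over its HU image
#'
#' Greyscale HU background with the segmented mask and the click overlaid.
#'
#' @param object a `nodule_segmentation`.
#' @param hu the HU matrix the segmentation was computed on.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot nodule_segmentation
#' @export
autoplot.nodule_segmentation <- function(object, hu, ...) {
  df <- hu_raster_df(hu)
  df$mask <- as.vector(object$mask)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hu)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "HU") +
    ggplot2::geom_point(
      data = df[df$mask, , drop = FALSE],
      colour = "red", size = 0.2, alpha = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s segmentation (%d px)", object$provenance,
                      mask_area(object$mask)))
  if (!is.null(object$seed)) {
    p <- p + ggplot2::annotate("point", x = object$seed$col,
                               y = object$seed$row, colour = "cyan",
                               shape = 3, size = 3)
  }
  p
}

#' Plot member AUCs and weights of a BEED ensemble
#'
#' @param object a `beed_model`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot beed_model
#' @export
autoplot.beed_model <- function(object, ...) {
  df <- tidy.beed_model(object) |>
    tidyr::pivot_longer(c("auc", "weight"), names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$member),
                                   y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "ensemble member", y = NULL,
                  title = sprintf("BEED(%s): member AUCs and min-max weights",
                                  object$base_kind))
}

#' Plot feature-ranking scores
#'
#' @param object a `ranker_result` from [rank_features()].
#' @param top_n how many features to show.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ranker_result
#' @export
autoplot.ranker_result <- function(object, top_n = 20, ...) {
  df <- utils::head(object[order(object$rank), ], top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(title = paste0("feature relevance (", df$method[1], ")"),
                  x = "score", y = NULL)
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `beed_cv`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot beed_cv
#' @export
autoplot.beed_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_fold,
    c("accuracy", "sensitivity", "specificity", "auc"),
    names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = sprintf("%d-fold CV, BEED(%s)",
                                  object$config$folds,
                                  object$config$base_kind),
                  x = NULL, y = NULL)
}
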