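#' Click-seeded thresholding-based morphology segmentation
#'
#' The TM segmenter grows an 8-connected region from the clicked pixel
#' over `{hu >= threshold} & lung`, then applies one 3x3 erosion, removes
#' components not containing the click, and applies one 3x3 dilation.
#' An empty final mask marks the result null, which is the signal for the
#' candidate-fusion fallback ([segment_with_fallback()]).
#'
#' @name tm-segmentation
NULL

#' Construct a click seed
#'
#' @param row,col 1-based pixel indices.
#' @param start_hu HU value at the click; filled from the image by
#'   [tm_segment()] when `NA`.
#' @return an object of class `click_seed`.
#' @export
click_seed <- function(row, col, start_hu = NA_real_) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 start_hu = as.numeric(start_hu)),
            class = "click_seed")
}

check_seed_bounds <- function(seed, shape) {
  if (seed$row < 1 || seed$row > shape[1] || seed$col < 1 || seed$col > shape[2]) {
    stop("click seed lies outside the image", call. = FALSE)
  }
  invisible(TRUE)
}

#' Seeded region growing under a lower HU bound
#'
#' Returns the 8-connected component of
#' `{p : hu(p) >= threshold and lung(p)}` that contains the seed, or an
#' empty mask when the seed pixel itself fails either condition. The
#' threshold is a lower bound only; no upper bound is applied.
#'
#' @param hu numeric HU matrix.
#' @param lung logical lung mask, same shape (use a matrix of `TRUE` for
#'   unconstrained growth).
#' @param seed a [click_seed()].
#' @param threshold HU lower bound.
#' @return logical mask, same shape as `hu`.
#' @export
grow_region <- function(hu, lung, seed, threshold) {
  lung <- as_mask(lung)
  assert_same_shape(hu, lung, "image and lung mask")
  check_seed_bounds(seed, dim(hu))
  eligible <- (hu >= threshold) & lung
  idx <- flood_from(eligible, (seed$col - 1L) * nrow(hu) + seed$row)
  out <- empty_mask(dim(hu))
  out[idx] <- TRUE
  out
}

#' Keep the component addressed by the click
#'
#' Components of the mask (8-connected) not containing the seed are
#' treated as noise and removed. If erosion has displaced the click out of
#' every component, the component whose centroid is nearest the click is
#' kept instead of discarding everything.
#'
#' @param mask logical matrix.
#' @param seed a [click_seed()].
#' @return logical matrix with a single component (or empty if `mask` is).
#' @export
remove_noise <- function(mask, seed) {
  mask <- as_mask(mask)
  if (!any(mask)) return(mask)
  check_seed_bounds(seed, dim(mask))
  lab <- label_components(mask)
  keep <- lab[seed$row, seed$col]
  if (keep == 0L) {
    labs <- sort(unique(lab[lab > 0L]))
    d2 <- vapply(labs, function(l) {
      ctr <- mask_centroid(lab == l)
      (ctr[1] - seed$row)^2 + (ctr[2] - seed$col)^2
    }, numeric(1))
    keep <- labs[which.min(d2)]
  }
  lab == keep
}

#' Run the full TM segmentation
#'
#' Derives the adaptive threshold from the clicked HU through the
#' calibration chain (mean model, spread model, `avg - alpha * std`), then
#' grows, erodes (3x3, 1 iteration), removes noise, and dilates (3x3, 1
#' iteration). If erosion empties the mask the result is null so the
#' fallback can engage.
#'
#' @param hu numeric HU matrix.
#' @param lung logical lung mask.
#' @param seed a [click_seed()]; `start_hu` is read from `hu` when `NA`.
#' @param calib a [threshold_calibration()].
#' @param alpha spread weight; defaults to the calibration's.
#' @return an object of class `nodule_segmentation`: fields `mask`,
#'   `provenance` (`"TM"`), `threshold`, `is_null`, `seed`, `stage_areas`.
#' @examples
#' ph <- make_phantom(phantom_spec(image_size = c(128, 128),
#'                                 nodules = list(phantom_nodule(c(64, 40), 8))))
#' seg <- tm_segment(to_hounsfield(ph$slice), ph$lung, ph$click,
#'                   default_calibration())
#' seg$is_null
#' @export
tm_segment <- function(hu, lung, seed, calib, alpha = calib$alpha) {
  stopifnot(inherits(calib, "threshold_calibration"))
  check_seed_bounds(seed, dim(hu))
  if (is.na(seed$start_hu)) seed$start_hu <- hu[seed$row, seed$col]
  thr <- threshold_from_click(seed$start_hu, calib, alpha = alpha)

  grown <- grow_region(hu, lung, seed, thr)
  eroded <- erode_mask(grown, 3, 1)
  cleaned <- remove_noise(eroded, seed)
  final <- dilate_mask(cleaned, 3, 1)

  new_segmentation(final, provenance = "TM", threshold = thr, seed = seed,
                   stage_areas = c(grown = mask_area(grown),
                                   eroded = mask_area(eroded),
                                   cleaned = mask_area(cleaned),
                                   final = mask_area(final)))
}

new_segmentation <- function(mask, provenance, threshold = NA_real_,
                             seed = NULL, stage_areas = NULL) {
  structure(
    list(mask = as_mask(mask), provenance = provenance,
         threshold = threshold, is_null = !any(mask),
         seed = seed, stage_areas = stage_areas),
    class = "nodule_segmentation"
  )
}

#' @export
print.nodule_segmentation <- function(x, ...) {
  cat(sprintf("<nodule_segmentation> %s, %s, area %d px",
              x$provenance, if (x$is_null) "null" else "non-null",
              mask_area(x$mask)))
  if (is.finite(x$threshold)) cat(sprintf(", threshold %.1f HU", x$threshold))
  cat("\n")
  invisible(x)
}

#' Classical lung mask for phantoms and demos
#'
#' Thresholds at `hu < cutoff`, drops components touching the image border
#' (outside air), keeps the two largest remaining components, and fills
#' their holes. Intended for the package's synthetic phantoms; clinical
#' lung segmentation is expected to come from a dedicated model and be
#' supplied as an input mask.
#'
#' @param hu numeric HU matrix.
#' @param cutoff HU upper bound for lung/air, default -500.
#' @return logical lung mask.
#' @export
lung_mask_classical <- function(hu, cutoff = -500) {
  lab <- label_components(hu < cutoff)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  lab[lab %in% border] <- 0L
  sizes <- table(lab[lab > 0L])
  if (!length(sizes)) return(empty_mask(dim(hu)))
  keep <- as.integer(names(sort(sizes, decreasing = TRUE)))[seq_len(min(2, length(sizes)))]
  m <- matrix(lab %in% keep, nrow(hu), ncol(hu))
  as.array(EBImage::fillHull(m * 1)) > 0
}
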