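#' Anchor accounting and candidate fusion
#'
#' A full region-proposal scan evaluates anchors at every position of
#' every feature-map level; fixing the anchor to a small window around the
#' clicked pixel cuts that to `window^2` positions per level. With the
#' default pyramid (512x512 input, strides 4/8/16/32/64, one anchor per
#' position, 3x3 window over 5 levels) the counts are 21824 vs 45, a
#' ~473-fold reduction.
#'
#' When the click-seeded detector produces several candidate masks, the
#' retained candidate is the one overlapping most with the union of all
#' pairwise intersections — i.e. the mask most corroborated by the others.
#'
#' @name candidate-fusion
NULL

#' Anchor-scan configuration
#'
#' @param image_size `c(rows, cols)` of the network input.
#' @param strides per-level subsampling factors, positive and increasing.
#' @param window odd side of the click-fixed window, default 3.
#' @param anchors_per_position anchors evaluated at each position.
#' @return an object of class `anchor_config`.
#' @export
anchor_config <- function(image_size = c(512, 512),
                          strides = c(4, 8, 16, 32, 64),
                          window = 3, anchors_per_position = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 1),
            all(strides > 0), !is.unsorted(strides, strictly = TRUE),
            anchors_per_position >= 1)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 strides = as.integer(strides),
                 window = as.integer(window),
                 anchors_per_position = as.integer(anchors_per_position)),
            class = "anchor_config")
}

#' Anchor count of a full feature-pyramid scan
#'
#' Sum over levels of `ceil(rows/stride) * ceil(cols/stride) *
#' anchors_per_position`.
#'
#' @param cfg an [anchor_config()].
#' @return integer anchor count.
#' @examples
#' count_full_scan_anchors(anchor_config())  # 21824
#' @export
count_full_scan_anchors <- function(cfg) {
  stopifnot(inherits(cfg, "anchor_config"))
  sum(ceiling(cfg$image_size[1] / cfg$strides) *
        ceiling(cfg$image_size[2] / cfg$strides)) * cfg$anchors_per_position
}

#' Anchor count of the click-fixed window
#'
#' `window^2` positions per level (times `anchors_per_position`),
#' truncated where the window runs off the feature-map border. The click
#' defaults to the image centre (an interior position at every level).
#'
#' @param cfg an [anchor_config()].
#' @param click optional `c(row, col)` image coordinates of the click.
#' @return integer anchor count.
#' @examples
#' count_fixed_anchors(anchor_config())  # 45
#' @export
count_fixed_anchors <- function(cfg, click = NULL) {
  stopifnot(inherits(cfg, "anchor_config"))
  if (is.null(click)) click <- cfg$image_size / 2
  half <- (cfg$window - 1L) / 2L
  total <- 0L
  for (s in cfg$strides) {
    fmap <- ceiling(cfg$image_size / s)
    pos <- pmin(pmax(ceiling(click / s), 1), fmap)
    nr <- min(pos[1] + half, fmap[1]) - max(pos[1] - half, 1) + 1
    nc <- min(pos[2] + half, fmap[2]) - max(pos[2] - half, 1) + 1
    total <- total + nr * nc
  }
  as.integer(total * cfg$anchors_per_position)
}

#' Select the most corroborated candidate mask
#'
#' Builds `U`, the union of all pairwise intersections of distinct
#' candidates, and returns the candidate with the largest `|candidate &
#' U|`. Ties go to the larger candidate, then to list order. A singleton
#' list returns its only mask; an empty list returns an empty mask of
#' `shape`.
#'
#' @param candidates list of logical masks of identical shape.
#' @param shape `c(rows, cols)` used only when `candidates` is empty.
#' @return a logical mask drawn from `candidates` (or empty).
#' @export
select_candidate <- function(candidates, shape = NULL) {
  candidates <- lapply(candidates, as_mask)
  if (!length(candidates)) {
    if (is.null(shape)) stop("empty candidate set and no shape given", call. = FALSE)
    return(empty_mask(shape))
  }
  if (length(candidates) == 1) return(candidates[[1]])
  for (m in candidates[-1]) assert_same_shape(candidates[[1]], m, "candidates")

  u <- empty_mask(dim(candidates[[1]]))
  n <- length(candidates)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- u | (candidates[[i]] & candidates[[j]])
    }
  }
  overlap <- vapply(candidates, function(m) sum(m & u), numeric(1))
  area <- vapply(candidates, sum, numeric(1))
  best <- order(-overlap, -area)[1]
  candidates[[best]]
}

#' Multi-alpha fallback candidate provider
#'
#' The default fallback provider re-runs the TM chain at several spread
#' weights with the lung constraint removed, yielding a small candidate
#' set for [select_candidate()]. Any external detector can replace it: a
#' provider is a function `(hu, seed) -> list of logical masks`.
#'
#' @param calib a [threshold_calibration()].
#' @param alphas spread weights to try.
#' @return a provider function.
#' @export
multialpha_provider <- function(calib, alphas = c(1, 2, 3)) {
  stopifnot(inherits(calib, "threshold_calibration"))
  function(hu, seed) {
    no_lung <- matrix(TRUE, nrow(hu), ncol(hu))
    lapply(alphas, function(a) {
      tm_segment(hu, no_lung, seed, calib, alpha = a)$mask
    })
  }
}

#' Segment with the TM -> fallback switch
#'
#' Runs [tm_segment()]; when the result is null, asks `provider` for
#' candidate masks and resolves them with [select_candidate()]. Fallback
#' candidates are not restricted to the lung mask, which is what lets the
#' pipeline recover juxtapleural nodules the lung-constrained path cannot
#' reach.
#'
#' @inheritParams tm_segment
#' @param provider function `(hu, seed) -> list of masks`; defaults to
#'   [multialpha_provider()] on `calib`.
#' @return a `nodule_segmentation` with provenance `"TM"` or `"FALLBACK"`.
#' @export
segment_with_fallback <- function(hu, lung, seed, calib,
                                  alpha = calib$alpha, provider = NULL) {
  tm <- tm_segment(hu, lung, seed, calib, alpha = alpha)
  if (!tm$is_null) return(tm)
  if (is.null(provider)) provider <- multialpha_provider(calib)
  cands <- tryCatch(provider(hu, seed), error = function(e) {
    stop("fallback provider failed after a null TM result (TM threshold ",
         signif(tm$threshold, 6), "): ", conditionMessage(e), call. = FALSE)
  })
  mask <- select_candidate(cands, shape = dim(hu))
  out <- new_segmentation(mask, provenance = "FALLBACK", seed = tm$seed,
                          stage_areas = c(tm$stage_areas,
                                          fallback = mask_area(mask)))
  out$tm_threshold <- tm$threshold
  out
}
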