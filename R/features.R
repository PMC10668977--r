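#' Radiomics-lite features of a segmented nodule
#'
#' A compact, fully reproducible feature set: first-order HU statistics on
#' the masked pixels, 2-D shape descriptors of the mask, and grey-level
#' co-occurrence (GLCM) texture on a 32-bin HU quantisation, averaged over
#' the four standard offsets (0,1), (1,0), (1,1), (1,-1). It deliberately
#' does not chase parity with commercial radiomics inventories; the
#' contract is deterministic, translation-invariant features suitable for
#' the downstream selection and classification machinery.
#'
#' @name radiomics-features
NULL

#' Extract the feature vector of a masked nodule
#'
#' @param hu numeric HU matrix.
#' @param mask logical nodule mask, same shape, at least 2 pixels.
#' @return one-row tibble of named features (first-order `hu_*`, shape,
#'   and `glcm_*` texture).
#' @export
extract_features <- function(hu, mask) {
  mask <- as_mask(mask)
  assert_same_shape(hu, mask, "image and mask")
  if (sum(mask) < 2) stop("mask must contain at least 2 pixels", call. = FALSE)
  v <- hu[mask]

  s <- stats::sd(v)
  skew <- if (s == 0) 0 else e1071::skewness(v)
  kurt <- if (s == 0) 0 else e1071::kurtosis(v)
  q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE)

  # entropy of a 32-bin equal-width histogram over the masked HU range
  ent <- if (diff(range(v)) == 0) 0 else {
    p <- tabulate(cut(v, breaks = 32, labels = FALSE, include.lowest = TRUE), 32)
    p <- p[p > 0] / length(v)
    -sum(p * log2(p))
  }

  shp <- shape_features(mask)
  glcm <- glcm_features(hu, mask, n_bins = 32)

  tibble::tibble(
    hu_mean = mean(v), hu_std = s, hu_min = min(v), hu_max = max(v),
    hu_median = q[2], hu_p10 = q[1], hu_p90 = q[3],
    hu_range = diff(range(v)),
    hu_skewness = skew, hu_kurtosis = kurt,
    hu_energy = sum(v^2), hu_entropy = ent,
    !!!shp, !!!glcm
  )
}

shape_features <- function(mask) {
  area <- sum(mask)
  sf <- EBImage::computeFeatures.shape(mask * 1)
  mf <- EBImage::computeFeatures.moment(mask * 1)
  perim <- as.numeric(sf[1, "s.perimeter"])
  ecc <- as.numeric(mf[1, "m.eccentricity"])

  idx <- which(mask, arr.ind = TRUE)
  # convex hull over pixel corner points so a filled rectangle has solidity 1
  corners <- rbind(idx + 0.5, idx - 0.5,
                   cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
                   cbind(idx[, 1] - 0.5, idx[, 2] + 0.5))
  h <- grDevices::chull(corners)
  hp <- corners[h, , drop = FALSE]
  hull_area <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                         hp[, 2] * c(hp[-1, 1], hp[1, 1]))) / 2
  bbox_area <- prod(apply(idx, 2, function(z) diff(range(z)) + 1))

  list(
    area_px = area,
    perimeter_px = perim,
    equivalent_diameter = 2 * sqrt(area / pi),
    eccentricity = ecc,
    solidity = if (hull_area > 0) min(area / hull_area, 1) else 1,
    extent = area / bbox_area,
    compactness = if (perim > 0) 4 * pi * area / perim^2 else 0
  )
}

.glcm_offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

glcm_features <- function(hu, mask, n_bins = 32) {
  v <- hu[mask]
  # quantise masked pixels into equal-width bins over their own range
  if (diff(range(v)) == 0) {
    qimg <- matrix(NA_integer_, nrow(hu), ncol(hu))
    qimg[mask] <- 1L
  } else {
    br <- seq(min(v), max(v), length.out = n_bins + 1)
    qimg <- matrix(NA_integer_, nrow(hu), ncol(hu))
    qimg[mask] <- cut(v, breaks = br, labels = FALSE, include.lowest = TRUE)
  }

  per_off <- lapply(.glcm_offsets, function(off) {
    a <- qimg
    b <- shift_int(qimg, -off[1], -off[2])   # b[r,c] = qimg[r+dr, c+dc]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NULL)
    # symmetric co-occurrence counts
    tab <- table(factor(c(a[ok], b[ok]), levels = seq_len(n_bins)),
                 factor(c(b[ok], a[ok]), levels = seq_len(n_bins)))
    p <- tab / sum(tab)
    i <- matrix(seq_len(n_bins), n_bins, n_bins)
    j <- t(i)
    mu_i <- sum(i * p); mu_j <- sum(j * p)
    s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
    corr <- if (s_i == 0 || s_j == 0) 1 else
      sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
    c(contrast = sum(p * (i - j)^2),
      correlation = corr,
      energy = sum(p^2),
      homogeneity = sum(p / (1 + abs(i - j))))
  })
  per_off <- per_off[!vapply(per_off, is.null, logical(1))]
  if (!length(per_off)) {
    avg <- c(contrast = 0, correlation = 1, energy = 1, homogeneity = 1)
  } else {
    avg <- Reduce(`+`, per_off) / length(per_off)
  }
  as.list(stats::setNames(as.numeric(avg), paste0("glcm_", names(avg))))
}

# integer-matrix shift with NA padding
shift_int <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_integer_, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Rank features against a binary label
#'
#' Four univariate rankers, all returning higher-is-more-relevant scores:
#' * `chi2` — chi-squared statistic of per-class sums of the min-max
#'   scaled (hence non-negative) feature against the class prior;
#' * `anova_f` — one-way ANOVA F statistic between classes;
#' * `info_gain` — reduction in label entropy after splitting the feature
#'   at its median;
#' * `pearson` — absolute Pearson correlation with the 0/1 label.
#'
#' Constant features score 0 and are flagged degenerate; infinite
#' statistics (perfect separation under `anova_f`) are kept and flagged.
#'
#' @param table data frame with a 0/1 `label` column; every other numeric
#'   column is treated as a feature.
#' @param method one of `"chi2"`, `"anova_f"`, `"info_gain"`, `"pearson"`.
#' @return a tibble (class `ranker_result`) with columns `feature`,
#'   `method`, `score`, `rank`, `degenerate`.
#' @export
rank_features <- function(table, method = c("chi2", "anova_f", "info_gain", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), "label" %in% names(table))
  lab <- as_binary_label(table$label)
  if (length(unique(lab)) < 2) stop("table must contain both classes", call. = FALSE)
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   c("label", "id"))
  if (!length(feats)) stop("no numeric feature columns", call. = FALSE)

  score_one <- function(x) {
    if (stats::sd(x) == 0) return(c(score = 0, degenerate = 1))
    s <- switch(method,
      chi2 = chi2_score(x, lab),
      anova_f = suppressWarnings(
        as.numeric(stats::anova(stats::lm(x ~ factor(lab)))[["F value"]][1])),
      info_gain = info_gain_score(x, lab),
      pearson = abs(stats::cor(x, lab))
    )
    if (is.na(s)) s <- 0
    c(score = s, degenerate = as.numeric(!is.finite(s)))
  }
  sc <- vapply(feats, function(f) score_one(table[[f]]), numeric(2))

  out <- tibble::tibble(
    feature = feats, method = method,
    score = unname(sc["score", ]), degenerate = unname(sc["degenerate", ] > 0)
  )
  out <- out[order(-out$score, out$feature), ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("ranker_result", class(out))
  out
}

chi2_score <- function(x, lab) {
  rng <- range(x)
  xs <- (x - rng[1]) / (rng[2] - rng[1])
  total <- sum(xs)
  if (total == 0) return(0)
  obs <- c(sum(xs[lab == 0]), sum(xs[lab == 1]))
  expd <- total * c(mean(lab == 0), mean(lab == 1))
  sum((obs - expd)^2 / expd)
}

entropy2 <- function(lab) {
  p <- table(lab) / length(lab)
  p <- p[p > 0]
  -sum(p * log2(p))
}

info_gain_score <- function(x, lab) {
  split <- x > stats::median(x)
  h0 <- entropy2(lab)
  h1 <- 0
  for (side in c(TRUE, FALSE)) {
    n <- sum(split == side)
    if (n > 0) h1 <- h1 + n / length(lab) * entropy2(lab[split == side])
  }
  h0 - h1
}

#' Keep the top-k ranked features
#'
#' @param ranks a `ranker_result` from [rank_features()].
#' @param k number of features to keep; ties broken by score then feature
#'   name order.
#' @return character vector of `k` feature names.
#' @export
select_top_k <- function(ranks, k) {
  stopifnot(inherits(ranks, "ranker_result"))
  if (k < 1 || k > nrow(ranks)) {
    stop("k must be between 1 and the number of features", call. = FALSE)
  }
  ranks$feature[order(-ranks$score, ranks$feature)][seq_len(k)]
}
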