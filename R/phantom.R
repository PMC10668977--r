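#' Synthetic CT phantoms and imbalanced feature tables
#'
#' The generators emulate exactly the structure the segmentation and
#' classification machinery relies on: a 2-D chest-like slice (air
#' background near -1000 HU, soft-tissue body near 0 HU, two elliptical
#' lung fields near -800 HU, Gaussian per-tissue noise) with disc nodules
#' of configurable mean/spread HU and ground-truth masks; calibration
#' samples drawn from a known linear model; and two-class Gaussian
#' feature tables at a 160:30 majority:minority ratio. They do not model
#' beam hardening, streaks, vasculature or real nodule texture — passing
#' tests demonstrate the algorithmic contracts, not clinical performance.
#'
#' @name synthetic-phantom
NULL

#' Describe one phantom nodule
#'
#' @param center `c(row, col)` of the disc centre.
#' @param radius disc radius in pixels (>= 2).
#' @param mean_hu,sd_hu HU distribution inside the nodule.
#' @param juxtapleural if `TRUE` the nodule is placed astride the left
#'   lung boundary (its centroid outside the lung mask), which defeats the
#'   lung-constrained TM path and exercises the fallback; `center` is then
#'   ignored.
#' @return a list describing the nodule.
#' @export
phantom_nodule <- function(center, radius = 10, mean_hu = -300, sd_hu = 30,
                           juxtapleural = FALSE) {
  if (radius < 2) stop("nodule radius must be >= 2 px", call. = FALSE)
  list(center = center, radius = radius, mean_hu = mean_hu, sd_hu = sd_hu,
       juxtapleural = juxtapleural)
}

#' Phantom specification
#'
#' Defaults: 512x512 slice, body 0 +/- 20 HU, lungs -800 +/- 40 HU, air
#' -1000 +/- 10 HU, one 12-px nodule at -300 +/- 30 HU inside the left
#' lung. Lung ellipses are placed symmetrically about the body centre.
#'
#' @param image_size `c(rows, cols)`.
#' @param body_hu,lung_hu,air_hu `c(mean, sd)` per tissue.
#' @param nodules list of [phantom_nodule()]s; `NULL` gives the default
#'   single nodule, `list()` gives none.
#' @param seed integer noise seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(512, 512),
                         body_hu = c(0, 20), lung_hu = c(-800, 40),
                         air_hu = c(-1000, 10),
                         nodules = NULL, seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 32))
  geom <- phantom_geometry(image_size)
  if (is.null(nodules)) {
    nodules <- list(phantom_nodule(
      center = round(geom$lung_centers[[1]] + c(-0.1, -0.1) * geom$lung_axes[[1]]),
      radius = max(2L, round(image_size[1] / 42))))
  }
  for (nd in nodules) {
    if (nd$mean_hu <= lung_hu[1]) {
      stop("nodule mean HU must exceed the lung mean HU", call. = FALSE)
    }
  }
  structure(list(image_size = as.integer(image_size), body_hu = body_hu,
                 lung_hu = lung_hu, air_hu = air_hu, nodules = nodules,
                 seed = as.integer(seed), geom = geom),
            class = "phantom_spec")
}

# body ellipse + two lung ellipses, scaled to the image
phantom_geometry <- function(image_size) {
  r0 <- image_size[1] / 2; c0 <- image_size[2] / 2
  list(
    body_center = c(r0, c0),
    body_axes = c(0.42 * image_size[1], 0.46 * image_size[2]),
    lung_centers = list(c(r0, c0 - 0.22 * image_size[2]),
                        c(r0, c0 + 0.22 * image_size[2])),
    lung_axes = list(c(0.30 * image_size[1], 0.16 * image_size[2]),
                     c(0.30 * image_size[1], 0.16 * image_size[2]))
  )
}

ellipse_mask <- function(shape, center, axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

disc_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Generate a CT phantom
#'
#' Builds the HU field tissue by tissue, encodes it as stored values under
#' intercept -1024 / slope 1, and returns the slice together with the
#' lung mask, the nodule ground truth, and a click seed at the (first)
#' nodule centroid.
#'
#' @param spec a [phantom_spec()].
#' @param click_jitter optional integer; the click is displaced uniformly
#'   within `[-click_jitter, click_jitter]` in each axis to test
#'   robustness to imprecise clicks.
#' @return list with elements `slice` ([ct_slice()]), `lung`, `truth`
#'   (logical masks), `click` ([click_seed()] or `NULL` when the spec has
#'   no nodules), and `spec`.
#' @export
make_phantom <- function(spec, click_jitter = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$image_size
  geom <- spec$geom

  body <- ellipse_mask(shape, geom$body_center, geom$body_axes)
  lung <- ellipse_mask(shape, geom$lung_centers[[1]], geom$lung_axes[[1]]) |
    ellipse_mask(shape, geom$lung_centers[[2]], geom$lung_axes[[2]])
  lung <- lung & body

  nodules <- lapply(spec$nodules, function(nd) {
    if (nd$juxtapleural) {
      # centre just outside the left lung's lateral boundary
      ctr <- round(c(geom$lung_centers[[1]][1],
                     geom$lung_centers[[1]][2] - geom$lung_axes[[1]][2] - 2))
      nd$center <- ctr
    }
    if (any(nd$center - nd$radius < 1) ||
        nd$center[1] + nd$radius > shape[1] ||
        nd$center[2] + nd$radius > shape[2]) {
      stop("nodule extends outside the image", call. = FALSE)
    }
    nd
  })

  hu <- withr::with_seed(spec$seed, {
    hu <- matrix(stats::rnorm(prod(shape), spec$air_hu[1], spec$air_hu[2]),
                 shape[1], shape[2])
    hu[body] <- stats::rnorm(sum(body), spec$body_hu[1], spec$body_hu[2])
    hu[lung] <- stats::rnorm(sum(lung), spec$lung_hu[1], spec$lung_hu[2])
    for (nd in nodules) {
      d <- disc_mask(shape, nd$center, nd$radius)
      hu[d] <- stats::rnorm(sum(d), nd$mean_hu, nd$sd_hu)
    }
    hu
  })

  truth <- empty_mask(shape)
  for (nd in nodules) truth <- truth | disc_mask(shape, nd$center, nd$radius)

  slice <- ct_slice(round(hu + 1024), intercept = -1024, slope = 1)
  hu_q <- to_hounsfield(slice)

  click <- NULL
  if (length(nodules)) {
    first <- disc_mask(shape, nodules[[1]]$center, nodules[[1]]$radius)
    ctr <- round(mask_centroid(first))
    if (click_jitter > 0) {
      ctr <- ctr + withr::with_seed(spec$seed + 1L,
        sample(-click_jitter:click_jitter, 2, replace = TRUE))
    }
    click <- click_seed(ctr[1], ctr[2], start_hu = hu_q[ctr[1], ctr[2]])
  }

  list(slice = slice, lung = lung, truth = truth, click = click, spec = spec)
}

#' Generate calibration samples from a known linear model
#'
#' Clicked HU values are drawn uniformly on `[-500, -100]`; the nodule
#' mean follows `avg = b0 + b1 * start + e` and the spread follows
#' `std = c0 + c1 * start + c2 * avg + e'`. The generating coefficients
#' are attached as attributes `"mean_coefs"` and `"std_coefs"` so
#' parameter-recovery tests can compare against truth.
#'
#' @param n number of samples (>= 3).
#' @param seed integer seed.
#' @param mean_coefs generating `c(b0, b1)`; defaults to the shipped mean
#'   model (-173.34, 0.71).
#' @param std_coefs generating `c(c0, c1, c2)`.
#' @param sigma_avg,sigma_std Gaussian noise levels (0 for noiseless).
#' @return tibble with columns `start`, `avg`, `std`.
#' @export
make_calibration_set <- function(n, seed = 1L,
                                 mean_coefs = c(-173.34, 0.71),
                                 std_coefs = c(25, 0.01, -0.04),
                                 sigma_avg = 5, sigma_std = 1) {
  stopifnot(n >= 3)
  out <- withr::with_seed(seed, {
    start <- stats::runif(n, -500, -100)
    avg <- mean_coefs[1] + mean_coefs[2] * start + stats::rnorm(n, 0, sigma_avg)
    std <- pmax(std_coefs[1] + std_coefs[2] * start + std_coefs[3] * avg +
                  stats::rnorm(n, 0, sigma_std), 0)
    tibble::tibble(start = start, avg = avg, std = std)
  })
  attr(out, "mean_coefs") <- mean_coefs
  attr(out, "std_coefs") <- std_coefs
  out
}

#' Specification of a synthetic imbalanced feature table
#'
#' Defaults mirror the study conditions the classifier targets: 160
#' majority (invasive, label 1) vs 30 minority (non-invasive, label 0)
#' rows, 20 features of which 5 are informative, unit noise, and a class
#' mean shift of 1.2 per informative feature — enough overlap that a
#' single classifier trained on the raw imbalance under-serves the
#' minority class.
#'
#' @param n_majority,n_minority class sizes.
#' @param n_features,n_informative feature counts.
#' @param delta class mean shift per informative feature.
#' @param sigma within-class standard deviation.
#' @param seed integer seed.
#' @return an object of class `table_spec`.
#' @export
table_spec <- function(n_majority = 160, n_minority = 30,
                       n_features = 20, n_informative = 5,
                       delta = 1.2, sigma = 1, seed = 1L) {
  stopifnot(n_majority >= 1, n_minority >= 1,
            n_informative <= n_features, n_features >= 1)
  structure(list(n_majority = n_majority, n_minority = n_minority,
                 n_features = n_features, n_informative = n_informative,
                 delta = delta, sigma = sigma, seed = as.integer(seed)),
            class = "table_spec")
}

#' Generate an imbalanced two-class Gaussian feature table
#'
#' Informative features are `N(+delta/2, sigma^2)` for the majority
#' (label 1) class and `N(-delta/2, sigma^2)` for the minority; the rest
#' are `N(0, sigma^2)` for both.
#'
#' @param spec a [table_spec()].
#' @return tibble with `id`, `label`, and feature columns `f01`, `f02`, ...
#' @export
make_feature_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  n <- spec$n_majority + spec$n_minority
  lab <- c(rep(1L, spec$n_majority), rep(0L, spec$n_minority))
  shift <- ifelse(lab == 1, spec$delta / 2, -spec$delta / 2)
  x <- withr::with_seed(spec$seed, {
    x <- matrix(stats::rnorm(n * spec$n_features, 0, spec$sigma),
                n, spec$n_features)
    if (spec$n_informative > 0) {
      x[, seq_len(spec$n_informative)] <-
        x[, seq_len(spec$n_informative), drop = FALSE] + shift
    }
    x
  })
  colnames(x) <- sprintf("f%02d", seq_len(spec$n_features))
  dplyr::bind_cols(tibble::tibble(id = seq_len(n), label = lab),
                   tibble::as_tibble(x))
}
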