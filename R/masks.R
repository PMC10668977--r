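#' Binary mask utilities and 3x3 morphology
#'
#' Masks are plain logical matrices sharing the shape of the image they
#' annotate. Morphology uses a square structuring element of ones with
#' everything outside the grid treated as background, so objects touching
#' the image border erode at the border like any other boundary.
#'
#' @name mask-ops
NULL

as_mask <- function(x) {
  if (is.logical(x) && is.matrix(x)) return(x)
  if (!is.matrix(x)) stop("a mask must be a matrix", call. = FALSE)
  m <- x != 0
  storage.mode(m) <- "logical"
  m
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share the same shape (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mask <- function(mask, dr, dc) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- mask[rs - dr, cs - dc]
  out
}

morph_offsets <- function(kernel_size) {
  if (kernel_size %% 2 == 0 || kernel_size < 1) {
    stop("kernel_size must be a positive odd integer", call. = FALSE)
  }
  r <- (kernel_size - 1L) / 2L
  expand.grid(dr = -r:r, dc = -r:r)
}

#' Binary erosion with a square structuring element
#'
#' A pixel survives erosion when every pixel under the structuring element
#' is foreground; pixels outside the grid count as background, so the
#' border always erodes.
#'
#' @param mask logical matrix.
#' @param kernel_size odd side length of the square structuring element.
#' @param iterations number of passes.
#' @return logical matrix of the same shape.
#' @export
erode_mask <- function(mask, kernel_size = 3, iterations = 1) {
  mask <- as_mask(mask)
  off <- morph_offsets(kernel_size)
  for (it in seq_len(iterations)) {
    acc <- matrix(TRUE, nrow(mask), ncol(mask))
    for (k in seq_len(nrow(off))) {
      acc <- acc & shift_mask(mask, off$dr[k], off$dc[k])
    }
    mask <- acc
  }
  mask
}

#' Binary dilation with a square structuring element
#'
#' @inheritParams erode_mask
#' @return logical matrix of the same shape.
#' @export
dilate_mask <- function(mask, kernel_size = 3, iterations = 1) {
  mask <- as_mask(mask)
  off <- morph_offsets(kernel_size)
  for (it in seq_len(iterations)) {
    acc <- matrix(FALSE, nrow(mask), ncol(mask))
    for (k in seq_len(nrow(off))) {
      acc <- acc | shift_mask(mask, off$dr[k], off$dc[k])
    }
    mask <- acc
  }
  mask
}

# 8-connected component labelling by repeated vectorised flood fill.
# Returns an integer matrix, 0 = background.
label_components <- function(mask) {
  mask <- as_mask(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  todo <- which(mask & lab == 0L)
  next_lab <- 0L
  while (length(todo)) {
    next_lab <- next_lab + 1L
    comp <- flood_from(mask, todo[1])
    lab[comp] <- next_lab
    todo <- which(mask & lab == 0L)
  }
  lab
}

# vectorised 8-neighbour flood fill from a linear seed index over `eligible`;
# returns the linear indices of the connected component (empty if seed fails)
flood_from <- function(eligible, seed_idx) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  if (!eligible[seed_idx]) return(integer(0))
  visited <- matrix(FALSE, nr, nc)
  visited[seed_idx] <- TRUE
  frontier <- seed_idx
  while (length(frontier)) {
    r <- ((frontier - 1L) %% nr) + 1L
    c <- ((frontier - 1L) %/% nr) + 1L
    nb_r <- c(r - 1L, r - 1L, r - 1L, r, r, r + 1L, r + 1L, r + 1L)
    nb_c <- c(c - 1L, c, c + 1L, c - 1L, c + 1L, c - 1L, c, c + 1L)
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
    idx <- (nb_c[ok] - 1L) * nr + nb_r[ok]
    idx <- unique(idx[eligible[idx] & !visited[idx]])
    visited[idx] <- TRUE
    frontier <- idx
  }
  which(visited)
}

mask_area <- function(mask) sum(as_mask(mask))

empty_mask <- function(shape) matrix(FALSE, shape[1], shape[2])

mask_centroid <- function(mask) {
  idx <- which(as_mask(mask))
  if (!length(idx)) return(c(NA_real_, NA_real_))
  nr <- nrow(mask)
  c(mean(((idx - 1L) %% nr) + 1L), mean(((idx - 1L) %/% nr) + 1L))
}
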