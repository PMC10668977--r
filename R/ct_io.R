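#' CT slice container and Hounsfield-unit conversion
#'
#' A `ct_slice` holds the stored pixel values of a single 2-D CT slice
#' together with the linear rescale metadata carried by CT DICOM headers.
#' Hounsfield units (HU) are recovered with the standard affine transform
#' `HU = intercept + slope * stored_value`; air sits near -1000 HU, water
#' at 0 HU, soft tissue around 0-100 HU.
#'
#' @param stored_values integer (or numeric) matrix of raw stored values.
#' @param intercept rescale intercept, in HU.
#' @param slope rescale slope, in HU per stored unit.
#' @param spacing optional pixel spacing `c(row_mm, col_mm)`.
#' @return an object of class `ct_slice`.
#' @examples
#' sl <- ct_slice(matrix(0L, 4, 4), intercept = -1024, slope = 1)
#' range(to_hounsfield(sl))
#' @export
ct_slice <- function(stored_values, intercept = 0, slope = 1, spacing = NULL) {
  if (!is.matrix(stored_values) || length(stored_values) == 0) {
    stop("stored_values must be a non-empty matrix", call. = FALSE)
  }
  if (!is.finite(intercept) || !is.finite(slope)) {
    stop("rescale intercept and slope must be finite", call. = FALSE)
  }
  if (!is.null(spacing)) {
    stopifnot(length(spacing) == 2, all(spacing > 0))
  }
  structure(
    list(stored_values = stored_values,
         intercept = as.numeric(intercept),
         slope = as.numeric(slope),
         spacing = spacing),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d stored values, intercept %g HU, slope %g\n",
              nrow(x$stored_values), ncol(x$stored_values),
              x$intercept, x$slope))
  invisible(x)
}

#' @export
dim.ct_slice <- function(x) dim(x$stored_values)

#' Convert stored values to Hounsfield units
#'
#' Applies `HU = intercept + slope * stored_value` cellwise.
#'
#' @param slice a [ct_slice()].
#' @return numeric matrix of HU values, same shape as the slice.
#' @export
to_hounsfield <- function(slice) {
  stopifnot(inherits(slice, "ct_slice"))
  if (!is.finite(slice$intercept) || !is.finite(slice$slope)) {
    stop("rescale metadata is not finite", call. = FALSE)
  }
  slice$intercept + slice$slope * slice$stored_values
}

#' Read a single CT slice
#'
#' Supported formats: a single-frame uncompressed little-endian DICOM file
#' (`format = "dicom"`), or a plain-text matrix of stored values with a JSON
#' sidecar holding the rescale metadata (`format = "raw"`, sidecar
#' `<path>.json` with fields `intercept`, `slope`, optionally `spacing`).
#' DICOM files missing the rescale tags fall back to the identity transform
#' (intercept 0, slope 1) with a warning.
#'
#' @param path file path.
#' @param format `"dicom"` or `"raw"`; guessed from the extension by default.
#' @return a [ct_slice()].
#' @export
read_slice <- function(path, format = c("auto", "dicom", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom" else "raw"
  }
  switch(format, dicom = read_dicom_slice(path), raw = read_raw_slice(path))
}

read_raw_slice <- function(path) {
  sv <- as.matrix(utils::read.table(path))
  dimnames(sv) <- NULL
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ct_slice(sv,
           intercept = meta$intercept %||% 0,
           slope = meta$slope %||% 1,
           spacing = meta$spacing)
}

write_raw_slice <- function(slice, path) {
  utils::write.table(slice$stored_values, path,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(intercept = slice$intercept, slope = slice$slope,
         spacing = slice$spacing),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read a binary mask
#'
#' PNG (any nonzero pixel is foreground), NIfTI, or plain-text 0/1 matrix.
#'
#' @param path file path; extension selects the reader.
#' @param reference_shape optional `c(rows, cols)`; an error is raised when
#'   the mask shape disagrees.
#' @return logical matrix.
#' @export
read_mask <- function(path, reference_shape = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img > 0
  } else if (ext %in% c("nii", "gz")) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) > 2) arr <- arr[, , 1]
    arr != 0
  } else {
    as.matrix(utils::read.table(path)) != 0
  }
  dimnames(m) <- NULL
  storage.mode(m) <- "logical"
  if (!is.null(reference_shape) && !identical(dim(m), as.integer(reference_shape))) {
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match the declared reference shape", call. = FALSE)
  }
  m
}

#' Write a binary mask
#'
#' PNG masks are written as 0/255 grayscale; `.nii`/`.nii.gz` via NIfTI;
#' anything else as a plain-text 0/1 matrix. `write_mask()` then
#' [read_mask()] round-trips bit-exactly.
#'
#' @param mask logical matrix.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(mask * 1, path)
  } else if (ext %in% c("nii", "gz")) {
    RNifti::writeNifti(RNifti::asNifti(mask * 1L), path)
  } else {
    utils::write.table(mask * 1L, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
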