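# Minimal single-slice DICOM reader.
#
# Scope: one uncompressed little-endian frame (implicit or explicit VR),
# 8/16-bit integer pixels, flat dataset (no sequences with undefined
# length). That covers what single-slice CT exports carry; anything
# fancier should be converted upstream.

dcm_u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}

dcm_u32 <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}

dcm_tag <- function(group, element) sprintf("%04x,%04x", group, element)

# VRs whose explicit-VR encoding uses a 2-byte reserved field + 4-byte length
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# walk a flat DICOM stream, returning a named list tag -> raw value
dcm_walk <- function(raw, start, explicit, stop_after_pixeldata = TRUE,
                     stop_before_group = NULL) {
  out <- list()
  pos <- start
  n <- length(raw)
  while (pos + 7L <= n + 1L && pos <= n) {
    group <- dcm_u16(raw, pos)
    element <- dcm_u16(raw, pos + 2L)
    if (!is.null(stop_before_group) && group >= stop_before_group) break
    pos <- pos + 4L
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% .dcm_long_vrs) {
        len <- dcm_u32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- dcm_u16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      len <- dcm_u32(raw, pos)
      pos <- pos + 4L
    }
    if (len == 4294967295) {
      stop("undefined-length DICOM elements are not supported", call. = FALSE)
    }
    value <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    out[[dcm_tag(group, element)]] <- value
    pos <- pos + len
    if (stop_after_pixeldata && group == 0x7fe0 && element == 0x0010) break
  }
  out
}

dcm_string <- function(elements, tag) {
  v <- elements[[tag]]
  if (is.null(v)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(v), fixed = TRUE))
}

dcm_us <- function(elements, tag) {
  v <- elements[[tag]]
  if (is.null(v)) return(NULL)
  dcm_u16(v, 1L)
}

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    meta <- dcm_walk(raw, 133L, explicit = TRUE, stop_after_pixeldata = FALSE,
                     stop_before_group = 3L)
    # group-2 meta is always explicit; the transfer syntax decides the rest
    ts <- dcm_string(meta, "0002,0010") %||% "1.2.840.10008.1.2.1"
    meta_len <- dcm_u32(meta[["0002,0000"]], 1L)
    # dataset starts after the (0002,0000) element (12 bytes) + declared length
    pos <- 133L + 12L + meta_len
    explicit <- ts != "1.2.840.10008.1.2"
    if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
      stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
    }
  } else {
    explicit <- TRUE  # headerless streams are assumed explicit LE
  }
  el <- dcm_walk(raw, pos, explicit = explicit)

  rows <- dcm_us(el, "0028,0010")
  cols <- dcm_us(el, "0028,0011")
  if (is.null(rows) || is.null(cols)) {
    stop("DICOM file lacks Rows/Columns", call. = FALSE)
  }
  bits <- dcm_us(el, "0028,0100") %||% 16L
  signed <- identical(dcm_us(el, "0028,0103"), 1L)
  px <- el[["7fe0,0010"]]
  if (is.null(px)) stop("DICOM file lacks PixelData", call. = FALSE)

  if (bits == 16L) {
    vals <- readBin(px, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  } else if (bits == 8L) {
    vals <- as.integer(px[seq_len(rows * cols)])
  } else {
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  }
  # DICOM PixelData is row-major (top row first)
  sv <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  intercept <- dcm_string(el, "0028,1052")
  slope <- dcm_string(el, "0028,1053")
  if (is.null(intercept) || is.null(slope)) {
    warning("DICOM rescale tags missing; assuming intercept 0, slope 1",
            call. = FALSE)
    intercept <- "0"; slope <- "1"
  }
  spacing <- dcm_string(el, "0028,0030")
  spacing <- if (is.null(spacing)) NULL else {
    as.numeric(strsplit(spacing, "\\\\")[[1]])
  }
  ct_slice(sv, intercept = as.numeric(intercept), slope = as.numeric(slope),
           spacing = spacing)
}
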