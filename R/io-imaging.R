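# Field/well image IO and tiling. Images are single-plane grayscale TIFFs,
# 8- or 16-bit unsigned, read and written losslessly at the native integer
# scale. The default filename convention is "{plate}_{well}_f{field}.tif";
# the parsing regex is configurable.

.default_field_pattern <- "^.*_([A-Za-z][0-9]{2})_f([0-3])\\.tiff?$"

#' Read a single camera field from a grayscale TIFF
#'
#' Pixels are loaded losslessly at native integer scale; the bit depth is
#' inferred from the file. Well id and field index are parsed from the
#' filename with `pattern` (two capture groups: well, field) unless given
#' explicitly.
#'
#' @param path path to a single-plane grayscale TIFF (uint8/uint16).
#' @param pattern regex with two capture groups applied to the basename.
#' @param wellId,fieldIndex override the filename parse.
#' @return a [FieldImage-class].
#' @export
readFieldImage <- function(path, pattern = .default_field_pattern,
                           wellId = NULL, fieldIndex = NULL) {
  raw <- tryCatch(
    tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = FALSE),
    error = function(e)
      stopTyped("ecms_not_tiff", "cannot read '%s' as TIFF: %s",
                path, conditionMessage(e)))
  if (length(dim(raw)) == 3L && dim(raw)[3L] > 1L)
    stopTyped("ecms_multichannel",
              "unsupported channel count (%d) in '%s': expected grayscale",
              dim(raw)[3L], path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  fmt <- attr(raw, "sample.format")
  if (!is.null(fmt) && !identical(fmt, "uint"))
    stopTyped("ecms_float_image",
              "unsupported sample format '%s' in '%s': expected unsigned integer",
              fmt, path)
  bits <- attr(raw, "bits.per.sample") %||% 16L
  if (!(bits %in% c(8L, 16L)))
    stopTyped("ecms_float_image",
              "unsupported bit depth %d in '%s' (expected 8 or 16)",
              bits, path)
  if (is.null(wellId) || is.null(fieldIndex)) {
    m <- regmatches(basename(path), regexec(pattern, basename(path)))[[1L]]
    if (length(m) < 3L)
      stopTyped("ecms_bad_filename",
                "filename '%s' does not match pattern '%s'",
                basename(path), pattern)
    wellId <- wellId %||% m[2L]
    fieldIndex <- fieldIndex %||% as.integer(m[3L])
  }
  px <- matrix(as.numeric(raw), nrow = nrow(raw))
  FieldImage(px, bitDepth = as.integer(bits), wellId = wellId,
             fieldIndex = fieldIndex)
}

# lossless integer-scale TIFF write shared by field and well writers
.writeTiff <- function(pixels, bitDepth, path) {
  tiff::writeTIFF(pixels / (2^bitDepth - 1), path,
                  bits.per.sample = as.integer(bitDepth),
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Write a field or well image as a grayscale TIFF
#'
#' The inverse of [readFieldImage()]: a write-then-read round trip is
#' bit-identical.
#'
#' @param object a [FieldImage-class] or [WellImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFieldImage <- function(object, path) {
  stopifnot(is(object, "FieldImage"))
  .writeTiff(object@pixels, object@bitDepth, path)
}

#' @rdname writeFieldImage
#' @export
writeWellImage <- function(object, path) {
  stopifnot(is(object, "WellImage"))
  .writeTiff(object@pixels, object@bitDepth, path)
}

#' Tile four fields into the per-well mosaic
#'
#' Assembles the 2 x 2 row-major mosaic analysed per well: by default field
#' 0 top-left, 1 top-right, 2 bottom-left, 3 bottom-right. Native
#' 1104 x 1104 px fields give a 2208 x 2208 px well image. The arrangement
#' is configurable because branch counts are invariant to it but visual QC
#' is not.
#'
#' @param fields list of exactly four [FieldImage-class] objects sharing
#'   dimensions, bit depth and well id, with field indices `{0,1,2,3}`.
#' @param order which field index goes at (top-left, top-right, bottom-left,
#'   bottom-right).
#' @param pixelSizeUm optional micrometres per pixel, carried on the mosaic.
#' @return a [WellImage-class].
#' @export
tileFields <- function(fields, order = 0:3, pixelSizeUm = NA_real_) {
  if (!is.list(fields) || length(fields) != 4L ||
      !all(vapply(fields, is, logical(1), "FieldImage")))
    stop("fields must be a list of exactly 4 FieldImage objects")
  idx <- vapply(fields, fieldIndex, integer(1))
  if (!setequal(idx, 0:3))
    stop("field indices must be exactly {0,1,2,3}")
  if (!setequal(order, 0:3) || length(order) != 4L)
    stop("order must be a permutation of 0:3")
  dims <- vapply(fields, function(f) dim(pixels(f)), integer(2))
  if (any(dims != dims[, 1L]))
    stop("all four fields must share dimensions")
  if (length(unique(vapply(fields, bitDepth, integer(1)))) != 1L)
    stop("all four fields must share bit depth")
  wells <- vapply(fields, wellId, character(1))
  if (length(unique(wells)) != 1L)
    stop("all four fields must share the well id: got ",
         paste(unique(wells), collapse = ", "))
  byIdx <- fields[match(order, idx)]
  top <- cbind(pixels(byIdx[[1L]]), pixels(byIdx[[2L]]))
  bottom <- cbind(pixels(byIdx[[3L]]), pixels(byIdx[[4L]]))
  WellImage(rbind(top, bottom), bitDepth = bitDepth(fields[[1L]]),
            wellId = wells[1L], sourceFields = as.integer(order),
            pixelSizeUm = pixelSizeUm)
}

#' Slice a well mosaic back into its four fields
#'
#' Inverse of [tileFields()]: quadrants are returned bit-exactly as
#' `FieldImage` objects with the indices recorded in `sourceFields` (or
#' `order`).
#'
#' @param well a [WellImage-class] with even dimensions.
#' @param order field index per quadrant; defaults to the mosaic's
#'   `sourceFields` (or 0:3).
#' @return list of four [FieldImage-class], in field-index order.
#' @export
sliceFields <- function(well, order = NULL) {
  stopifnot(is(well, "WellImage"))
  px <- pixels(well)
  if (nrow(px) %% 2L || ncol(px) %% 2L)
    stop("well image dimensions must be even")
  order <- order %||%
    (if (!anyNA(sourceFields(well))) sourceFields(well) else 0:3)
  hr <- nrow(px) / 2L
  hc <- ncol(px) / 2L
  quadrants <- list(px[1:hr, 1:hc], px[1:hr, (hc + 1):ncol(px)],
                    px[(hr + 1):nrow(px), 1:hc],
                    px[(hr + 1):nrow(px), (hc + 1):ncol(px)])
  out <- vector("list", 4L)
  for (q in 1:4) {
    fi <- order[q]
    out[[fi + 1L]] <- FieldImage(quadrants[[q]], bitDepth = bitDepth(well),
                                 wellId = wellId(well), fieldIndex = fi)
  }
  out
}
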