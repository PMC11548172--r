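#' Construct a MicroscopyImage
#'
#' Wraps a numeric pixel matrix with source-scale metadata. For frames built
#' in memory (phantoms, intermediate results) the source dtype defaults to
#' \code{"float"} and the source range to the observed range.
#'
#' @param pixels numeric matrix, rows = image rows.
#' @param sourceDtype \code{"uint8"}, \code{"uint16"} or \code{"float"}.
#' @param sourceRange numeric length-2 raw (min, max); defaults to the range
#'   of \code{pixels} (finite values).
#' @param normalized logical; set when \code{pixels} are already min-max
#'   scaled to \eqn{[0, 1]}.
#' @return a \linkS4class{MicroscopyImage}
#' @examples
#' img <- MicroscopyImage(matrix(runif(64), 8, 8), normalized = TRUE)
#' dim(img)
#' @export
MicroscopyImage <- function(pixels, sourceDtype = "float",
                            sourceRange = NULL, normalized = FALSE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(sourceRange)) {
    fin <- pixels[is.finite(pixels)]
    sourceRange <- if (length(fin)) range(fin) else c(0, 1)
  }
  new("MicroscopyImage", pixels = pixels, sourceDtype = sourceDtype,
      sourceRange = as.numeric(sourceRange), normalized = normalized)
}

#' @rdname MicroscopyImage-class
#' @export
setMethod("pixels", "MicroscopyImage", function(object) object@pixels)

#' @rdname MicroscopyImage-class
#' @export
setMethod("sourceDtype", "MicroscopyImage", function(object) object@sourceDtype)

#' @rdname MicroscopyImage-class
#' @export
setMethod("sourceRange", "MicroscopyImage", function(object) object@sourceRange)

#' @rdname MicroscopyImage-class
#' @export
setMethod("isNormalized", "MicroscopyImage", function(object) object@normalized)

#' @rdname MicroscopyImage-class
#' @export
setMethod("dim", "MicroscopyImage", function(x) dim(x@pixels))

setMethod("show", "MicroscopyImage", function(object) {
  cat(sprintf("MicroscopyImage %d x %d [%s]\n", nrow(object@pixels),
              ncol(object@pixels), object@sourceDtype))
  cat(sprintf("  source range: [%g, %g]  normalized: %s\n",
              object@sourceRange[1], object@sourceRange[2],
              object@normalized))
  cat(sprintf("  pixel range:  [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

.DTYPE_MAX <- c(uint8 = 255, uint16 = 65535)

#' Read a TIFF frame
#'
#' Reads a single-channel grayscale TIFF (baseline or BigTIFF, 8/16-bit
#' unsigned integer or 32-bit IEEE float) and records the storage type and
#' the raw intensity range so [normalizeFrame()] can rescale and outputs can
#' be mapped back. Multi-page files return the first page unless
#' \code{stack = TRUE}, in which case every page is returned as a list
#' element in file order.
#'
#' RGB or multi-sample TIFFs are rejected: collapsing channels silently
#' would discard information, so conversion to single-channel must happen
#' upstream.
#'
#' @param path path to a \code{.tif}/\code{.tiff} file.
#' @param stack logical; return all pages as a list of frames.
#' @return a \linkS4class{MicroscopyImage}, or a list of them when
#'   \code{stack = TRUE}.
#' @export
readFrame <- function(path, stack = FALSE) {
  if (!file.exists(path))
    .stopf("cannot read TIFF: file '%s' does not exist", path)
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE)),
    error = function(e) .stopf("cannot read TIFF '%s': %s",
                               path, conditionMessage(e)))
  if (length(pages) == 0L) .stopf("TIFF '%s' contains no pages", path)
  frames <- lapply(pages, .page_to_frame, path = path)
  if (stack) frames else frames[[1L]]
}

# one decoded TIFF page -> MicroscopyImage with raw-scale pixels
.page_to_frame <- function(page, path) {
  if (length(dim(page)) == 3L && dim(page)[3] > 1L)
    .stopf(paste0("TIFF '%s' has %d channels; convert to single-channel ",
                  "grayscale before reading (no silent channel collapse)"),
           path, dim(page)[3])
  if (length(dim(page)) == 3L) page <- page[, , 1L]
  fmt <- attr(page, "sample.format")
  bits <- attr(page, "bits.per.sample")
  if (identical(fmt, "float")) {
    dtype <- "float"
    raw <- page
  } else {
    # readTIFF scales unsigned integers to [0, 1]; undo to recover raw counts
    if (is.null(bits) || !bits %in% c(8L, 16L))
      .stopf("TIFF '%s': unsupported bit depth (%s)", path,
             if (is.null(bits)) "unknown" else bits)
    dtype <- if (bits == 8L) "uint8" else "uint16"
    raw <- round(page * .DTYPE_MAX[[dtype]])
  }
  raw <- matrix(as.numeric(raw), nrow(page), ncol(page))
  MicroscopyImage(raw, sourceDtype = dtype, sourceRange = range(raw),
                  normalized = FALSE)
}

#' Min-max normalize a frame to the unit interval
#'
#' Linearly rescales pixels using the frame's recorded source range:
#' \code{(x - min) / (max - min)}. A frame with zero dynamic range
#' (min = max) maps to all zeros rather than NaN, keeping the pipeline total
#' on degenerate inputs. Non-finite pixels are an error; silently clamping
#' them would corrupt training.
#'
#' @param img a \linkS4class{MicroscopyImage}.
#' @return a normalized \linkS4class{MicroscopyImage} with the original
#'   source range retained in metadata.
#' @examples
#' img <- MicroscopyImage(matrix(rep(c(10, 20, 30), length.out = 64), 8, 8))
#' range(pixels(normalizeFrame(img)))
#' @export
normalizeFrame <- function(img) {
  stopifnot(is(img, "MicroscopyImage"))
  p <- img@pixels
  if (any(!is.finite(p)))
    stop("frame contains NaN/Inf pixels; refusing to normalize", call. = FALSE)
  if (img@normalized) return(img)
  r <- img@sourceRange
  q <- if (r[2] > r[1]) (p - r[1]) / (r[2] - r[1]) else p * 0
  # guard against pixels outside the recorded source range
  q <- pmin(pmax(q, 0), 1)
  new("MicroscopyImage", pixels = q, sourceDtype = img@sourceDtype,
      sourceRange = r, normalized = TRUE)
}

#' Write a frame to TIFF
#'
#' Writes normalized pixels (in \eqn{[0, 1]}) as a single-page grayscale
#' TIFF. Integer targets quantize to the full dtype range, so a read/write
#' round trip deviates by at most one quantization step; \code{"float"}
#' writes 32-bit IEEE samples, which round-trip exactly.
#'
#' @param img \linkS4class{MicroscopyImage} or numeric matrix with values in
#'   \eqn{[0, 1]}.
#' @param path output path.
#' @param dtype \code{"uint8"}, \code{"uint16"} or \code{"float"}.
#' @return \code{path}, invisibly.
#' @export
writeFrame <- function(img, path, dtype = c("float", "uint16", "uint8")) {
  dtype <- match.arg(dtype)
  p <- .as_pixels(img)
  if (any(!is.finite(p))) stop("refusing to write non-finite pixels",
                               call. = FALSE)
  if (min(p) < 0 || max(p) > 1)
    stop("writeFrame expects pixels in [0, 1]; normalize first",
         call. = FALSE)
  ok <- tryCatch({
    if (dtype == "float") .write_float_tiff(p, path)
    else tiff::writeTIFF(p, path,
                         bits.per.sample = if (dtype == "uint8") 8L else 16L,
                         compression = "none")
    TRUE
  }, error = function(e) .stopf("cannot write TIFF '%s': %s", path,
                                conditionMessage(e)))
  invisible(path)
}

# Minimal single-strip little-endian grayscale float32 TIFF writer. The
# pre-installed TIFF bindings only write unsigned-integer samples; float
# output is required for lossless round trips, so the ten baseline IFD tags
# are emitted by hand. Validated in the test suite by reading the result
# back through libtiff.
.write_float_tiff <- function(mat, path) {
  h <- nrow(mat); w <- ncol(mat)
  nbytes <- h * w * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  wr4 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")
  writeBin(charToRaw("II"), con); wr2(42L)
  wr4(8L + nbytes)                       # IFD sits after the pixel strip
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  tag <- function(id, type, count, value) {
    wr2(id); wr2(type); wr4(count)
    if (type == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  wr2(10L)                               # entry count
  tag(256L, 4L, 1L, w)                   # ImageWidth
  tag(257L, 4L, 1L, h)                   # ImageLength
  tag(258L, 3L, 1L, 32L)                 # BitsPerSample
  tag(259L, 3L, 1L, 1L)                  # Compression: none
  tag(262L, 3L, 1L, 1L)                  # Photometric: BlackIsZero
  tag(273L, 4L, 1L, 8L)                  # StripOffsets
  tag(277L, 3L, 1L, 1L)                  # SamplesPerPixel
  tag(278L, 4L, 1L, h)                   # RowsPerStrip
  tag(279L, 4L, 1L, nbytes)              # StripByteCounts
  tag(339L, 3L, 1L, 3L)                  # SampleFormat: IEEE float
  wr4(0L)                                # no further IFD
  invisible(path)
}
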