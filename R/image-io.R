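#' Load a projection image
#'
#' Reads a single- or multi-page TIFF or a PNG as 8- or 16-bit grayscale.
#' Multi-page inputs (z-stacks) are reduced to a single frame by per-pixel
#' maximum, so either precomputed maximum projections or raw stacks may be
#' supplied. RGB images are rejected: the GFP channel must be extracted
#' upstream, since channel choice is a scientific decision.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param scale A [pixel_scale()].
#' @return A `projection_image`: list with `pixels` (numeric matrix in
#'   native intensity units, row 1 at top), `bit_depth` (8 or 16), `scale`
#'   and `source_path`.
#' @export
load_image <- function(path, scale) {
  stopifnot(inherits(scale, "pixel_scale"))
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) stop("unreadable TIFF: ", path,
                                               " (", conditionMessage(e), ")"))
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample")
    mats <- lapply(pages, drop_to_gray)
    px <- Reduce(pmax, mats)
    if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  } else if (ext == "png") {
    arr <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("unreadable PNG: ", path,
                                             " (", conditionMessage(e), ")"))
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    attributes(arr) <- attributes(arr)["dim"]
    # png::readPNG returns [0,1]; recover native integer units
    px <- round(drop_to_gray(arr) * (2^bits - 1))
  } else {
    stop("unsupported image format '.", ext, "': use TIFF or PNG")
  }
  new_projection_image(px, bit_depth = as.integer(bits), scale = scale,
                       source_path = path)
}

# reject RGB, return matrix; PNG/TIFF pages may carry an alpha/colour dim
drop_to_gray <- function(a) {
  if (length(dim(a)) == 3) {
    if (dim(a)[3] == 1) return(a[, , 1])
    ch <- a[, , seq_len(min(3, dim(a)[3])), drop = FALSE]
    rng <- apply(ch, 3, function(m) diff(range(m)))
    if (sum(rng > 0) > 1 &&
        any(abs(ch[, , 1] - ch[, , min(2, dim(ch)[3])]) > 1e-9)) {
      stop("RGB input rejected: extract the GFP channel upstream and ",
           "supply a single-channel grayscale image")
    }
    return(ch[, , 1])
  }
  as.matrix(a)
}

new_projection_image <- function(pixels, bit_depth, scale,
                                 source_path = "<memory>") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(dim(pixels) < 64))
    stop("image too small: need at least 64x64 pixels, got ",
         paste(dim(pixels), collapse = "x"))
  maxv <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > maxv)
    stop("intensities outside [0, ", maxv, "] for bit depth ", bit_depth)
  if (stats::sd(pixels) == 0)
    stop("blank frame: image has zero intensity variance")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 scale = scale, source_path = source_path),
            class = "projection_image")
}

#' Maximum-intensity projection of a list of frames
#'
#' Per-pixel maximum across frames. Idempotent: projecting a single frame
#' (or a projection) returns it unchanged.
#'
#' @param frames A matrix or list of equally sized matrices.
#' @return A matrix.
#' @export
max_project <- function(frames) {
  if (is.matrix(frames)) return(frames)
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stop("frames differ in size")
  Reduce(pmax, frames)
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %dx%d px, %d-bit, %.4g um/px (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$scale$microns_per_pixel, x$source_path))
  invisible(x)
}

#' Write a projection image to disk
#'
#' 16-bit images go to TIFF, 8-bit to TIFF or PNG depending on extension.
#'
#' @param img A `projection_image`.
#' @param path Output path (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "projection_image"))
  maxv <- 2^img$bit_depth - 1
  norm <- img$pixels / maxv
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (img$bit_depth != 8) stop("PNG output supported for 8-bit images only")
    png::writePNG(norm, path)
  } else {
    tiff::writeTIFF(norm, path, bits.per.sample = img$bit_depth)
  }
  invisible(path)
}

# coerce EBImage outputs back to plain matrices
as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# bilinear sampling of matrix m at fractional (row, col) positions
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}
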