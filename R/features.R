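#' Enhance a dendrite ROI for feature detection
#'
#' Three preprocessing steps prepare the cropped ROI for morphological
#' feature detection: a local contrast enhancement (CLAHE blended with the
#' original image, more weakly the noisier the background, so noisy
#' images are enhanced more gently), a white top-hat background
#' subtraction (2 um
#' disc) that removes soma halo and uneven illumination while preserving
#' bleb-sized structures, and a 4x bilinear upsampling that supplies
#' enough pixels for the morphological operations that follow. The
#' enhanced image also records `noise_level`, the robust dispersion
#' (median absolute deviation, scaled to be consistent with a Gaussian SD)
#' of the sub-Otsu background pixels, which downstream thresholds adapt
#' to.
#'
#' @param roi A `dendrite_roi` from [crop_dendrites()].
#' @param config An [analysis_config()].
#' @return An `enhanced_roi`: `pixels` (working [0,1] grid at 4x), `scale`
#'   (with `resize_factor = 4`), `noise_level`, and `roi` (the original
#'   ROI, kept so intensity descriptors can be measured in native units).
#' @export
enhance <- function(roi, config = analysis_config()) {
  stopifnot(inherits(roi, "dendrite_roi"))
  maxv <- 2^roi$bit_depth - 1
  w <- roi$pixels / maxv
  ot0 <- EBImage::otsu(w)
  bg <- w[w < ot0]
  noise0 <- if (length(bg) > 10) stats::mad(bg) else 0
  # noise-adaptive local contrast: CLAHE at a fixed clip limit, blended
  # with the original so noisy images are enhanced more gently
  # (alpha -> 1 as noise -> 0)
  alpha <- 1 / (1 + noise0 / config$clahe_noise_ref)
  cl <- apply_clahe(w, roi$scale, config$clahe_tile_um, config$clahe_clip)
  w <- alpha * cl + (1 - alpha) * w
  brush <- EBImage::makeBrush(odd_px(2 * config$tophat_radius_um, roi$scale),
                              shape = "disc")
  w <- as_mat(EBImage::whiteTopHat(w, brush))
  f <- as.integer(config$resize_factor)
  w <- as_mat(EBImage::resize(w, w = nrow(w) * f, h = ncol(w) * f))
  w <- pmin(pmax(w, 0), 1)
  ot <- EBImage::otsu(w)
  bg <- w[w < ot]
  noise <- if (length(bg) > 10) stats::mad(bg) else 0
  structure(list(pixels = w,
                 scale = pixel_scale(roi$scale$microns_per_pixel, f),
                 noise_level = noise, otsu_level = ot, roi = roi),
            class = "enhanced_roi")
}

# CLAHE with padding to tile-divisible dimensions
apply_clahe <- function(w, scale, tile_um, limit) {
  nx <- max(2L, round(nrow(w) / px_len(tile_um, scale)))
  ny <- max(2L, round(ncol(w) / px_len(tile_um, scale)))
  pr <- (nx - nrow(w) %% nx) %% nx
  pc <- (ny - ncol(w) %% ny) %% ny
  wp <- rbind(w, w[rev(seq_len(pr)), , drop = FALSE])
  wp <- cbind(wp, wp[, rev(seq_len(pc)), drop = FALSE])
  out <- as_mat(EBImage::clahe(wp, nx = nx, ny = ny, limit = limit,
                               keep.range = TRUE))
  out[seq_len(nrow(w)), seq_len(ncol(w)), drop = FALSE]
}

#' @export
print.enhanced_roi <- function(x, ...) {
  cat(sprintf("<enhanced_roi> %dx%d px at %.4g um/px (noise %.4g)\n",
              nrow(x$pixels), ncol(x$pixels), um_per_px(x$scale),
              x$noise_level))
  invisible(x)
}

#' Threshold the dendrites in an enhanced ROI
#'
#' Global threshold at the Otsu level plus `k_noise` times the recorded
#' noise level: noisier images get a higher threshold so background
#' fluctuations stay out of the foreground.
#'
#' @param eroi An [enhance()] result.
#' @param config An [analysis_config()].
#' @return A logical matrix (rough dendrite + feature outline).
#' @export
threshold_dendrites <- function(eroi, config = analysis_config()) {
  stopifnot(inherits(eroi, "enhanced_roi"))
  thr <- eroi$otsu_level + config$k_noise * eroi$noise_level
  mask <- eroi$pixels > thr
  if (!any(mask)) stop("no dendrites found: empty foreground after thresholding")
  mask
}

#' Locate feature seeds by horizontal erosion
#'
#' Blebs and other morphological abnormalities are *wider* than the
#' dendrite they sit on. Eroding the thresholded mask with a horizontal
#' line element longer than the nominal dendrite width removes the thin
#' vertical dendrites; the pixel clusters that survive (after a minimum
#' area filter) mark feature locations.
#'
#' @param mask Logical matrix from [threshold_dendrites()].
#' @param scale The working [pixel_scale()] (resize factor included).
#' @param config An [analysis_config()].
#' @return A list with `labels` (labeled matrix of surviving seeds) and
#'   `props` (tibble of per-seed descriptors). Zero seeds is a valid
#'   outcome (a healthy dendrite).
#' @export
erode_seeds <- function(mask, scale, config = analysis_config()) {
  len <- odd_px(config$erode_len_um, scale)
  kern <- matrix(1, nrow = 1, ncol = len)
  er <- as_mat(EBImage::erode(mask * 1, kern)) > 0.5
  lab <- as_mat(EBImage::bwlabel(er))
  props <- region_props(lab, scale = scale, contours = FALSE)
  props <- props[props$area_um2 >= config$min_feature_area_um2, , drop = FALSE]
  lab[!(lab %in% props$label)] <- 0L
  list(labels = lab, props = props)
}

#' Refine feature shapes with Chan-Vese active contours
#'
#' Horizontal erosion leaves jagged, horizontally biased clusters. Each
#' seed is dilated to an initial contour and evolved for a fixed iteration
#' budget by Chan-Vese energy minimization (morphological ACWE) on a local
#' window around the seed. Converged regions that merge are fused into a
#' single feature. Shape descriptors are computed on the converged
#' regions; intensity is sampled from the *original* un-enhanced ROI
#' (bilinear), in native units, so intensities stay comparable across
#' images.
#'
#' @param eroi An [enhance()] result.
#' @param seeds The [erode_seeds()] result.
#' @param config An [analysis_config()].
#' @return A tibble of features, one row each: centroid (um, ROI
#'   coordinates, y measured from the top), area/perimeter (um), shape
#'   descriptors (circularity, extent, eccentricity, min/max caliper) and
#'   `mean_intensity` in native units, plus bookkeeping columns used for
#'   dendrite matching. `dendrite` is `NA` until [match_features()].
#' @export
refine_features <- function(eroi, seeds, config = analysis_config()) {
  stopifnot(inherits(eroi, "enhanced_roi"))
  if (!nrow(seeds$props)) return(empty_features())
  scale <- eroi$scale
  um <- um_per_px(scale)
  pad <- round(px_len(config$cv_pad_um, scale))
  dil <- EBImage::makeBrush(odd_px(2 * config$cv_init_dilate_um, scale),
                            shape = "disc")
  nr <- nrow(eroi$pixels); nc <- ncol(eroi$pixels)
  open_len <- odd_px(config$erode_len_um, scale)
  open_kern <- matrix(1, 1, open_len)
  regions <- list()
  for (k in seq_len(nrow(seeds$props))) {
    p <- seeds$props[k, ]
    r0 <- max(1L, p$bbox_top - pad)
    r1 <- min(nr, p$bbox_top + p$bbox_height - 1L + pad)
    c0 <- max(1L, p$bbox_left - pad)
    c1 <- min(nc, p$bbox_left + p$bbox_width - 1L + pad)
    win <- eroi$pixels[r0:r1, c0:c1, drop = FALSE]
    init <- seeds$labels[r0:r1, c0:c1, drop = FALSE] == p$label
    init <- as_mat(EBImage::dilate(init * 1, dil)) > 0.5
    reg <- chan_vese(win, init, iterations = config$cv_iterations)
    # the contour may have crept along the (thin) dendrite ridge; a
    # horizontal opening with the erosion element removes anything not
    # wider than a dendrite, consistent with the feature definition
    reg <- as_mat(EBImage::opening(reg * 1, open_kern)) > 0.5
    if (any(reg)) {
      lab <- as_mat(EBImage::bwlabel(reg))
      hit <- unique(lab[lab > 0 & (seeds$labels[r0:r1, c0:c1] == p$label)])
      if (!length(hit)) hit <- unique(lab[lab > 0 & init])
      reg <- matrix(lab %in% hit, nrow(lab), ncol(lab))
    }
    if (!any(reg)) {
      message("feature seed ", p$label, " collapsed during refinement; dropped")
      next
    }
    ij <- which(reg, arr.ind = TRUE)
    regions[[length(regions) + 1]] <-
      (ij[, 2] + c0 - 2L) * nr + (ij[, 1] + r0 - 1L)   # global linear idx
  }
  if (!length(regions)) return(empty_features())
  groups <- fuse_overlapping(regions)
  native <- eroi$roi$pixels
  f <- scale$resize_factor
  props <- dplyr::bind_rows(lapply(groups, function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    loc <- matrix(0L, diff(range(r)) + 1L, diff(range(c)) + 1L)
    loc[cbind(r - min(r) + 1L, c - min(c) + 1L)] <- 1L
    p <- region_props(loc, scale = scale)
    p$centroid_row <- p$centroid_row + min(r) - 1L
    p$centroid_col <- p$centroid_col + min(c) - 1L
    p$bbox_top <- p$bbox_top + min(r) - 1L
    p$bbox_left <- p$bbox_left + min(c) - 1L
    p
  }))
  props$mean_intensity <- vapply(groups, function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    mean(bilinear_sample(native, (r - 0.5) / f + 0.5, (c - 0.5) / f + 0.5))
  }, 0)
  tibble::tibble(
    feature = seq_len(nrow(props)),
    centroid_y_um = props$centroid_row * um,
    centroid_x_um = props$centroid_col * um,
    area_um2 = props$area_um2,
    perimeter_um = props$perimeter_um,
    circularity = pmin(pmax(props$circularity, 0), 1.05),
    extent = props$extent,
    eccentricity = props$eccentricity,
    min_caliper_um = props$min_caliper_um,
    max_caliper_um = props$max_caliper_um,
    mean_intensity = props$mean_intensity,
    dendrite = NA_integer_,
    .row_px = props$centroid_row,
    .col_px = props$centroid_col)
}

# group regions (lists of linear pixel indices) whose pairwise overlap
# exceeds 30% of the smaller region; lightly touching regions stay distinct
fuse_overlapping <- function(regions) {
  n <- length(regions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ov <- length(intersect(regions[[i]], regions[[j]]))
      if (ov > 0.3 * min(length(regions[[i]]), length(regions[[j]]))) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  lapply(split(seq_len(n), roots), function(ii)
    sort(unique(unlist(regions[ii]))))
}

empty_features <- function() {
  tibble::tibble(feature = integer(), centroid_y_um = double(),
                 centroid_x_um = double(), area_um2 = double(),
                 perimeter_um = double(), circularity = double(),
                 extent = double(), eccentricity = double(),
                 min_caliper_um = double(), max_caliper_um = double(),
                 mean_intensity = double(), dendrite = integer(),
                 .row_px = double(), .col_px = double())
}

# Morphological Chan-Vese (ACWE): alternate a data-driven boundary update
# (pixels on the contour flip toward the nearer of the inside/outside
# means, minimizing the two-phase Chan-Vese energy) with a curvature-like
# morphological smoothing (alternating opening/closing with a 3x3 cross).
chan_vese <- function(img, init, iterations = 60L, lambda1 = 1, lambda2 = 1) {
  u <- init
  cross <- EBImage::makeBrush(3, shape = "diamond")
  for (it in seq_len(iterations)) {
    inside <- img[u]
    outside <- img[!u]
    if (!length(inside) || !length(outside)) break
    c1 <- mean(inside); c2 <- mean(outside)
    du <- as_mat(EBImage::dilate(u * 1, cross)) -
      as_mat(EBImage::erode(u * 1, cross))
    force <- lambda1 * (img - c1)^2 - lambda2 * (img - c2)^2
    band <- du > 0.5
    u[band & force < 0] <- TRUE
    u[band & force > 0] <- FALSE
    if (it %% 2L == 1L) {
      u <- as_mat(EBImage::dilate(as_mat(EBImage::erode(u * 1, cross)),
                                  cross)) > 0.5
    } else {
      u <- as_mat(EBImage::erode(as_mat(EBImage::dilate(u * 1, cross)),
                                 cross)) > 0.5
    }
  }
  u
}

#' Detect bleb features on a dendrite ROI
#'
#' Convenience wrapper: [enhance()], [threshold_dendrites()],
#' [erode_seeds()], [refine_features()].
#'
#' @param roi A `dendrite_roi`.
#' @param config An [analysis_config()].
#' @return List with `features` (tibble) and `eroi` (the enhanced ROI,
#'   reused by tracking and break detection).
#' @export
detect_features <- function(roi, config = analysis_config()) {
  eroi <- enhance(roi, config)
  mask <- threshold_dendrites(eroi, config)
  seeds <- erode_seeds(mask, eroi$scale, config)
  feats <- refine_features(eroi, seeds, config)
  list(features = feats, eroi = eroi, mask = mask)
}
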