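#' Global contrast stretch
#'
#' Linearly rescales intensities between the low/high quantiles of the
#' image to the full bit range, clipping outside. This guarantees the
#' dendrites -- much dimmer than the cell bodies -- are bright enough for
#' the downstream detection thresholds regardless of exposure.
#'
#' @param img A `projection_image`.
#' @param config An [analysis_config()].
#' @return A `projection_image` with stretched intensities.
#' @export
stretch_contrast <- function(img, config = analysis_config()) {
  stopifnot(inherits(img, "projection_image"))
  q <- stats::quantile(img$pixels, config$stretch_quantiles, names = FALSE)
  if (q[2] <= q[1])
    stop("blank frame: degenerate intensity window in contrast stretch")
  maxv <- 2^img$bit_depth - 1
  px <- (img$pixels - q[1]) / (q[2] - q[1])
  px <- pmin(pmax(px, 0), 1) * maxv
  out <- img
  out$pixels <- px
  out
}

#' Locate the cell bodies
#'
#' The four CEP somas are (after contrast stretching) the brightest mass in
#' the frame. A brightest-pixel threshold followed by a minimum-area filter
#' isolates them; surviving clusters are grouped by single linkage, and
#' more than one group farther apart than `multiworm_link_um` means more
#' than one worm is in the frame -- an unsupported condition reported as an
#' error rather than silently mis-cropped.
#'
#' @param img A contrast-stretched `projection_image`.
#' @param config An [analysis_config()].
#' @return A `cell_body_cluster`: list with `mask`, `centroids` (n x 2
#'   matrix, row/col px), `bounding_box` (top, left, height, width) and
#'   `axis_angle` (degrees from the row axis, in (-90, 90]).
#' @export
segment_cell_bodies <- function(img, config = analysis_config()) {
  stopifnot(inherits(img, "projection_image"))
  # brightest-pixel threshold, intensity-relative: the contrast stretch
  # anchors the 99.9th percentile at full range, so a fixed fraction of
  # full range isolates the brightest mass (the somas) independently of
  # how much empty background or dendrite is in the frame
  maxv <- 2^img$bit_depth - 1
  mask <- img$pixels >= config$soma_level_frac * maxv
  lab <- as_mat(EBImage::bwlabel(mask))
  props <- region_props(lab, scale = img$scale, contours = FALSE)
  props <- props[props$area_um2 >= config$soma_min_area_um2 &
                   props$minor_um >= config$soma_min_width_um, , drop = FALSE]
  if (!nrow(props)) stop("no cell body found")
  groups <- single_linkage_groups(
    cbind(props$centroid_row, props$centroid_col),
    px_len(config$multiworm_link_um, img$scale))
  if (max(groups) > 1)
    stop("multiple worms in frame: found ", max(groups),
         " separated bright clusters; only one worm per image is supported")
  keep <- props$label
  mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  # axis fit on the largest components only (somas dominate by area; a
  # stray bright bleb fragment must not steer the rotation)
  big <- props[order(-props$area_um2), , drop = FALSE]
  big <- big[seq_len(min(6L, nrow(big))), , drop = FALSE]
  cen <- cbind(big$centroid_row, big$centroid_col)
  idx <- which(mask, arr.ind = TRUE)
  bb <- c(top = min(idx[, 1]), left = min(idx[, 2]),
          height = diff(range(idx[, 1])) + 1L,
          width = diff(range(idx[, 2])) + 1L)
  structure(list(mask = mask,
                 centroids = cbind(props$centroid_row, props$centroid_col),
                 bounding_box = bb,
                 axis_angle = cluster_axis_angle(cen, idx)),
            class = "cell_body_cluster")
}

single_linkage_groups <- function(pts, cut_px) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  d <- stats::dist(pts)
  stats::cutree(stats::hclust(d, method = "single"), h = cut_px)
}

# angle (deg, from the row axis, (-90,90]) of the line through soma
# centroids; falls back to the pixel-cloud principal axis when <2 centroids
cluster_axis_angle <- function(cen, idx) {
  pts <- if (nrow(cen) >= 2) cen else idx
  v <- stats::prcomp(pts)$rotation[, 1]
  th <- atan2(v[2], v[1]) * 180 / pi
  th <- ((th + 90) %% 180) - 90
  if (th == -90) th <- 90
  th
}

#' Rotate the image so the dendrites run vertically
#'
#' The line fitted through the soma centroids is brought horizontal (the
#' dendrites emerge perpendicular to the row of cell bodies), i.e. the
#' dendrites end up aligned with the vertical (row) axis. The angle is
#' reported modulo 180 degrees; the up/down ambiguity is resolved later by
#' side selection, not here.
#'
#' @param img A `projection_image`.
#' @param cluster The [segment_cell_bodies()] result.
#' @param config An [analysis_config()].
#' @return List with `image` (rotated), `cluster` (re-segmented on the
#'   rotated frame) and `angle` (degrees applied, in (-90, 90]).
#' @export
orient_image <- function(img, cluster, config = analysis_config()) {
  stopifnot(inherits(img, "projection_image"),
            inherits(cluster, "cell_body_cluster"))
  phi <- cluster$axis_angle
  delta <- ((90 - phi + 90) %% 180) - 90
  out <- rotate_projection(img, delta)
  cl2 <- segment_cell_bodies(out, config)
  list(image = out, cluster = cl2, angle = delta)
}

rotate_projection <- function(img, angle_deg) {
  if (abs(angle_deg) < 1e-9) return(img)
  maxv <- 2^img$bit_depth - 1
  r <- as_mat(EBImage::rotate(img$pixels / maxv, angle_deg, bg.col = 0))
  out <- img
  out$pixels <- pmin(pmax(r, 0), 1) * maxv
  out
}

#' Split at the cell bodies and select the dendrite half
#'
#' The oriented frame is split horizontally at the soma bounding box. Each
#' half is binarized with a permissive (Otsu) threshold and its connected
#' components described by orientation, major-axis length, circularity and
#' area. The half with more elongated, near-vertical, non-circular
#' components -- the dendrites -- wins; ties break on summed major-axis
#' length. The winner is flipped if needed so the proximal (cell-body)
#' edge is the bottom edge.
#'
#' @param img Oriented `projection_image` (contrast-stretched).
#' @param cluster Its `cell_body_cluster`.
#' @param config An [analysis_config()].
#' @param native Optional second `projection_image` (same geometry, native
#'   intensities) cropped identically; used by the pipeline so metric
#'   intensities stay in native units.
#' @return A `dendrite_roi` (see [finalize_crop()] for the final object);
#'   here an intermediate with fields `pixels`, `native`, `scale`,
#'   `bit_depth`, `proximal_edge = "bottom"` and `transform`.
#' @export
split_and_select <- function(img, cluster, config = analysis_config(),
                             native = NULL) {
  stopifnot(inherits(img, "projection_image"))
  bb <- cluster$bounding_box
  nr <- nrow(img$pixels)
  top_rows <- seq_len(max(bb["top"] - 1L, 0L))
  bot_rows <- if (bb["top"] + bb["height"] <= nr)
    (bb["top"] + bb["height"]):nr else integer()
  halves <- list(top = top_rows, bottom = bot_rows)
  scores <- lapply(halves, function(rows) {
    if (length(rows) < 32) return(list(n = -1, len = 0, has_long = FALSE))
    side_score(img$pixels[rows, , drop = FALSE], img, config)
  })
  any_evidence <- vapply(scores, function(s) s$has_long, TRUE)
  if (!any(any_evidence))
    stop("no dendrites found on either side of the cell bodies")
  pick <- if (scores$top$n != scores$bottom$n) {
    if (scores$top$n > scores$bottom$n) "top" else "bottom"
  } else if (scores$top$len >= scores$bottom$len) "top" else "bottom"
  rows <- halves[[pick]]
  flip <- pick == "bottom"   # proximal (soma) edge must end up at the bottom
  sel <- img$pixels[rows, , drop = FALSE]
  nat <- if (is.null(native)) sel else native$pixels[rows, , drop = FALSE]
  if (flip) {
    sel <- sel[rev(seq_len(nrow(sel))), , drop = FALSE]
    nat <- nat[rev(seq_len(nrow(nat))), , drop = FALSE]
  }
  structure(list(pixels = sel, native = nat,
                 bit_depth = img$bit_depth, scale = img$scale,
                 proximal_edge = "bottom",
                 transform = list(rows = range(rows), flipped = flip,
                                  crop = NULL, angle = NULL)),
            class = "dendrite_roi")
}

side_score <- function(half, img, config) {
  rng <- range(half)
  if (diff(rng) <= 0) return(list(n = 0, len = 0, has_long = FALSE))
  norm <- (half - rng[1]) / diff(rng)
  mask <- norm > EBImage::otsu(norm)
  lab <- as_mat(EBImage::bwlabel(mask))
  props <- region_props(lab, scale = img$scale)
  props <- props[props$area_um2 >= 0.5, , drop = FALSE]
  if (!nrow(props)) return(list(n = 0, len = 0, has_long = FALSE))
  ok <- props$major_um >= config$side_major_axis_um &
    abs(props$orientation_deg) <= config$side_orient_tol_deg &
    props$circularity <= config$side_circ_max
  ok[is.na(ok)] <- FALSE
  list(n = sum(ok), len = sum(props$major_um[ok]),
       has_long = any(props$major_um >= config$side_major_axis_um))
}

#' Clean and tighten the dendrite crop
#'
#' Removes components touching the lateral borders (edge artifacts) and
#' any residual soma-like fragment (simultaneously high circularity and
#' large area), then crops to the tight bounding box of what remains plus
#' a physical margin.
#'
#' @param roi The [split_and_select()] output.
#' @param config An [analysis_config()].
#' @return A `dendrite_roi` whose `pixels` are the final cropped grid
#'   (native intensity units), with `transform` recording the crop.
#' @export
finalize_crop <- function(roi, config = analysis_config()) {
  stopifnot(inherits(roi, "dendrite_roi"))
  rng <- range(roi$pixels)
  if (diff(rng) <= 0) stop("no dendrites found: empty selection")
  norm <- (roi$pixels - rng[1]) / diff(rng)
  mask <- norm > EBImage::otsu(norm)
  lab <- as_mat(EBImage::bwlabel(mask))
  props <- region_props(lab, scale = roi$scale)
  drop <- props$touches_left | props$touches_right |
    (!is.na(props$circularity) &
       props$circularity > config$soma_circ_cutoff &
       props$area_um2 > config$soma_area_cutoff_um2)
  keep <- props[!drop, , drop = FALSE]
  keep <- keep[keep$major_um >= config$side_major_axis_um |
                 keep$area_um2 >= config$min_feature_area_um2, , drop = FALSE]
  if (!nrow(keep) || !any(keep$major_um >= config$side_major_axis_um))
    stop("no dendrites found after border cleanup")
  sel <- matrix(lab %in% keep$label, nrow(lab), ncol(lab))
  idx <- which(sel, arr.ind = TRUE)
  mg <- round(px_len(config$crop_margin_um, roi$scale))
  r0 <- max(1L, min(idx[, 1]) - mg); r1 <- min(nrow(sel), max(idx[, 1]) + mg)
  c0 <- max(1L, min(idx[, 2]) - mg); c1 <- min(ncol(sel), max(idx[, 2]) + mg)
  if (r1 - r0 + 1 < 32) stop("cropped ROI too small (<32 rows)")
  out <- roi
  out$pixels <- roi$native[r0:r1, c0:c1, drop = FALSE]
  out$native <- NULL
  out$transform$crop <- c(top = r0, left = c0,
                          height = r1 - r0 + 1L, width = c1 - c0 + 1L)
  out
}

#' Crop a projection image down to the dendrite-only region
#'
#' Full cropping stage: global contrast stretch, cell-body segmentation,
#' rotation to the canonical orientation (dendrites vertical), split at
#' the soma bounding box, dendrite-side selection, border cleanup and
#' tight crop. The returned ROI holds *native* intensity units so that
#' downstream intensity metrics are comparable across images, and its
#' proximal (cell-body) edge is always the bottom edge.
#'
#' @param img A `projection_image` (as from [load_image()]).
#' @param config An [analysis_config()].
#' @return A `dendrite_roi`: `pixels` (native units), `bit_depth`,
#'   `scale`, `proximal_edge = "bottom"`, `transform` (rotation angle and
#'   crop offsets back to source coordinates).
#' @export
crop_dendrites <- function(img, config = analysis_config()) {
  s <- stretch_contrast(img, config)
  cl <- segment_cell_bodies(s, config)
  o <- orient_image(s, cl, config)
  native_rot <- rotate_projection(img, o$angle)
  roi <- split_and_select(o$image, o$cluster, config, native = native_rot)
  roi <- finalize_crop(roi, config)
  roi$transform$angle <- o$angle
  roi
}

#' @export
print.dendrite_roi <- function(x, ...) {
  cat(sprintf("<dendrite_roi> %dx%d px, %d-bit, %.4g um/px, proximal edge: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$scale$microns_per_pixel, x$proximal_edge))
  invisible(x)
}
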