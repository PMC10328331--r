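# Connected-component shape descriptors.
#
# Works on a labeled matrix (EBImage::bwlabel output). Perimeter is the
# length of the 0.5-level contour polygon (sub-pixel, unbiased on discrete
# discs, unlike boundary-pixel counts); min/max caliper (Feret) diameters
# come from rotating calipers on the convex hull of that contour.

region_props <- function(labels, scale = NULL, intensity = NULL,
                         contours = TRUE) {
  labels <- as_mat(labels)
  n <- max(labels)
  um <- if (is.null(scale)) 1 else um_per_px(scale)
  if (n == 0) return(empty_props())
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  by_lab <- split(seq_along(lab), lab)
  out <- lapply(names(by_lab), function(lb) {
    i <- by_lab[[lb]]
    r <- rows[i]; c <- cols[i]
    a_px <- length(i)
    rmin <- min(r); rmax <- max(r); cmin <- min(c); cmax <- max(c)
    h <- rmax - rmin + 1L; w <- cmax - cmin + 1L
    cen_r <- mean(r); cen_c <- mean(c)
    # second central moments with the 1/12 single-pixel term
    vr <- if (a_px > 1) stats::var(r) * (a_px - 1) / a_px + 1 / 12 else 1 / 12
    vc <- if (a_px > 1) stats::var(c) * (a_px - 1) / a_px + 1 / 12 else 1 / 12
    vrc <- if (a_px > 1) stats::cov(r, c) * (a_px - 1) / a_px else 0
    tr2 <- (vr + vc) / 2
    det_half <- sqrt(((vr - vc) / 2)^2 + vrc^2)
    l1 <- tr2 + det_half; l2 <- max(tr2 - det_half, 1e-12)
    major_px <- 4 * sqrt(l1); minor_px <- 4 * sqrt(l2)
    ecc <- sqrt(max(0, 1 - l2 / l1))
    # orientation of major axis measured from the row (vertical) axis,
    # mapped to (-90, 90]
    v <- eigen(matrix(c(vr, vrc, vrc, vc), 2), symmetric = TRUE)$vectors[, 1]
    th <- atan2(v[2], v[1]) * 180 / pi
    th <- ((th + 90) %% 180) - 90
    if (th == -90) th <- 90
    perim_px <- NA_real_; min_cal <- NA_real_; max_cal <- NA_real_
    if (contours) {
      poly <- component_contour(r, c, rmin, cmin, h, w)
      perim_px <- poly$perimeter
      cal <- hull_calipers(poly$pts)
      min_cal <- cal[1]; max_cal <- cal[2]
    }
    circ <- if (is.na(perim_px) || perim_px <= 0) NA_real_ else
      min(4 * pi * a_px / perim_px^2, 1.05)
    mint <- if (is.null(intensity)) NA_real_ else
      mean(intensity[cbind(r, c)])
    tibble::tibble(
      label = as.integer(lb), area_px = a_px, area_um2 = a_px * um^2,
      centroid_row = cen_r, centroid_col = cen_c,
      bbox_top = rmin, bbox_left = cmin, bbox_height = h, bbox_width = w,
      perimeter_um = perim_px * um, circularity = circ,
      extent = a_px / (h * w), eccentricity = ecc,
      major_um = major_px * um, minor_um = minor_px * um,
      orientation_deg = th,
      min_caliper_um = min_cal * um, max_caliper_um = max_cal * um,
      mean_intensity = mint,
      touches_left = cmin == 1L, touches_right = cmax == ncol(labels),
      touches_top = rmin == 1L, touches_bottom = rmax == nrow(labels))
  })
  dplyr::bind_rows(out)
}

empty_props <- function() {
  tibble::tibble(label = integer(), area_px = integer(), area_um2 = double(),
                 centroid_row = double(), centroid_col = double(),
                 bbox_top = integer(), bbox_left = integer(),
                 bbox_height = integer(), bbox_width = integer(),
                 perimeter_um = double(), circularity = double(),
                 extent = double(), eccentricity = double(),
                 major_um = double(), minor_um = double(),
                 orientation_deg = double(),
                 min_caliper_um = double(), max_caliper_um = double(),
                 mean_intensity = double(),
                 touches_left = logical(), touches_right = logical(),
                 touches_top = logical(), touches_bottom = logical())
}

# 0.5-level contour of one component; returns polygon points (row, col)
# and total perimeter (sum over all contour rings, so holes count)
component_contour <- function(r, c, rmin, cmin, h, w) {
  m <- matrix(0, h + 2L, w + 2L)
  m[cbind(r - rmin + 2L, c - cmin + 2L)] <- 1
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (!length(cl)) { # single pixel fallback
    return(list(pts = cbind(r - rmin + 1, c - cmin + 1), perimeter = 4))
  }
  per <- 0
  pts <- NULL
  for (ring in cl) {
    x <- ring$x; y <- ring$y
    if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
      x <- c(x, x[1]); y <- c(y, y[1])
    }
    per <- per + sum(sqrt(diff(x)^2 + diff(y)^2))
    pts <- rbind(pts, cbind(x, y))
  }
  list(pts = pts, perimeter = per)
}

# rotating calipers on the convex hull: c(min_feret, max_feret) in px
hull_calipers <- function(pts) {
  pts <- unique(round(pts, 6))
  if (nrow(pts) == 1) return(c(1, 1))
  if (nrow(pts) == 2) {
    d <- sqrt(sum((pts[1, ] - pts[2, ])^2))
    return(c(0, d))
  }
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh == 2) {
    d <- sqrt(sum((hp[1, ] - hp[2, ])^2))
    return(c(0, d))
  }
  dmax <- 0
  for (i in seq_len(nh - 1)) {
    d2 <- (hp[(i + 1):nh, 1] - hp[i, 1])^2 + (hp[(i + 1):nh, 2] - hp[i, 2])^2
    dmax <- max(dmax, max(d2))
  }
  wmin <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    nrm <- c(-e[2], e[1]) / len
    proj <- hp %*% nrm
    wmin <- min(wmin, max(proj) - min(proj))
  }
  c(wmin, sqrt(dmax))
}
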