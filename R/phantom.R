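#' Specify a synthetic worm-head phantom
#'
#' Describes a synthetic maximum-projection image of the *C. elegans* head:
#' a row of four bright cell bodies (somas) with four roughly parallel,
#' slightly curved dendrites emerging from them, optional bleb features
#' (bright Gaussian blobs on the dendrite), optional breaks (zeroed spans),
#' sensor noise, a background illumination gradient, and an arbitrary
#' in-plane rotation. Rendering a spec with [render_phantom()] also emits
#' exact ground truth, so every pipeline stage can be validated without
#' real microscope data.
#'
#' In the canonical (unrotated) frame the somas sit at the bottom of the
#' image and the dendrites run upward, matching the pipeline's canonical
#' orientation (proximal edge at the bottom).
#'
#' @param pixel_size um/px of the simulated camera (e.g. 0.1 for a 63x
#'   setup, 0.2 for a 40x setup).
#' @param bit_depth 8 or 16.
#' @param image_size Integer `(rows, cols)` of the frame.
#' @param n_dendrites Number of rendered dendrites, 0..4.
#' @param dendrite_length Vertical extent of each dendrite (um).
#' @param dendrite_width Dendrite FWHM (um); CEP dendrites are ~0.5--1 um.
#' @param dendrite_spacing Horizontal spacing between dendrites (um).
#' @param curvature_amplitude Amplitude (um) of the gentle sinusoidal bow
#'   shared by all dendrites.
#' @param rotation In-plane rotation (degrees) applied to the whole scene
#'   geometry, positive tilting the dendrites toward increasing column.
#' @param soma_diameter Soma disc diameter (um); 0 renders no cell bodies.
#' @param dendrite_peak,soma_peak Peak intensities as fractions of the
#'   dynamic range.
#' @param blebs Data frame (or NULL) with columns `dendrite`,
#'   `position` (normalized 0 proximal .. 1 distal along the arc),
#'   `diameter` (um, FWHM) and optionally `peak` (fraction of range;
#'   default 1.5x the dendrite peak -- blebs are conspicuously bright).
#' @param breaks Data frame (or NULL) with columns `dendrite`,
#'   `start` (normalized arc position) and `length` (um): the dendrite
#'   signal is zeroed over that span.
#' @param noise_sigma Gaussian read-noise SD as a fraction of the dynamic
#'   range; 0 renders a noiseless image (shot noise is disabled too).
#' @param shot_photons Photon budget at full scale for Poisson shot noise
#'   (applied only when `noise_sigma > 0`).
#' @param background_gradient Linear illumination ramp across the frame
#'   (fraction of range from top row to bottom row).
#' @param seed Integer; the same spec and seed render bit-identical images.
#' @return A `phantom_spec`.
#' @seealso [render_phantom()], [phantom_suite()]
#' @export
phantom_spec <- function(pixel_size = 0.1,
                         bit_depth = 16L,
                         image_size = NULL,
                         n_dendrites = 4L,
                         dendrite_length = 40,
                         dendrite_width = 0.7,
                         dendrite_spacing = 4,
                         curvature_amplitude = 1,
                         rotation = 0,
                         soma_diameter = 3,
                         dendrite_peak = 0.45,
                         soma_peak = 0.95,
                         blebs = NULL,
                         breaks = NULL,
                         noise_sigma = 0.02,
                         shot_photons = 800,
                         background_gradient = 0,
                         seed = 1L) {
  if (is.null(image_size)) {
    # big enough to hold the scene at any rotation up to ~35 degrees
    span_um <- dendrite_length + soma_diameter + 18
    wide_um <- (max(n_dendrites, 1) - 1) * dendrite_spacing +
      2 * curvature_amplitude + 14
    if (abs(rotation) > 1e-6) {
      a <- abs(rotation) * pi / 180
      wide_um <- span_um * sin(a) + wide_um * cos(a) + 6
      span_um <- span_um * cos(a) + wide_um * sin(a) / 2
    }
    image_size <- c(ceiling(span_um / pixel_size), ceiling(wide_um / pixel_size))
  }
  blebs <- normalize_bleb_table(blebs, default_peak = min(1, 1.5 * dendrite_peak))
  breaks <- normalize_break_table(breaks)
  stopifnot(bit_depth %in% c(8L, 16L), n_dendrites >= 0, n_dendrites <= 4,
            dendrite_length > 0, dendrite_width > 0,
            noise_sigma >= 0, all(image_size >= 64))
  if (nrow(blebs) && any(!(blebs$dendrite %in% seq_len(n_dendrites))))
    stop("bleb references a dendrite that is not rendered")
  if (nrow(breaks) && any(!(breaks$dendrite %in% seq_len(n_dendrites))))
    stop("break references a dendrite that is not rendered")
  if (nrow(breaks) && any(breaks$start < 0 | breaks$start > 1))
    stop("break start positions must be in [0, 1]")
  structure(list(pixel_size = pixel_size, bit_depth = as.integer(bit_depth),
                 image_size = as.integer(image_size),
                 n_dendrites = as.integer(n_dendrites),
                 dendrite_length = dendrite_length,
                 dendrite_width = dendrite_width,
                 dendrite_spacing = dendrite_spacing,
                 curvature_amplitude = curvature_amplitude,
                 rotation = rotation, soma_diameter = soma_diameter,
                 dendrite_peak = dendrite_peak, soma_peak = soma_peak,
                 blebs = blebs, breaks = breaks,
                 noise_sigma = noise_sigma, shot_photons = shot_photons,
                 background_gradient = background_gradient,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

normalize_bleb_table <- function(blebs, default_peak) {
  if (is.null(blebs) || !NROW(blebs))
    return(tibble::tibble(dendrite = integer(), position = double(),
                          diameter = double(), peak = double()))
  blebs <- tibble::as_tibble(blebs)
  stopifnot(all(c("dendrite", "position", "diameter") %in% names(blebs)))
  if (!"peak" %in% names(blebs)) blebs$peak <- default_peak
  blebs$dendrite <- as.integer(blebs$dendrite)
  blebs
}

normalize_break_table <- function(breaks) {
  if (is.null(breaks) || !NROW(breaks))
    return(tibble::tibble(dendrite = integer(), start = double(),
                          length = double()))
  breaks <- tibble::as_tibble(breaks)
  stopifnot(all(c("dendrite", "start", "length") %in% names(breaks)))
  breaks$dendrite <- as.integer(breaks$dendrite)
  breaks
}

#' Render a phantom and its ground truth
#'
#' Dendrites are drawn as Gaussian-profile ridges along smoothly curved
#' centerlines; blebs as brighter isotropic Gaussian blobs centred on the
#' centerline; breaks as zeroed spans; somas as soft-edged bright discs.
#' Rotation is applied to the scene *geometry* before rasterization, so no
#' interpolation artifacts enter and the emitted truth is exact in final
#' image coordinates. Shot (Poisson) and read (Gaussian) noise plus a
#' linear background ramp are added last, then the image is quantized to
#' the requested bit depth.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (a `projection_image`) and `truth` (a
#'   `phantom_truth`: per-dendrite centerlines in final px coordinates,
#'   arc lengths, true percent remaining, bleb records and the expected
#'   categorical score per dendrite).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  px <- spec$pixel_size
  img <- matrix(0, nr, nc)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- spec$rotation * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) # acts on (row,col)
  rotate_pts <- function(p) { # p: n x 2 (row, col)
    sweep(sweep(p, 2, ctr) %*% t(rot), 2, ctr, `+`)
  }

  sigma_px <- spec$dendrite_width / 2.355 / px
  len_px <- spec$dendrite_length / px
  soma_r_px <- spec$soma_diameter / 2 / px
  bottom_margin_px <- 8 / px
  soma_row <- nr - bottom_margin_px - soma_r_px
  base_row <- soma_row - soma_r_px - 0.5 / px  # dendrite proximal end
  xs <- ctr[2] + (seq_len(max(spec$n_dendrites, 1)) -
                    (max(spec$n_dendrites, 1) + 1) / 2) *
    spec$dendrite_spacing / px
  amp_px <- spec$curvature_amplitude / px

  centerlines <- list(); lengths_um <- numeric(0)
  truth_rows <- list()
  for (i in seq_len(spec$n_dendrites)) {
    t <- seq(0, 1, length.out = 2048)
    rowc <- base_row - t * len_px
    colc <- xs[i] + amp_px * sin(pi * t)
    pts <- rotate_pts(cbind(rowc, colc))
    seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    s <- c(0, cumsum(seg)) * px              # arc length from proximal, um
    L <- s[length(s)]
    brks_i <- spec$breaks[spec$breaks$dendrite == i, , drop = FALSE]
    broken <- rep(FALSE, length(t))
    for (b in seq_len(nrow(brks_i))) {
      s0 <- brks_i$start[b] * L
      s1 <- s0 + brks_i$length[b]
      if (s1 > L + 1e-6) stop("break extends past the dendrite tip")
      broken <- broken | (s >= s0 & s <= s1)
    }
    draw_ridge(img, pts, broken, sigma_px, spec$dendrite_peak) -> img
    if (any(pts[, 1] < 1 | pts[, 1] > nr | pts[, 2] < 1 | pts[, 2] > nc))
      stop("dendrite leaves the frame after rotation; enlarge image_size")
    centerlines[[i]] <- tibble::tibble(row = pts[, 1], col = pts[, 2],
                                       arc_um = s, broken = broken)
    lengths_um[i] <- L
    blb_i <- spec$blebs[spec$blebs$dendrite == i, , drop = FALSE]
    for (b in seq_len(nrow(blb_i))) {
      sb <- blb_i$position[b] * L
      k <- which.min(abs(s - sb))
      cen <- pts[k, ]
      if (cen[1] < 1 || cen[1] > nr || cen[2] < 1 || cen[2] > nc)
        stop("bleb outside the frame after rotation")
      img <- draw_blob(img, cen, blb_i$diameter[b] / 2.355 / px, blb_i$peak[b])
      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        dendrite = i, position = blb_i$position[b],
        diameter = blb_i$diameter[b], row = cen[1], col = cen[2])
    }
  }

  if (spec$soma_diameter > 0 && spec$n_dendrites > 0) {
    scen <- rotate_pts(cbind(rep(soma_row, spec$n_dendrites),
                             xs[seq_len(spec$n_dendrites)]))
    for (i in seq_len(nrow(scen)))
      img <- draw_disc(img, scen[i, ], soma_r_px, spec$soma_peak)
  } else scen <- NULL

  if (spec$background_gradient != 0) {
    img <- img + spec$background_gradient *
      matrix((seq_len(nr) - 1) / (nr - 1), nr, nc)
  }
  img <- pmin(img, 1)
  if (spec$noise_sigma > 0) {
    if (spec$shot_photons > 0) {
      img <- matrix(stats::rpois(length(img), img * spec$shot_photons) /
                      spec$shot_photons, nr, nc)
    }
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma), nr, nc)
    img <- pmin(pmax(img, 0), 1)
  }
  maxv <- 2^spec$bit_depth - 1
  pix <- round(img * maxv)

  per_dend <- tibble::tibble(
    dendrite = seq_len(spec$n_dendrites),
    length_um = lengths_um,
    break_um = vapply(seq_len(spec$n_dendrites), function(i)
      sum(spec$breaks$length[spec$breaks$dendrite == i]), 0),
    n_blebs = vapply(seq_len(spec$n_dendrites), function(i)
      sum(spec$blebs$dendrite == i), 0L))
  per_dend$percent_remaining <-
    100 * (per_dend$length_um - per_dend$break_um) / per_dend$length_um
  per_dend$score <- score_degeneration(per_dend$percent_remaining,
                                       per_dend$n_blebs)

  truth <- structure(list(
    centerlines = centerlines,
    soma_centers = scen,
    dendrites = per_dend,
    blebs = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
      tibble::tibble(dendrite = integer(), position = double(),
                     diameter = double(), row = double(), col = double()),
    rotation = spec$rotation,
    spec = spec), class = "phantom_truth")

  image <- new_projection_image(pix, bit_depth = spec$bit_depth,
                                scale = pixel_scale(spec$pixel_size),
                                source_path = sprintf("<phantom seed=%d>", spec$seed))
  list(image = image, truth = truth)
}

# add a Gaussian-profile ridge along pts (n x 2, ordered), skipping broken
# samples; per-row drawing with tilt-corrected horizontal sigma
draw_ridge <- function(img, pts, broken, sigma_px, peak) {
  nr <- nrow(img); nc <- ncol(img)
  ord <- order(pts[, 1])
  pr <- pts[ord, 1]; pc <- pts[ord, 2]; bk <- broken[ord]
  # tangent row-components for horizontal width correction
  tr <- c(diff(pr), pr[length(pr)] - pr[length(pr) - 1])
  tc <- c(diff(pc), pc[length(pc)] - pc[length(pc) - 1])
  tn <- sqrt(tr^2 + tc^2); tr <- tr / pmax(tn, 1e-9)
  r0 <- max(1L, ceiling(min(pr))); r1 <- min(nr, floor(max(pr)))
  if (r1 < r0) return(img)
  rows <- r0:r1
  xc <- stats::approx(pr, pc, xout = rows, ties = "ordered")$y
  trow <- abs(stats::approx(pr, tr, xout = rows, ties = "ordered")$y)
  bfun <- stats::approx(pr, as.numeric(bk), xout = rows, ties = "ordered")$y
  sig_h <- sigma_px / pmax(trow, 0.3)
  for (k in seq_along(rows)) {
    if (bfun[k] > 0) next
    w <- ceiling(4 * sig_h[k])
    c0 <- max(1L, floor(xc[k] - w)); c1 <- min(nc, ceiling(xc[k] + w))
    if (c1 < c0) next
    cs <- c0:c1
    prof <- peak * exp(-((cs - xc[k])^2) / (2 * sig_h[k]^2))
    img[rows[k], cs] <- pmax(img[rows[k], cs], prof)
  }
  img
}

# add an isotropic Gaussian blob
draw_blob <- function(img, cen, sigma_px, peak) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(4 * sigma_px)
  r0 <- max(1L, floor(cen[1] - w)); r1 <- min(nr, ceiling(cen[1] + w))
  c0 <- max(1L, floor(cen[2] - w)); c1 <- min(nc, ceiling(cen[2] + w))
  rs <- r0:r1; cs <- c0:c1
  g <- outer(exp(-((rs - cen[1])^2) / (2 * sigma_px^2)),
             exp(-((cs - cen[2])^2) / (2 * sigma_px^2)))
  img[rs, cs] <- pmax(img[rs, cs], peak * g)
  img
}

# soft-edged disc (logistic edge, ~1 px roll-off)
draw_disc <- function(img, cen, radius_px, peak) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(radius_px + 4)
  r0 <- max(1L, floor(cen[1] - w)); r1 <- min(nr, ceiling(cen[1] + w))
  c0 <- max(1L, floor(cen[2] - w)); c1 <- min(nc, ceiling(cen[2] + w))
  rs <- r0:r1; cs <- c0:c1
  d <- sqrt(outer((rs - cen[1])^2, (cs - cen[2])^2, `+`))
  img[rs, cs] <- pmax(img[rs, cs], peak / (1 + exp((d - radius_px) / 0.7)))
  img
}

#' Catalogue of validation phantoms
#'
#' A fixed set of phantom specs with truth covering the conditions the
#' pipeline must handle: a healthy head, each categorical score bin 0--4,
#' rotated scenes, both bit depths, and the two simulated camera setups
#' (0.1 and 0.2 um/px, emulating 63x and 40x objectives). Negative
#' fixtures (a two-worm frame, a somaless frame) are available from
#' [phantom_negative()] since they are specified as compositions rather
#' than single specs.
#'
#' @param noise_sigma Read-noise level shared by the suite fixtures.
#' @return A named list of `phantom_spec` objects.
#' @export
phantom_suite <- function(noise_sigma = 0.02) {
  blebs3 <- tibble::tibble(dendrite = 2, position = c(0.25, 0.5, 0.75),
                           diameter = 2.5)
  blebs6 <- tibble::tibble(dendrite = rep(c(2, 3), each = 3),
                           position = rep(c(0.2, 0.45, 0.7), 2),
                           diameter = 2.5)
  list(
    healthy = phantom_spec(noise_sigma = noise_sigma, seed = 101L),
    score0 = phantom_spec(noise_sigma = noise_sigma, seed = 102L),
    score1 = phantom_spec(blebs = blebs3, noise_sigma = noise_sigma,
                          seed = 103L),
    score2 = phantom_spec(blebs = tibble::tibble(
      dendrite = 2, position = seq(0.15, 0.85, length.out = 6),
      diameter = 2.5), noise_sigma = noise_sigma, seed = 104L),
    score3 = phantom_spec(breaks = tibble::tibble(
      dendrite = 3, start = 0.4, length = 10),
      noise_sigma = noise_sigma, seed = 105L),
    score4 = phantom_spec(breaks = tibble::tibble(
      dendrite = c(2, 2, 2), start = c(0.15, 0.45, 0.75),
      length = c(8, 8, 8)), noise_sigma = noise_sigma, seed = 106L),
    rotated_plus = phantom_spec(rotation = 30, blebs = blebs3,
                                noise_sigma = noise_sigma, seed = 107L),
    rotated_minus = phantom_spec(rotation = -30, noise_sigma = noise_sigma,
                                 seed = 108L),
    eightbit = phantom_spec(bit_depth = 8L, blebs = blebs3,
                            noise_sigma = noise_sigma, seed = 109L),
    lowmag = phantom_spec(pixel_size = 0.2, blebs = blebs3,
                          noise_sigma = noise_sigma, seed = 110L),
    lowmag_break = phantom_spec(pixel_size = 0.2, breaks = tibble::tibble(
      dendrite = 2, start = 0.5, length = 8),
      noise_sigma = noise_sigma, seed = 111L),
    mixed = phantom_spec(blebs = blebs6, breaks = tibble::tibble(
      dendrite = 1, start = 0.6, length = 8),
      noise_sigma = noise_sigma, seed = 112L)
  )
}

#' Negative fixtures: frames the pipeline must refuse
#'
#' @param which `"multiworm"` (two worm heads ~100 um apart in one frame)
#'   or `"nosoma"` (dendrites only, no cell bodies).
#' @param noise_sigma Read-noise level.
#' @param seed Integer seed.
#' @return A `projection_image`.
#' @export
phantom_negative <- function(which = c("multiworm", "nosoma"),
                             noise_sigma = 0.02, seed = 201L) {
  which <- match.arg(which)
  if (which == "nosoma") {
    sp <- phantom_spec(soma_diameter = 0, noise_sigma = noise_sigma,
                       seed = seed)
    return(render_phantom(sp)$image)
  }
  sp <- phantom_spec(noise_sigma = 0, seed = seed)
  a <- render_phantom(sp)$image
  nr <- nrow(a$pixels); nc <- ncol(a$pixels)
  off <- round(100 / sp$pixel_size)   # 100 um apart
  canvas <- matrix(0, nr, nc + off)
  canvas[, seq_len(nc)] <- a$pixels
  canvas[, off + seq_len(nc)] <- pmax(canvas[, off + seq_len(nc)], a$pixels)
  maxv <- 2^sp$bit_depth - 1
  if (noise_sigma > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    canvas <- canvas / maxv +
      matrix(stats::rnorm(length(canvas), 0, noise_sigma), nrow(canvas))
    canvas <- round(pmin(pmax(canvas, 0), 1) * maxv)
  }
  new_projection_image(canvas, bit_depth = sp$bit_depth,
                       scale = pixel_scale(sp$pixel_size),
                       source_path = "<phantom multiworm>")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d dendrite(s), %d bleb(s), rotation %g deg\n",
              nrow(x$dendrites), nrow(x$blebs), x$rotation))
  print(x$dendrites)
  invisible(x)
}

#' Tidy phantom truth: the per-dendrite truth table
#' @param x A `phantom_truth`.
#' @param ... Unused.
#' @return Tibble with true length, break length, bleb count, percent
#'   remaining and expected score per dendrite.
#' @export
tidy.phantom_truth <- function(x, ...) x$dendrites
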