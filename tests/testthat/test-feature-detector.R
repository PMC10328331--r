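test_that("enhancement flattens background and suppresses illumination gradients", {
  # flat background + one dendrite: background near zero after subtraction
  sp <- quiet_spec(n_dendrites = 1)
  roi <- crop_dendrites(render_phantom(sp)$image)
  er <- enhance(roi)
  expect_equal(dim(er$pixels), 4L * dim(roi$pixels))
  expect_equal(er$scale$resize_factor, 4L)
  bgcols <- c(1:10, (ncol(er$pixels) - 9):ncol(er$pixels))
  expect_lt(stats::median(er$pixels[, bgcols]), 0.02)
  # linear gradient: post-subtraction row-trend slope reduced >= 10x
  # (ROI built directly around the dendrite; the gradient is an
  # enhancement concern, not a cropping one)
  spg <- quiet_spec(n_dendrites = 1, background_gradient = 0.3)
  phg <- render_phantom(spg)
  cl <- phg$truth$centerlines[[1]]
  rows <- ceiling(min(cl$row)):floor(max(cl$row))
  cols <- round(mean(cl$col)) + (-60:60)
  roig <- as_roi(phg$image$pixels[rows, cols])
  erg <- enhance(roig)
  slope <- function(m) {
    rowbg <- apply(m, 1, stats::median)
    abs(stats::coef(stats::lm(rowbg ~ seq_along(rowbg)))[2])
  }
  maxv <- 2^roig$bit_depth - 1
  s_before <- slope(roig$pixels / maxv)
  s_after <- slope(erg$pixels) / 4   # per-row slope at 4x row spacing
  expect_lt(s_after, s_before / 10)
})

test_that("dendrite thresholding hugs the centerlines and resists noise", {
  sp <- quiet_spec()
  ph <- render_phantom(sp)
  an_roi <- crop_dendrites(ph$image)
  er <- enhance(an_roi)
  mask <- threshold_dendrites(er)
  # foreground must cover the centerline and stay within 1 um of it
  crop <- an_roi$transform$crop
  f <- 4
  on_center <- 0L; n_rows <- 0L
  dist_ok <- TRUE
  centers <- lapply(ph$truth$centerlines, function(cl) {
    rr <- (cl$row - crop[["top"]] + 1 - 0.5) * f + 0.5
    cc <- (cl$col - crop[["left"]] + 1 - 0.5) * f + 0.5
    cbind(rr, cc)
  })
  for (cl in centers) {
    ok <- cl[, 1] >= 1 & cl[, 1] <= nrow(mask)
    pts <- unique(round(cl[ok, , drop = FALSE]))
    pts <- pts[pts[, 1] >= 1 & pts[, 2] >= 1 &
                 pts[, 1] <= nrow(mask) & pts[, 2] <= ncol(mask), ,
               drop = FALSE]
    on_center <- on_center + sum(mask[pts])
    n_rows <- n_rows + nrow(pts)
  }
  expect_gt(on_center / n_rows, 0.98)
  # all foreground within 1 um (40 working px) of some centerline column
  fg <- which(mask, arr.ind = TRUE)
  allc <- do.call(rbind, centers)
  samp <- fg[seq(1, nrow(fg), length.out = min(500, nrow(fg))), , drop = FALSE]
  for (i in seq_len(nrow(samp))) {
    d <- sqrt(min((allc[, 1] - samp[i, 1])^2 + (allc[, 2] - samp[i, 2])^2))
    if (d > 40) { dist_ok <- FALSE; break }
  }
  expect_true(dist_ok)
  # with 5% noise, false-positive foreground stays below 1% of the frame
  spn <- phantom_spec(curvature_amplitude = 0, noise_sigma = 0.05, seed = 5L)
  roin <- crop_dendrites(render_phantom(spn)$image)
  ern <- enhance(roin)
  maskn <- threshold_dendrites(ern)
  offc <- maskn
  for (cl in centers) {  # same geometry: blank out a 1.5 um band per dendrite
    cc <- round(stats::median(cl[, 2]))
    cols <- max(1, cc - 60):min(ncol(offc), cc + 60)
    offc[, cols] <- FALSE
  }
  expect_lt(mean(offc), 0.01)
  # degenerate input
  blank <- as_eroi(matrix(0, 256, 256), an_roi)
  expect_error(threshold_dendrites(blank), "no dendrites")
})

test_that("horizontal erosion finds blebs but not bare dendrites", {
  cfg <- analysis_config()
  # bleb-free dendrite (0.6 um wide), element 1.4 um -> zero seeds
  sp0 <- quiet_spec(dendrite_width = 0.6)
  roi0 <- crop_dendrites(render_phantom(sp0)$image)
  er0 <- enhance(roi0)
  s0 <- erode_seeds(threshold_dendrites(er0), er0$scale, cfg)
  expect_equal(nrow(s0$props), 0L)
  # one 2.5 um bleb -> exactly one seed within 1 um of the bleb centre
  sp1 <- quiet_spec(dendrite_width = 0.6,
                    blebs = tibble::tibble(dendrite = 2, position = 0.5,
                                           diameter = 2.5))
  ph1 <- render_phantom(sp1)
  roi1 <- crop_dendrites(ph1$image)
  er1 <- enhance(roi1)
  s1 <- erode_seeds(threshold_dendrites(er1), er1$scale, cfg)
  expect_equal(nrow(s1$props), 1L)
  crop <- roi1$transform$crop
  b <- ph1$truth$blebs
  seed_roi_row <- (s1$props$centroid_row - 0.5) / 4 + 0.5
  seed_roi_col <- (s1$props$centroid_col - 0.5) / 4 + 0.5
  d_um <- sqrt((seed_roi_row - (b$row - crop[["top"]] + 1))^2 +
                 (seed_roi_col - (b$col - crop[["left"]] + 1))^2) * 0.1
  expect_lt(d_um, 1)
  # two blebs 10 um apart -> two seeds
  sp2 <- quiet_spec(dendrite_width = 0.6,
                    blebs = tibble::tibble(dendrite = 2,
                                           position = c(0.35, 0.6),
                                           diameter = 2.5))
  roi2 <- crop_dendrites(render_phantom(sp2)$image)
  er2 <- enhance(roi2)
  s2 <- erode_seeds(threshold_dendrites(er2), er2$scale, cfg)
  expect_equal(nrow(s2$props), 2L)
})

test_that("erosion seed count never decreases when a bleb is added", {
  base_blebs <- list(
    NULL,
    tibble::tibble(dendrite = 2, position = 0.4, diameter = 2.5),
    tibble::tibble(dendrite = c(2, 3), position = c(0.4, 0.6),
                   diameter = 2.5))
  counts <- vapply(base_blebs, function(b) {
    roi <- crop_dendrites(render_phantom(quiet_spec(blebs = b))$image)
    er <- enhance(roi)
    nrow(erode_seeds(threshold_dendrites(er), er$scale)$props)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("Chan-Vese refinement recovers the area of a hard-edged disk within 15%", {
  # synthetic enhanced ROI: one sharp disk (radius 50 working px = 1.25 um)
  nr <- 300; nc <- 300
  d <- sqrt(outer((1:nr - 150)^2, (1:nc - 150)^2, `+`))
  img <- 0.05 + 0.75 * (d <= 50)
  roi <- as_roi(matrix(0.4 * 65535, nr / 4, nc / 4))
  er <- as_eroi(img, roi, noise_level = 0.001)
  seeds <- erode_seeds(threshold_dendrites(er), er$scale)
  expect_equal(nrow(seeds$props), 1L)
  ft <- refine_features(er, seeds)
  expect_equal(nrow(ft), 1L)
  true_area <- pi * 1.25^2
  expect_lt(abs(ft$area_um2 - true_area) / true_area, 0.15)
  expect_gte(ft$circularity, 0.85)
})

test_that("refinement keeps a phantom bleb circular and well-behaved", {
  sp <- quiet_spec(blebs = tibble::tibble(dendrite = 2, position = 0.5,
                                          diameter = 2.5, peak = 0.9))
  det <- detect_features(crop_dendrites(render_phantom(sp)$image))
  expect_equal(nrow(det$features), 1L)
  ft <- det$features
  expect_gte(ft$circularity, 0.8)
  expect_true(ft$min_caliper_um <= ft$max_caliper_um)
  expect_true(ft$extent >= 0 && ft$extent <= 1)
  # refinement cannot teleport the centroid beyond the seed's bbox diagonal
  er <- det$eroi
  seeds <- erode_seeds(threshold_dendrites(er), er$scale)
  diag_px <- sqrt(seeds$props$bbox_height^2 + seeds$props$bbox_width^2)
  d <- sqrt((ft$.row_px - seeds$props$centroid_row)^2 +
              (ft$.col_px - seeds$props$centroid_col)^2)
  expect_lt(d, diag_px)
})

test_that("descriptor conventions: filled rectangle has extent 1, a cross far less", {
  rect <- matrix(0L, 60, 80)
  rect[20:40, 25:55] <- 1L
  pr <- cepdeg:::region_props(rect, scale = pixel_scale(0.1, 4L))
  expect_identical(pr$extent, 1)
  cross <- matrix(0L, 60, 60)
  cross[28:32, 10:50] <- 1L
  cross[10:50, 28:32] <- 1L
  pc <- cepdeg:::region_props(cross, scale = pixel_scale(0.1, 4L))
  expect_lte(pc$extent, 0.4)
  # calipers: rectangle 21 x 31 px -> min ~21, max ~ diagonal
  expect_equal(pr$min_caliper_um, 21 * 0.025, tolerance = 0.1)
  expect_equal(pr$max_caliper_um, sqrt(21^2 + 31^2) * 0.025, tolerance = 0.1)
})

test_that("feature detection is invariant to pixel size and bit depth", {
  blebs <- tibble::tibble(dendrite = c(2, 3), position = c(0.35, 0.65),
                          diameter = 2.5)
  cases <- list(
    phantom_spec(pixel_size = 0.1, blebs = blebs, noise_sigma = 0, seed = 3L),
    phantom_spec(pixel_size = 0.2, blebs = blebs, noise_sigma = 0, seed = 3L),
    phantom_spec(pixel_size = 0.1, bit_depth = 8L, blebs = blebs,
                 noise_sigma = 0, seed = 3L))
  res <- lapply(cases, function(sp) analyze_image(render_phantom(sp)$image))
  counts <- vapply(res, function(a) sum(a$reports$feature_count), 0L)
  expect_true(all(counts == 2L))
  lens <- vapply(res, function(a) mean(a$reports$dendrite_length_um), 0)
  expect_lt(max(abs(lens - lens[1])) / lens[1], 0.05)
})
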