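test_that("row maxima land on ridge centres, at most four per row", {
  # constructed row: 4 well-separated Gaussian ridges
  nr <- 64; nc <- 800
  centers <- c(120, 300, 480, 660)
  row <- rep(0.02, nc)
  for (cc in centers) row <- row + 0.6 * exp(-((1:nc - cc)^2) / (2 * 12^2))
  img <- matrix(rep(row, each = nr), nr, nc, byrow = FALSE)
  roi <- as_roi(matrix(0.4 * 65535, nr / 4, nc / 4))
  er <- as_eroi(img, roi, noise_level = 0.005)
  cand <- row_maxima(er)
  hits <- which(cand[32, ])
  expect_length(hits, 4L)
  # within 0.3 um (12 working px) of the ridge centres
  expect_true(all(abs(sort(hits) - centers) <= 12))
  # flat row -> no marks
  imgf <- img; imgf[10, ] <- 0.02
  erf <- as_eroi(imgf, roi, noise_level = 0.005)
  expect_equal(sum(row_maxima(erf)[10, ]), 0L)
  # a row crossing a break on ridge 2 -> at most 3 marks
  imgb <- img
  imgb[20, 240:360] <- 0.02
  erb <- as_eroi(imgb, roi, noise_level = 0.005)
  expect_lte(sum(row_maxima(erb)[20, ]), 3L)
  # never more than 4, even with many ridges
  row8 <- rep(0.02, nc)
  for (cc in seq(60, 740, by = 97))
    row8 <- row8 + 0.6 * exp(-((1:nc - cc)^2) / (2 * 10^2))
  img8 <- matrix(rep(row8, each = nr), nr, nc)
  er8 <- as_eroi(img8, roi, noise_level = 0.005)
  expect_true(all(rowSums(row_maxima(er8)) <= 4L))
})

test_that("vertical closing bridges dotted runs but not parallel neighbours", {
  sc <- pixel_scale(0.1, 4L)   # 0.025 um per working px
  m <- matrix(FALSE, 800, 400)
  m[seq(100, 700, by = 80), 200] <- TRUE    # 2 um gaps along one column
  frag <- bridge_and_skeletonize(m, sc)
  expect_equal(max(frag), 1L)
  # rows between the first and last dot are filled in
  expect_true(all(frag[seq(100, 660), 200] == 1L))
  # two parallel dotted lines 4 um (160 px) apart stay two fragments
  m2 <- m
  m2[seq(100, 700, by = 80), 360] <- TRUE
  frag2 <- bridge_and_skeletonize(m2, sc)
  expect_equal(max(frag2), 2L)
  # empty grid -> empty fragment set
  expect_equal(max(bridge_and_skeletonize(matrix(FALSE, 64, 64), sc)), 0L)
})

test_that("binning assigns points to the nearest running average, max four tracks", {
  sc <- pixel_scale(0.1, 4L)
  nr <- 1200
  centers <- c(80, 200, 320, 440)
  m <- matrix(0L, nr, 520)
  for (k in seq_along(centers)) m[cbind(1:nr, centers[k])] <- 1L
  raw <- bin_fragments(m, sc)
  expect_length(raw, 4L)
  # a duplicate candidate near track 2 in one row: farther point dropped
  m2 <- m
  m2[600, 206] <- 1L   # 6 px away vs 0 px for the true point
  raw2 <- bin_fragments(m2, sc)
  expect_length(raw2, 4L)
  x600 <- vapply(raw2, function(t) t$x[t$rows == 600][1], 0)
  expect_true(200 %in% x600)
  expect_false(206 %in% x600)
  # a fifth persistent column beyond the gate never claims a slot
  m3 <- m
  m3[, 30] <- 0L
  m3[cbind(1:nr, 30)] <- 1L
  raw3 <- suppressWarnings(bin_fragments(m3, sc))
  expect_lte(length(raw3), 4L)
})

test_that("finalized tracks are total on their span and ordered left to right", {
  sc <- pixel_scale(0.1, 4L)
  rows <- c(1:300, 501:800)                    # 30%+ missing interior rows
  raw <- list(list(rows = rows, x = rep(300, length(rows)),
                   detected = rep(TRUE, length(rows))),
              list(rows = 1:800, x = rep(100, 800),
                   detected = rep(TRUE, 800)))
  tr <- finalize_tracks(raw, sc)
  expect_length(tr, 2L)
  # re-indexed left to right by mean x
  expect_equal(vapply(tr, function(t) t$index, 0L), c(1L, 2L))
  expect_lt(mean(tr[[1]]$x), mean(tr[[2]]$x))
  # total on span, interpolated rows flagged
  t2 <- tr[[2]]   # the one with the gap
  expect_equal(t2$rows, 1:800)
  expect_false(any(is.na(t2$x)))
  expect_false(any(t2$detected[301:500]))
  # a track with <2 detected rows is dropped with a note
  expect_message(
    out <- finalize_tracks(list(list(rows = 5L, x = 10, detected = TRUE)), sc),
    "<2 detected rows")
  expect_length(out, 0L)
})

test_that("zig-zag detection noise is smoothed to within 0.3 um of the centreline", {
  sc <- pixel_scale(0.1, 4L)
  rows <- 1:800
  x <- 200 + rep(c(-1, 1), length.out = 800)   # +-1 px zig-zag
  raw <- list(list(rows = rows, x = x, detected = rep(TRUE, 800)))
  tr <- finalize_tracks(raw, sc)[[1]]
  expect_lt(max(abs(tr$x - 200)) * 0.025, 0.3)
})

test_that("a healthy four-dendrite phantom yields exactly four accurate tracks", {
  ph <- healthy_phantom()
  an <- healthy_analysis()
  expect_length(an$tracks, 4L)
  # every row of every track has exactly one x; indices unique and ordered
  idx <- vapply(an$tracks, function(t) t$index, 0L)
  expect_equal(idx, 1:4)
  for (t in an$tracks) {
    expect_equal(length(t$x), length(t$rows))
    expect_equal(t$rows, seq(min(t$rows), max(t$rows)))
  }
  # tracks follow the true centerlines (mean abs deviation <= 0.5 um)
  crop <- an$roi$transform$crop
  for (k in 1:4) {
    cl <- ph$truth$centerlines[[k]]
    t <- an$tracks[[k]]
    roi_row <- (t$rows - 0.5) / 4 + 0.5 + crop[["top"]] - 1
    roi_col <- (t$x - 0.5) / 4 + 0.5 + crop[["left"]] - 1
    tr_x <- stats::approx(cl$row, cl$col, xout = roi_row, rule = 2)$y
    mad_um <- mean(abs(roi_col - tr_x)) * 0.1
    expect_lt(mad_um, 0.5)
  }
})

test_that("track count equals the number of rendered dendrites (D <= 4)", {
  for (d in c(2L, 3L)) {
    sp <- phantom_spec(n_dendrites = d, noise_sigma = 0.02,
                       seed = 60L + d)
    an <- analyze_image(render_phantom(sp)$image)
    expect_length(an$tracks, d)
  }
})
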