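test_that("break binarization covers intact dendrites and opens at gaps", {
  # continuous dendrites: foreground on >= 99% of centreline rows
  an <- healthy_analysis()
  mask <- binarize_for_breaks(an$eroi)
  covered <- vapply(an$tracks, function(t) {
    mean(vapply(seq_along(t$rows), function(i) {
      cols <- max(1, round(t$x[i]) - 20):min(ncol(mask), round(t$x[i]) + 20)
      any(mask[t$rows[i], cols])
    }, TRUE))
  }, 0)
  expect_true(all(covered >= 0.99))
  # a 5 um zeroed gap opens the mask there
  bp <- break_phantom()
  anb <- analyze_image(bp$image)
  maskb <- binarize_for_breaks(anb$eroi)
  t3 <- anb$tracks[[3]]
  gap_rows <- anb$breaks$dendrite == 3
  expect_true(any(gap_rows))
  # blank enhanced ROI -> empty mask, not an error
  blank <- as_eroi(matrix(0, 128, 128), as_roi(matrix(0.1, 32, 32)))
  expect_false(any(binarize_for_breaks(blank)))
})

test_that("detected break lengths match rendered gaps", {
  # intact dendrite: no breaks at all
  expect_equal(nrow(healthy_analysis()$breaks), 0L)
  # one 5 um gap: one break, length within 1 um
  an1 <- analyze_image(break_phantom()$image)
  b1 <- an1$breaks
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$dendrite, 3L)
  expect_lt(abs(b1$length_um - 5), 1)
  # two gaps of 3 and 8 um: two breaks, total within 1.5 um of 11
  sp2 <- phantom_spec(breaks = tibble::tibble(dendrite = 2,
                                              start = c(0.2, 0.6),
                                              length = c(3, 8)),
                      noise_sigma = 0.02, seed = 91L)
  an2 <- analyze_image(render_phantom(sp2)$image)
  b2 <- an2$breaks
  expect_equal(nrow(b2), 2L)
  expect_lt(abs(sum(b2$length_um) - 11), 1.5)
  expect_equal(b2$length_um, b2$y_end_um - b2$y_start_um)
})

test_that("features are matched to the dendrite under them, distant ones unassigned", {
  bp <- bleb_phantom()
  an <- analyze_image(bp$image)
  expect_equal(nrow(an$features), 3L)
  expect_true(all(an$features$dendrite == 2L))
  # equidistant tie goes to the lower index; far features stay NA
  tr1 <- as_track(1:400, rep(100, 400), index = 1L)
  tr2 <- as_track(1:400, rep(180, 400), index = 2L)
  ft <- cepdeg:::empty_features()
  ft[1, ] <- list(1L, 5, 3.5, 1, 4, 0.9, 0.8, 0.5, 1, 1.2, 500,
                  NA_integer_, 200, 140)   # exactly between the tracks
  ft[2, ] <- list(2L, 5, 17.5, 1, 4, 0.9, 0.8, 0.5, 1, 1.2, 500,
                  NA_integer_, 200, 700)   # 10+ um from every track
  got <- suppressMessages(match_features(ft, list(tr1, tr2)))
  expect_equal(got$dendrite[1], 1L)
  expect_true(is.na(got$dendrite[2]))
})

test_that("report arithmetic follows the definitions on constructed inputs", {
  cfg <- analysis_config()
  roi <- as_roi(matrix(0.5 * 65535, 110, 60))
  # straight vertical track: 400 working rows = 10 um at 0.025 um/px
  tr <- as_track(1:400, rep(120, 400), index = 1L)
  no_breaks <- tibble::tibble(dendrite = integer(), y_start_um = double(),
                              y_end_um = double(), length_um = double())
  rep0 <- compute_report(roi, tr, no_breaks, cepdeg:::empty_features(), cfg)
  # 400 rows at 0.025 um/row span 10 um (pixel-extent convention)
  expect_equal(rep0$dendrite_length_um, 10, tolerance = 1e-9)
  expect_equal(rep0$percent_remaining, 100)
  expect_equal(rep0$feature_count, 0L)
  expect_equal(rep0$features_per_length, 0)
  # feature aggregates are NA (not zero) when no features matched
  expect_true(is.na(rep0$mean_feature_area_um2))
  expect_true(is.na(rep0$mean_feature_intensity))
  expect_false(rep0$unreliable)
  # one 2.5 um break: conservation and percentages
  brk <- tibble::tibble(dendrite = 1L, y_start_um = 3, y_end_um = 5.5,
                        length_um = 2.5)
  rep1 <- compute_report(roi, tr, brk, cepdeg:::empty_features(), cfg)
  expect_equal(rep1$remaining_length_um + rep1$total_break_length_um,
               rep1$dendrite_length_um, tolerance = 0.03)
  expect_equal(rep1$percent_remaining, 100 * 7.5 / 10, tolerance = 0.1)
  # three features on the track: rates and normalized locations
  ft <- cepdeg:::empty_features()
  for (i in 1:3) ft[i, ] <- list(
    i, i * 2.5, 3, 1, 4, 0.9, 0.8, 0.5, 1, 1.2, 500, NA_integer_,
    i * 100, 120)
  ft$dendrite <- 1L
  rep3 <- compute_report(roi, tr, no_breaks, ft, cfg)
  expect_equal(rep3$feature_count, 3L)
  expect_equal(rep3$features_per_length, 3 / 10, tolerance = 1e-9)
  expect_equal(rep3$features_per_remaining, 3 / 10, tolerance = 1e-9)
  # proximal end (bottom row) -> location ~ 0; distal tip -> ~ 1
  ft_prox <- ft[1, ]; ft_prox$.row_px <- 400
  ft_dist <- ft[1, ]; ft_dist$.row_px <- 1
  expect_lt(compute_report(roi, tr, no_breaks, ft_prox,
                           cfg)$mean_normalized_feature_location, 0.05)
  expect_gt(compute_report(roi, tr, no_breaks, ft_dist,
                           cfg)$mean_normalized_feature_location, 0.95)
  # degenerate track -> flagged unreliable
  short <- as_track(1:100, rep(120, 100), index = 1L)
  expect_true(compute_report(roi, short, no_breaks,
                             cepdeg:::empty_features(), cfg)$unreliable)
})

test_that("phantom arithmetic: 40 um dendrite with a 10 um break reports ~75%", {
  sp <- phantom_spec(curvature_amplitude = 0, noise_sigma = 0.02, seed = 14L,
                     breaks = tibble::tibble(dendrite = 2, start = 0.35,
                                             length = 10))
  an <- analyze_image(render_phantom(sp)$image)
  r2 <- an$reports[an$reports$dendrite == 2, ]
  expect_lt(abs(r2$percent_remaining - 75), 5)
  expect_equal(r2$categorical_score, 3L)
})

test_that("categorical scoring reproduces the published bins with break precedence", {
  expect_identical(score_degeneration(100, 0), 0L)
  expect_identical(score_degeneration(100, 3), 1L)
  expect_identical(score_degeneration(100, 8), 2L)
  expect_identical(score_degeneration(70, 0), 3L)
  expect_identical(score_degeneration(70, 12), 3L)   # break precedence
  expect_identical(score_degeneration(30, 10), 4L)
  # boundary semantics: 85 inclusive -> 3; 50 inclusive -> 3; 5 blebs -> 2
  expect_identical(score_degeneration(85, 0), 3L)
  expect_identical(score_degeneration(50, 0), 3L)
  expect_identical(score_degeneration(49.999, 0), 4L)
  expect_identical(score_degeneration(100, 5), 2L)
  expect_identical(score_degeneration(100, 4), 1L)
})

test_that("scoring is total, deterministic and monotone", {
  ps <- seq(0, 100, by = 2.5)
  ks <- 0:12
  grid <- expand.grid(p = ps, k = ks)
  s <- score_degeneration(grid$p, grid$k)
  expect_true(all(s %in% 0:4))
  expect_identical(s, score_degeneration(grid$p, grid$k))
  # monotone non-increasing in percent_remaining at fixed feature count
  for (k in c(0L, 3L, 7L)) {
    sk <- score_degeneration(ps, k)
    expect_true(all(diff(sk) <= 0))
  }
  # monotone non-decreasing in feature count within the no-break branch
  s_up <- score_degeneration(95, ks)
  expect_true(all(diff(s_up) >= 0))
})

test_that("dendrite lengths recovered across the fixture catalogue stay within 5%", {
  for (case in suite_analyses()) {
    truth <- case$truth
    got <- case$analysis$reports
    expect_length(case$analysis$tracks, 4L)
    for (k in 1:4) {
      tk <- truth[truth$dendrite == k, ]
      gk <- got[got$dendrite == k, ]
      expect_lt(abs(gk$dendrite_length_um - tk$length_um) / tk$length_um,
                0.05)
    }
  }
})
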