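# Shared fixtures. Rendered once per test run and reused: rendering is
# deterministic (seeded), so caching changes nothing but wall time.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, fixture_cache)) assign(key, force(expr), fixture_cache)
  get(key, fixture_cache)
}

healthy_phantom <- function() cached("healthy", {
  render_phantom(phantom_spec(noise_sigma = 0.02, seed = 42L))
})

healthy_analysis <- function() cached("healthy_an", {
  analyze_image(healthy_phantom()$image)
})

bleb_phantom <- function() cached("bleb", {
  render_phantom(phantom_spec(
    blebs = tibble::tibble(dendrite = 2, position = c(0.25, 0.5, 0.75),
                           diameter = 2.5),
    noise_sigma = 0.02, seed = 77L))
})

break_phantom <- function() cached("break", {
  render_phantom(phantom_spec(
    breaks = tibble::tibble(dendrite = 3, start = 0.4, length = 5),
    noise_sigma = 0.02, seed = 88L))
})

# small, quiet phantom for cheap per-stage tests (no curvature, no noise)
quiet_spec <- function(...) {
  phantom_spec(curvature_amplitude = 0, noise_sigma = 0, seed = 5L, ...)
}

# a bare ROI carrying given pixels, for synthetic-stage tests
as_roi <- function(pixels, microns_per_pixel = 0.1, bit_depth = 16L) {
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 scale = pixel_scale(microns_per_pixel),
                 proximal_edge = "bottom",
                 transform = list(rows = c(1L, nrow(pixels)), flipped = FALSE,
                                  crop = NULL, angle = 0)),
            class = "dendrite_roi")
}

# a bare enhanced ROI (working grid already at the given resize factor)
as_eroi <- function(pixels, roi, noise_level = 0.01, resize_factor = 4L) {
  structure(list(pixels = pixels,
                 scale = pixel_scale(roi$scale$microns_per_pixel,
                                     resize_factor),
                 noise_level = noise_level,
                 otsu_level = EBImage::otsu(pixels), roi = roi),
            class = "enhanced_roi")
}

# a bare track at the working (4x) resolution
as_track <- function(rows, x, microns_per_pixel = 0.1, index = 1L,
                     detected = NULL, resize_factor = 4L) {
  structure(list(index = index, rows = rows, x = x,
                 detected = detected %||% rep(TRUE, length(rows)),
                 scale = pixel_scale(microns_per_pixel, resize_factor)),
            class = "dendrite_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-pipeline analyses of the whole fixture catalogue (truth + reports)
suite_analyses <- function() cached("suite_analyses", {
  lapply(phantom_suite(), function(sp) {
    ph <- render_phantom(sp)
    an <- suppressWarnings(suppressMessages(analyze_image(ph$image)))
    list(truth = tidy(ph$truth), analysis = an)
  })
})

# brute-force per-row break scan (no run-length machinery): the oracle
# that detect_breaks must agree with
brute_force_break_scan <- function(track, mask, cfg) {
  um <- track$scale$microns_per_pixel / track$scale$resize_factor
  tol <- max(0L, round(cfg$probe_tol_um / um))
  min_rows <- max(1L, round(cfg$min_break_um / um))
  segs <- list(); run_start <- NA
  for (i in seq_along(track$rows)) {
    c0 <- max(1L, floor(track$x[i] - tol))
    c1 <- min(ncol(mask), ceiling(track$x[i] + tol))
    miss <- !any(mask[track$rows[i], c0:c1])
    if (miss && is.na(run_start)) run_start <- i
    if ((!miss || i == length(track$rows)) && !is.na(run_start)) {
      run_end <- if (miss) i else i - 1L
      if (run_end - run_start + 1L >= min_rows)
        segs[[length(segs) + 1L]] <- c(run_start, run_end)
      run_start <- NA
    }
  }
  segs
}

# small seeded phantoms plus truth-derived tracks and a plain threshold
# mask at working scale, for break-detection equivalence checks
break_oracle_cases <- function(n_phantoms) {
  out <- list()
  set.seed(123)
  for (rep in seq_len(n_phantoms)) {
    has_break <- rep %% 2 == 0
    brk <- if (has_break) {
      st <- runif(1, 0.15, 0.6)
      tibble::tibble(dendrite = sample(1:4, 1), start = st,
                     length = runif(1, 3, min(10, (0.95 - st) * 25)))
    } else NULL
    sp <- phantom_spec(image_size = c(420, 200), dendrite_length = 25,
                       breaks = brk, noise_sigma = runif(1, 0, 0.04),
                       seed = 1000L + rep)
    ph <- render_phantom(sp)
    px <- ph$image$pixels / 65535
    mask0 <- px > 0.1
    f <- 2L
    mask <- mask0[rep(seq_len(nrow(mask0)), each = f),
                  rep(seq_len(ncol(mask0)), each = f)]
    tracks <- lapply(seq_len(4), function(k) {
      cl <- ph$truth$centerlines[[k]]
      rows <- seq(ceiling(min(cl$row)), floor(max(cl$row)))
      x <- stats::approx(cl$row, cl$col, xout = rows)$y
      tr <- as_track(round((rows - 0.5) * f + 0.5), (x - 0.5) * f + 0.5,
                     microns_per_pixel = sp$pixel_size, index = k,
                     resize_factor = f)
      tr
    })
    out[[rep]] <- list(mask = mask, tracks = tracks,
                       um = sp$pixel_size / f)
  }
  out
}

report_stub <- function(percent_remaining, feature_count) {
  tibble::tibble(percent_remaining = percent_remaining,
                 feature_count = feature_count)
}
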