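#' Per-row local maxima (ridge candidates)
#'
#' Starting at the top (distal end) of the enhanced ROI, each pixel row is
#' scanned for up to four local intensity maxima -- the four dendrites
#' crossing that row. A maximum must clear a prominence floor tied to the
#' recorded noise level, sit above the noise-adaptive dendrite threshold,
#' and be separated from stronger accepted peaks by a minimum physical
#' distance. Rows crossing a break or
#' a lost dendrite legitimately carry fewer than four marks.
#'
#' @param eroi An [enhance()] result.
#' @param config An [analysis_config()].
#' @return A logical matrix marking candidate points.
#' @export
row_maxima <- function(eroi, config = analysis_config()) {
  stopifnot(inherits(eroi, "enhanced_roi"))
  img <- eroi$pixels
  min_sep <- px_len(config$peak_min_sep_um, eroi$scale)
  prom_floor <- config$peak_prom_mult * eroi$noise_level
  # a ridge point must clear the same noise-adaptive level that defines
  # dendrite foreground; rows where the dendrite is absent (breaks, frame
  # margins) then carry no marks and are later interpolated across
  height_floor <- eroi$otsu_level + config$k_noise * eroi$noise_level
  out <- matrix(FALSE, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    p <- find_row_peaks(img[r, ], prom_floor, height_floor, min_sep, 4L)
    if (length(p)) out[r, p] <- TRUE
  }
  out
}

# peak finder: local maxima above a height floor, with true topographic
# prominence >= prom_floor, greedily thinned to min_sep (strongest first),
# at most max_peaks returned
find_row_peaks <- function(v, prom_floor, height_floor, min_sep, max_peaks) {
  n <- length(v)
  if (n < 3) return(integer())
  d <- diff(v)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[v[cand] >= height_floor]
  if (!length(cand)) return(integer())
  proms <- vapply(cand, function(i) peak_prominence(v, i), 0)
  cand <- cand[proms >= prom_floor]
  if (!length(cand)) return(integer())
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- integer()
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
    if (length(keep) == max_peaks) break
  }
  sort(keep)
}

peak_prominence <- function(v, i) {
  h <- v[i]
  left <- if (i > 1) v[seq_len(i - 1)] else numeric()
  right <- if (i < length(v)) v[(i + 1):length(v)] else numeric()
  base_side <- function(side) {
    higher <- which(side >= h)
    if (!length(higher)) return(min(c(side, h)))
    min(side[seq(from = length(side), to = max(higher))])
  }
  lb <- if (length(left)) base_side(rev(left)) else h
  rb <- if (length(right)) base_side(right) else h
  # prominence relative to the higher of the two key saddles; an edge-bounded
  # peak keys off the lower edge minimum
  h - max(min(lb, h), min(rb, h))
}

#' Bridge candidate points and skeletonize into track fragments
#'
#' A morphological closing with a vertical structuring element joins
#' same-dendrite candidate runs across small detection dropouts (true
#' breaks are re-detected later against the binarized dendrite image, so
#' bridging across them here is intended: tracks must span breaks). A
#' small horizontal dilation first absorbs single-pixel x jitter. The
#' closed objects are then reduced to one-pixel-wide fragments by per-row
#' run centres and labeled by connectivity.
#'
#' @param candidates Logical matrix from [row_maxima()].
#' @param scale Working [pixel_scale()].
#' @param config An [analysis_config()].
#' @return Integer matrix of labeled skeleton fragments.
#' @export
bridge_and_skeletonize <- function(candidates, scale,
                                   config = analysis_config()) {
  if (!any(candidates)) return(matrix(0L, nrow(candidates), ncol(candidates)))
  hb <- odd_px(2 * config$hbridge_um, scale)
  m <- candidates * 1
  if (hb > 1) m <- as_mat(EBImage::dilate(m, matrix(1, 1, hb)))
  vlen <- odd_px(config$vclose_um, scale)
  # pad vertically so the closing cannot smear objects into the borders
  # (erosion treats out-of-frame pixels as foreground)
  z <- matrix(0, vlen, ncol(m))
  m <- rbind(z, m, z)
  m <- as_mat(EBImage::closing(m, matrix(1, vlen, 1))) > 0.5
  m <- m[(vlen + 1):(nrow(m) - vlen), , drop = FALSE]
  sk <- skeleton_row_centers(m)
  as_mat(EBImage::bwlabel(sk)) |> apply_int()
}

apply_int <- function(m) { storage.mode(m) <- "integer"; m }

# reduce each horizontal run of foreground to its centre pixel
skeleton_row_centers <- function(m) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    x <- m[r, ]
    if (!any(x)) next
    rl <- rle(x)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values)
    out[r, floor((starts[fg] + ends[fg]) / 2)] <- TRUE
  }
  out
}

#' Bin skeleton fragments into dendrite tracks
#'
#' Proceeding row by row from the distal (top) end, each fragment point is
#' assigned to the dendrite whose running-average x position (an
#' exponential moving average) is nearest, within a gating distance. When
#' two points compete for the same dendrite in one row, the point farther
#' from the running average is discarded, so no row ever contributes more
#' than one x per dendrite -- and never more than four points total.
#' Points beyond every gate seed a new dendrite, but only while fewer than
#' four exist and only in the distal leading fraction of rows (late
#' artifacts must not claim a track slot). Equidistant ties go to the
#' lower dendrite index.
#'
#' @param fragments Labeled matrix from [bridge_and_skeletonize()].
#' @param scale Working [pixel_scale()].
#' @param config An [analysis_config()].
#' @return A list of raw tracks: for each, integer `rows`, numeric `x`
#'   (px), logical `detected` (all TRUE here; interpolation comes later).
#' @export
bin_fragments <- function(fragments, scale, config = analysis_config()) {
  nr <- nrow(fragments)
  pts <- which(fragments > 0, arr.ind = TRUE)
  if (!nrow(pts)) return(list())
  gate <- px_len(config$gate_um, scale)
  wgt <- config$ema_weight
  seed_last_row <- ceiling(config$seed_row_frac * nr)
  by_row <- split(pts[, 2], pts[, 1])
  ema <- numeric(0)
  tracks <- list()
  n_unassigned <- 0L
  for (rn in names(by_row)) {
    r <- as.integer(rn)
    xs <- sort(by_row[[rn]])
    claimed <- rep(NA_integer_, length(ema))  # point index claiming dendrite
    assign_x <- rep(NA_real_, length(ema))
    leftover <- numeric(0)
    for (x in xs) {
      if (length(ema)) {
        dists <- abs(x - ema)
        j <- which(dists == min(dists))[1]   # tie -> lower index
        if (dists[j] <= gate) {
          if (is.na(claimed[j]) || abs(assign_x[j] - ema[j]) > dists[j]) {
            if (!is.na(claimed[j])) n_unassigned <- n_unassigned + 1L
            claimed[j] <- 1L; assign_x[j] <- x
          } else n_unassigned <- n_unassigned + 1L
          next
        }
      }
      leftover <- c(leftover, x)
    }
    for (x in leftover) {
      if (length(ema) < 4 && r <= seed_last_row) {
        ema <- c(ema, x)
        tracks[[length(tracks) + 1]] <- list(rows = integer(), x = numeric())
        claimed <- c(claimed, 1L); assign_x <- c(assign_x, x)
      } else n_unassigned <- n_unassigned + 1L
    }
    for (j in seq_along(ema)) {
      if (!is.na(claimed[j])) {
        tracks[[j]]$rows <- c(tracks[[j]]$rows, r)
        tracks[[j]]$x <- c(tracks[[j]]$x, assign_x[j])
        ema[j] <- (1 - wgt) * ema[j] + wgt * assign_x[j]
      }
    }
  }
  if (n_unassigned > 0.05 * nrow(pts))
    warning("more than 4 persistent candidate columns: ", n_unassigned,
            " of ", nrow(pts), " points discarded by the 4-track gate")
  lapply(tracks, function(t) list(rows = t$rows, x = t$x,
                                  detected = rep(TRUE, length(t$rows))))
}

#' Interpolate, smooth and index the dendrite tracks
#'
#' Missing interior rows are filled by linear interpolation, the x trace
#' is smoothed with a physical moving-average window, and tracks are
#' re-indexed left to right by mean x. The detected/interpolated
#' distinction is preserved (`detected` flag per row): break detection
#' probes the binarized image along *all* rows but other consumers may
#' care which rows were observed. Tracks with fewer than two detected
#' rows are dropped with a note.
#'
#' @param tracks Output of [bin_fragments()].
#' @param scale Working [pixel_scale()].
#' @param config An [analysis_config()].
#' @return A list of `dendrite_track` objects: `index`, integer `rows`
#'   (full span, step 1), numeric `x` (px, total on the span), logical
#'   `detected`, and `scale`.
#' @export
finalize_tracks <- function(tracks, scale, config = analysis_config()) {
  keep <- list()
  for (t in tracks) {
    if (length(unique(t$rows)) < 2) {
      message("dropping a track with <2 detected rows")
      next
    }
    ord <- order(t$rows)
    rows <- t$rows[ord]; x <- t$x[ord]
    span <- seq(min(rows), max(rows))
    xi <- stats::approx(rows, x, xout = span, ties = "mean")$y
    w <- odd_px(config$smooth_window_um, scale)
    if (w > 1 && length(xi) > w) {
      sm <- stats::filter(xi, rep(1 / w, w), sides = 2)
      xi <- ifelse(is.na(sm), xi, as.numeric(sm))
    }
    keep[[length(keep) + 1]] <- list(rows = span, x = xi,
                                     detected = span %in% rows)
  }
  if (!length(keep)) return(list())
  ord <- order(vapply(keep, function(t) mean(t$x), 0))
  out <- list()
  for (i in seq_along(ord)) {
    t <- keep[[ord[i]]]
    out[[i]] <- structure(list(index = i, rows = t$rows, x = t$x,
                               detected = t$detected, scale = scale),
                          class = "dendrite_track")
  }
  out
}

#' Trace the dendrites in an enhanced ROI
#'
#' Wrapper: [row_maxima()], [bridge_and_skeletonize()], [bin_fragments()],
#' [finalize_tracks()].
#'
#' @param eroi An [enhance()] result.
#' @param config An [analysis_config()].
#' @return A list of up to four `dendrite_track` objects, indexed left to
#'   right.
#' @export
track_dendrites <- function(eroi, config = analysis_config()) {
  cand <- row_maxima(eroi, config)
  frag <- bridge_and_skeletonize(cand, eroi$scale, config)
  raw <- bin_fragments(frag, eroi$scale, config)
  finalize_tracks(raw, eroi$scale, config)
}

#' @export
print.dendrite_track <- function(x, ...) {
  um <- um_per_px(x$scale)
  cat(sprintf("<dendrite_track %d> rows %d-%d (%.1f um), %d%% detected\n",
              x$index, min(x$rows), max(x$rows),
              diff(range(x$rows)) * um, round(100 * mean(x$detected))))
  invisible(x)
}

#' Tidy a dendrite track into a tibble
#'
#' @param x A `dendrite_track`.
#' @param ... Unused.
#' @return Tibble with `dendrite`, `row`, `y_um` (from the top of the
#'   ROI), `x_um` and `detected`.
#' @export
tidy.dendrite_track <- function(x, ...) {
  um <- um_per_px(x$scale)
  tibble::tibble(dendrite = x$index, row = x$rows, y_um = x$rows * um,
                 x_um = x$x * um, detected = x$detected)
}
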