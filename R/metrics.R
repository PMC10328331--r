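#' Permissive dendrite binarization for break detection
#'
#' An independent binarization intended to answer "is there *any* dendrite
#' signal at this row?", not to delineate shape: the threshold is a
#' configurable fraction (default 0.5) of the feature-detection threshold,
#' so dim-but-intact dendrite stretches are not scored as broken. An empty
#' mask is a valid outcome (a fully lost dendrite), not an error.
#'
#' @param eroi An [enhance()] result.
#' @param config An [analysis_config()].
#' @return A logical matrix on the working grid.
#' @export
binarize_for_breaks <- function(eroi, config = analysis_config()) {
  stopifnot(inherits(eroi, "enhanced_roi"))
  thr <- config$break_thresh_frac *
    (eroi$otsu_level + config$k_noise * eroi$noise_level)
  eroi$pixels > thr
}

#' Detect breaks along a dendrite track
#'
#' Walking the track row by row, the binarized dendrite image is probed
#' within a lateral tolerance around the track's x position. Maximal runs
#' of rows with no foreground, at least the minimum break length long,
#' become break segments.
#'
#' @param track A `dendrite_track`.
#' @param mask Logical matrix from [binarize_for_breaks()].
#' @param config An [analysis_config()].
#' @return Tibble of breaks: `dendrite`, `y_start_um`, `y_end_um` (ROI
#'   coordinates measured from the top), `length_um`.
#' @export
detect_breaks <- function(track, mask, config = analysis_config()) {
  stopifnot(inherits(track, "dendrite_track"))
  um <- um_per_px(track$scale)
  tol <- max(0L, round(px_len(config$probe_tol_um, track$scale)))
  min_rows <- max(1L, round(px_len(config$min_break_um, track$scale)))
  nc <- ncol(mask)
  miss <- vapply(seq_along(track$rows), function(i) {
    r <- track$rows[i]
    c0 <- max(1L, floor(track$x[i] - tol))
    c1 <- min(nc, ceiling(track$x[i] + tol))
    !any(mask[r, c0:c1])
  }, TRUE)
  rl <- rle(miss)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  sel <- which(rl$values & rl$lengths >= min_rows)
  # pixel-extent convention: a run of k rows spans k*um, so
  # length == y_end - y_start holds exactly
  tibble::tibble(
    dendrite = rep(track$index, length(sel)),
    y_start_um = (track$rows[starts[sel]] - 0.5) * um,
    y_end_um = (track$rows[ends[sel]] + 0.5) * um,
    length_um = rl$lengths[sel] * um)
}

#' Match detected features to dendrites
#'
#' Each feature is assigned to the track minimizing the horizontal
#' distance between the feature centroid and the track's x position at
#' the feature's row, provided that distance is within a gating distance;
#' features beyond every gate are left unassigned (and excluded from
#' per-dendrite aggregates). Equidistant ties go to the lower index.
#'
#' @param features Feature tibble from [refine_features()].
#' @param tracks List of `dendrite_track`s from [finalize_tracks()].
#' @param config An [analysis_config()].
#' @return The feature tibble with `dendrite` filled in (NA = unassigned).
#' @export
match_features <- function(features, tracks, config = analysis_config()) {
  if (!nrow(features) || !length(tracks)) return(features)
  scale <- tracks[[1]]$scale
  gate <- px_len(config$match_gate_um, scale)
  for (i in seq_len(nrow(features))) {
    r <- features$.row_px[i]; x <- features$.col_px[i]
    best <- NA_integer_; bestd <- Inf
    for (t in tracks) {
      rr <- min(max(r, min(t$rows)), max(t$rows))
      tx <- t$x[which.min(abs(t$rows - rr))]
      d <- abs(x - tx)
      if (d < bestd - 1e-9) { bestd <- d; best <- t$index }
    }
    if (is.finite(bestd) && bestd <= gate) features$dendrite[i] <- best
  }
  n_un <- sum(is.na(features$dendrite))
  if (n_un) message(n_un, " feature(s) beyond the matching gate left unassigned")
  features
}

#' The twenty degeneration metrics, in report order
#' @export
metric_names <- function() c(
  "dendrite_length_um", "remaining_length_um", "percent_remaining",
  "break_count", "total_break_length_um", "largest_break_length_um",
  "mean_dendrite_intensity", "feature_count", "features_per_length",
  "features_per_remaining", "mean_feature_intensity",
  "total_feature_area_um2", "mean_feature_area_um2",
  "mean_feature_perimeter_um", "mean_feature_circularity",
  "mean_feature_extent", "mean_feature_eccentricity",
  "mean_min_caliper_um", "mean_max_caliper_um",
  "mean_normalized_feature_location")

#' Compute the per-dendrite degeneration report
#'
#' Aggregates one dendrite's track, breaks and matched features into the
#' twenty-metric record:
#' dendrite length (track arc length), remaining length (length minus
#' total break length), percent remaining, break count / total / largest,
#' mean dendrite intensity (native units, sampled along non-break track
#' rows of the original ROI), feature count and the two length-normalized
#' feature rates (per dendrite length and per *remaining* length -- the
#' "weighted feature count"), mean feature intensity, total/mean feature
#' area, mean perimeter, circularity, extent, eccentricity, min/max
#' caliper, and the mean normalized feature location (0 at the proximal
#' cell-body end, 1 at the distal tip). Feature aggregates are `NA` (not
#' zero) when no feature was matched; counts and rates are 0.
#'
#' @param roi The `dendrite_roi` (for native intensities).
#' @param track A `dendrite_track`.
#' @param breaks Tibble from [detect_breaks()] for this track.
#' @param features Matched feature tibble (all features; filtered to this
#'   dendrite internally).
#' @param config An [analysis_config()].
#' @return One-row tibble: `dendrite`, the 20 metrics, `categorical_score`,
#'   `unreliable`.
#' @export
compute_report <- function(roi, track, breaks, features,
                           config = analysis_config()) {
  stopifnot(inherits(track, "dendrite_track"))
  um <- um_per_px(track$scale)
  f <- track$scale$resize_factor
  dx <- diff(track$x)
  # pixel-extent convention (n rows span n*um, matching break lengths):
  # polyline arc length plus one row extent
  len <- (sum(sqrt(1 + dx^2)) + 1) * um
  brk <- breaks[breaks$dendrite == track$index, , drop = FALSE]
  total_break <- sum(brk$length_um)
  remaining <- max(len - total_break, 0)
  pct <- if (len > 0) 100 * remaining / len else 0
  # mean dendrite intensity along non-break rows, native units
  in_break <- rep(FALSE, length(track$rows))
  for (k in seq_len(nrow(brk))) {
    in_break <- in_break | (track$rows * um >= brk$y_start_um[k] &
                              track$rows * um <= brk$y_end_um[k])
  }
  rs <- track$rows[!in_break]; xs <- track$x[!in_break]
  dint <- if (length(rs)) {
    mean(bilinear_sample(roi$pixels, (rs - 0.5) / f + 0.5,
                         (xs - 0.5) / f + 0.5))
  } else NA_real_
  ft <- features[!is.na(features$dendrite) &
                   features$dendrite == track$index, , drop = FALSE]
  nf <- nrow(ft)
  # normalized location: arc distance from the proximal (bottom) end
  norm_loc <- if (nf) {
    arc <- cumsum(c(0, sqrt(1 + dx^2))) * um     # from top (distal)
    vapply(ft$.row_px, function(r) {
      i <- which.min(abs(track$rows - min(max(r, min(track$rows)),
                                          max(track$rows))))
      (len - arc[i]) / len
    }, 0)
  } else numeric()
  agg <- function(x) if (nf) mean(x) else NA_real_
  rep_row <- tibble::tibble(
    dendrite = track$index,
    dendrite_length_um = len,
    remaining_length_um = remaining,
    percent_remaining = pct,
    break_count = nrow(brk),
    total_break_length_um = total_break,
    largest_break_length_um = if (nrow(brk)) max(brk$length_um) else 0,
    mean_dendrite_intensity = dint,
    feature_count = nf,
    features_per_length = if (len > 0) nf / len else NA_real_,
    features_per_remaining = if (remaining > 0) nf / remaining else NA_real_,
    mean_feature_intensity = agg(ft$mean_intensity),
    total_feature_area_um2 = if (nf) sum(ft$area_um2) else NA_real_,
    mean_feature_area_um2 = agg(ft$area_um2),
    mean_feature_perimeter_um = agg(ft$perimeter_um),
    mean_feature_circularity = agg(ft$circularity),
    mean_feature_extent = agg(ft$extent),
    mean_feature_eccentricity = agg(ft$eccentricity),
    mean_min_caliper_um = agg(ft$min_caliper_um),
    mean_max_caliper_um = agg(ft$max_caliper_um),
    mean_normalized_feature_location = if (nf) mean(norm_loc) else NA_real_)
  rep_row$categorical_score <- score_degeneration(rep_row$percent_remaining,
                                                  rep_row$feature_count)
  rep_row$unreliable <- len < config$min_track_um
  rep_row
}

#' Categorical 0--4 degeneration score
#'
#' Bins the continuous metrics into the five-level categorical scale used
#' for manual scoring, with breakage taking precedence over blebbing (a
#' detected break makes the score at least 3):
#' percent remaining below 50 scores 4; between 50 and 85 (inclusive)
#' scores 3; above 85 the score depends on blebs only -- none scores 0,
#' one to four score 1, five or more score 2.
#'
#' @param percent_remaining Numeric vector, 0--100.
#' @param feature_count Integer vector (same length or length 1).
#' @return Integer vector of scores 0--4.
#' @examples
#' score_degeneration(c(100, 100, 100, 70, 30), c(0, 3, 8, 0, 10))
#' @export
score_degeneration <- function(percent_remaining, feature_count) {
  n <- max(length(percent_remaining), length(feature_count))
  p <- rep_len(percent_remaining, n)
  k <- rep_len(feature_count, n)
  stopifnot(all(is.finite(p)), all(is.finite(k)), all(k >= 0))
  out <- integer(n)
  out[p < 50] <- 4L
  out[p >= 50 & p <= 85] <- 3L
  up <- p > 85
  out[up & k == 0] <- 0L
  out[up & k >= 1 & k < 5] <- 1L
  out[up & k >= 5] <- 2L
  out
}

#' Write / read a dendrite report table
#'
#' RFC-4180 CSV with a header row: identifier columns (`image`,
#' `dendrite`), the twenty metric columns in canonical order,
#' `categorical_score` and `unreliable`. The reader restores the exact
#' column types, so a write/read round trip is value-identical.
#'
#' @param reports Tibble of reports (rows = dendrites).
#' @param path Output path.
#' @return `path` invisibly (writer); the report tibble (reader).
#' @export
write_report <- function(reports, path) {
  stopifnot(nrow(reports) >= 1)
  cols <- c("image", "dendrite", metric_names(), "categorical_score",
            "unreliable")
  missing <- setdiff(cols, names(reports))
  if (length(missing))
    stop("report is missing column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(reports[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (m in metric_names()) df[[m]] <- as.numeric(df[[m]])
  df$dendrite <- as.integer(df$dendrite)
  df$break_count <- as.integer(df$break_count)
  df$feature_count <- as.integer(df$feature_count)
  df$categorical_score <- as.integer(df$categorical_score)
  df$unreliable <- as.logical(df$unreliable)
  tibble::as_tibble(df)
}
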