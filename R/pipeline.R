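#' Analyze one projection image
#'
#' Full pipeline on a single image: crop to the dendrite ROI, enhance,
#' detect bleb features, trace the dendrites, detect breaks, match
#' features to dendrites and compute the per-dendrite twenty-metric
#' report with its categorical score.
#'
#' @param img A `projection_image` (from [load_image()] or
#'   [render_phantom()]), or a file path (then `scale` is required).
#' @param scale A [pixel_scale()]; ignored when `img` is already a
#'   `projection_image`.
#' @param config An [analysis_config()].
#' @return A `cep_analysis` list: `reports` (tibble, one row per
#'   dendrite), `features`, `tracks`, `breaks`, `roi`, `eroi`.
#' @export
analyze_image <- function(img, scale = NULL, config = analysis_config()) {
  if (is.character(img)) {
    stopifnot(!is.null(scale))
    img <- load_image(img, scale)
  }
  stopifnot(inherits(img, "projection_image"))
  roi <- crop_dendrites(img, config)
  det <- detect_features(roi, config)
  tracks <- track_dendrites(det$eroi, config)
  if (!length(tracks)) stop("no dendrites could be tracked")
  bmask <- binarize_for_breaks(det$eroi, config)
  breaks <- dplyr::bind_rows(lapply(tracks, detect_breaks, mask = bmask,
                                    config = config))
  features <- match_features(det$features, tracks, config)
  reports <- dplyr::bind_rows(lapply(tracks, function(t)
    compute_report(roi, t, breaks, features, config)))
  reports <- tibble::add_column(reports, image = img$source_path,
                                .before = 1)
  structure(list(reports = reports, features = features, tracks = tracks,
                 breaks = breaks, roi = roi, eroi = det$eroi,
                 image = img$source_path),
            class = "cep_analysis")
}

#' @export
print.cep_analysis <- function(x, ...) {
  cat(sprintf("<cep_analysis> %s: %d dendrite(s), %d feature(s), %d break(s)\n",
              x$image, length(x$tracks), nrow(x$features), nrow(x$breaks)))
  print(x$reports[, c("dendrite", "dendrite_length_um", "percent_remaining",
                      "feature_count", "categorical_score")])
  invisible(x)
}

#' Tidy an analysis: the per-dendrite report tibble
#' @param x A `cep_analysis`.
#' @param ... Unused.
#' @export
tidy.cep_analysis <- function(x, ...) x$reports

#' Glance at an analysis: one-row image summary
#' @param x A `cep_analysis`.
#' @param ... Unused.
#' @export
glance.cep_analysis <- function(x, ...) {
  tibble::tibble(image = x$image, n_dendrites = length(x$tracks),
                 n_features = nrow(x$features), n_breaks = nrow(x$breaks),
                 mean_percent_remaining = mean(x$reports$percent_remaining),
                 max_score = max(x$reports$categorical_score))
}

#' Analyze a batch of images
#'
#' Runs [analyze_image()] on each input. Images that fail the error checks
#' (no cell body, multiple worms, no dendrites, blank frame) are logged
#' and skipped rather than aborting the batch; per-image outcomes are
#' returned alongside the combined report.
#'
#' @param paths Character vector of image paths, or a list of
#'   `projection_image` objects.
#' @param scale A [pixel_scale()] (required for paths).
#' @param config An [analysis_config()].
#' @return A `cep_batch` list: `reports` (combined tibble), `log` (tibble
#'   of per-image status), `analyses` (list of `cep_analysis` for the
#'   successes).
#' @export
run_pipeline <- function(paths, scale = NULL, config = analysis_config()) {
  stopifnot(length(paths) >= 1)
  if (!is.list(paths)) paths <- as.list(paths)
  results <- list(); logs <- list(); analyses <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    id <- if (is.character(p)) p else
      if (inherits(p, "projection_image")) p$source_path else sprintf("input %d", i)
    res <- tryCatch(analyze_image(p, scale, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", id, ": ", conditionMessage(res))
      logs[[i]] <- tibble::tibble(image = id, status = "skipped",
                                  reason = conditionMessage(res),
                                  n_dendrites = 0L)
    } else {
      logs[[i]] <- tibble::tibble(image = id, status = "ok",
                                  reason = NA_character_,
                                  n_dendrites = length(res$tracks))
      results[[length(results) + 1]] <- res$reports
      analyses[[length(analyses) + 1]] <- res
    }
  }
  log <- dplyr::bind_rows(logs)
  if (!length(results)) {
    stop("all images failed:\n",
         paste(sprintf("  %s: %s", log$image, log$reason), collapse = "\n"))
  }
  structure(list(reports = dplyr::bind_rows(results), log = log,
                 analyses = analyses),
            class = "cep_batch")
}

#' @export
print.cep_batch <- function(x, ...) {
  cat(sprintf("<cep_batch> %d image(s): %d ok, %d skipped; %d dendrite reports\n",
              nrow(x$log), sum(x$log$status == "ok"),
              sum(x$log$status == "skipped"), nrow(x$reports)))
  invisible(x)
}

#' Tidy a batch: the combined report tibble
#' @param x A `cep_batch`.
#' @param ... Unused.
#' @export
tidy.cep_batch <- function(x, ...) x$reports

#' Glance at a batch: run counts
#' @param x A `cep_batch`.
#' @param ... Unused.
#' @export
glance.cep_batch <- function(x, ...) {
  tibble::tibble(n_images = nrow(x$log),
                 n_ok = sum(x$log$status == "ok"),
                 n_skipped = sum(x$log$status == "skipped"),
                 n_dendrites = nrow(x$reports))
}

#' Write per-image feature/track geometry as a JSON sidecar
#'
#' @param analysis A `cep_analysis`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(analysis, path) {
  stopifnot(inherits(analysis, "cep_analysis"))
  feats <- analysis$features
  feats <- feats[, setdiff(names(feats), c(".row_px", ".col_px"))]
  obj <- list(
    image = analysis$image,
    features = feats,
    tracks = lapply(analysis$tracks, function(t) tidy(t)),
    breaks = analysis$breaks)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
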