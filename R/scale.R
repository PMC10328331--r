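#' Physical pixel scale
#'
#' Records the camera pixel size and any internal resize factor. Every
#' size-dependent parameter in the pipeline is expressed in micrometres and
#' converted to pixels through this object, which is what makes the
#' analysis portable across microscopy setups (63x vs 40x objectives,
#' different cameras) without retuning.
#'
#' @param microns_per_pixel Positive scalar, camera pixel size in um/px.
#' @param resize_factor Positive integer; internal upsampling factor
#'   (the feature-detection stage works at 4x). Default 1.
#' @return A `pixel_scale` object.
#' @examples
#' pixel_scale(0.1)
#' @export
pixel_scale <- function(microns_per_pixel, resize_factor = 1L) {
  stopifnot(is.numeric(microns_per_pixel), length(microns_per_pixel) == 1,
            is.finite(microns_per_pixel), microns_per_pixel > 0)
  resize_factor <- as.integer(resize_factor)
  stopifnot(length(resize_factor) == 1, resize_factor >= 1)
  structure(list(microns_per_pixel = as.numeric(microns_per_pixel),
                 resize_factor = resize_factor),
            class = "pixel_scale")
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("<pixel_scale> %.4g um/px (resize %dx, effective %.4g um/px)\n",
              x$microns_per_pixel, x$resize_factor, um_per_px(x)))
  invisible(x)
}

# effective um per pixel at the current working resolution
um_per_px <- function(scale) scale$microns_per_pixel / scale$resize_factor

# convert a physical length (um) to pixels at the working resolution
px_len <- function(um, scale) um / um_per_px(scale)

# odd integer >= 1 approximating a physical length in pixels
odd_px <- function(um, scale) {
  n <- max(1L, round(px_len(um, scale)))
  if (n %% 2L == 0L) n + 1L else as.integer(n)
}

#' Analysis configuration
#'
#' All tunable parameters of the pipeline in one flat list. Every length is
#' in micrometres (never raw pixels); intensities are fractions of the
#' image dynamic range. Defaults are documented per argument and motivated
#' in the methods vignette.
#'
#' @param stretch_quantiles Length-2 numeric; intensity quantiles mapped to
#'   the full bit range by the initial global contrast stretch.
#' @param soma_level_frac Brightest-pixel threshold for cell-body
#'   segmentation, as a fraction of the full (stretched) dynamic range.
#' @param soma_min_area_um2 Minimum area (um^2) of a soma candidate.
#' @param soma_min_width_um Minimum minor-axis width (um) of a soma
#'   candidate (rejects bright ridge crests of dendrites).
#' @param multiworm_link_um Single-linkage distance (um) beyond which
#'   surviving soma clusters are treated as separate worms (an error:
#'   exactly one worm may be in frame).
#' @param side_major_axis_um Minimum major-axis length (um) for a component
#'   to count as dendrite-like evidence during side selection.
#' @param side_orient_tol_deg Maximum deviation from vertical (degrees) for
#'   dendrite-like evidence.
#' @param side_circ_max Maximum circularity (4*pi*A/P^2) for dendrite-like
#'   evidence.
#' @param soma_circ_cutoff,soma_area_cutoff_um2 A component with
#'   circularity above the first AND area above the second is treated as a
#'   residual soma fragment and removed from the ROI.
#' @param crop_margin_um Margin (um) kept around the dendrite bounding box
#'   in the final crop.
#' @param clahe_clip Clip limit of the local contrast enhancement (CLAHE).
#' @param clahe_noise_ref Noise scale (fraction of range) controlling how
#'   strongly the CLAHE output is blended with the original: the blend
#'   weight is `1 / (1 + noise / clahe_noise_ref)`, so noisier images are
#'   enhanced more gently.
#' @param clahe_tile_um Approximate CLAHE tile size (um).
#' @param tophat_radius_um Disc radius (um) of the white top-hat background
#'   subtraction.
#' @param resize_factor Upsampling factor of the feature-detection stage.
#' @param k_noise Multiplier on the estimated noise level added to the Otsu
#'   level when thresholding dendrites (noisier image, higher threshold).
#' @param erode_len_um Length (um) of the horizontal erosion element that
#'   removes thin vertical dendrites; roughly 2x the nominal dendrite width
#'   so only wider-than-dendrite features survive.
#' @param min_feature_area_um2 Minimum area (um^2) of a feature seed.
#' @param cv_iterations Chan-Vese iteration budget per seed.
#' @param cv_init_dilate_um Dilation (um) of the seed used as the initial
#'   contour.
#' @param cv_pad_um Window padding (um) around a seed for contour
#'   evolution.
#' @param peak_prom_mult Prominence floor for row maxima, as a multiple of
#'   the recorded noise level.
#' @param peak_min_sep_um Minimum separation (um) between row maxima.
#' @param vclose_um Length (um) of the vertical closing element bridging
#'   detection dropouts along a dendrite.
#' @param hbridge_um Half-width (um) of the small horizontal dilation that
#'   stabilizes track connectivity before vertical closing.
#' @param ema_weight Weight of the exponential moving average tracking each
#'   dendrite's running x position.
#' @param gate_um Gating distance (um) for assigning a point to a dendrite.
#' @param seed_row_frac New dendrites may only be seeded within this
#'   leading fraction of rows (distal region).
#' @param smooth_window_um Moving-average smoothing window (um) for
#'   finalized tracks.
#' @param break_thresh_frac Break binarization threshold as a fraction of
#'   the feature-detection threshold (permissive on purpose: the question
#'   is "any dendrite signal here?", not shape).
#' @param probe_tol_um Lateral tolerance (um) around the track when probing
#'   the break mask.
#' @param min_break_um Minimum break length (um); shorter dropouts are
#'   sensor noise.
#' @param match_gate_um Maximum distance (um) between a feature and a track
#'   for the feature to be assigned to that dendrite.
#' @param min_track_um Tracks shorter than this (um) yield reports flagged
#'   unreliable.
#' @param seed Integer seed for any stochastic steps (none in the core
#'   pipeline; kept for reproducibility of optional extras).
#' @return A named list with class `analysis_config`.
#' @examples
#' cfg <- analysis_config()
#' cfg$erode_len_um
#' @export
analysis_config <- function(stretch_quantiles = c(0.005, 0.999),
                            soma_level_frac = 0.8,
                            soma_min_area_um2 = 4,
                            soma_min_width_um = 1.5,
                            multiworm_link_um = 25,
                            side_major_axis_um = 10,
                            side_orient_tol_deg = 30,
                            side_circ_max = 0.5,
                            soma_circ_cutoff = 0.8,
                            soma_area_cutoff_um2 = 4,
                            crop_margin_um = 2,
                            clahe_clip = 2,
                            clahe_noise_ref = 0.02,
                            clahe_tile_um = 16,
                            tophat_radius_um = 2,
                            resize_factor = 4L,
                            k_noise = 1.0,
                            erode_len_um = 1.4,
                            min_feature_area_um2 = 0.25,
                            cv_iterations = 60L,
                            cv_init_dilate_um = 0.3,
                            cv_pad_um = 3,
                            peak_prom_mult = 2,
                            peak_min_sep_um = 1.0,
                            vclose_um = 5,
                            hbridge_um = 0.1,
                            ema_weight = 0.1,
                            gate_um = 2,
                            seed_row_frac = 0.25,
                            smooth_window_um = 2,
                            break_thresh_frac = 0.5,
                            probe_tol_um = 0.5,
                            min_break_um = 0.5,
                            match_gate_um = 2,
                            min_track_um = 5,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$stretch_quantiles) == 2,
            cfg$stretch_quantiles[1] < cfg$stretch_quantiles[2],
            cfg$soma_level_frac > 0, cfg$soma_level_frac < 1,
            cfg$erode_len_um > 0, cfg$k_noise >= 0,
            cfg$resize_factor >= 1)
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a flat key = value text file
#'
#' Lines of the form `name = value`; `#` starts a comment. Unknown keys are
#' an error. Values are parsed as numeric (length-2 values comma-separated).
#'
#' @param path Path to the configuration file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) return(analysis_config())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- lapply(kv, function(p) as.numeric(strsplit(trimws(p[2]), ",")[[1]]))
  known <- names(formals(analysis_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, stats::setNames(vals, keys))
}
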