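# End-to-end analysis: folder -> per-ROI -> per-image -> per-episode
# tables, under a single validated configuration.

#' Pipeline configuration
#'
#' All tunables of the analysis in one validated, serialisable object.
#' Defaults are the package's declared analysis conditions.
#'
#' @param channels `"ab"` (default; the hue plane, robust to overall
#'   lightness changes) or `"lab"` (all three channels).
#' @param method BD estimator: `"histogram"` (default) or `"gaussian"`.
#' @param window_minutes Episode window for `mode = "window"`
#'   (default 30).
#' @param episode_mode `"window"` (timestamp chaining) or `"app"`
#'   (attack-record delimited).
#' @param inset_frac ROI inset margin as a fraction of local digit width
#'   (default 0.2).
#' @param min_pixels Minimum pixels per usable ROI / distribution
#'   (default 50).
#' @param bd_cap Sentinel replacing infinite BD (default 50).
#' @param seed Integer seed recorded in provenance.
#' @param exclusion_file Optional plain-text exclusion list.
#' @param dorsal_only Analyse only images whose aspect metadata is
#'   `"dorsal"` or `"unknown"` (default TRUE drops palmar views).
#' @return A validated `rp_config` list.
#' @export
rp_config <- function(channels = c("ab", "lab"),
                      method = c("histogram", "gaussian"),
                      window_minutes = 30,
                      episode_mode = c("window", "app"),
                      inset_frac = 0.2,
                      min_pixels = 50,
                      bd_cap = 50,
                      seed = 1L,
                      exclusion_file = NULL,
                      dorsal_only = TRUE) {
  channels <- match.arg(channels)
  method <- match.arg(method)
  episode_mode <- match.arg(episode_mode)
  if (!is.numeric(window_minutes) || window_minutes <= 0) {
    stop("invalid config field 'window_minutes': must be > 0")
  }
  if (inset_frac < 0 || inset_frac >= 0.5) {
    stop("invalid config field 'inset_frac': must be in [0, 0.5)")
  }
  if (min_pixels < 1) stop("invalid config field 'min_pixels': must be >= 1")
  if (bd_cap <= 0) stop("invalid config field 'bd_cap': must be > 0")
  structure(
    list(
      channels = channels, method = method,
      window_minutes = window_minutes, episode_mode = episode_mode,
      inset_frac = inset_frac, min_pixels = min_pixels, bd_cap = bd_cap,
      seed = as.integer(seed), exclusion_file = exclusion_file,
      dorsal_only = dorsal_only
    ),
    class = "rp_config"
  )
}

#' Read / write a pipeline configuration
#'
#' Plain YAML with full defaulting: fields absent from the file take the
#' [rp_config()] defaults, so a config round-trips losslessly.
#'
#' @param path YAML file path.
#' @return [read_config()] returns an `rp_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(rp_config)))
  do.call(rp_config, vals[keep])
}

#' @rdname read_config
#' @param config An `rp_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "rp_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.channel_set <- function(config) {
  if (config$channels == "ab") c("a", "b") else c("L", "a", "b")
}

#' Analyse an app-style data folder end to end
#'
#' Runs the full measurement chain on every analysable image: ROI layout
#' (landmark sidecar first, built-in segmentation as fallback), pixel
#' extraction, L*a*b* conversion, per-ROI Bhattacharyya distance against
#' the dorsal reference, per-image mean BD, episode grouping, and
#' per-episode mean BD joined to questionnaire data (per-attack severity
#' in app mode; the day's RCS in window mode).
#'
#' @param root Dataset root (layout as in [generate_dataset()] /
#'   [scan_app_folder()]).
#' @param config An [rp_config()].
#' @param out_dir Optional directory; when given, the per-ROI, per-image
#'   and per-episode tables are written as CSV together with a
#'   provenance record (config, seed, package version).
#' @return List of class `rp_analysis`: tibbles `roi` (one row per
#'   image-ROI), `images` (per-image mean BD), `episodes` (per-episode
#'   mean BD with severity/RCS), `skipped` (unanalysable images), the
#'   `config` and the `summary` ([summary_report()]).
#' @export
analyze_folder <- function(root, config = rp_config(), out_dir = NULL) {
  stopifnot(inherits(config, "rp_config"))
  scan <- scan_app_folder(root)
  images <- apply_exclusion_list(scan$images, config$exclusion_file)
  if (config$dorsal_only) {
    images <- images[images$aspect != "palmar", , drop = FALSE]
  }
  if (!nrow(images)) stop("zero analysable images in ", root)
  channels <- .channel_set(config)
  breaks <- bd_breaks(channels)
  roi_rows <- vector("list", nrow(images))
  img_flags <- character(nrow(images))
  for (i in seq_len(nrow(images))) {
    img <- read_hand_image(images$path[i], patient_id = images$patient_id[i],
                           aspect = images$aspect[i])
    img$timestamp <- images$timestamp[i] # scan already resolved provenance
    rois <- tryCatch(
      rois_for_image(img, inset_frac = config$inset_frac,
                     min_pixels = config$min_pixels),
      error = function(e) NULL
    )
    if (is.null(rois)) {
      img_flags[i] <- "unanalysable"
      next
    }
    px <- extract_roi_pixels(img, rois)
    bd <- roi_bd(px, channels = channels, method = config$method,
                 breaks = breaks, min_pixels = config$min_pixels,
                 cap = config$bd_cap)
    bd$patient_id <- images$patient_id[i]
    bd$source_path <- images$path[i]
    bd$timestamp <- images$timestamp[i]
    roi_rows[[i]] <- bd
  }
  roi_tbl <- dplyr::bind_rows(roi_rows)
  skipped <- images[img_flags == "unanalysable", , drop = FALSE]
  if (!nrow(roi_tbl)) stop("zero analysable images in ", root)
  img_bd <- image_mean_bd(roi_tbl)
  img_meta <- dplyr::left_join(
    images[images$path %in% img_bd$source_path, , drop = FALSE],
    img_bd[, c("source_path", "mean_bd", "n_rois")],
    by = c("path" = "source_path")
  )
  grouped <- if (config$episode_mode == "window") {
    group_by_window(img_meta, window_minutes = config$window_minutes)
  } else {
    group_by_app(img_meta, scan$attacks)
  }
  episodes <- episode_mean_bd(grouped)
  if (config$episode_mode == "window" && nrow(scan$attacks)) {
    # join severity of the attack whose end time falls just after the
    # episode (window mode still benefits from app records when present)
    episodes$severity <- vapply(seq_len(nrow(episodes)), function(j) {
      a <- scan$attacks[scan$attacks$patient_id == episodes$patient_id[j], ]
      if (!nrow(a)) return(NA_integer_)
      ok <- which(a$end_time >= episodes$end[j] &
                    a$end_time <= episodes$end[j] + 30 * 60)
      if (length(ok)) as.integer(a$severity[ok[1]]) else NA_integer_
    }, integer(1))
  }
  if (nrow(scan$daily)) {
    daily <- scan$daily[, c("patient_id", "date", "rcs")]
    episodes$date <- format(episodes$start, "%Y-%m-%d", tz = "UTC")
    episodes <- dplyr::left_join(episodes, daily,
                                 by = c("patient_id", "date"))
  }
  episodes$mode <- config$episode_mode
  res <- structure(
    list(
      roi = roi_tbl, images = img_meta, episodes = episodes,
      skipped = skipped, config = config,
      summary = summary_report(episodes, img_meta)
    ),
    class = "rp_analysis"
  )
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @export
print.rp_analysis <- function(x, ...) {
  cat("<rp_analysis>\n")
  print(x$summary)
  if (nrow(x$skipped)) cat(nrow(x$skipped), "image(s) skipped as unanalysable\n")
  invisible(x)
}

#' Write analysis tables and provenance to a directory
#'
#' @param analysis An `rp_analysis`.
#' @param out_dir Destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(analysis$roi, file.path(out_dir, "roi_bd.csv"))
  readr::write_csv(analysis$images, file.path(out_dir, "image_bd.csv"))
  readr::write_csv(analysis$episodes, file.path(out_dir, "episode_bd.csv"))
  prov <- list(
    package = "raynaudbd",
    version = as.character(utils::packageVersion("raynaudbd")),
    config = unclass(analysis$config),
    n_images = nrow(analysis$images),
    n_episodes = nrow(analysis$episodes)
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
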