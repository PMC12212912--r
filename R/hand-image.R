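# Core containers: a decoded hand photograph and a labelled ROI set.

#' Construct a hand image object
#'
#' A decoded photograph plus its capture metadata. Pixels are stored as an
#' H x W x 3 array of sRGB values in \[0, 255\] (row = image y, top-down;
#' column = image x, left-right), exactly as taken — no colour processing
#' is applied on ingest.
#'
#' @param pixels H x W x 3 numeric array, sRGB in \[0, 255\].
#' @param timestamp Capture time (`POSIXct`) or `NA` if unknown.
#' @param patient_id Patient identifier string.
#' @param source_path Provenance: where the raster came from.
#' @param aspect `"dorsal"`, `"palmar"` or `"unknown"` — supplied as
#'   metadata, never inferred from the image.
#' @param timestamp_source `"exif"`, `"mtime"`, `"synthetic"` or `"none"`.
#' @return A `hand_image` object.
#' @export
hand_image <- function(pixels, timestamp = as.POSIXct(NA),
                       patient_id = NA_character_,
                       source_path = NA_character_,
                       aspect = c("unknown", "dorsal", "palmar"),
                       timestamp_source = "none") {
  aspect <- match.arg(aspect)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (any(pixels < -1e-6 | pixels > 255 + 1e-6)) {
    stop("pixel values outside [0, 255]; expected 8-bit sRGB")
  }
  structure(
    list(
      pixels = pixels, timestamp = timestamp, patient_id = patient_id,
      source_path = source_path, aspect = aspect,
      timestamp_source = timestamp_source
    ),
    class = "hand_image"
  )
}

#' @export
print.hand_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<hand_image %dx%d, patient %s, %s, taken %s (%s)>\n",
    d[2], d[1], x$patient_id, x$aspect,
    if (is.na(x$timestamp)) "unknown" else .format_exif_time(x$timestamp),
    x$timestamp_source
  ))
  invisible(x)
}

#' Construct an ROI set
#'
#' A label image over the photograph: 0 = background, 1-24 = digit ROIs
#' (three per digit — distal, middle, proximal — on eight non-thumb
#' digits across the two hands), 25 = the dorsal reference ROI. Labels
#' are mutually exclusive by construction (one integer per pixel).
#'
#' @param labels Integer matrix (H x W) of ROI labels.
#' @param digit_of_roi Tibble mapping `roi_id` to `digit` (1-8, left to
#'   right) and `part` (`"distal"`, `"middle"`, `"proximal"`, or
#'   `"reference"`).
#' @param min_pixels ROIs with fewer pixels are flagged degenerate
#'   (default 50).
#' @param partial TRUE when fewer digits than expected were resolvable.
#' @return An `roi_set` with per-ROI pixel counts and degeneracy flags.
#' @export
roi_set <- function(labels, digit_of_roi, min_pixels = 50, partial = FALSE) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  counts <- tibble::tibble(
    roi_id = ids,
    n_pixels = vapply(ids, function(i) sum(labels == i), integer(1))
  )
  counts$degenerate <- counts$n_pixels < min_pixels
  structure(
    list(
      labels = labels,
      digit_of_roi = tibble::as_tibble(digit_of_roi),
      n_pixels = counts,
      partial = partial
    ),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  n_digit <- sum(x$n_pixels$roi_id <= 24)
  cat(sprintf(
    "<roi_set: %d digit ROIs + %d reference, %d degenerate%s>\n",
    n_digit, sum(x$n_pixels$roi_id == 25L),
    sum(x$n_pixels$degenerate),
    if (isTRUE(x$partial)) ", partial" else ""
  ))
  invisible(x)
}

#' Extract per-ROI pixel values
#'
#' Masks the image with the ROI label matrix and returns a tidy table of
#' sRGB values, one row per pixel, tagged with its ROI. Extraction is a
#' pure lookup: counts match mask areas exactly and pixel order carries no
#' meaning downstream (all statistics are permutation-invariant).
#'
#' @param image A [hand_image()].
#' @param rois An [roi_set()] with labels matching the image dimensions.
#' @return Tibble: `roi_id`, `digit`, `part`, `R`, `G`, `B`.
#' @export
extract_roi_pixels <- function(image, rois) {
  stopifnot(inherits(image, "hand_image"), inherits(rois, "roi_set"))
  d <- dim(image$pixels)
  if (!all(dim(rois$labels) == d[1:2])) {
    stop("ROI label matrix does not match image dimensions")
  }
  sel <- rois$labels > 0L
  idx <- which(sel)
  out <- tibble::tibble(
    roi_id = as.integer(rois$labels[idx]),
    R = image$pixels[, , 1][idx],
    G = image$pixels[, , 2][idx],
    B = image$pixels[, , 3][idx]
  )
  out <- dplyr::left_join(out, rois$digit_of_roi, by = "roi_id")
  dplyr::select(out, "roi_id", "digit", "part", "R", "G", "B")
}
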