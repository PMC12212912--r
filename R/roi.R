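# ROI geometry: from a hand outline to the 25-ROI layout.
#
# The layout rule: each of the eight non-thumb digits (two hands
# photographed together) carries three ROIs — distal, middle and proximal
# thirds of its vertical extent, inset from the border — giving 24 digit
# ROIs, plus one dorsal reference ROI centred on the dorsum of the larger
# hand, an area typically unaffected by vasospasm.

#' Segment a hand outline from a fixture-style image
#'
#' Fallback segmentation for images with a near-uniform background (the
#' synthetic fixtures): estimates the background colour from the image
#' border, thresholds on Delta-E distance to it in L*a*b*, cleans up with
#' morphological opening, and traces the border of each sufficiently
#' large connected component. Externally fitted landmark sidecar files
#' are the faithful path for real photographs and take precedence in
#' [rois_for_image()].
#'
#' @param image A [hand_image()].
#' @param delta_e_threshold Foreground threshold on Delta-E to the
#'   background estimate (default 12).
#' @param min_component_frac Components smaller than this fraction of the
#'   image are discarded (default 0.02).
#' @param every Keep every `every`-th border point (default 3).
#' @return Landmark tibble (`point_index`, `x`, `y`, `label`), one
#'   `label` per detected hand ordered left to right. If no hand-like
#'   component is found the tibble is empty and carries attribute
#'   `unanalysable = TRUE`.
#' @export
segment_hand <- function(image, delta_e_threshold = 12,
                         min_component_frac = 0.02, every = 3L) {
  stopifnot(inherits(image, "hand_image"))
  d <- dim(image$pixels)
  h <- d[1]; w <- d[2]
  rgbm <- cbind(c(image$pixels[, , 1]), c(image$pixels[, , 2]),
                c(image$pixels[, , 3]))
  lab <- as.matrix(srgb_to_lab(rgbm))
  border <- matrix(FALSE, h, w)
  border[c(1, 2, h - 1, h), ] <- TRUE
  border[, c(1, 2, w - 1, w)] <- TRUE
  bg <- apply(lab[c(border), , drop = FALSE], 2, stats::median)
  dist <- sqrt(rowSums(sweep(lab, 2, bg)^2))
  fg <- matrix(dist > delta_e_threshold, h, w)
  img <- EBImage::Image(t(fg))
  img <- EBImage::opening(img, EBImage::makeBrush(3, "box"))
  labels <- EBImage::bwlabel(img)
  tab <- table(labels[labels > 0])
  keep <- as.integer(names(tab)[tab >= min_component_frac * h * w])
  if (!length(keep)) {
    out <- tibble::tibble(point_index = integer(), x = numeric(),
                          y = numeric(), label = character())
    attr(out, "unanalysable") <- TRUE
    warning("no hand-like component found; image flagged unanalysable")
    return(out)
  }
  # order components left to right; at most two hands
  cx <- vapply(keep, function(k) mean(which(labels == k, arr.ind = TRUE)[, 1]),
               numeric(1))
  keep <- keep[order(cx)]
  if (length(keep) > 2) keep <- keep[seq_len(2)]
  out <- purrr::imap_dfr(keep, function(k, i) {
    cont <- EBImage::ocontour(EBImage::Image(t(t(labels) == k)))[[1]]
    sel <- seq(1, nrow(cont), by = every)
    tibble::tibble(
      point_index = seq_along(sel),
      x = cont[sel, 1] + 1,
      y = cont[sel, 2] + 1,
      label = paste0("hand", i)
    )
  })
  attr(out, "unanalysable") <- FALSE
  out
}

#' Define the 25-ROI layout from hand-border landmarks
#'
#' Rasterises each hand's border polygon, locates the palm as the band of
#' rows whose filled width is at least 60% of the hand's maximum width,
#' identifies digits as the connected components above the palm, and lays
#' three inset ROIs (distal/middle/proximal thirds) along each digit.
#' Digits are numbered 1-8 left to right across the two hands. The dorsal
#' reference ROI (label 25) is centred on the palm of the hand with the
#' larger filled area.
#'
#' @param landmarks Landmark tibble as from [segment_hand()] or
#'   [read_landmarks()].
#' @param image_size (width, height) of the parent image in pixels.
#' @param inset_frac ROIs are inset from the digit border by this
#'   fraction of the local digit width (default 0.2).
#' @param min_pixels Minimum usable ROI area (default 50); smaller ROIs
#'   are flagged degenerate.
#' @param digits_per_hand Expected digit count per hand (default 4,
#'   non-thumb digits). Fewer resolvable digits yields a partial ROI set.
#' @return An [roi_set()]; `partial` is TRUE when fewer than
#'   `2 * digits_per_hand` digits were resolvable.
#' @export
define_rois <- function(landmarks, image_size, inset_frac = 0.2,
                        min_pixels = 50, digits_per_hand = 4) {
  stopifnot(all(c("x", "y", "label") %in% names(landmarks)))
  w <- image_size[1]; h <- image_size[2]
  hands <- split(landmarks, landmarks$label)
  # preserve left-to-right order by each polygon's mean x
  hands <- hands[order(vapply(hands, function(p) mean(p$x), numeric(1)))]
  masks <- lapply(hands, function(p) {
    if (nrow(p) < 3) stop("degenerate landmarks: fewer than 3 points")
    area <- abs(sum(p$x * c(p$y[-1], p$y[1]) - c(p$x[-1], p$x[1]) * p$y)) / 2
    if (area < 9) stop("degenerate landmarks: collinear or near-zero-area outline")
    .fill_polygon(p$x, p$y, w, h)
  })
  labels <- matrix(0L, h, w)
  parts <- c("distal", "middle", "proximal")
  map <- list()
  digit_idx <- 0L
  n_expected <- 2L * digits_per_hand # full layout: both hands in frame
  palm_info <- vector("list", length(masks))
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    width_of_row <- rowSums(m)
    if (!any(width_of_row > 0)) next
    palm_rows <- which(width_of_row >= 0.6 * max(width_of_row))
    palm_info[[k]] <- list(rows = palm_rows, area = sum(m))
    digit_region <- m
    digit_region[min(palm_rows):h, ] <- FALSE
    comp <- EBImage::bwlabel(EBImage::Image(t(digit_region)))
    comp <- t(EBImage::imageData(comp))
    tab <- table(comp[comp > 0])
    ids <- as.integer(names(tab)[tab >= 30])
    if (!length(ids)) next
    cx <- vapply(ids, function(i) mean(which(comp == i, arr.ind = TRUE)[, 2]),
                 numeric(1))
    ids <- ids[order(cx)]
    for (i in ids) {
      digit_idx <- digit_idx + 1L
      px <- which(comp == i, arr.ind = TRUE)
      rows <- range(px[, 1])
      cuts <- round(seq(rows[1], rows[2] + 1, length.out = 4))
      width <- diff(range(px[, 2])) + 1
      margin <- max(1L, round(inset_frac * width))
      for (p in 1:3) {
        roi_id <- (digit_idx - 1L) * 3L + p
        lo <- cuts[p] + 2L
        hi <- cuts[p + 1] - 3L
        sel <- px[px[, 1] >= lo & px[, 1] <= hi, , drop = FALSE]
        if (nrow(sel)) {
          for (rr in unique(sel[, 1])) {
            xs <- sel[sel[, 1] == rr, 2]
            keep <- xs[xs >= min(xs) + margin & xs <= max(xs) - margin]
            labels[rr, keep] <- roi_id
          }
        }
        map[[length(map) + 1]] <- tibble::tibble(
          roi_id = roi_id, digit = digit_idx, part = parts[p]
        )
      }
    }
  }
  if (digit_idx == 0) stop("no digits resolvable from landmarks")
  # dorsal reference: central box of the larger hand's palm
  areas <- vapply(palm_info, function(x) if (is.null(x)) 0 else x$area, numeric(1))
  k <- which.max(areas)
  m <- masks[[k]]
  prows <- palm_info[[k]]$rows
  row_lo <- round(min(prows) + 0.25 * diff(range(prows)))
  row_hi <- round(max(prows) - 0.25 * diff(range(prows)))
  for (rr in row_lo:row_hi) {
    xs <- which(m[rr, ])
    if (!length(xs)) next
    span <- max(xs) - min(xs)
    keep <- xs[xs >= min(xs) + 0.25 * span & xs <= max(xs) - 0.25 * span]
    labels[rr, keep] <- 25L
  }
  map[[length(map) + 1]] <- tibble::tibble(
    roi_id = 25L, digit = NA_integer_, part = "reference"
  )
  roi_set(labels, dplyr::bind_rows(map), min_pixels = min_pixels,
          partial = digit_idx < n_expected)
}

#' Resolve ROIs for an image: landmark sidecar first, fallback second
#'
#' If a `<image>_landmarks.csv` sidecar exists next to the source file it
#' wins; otherwise the built-in [segment_hand()] fallback is used.
#'
#' @param image A [hand_image()].
#' @param ... Passed to [define_rois()].
#' @return An [roi_set()], or `NULL` (with a warning) when the image is
#'   unanalysable.
#' @export
rois_for_image <- function(image, ...) {
  d <- dim(image$pixels)
  sidecar <- if (!is.na(image$source_path)) .landmark_sidecar(image$source_path)
  lm <- if (!is.null(sidecar) && file.exists(sidecar)) {
    read_landmarks(sidecar, image_size = c(d[2], d[1]))
  } else {
    segment_hand(image)
  }
  if (isTRUE(attr(lm, "unanalysable")) || nrow(lm) == 0) return(NULL)
  define_rois(lm, image_size = c(d[2], d[1]), ...)
}

# Rasterise a polygon (1-based pixel coordinates) into an H x W logical
# mask using even-odd point-in-polygon tests on pixel centres.
.fill_polygon <- function(px, py, w, h) {
  bnd <- list(x = c(px, px[1]), y = c(py, py[1]))
  x0 <- max(1L, floor(min(px))); x1 <- min(w, ceiling(max(px)))
  y0 <- max(1L, floor(min(py))); y1 <- min(h, ceiling(max(py)))
  grid <- expand.grid(x = x0:x1, y = y0:y1)
  inside <- mgcv::in.out(cbind(bnd$x, bnd$y), cbind(grid$x, grid$y))
  m <- matrix(FALSE, h, w)
  m[cbind(grid$y[inside], grid$x[inside])] <- TRUE
  m
}
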