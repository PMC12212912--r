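# Colour distributions and the Bhattacharyya distance.
#
# Each ROI's pixels form a distribution of colour values; the colour shift
# of a digit region relative to the dorsal reference is scored as the
# Bhattacharyya distance BD = -ln(BC) between the two distributions, where
# BC = sum_i sqrt(p_i q_i) for histograms. BD is 0 for identical
# distributions and grows without bound as they separate.

#' Default histogram bin edges for L*a*b* channels
#'
#' Comparable histograms need shared, fixed edges. Defaults: width-2 bins
#' over \[-60, 60\] in a* and b*, and over \[0, 100\] in L*. Values outside
#' the range are counted in the nearest edge bin.
#'
#' @param channels Character vector drawn from `c("L", "a", "b")`.
#' @return Named list of numeric edge vectors.
#' @export
bd_breaks <- function(channels = c("a", "b")) {
  edges <- list(
    L = seq(0, 100, by = 2),
    a = seq(-60, 60, by = 2),
    b = seq(-60, 60, by = 2)
  )
  stopifnot(all(channels %in% names(edges)))
  edges[channels]
}

#' Build a colour distribution from L*a*b* pixels
#'
#' Represents an ROI's colour either as a normalised multi-dimensional
#' histogram over fixed global bin edges (the default; any two histograms
#' built with the same `breaks` are directly comparable) or as a fitted
#' Gaussian (mean vector and covariance).
#'
#' @param lab Data frame of pixels with columns `L`, `a`, `b` (from
#'   [srgb_to_lab()]).
#' @param channels Channel subset used, default `c("a", "b")` — the hue
#'   plane, insensitive to overall lightness. `c("L", "a", "b")` enables
#'   the full three-channel mode.
#' @param method `"histogram"` or `"gaussian"`.
#' @param breaks Bin edges as from [bd_breaks()]; ignored for the Gaussian.
#' @param min_pixels Distributions built from fewer pixels are flagged
#'   degenerate (default 50) and excluded from aggregation downstream.
#' @return A `colour_distribution` object.
#' @export
lab_distribution <- function(lab, channels = c("a", "b"),
                             method = c("histogram", "gaussian"),
                             breaks = bd_breaks(channels),
                             min_pixels = 50) {
  method <- match.arg(method)
  lab <- as.data.frame(lab)
  stopifnot(all(channels %in% names(lab)))
  m <- as.matrix(lab[, channels, drop = FALSE])
  if (any(!is.finite(m))) stop("non-finite L*a*b* values")
  n <- nrow(m)
  degenerate <- n < min_pixels
  if (method == "histogram") {
    stopifnot(identical(names(breaks), channels))
    nb <- vapply(breaks, function(e) length(e) - 1L, integer(1))
    idx <- rep(0L, n)
    mult <- 1L
    for (j in seq_along(channels)) {
      e <- breaks[[j]]
      bj <- findInterval(m[, j], e, rightmost.closed = TRUE)
      bj <- pmin(pmax(bj, 1L), nb[j]) # clamp out-of-range into edge bins
      idx <- idx + (bj - 1L) * mult
      mult <- mult * nb[j]
    }
    counts <- tabulate(idx + 1L, nbins = prod(nb))
    p <- if (n > 0) counts / n else counts
    out <- list(
      method = "histogram", channels = channels, breaks = breaks,
      prob = p, n = n, degenerate = degenerate
    )
  } else {
    mu <- colMeans(m)
    sigma <- if (n > 1) stats::cov(m) else matrix(0, length(channels), length(channels))
    out <- list(
      method = "gaussian", channels = channels,
      mean = mu, cov = sigma, n = n, degenerate = degenerate
    )
  }
  structure(out, class = "colour_distribution")
}

#' @export
print.colour_distribution <- function(x, ...) {
  cat(sprintf(
    "<colour_distribution: %s over (%s), n = %d%s>\n",
    x$method, paste(x$channels, collapse = ", "), x$n,
    if (isTRUE(x$degenerate)) ", degenerate" else ""
  ))
  invisible(x)
}

#' Bhattacharyya coefficient and distance between two colour distributions
#'
#' For histograms, BC = sum over bins of sqrt(p_i q_i) and BD = -ln(BC),
#' after additive smoothing (`eps`) on the union support so that
#' near-disjoint histograms do not produce spuriously zero coefficients.
#' Fully disjoint supports are reported as BC = 0 with BD capped at the
#' sentinel and flagged. For Gaussians the closed form is used:
#' BD = 1/8 (m1-m2)' S^-1 (m1-m2) + 1/2 ln( det S / sqrt(det S1 det S2) ),
#' with S the average covariance.
#'
#' @param p,q `colour_distribution` objects with identical method,
#'   channels and (for histograms) bin edges.
#' @param eps Additive smoothing mass per union-support bin (default 1e-9).
#' @param cap Sentinel value replacing infinite BD (default 50); capped
#'   records carry `capped = TRUE`.
#' @return One-row tibble: `bc`, `bd`, `capped`, `estimator`, `channels`,
#'   `degenerate` (TRUE if either input was degenerate).
#' @export
bhattacharyya <- function(p, q, eps = 1e-9, cap = 50) {
  stopifnot(inherits(p, "colour_distribution"), inherits(q, "colour_distribution"))
  if (!identical(p$method, q$method)) stop("distributions use different estimators")
  if (!identical(p$channels, q$channels)) stop("distributions use different channel subsets")
  capped <- FALSE
  if (p$method == "histogram") {
    if (!identical(p$breaks, q$breaks)) stop("histograms built on different bin edges")
    pp <- p$prob
    qq <- q$prob
    raw_bc <- sum(sqrt(pp * qq))
    if (raw_bc == 0) {
      bc <- 0
      bd <- cap
      capped <- TRUE
    } else {
      support <- pp > 0 | qq > 0
      pp[support] <- pp[support] + eps
      qq[support] <- qq[support] + eps
      pp <- pp / sum(pp)
      qq <- qq / sum(qq)
      bc <- min(sum(sqrt(pp * qq)), 1)
      bd <- -log(bc)
    }
  } else {
    d <- p$mean - q$mean
    s <- (p$cov + q$cov) / 2
    dets1 <- det(p$cov)
    dets2 <- det(q$cov)
    if (abs(det(s)) < 1e-12 || dets1 <= 0 || dets2 <= 0) {
      # singular covariance: regularise with a small ridge
      jitter <- 1e-8 + 1e-6 * mean(diag(s))
      k <- nrow(s)
      s <- s + diag(jitter, k)
      p_cov <- p$cov + diag(jitter, k)
      q_cov <- q$cov + diag(jitter, k)
      dets1 <- det(p_cov)
      dets2 <- det(q_cov)
    }
    bd <- as.numeric(t(d) %*% solve(s, d)) / 8 +
      0.5 * log(det(s) / sqrt(dets1 * dets2))
    bd <- max(bd, 0)
    if (bd > cap) {
      bd <- cap
      capped <- TRUE
    }
    bc <- exp(-bd)
  }
  tibble::tibble(
    bc = bc, bd = bd, capped = capped,
    estimator = p$method,
    channels = paste(p$channels, collapse = ""),
    degenerate = isTRUE(p$degenerate) || isTRUE(q$degenerate)
  )
}

#' Per-ROI Bhattacharyya distances against the dorsal reference
#'
#' The per-image workhorse: takes the tidy pixel table of one image (as
#' returned by [extract_roi_pixels()]), converts each ROI's pixels to
#' L*a*b*, builds one colour distribution per ROI, and scores every digit
#' ROI against the dorsal reference ROI.
#'
#' @param pixels Tidy pixel table with columns `roi_id`, `digit`, `part`,
#'   `R`, `G`, `B`.
#' @param reference_roi Label of the reference ROI (default 25, the
#'   dorsum).
#' @param channels,method,breaks,min_pixels,eps,cap Passed to
#'   [lab_distribution()] and [bhattacharyya()].
#' @return Tibble with one row per digit ROI: `roi_id`, `digit`, `part`,
#'   `reference_roi`, `n_pixels`, `bc`, `bd`, `capped`, `estimator`,
#'   `channels`, `degenerate`.
#' @export
roi_bd <- function(pixels, reference_roi = 25L, channels = c("a", "b"),
                   method = c("histogram", "gaussian"),
                   breaks = bd_breaks(channels), min_pixels = 50,
                   eps = 1e-9, cap = 50) {
  method <- match.arg(method)
  stopifnot(all(c("roi_id", "R", "G", "B") %in% names(pixels)))
  if (!reference_roi %in% pixels$roi_id) {
    stop("reference ROI ", reference_roi, " absent from pixel table")
  }
  lab <- srgb_to_lab(pixels[, c("R", "G", "B")])
  px <- dplyr::bind_cols(
    pixels[, intersect(c("roi_id", "digit", "part"), names(pixels))], lab
  )
  dists <- px |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_map(function(d, key) {
      list(
        roi_id = key$roi_id,
        digit = if ("digit" %in% names(d)) d$digit[1] else NA_integer_,
        part = if ("part" %in% names(d)) d$part[1] else NA_character_,
        n_pixels = nrow(d),
        dist = lab_distribution(d, channels = channels, method = method,
                                breaks = breaks, min_pixels = min_pixels)
      )
    })
  ref <- dists[[which(vapply(dists, function(x) x$roi_id, numeric(1)) == reference_roi)]]
  digit_rois <- Filter(function(x) x$roi_id != reference_roi, dists)
  purrr::map_dfr(digit_rois, function(x) {
    rec <- bhattacharyya(x$dist, ref$dist, eps = eps, cap = cap)
    dplyr::bind_cols(
      tibble::tibble(
        roi_id = x$roi_id, digit = x$digit, part = x$part,
        reference_roi = reference_roi, n_pixels = x$n_pixels
      ),
      rec
    )
  })
}

#' Per-image mean Bhattacharyya distance
#'
#' Averages BD over all usable (non-degenerate) digit ROIs of each image —
#' the image-level severity summary that is then averaged again over an
#' episode. Images with zero usable ROIs are dropped with a warning.
#'
#' @param bd_records Tidy BD table: one row per (image, ROI), with at
#'   least `bd` and `degenerate` columns plus the image identifier
#'   columns named in `by`.
#' @param by Character vector of columns identifying an image.
#' @return Tibble with the `by` columns plus `mean_bd` and `n_rois` (the
#'   number of contributing ROIs).
#' @export
image_mean_bd <- function(bd_records, by = intersect(
                            c("patient_id", "source_path", "timestamp"),
                            names(bd_records)
                          )) {
  stopifnot("bd" %in% names(bd_records), length(by) > 0)
  if (!"degenerate" %in% names(bd_records)) bd_records$degenerate <- FALSE
  out <- bd_records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_bd = mean(.data$bd[!.data$degenerate]),
      n_rois = sum(!.data$degenerate),
      .groups = "drop"
    )
  bad <- out$n_rois == 0
  if (any(bad)) {
    warning(sum(bad), " image(s) had no usable ROI and were dropped")
    out <- out[!bad, , drop = FALSE]
  }
  out
}
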