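# Colour-checker correction: a simplified card-correction analogue used
# to ask whether correction would matter, not to apply it routinely. The
# study's conclusion — corrections are small next to the colour changes of
# an attack — becomes a measurable comparison of two Delta-E magnitudes.

#' Estimate and apply a linear colour correction from checker patches
#'
#' Fits the least-squares 3x3 linear transform, in linear (de-gammaed)
#' RGB, that maps the measured mean colours of the card patches to their
#' known reference values, applies it to the whole image, and reports the
#' correction magnitude as the mean Delta-E (L*a*b* Euclidean distance)
#' between original and corrected pixels over the evaluation region.
#'
#' @param image A [hand_image()].
#' @param patch_masks List of logical H x W masks, one per card patch.
#' @param reference_srgb Matrix (n_patches x 3) of the patches' reference
#'   sRGB values in \[0, 255\]. At least 3 patches are required.
#' @param eval_mask Optional logical mask of pixels over which the
#'   magnitude is computed (e.g. the hand region); defaults to the whole
#'   image.
#' @return List: `corrected` (a [hand_image()]), `transform` (the 3x3
#'   matrix), `magnitude` (mean Delta-E original vs corrected).
#' @export
colour_correction <- function(image, patch_masks, reference_srgb,
                              eval_mask = NULL) {
  stopifnot(inherits(image, "hand_image"))
  reference_srgb <- .as_rgb_matrix(reference_srgb)
  if (length(patch_masks) < 3 || nrow(reference_srgb) != length(patch_masks)) {
    stop("need >= 3 patch ROIs with matching reference values")
  }
  to_lin <- function(x) {
    x <- x / 255
    ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  }
  from_lin <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    255 * ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
  }
  measured <- t(vapply(patch_masks, function(m) {
    idx <- which(m)
    c(mean(image$pixels[, , 1][idx]), mean(image$pixels[, , 2][idx]),
      mean(image$pixels[, , 3][idx]))
  }, numeric(3)))
  m_lin <- to_lin(measured)
  r_lin <- to_lin(reference_srgb)
  if (qr(m_lin)$rank < 3) stop("rank-deficient patch set: patches are collinear in RGB")
  # measured %*% t(A) ~ reference  => A' = lstsq(measured, reference)
  a_t <- qr.solve(m_lin, r_lin)
  d <- dim(image$pixels)
  flat <- cbind(c(image$pixels[, , 1]), c(image$pixels[, , 2]),
                c(image$pixels[, , 3]))
  corr_lin <- to_lin(flat) %*% a_t
  corr <- from_lin(corr_lin)
  out_px <- array(0, dim = d)
  out_px[, , 1] <- corr[, 1]
  out_px[, , 2] <- corr[, 2]
  out_px[, , 3] <- corr[, 3]
  sel <- if (is.null(eval_mask)) rep(TRUE, nrow(flat)) else c(eval_mask)
  magnitude <- mean(delta_e(
    as.matrix(srgb_to_lab(flat[sel, , drop = FALSE])),
    as.matrix(srgb_to_lab(corr[sel, , drop = FALSE]))
  ))
  corrected <- hand_image(
    out_px, timestamp = image$timestamp, patient_id = image$patient_id,
    source_path = image$source_path, aspect = image$aspect,
    timestamp_source = image$timestamp_source
  )
  list(corrected = corrected, transform = t(a_t), magnitude = magnitude)
}
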