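# sRGB <-> CIE L*a*b* conversion (IEC 61966-2-1 gamma, D65 white, 2 deg
# observer). Implemented directly from the standard constants: hand
# photographs are treated "as taken", i.e. assumed sRGB, and the whole
# pipeline's colour contract rests on this transform being the canonical one.

# sRGB -> XYZ matrix for the D65 white point.
.srgb_xyz <- matrix(
  c(0.412453, 0.357580, 0.180423,
    0.212671, 0.715160, 0.072169,
    0.019334, 0.119193, 0.950227),
  nrow = 3, byrow = TRUE
)
# Reference white = transform of RGB (1,1,1); guarantees white -> (100, 0, 0).
.d65_white <- as.numeric(.srgb_xyz %*% rep(1, 3))

#' Convert sRGB pixel values to CIE L*a*b*
#'
#' Applies the standard sRGB decoding (IEC 61966-2-1 piecewise gamma),
#' the sRGB-to-XYZ matrix for the D65 white point (2 degree observer), and
#' the CIE L*a*b* formulas. The conversion is total: any value in
#' \[0, 255\] maps to finite L* in \[0, 100\] and a*, b* hue coordinates.
#'
#' @param rgb A numeric matrix or data frame with three columns (R, G, B)
#'   of sRGB values in \[0, 255\], one row per pixel. A length-3 vector is
#'   treated as a single pixel.
#' @return A tibble with columns `L`, `a`, `b`.
#' @examples
#' srgb_to_lab(c(255, 255, 255)) # L* = 100, neutral
#' srgb_to_lab(rbind(c(200, 160, 140), c(0, 0, 0)))
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- .as_rgb_matrix(rgb)
  x <- rgb / 255
  lin <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_xyz)
  tt <- sweep(xyz, 2, .d65_white, "/")
  d <- 6 / 29
  f <- ifelse(tt > d^3, tt^(1 / 3), tt / (3 * d^2) + 4 / 29)
  tibble::tibble(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
}

#' Convert CIE L*a*b* values to sRGB
#'
#' Inverse of [srgb_to_lab()]. Colours outside the sRGB gamut are clipped
#' channel-wise to \[0, 255\]; whether clipping occurred is reported in the
#' `"gamut_clipped"` attribute of the result.
#'
#' @param lab A numeric matrix or data frame with columns (L, a, b), one
#'   row per pixel; a length-3 vector is one pixel.
#' @return A tibble with columns `R`, `G`, `B` in \[0, 255\] and attribute
#'   `gamut_clipped` (logical, one flag per pixel).
#' @export
lab_to_srgb <- function(lab) {
  lab <- .as_rgb_matrix(lab)
  d <- 6 / 29
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(f) ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, .d65_white, "*")
  lin <- xyz %*% t(solve(.srgb_xyz))
  clipped <- rowSums(lin < -1e-9 | lin > 1 + 1e-9) > 0
  lin <- pmin(pmax(lin, 0), 1)
  x <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- tibble::tibble(R = 255 * x[, 1], G = 255 * x[, 2], B = 255 * x[, 3])
  attr(out, "gamut_clipped") <- clipped
  out
}

#' Euclidean colour difference in L*a*b* space
#'
#' The classic Delta-E (CIE76): the Euclidean distance between two colours
#' in L*a*b* coordinates, row by row.
#'
#' @param lab1,lab2 Matrices/data frames of L*a*b* rows, recycled to a
#'   common length.
#' @return Numeric vector of distances.
#' @export
delta_e <- function(lab1, lab2) {
  lab1 <- .as_rgb_matrix(lab1)
  lab2 <- .as_rgb_matrix(lab2)
  if (nrow(lab1) == 1 && nrow(lab2) > 1) lab1 <- lab1[rep(1, nrow(lab2)), , drop = FALSE]
  if (nrow(lab2) == 1 && nrow(lab1) > 1) lab2 <- lab2[rep(1, nrow(lab1)), , drop = FALSE]
  sqrt(rowSums((lab1 - lab2)^2))
}

.as_rgb_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:3])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 3) stop("expected 3 colour channels, got ", ncol(x))
  storage.mode(x) <- "double"
  unname(x)
}
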