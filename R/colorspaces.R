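# Colour-space conversions for the twelve analysis channels:
# R, G, B (8-bit), L*, u*, v* (CIE 1976, D65), H, S, I (arccos HSI variant,
# hue in radians) and Rn, Gn, Bn (chromaticity / normalized RGB).
#
# Conversions are implemented from the CIE / IEC definitions directly: the
# channel values are the raw material of every downstream feature, so their
# definition is part of the method, not an interchangeable backend.

#' Channel codes of the analysis colour spaces
#'
#' The public naming contract reused by the feature registry and MEPAT
#' files: `R,G,B` (8-bit RGB), `L,u,v` (CIE-L*u*v*), `H,S,I` (hue in radians,
#' saturation, intensity), `Rn,Gn,Bn` (normalized RGB).
#'
#' @return character vector of the 12 channel codes, in canonical order.
#' @export
channel_codes <- function() {
  c("R", "G", "B", "L", "u", "v", "H", "S", "I", "Rn", "Gn", "Bn")
}

# Fixed histogram ranges per channel (used by channel_histogram): 8-bit
# channels span 0..255, L* 0..100, u*/v* fixed symmetric gamuts, hue one
# full turn, unit-interval channels 0..1.
channel_range <- function(code) {
  switch(code,
    R = , G = , B = c(0, 255),
    L = c(0, 100),
    u = c(-134, 220),
    v = c(-140, 122),
    H = c(0, 2 * pi),
    S = , I = , Rn = , Gn = , Bn = c(0, 1),
    stop_gummix(paste0("unknown channel code: ", code), "registry")
  )
}

#' RGB to HSI (arccos formulation)
#'
#' Converts 8-bit RGB pixels to hue/saturation/intensity. Intensity is the
#' channel mean rescaled to `[0,1]`; saturation is `1 - min/mean`; hue is
#' the arccos-formulation angle in radians on `[0, 2*pi)`. Hue is undefined
#' (returned as `NA`) for achromatic pixels (`S = 0`), and is masked rather
#' than imputed throughout the package.
#'
#' @param rgb numeric `N x 3` matrix of 8-bit values (0..255).
#' @return `N x 3` matrix with columns `H`, `S`, `I`.
#' @export
rgb_to_hsi <- function(rgb) {
  rgb <- as_pixmat(rgb)
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  s3 <- r + g + b
  i <- s3 / (3 * 255)
  mn <- pmin(r, g, b)
  s <- ifelse(s3 > 0, 1 - 3 * mn / s3, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  ratio <- ifelse(den > 0, pmin(pmax(num / den, -1), 1), NA_real_)
  theta <- acos(ratio)
  h <- ifelse(b <= g, theta, 2 * pi - theta)
  h[s <= 0 | !is.finite(h)] <- NA_real_
  h[!is.na(h) & h >= 2 * pi] <- 0
  cbind(H = h, S = s, I = i)
}

# sRGB (IEC 61966-2-1) linearization and its D65 RGB->XYZ matrix.
srgb_to_linear <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}

linear_to_srgb <- function(lin) {
  lin <- pmin(pmax(lin, 0), 1)
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
}

.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.WHITE_D65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

#' RGB to CIE-L*u*v*
#'
#' 8-bit sRGB values are gamma-expanded, mapped to CIE XYZ (D65 white,
#' IEC 61966-2-1 primaries) and then to CIE 1976 L*u*v*. Black maps to
#' `(0, 0, 0)`.
#'
#' @param rgb numeric `N x 3` matrix of 8-bit values (0..255).
#' @return `N x 3` matrix with columns `L`, `u`, `v`.
#' @export
rgb_to_luv <- function(rgb) {
  rgb <- as_pixmat(rgb)
  lin <- srgb_to_linear(rgb / 255)
  xyz <- lin %*% t(.M_RGB2XYZ)
  X <- xyz[, 1]; Y <- xyz[, 2]; Z <- xyz[, 3]
  yr <- Y / .WHITE_D65[["Y"]]
  eps <- (6 / 29)^3
  L <- ifelse(yr > eps, 116 * yr^(1 / 3) - 16, (29 / 3)^3 * yr)
  den <- X + 15 * Y + 3 * Z
  wden <- sum(.WHITE_D65 * c(1, 15, 3))
  un <- 4 * .WHITE_D65[["X"]] / wden
  vn <- 9 * .WHITE_D65[["Y"]] / wden
  up <- ifelse(den > 0, 4 * X / den, un)
  vp <- ifelse(den > 0, 9 * Y / den, vn)
  u <- 13 * L * (up - un)
  v <- 13 * L * (vp - vn)
  cbind(L = L, u = u, v = v)
}

# Inverse of rgb_to_luv (needed to hand a mean-shift-filtered image back on
# the sRGB scale). Values are clipped into gamut.
luv_to_rgb <- function(luv) {
  L <- luv[, 1]; u <- luv[, 2]; v <- luv[, 3]
  wden <- sum(.WHITE_D65 * c(1, 15, 3))
  un <- 4 * .WHITE_D65[["X"]] / wden
  vn <- 9 * .WHITE_D65[["Y"]] / wden
  pos <- L > 0
  up <- ifelse(pos, u / (13 * L) + un, un)
  vp <- ifelse(pos, v / (13 * L) + vn, vn)
  Y <- ifelse(L > 8, .WHITE_D65[["Y"]] * ((L + 16) / 116)^3,
              .WHITE_D65[["Y"]] * L * (3 / 29)^3)
  X <- ifelse(vp > 0, Y * 9 * up / (4 * vp), 0)
  Z <- ifelse(vp > 0, Y * (12 - 3 * up - 20 * vp) / (4 * vp), 0)
  lin <- cbind(X, Y, Z) %*% t(solve(.M_RGB2XYZ))
  clip255(linear_to_srgb(lin) * 255)
}

#' RGB to normalized RGB (chromaticity)
#'
#' `Rn = R/(R+G+B)` and likewise for `Gn`, `Bn`, suppressing brightness so
#' the channels respond to colour composition only. The black pixel
#' (sum 0), where the normalization is undefined, maps to `(1/3, 1/3, 1/3)`.
#'
#' @param rgb numeric `N x 3` matrix of 8-bit values (0..255).
#' @return `N x 3` matrix with columns `Rn`, `Gn`, `Bn`; rows sum to 1.
#' @export
rgb_to_nrgb <- function(rgb) {
  rgb <- as_pixmat(rgb)
  s <- rowSums(rgb)
  out <- rgb / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 1 / 3
  colnames(out) <- c("Rn", "Gn", "Bn")
  out
}

as_pixmat <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  if (ncol(rgb) != 3L) stop_gummix("pixel matrix must have 3 columns", "input")
  rgb
}

#' Compute all twelve analysis channels for a set of pixels
#'
#' @param rgb numeric `N x 3` matrix of 8-bit RGB values.
#' @return `N x 12` matrix with columns named by [channel_codes()]. The `H`
#'   column contains `NA` at achromatic pixels (undefined hue).
#' @export
channel_set <- function(rgb) {
  rgb <- as_pixmat(rgb)
  out <- cbind(
    R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
    rgb_to_luv(rgb),
    rgb_to_hsi(rgb),
    rgb_to_nrgb(rgb)
  )
  colnames(out) <- channel_codes()
  out
}
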