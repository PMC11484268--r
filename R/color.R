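# Color-space conversions. sRGB is stored as intensities in [0, 255]; linear
# RGB lives in the unit cube; CIELAB uses the D65 white point via
# grDevices::convertColor.

#' Convert sRGB intensities to linear RGB
#'
#' Inverts the sRGB transfer function (gamma expansion), mapping intensities
#' in \code{[0, 255]} to linear-light RGB in \code{[0, 1]}. Euclidean
#' distances in linear RGB track physical intensity differences, which is the
#' space the color clustering and dispersion metrics operate in.
#'
#' @param x Numeric vector, matrix or array of sRGB intensities in
#'   \code{[0, 255]}.
#' @return Object of the same shape with linear RGB values in \code{[0, 1]}.
#' @export
srgbToLinear <- function(x) {
  v <- x / 255
  out <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Convert linear RGB to sRGB intensities
#'
#' Inverse of \code{\link{srgbToLinear}}: applies the sRGB transfer function
#' and scales to \code{[0, 255]}. Values are clipped to the displayable range.
#'
#' @param x Numeric vector, matrix or array of linear RGB values.
#' @return Object of the same shape with sRGB intensities in \code{[0, 255]}.
#' @export
linearToSrgb <- function(x) {
  v <- .clamp(x, 0, 1)
  out <- ifelse(v <= 0.0031308, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055)
  out <- out * 255
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# n x 3 sRGB matrix in [0, 255] -> n x 3 CIELAB (D65).
#' @importFrom grDevices convertColor
.srgbToLab <- function(rgb) {
  grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
}

# n x 3 CIELAB -> n x 3 sRGB in [0, 255], clipped to gamut.
.labToSrgb <- function(lab) {
  .clamp(grDevices::convertColor(lab, from = "Lab", to = "sRGB"), 0, 1) * 255
}

# H x W x 3 sRGB image -> H x W x 3 CIELAB image (and back).
.imageToLab <- function(img) {
  d <- dim(img)
  lab <- .srgbToLab(matrix(img, ncol = 3))
  array(lab, d)
}

.labToImage <- function(lab) {
  d <- dim(lab)
  rgb <- .labToSrgb(matrix(lab, ncol = 3))
  array(rgb, d)
}

#' CIELAB color difference
#'
#' Euclidean distance in CIELAB (the classic Delta-E 1976).
#'
#' @param lab1,lab2 Length-3 CIELAB vectors or n x 3 matrices.
#' @return Numeric Delta-E value(s).
#' @export
deltaE <- function(lab1, lab2) {
  d <- rbind(lab1) - rbind(lab2)
  sqrt(rowSums(d^2))
}
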