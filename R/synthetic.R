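# Seeded synthetic generator of lesion images and progression sequences with
# known ground truth. Emulates registered dermoscopic frames: a roughly
# elliptical pigmented lesion on lighter skin, with controllable asymmetry
# (odd-harmonic boundary warp), border sharpness (Gaussian blur), 1-4 color
# modes (angular palette sectors), multiplicative band-limited texture,
# channel noise, diameter growth and global illumination drift.

#' Specification of one synthetic lesion image
#'
#' @param canvas Integer (H, W) canvas size (default 160 x 160).
#' @param center (row, col) lesion center; default the canvas center.
#' @param radius Semi-major axis in px (default 35).
#' @param eccentricity Ellipse eccentricity in \code{[0, 1)} (default 0).
#' @param orientation Major-axis angle vs the image x-axis, radians
#'   (default 0).
#' @param asymmetryWarp Amplitude in \code{[0, 1]} of the odd-harmonic radial
#'   boundary perturbation (default 0; larger = more asymmetric).
#' @param borderBlurSigma Gaussian blur sigma in px applied to the rendered
#'   image (default 0; larger = fuzzier border).
#' @param palette List with \code{colors} (k x 3 matrix of linear-RGB rows,
#'   k in 1..4) and \code{fractions} (length k, summing to 1). Default: one
#'   medium-brown mode.
#' @param noiseSigma Gaussian channel noise sd in linear RGB (default 0.01).
#' @param skinColor Length-3 sRGB background skin color (default a light
#'   skin tone, c(205, 175, 150)).
#' @param textureAmp Amplitude in \code{[0, 1]} of the multiplicative
#'   band-limited texture inside the lesion (default 0.1).
#' @param skinTextureAmp Amplitude of the static band-limited skin texture
#'   (default 0.08, a mild mottling). Anchored to canvas coordinates, so it
#'   does not move across the frames of a progression - like real skin
#'   around a changing lesion.
#' @param seed Integer seed; all randomness (harmonic phases, texture,
#'   noise) is a pure function of the spec including this seed.
#' @return A validated \code{LesionSpec} (list).
#' @export
lesionSpec <- function(canvas = c(160L, 160L), center = NULL, radius = 35,
                       eccentricity = 0, orientation = 0, asymmetryWarp = 0,
                       borderBlurSigma = 0,
                       palette = list(colors = matrix(c(0.35, 0.2, 0.12),
                                                      1, 3),
                                      fractions = 1),
                       noiseSigma = 0.01,
                       skinColor = c(205, 175, 150), textureAmp = 0.1,
                       skinTextureAmp = 0.08, seed = 1L) {
  canvas <- as.integer(canvas)
  if (is.null(center)) center <- (canvas + 1) / 2
  spec <- list(canvas = canvas, center = center, radius = radius,
               eccentricity = eccentricity, orientation = orientation,
               asymmetryWarp = asymmetryWarp,
               borderBlurSigma = borderBlurSigma, palette = palette,
               noiseSigma = noiseSigma, skinColor = skinColor,
               textureAmp = textureAmp, skinTextureAmp = skinTextureAmp,
               seed = as.integer(seed))
  class(spec) <- "LesionSpec"
  .validateLesionSpec(spec)
  spec
}

.validateLesionSpec <- function(spec) {
  with(spec, {
    if (eccentricity < 0 || eccentricity >= 1)
      stop("eccentricity must lie in [0, 1)")
    if (asymmetryWarp < 0 || asymmetryWarp > 1)
      stop("asymmetryWarp must lie in [0, 1]")
    k <- nrow(palette$colors)
    if (k < 1L || k > 4L) stop("palette must have 1-4 colors")
    if (length(palette$fractions) != k ||
        abs(sum(palette$fractions) - 1) > 1e-9)
      stop("palette fractions must sum to 1")
    maxR <- radius * (1 + asymmetryWarp)
    margin <- min(center[1] - 1, canvas[1] - center[1],
                  center[2] - 1, canvas[2] - center[2]) - maxR
    if (margin < 10) stop("lesion exceeds canvas (needs a 10-px margin)")
  })
  invisible(spec)
}

# Seeded structural parameters shared by all frames of a progression:
# odd-harmonic weights/phases for the boundary warp and texture waves.
.lesionStructure <- function(seed) {
  .withSeed(seed, {
    w <- abs(stats::rnorm(3)) + 0.1
    list(harmWeights = w / sum(w),
         harmPhases = stats::runif(3, 0, 2 * pi),
         texFreq = matrix(stats::runif(8, 2, 6) *
                            sample(c(-1, 1), 8, replace = TRUE), 4, 2),
         texPhase = stats::runif(4, 0, 2 * pi),
         skinFreq = matrix(stats::runif(8, 0.15, 0.7) *
                             sample(c(-1, 1), 8, replace = TRUE), 4, 2),
         skinPhase = stats::runif(4, 0, 2 * pi))
  })
}

# Analytic boundary radius at polar angle phi (ellipse frame).
.boundaryRadius <- function(phi, radius, ecc, warp, struct) {
  a <- radius; b <- radius * sqrt(1 - ecc^2)
  re <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  harm <- c(3, 5, 7)
  p <- rep(0, length(phi))
  for (i in 1:3)
    p <- p + struct$harmWeights[i] * sin(harm[i] * phi + struct$harmPhases[i])
  re * (1 + warp * p)
}

#' Generate one synthetic lesion frame
#'
#' Renders the lesion described by \code{spec}: an elliptical boundary
#' modulated by a seeded odd-harmonic radial perturbation, interior colored
#' by angular palette sectors with multiplicative band-limited texture and
#' Gaussian channel noise (in linear RGB), composited onto uniform skin,
#' optionally blurred. The returned mask is the exact pre-blur boundary.
#'
#' @param spec A \code{LesionSpec} from \code{\link{lesionSpec}}.
#' @param noiseSeed Seed for the per-frame pixel noise; defaults to
#'   \code{spec$seed}. Progressions vary it per frame while keeping the
#'   structural seed fixed, so the lesion is the "same tissue" across frames.
#' @return A \linkS4class{LesionFrame} with attribute \code{groundTruth}: a
#'   list with the exact \code{area} (px), analytic \code{majorAxisLen}
#'   (extent along the major-axis direction), \code{palette},
#'   \code{asymmetryWarp} and \code{center}.
#' @examples
#' fr <- generateLesion(lesionSpec(radius = 40, seed = 2))
#' attr(fr, "groundTruth")$majorAxisLen
#' @export
generateLesion <- function(spec, noiseSeed = spec$seed) {
  .validateLesionSpec(spec)
  st <- .lesionStructure(spec$seed)
  h <- spec$canvas[1]; w <- spec$canvas[2]
  grid <- expand.grid(r = seq_len(h), c = seq_len(w))
  dx <- grid$c - spec$center[2]; dy <- grid$r - spec$center[1]
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  xr <- co * dx + si * dy          # ellipse-frame coordinates
  yr <- -si * dx + co * dy
  phi <- atan2(yr, xr)
  rho <- sqrt(xr^2 + yr^2)
  rb <- .boundaryRadius(phi, spec$radius, spec$eccentricity,
                        spec$asymmetryWarp, st)
  mask <- matrix(rho <= rb, h, w)

  # palette sector per pixel (angular fractions, ellipse frame)
  k <- nrow(spec$palette$colors)
  cuts <- cumsum(spec$palette$fractions)
  frac <- (phi + pi) / (2 * pi)
  sector <- pmin(findInterval(frac, c(0, cuts[-k]), rightmost.closed = FALSE),
                 k)
  # texture in lesion-normalized coordinates so it grows with the lesion
  a <- spec$radius; b <- spec$radius * sqrt(1 - spec$eccentricity^2)
  tx <- xr / a; ty <- yr / b
  tex <- rep(0, length(tx))
  for (i in 1:4)
    tex <- tex + cos(st$texFreq[i, 1] * tx + st$texFreq[i, 2] * ty +
                       st$texPhase[i])
  tex <- tex / max(abs(tex))   # unit amplitude: textureAmp is the modulation

  # static skin texture in canvas coordinates: it does not move between
  # the frames of a progression
  skinTex <- rep(0, length(dx))
  for (i in 1:4)
    skinTex <- skinTex + cos(st$skinFreq[i, 1] * grid$c +
                               st$skinFreq[i, 2] * grid$r + st$skinPhase[i])
  skinTex <- skinTex / max(abs(skinTex))

  skinLin <- srgbToLinear(spec$skinColor)
  lin <- array(rep(skinLin, each = h * w), dim = c(h, w, 3))
  for (ch in 1:3)
    lin[, , ch] <- lin[, , ch] *
      (1 + spec$skinTextureAmp * matrix(skinTex, h, w))
  mv <- as.vector(mask)
  for (ch in 1:3) {
    base <- spec$palette$colors[sector, ch] * (1 + spec$textureAmp * tex)
    plane <- lin[, , ch]
    plane[mv] <- base[mv]
    lin[, , ch] <- plane
  }
  if (spec$noiseSigma > 0) {
    noise <- .withSeed(noiseSeed,
                       stats::rnorm(h * w * 3, 0, spec$noiseSigma))
    lin <- lin + array(noise, dim = dim(lin))
  }
  img <- linearToSrgb(.clamp(lin, 0, 1))
  if (spec$borderBlurSigma > 0) {
    for (ch in 1:3)
      img[, , ch] <- EBImage::gblur(img[, , ch],
                                    sigma = spec$borderBlurSigma)
  }
  img <- round(.clamp(img, 0, 255))
  frame <- LesionFrame(img, mask = mask)
  gt <- list(
    area = sum(mask),
    majorAxisLen = .boundaryRadius(0, spec$radius, spec$eccentricity,
                                   spec$asymmetryWarp, st) +
      .boundaryRadius(pi, spec$radius, spec$eccentricity,
                      spec$asymmetryWarp, st),
    palette = spec$palette,
    asymmetryWarp = spec$asymmetryWarp,
    center = spec$center)
  attr(frame, "groundTruth") <- gt
  frame
}

#' Specification of a synthetic lesion progression
#'
#' @param nFrames Number of frames (>= 2).
#' @param start,end \code{LesionSpec}s sharing canvas and center; geometry,
#'   palette, blur, warp, noise and texture are interpolated between them.
#' @param interpolation \code{"linear"} or \code{"sigmoid"} schedule.
#' @param illuminationDrift Length-3 sRGB offset reached at the last frame
#'   (added uniformly to the whole image, ramping linearly from zero);
#'   exercises the color normalization.
#' @param confidenceCurve List with \code{start}, \code{end} (nevus-class
#'   confidences in \code{[0, 1]}) and \code{steepness} of the sigmoid
#'   transition.
#' @return A validated \code{ProgressionSpec} (list).
#' @export
progressionSpec <- function(nFrames, start, end, interpolation = "linear",
                            illuminationDrift = c(0, 0, 0),
                            confidenceCurve = list(start = 0.97, end = 0.1,
                                                   steepness = 8)) {
  if (nFrames < 2L) stop("nFrames must be >= 2")
  if (!identical(start$canvas, end$canvas) ||
      max(abs(start$center - end$center)) > 1e-9)
    stop("start and end must share canvas and center")
  interpolation <- match.arg(interpolation, c("linear", "sigmoid"))
  structure(list(nFrames = as.integer(nFrames), start = start, end = end,
                 interpolation = interpolation,
                 illuminationDrift = illuminationDrift,
                 confidenceCurve = confidenceCurve),
            class = "ProgressionSpec")
}

# Pad a palette to k entries by replicating its last color at zero fraction:
# new color modes of a progression emerge by drifting away from the base
# color (continuous morph), not by appearing fully formed.
.padPalette <- function(pal, k) {
  k0 <- nrow(pal$colors)
  if (k0 >= k) return(pal)
  base <- pal$colors[k0, , drop = FALSE]
  list(colors = rbind(pal$colors,
                      base[rep(1, k - k0), , drop = FALSE]),
       fractions = c(pal$fractions, rep(0, k - k0)))
}

#' Generate a synthetic lesion progression
#'
#' Interpolates every lesion property between the start and end specs over
#' \code{nFrames} frames (the structural seed is shared so the lesion keeps
#' its identity; pixel noise is redrawn per frame), adds the illumination
#' drift, and attaches a sigmoid nevus-confidence series plus per-frame
#' ground truth.
#'
#' @param pspec A \code{ProgressionSpec} from \code{\link{progressionSpec}}.
#' @return List with \code{sequence} (\linkS4class{FrameSequence}),
#'   \code{confidence} (numeric vector) and \code{groundTruth} (data frame
#'   with per-frame analytic diameter, warp amplitude and palette size).
#' @export
generateProgression <- function(pspec) {
  n <- pspec$nFrames
  s <- pspec$start; e <- pspec$end
  t <- (seq_len(n) - 1) / (n - 1)
  wgt <- if (pspec$interpolation == "sigmoid") {
    z <- 1 / (1 + exp(-pspec$confidenceCurve$steepness * (t - 0.5)))
    (z - z[1]) / (z[n] - z[1])
  } else t
  k <- max(nrow(s$palette$colors), nrow(e$palette$colors))
  kS <- nrow(s$palette$colors); kE <- nrow(e$palette$colors)
  palS <- .padPalette(s$palette, k)
  palE <- .padPalette(e$palette, k)
  # padded sectors all carry the base color, so the padded side's fraction
  # split is a free gauge: pin it to the other side's fractions so sector
  # geometry is constant and only the colors drift
  if (kS < k) palS$fractions <- palE$fractions
  if (kE < k) palE$fractions <- palS$fractions
  framesList <- vector("list", n)
  gt <- vector("list", n)
  for (f in seq_len(n)) {
    wf <- wgt[f]
    lerp <- function(a, b) a + (b - a) * wf
    pal <- list(colors = palS$colors + (palE$colors - palS$colors) * wf,
                fractions = palS$fractions +
                  (palE$fractions - palS$fractions) * wf)
    spec <- lesionSpec(canvas = s$canvas, center = s$center,
                       radius = lerp(s$radius, e$radius),
                       eccentricity = lerp(s$eccentricity, e$eccentricity),
                       orientation = lerp(s$orientation, e$orientation),
                       asymmetryWarp = lerp(s$asymmetryWarp, e$asymmetryWarp),
                       borderBlurSigma = lerp(s$borderBlurSigma,
                                              e$borderBlurSigma),
                       palette = pal, noiseSigma = lerp(s$noiseSigma,
                                                        e$noiseSigma),
                       skinColor = s$skinColor,
                       textureAmp = lerp(s$textureAmp, e$textureAmp),
                       skinTextureAmp = lerp(s$skinTextureAmp,
                                             e$skinTextureAmp),
                       seed = s$seed)
    fr <- generateLesion(spec, noiseSeed = s$seed + 7919L * f)
    drift <- pspec$illuminationDrift * t[f]
    if (any(drift != 0)) {
      img <- frameImage(fr)
      for (ch in 1:3) img[, , ch] <- img[, , ch] + drift[ch]
      fr2 <- LesionFrame(round(.clamp(img, 0, 255)), mask = frameMask(fr))
      attr(fr2, "groundTruth") <- attr(fr, "groundTruth")
      fr <- fr2
    }
    framesList[[f]] <- fr
    g <- attr(fr, "groundTruth")
    gt[[f]] <- data.frame(frame_index = f - 1L,
                          diameter = g$majorAxisLen,
                          asymmetry_warp = g$asymmetryWarp,
                          n_colors = sum(pal$fractions > 0.01))
  }
  cc <- pspec$confidenceCurve
  z <- 1 / (1 + exp(-cc$steepness * (t - 0.5)))
  z <- (z - z[1]) / (z[n] - z[1])
  conf <- cc$start + (cc$end - cc$start) * z
  list(sequence = FrameSequence(framesList), confidence = conf,
       groundTruth = do.call(rbind, gt))
}

#' Nevus-to-melanoma progression preset
#'
#' A 20-frame (by default) progression emulating the qualitative pattern of
#' simulated nevus-to-melanoma transitions: the boundary warps (asymmetry
#' up), the border sharpens (blur 4 px down to 1 px, matching the observed
#' darkening/sharpening of simulated melanomas), one brown color mode drifts
#' apart into three chromatically distinct modes - reddish-brown,
#' grey-brown and blue-grey, the classic variegation tones - while internal
#' texture and noise grow (dispersion up), the diameter grows, a mild global
#' illumination drift accumulates (exercising the color normalization), and
#' the nevus confidence decays sigmoidally from 0.97 to 0.08.
#'
#' @param nFrames Number of frames (default 20).
#' @param seed Master seed (default 7).
#' @return A \code{ProgressionSpec}.
#' @export
presetNevusToMelanoma <- function(nFrames = 20L, seed = 7L) {
  skin <- c(160, 130, 110)
  start <- lesionSpec(radius = 32, eccentricity = 0.15, orientation = 0.4,
                      asymmetryWarp = 0.02, borderBlurSigma = 4,
                      skinColor = skin,
                      palette = list(colors = matrix(c(0.36, 0.22, 0.13),
                                                     1, 3),
                                     fractions = 1),
                      noiseSigma = 0.01, textureAmp = 0.15, seed = seed)
  end <- lesionSpec(radius = 40, eccentricity = 0.35, orientation = 0.4,
                    asymmetryWarp = 0.4, borderBlurSigma = 1,
                    skinColor = skin,
                    palette = list(colors = matrix(c(0.46, 0.17, 0.10,
                                                     0.24, 0.26, 0.18,
                                                     0.16, 0.18, 0.26),
                                                   3, 3, byrow = TRUE),
                                   fractions = c(0.4, 0.4, 0.2)),
                    noiseSigma = 0.03, textureAmp = 0.3, seed = seed)
  progressionSpec(nFrames, start, end, interpolation = "linear",
                  illuminationDrift = c(10, 8, 6),
                  confidenceCurve = list(start = 0.97, end = 0.08,
                                         steepness = 8))
}
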