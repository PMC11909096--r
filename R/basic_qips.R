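## Histogram-based global statistics: image dimensions, RMS contrast,
## lightness entropy, channel means/SDs, color entropy. All are invariant
## under spatial permutation of pixels.

# Shannon entropy (bits) of counts in equal-width bins over [lo, hi]
.hist_entropy <- function(x, bins, lo, hi) {
  idx <- floor((x - lo) / (hi - lo) * bins) + 1L
  idx[idx > bins] <- bins           # right edge closed
  idx[idx < 1L] <- 1L
  p <- tabulate(idx, nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# population standard deviation
.psd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Image size
#'
#' Scalar size of an image; the default (and the field's convention) is the
#' sum of width and height.
#'
#' @param img a [qip_image] or [qip_gray].
#' @param method one of `"sum"`, `"product"`, `"diagonal"`, `"min"`, `"max"`.
#' @return size in pixels (pixels squared for `"product"`).
#' @export
image_size <- function(img, method = c("sum", "product", "diagonal", "min", "max")) {
  method <- match.arg(method)
  d <- dim(img); h <- d[1]; w <- d[2]
  switch(method,
         sum = w + h,
         product = w * h,
         diagonal = sqrt(w^2 + h^2),
         min = min(w, h),
         max = max(w, h))
}

#' Aspect ratio (width / height)
#' @param img a [qip_image] or [qip_gray].
#' @return dimensionless ratio W / H.
#' @export
aspect_ratio <- function(img) {
  d <- dim(img)
  d[2] / d[1]
}

#' RMS contrast
#'
#' Population standard deviation of the CIELAB L* channel.
#'
#' @param img a [qip_image] or a `qip_lab` object.
#' @return contrast in L* units.
#' @export
rms_contrast <- function(img) {
  lab <- if (inherits(img, "qip_lab")) img else convert_color(img, "lab")
  .psd(lab$L)
}

#' Lightness entropy
#'
#' Shannon entropy (bits) of the L* histogram: 256 equal-width bins over
#' \[0, 100\], so a uniformly occupied histogram scores 8 bits.
#'
#' @param img a [qip_image] or `qip_lab`.
#' @param bins histogram bin count (default 256).
#' @return entropy in bits, within \[0, log2(bins)\].
#' @export
lightness_entropy <- function(img, bins = 256L) {
  stopifnot(bins >= 2L)
  lab <- if (inherits(img, "qip_lab")) img else convert_color(img, "lab")
  .hist_entropy(as.vector(lab$L), bins, 0, 100)
}

#' Color entropy
#'
#' Shannon entropy (bits) of the HSV hue histogram (256 equal bins on
#' \[0, 1)).
#'
#' @param img a [qip_image] or `qip_hsv`.
#' @param bins histogram bin count (default 256).
#' @return entropy in bits, within \[0, log2(bins)\].
#' @export
color_entropy <- function(img, bins = 256L) {
  stopifnot(bins >= 2L)
  hsv <- if (inherits(img, "qip_hsv")) img else convert_color(img, "hsv")
  .hist_entropy(as.vector(hsv$h), bins, 0, 1)
}

#' Means and standard deviations of nine color channels
#'
#' R, G, B (0-255), CIELAB L*, a*, b*, and HSV H, S, V (0-1). Hue uses plain
#' linear statistics on \[0, 1); standard deviations are population SDs.
#'
#' @param img a [qip_image].
#' @return data frame with columns `channel`, `mean`, `sd` (9 rows).
#' @export
color_channel_stats <- function(img) {
  stopifnot(inherits(img, "qip_image"))
  lab <- convert_color(img, "lab")
  hsv <- convert_color(img, "hsv")
  chans <- list(R = img$pixels[, , 1L], G = img$pixels[, , 2L],
                B = img$pixels[, , 3L],
                L = lab$L, a = lab$a, b = lab$b,
                H = hsv$h, S = hsv$s, V = hsv$v)
  data.frame(channel = names(chans),
             mean = vapply(chans, mean, numeric(1)),
             sd = vapply(chans, .psd, numeric(1)),
             row.names = NULL)
}
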