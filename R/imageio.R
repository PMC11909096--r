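#' @importFrom stats fft median sd var cor quantile runif rnorm
#' @importFrom grDevices rgb2hsv convertColor
#' @importFrom utils write.csv read.csv
NULL

#' Construct a raster image object
#'
#' The universal input of every measure: an H x W x 3 array of 8-bit sRGB
#' intensities in \[0, 255\]. Grayscale matrices are promoted to three equal
#' channels.
#'
#' @param pixels numeric H x W x 3 array (or H x W matrix, promoted) with
#'   values in \[0, 255\]; rows index height.
#' @param source_id text label carried through to batch output.
#' @return an object of class `qip_image`.
#' @export
qip_image <- function(pixels, source_id = "image") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("zero-area image")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, source_id = source_id), class = "qip_image")
}

#' @export
print.qip_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<qip_image '%s': %d x %d px, 3 channels>\n", x$source_id, d[1], d[2]))
  invisible(x)
}

#' @export
dim.qip_image <- function(x) dim(x$pixels)[1:2]

#' Construct a grayscale image object
#'
#' @param pixels numeric H x W matrix.
#' @param scale `"gray8"` (values in \[0, 255\]) or `"lstar"` (CIELAB L*,
#'   values in \[0, 100\]).
#' @param source_id text label.
#' @return an object of class `qip_gray`.
#' @export
qip_gray <- function(pixels, scale = c("gray8", "lstar"), source_id = "image") {
  scale <- match.arg(scale)
  stopifnot(is.matrix(pixels))
  hi <- if (scale == "gray8") 255 else 100
  if (anyNA(pixels) || min(pixels) < -1e-9 || max(pixels) > hi + 1e-9) {
    stop(sprintf("gray values outside declared '%s' range [0, %g]", scale, hi))
  }
  structure(list(pixels = pixels, scale = scale, source_id = source_id),
            class = "qip_gray")
}

#' @export
dim.qip_gray <- function(x) dim(x$pixels)

#' @export
print.qip_gray <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<qip_gray '%s': %d x %d px, scale %s>\n", x$source_id, d[1], d[2], x$scale))
  invisible(x)
}

#' Load a raster image from disk
#'
#' Reads PNG, JPEG or TIFF through EBImage and normalizes to the package's
#' canonical form: 8-bit RGB, grayscale promoted to three channels, alpha
#' composited over white, 16-bit inputs rescaled to 8-bit.
#'
#' @param path file path of a PNG, JPEG or TIFF image.
#' @param source_id label for the image; defaults to the file name.
#' @return a [qip_image].
#' @export
load_image <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e) stop("failed to load '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  dat <- EBImage::imageData(img)  # x (width) first, in [0, 1]
  if (length(dim(dat)) == 2L) dat <- array(dat, dim = c(dim(dat), 1L))
  if (dim(dat)[1] < 1L || dim(dat)[2] < 1L) stop("zero-area image: ", path)
  nc <- dim(dat)[3]
  if (nc == 2L) {           # gray + alpha
    a <- dat[, , 2L]
    g <- dat[, , 1L] * a + (1 - a)
    dat <- array(rep(g, 3L), dim = c(dim(g), 3L))
  } else if (nc == 1L) {
    dat <- array(rep(dat[, , 1L], 3L), dim = c(dim(dat)[1:2], 3L))
  } else if (nc >= 4L) {    # straight alpha over white
    a <- dat[, , 4L]
    dat <- array(c(dat[, , 1L] * a + (1 - a),
                   dat[, , 2L] * a + (1 - a),
                   dat[, , 3L] * a + (1 - a)), dim = c(dim(dat)[1:2], 3L))
  } else {
    dat <- dat[, , 1:3, drop = FALSE]
  }
  px <- aperm(dat, c(2L, 1L, 3L)) * 255   # rows index height
  px[px < 0] <- 0; px[px > 255] <- 255
  qip_image(round(px), source_id = source_id)
}

## ---- color conversion -----------------------------------------------------

# vectorized sRGB (D65) -> CIELAB; input in [0,255], output L in [0,100]
.srgb_to_lab <- function(r, g, b) {
  lin <- function(c) {
    c <- c / 255
    lo <- c <= 0.04045
    c[lo] <- c[lo] / 12.92
    c[!lo] <- ((c[!lo] + 0.055) / 1.055)^2.4
    c
  }
  rl <- lin(r); gl <- lin(g); bl <- lin(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  # D65 reference white
  X <- X / 0.95047; Z <- Z / 1.08883
  f <- function(t) {
    d <- 6 / 29
    hi <- t > d^3
    t[hi] <- t[hi]^(1 / 3)
    t[!hi] <- t[!hi] / (3 * d^2) + 4 / 29
    t
  }
  fX <- f(X); fY <- f(Y); fZ <- f(Z)
  list(L = 116 * fY - 16, a = 500 * (fX - fY), b = 200 * (fY - fZ))
}

# CIELAB -> sRGB in [0,255] (used by round-trip tests)
.lab_to_srgb <- function(L, a, b) {
  d <- 6 / 29
  fY <- (L + 16) / 116
  fX <- fY + a / 500
  fZ <- fY - b / 200
  finv <- function(t) ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
  X <- finv(fX) * 0.95047; Y <- finv(fY); Z <- finv(fZ) * 1.08883
  rl <-  3.2404542 * X - 1.5371385 * Y - 0.4985314 * Z
  gl <- -0.9692660 * X + 1.8760108 * Y + 0.0415560 * Z
  bl <-  0.0556434 * X - 0.2040259 * Y + 1.0572252 * Z
  gam <- function(c) {
    c[c < 0] <- 0; c[c > 1] <- 1
    ifelse(c <= 0.0031308, 12.92 * c, 1.055 * c^(1 / 2.4) - 0.055)
  }
  list(r = gam(rl) * 255, g = gam(gl) * 255, b = gam(bl) * 255)
}

# legacy luma weights; kept as a named constant so parity checks are possible
.LUMA <- c(0.299, 0.587, 0.114)

#' Convert an image between color representations
#'
#' `gray8` uses the legacy luma weights 0.299/0.587/0.114; `lab` is CIELAB
#' under sRGB primaries and D65 white (one shared conversion for the whole
#' suite); `hsv` has all three channels on \[0, 1\] (H in \[0, 1)).
#'
#' @param img a [qip_image].
#' @param target one of `"gray8"`, `"lab"`, `"hsv"`.
#' @return a `qip_gray`, `qip_lab` or `qip_hsv` object of the same H x W.
#' @export
convert_color <- function(img, target = c("gray8", "lab", "hsv")) {
  stopifnot(inherits(img, "qip_image"))
  target <- match.arg(target)
  p <- img$pixels
  d <- dim(p)
  r <- matrix(p[, , 1L], d[1], d[2])
  g <- matrix(p[, , 2L], d[1], d[2])
  b <- matrix(p[, , 3L], d[1], d[2])
  if (target == "gray8") {
    gray <- .LUMA[1] * r + .LUMA[2] * g + .LUMA[3] * b
    return(qip_gray(gray, scale = "gray8", source_id = img$source_id))
  }
  if (target == "lab") {
    lab <- .srgb_to_lab(r, g, b)
    return(structure(list(L = matrix(lab$L, nrow(r)), a = matrix(lab$a, nrow(r)),
                          b = matrix(lab$b, nrow(r)), source_id = img$source_id),
                     class = "qip_lab"))
  }
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 255)
  h <- matrix(hsv[1L, ], nrow(r)); h[h >= 1] <- 0
  structure(list(h = h, s = matrix(hsv[2L, ], nrow(r)),
                 v = matrix(hsv[3L, ], nrow(r)), source_id = img$source_id),
            class = "qip_hsv")
}

#' @export
dim.qip_lab <- function(x) dim(x$L)

#' @export
dim.qip_hsv <- function(x) dim(x$h)

## ---- size standardization -------------------------------------------------

.resize_channel <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  e <- EBImage::resize(EBImage::Image(t(m)), w = w, h = h, filter = "bilinear")
  t(EBImage::imageData(e))
}

# largest integer H' x W' with H'*W' <= cap preserving W/H; never upscales
.cap_dims <- function(h, w, cap) {
  if (h * w <= cap) return(c(h, w))
  s <- sqrt(cap / (h * w))
  h2 <- max(1L, floor(h * s)); w2 <- max(1L, floor(w * s))
  # nudge up while still under the cap (floor can undershoot)
  while ((h2 + 1) * round((h2 + 1) * w / h) <= cap && h2 + 1 <= h) {
    h2 <- h2 + 1L; w2 <- round(h2 * w / h)
  }
  c(h2, max(1L, w2))
}

.largest_pow2 <- function(n) 2^floor(log2(n))

#' Standardized resizing, cropping and padding
#'
#' Applies one of the size policies every downstream measure relies on.
#' Resampling is bilinear with pixel-center alignment throughout.
#'
#' @param img a [qip_image] or [qip_gray].
#' @param kind one of `"longest_side"`, `"total_pixels"`, `"fixed_square"`,
#'   `"max_pixels_cap"`, `"center_crop_square_pow2"`, `"pad_square_mean_gray"`.
#' @param value target in pixels: side length for `longest_side` /
#'   `fixed_square`, pixel count for `total_pixels` / `max_pixels_cap`;
#'   ignored by the crop/pad policies.
#' @return the same kind of object as `img`.
#' @export
standardize_size <- function(img, kind = c("longest_side", "total_pixels",
                                           "fixed_square", "max_pixels_cap",
                                           "center_crop_square_pow2",
                                           "pad_square_mean_gray"),
                             value = NULL) {
  kind <- match.arg(kind)
  gray <- inherits(img, "qip_gray")
  stopifnot(gray || inherits(img, "qip_image"))
  d <- dim(img); h <- d[1]; w <- d[2]
  if (kind %in% c("longest_side", "total_pixels", "fixed_square", "max_pixels_cap")) {
    stopifnot(is.numeric(value), value > 0)
  }
  target <- switch(kind,
    longest_side = {
      if (h >= w) c(value, max(1L, round(value * w / h)))
      else        c(max(1L, round(value * h / w)), value)
    },
    total_pixels = {
      s <- sqrt(value / (h * w))
      c(max(1L, round(h * s)), max(1L, round(w * s)))
    },
    fixed_square = c(value, value),
    max_pixels_cap = .cap_dims(h, w, value),
    NULL)
  reshape <- function(px) {
    if (!is.null(target)) {
      if (gray) return(.resize_channel(px, target[1], target[2]))
      out <- array(0, c(target, 3L))
      for (k in 1:3) out[, , k] <- .resize_channel(px[, , k], target[1], target[2])
      return(out)
    }
    if (kind == "center_crop_square_pow2") {
      side <- .largest_pow2(min(h, w))
      if (side < 1) stop("image too small to crop")
      r0 <- floor((h - side) / 2); c0 <- floor((w - side) / 2)
      if (gray) px[r0 + seq_len(side), c0 + seq_len(side)]
      else      px[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
    } else {  # pad_square_mean_gray
      side <- max(h, w)
      r0 <- floor((side - h) / 2); c0 <- floor((side - w) / 2)
      if (gray) {
        out <- matrix(mean(px), side, side)
        out[r0 + seq_len(h), c0 + seq_len(w)] <- px
        out
      } else {
        out <- array(0, c(side, side, 3L))
        for (k in 1:3) {
          ch <- matrix(mean(px[, , k]), side, side)
          ch[r0 + seq_len(h), c0 + seq_len(w)] <- px[, , k]
          out[, , k] <- ch
        }
        out
      }
    }
  }
  px <- reshape(if (gray) img$pixels else img$pixels)
  if (gray) {
    hi <- if (img$scale == "gray8") 255 else 100
    px[px < 0] <- 0; px[px > hi] <- hi
    qip_gray(px, scale = img$scale, source_id = img$source_id)
  } else {
    px[px < 0] <- 0; px[px > 255] <- 255
    qip_image(px, source_id = img$source_id)
  }
}
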