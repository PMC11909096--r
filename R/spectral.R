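## Fourier-spectrum and box-counting scale-invariance measures: radially
## averaged spectra, the three slope-fitting protocols, spectrum sigma, and
## the 2D / 3D box-counting fractal dimensions.

# cache of rounded-radius index grids, keyed by image side
.radius_cache <- new.env(parent = emptyenv())

.radius_index <- function(n) {
  key <- as.character(n)
  got <- .radius_cache[[key]]
  if (!is.null(got)) return(got)
  r <- as.integer(round(.freq_radius(n)))
  .radius_cache[[key]] <- r
  r
}

#' Radially averaged Fourier spectrum
#'
#' 2D DFT of a square grayscale image; annuli are integer radii (rounded
#' Euclidean frequency in cycles/image) and the spectrum value at radius f
#' is the mean amplitude (or power) over the annulus. DC is excluded.
#'
#' @param img a `qip_gray` with equal sides.
#' @param mode `"amplitude"` or `"power"`.
#' @return data frame with `f` (1 .. side/2) and `value`.
#' @export
radial_spectrum <- function(img, mode = c("amplitude", "power")) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "qip_gray"))
  p <- img$pixels
  if (nrow(p) != ncol(p)) {
    stop("radial_spectrum needs a square image; apply standardize_size first")
  }
  n <- nrow(p)
  amp <- Mod(stats::fft(p)) / (n * n)
  r <- .radius_index(n)
  val <- if (mode == "power") amp^2 else amp
  fmax <- n %/% 2
  sel <- r >= 1 & r <= fmax
  ri <- r[sel]
  tot <- rowsum(val[sel], ri)
  cnt <- tabulate(ri, nbins = fmax)
  f <- as.integer(rownames(tot))
  data.frame(f = f, value = as.numeric(tot) / cnt[f])
}

# OLS of y on x returning slope/intercept/diagnostics
.ols <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  b <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  a <- ym - b * xm
  r <- y - (a + b * x)
  list(slope = b, intercept = a, residuals = r, mse = mean(r^2))
}

# Cook's distance for simple linear regression
.cooks <- function(x, r) {
  n <- length(x)
  xm <- mean(x)
  hii <- 1 / n + (x - xm)^2 / sum((x - xm)^2)
  s2 <- sum(r^2) / (n - 2)
  (r^2 / (2 * s2)) * hii / (1 - hii)^2
}

# log10 binning: `nbins` equal-width bins in log10 f over [flo, fhi];
# bin value = mean log10 of the spectrum, empty bins dropped
.log_bin <- function(f, v, flo, fhi, nbins = 100L) {
  lx <- log10(f); ly <- log10(v)
  edges <- seq(log10(flo), log10(fhi), length.out = nbins + 1L)
  idx <- findInterval(lx, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > nbins] <- nbins
  bx <- tapply(lx, idx, mean); by <- tapply(ly, idx, mean)
  list(x = as.numeric(bx), y = as.numeric(by))
}

#' Fourier spectrum slope
#'
#' Three published protocols, differing in pre-processing, spectrum mode,
#' frequency exclusion and binning:
#' \describe{
#'   \item{spehar}{8-bit grayscale, center crop to the largest power-of-two
#'     square; amplitude spectrum; all radii 1 .. N/2 fitted, then points
#'     with Cook's distance above `cooks_threshold` (default 4/m) removed
#'     and the line refitted once.}
#'   \item{redies}{8-bit grayscale, padded to a square with the mean gray
#'     value and resized to 1024 x 1024; power spectrum; radii 10-256
#'     cycles/image retained; 100 equal log-frequency bins fitted.}
#'   \item{mather}{CIELAB L* channel, center crop to the largest
#'     power-of-two square and resize to 1024 x 1024; amplitude spectrum;
#'     the lowest and highest quartiles of the available radii dropped and
#'     the middle half fitted.}
#' }
#'
#' @param img a [qip_image] or `qip_gray`.
#' @param method `"spehar"`, `"redies"` or `"mather"`.
#' @param cooks_threshold influence cutoff for the spehar pruning pass;
#'   `NULL` uses 4/m with m the number of fitted radii.
#' @return list (class `qip_slope_fit`) with `slope`, `intercept`, `sigma`
#'   (mean squared residual of the fitted points), `f`, `logf`, `logv`,
#'   `method`, `n_half`; slope is `NaN` with a warning for constant images.
#' @export
fourier_slope <- function(img, method = c("spehar", "redies", "mather"),
                          cooks_threshold = NULL) {
  method <- match.arg(method)
  prep <- switch(method,
    spehar = {
      g <- if (inherits(img, "qip_gray")) img else convert_color(img, "gray8")
      standardize_size(g, "center_crop_square_pow2")
    },
    redies = {
      g <- if (inherits(img, "qip_gray")) img else convert_color(img, "gray8")
      g <- standardize_size(g, "pad_square_mean_gray")
      standardize_size(g, "fixed_square", 1024)
    },
    mather = {
      lab <- if (inherits(img, "qip_gray")) {
        # grayscale input: promote to RGB for the CIELAB transform
        convert_color(qip_image(img$pixels, img$source_id), "lab")
      } else convert_color(img, "lab")
      g <- qip_gray(pmin(pmax(lab$L, 0), 100), scale = "lstar",
                    source_id = if (!is.null(img$source_id)) img$source_id else "image")
      g <- standardize_size(g, "center_crop_square_pow2")
      standardize_size(g, "fixed_square", 1024)
    })
  mode <- if (method == "redies") "power" else "amplitude"
  spec <- radial_spectrum(prep, mode)
  n_half <- nrow(prep$pixels) %/% 2
  spec <- spec[spec$value > 0, ]
  if (nrow(spec) < 3L) {
    warning("degenerate spectrum (constant image?): slope is NaN")
    return(structure(list(slope = NaN, intercept = NaN, sigma = NaN,
                          f = integer(0), logf = numeric(0), logv = numeric(0),
                          method = method, n_half = n_half),
                     class = "qip_slope_fit"))
  }
  if (method == "redies") {
    keep <- spec$f >= 10 & spec$f <= 256
    spec <- spec[keep, ]
    bb <- .log_bin(spec$f, spec$value, 10, 256)
    fit <- .ols(bb$x, bb$y)
    return(structure(list(slope = fit$slope, intercept = fit$intercept,
                          sigma = fit$mse, f = spec$f,
                          logf = bb$x, logv = bb$y,
                          raw_logf = log10(spec$f), raw_logv = log10(spec$value),
                          method = method, n_half = n_half),
                     class = "qip_slope_fit"))
  }
  if (method == "mather") {
    m <- nrow(spec)
    qs <- floor(m / 4)
    spec <- spec[(qs + 1):(m - qs), ]
  }
  lx <- log10(spec$f); ly <- log10(spec$value)
  fit <- .ols(lx, ly)
  if (method == "spehar") {
    thr <- if (is.null(cooks_threshold)) 4 / length(lx) else cooks_threshold
    cd <- .cooks(lx, fit$residuals)
    keep <- cd <= thr
    if (sum(keep) >= 3L && any(!keep)) {
      lx <- lx[keep]; ly <- ly[keep]
      spec <- spec[keep, ]
      fit <- .ols(lx, ly)
    }
  }
  structure(list(slope = fit$slope, intercept = fit$intercept, sigma = fit$mse,
                 f = spec$f, logf = lx, logv = ly,
                 method = method, n_half = n_half),
            class = "qip_slope_fit")
}

#' @export
print.qip_slope_fit <- function(x, ...) {
  cat(sprintf("<Fourier slope fit [%s]: slope %.4f, sigma %.5f, %d points>\n",
              x$method, x$slope, x$sigma, length(x$logf)))
  invisible(x)
}

#' Fourier spectrum sigma
#'
#' Mean squared residual of the log power spectrum about the fitted
#' regression line of the redies protocol (power spectrum, 10-256
#' cycles/image, line fitted on log-binned points). `binned = FALSE`
#' evaluates residuals at every raw radius (the original convention, which
#' over-represents high frequencies); `binned = TRUE` at the binned points.
#'
#' @param img a [qip_image] or `qip_gray`.
#' @param binned residuals on binned (`TRUE`) or raw (`FALSE`) points.
#' @return sigma (>= 0); `NaN` with a warning for degenerate images.
#' @export
fourier_sigma <- function(img, binned = FALSE) {
  fit <- fourier_slope(img, "redies")
  if (is.nan(fit$slope)) return(NaN)
  if (binned) return(fit$sigma)
  r <- fit$raw_logv - (fit$intercept + fit$slope * fit$raw_logf)
  mean(r^2)
}

## ---- box counting ---------------------------------------------------------

# per-box min/max by factor-2 pooling; m must have power-of-two sides
.pool2 <- function(m, fun) {
  h <- nrow(m); w <- ncol(m)
  a <- m[seq(1, h, 2), seq(1, w, 2)]
  b <- m[seq(2, h, 2), seq(1, w, 2)]
  c_ <- m[seq(1, h, 2), seq(2, w, 2)]
  d <- m[seq(2, h, 2), seq(2, w, 2)]
  fun(fun(a, b), fun(c_, d))
}

# boundary-pixel mask of a logical matrix: TRUE where the value differs from
# the right or lower neighbour
.edge_mask <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  (bw != bw[, c(2:w, w)]) | (bw != bw[c(2:h, h), ])
}

#' 2D box-counting fractal dimension
#'
#' The image is center-cropped to the largest power-of-two square and
#' binarized at its mean lightness; boundary pixels (where the binary value
#' changes) are box-counted over sides L = side/2, side/4, ..., 4, and D is
#' the OLS slope of log2 N versus log2(1/L) over scales with N > 0.
#'
#' @param img a [qip_image] (binarized on L*) or `qip_gray` (binarized on
#'   its own scale).
#' @return list (class `qip_fractal`) with `D`, `kind = "2D"`, `L`, `N`;
#'   `D` in \[1, 2\] for well-behaved patterns (out-of-range fits are
#'   reported, never clamped). `NaN` with a warning when binarization
#'   degenerates.
#' @export
fractal_dim_2d <- function(img) {
  g <- if (inherits(img, "qip_gray")) img$pixels
       else convert_color(img, "lab")$L
  side <- .largest_pow2(min(dim(g)))
  r0 <- floor((nrow(g) - side) / 2); c0 <- floor((ncol(g) - side) / 2)
  g <- g[r0 + seq_len(side), c0 + seq_len(side)]
  bw <- g < mean(g)
  if (all(bw) || !any(bw)) {
    warning("binarization produced a single class: 2D fractal dimension is NaN")
    return(structure(list(D = NaN, kind = "2D", L = numeric(0), N = numeric(0)),
                     class = "qip_fractal"))
  }
  e <- .edge_mask(bw)
  Ls <- 2^seq(log2(4), log2(side / 2))    # 4, 8, ..., side/2
  has <- e
  counts <- numeric(0); sizes <- numeric(0)
  L <- 1
  while (L < max(Ls)) {
    has <- .pool2(has, `|`)
    L <- L * 2
    if (L %in% Ls) {
      counts <- c(counts, sum(has))
      sizes <- c(sizes, L)
    }
  }
  ok <- counts > 0
  if (sum(ok) < 2L) {
    warning("not enough occupied scales: 2D fractal dimension is NaN")
    return(structure(list(D = NaN, kind = "2D", L = sizes, N = counts),
                     class = "qip_fractal"))
  }
  fit <- .ols(log2(1 / sizes[ok]), log2(counts[ok]))
  structure(list(D = fit$slope, kind = "2D", L = sizes, N = counts),
            class = "qip_fractal")
}

#' 3D (differential) box-counting fractal dimension
#'
#' The lightness surface over the largest centered power-of-two square is
#' box-counted with boxes of side s = side/2, ..., 4: each s x s column
#' contributes floor(range / h) + 1 boxes, with box height
#' h = s * 255 / side (lightness rescaled to 0-255). D is the OLS slope of
#' ln N versus ln(1/s).
#'
#' @param img a [qip_image] (L* rescaled to 0-255) or `qip_gray` (gray8).
#' @return list (class `qip_fractal`) with `D`, `kind = "3D"`, `L`, `N`;
#'   `D` in \[2, 3\] for well-behaved surfaces. `NaN` with a warning for
#'   constant images.
#' @export
fractal_dim_3d <- function(img) {
  g <- if (inherits(img, "qip_gray")) {
    if (img$scale == "gray8") img$pixels else img$pixels * 2.55
  } else convert_color(img, "lab")$L * 2.55
  side <- .largest_pow2(min(dim(g)))
  r0 <- floor((nrow(g) - side) / 2); c0 <- floor((ncol(g) - side) / 2)
  g <- g[r0 + seq_len(side), c0 + seq_len(side)]
  if (max(g) == min(g)) {
    warning("constant image: 3D fractal dimension is NaN")
    return(structure(list(D = NaN, kind = "3D", L = numeric(0), N = numeric(0)),
                     class = "qip_fractal"))
  }
  sizes <- 2^seq(log2(4), log2(side / 2))  # 4 .. side/2
  mn <- g; mx <- g
  s <- 1
  counts <- numeric(0); used <- numeric(0)
  while (s < max(sizes)) {
    mn <- .pool2(mn, pmin); mx <- .pool2(mx, pmax)
    s <- s * 2
    if (s %in% sizes) {
      h <- s * 255 / side
      counts <- c(counts, sum(floor((mx - mn) / h) + 1))
      used <- c(used, s)
    }
  }
  fit <- .ols(log(1 / used), log(counts))
  structure(list(D = fit$slope, kind = "3D", L = used, N = counts),
            class = "qip_fractal")
}

#' @export
print.qip_fractal <- function(x, ...) {
  cat(sprintf("<%s box-counting fit: D = %.4f over %d scales>\n",
              x$kind, x$D, length(x$L)))
  invisible(x)
}
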