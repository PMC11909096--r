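## Deterministic synthetic-image generators. Every generator is a pure
## function of its parameters and seed: identical calls are bit-identical.
## Their construction-time ground truth (spectral exponent, Hurst exponent,
## orientation counts, exact symmetry) is what the measure tests recover.

# isolated RNG scope; stream depends on seed plus a per-generator tag so
# adding generators never shifts existing fixtures
.with_fixture_rng <- function(seed, tag, fun) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  tweak <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  set.seed((as.integer(seed) + tweak) %% .Machine$integer.max)
  fun()
}

# centered frequency radius grid for an N x N DFT (cycles/image)
.freq_radius <- function(n) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  fx <- matrix(rep(f, each = n), n, n)
  fy <- matrix(rep(f, times = n), n, n)
  sqrt(fx^2 + fy^2)
}

.rescale_gray <- function(z, quantize) {
  rng <- range(z)
  if (diff(rng) == 0) z[] <- 127.5 else z <- (z - rng[1]) / diff(rng) * 255
  if (quantize) z <- round(z)
  z
}

#' Random-phase image with a prescribed spectral exponent
#'
#' Synthesizes a grayscale image whose radial amplitude spectrum follows
#' f^(-alpha) with uniformly random phases (Hermitian-symmetric, so the
#' inverse transform is real). The DC component is mid-gray. Values are
#' rescaled to the \[0, 255\] range; by default they are kept continuous so
#' the constructed spectrum is exact (set `quantize = TRUE` for true 8-bit
#' output).
#'
#' @param size image side in pixels (a power of two).
#' @param alpha spectral amplitude exponent (>= 0).
#' @param seed integer seed; same seed, same image.
#' @param quantize round to integer gray levels.
#' @return a `qip_gray` (gray8 scale) of `size` x `size`.
#' @export
random_phase_image <- function(size, alpha, seed, quantize = FALSE) {
  stopifnot(size >= 4, bitwAnd(size, size - 1L) == 0, alpha >= 0)
  .with_fixture_rng(seed, "random_phase", function() {
    r <- .freq_radius(size)
    amp <- ifelse(r > 0, r^(-alpha), 0)
    wn <- matrix(stats::rnorm(size * size), size, size)
    W <- stats::fft(wn)
    ph <- W / ifelse(Mod(W) > 0, Mod(W), 1)   # unit-modulus, Hermitian
    z <- stats::fft(amp * ph, inverse = TRUE) / (size * size)
    stopifnot(max(abs(Im(z))) < 1e-6 * (max(abs(Re(z))) + 1e-12))
    qip_gray(.rescale_gray(Re(z), quantize), scale = "gray8",
             source_id = sprintf("random_phase_a%.3f_s%d", alpha, seed))
  })
}

#' Fractional-Brownian-motion gray surface
#'
#' Spectral synthesis of a sampled fBm surface with Hurst exponent H. The
#' continuous process has power-spectrum exponent -(2H + 2); sampling folds
#' the out-of-band power back into the spectrum, so the synthesis sums the
#' aliased spectral replicas (`alias_k` shifts per axis) instead of using
#' the bare power law. The surface's radial power-spectrum slope is
#' -(2H + 2) over the resolved range and its box-counting dimension
#' approaches 3 - H.
#'
#' @param size image side (power of two).
#' @param hurst Hurst exponent in (0, 1).
#' @param seed integer seed.
#' @param quantize round to integer gray levels.
#' @param alias_k number of aliased replicas summed per axis (0 gives the
#'   bare band-limited power law, whose fine-scale increments are smoother
#'   than true sampled fBm).
#' @return a `qip_gray` of `size` x `size`.
#' @export
fbm_surface <- function(size, hurst, seed, quantize = FALSE, alias_k = 6L) {
  stopifnot(hurst > 0, hurst < 1, size >= 4, bitwAnd(size, size - 1L) == 0)
  beta <- 2 * hurst + 2
  n <- size
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  fx <- matrix(rep(f, each = n), n, n)
  fy <- matrix(rep(f, times = n), n, n)
  P <- matrix(0, n, n)
  for (kx in -alias_k:alias_k) {
    for (ky in -alias_k:alias_k) {
      r2 <- (fx + kx * n)^2 + (fy + ky * n)^2
      nz <- r2 > 0
      P[nz] <- P[nz] + r2[nz]^(-beta / 2)
    }
  }
  P[1L, 1L] <- 0
  amp <- sqrt(P)
  .with_fixture_rng(seed, "fbm_surface", function() {
    W <- stats::fft(matrix(stats::rnorm(n * n), n, n))
    ph <- W / ifelse(Mod(W) > 0, Mod(W), 1)
    z <- Re(stats::fft(amp * ph, inverse = TRUE)) / (n * n)
    qip_gray(.rescale_gray(z, quantize), scale = "gray8",
             source_id = sprintf("fbm_H%.2f_s%d", hurst, seed))
  })
}

#' Line-segment pattern with a controlled orientation distribution
#'
#' Dark anti-aliased segments of fixed length on a white ground. Orientation
#' law: a single angle, `k` evenly spaced discrete angles cycled over the
#' segments, or a stratified uniform spread; layout places segment centers on
#' a regular lattice or at seeded random positions. Segments are drawn at 4x
#' supersampling and box-downsampled.
#'
#' @param size image side in pixels.
#' @param n_segments number of segments.
#' @param orientation_law `"single"`, `"discrete"` or `"uniform"`.
#' @param theta angle in degrees for `"single"` (segment direction).
#' @param k number of discrete orientations for `"discrete"`.
#' @param layout `"lattice"` or `"random"`.
#' @param seg_len,seg_width segment geometry in pixels.
#' @param seed integer seed (used by the random layout and the uniform jitter
#'   of nothing else: orientation counts are exact by construction).
#' @return a `qip_gray`, with attribute `"orientations"` holding the drawn
#'   angles in degrees.
#' @export
line_pattern <- function(size, n_segments,
                         orientation_law = c("single", "discrete", "uniform"),
                         theta = 0, k = 4L, layout = c("lattice", "random"),
                         seg_len = NULL, seg_width = 2, seed = 1) {
  orientation_law <- match.arg(orientation_law)
  layout <- match.arg(layout)
  if (is.null(seg_len)) seg_len <- max(8, round(size / 10))
  if (seg_len + 2 > size) stop("segments do not fit in the image")
  angles <- switch(orientation_law,
    single = rep(theta, n_segments),
    discrete = (180 / k) * ((seq_len(n_segments) - 1L) %% k),
    uniform = 180 * (seq_len(n_segments) - 0.5) / n_segments)
  .with_fixture_rng(seed, "line_pattern", function() {
    ss <- 4L
    n2 <- size * ss
    canvas <- matrix(0, n2, n2)  # accumulate ink
    margin <- seg_len / 2 + seg_width
    if (layout == "lattice") {
      g <- ceiling(sqrt(n_segments))
      if (g^2 < n_segments) g <- g + 1L
      step <- (size - 2 * margin) / max(1, g - 1)
      if (step <= 0) stop("infeasible packing: too many segments for the image")
      pos <- expand.grid(ix = 0:(g - 1), iy = 0:(g - 1))[seq_len(n_segments), ]
      cx <- margin + pos$ix * step
      cy <- margin + pos$iy * step
    } else {
      cx <- stats::runif(n_segments, margin, size - margin)
      cy <- stats::runif(n_segments, margin, size - margin)
    }
    if (orientation_law == "uniform")
      angles <- sample(angles)     # decouple angle from position rank
    for (i in seq_len(n_segments)) {
      a <- angles[i] * pi / 180
      ux <- cos(a); uy <- -sin(a)  # y grows downward; angle measured CCW
      x0 <- cx[i] * ss; y0 <- cy[i] * ss
      hl <- seg_len * ss / 2; hw <- seg_width * ss / 2
      xr <- max(1, floor(x0 - hl - hw)):min(n2, ceiling(x0 + hl + hw))
      yr <- max(1, floor(y0 - hl - hw)):min(n2, ceiling(y0 + hl + hw))
      px <- matrix(rep(xr - 0.5, each = length(yr)), length(yr))
      py <- matrix(rep(yr - 0.5, times = length(xr)), length(yr))
      dx <- px - x0; dy <- py - y0
      t_ <- dx * ux + dy * uy
      t_[t_ > hl] <- hl; t_[t_ < -hl] <- -hl
      d2 <- (dx - t_ * ux)^2 + (dy - t_ * uy)^2
      ink <- d2 <= hw^2
      canvas[yr, xr][ink] <- 1
    }
    # 4x box down-sample
    m <- matrix(0, size, size)
    for (dy in 0:(ss - 1)) for (dx in 0:(ss - 1)) {
      m <- m + canvas[seq(1 + dy, n2, by = ss), seq(1 + dx, n2, by = ss)]
    }
    g8 <- 255 * (1 - m / ss^2)
    out <- qip_gray(g8, scale = "gray8",
                    source_id = sprintf("lines_%s_%s_n%d", orientation_law,
                                        layout, n_segments))
    attr(out, "orientations") <- angles
    out
  })
}

#' Exactly mirror-symmetric composite
#'
#' Concatenates an image with its reflection so the result is bit-exactly
#' symmetric about the chosen axis (the output side along that axis is even).
#'
#' @param img a [qip_image] or `qip_gray`.
#' @param axis `"lr"` (vertical mirror axis) or `"ud"`.
#' @return same kind of object as `img`.
#' @export
mirrored_composite <- function(img, axis = c("lr", "ud")) {
  axis <- match.arg(axis)
  flip <- function(m) if (axis == "lr") m[, ncol(m):1, drop = FALSE]
                      else m[nrow(m):1, , drop = FALSE]
  glue <- function(m) if (axis == "lr") cbind(m, flip(m)) else rbind(m, flip(m))
  if (inherits(img, "qip_gray")) {
    return(qip_gray(glue(img$pixels), scale = img$scale,
                    source_id = paste0(img$source_id, "_mirror_", axis)))
  }
  stopifnot(inherits(img, "qip_image"))
  ch <- lapply(1:3, function(k) glue(img$pixels[, , k]))
  qip_image(array(unlist(ch), c(dim(ch[[1]]), 3L)),
            source_id = paste0(img$source_id, "_mirror_", axis))
}

#' Tiled texture
#'
#' Repeats a tile `reps` x `reps` times; aligned tilings make the
#' self-similarity measures approach 1 by construction.
#'
#' @param tile a [qip_image] or `qip_gray` used as the repeating unit.
#' @param reps repetitions per side.
#' @return same kind of object as `tile`.
#' @export
tiled_texture <- function(tile, reps) {
  stopifnot(reps >= 1)
  rep_mat <- function(m) {
    row <- do.call(cbind, rep(list(m), reps))
    do.call(rbind, rep(list(row), reps))
  }
  if (inherits(tile, "qip_gray")) {
    return(qip_gray(rep_mat(tile$pixels), scale = tile$scale,
                    source_id = paste0(tile$source_id, "_tiled")))
  }
  stopifnot(inherits(tile, "qip_image"))
  ch <- lapply(1:3, function(k) rep_mat(tile$pixels[, , k]))
  qip_image(array(unlist(ch), c(dim(ch[[1]]), 3L)),
            source_id = paste0(tile$source_id, "_tiled"))
}

#' Elementary fixtures: constant field, step edge, sinusoidal grating
#'
#' @param size image side in pixels.
#' @param value constant gray level.
#' @return a `qip_gray`.
#' @export
constant_image <- function(size, value = 128) {
  qip_gray(matrix(value, size, size), scale = "gray8", source_id = "constant")
}

#' @rdname constant_image
#' @param at column index of the first bright column.
#' @param lo,hi gray levels left/right of the step.
#' @export
step_edge <- function(size, at = ceiling(size / 2), lo = 0, hi = 255) {
  m <- matrix(lo, size, size)
  m[, at:size] <- hi
  qip_gray(m, scale = "gray8", source_id = "step_edge")
}

#' @rdname constant_image
#' @param wavelength grating period in pixels.
#' @param orientation grating orientation in degrees (0 = vertical bars,
#'   i.e. modulation along x).
#' @param phase phase offset in radians.
#' @export
grating <- function(size, wavelength = 8, orientation = 0, phase = 0) {
  x <- matrix(rep(0:(size - 1), each = size), size, size)
  y <- matrix(rep(0:(size - 1), times = size), size, size)
  a <- orientation * pi / 180
  u <- x * cos(a) + y * sin(a)
  g <- 127.5 + 127.5 * sin(2 * pi * u / wavelength + phase)
  qip_gray(g, scale = "gray8", source_id = "grating")
}
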