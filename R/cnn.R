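## First-layer convolutional-feature measures. A bank of 96 kernels of size
## 11 x 11 x 3 is correlated with the 511 x 511 working image at stride 4
## (126 x 126 response lattice) and rectified at zero. The odd working side
## keeps the lattice closed under reflection, which is what lets the
## symmetry scores reach 1.0 on mirrored composites.
##
## The default bank is a seeded surrogate of oriented edge kernels and
## color-opponent center-surround blobs, zero-mean per kernel. Pretrained
## conv1 weights can be supplied as a raw float32 asset; they are never
## downloaded.

.CONV_INPUT <- 511L
.CONV_KERN <- 11L
.CONV_STRIDE <- 4L
.CONV_MAPSIDE <- (511L - 11L) %/% 4L + 1L   # 126

#' Surrogate first-layer filter bank
#'
#' 96 zero-mean kernels (11 x 11 x 3): 64 oriented luminance edge kernels
#' (Gabor pairs over orientations and wavelengths, identical across RGB) and
#' 32 color-opponent center-surround kernels (red-green and blue-yellow,
#' both polarities, several widths). Deterministic given the seed, which
#' jitters orientations, wavelengths and envelope widths.
#'
#' @param seed integer seed.
#' @return list (class `qip_filter_bank`) with `kernels` (11 x 11 x 3 x 96
#'   array) and `source` tag.
#' @export
surrogate_filter_bank <- function(seed = 1L) {
  ks <- .CONV_KERN
  coords <- seq_len(ks) - (ks + 1) / 2
  x <- matrix(rep(coords, each = ks), ks)
  y <- matrix(rep(coords, times = ks), ks)
  .with_fixture_rng(seed, "surrogate_bank", function() {
    kern <- array(0, c(ks, ks, 3L, 96L))
    i <- 1L
    # 64 oriented luminance kernels: 16 orientations x 2 wavelengths x 2 phases
    for (th0 in (0:15) * pi / 16) {
      for (wl0 in c(4.5, 9)) {
        th <- th0 + stats::rnorm(1, 0, 0.02)
        wl <- wl0 * exp(stats::rnorm(1, 0, 0.03))
        sg <- 0.35 * wl + 1
        xr <- x * cos(th) + y * sin(th)
        yr <- -x * sin(th) + y * cos(th)
        env <- exp(-(xr^2 + yr^2) / (2 * sg^2))
        for (ph in c(0, pi / 2)) {
          g <- env * cos(2 * pi * xr / wl + ph)
          g <- g - mean(g)
          g <- g / sqrt(sum(g^2))
          for (ch in 1:3) kern[, , ch, i] <- g
          i <- i + 1L
        }
      }
    }
    # 32 color-opponent center-surround kernels
    op <- list(c(1, -1, 0), c(-1, 1, 0), c(0, -0.5, 1), c(0.5, 0.5, -1))
    for (o in op) {
      for (sg0 in c(1, 1.6, 2.5, 4)) {
        for (pol in c(1, -1)) {
          sg <- sg0 * exp(stats::rnorm(1, 0, 0.05))
          ctr <- exp(-(x^2 + y^2) / (2 * sg^2))
          sur <- exp(-(x^2 + y^2) / (2 * (2 * sg)^2))
          dog <- pol * (ctr / sum(ctr) - sur / sum(sur))
          dog <- dog / sqrt(sum(dog^2))
          for (ch in 1:3) {
            k <- dog * o[ch]
            kern[, , ch, i] <- k - mean(k)
          }
          i <- i + 1L
        }
      }
    }
    structure(list(kernels = kern, source = sprintf("surrogate(seed=%d)", seed)),
              class = "qip_filter_bank")
  })
}

#' Load a pretrained first-layer filter bank from a tensor asset
#'
#' Reads a raw little-endian float32 file holding a 96 x 3 x 11 x 11 tensor
#' in C (row-major) order: filter, channel (R, G, B), kernel row, kernel
#' column. The asset is user-supplied; it is never downloaded.
#'
#' @param path path of the tensor file (96*3*11*11 = 34848 floats).
#' @param md5 optional MD5 checksum to verify before loading.
#' @return a `qip_filter_bank` with source `"pretrained_asset"`.
#' @export
load_filter_bank <- function(path, md5 = NULL) {
  if (!file.exists(path)) {
    stop("pretrained conv1 weights not found at '", path,
         "'; supply the 96x3x11x11 float32 tensor asset or use ",
         "surrogate_filter_bank()")
  }
  if (!is.null(md5)) {
    have <- tools::md5sum(path)
    if (!identical(unname(have), md5)) stop("checksum mismatch for ", path)
  }
  n <- 96L * 3L * 11L * 11L
  v <- readBin(path, what = "numeric", size = 4L, n = n + 1L, endian = "little")
  if (length(v) != n) stop("expected exactly ", n, " float32 values in ", path)
  # C order [filter][channel][ky][kx] -> R array [ky, kx, ch, filter]
  kern <- aperm(array(v, dim = c(11L, 11L, 3L, 96L)), c(2L, 1L, 3L, 4L))
  structure(list(kernels = kern, source = "pretrained_asset"),
            class = "qip_filter_bank")
}

# channel-mean preprocessing: per-image means for surrogate banks, fixed
# training means for pretrained assets
.conv_preprocess <- function(px, bank) {
  if (identical(bank$source, "pretrained_asset")) {
    mu <- c(123, 117, 104)  # conventional training channel means (R, G, B)
  } else {
    mu <- c(mean(px[, , 1L]), mean(px[, , 2L]), mean(px[, , 3L]))
  }
  for (k in 1:3) px[, , k] <- px[, , k] - mu[k]
  px
}

#' First-layer feature responses
#'
#' Resizes to the 511 x 511 working size (the nominal 512 input minus a
#' one-pixel trim, applied as a single resampling step so that reflections
#' commute with the resize and the stride-4 lattice is closed under
#' reflection), subtracts channel means, computes the valid-correlation
#' response of every kernel at stride 4 and rectifies at zero.
#'
#' @param img a [qip_image].
#' @param bank a `qip_filter_bank`.
#' @param rectify apply the rectification (default TRUE; FALSE exposes the
#'   linear responses for diagnostics).
#' @return 126 x 126 x 96 array of non-negative responses.
#' @export
conv1_features <- function(img, bank = surrogate_filter_bank(),
                           rectify = TRUE) {
  stopifnot(inherits(img, "qip_image"), inherits(bank, "qip_filter_bank"))
  img <- standardize_size(img, "fixed_square", .CONV_INPUT)
  px <- .conv_preprocess(img$pixels, bank)
  m <- .CONV_MAPSIDE
  starts <- seq(1L, by = .CONV_STRIDE, length.out = m)
  # patch matrix: m^2 positions x (11*11*3) taps
  P <- matrix(0, m * m, .CONV_KERN * .CONV_KERN * 3L)
  col <- 1L
  for (ch in 1:3) {
    for (kx in seq_len(.CONV_KERN)) {
      for (ky in seq_len(.CONV_KERN)) {
        P[, col] <- as.vector(px[starts + ky - 1L, starts + kx - 1L, ch])
        col <- col + 1L
      }
    }
  }
  # W rows follow [ky, kx, ch] with ky fastest, matching P's column order
  W <- matrix(bank$kernels, ncol = 96L)
  R <- P %*% W
  if (rectify) R[R < 0] <- 0
  array(R, dim = c(m, m, 96L))
}

# flip a bank's kernels spatially
.flip_bank <- function(bank, axis = c("lr", "ud", "both")) {
  axis <- match.arg(axis)
  k <- bank$kernels
  if (axis %in% c("lr", "both")) k <- k[, 11:1, , , drop = FALSE]
  if (axis %in% c("ud", "both")) k <- k[11:1, , , , drop = FALSE]
  structure(list(kernels = k, source = bank$source), class = "qip_filter_bank")
}

# response stack of img under an axis-flipped bank, then flipped back onto
# the original lattice
.mirror_stack <- function(img, bank, axis) {
  R <- conv1_features(img, .flip_bank(bank, axis))
  m <- dim(R)[1]
  if (axis %in% c("lr", "both")) R <- R[, m:1, , drop = FALSE]
  if (axis %in% c("ud", "both")) R <- R[m:1, , , drop = FALSE]
  R
}

#' CNN feature-based symmetry
#'
#' Compares the rectified first-layer response stack with the stack obtained
#' from mirrored kernels, mapped back onto the response lattice:
#' sym = sum(min) / sum(max) element-wise over all filters and positions.
#' `"lrud"` intersects all four stacks (identity, left-right, up-down,
#' 180-degree), so it can only be smaller than either single-axis score.
#'
#' @param img a [qip_image].
#' @param bank a `qip_filter_bank`.
#' @param axis `"lr"`, `"ud"` or `"lrud"`.
#' @return symmetry in \[0, 1\]; `NaN` with a warning when the response
#'   stack is all zero.
#' @export
cnn_symmetry <- function(img, bank = surrogate_filter_bank(),
                         axis = c("lr", "ud", "lrud")) {
  axis <- match.arg(axis)
  R <- conv1_features(img, bank)
  stacks <- switch(axis,
    lr = list(R, .mirror_stack(img, bank, "lr")),
    ud = list(R, .mirror_stack(img, bank, "ud")),
    lrud = list(R, .mirror_stack(img, bank, "lr"),
                .mirror_stack(img, bank, "ud"),
                .mirror_stack(img, bank, "both")))
  lo <- stacks[[1L]]; hi <- stacks[[1L]]
  for (s in stacks[-1L]) {
    lo <- pmin(lo, s); hi <- pmax(hi, s)
  }
  denom <- sum(hi)
  if (denom <= 0) {
    warning("all-zero response stack: CNN symmetry is NaN")
    return(NaN)
  }
  sum(lo) / denom
}

# per-filter max over an n x n partition of the response maps -> 96 x n^2
.pooled_grid <- function(stack, n = 8L) {
  m <- dim(stack)[1]
  b <- round((0:n) * m / n)
  out <- matrix(0, dim(stack)[3], n * n)
  cell <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sub <- stack[(b[i] + 1):b[i + 1], (b[j] + 1):b[j + 1], , drop = FALSE]
      out[, cell] <- apply(sub, 3L, max)
      cell <- cell + 1L
    }
  }
  out
}

#' CNN feature-based self-similarity
#'
#' The ground histogram is the 96-vector of per-filter maxima over the whole
#' response stack, normalized to sum 1; each section of an 8 x 8 partition
#' yields the analogous normalized vector, compared to the ground with the
#' histogram intersection kernel. The score is the median over the 64
#' sections.
#'
#' @param img a [qip_image].
#' @param bank a `qip_filter_bank`.
#' @return self-similarity in \[0, 1\]; `NaN` with a warning for an all-zero
#'   stack.
#' @export
cnn_self_similarity <- function(img, bank = surrogate_filter_bank()) {
  stack <- conv1_features(img, bank)
  ground <- apply(stack, 3L, max)
  if (sum(ground) <= 0) {
    warning("all-zero response stack: CNN self-similarity is NaN")
    return(NaN)
  }
  ground <- ground / sum(ground)
  pooled <- .pooled_grid(stack, 8L)
  sims <- apply(pooled, 2L, function(v) {
    s <- sum(v)
    if (s <= 0) return(0)
    .hik(v / s, ground)
  })
  stats::median(sims)
}

#' CNN feature variances: sparseness and variability
#'
#' From the pooled grid (per-filter max in each of n x n subregions):
#' sparseness is the mean over subregions of the variance across the 96
#' filter values within the subregion; variability is the median over
#' filters of the variance of that filter's pooled values across
#' subregions. Population variances throughout.
#'
#' @param img a [qip_image].
#' @param bank a `qip_filter_bank`.
#' @param n grid side (default 8).
#' @return list with `sparseness` and `variability`.
#' @export
cnn_variances <- function(img, bank = surrogate_filter_bank(), n = 8L) {
  stack <- conv1_features(img, bank)
  pooled <- .pooled_grid(stack, n)   # 96 x n^2
  pvar <- function(v) mean((v - mean(v))^2)
  list(sparseness = mean(apply(pooled, 2L, pvar)),
       variability = stats::median(apply(pooled, 1L, pvar)))
}
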