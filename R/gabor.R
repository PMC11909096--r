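## Gabor-bank edge measures: edge density and first-/second-order
## edge-orientation entropy (EOE).
##
## The bank holds 24 quadrature pairs at 15-degree spacing. Filtering is
## circular (FFT) convolution, so toroidal fixtures are exactly
## translation-invariant.

#' Build the oriented Gabor filter bank
#'
#' `n_orient` quadrature kernel pairs with orientations `k * 360 / n_orient`
#' degrees. Even kernels are DC-corrected inside the Gaussian envelope so
#' every kernel is zero-mean; odd kernels are zero-mean by antisymmetry.
#'
#' @param n_orient number of orientations (default 24, spanning 360 degrees).
#' @param wavelength carrier wavelength in pixels.
#' @param sigma Gaussian envelope width in pixels.
#' @param gamma spatial aspect ratio of the envelope.
#' @return list of `n_orient` elements, each with `even` and `odd` kernel
#'   matrices and the orientation in degrees (class `qip_gabor_bank`).
#' @export
gabor_bank <- function(n_orient = 24L, wavelength = 8, sigma = 4, gamma = 1) {
  half <- ceiling(3 * sigma)
  coords <- -half:half
  x <- matrix(rep(coords, each = length(coords)), length(coords))
  y <- matrix(rep(coords, times = length(coords)), length(coords))
  kernels <- lapply(seq_len(n_orient) - 1L, function(k) {
    th <- k * 2 * pi / n_orient
    xr <- x * cos(th) + y * sin(th)
    yr <- -x * sin(th) + y * cos(th)
    env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
    even <- env * cos(2 * pi * xr / wavelength)
    odd <- env * sin(2 * pi * xr / wavelength)
    even <- even - env * sum(even) / sum(env)   # DC-free
    list(even = even, odd = odd, theta_deg = k * 360 / n_orient)
  })
  structure(kernels, class = "qip_gabor_bank",
            wavelength = wavelength, sigma = sigma)
}

# circular convolution of image with kernel (kernel centered), via FFT
.fft_filter <- function(img_fft, kern, h, w) {
  kh <- nrow(kern); kw <- ncol(kern)
  pad <- matrix(0, h, w)
  # place kernel wrapped around the origin
  ro <- (nrow(kern) - 1L) / 2L; co <- (ncol(kern) - 1L) / 2L
  ridx <- ((seq_len(kh) - 1L - ro) %% h) + 1L
  cidx <- ((seq_len(kw) - 1L - co) %% w) + 1L
  pad[ridx, cidx] <- kern
  Re(stats::fft(img_fft * Conj(stats::fft(pad)), inverse = TRUE)) / (h * w)
}

#' Gabor edge field
#'
#' Downscales the image to at most `max_pixels` pixels (aspect-preserving,
#' never upscaling), filters it with the quadrature bank, and records for
#' every pixel the maximum quadrature energy over orientations, the winning
#' orientation label, and the total energy summed over all filters.
#'
#' @param img a `qip_gray` (gray8) or [qip_image] (converted via luma).
#' @param bank a `qip_gabor_bank`.
#' @param max_pixels size cap applied before filtering (default 120000).
#' @return list with `strength`, `label` (1-based orientation index),
#'   `energy_total` (sum over pixels and filters), `n_orient`
#'   (class `qip_edge_field`).
#' @export
gabor_edge_field <- function(img, bank = gabor_bank(), max_pixels = 120000) {
  if (inherits(img, "qip_image")) img <- convert_color(img, "gray8")
  stopifnot(inherits(img, "qip_gray"))
  img <- standardize_size(img, "max_pixels_cap", max_pixels)
  p <- img$pixels
  h <- nrow(p); w <- ncol(p)
  pf <- stats::fft(p)
  best <- matrix(-Inf, h, w); lab <- matrix(1L, h, w); tot <- 0
  energy_sum <- matrix(0, h, w)
  for (k in seq_along(bank)) {
    ev <- .fft_filter(pf, bank[[k]]$even, h, w)
    od <- .fft_filter(pf, bank[[k]]$odd, h, w)
    e <- sqrt(ev^2 + od^2)
    energy_sum <- energy_sum + e
    take <- e > best
    lab[take] <- k
    best[take] <- e[take]
  }
  structure(list(strength = best, label = lab,
                 energy_total = sum(energy_sum), n_orient = length(bank),
                 source_id = img$source_id),
            class = "qip_edge_field")
}

#' Edge density
#'
#' Sum of quadrature edge energies over all pixels and all orientations of
#' the bank. The 120,000-pixel cap applied when the field is built keeps the
#' raw sum comparable across image sizes.
#'
#' @param field a `qip_edge_field`.
#' @return edge density (>= 0).
#' @export
edge_density <- function(field) {
  stopifnot(inherits(field, "qip_edge_field"))
  field$energy_total
}

#' First-order edge-orientation entropy
#'
#' Shannon entropy (bits) of the orientation histogram that accumulates edge
#' strength per dominant orientation label.
#'
#' @param field a `qip_edge_field`.
#' @return entropy in \[0, log2(n_orient)\] bits; `NaN` with a warning when
#'   total strength is zero.
#' @export
first_order_eoe <- function(field) {
  stopifnot(inherits(field, "qip_edge_field"))
  hh <- vapply(seq_len(field$n_orient),
               function(k) sum(field$strength[field$label == k]), numeric(1))
  if (sum(hh) <= 0) {
    warning("zero-strength edge field: first-order EOE is NaN")
    return(NaN)
  }
  p <- hh / sum(hh); p <- p[p > 0]
  -sum(p * log2(p))
}

#' Select the strongest edges of a field
#'
#' @param field a `qip_edge_field`.
#' @param n_edges cap on the number of records (default 10000).
#' @return data frame `x`, `y` (1-based pixel coordinates), `label`,
#'   `theta_deg`, `strength`, sorted by descending strength (ties by pixel
#'   index, so the set is deterministic).
#' @export
strongest_edges <- function(field, n_edges = 10000L) {
  stopifnot(inherits(field, "qip_edge_field"))
  h <- nrow(field$strength); w <- ncol(field$strength)
  ord <- order(-as.vector(field$strength), seq_len(h * w))
  keep <- ord[seq_len(min(n_edges, h * w))]
  rows <- ((keep - 1L) %% h) + 1L
  cols <- ((keep - 1L) %/% h) + 1L
  data.frame(x = cols, y = rows, label = field$label[keep],
             theta_deg = (field$label[keep] - 1L) * 360 / field$n_orient,
             strength = field$strength[keep])
}

#' Second-order edge-orientation entropy
#'
#' Shannon entropy (bits) of the histogram of pairwise orientation
#' differences (theta_i - theta_j, modulo 360, over `bins` equal bins) for
#' every unordered pair of strong edges at Euclidean distance of at least
#' `min_dist` pixels. Pairs are enumerated exactly; the pair loop is batched
#' but never sampled.
#'
#' @param edges data frame from [strongest_edges] (or any frame with `x`,
#'   `y`, `theta_deg`).
#' @param min_dist minimum pair distance in pixels (default 20).
#' @param bins orientation-difference bins (default 24).
#' @return entropy in \[0, log2(bins)\] bits; `NaN` with a warning if no
#'   pair qualifies.
#' @export
second_order_eoe <- function(edges, min_dist = 20, bins = 24L) {
  stopifnot(is.data.frame(edges), all(c("x", "y", "theta_deg") %in% names(edges)))
  n <- nrow(edges)
  if (n < 2L) {
    warning("fewer than two edges: second-order EOE is NaN")
    return(NaN)
  }
  width <- 360 / bins
  counts <- numeric(bins)
  x <- edges$x; y <- edges$y; th <- edges$theta_deg
  md2 <- min_dist^2
  block <- max(1L, floor(2e6 / n))
  i <- 1L
  while (i < n) {
    ii <- i:min(i + block - 1L, n - 1L)
    # pairs (a, b) with a in ii, b > a
    for (a in ii) {
      b <- (a + 1L):n
      ok <- (x[b] - x[a])^2 + (y[b] - y[a])^2 >= md2
      if (any(ok)) {
        d <- (th[a] - th[b][ok]) %% 360
        idx <- floor(d / width) + 1L
        idx[idx > bins] <- bins
        counts <- counts + tabulate(idx, nbins = bins)
      }
    }
    i <- i + block
  }
  if (sum(counts) == 0) {
    warning("no edge pairs at the required distance: second-order EOE is NaN")
    return(NaN)
  }
  p <- counts / sum(counts); p <- p[p > 0]
  -sum(p * log2(p))
}
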