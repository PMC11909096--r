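## Pixel-based composition measures: APB Balance score, deviation of the
## center of mass (DCM), mirror symmetry, and homogeneity.
##
## Coordinate convention: 0-based pixel centers, x = column, y = row; the
## geometric center is ((W-1)/2, (H-1)/2).

# perceptual mass per pixel under a polarity
.mass_weights <- function(img, polarity = c("dark_heavy", "bright_heavy")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(img, "qip_gray"), img$scale == "gray8")
  if (polarity == "dark_heavy") 255 - img$pixels else img$pixels
}

# membership masks for the eight Wilson & Chatterjee area pairs.
# Each element: list(a = logical H x W, b = logical H x W).
.area_pairs <- function(h, w) {
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  # signed offsets for the four axes (half-plane splits exclude the axis itself)
  s_v <- x - cx                               # vertical axis
  s_h <- y - cy                               # horizontal axis
  s_d1 <- y * (w - 1) - x * (h - 1)           # major diagonal (TL-BR)
  s_d2 <- y * (w - 1) + x * (h - 1) - (h - 1) * (w - 1)  # minor diagonal
  half <- function(s) list(a = s < 0, b = s > 0)
  # outer pair: two lines parallel to the axis, symmetric about it, placed
  # so the band between them holds half the image (the 25%/75% positions
  # when the extent divides evenly); the pair is the two corresponding
  # outer strips, which have equal areas by construction.
  band <- function(s) {
    a <- abs(s)
    vals <- sort(unique(as.vector(a)))
    cum <- vapply(vals, function(v) sum(a <= v), numeric(1))
    t_ <- vals[which.min(abs(cum - length(a) / 2))]
    list(a = s < -t_, b = s > t_)
  }
  list(vertical = half(s_v), horizontal = half(s_h),
       diag_major = half(s_d1), diag_minor = half(s_d2),
       band_vertical = band(s_v), band_horizontal = band(s_h),
       band_diag_major = band(s_d1), band_diag_minor = band(s_d2))
}

#' APB Balance score
#'
#' Mean percent imbalance of perceptual mass over eight axis-defined pairs of
#' equally sized areas: the two half-planes across each of the vertical,
#' horizontal and both diagonal axes, plus, per axis, the two outer strips
#' beyond a pair of parallel lines that enclose half the image. 0 means
#' perfectly balanced; any image symmetric under all four axis reflections
#' scores exactly 0.
#'
#' @param img a `qip_gray` on the 8-bit scale.
#' @param polarity `"dark_heavy"` (mass = 255 - gray) or `"bright_heavy"`
#'   (mass = gray).
#' @return percent in \[0, 100\]; `NaN` with a warning when the image carries
#'   no mass under the chosen polarity.
#' @export
balance_score <- function(img, polarity = c("dark_heavy", "bright_heavy")) {
  wts <- .mass_weights(img, polarity)
  if (sum(wts) <= 0) {
    warning("blank image under chosen polarity: Balance undefined")
    return(NaN)
  }
  prs <- .area_pairs(nrow(wts), ncol(wts))
  d <- vapply(prs, function(p) {
    m1 <- sum(wts[p$a]); m2 <- sum(wts[p$b])
    if (m1 + m2 == 0) 0 else 100 * abs(m1 - m2) / (m1 + m2)
  }, numeric(1))
  mean(d)
}

#' Deviation of the center of mass (DCM)
#'
#' Euclidean distance between the center of perceptual mass and the geometric
#' center, as a percentage of the distance from the center to a corner pixel
#' center (the maximum possible).
#'
#' @inheritParams balance_score
#' @return percent in \[0, 100\]; `NaN` with a warning for zero total mass.
#' @export
dcm_score <- function(img, polarity = c("dark_heavy", "bright_heavy")) {
  wts <- .mass_weights(img, polarity)
  tot <- sum(wts)
  if (tot <= 0) {
    warning("blank image under chosen polarity: DCM undefined")
    return(NaN)
  }
  h <- nrow(wts); w <- ncol(wts)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  mx <- sum(wts * x) / tot; my <- sum(wts * y) / tot
  dmax <- sqrt(cx^2 + cy^2)
  if (dmax == 0) return(0)
  100 * sqrt((mx - cx)^2 + (my - cy)^2) / dmax
}

#' Mirror symmetry score
#'
#' Per axis, symmetry is 100 * (1 - mean |I(p) - I(mirror(p))| / 255) over all
#' pixels. Square images average the vertical, horizontal, main-diagonal and
#' anti-diagonal axes; non-square images the vertical and horizontal axes
#' only.
#'
#' @param img a `qip_gray` on the 8-bit scale.
#' @return percent in \[0, 100\]; 100 for images symmetric under every
#'   applicable axis.
#' @export
mirror_symmetry <- function(img) {
  stopifnot(inherits(img, "qip_gray"), img$scale == "gray8")
  p <- img$pixels
  h <- nrow(p); w <- ncol(p)
  ax <- function(q) 100 * (1 - mean(abs(p - q)) / 255)
  vals <- c(ax(p[, w:1, drop = FALSE]),      # vertical axis (left-right)
            ax(p[h:1, , drop = FALSE]))      # horizontal axis (up-down)
  if (h == w) {
    vals <- c(vals,
              ax(t(p)),                      # main diagonal
              ax(t(p)[h:1, w:1, drop = FALSE]))  # anti-diagonal
  }
  mean(vals)
}

#' Homogeneity of the spatial distribution of dark pixels
#'
#' The image is binarized with Otsu's threshold (black = strictly below); the
#' black-pixel counts over an n x m grid give three normalized Shannon
#' entropies, each scaled to percent: over all cells (/ log2(nm)), over row
#' sums (/ log2(n)) and over column sums (/ log2(m)). The headline value is
#' the mean of the row and column components.
#'
#' @param img a `qip_gray` on the 8-bit scale.
#' @param n,m grid rows and columns (default 10 x 10).
#' @return list with `cells_pct`, `rows_pct`, `cols_pct`, `final_pct`.
#' @export
homogeneity <- function(img, n = 10L, m = 10L) {
  stopifnot(inherits(img, "qip_gray"), img$scale == "gray8", n >= 2L, m >= 2L)
  p <- img$pixels
  nan_out <- list(cells_pct = NaN, rows_pct = NaN, cols_pct = NaN, final_pct = NaN)
  if (length(unique(as.vector(p))) < 2L) {
    warning("constant image: Otsu threshold undefined, Homogeneity is NaN")
    return(nan_out)
  }
  thr <- EBImage::otsu(EBImage::Image(t(p) / 255), range = c(0, 1), levels = 256) * 255
  black <- p < thr
  if (!any(black)) {
    warning("no pixels below the Otsu threshold: Homogeneity is NaN")
    return(nan_out)
  }
  h <- nrow(p); w <- ncol(p)
  rb <- round((0:n) * h / n); cb <- round((0:m) * w / m)
  counts <- matrix(0, n, m)
  for (i in seq_len(n)) {
    rows <- (rb[i] + 1):rb[i + 1]
    for (j in seq_len(m)) {
      counts[i, j] <- sum(black[rows, (cb[j] + 1):cb[j + 1]])
    }
  }
  ent <- function(cnt) {
    pr <- cnt / sum(cnt)
    pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }
  cells_pct <- 100 * ent(as.vector(counts)) / log2(n * m)
  rows_pct <- 100 * ent(rowSums(counts)) / log2(n)
  cols_pct <- 100 * ent(colSums(counts)) / log2(m)
  list(cells_pct = cells_pct, rows_pct = rows_pct, cols_pct = cols_pct,
       final_pct = (rows_pct + cols_pct) / 2)
}
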