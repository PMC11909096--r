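## Oriented-gradient measures: combined L*a*b* gradient image, HOG
## complexity, the orientation-histogram pyramid (PHOG), self-similarity via
## the histogram intersection kernel, and anisotropy.

# central differences with replicate borders
.cdiff <- function(m, along = c("x", "y")) {
  along <- match.arg(along)
  h <- nrow(m); w <- ncol(m)
  if (along == "x") {
    (m[, c(2:w, w), drop = FALSE] - m[, c(1, 1:(w - 1)), drop = FALSE]) / 2
  } else {
    (m[c(2:h, h), , drop = FALSE] - m[c(1, 1:(h - 1)), , drop = FALSE]) / 2
  }
}

#' Combined L*a*b* gradient image
#'
#' Per-channel gradient magnitude by central differences (replicate borders);
#' each pixel takes the strongest magnitude among the L*, a*, b* channels,
#' with the orientation of the winning channel (ties resolved in L*, a*, b*
#' order). Orientations are signed, in degrees \[0, 360).
#'
#' @param img a [qip_image] or `qip_lab`.
#' @return list with `strength` and `orientation` matrices
#'   (class `qip_gradient`).
#' @export
gradient_image <- function(img) {
  lab <- if (inherits(img, "qip_lab")) img else convert_color(img, "lab")
  best_mag <- NULL; best_ori <- NULL
  for (ch in list(lab$L, lab$a, lab$b)) {
    gx <- .cdiff(ch, "x"); gy <- .cdiff(ch, "y")
    mag <- sqrt(gx^2 + gy^2)
    ori <- (atan2(gy, gx) * 180 / pi) %% 360
    if (is.null(best_mag)) {
      best_mag <- mag; best_ori <- ori
    } else {
      take <- mag > best_mag          # strict: earlier channel wins ties
      best_ori[take] <- ori[take]
      best_mag[take] <- mag[take]
    }
  }
  structure(list(strength = best_mag, orientation = best_ori,
                 source_id = if (!is.null(img$source_id)) img$source_id else "image"),
            class = "qip_gradient")
}

#' HOG complexity
#'
#' Mean strength of the combined gradient image. Values depend on image
#' size, so a fixed `resize_to` total pixel count is recommended when
#' comparing images.
#'
#' @param img a [qip_image].
#' @param resize_to optional total pixel count applied before the gradient
#'   (aspect-preserving); `NULL` computes on the native size.
#' @return mean gradient strength (L*/a*/b* units per pixel).
#' @export
complexity_hog <- function(img, resize_to = NULL) {
  stopifnot(inherits(img, "qip_image"))
  if (!is.null(resize_to)) img <- standardize_size(img, "total_pixels", resize_to)
  mean(gradient_image(img)$strength)
}

# orientation bin index: `bins` equal bins over 360 deg, bin 1 centered at 0
.ori_bin <- function(theta, bins) {
  width <- 360 / bins
  b <- floor(((theta + width / 2) %% 360) / width) + 1L
  b[b > bins] <- bins
  b
}

#' Build a pyramid of orientation histograms (PHOG)
#'
#' Level `l` divides the image into a 2^l x 2^l grid (1, 4, 16, 64 sections
#' for levels 0-3); each section holds a 16-bin histogram of gradient
#' strength by orientation (equal 22.5 degree bins over the full 360
#' degrees, bin 1 centered at 0). Section boundaries sit at
#' `round(k * side / 2^l)`.
#'
#' @param g a `qip_gradient` from [gradient_image].
#' @param bins orientation bins (default 16).
#' @param max_level deepest pyramid level, at most 3 (histograms become
#'   unstable in smaller sections).
#' @return list of levels; level `l + 1` is a `bins` x `4^l` matrix whose
#'   columns are section histograms (row-major section order).
#' @export
build_phog <- function(g, bins = 16L, max_level = 3L) {
  stopifnot(inherits(g, "qip_gradient"), bins >= 2L)
  if (max_level > 3L) stop("max_level above 3 is not supported: histograms become unstable")
  h <- nrow(g$strength); w <- ncol(g$strength)
  bin_idx <- .ori_bin(g$orientation, bins)
  out <- vector("list", max_level + 1L)
  for (lev in 0:max_level) {
    k <- 2^lev
    rb <- round((0:k) * h / k); cb <- round((0:k) * w / k)
    hist_mat <- matrix(0, bins, k * k)
    s <- 1L
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        rows <- (rb[i] + 1):rb[i + 1]; cols <- (cb[j] + 1):cb[j + 1]
        idx <- bin_idx[rows, cols]
        wt <- g$strength[rows, cols]
        hist_mat[, s] <- vapply(seq_len(bins),
                                function(b) sum(wt[idx == b]), numeric(1))
        s <- s + 1L
      }
    }
    out[[lev + 1L]] <- hist_mat
  }
  structure(out, class = "qip_phog", bins = bins)
}

# histogram intersection kernel of two sum-1 histograms
.hik <- function(a, b) sum(pmin(a, b))

#' PHOG-based self-similarity
#'
#' Every section histogram and the ground (level 0) histogram are normalized
#' to sum 1 and compared with the histogram intersection kernel
#' (sum of bin-wise minima, in \[0, 1\]); per-level values are section
#' means, and the result is the weighted mean over the requested levels.
#' Sections without any gradient mass contribute similarity 0.
#'
#' @param pyr a `qip_phog` from [build_phog].
#' @param levels pyramid levels to include (default 1:3).
#' @param weights per-level weights (default equal).
#' @return self-similarity in \[0, 1\]; `NaN` with a warning for a
#'   zero-gradient image.
#' @export
phog_self_similarity <- function(pyr, levels = 1:3, weights = NULL) {
  stopifnot(inherits(pyr, "qip_phog"), all(levels >= 1), all(levels < length(pyr)))
  if (is.null(weights)) weights <- rep(1, length(levels))
  stopifnot(length(weights) == length(levels), all(weights >= 0), sum(weights) > 0)
  ground <- pyr[[1L]][, 1L]
  if (sum(ground) <= 0) {
    warning("zero-gradient image: PHOG self-similarity is NaN")
    return(NaN)
  }
  ground <- ground / sum(ground)
  lv <- vapply(levels, function(l) {
    hm <- pyr[[l + 1L]]
    sims <- apply(hm, 2L, function(hh) {
      s <- sum(hh)
      if (s <= 0) return(0)
      .hik(hh / s, ground)
    })
    mean(sims)
  }, numeric(1))
  sum(lv * weights) / sum(weights)
}

#' Anisotropy of gradient orientations
#'
#' The 64 level-3 section histograms are summed bin-wise, normalized to sum
#' 1, and the population standard deviation of the 16 normalized bin values
#' is returned. 0 means all orientations carry equal strength; a single
#' dominant orientation gives the one-hot maximum sqrt(bins - 1) / bins.
#'
#' @param pyr a `qip_phog` with level 3 present.
#' @return anisotropy (dimensionless, >= 0); `NaN` with a warning for a
#'   zero-gradient image.
#' @export
anisotropy <- function(pyr) {
  stopifnot(inherits(pyr, "qip_phog"), length(pyr) >= 4L)
  tot <- rowSums(pyr[[4L]])
  if (sum(tot) <= 0) {
    warning("zero-gradient image: Anisotropy is NaN")
    return(NaN)
  }
  p <- tot / sum(tot)
  sqrt(mean((p - mean(p))^2))
}
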