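# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (explicit loops over pixels/boxes/pairs) so that they
# stay independent of the vectorized implementation paths they check.

rgb_from_gray <- function(g) {
  m <- if (inherits(g, "qip_gray")) g$pixels else g
  qip_image(array(rep(m, 3L), c(dim(m), 3L)))
}

# --- balance / DCM / mirror oracles (pixel-center coordinates, 0-based) ----

oracle_masses <- function(wts) {
  h <- nrow(wts); w <- ncol(wts)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  s_of <- function(x, y) c(v = x - cx, h = y - cy,
                           d1 = y * (w - 1) - x * (h - 1),
                           d2 = y * (w - 1) + x * (h - 1) - (h - 1) * (w - 1))
  all_s <- matrix(0, h * w, 4)
  k <- 1L
  for (i in 0:(h - 1)) for (j in 0:(w - 1)) {
    all_s[k, ] <- s_of(j, i); k <- k + 1L
  }
  all_s
}

oracle_balance <- function(wts) {
  s <- oracle_masses(wts)
  wv <- as.vector(t(wts))   # row-major, matching oracle_masses enumeration
  ds <- numeric(0)
  for (ax in 1:4) {
    m1 <- sum(wv[s[, ax] < 0]); m2 <- sum(wv[s[, ax] > 0])
    ds <- c(ds, if (m1 + m2 == 0) 0 else 100 * abs(m1 - m2) / (m1 + m2))
  }
  for (ax in 1:4) {
    a <- abs(s[, ax])
    best_v <- NA; best_d <- Inf
    for (v in sort(unique(a))) {
      d <- abs(sum(a <= v) - length(a) / 2)
      if (d < best_d) { best_d <- d; best_v <- v }
    }
    m1 <- sum(wv[s[, ax] < -best_v]); m2 <- sum(wv[s[, ax] > best_v])
    ds <- c(ds, if (m1 + m2 == 0) 0 else 100 * abs(m1 - m2) / (m1 + m2))
  }
  mean(ds)
}

oracle_dcm <- function(wts) {
  h <- nrow(wts); w <- ncol(wts)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  sx <- 0; sy <- 0; tot <- 0
  for (i in 1:h) for (j in 1:w) {
    sx <- sx + wts[i, j] * (j - 1); sy <- sy + wts[i, j] * (i - 1)
    tot <- tot + wts[i, j]
  }
  100 * sqrt((sx / tot - cx)^2 + (sy / tot - cy)^2) / sqrt(cx^2 + cy^2)
}

oracle_mirror <- function(p) {
  h <- nrow(p); w <- ncol(p)
  axis_score <- function(map) {
    tot <- 0
    for (i in 1:h) for (j in 1:w) {
      q <- map(i, j)
      tot <- tot + abs(p[i, j] - p[q[1], q[2]])
    }
    100 * (1 - tot / (h * w) / 255)
  }
  vals <- c(axis_score(function(i, j) c(i, w + 1 - j)),
            axis_score(function(i, j) c(h + 1 - i, j)))
  if (h == w) {
    vals <- c(vals, axis_score(function(i, j) c(j, i)),
              axis_score(function(i, j) c(w + 1 - j, h + 1 - i)))
  }
  mean(vals)
}

# --- 2D box-count oracle: per-box double loop over a binary matrix --------

oracle_boxcount_2d <- function(bw, L) {
  h <- nrow(bw); w <- ncol(bw)
  # edge pixels: value differs from right or lower neighbour (replicated)
  edge <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    r <- if (j < w) bw[i, j + 1] else bw[i, j]
    d <- if (i < h) bw[i + 1, j] else bw[i, j]
    edge[i, j] <- (bw[i, j] != r) || (bw[i, j] != d)
  }
  cnt <- 0L
  for (bi in seq(1, h, by = L)) {
    for (bj in seq(1, w, by = L)) {
      if (any(edge[bi:(bi + L - 1), bj:(bj + L - 1)])) cnt <- cnt + 1L
    }
  }
  cnt
}

# --- second-order EOE oracle: all-pairs double loop ------------------------

oracle_eoe2 <- function(edges, min_dist = 20, bins = 24L) {
  n <- nrow(edges)
  counts <- numeric(bins)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((edges$x[i] - edges$x[j])^2 + (edges$y[i] - edges$y[j])^2)
      if (d >= min_dist) {
        dd <- (edges$theta_deg[i] - edges$theta_deg[j]) %% 360
        b <- floor(dd / (360 / bins)) + 1L
        if (b > bins) b <- bins
        counts[b] <- counts[b] + 1
      }
    }
  }
  if (sum(counts) == 0) return(NaN)
  p <- counts / sum(counts); p <- p[p > 0]
  -sum(p * log2(p))
}

# --- shared small fixtures -------------------------------------------------

# image symmetric under left-right, up-down and both diagonal reflections
four_axis_symmetric <- function(side = 32, seed = 5) {
  set.seed(seed)
  q <- matrix(runif((side / 2)^2, 0, 255), side / 2)
  q <- (q + t(q)) / 2                       # diagonal symmetry of the quadrant
  top <- cbind(q, q[, (side / 2):1])
  qip_gray(rbind(top, top[(side / 2):1, ]))
}

# RGB mirrored composite, exactly symmetric about the chosen axis
lattice_symmetric_rgb <- function(seed = 9, axis = c("lr", "ud")) {
  axis <- match.arg(axis)
  set.seed(seed)
  core <- matrix(runif(256 * 128, 0, 255), 256, 128)
  if (axis == "ud") core <- t(core)
  rgb_from_gray(mirrored_composite(qip_gray(core), axis)$pixels)
}
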