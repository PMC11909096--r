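test_that("gradient image reduces to the active channel and localizes a step", {
  expect_true(all(gradient_image(qip_image(array(99, c(8, 8, 3))))$strength == 0))

  # gray image varies only in L*: combined gradient equals the L* gradient
  set.seed(6)
  m <- matrix(runif(400, 0, 255), 20, 20)
  g <- gradient_image(rgb_from_gray(m))
  L <- convert_color(rgb_from_gray(m), "lab")$L
  gx <- qipr:::.cdiff(L, "x"); gy <- qipr:::.cdiff(L, "y")
  expect_equal(g$strength, sqrt(gx^2 + gy^2), tolerance = 1e-12)

  # vertical step: strength confined to the two adjoining columns, with the
  # closed-form central-difference magnitude
  se <- step_edge(50, at = 26)
  gs <- gradient_image(rgb_from_gray(se$pixels))$strength
  Lhi <- convert_color(rgb_from_gray(matrix(255, 1, 1)), "lab")$L[1, 1]
  expect_equal(unique(round(gs[, 25], 6)), round(Lhi / 2, 6))
  expect_equal(unique(round(gs[, 26], 6)), round(Lhi / 2, 6))
  expect_true(all(gs[, -c(25, 26)] == 0))
})

test_that("complexity equals direct summation and grows under superposition", {
  se <- step_edge(100, at = 51)
  img <- rgb_from_gray(se$pixels)
  g <- gradient_image(img)
  expect_equal(complexity_hog(img), sum(g$strength) / (100 * 100))

  two <- se$pixels; two[, 20:40] <- 128
  expect_gt(complexity_hog(rgb_from_gray(two)), complexity_hog(img))
})

test_that("the pyramid has the right shape and conserves gradient mass", {
  set.seed(7)
  img <- rgb_from_gray(matrix(runif(97 * 103, 0, 255), 97, 103))
  pyr <- build_phog(gradient_image(img))
  expect_equal(vapply(pyr, ncol, integer(1)), c(1L, 4L, 16L, 64L))
  for (lev in 2:4) {
    expect_equal(rowSums(pyr[[lev]]), pyr[[1]][, 1], tolerance = 1e-6)
  }
  expect_error(build_phog(gradient_image(img), max_level = 4), "unstable")
})

test_that("self-similarity matches the hand-computed HIK on a quadrant field", {
  # one distinct orientation per quadrant, equal mass: each level-1 section
  # is one-hot, the ground is (1/4, 1/4, 1/4, 1/4) -> HIK = 1/4 each
  s <- matrix(1, 64, 64)
  o <- matrix(0, 64, 64)
  o[1:32, 33:64] <- 45; o[33:64, 1:32] <- 90; o[33:64, 33:64] <- 135
  g <- structure(list(strength = s, orientation = o), class = "qip_gradient")
  pyr <- build_phog(g)
  expect_equal(phog_self_similarity(pyr, levels = 1), 0.25, tolerance = 1e-12)

  # identical normalized histograms give HIK exactly 1
  u <- structure(list(strength = s, orientation = matrix(45, 64, 64)),
                 class = "qip_gradient")
  expect_equal(phog_self_similarity(build_phog(u)), 1)
})

test_that("tiled textures are highly self-similar", {
  set.seed(9)
  tile <- qip_gray(matrix(runif(64 * 64, 0, 255), 64, 64))
  big <- rgb_from_gray(tiled_texture(tile, 8)$pixels)
  pyr <- build_phog(gradient_image(big))
  expect_gte(phog_self_similarity(pyr), 0.95)
})

test_that("anisotropy spans uniform and one-hot extremes", {
  s <- matrix(1, 64, 64)
  # equal mass in all 16 bins
  o <- matrix(rep(seq(0, 337.5, by = 22.5), length.out = 64 * 64), 64, 64)
  g <- structure(list(strength = s, orientation = o), class = "qip_gradient")
  expect_equal(anisotropy(build_phog(g)), 0, tolerance = 1e-12)
  # single orientation: closed-form one-hot SD
  u <- structure(list(strength = s, orientation = matrix(0, 64, 64)),
                 class = "qip_gradient")
  expect_equal(anisotropy(build_phog(u)), sqrt(15) / 16, tolerance = 1e-12)
  # isotropic random line pattern scores below a single-orientation one
  iso <- line_pattern(128, 24, "uniform", layout = "random", seed = 2)
  par <- line_pattern(128, 24, "single", theta = 30, layout = "random", seed = 2)
  a_iso <- anisotropy(build_phog(gradient_image(rgb_from_gray(iso$pixels))))
  a_par <- anisotropy(build_phog(gradient_image(rgb_from_gray(par$pixels))))
  expect_lt(a_iso, a_par)
})

test_that("a 90-degree rotation permutes bins but leaves the scores unchanged", {
  set.seed(10)
  m <- matrix(runif(96 * 96, 0, 255), 96, 96)
  img <- rgb_from_gray(m)
  rot <- rgb_from_gray(t(m)[96:1, ])   # 90 deg counter-clockwise
  p1 <- build_phog(gradient_image(img))
  p2 <- build_phog(gradient_image(rot))
  expect_equal(complexity_hog(img), complexity_hog(rot), tolerance = 1e-9)
  expect_equal(anisotropy(p1), anisotropy(p2), tolerance = 1e-9)
  expect_equal(phog_self_similarity(p1), phog_self_similarity(p2),
               tolerance = 1e-9)
  # ground histogram shifts by exactly 4 bin positions
  h1 <- p1[[1]][, 1]; h2 <- p2[[1]][, 1]
  expect_equal(h2, h1[((0:15 + 4) %% 16) + 1], tolerance = 1e-6)
})

test_that("degenerate gradient fields yield NaN with a warning", {
  g <- gradient_image(qip_image(array(100, c(32, 32, 3))))
  pyr <- build_phog(g)
  expect_warning(v <- phog_self_similarity(pyr), "zero-gradient")
  expect_true(is.nan(v))
  expect_warning(a <- anisotropy(pyr), "zero-gradient")
  expect_true(is.nan(a))
})
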