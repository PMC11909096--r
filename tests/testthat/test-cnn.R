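bank <- surrogate_filter_bank(1)

test_that("the surrogate bank is well-formed and deterministic", {
  expect_equal(dim(bank$kernels), c(11L, 11L, 3L, 96L))
  expect_lt(max(abs(apply(bank$kernels, 4, sum))), 1e-9)
  expect_identical(bank$kernels, surrogate_filter_bank(1)$kernels)
  expect_false(identical(bank$kernels, surrogate_filter_bank(2)$kernels))
})

test_that("response stacks have the documented lattice and are linear pre-rectification", {
  set.seed(20)
  m <- matrix(runif(512 * 512, 0, 255), 512, 512)
  img <- rgb_from_gray(m)
  st <- conv1_features(img, bank)
  expect_equal(dim(st), c(126L, 126L, 96L))
  expect_true(min(st) >= 0)

  # constant image: every map is spatially constant
  cst <- conv1_features(qip_image(array(200, c(64, 64, 3))), bank,
                        rectify = FALSE)
  expect_lt(max(abs(sweep(cst, 3, apply(cst, 3, mean)))), 1e-8)

  # linearity of the pre-rectification responses under input scaling
  lin1 <- conv1_features(img, bank, rectify = FALSE)
  half <- qip_image(img$pixels * 0.5)
  lin2 <- conv1_features(half, bank, rectify = FALSE)
  expect_equal(lin2, 0.5 * lin1, tolerance = 1e-6)

  # dense-correlation oracle at sampled lattice positions
  work <- standardize_size(img, "fixed_square", 511)
  px <- qipr:::.conv_preprocess(work$pixels, bank)
  set.seed(21)
  for (i in 1:6) {
    py <- sample(0:125, 1); pxx <- sample(0:125, 1); fl <- sample(1:96, 1)
    patch <- px[py * 4 + 1:11, pxx * 4 + 1:11, , drop = FALSE]
    ref <- sum(patch * bank$kernels[, , , fl])
    expect_equal(lin1[py + 1, pxx + 1, fl], ref, tolerance = 1e-8)
  }
})

test_that("mirror-symmetric composites score symmetry exactly one", {
  simg <- lattice_symmetric_rgb(seed = 9, axis = "lr")
  expect_equal(cnn_symmetry(simg, bank, "lr"), 1, tolerance = 1e-9)
  uimg <- lattice_symmetric_rgb(seed = 10, axis = "ud")
  expect_equal(cnn_symmetry(uimg, bank, "ud"), 1, tolerance = 1e-9)
})

test_that("symmetry scores respect flip equivariance and intersection ordering", {
  im <- random_phase_image(128, 1.1, seed = 22)
  img <- rgb_from_gray(im$pixels)
  flp <- rgb_from_gray(im$pixels[, ncol(im$pixels):1])
  expect_equal(cnn_symmetry(img, bank, "lr"), cnn_symmetry(flp, bank, "lr"),
               tolerance = 1e-9)
  s_lr <- cnn_symmetry(img, bank, "lr")
  s_ud <- cnn_symmetry(img, bank, "ud")
  s_all <- cnn_symmetry(img, bank, "lrud")
  expect_lte(s_all, min(s_lr, s_ud) + 1e-12)
  expect_gte(s_all, 0); expect_lte(s_lr, 1)
})

test_that("self-similarity and variances match brute-force recomputation", {
  im <- random_phase_image(128, 1.0, seed = 23)
  img <- rgb_from_gray(im$pixels)
  st <- conv1_features(img, bank)

  # oracle: explicit loops over the 8 x 8 partition
  ground <- apply(st, 3, max); ground <- ground / sum(ground)
  b <- round((0:8) * 126 / 8)
  sims <- numeric(0); pooled <- matrix(0, 96, 64)
  cell <- 1
  for (i in 1:8) for (j in 1:8) {
    sub <- st[(b[i] + 1):b[i + 1], (b[j] + 1):b[j + 1], , drop = FALSE]
    v <- apply(sub, 3, max)
    pooled[, cell] <- v
    sims <- c(sims, sum(pmin(v / sum(v), ground)))
    cell <- cell + 1
  }
  expect_equal(cnn_self_similarity(img, bank), median(sims), tolerance = 1e-12)

  v <- cnn_variances(img, bank)
  pvar <- function(x) mean((x - mean(x))^2)
  expect_equal(v$sparseness, mean(apply(pooled, 2, pvar)), tolerance = 1e-12)
  expect_equal(v$variability, median(apply(pooled, 1, pvar)), tolerance = 1e-12)

  # filter-order permutation invariance
  perm <- bank
  perm$kernels <- perm$kernels[, , , sample(96)]
  vp <- cnn_variances(img, perm)
  expect_equal(vp$sparseness, v$sparseness, tolerance = 1e-9)
  expect_equal(vp$variability, v$variability, tolerance = 1e-9)
})

test_that("tiled textures are CNN-self-similar and constants degenerate to NaN", {
  set.seed(24)
  tile <- qip_gray(matrix(runif(64 * 64, 0, 255), 64, 64))
  big <- rgb_from_gray(tiled_texture(tile, 8)$pixels)
  expect_gte(cnn_self_similarity(big, bank), 0.95)

  cst <- qip_image(array(128, c(64, 64, 3)))
  expect_warning(s <- cnn_self_similarity(cst, bank), "all-zero")
  expect_true(is.nan(s))
  expect_warning(sy <- cnn_symmetry(cst, bank, "lr"), "all-zero")
  expect_true(is.nan(sy))
  expect_equal(cnn_variances(cst, bank)$variability, 0)
})

test_that("variability vanishes exactly when pooled maps are constant", {
  # vertical grating: every filter's pooled value is constant across cells
  gr <- grating(512, 8, 90)
  img <- rgb_from_gray(gr$pixels)
  v <- cnn_variances(img, bank)
  expect_gt(v$sparseness, 0)
  # pooled maps constant along the grating axis cells => tiny variability
  # relative to sparseness for this stationary stimulus
  expect_lt(v$variability, 0.05 * v$sparseness)
})

test_that("a pretrained tensor asset round-trips through the reader", {
  tmp <- withr::local_tempfile(fileext = ".bin")
  set.seed(25)
  w <- array(rnorm(96 * 3 * 11 * 11), c(96, 3, 11, 11))
  writeBin(as.numeric(aperm(w, c(4, 3, 2, 1))), tmp, size = 4, endian = "little")
  bk <- load_filter_bank(tmp)
  expect_equal(bk$source, "pretrained_asset")
  expect_equal(bk$kernels[2, 3, 1, 5], w[5, 1, 2, 3], tolerance = 1e-6)
  expect_error(load_filter_bank(file.path(tempdir(), "no_such.bin")),
               "surrogate_filter_bank")
})
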