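# Averaging and the evaluation metrics: MSE, SSIM, MS-SSIM, CNR.

test_that("mse satisfies its identities and matches a direct summation oracle", {
  a <- textured_image(24, 24, seed = 50)
  expect_identical(mse(a, a), 0)
  expect_identical(mse(matrix(0, 8, 8), matrix(1, 8, 8)), 1)
  b <- textured_image(24, 24, seed = 51)
  lo <- min(a, b); hi <- max(a, b)
  an <- (a - lo) / (hi - lo); bn <- (b - lo) / (hi - lo)
  oracle <- sum((bn - an)^2) / length(an)
  expect_equal(mse(a, b), oracle, tolerance = 1e-12)
  expect_error(mse(a, b[1:8, ]), "identical shape")
})

test_that("ssim equals 1 on identical inputs and its constant closed form", {
  a <- textured_image(24, 24, seed = 52) / 6
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim(a, a, method = "global"), 1, tolerance = 1e-12)
  # constant images a != b: variances vanish, global form reduces to
  # (2ab + c1) / (a^2 + b^2 + c1)
  av <- 0.3; bv <- 0.7
  c1 <- 0.01^2
  expect_equal(ssim(matrix(av, 16, 16), matrix(bv, 16, 16), method = "global",
                    normalize = FALSE),
               (2 * av * bv + c1) / (av^2 + bv^2 + c1), tolerance = 1e-12)
})

test_that("ssim is negative for an anticorrelated pair", {
  x <- matrix(rep(c(0.1, 0.9), length.out = 24 * 24), 24, 24)
  expect_lt(ssim(x, 1 - x, method = "global", normalize = FALSE), 0)
})

test_that("ms_ssim reduces to ssim at one scale and stays in [0, 1]", {
  a <- textured_image(32, 32, seed = 53) / 6
  b <- textured_image(32, 32, seed = 54) / 6
  expect_equal(suppressWarnings(ms_ssim(a, a)), 1, tolerance = 1e-9)
  expect_equal(ms_ssim(a, b, scales = 1L), ssim(a, b), tolerance = 1e-12)
  for (s in 1:10) {
    x <- textured_image(24, 24, seed = 100 + s) / 6
    y <- textured_image(24, 24, seed = 200 + s) / 6
    v <- ms_ssim(x, y, scales = 2L)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_warning(ms_ssim(textured_image(32, 32) / 6, textured_image(32, 32) / 6,
                         scales = 5L), "reducing")
})

test_that("cnr matches its plug-in formula and grows like sqrt(k) under averaging", {
  octreg3d:::with_seed(60, {
    img <- matrix(0.2 + rnorm(64 * 64, 0, 0.05), 64, 64)
    fg <- matrix(FALSE, 64, 64); fg[20:44, 20:44] <- TRUE
    img[fg] <- 0.8 + rnorm(sum(fg), 0, 0.05)
    bg <- !fg
    expect_equal(cnr(img, fg, bg), 12, tolerance = 2)
    expect_lt(abs(cnr(matrix(rnorm(32^2), 32, 32),
                      fg[1:32, 1:32], !fg[1:32, 1:32])), 1)
  })
  expect_error(cnr(matrix(1, 4, 4), matrix(TRUE, 4, 4), matrix(TRUE, 4, 4)),
               "disjoint")
  # Monte-Carlo sqrt(k) growth of CNR with averaging
  octreg3d:::with_seed(61, {
    fg <- matrix(FALSE, 48, 48); fg[16:32, 16:32] <- TRUE
    ratios <- vapply(1:10, function(r) {
      draws <- replicate(9, {
        m <- matrix(0.2 + rnorm(48 * 48, 0, 0.06), 48, 48)
        m[fg] <- 0.8 + rnorm(sum(fg), 0, 0.06)
        m
      }, simplify = FALSE)
      cnr(Reduce(`+`, draws) / 9, fg, !fg) / cnr(draws[[1]], fg, !fg)
    }, numeric(1))
    expect_equal(mean(ratios), 3, tolerance = 0.5)  # sqrt(9)
  })
})

test_that("average_volumes averages voxelwise and excludes zero-filled voxels", {
  a <- generate_phantom(phantom_params(shape = c(8L, 16L, 16L),
                                       speckle_variance = 0, seed = 70))
  expect_identical(average_volumes(volume_set(list(a)))$data, a$data)
  b <- a; b$data <- b$data + 2
  avg <- average_volumes(volume_set(list(a, b)))
  expect_equal(avg$data, a$data + 1)
  # zero-filled region of one member is excluded from the denominator
  c1 <- a; c1$data[1:3, , ] <- 0
  avg2 <- average_volumes(volume_set(list(a, c1)))
  expect_equal(avg2$data[1:3, , ], a$data[1:3, , ])
  expect_equal(avg2$data[4:8, , ], a$data[4:8, , ])
})

test_that("averaging independent speckle reduces voxel variance about k-fold", {
  tpl <- generate_phantom(phantom_params(shape = c(16L, 32L, 32L),
                                         speckle_variance = 0, seed = 71))
  copies <- lapply(1:10, function(m)
    corrupt(tpl, zero_trace_n(16), seed = 500 + m, speckle_variance = 0.05)$volume)
  avg <- average_volumes(volume_set(copies))
  v1 <- mean((copies[[1]]$data - tpl$data)^2)
  v10 <- mean((avg$data - tpl$data)^2)
  expect_lt(v10 / v1, 0.2)
})

test_that("metrics_vs_k is exact on identical noise-free copies", {
  tpl <- generate_phantom(phantom_params(shape = c(24L, 48L, 48L),
                                         speckle_variance = 0, seed = 72))
  rep <- suppressWarnings(metrics_vs_k(tpl, volume_set(list(tpl, tpl, tpl))))
  expect_true(all(rep$mse < 1e-12))  # k=3 mean is exact only to rounding
  expect_true(all(abs(rep$ms_ssim - 1) < 1e-6))
  expect_identical(rep$k, 1:3)
})
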