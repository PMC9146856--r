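test_that("a constant image concentrates all GLCM mass in one diagonal cell", {
  fr <- uniform_frame(120, 120, 120)
  p <- compute_glcm(fr, glcm_params())
  lev <- floor(120 * 32 / 256) # luminance of an equal-channel grey is itself
  expect_equal(p[lev + 1, lev + 1], 1)
  expect_equal(sum(p), 1)
  expect_equal(glcm_contrast(p), 0)
})

test_that("two-level column image reproduces the hand-enumerated GLCM", {
  # 2x2 image, columns at grey 0 and 255, two horizontal pairs; with the
  # symmetric convention p(0,1) = p(1,0) = 1/2 and contrast 1
  fr <- grey_frame(matrix(c(0, 0, 255, 255), 2, 2))
  p <- compute_glcm(fr, glcm_params(n_levels = 2, distance = 1, angles = 0))
  expect_equal(p[1, 2], 0.5)
  expect_equal(p[2, 1], 0.5)
  expect_equal(p[1, 1] + p[2, 2], 0)
  expect_equal(glcm_contrast(p), 1.0)
})

test_that("checkerboard contrast equals the squared level separation", {
  fr <- checkerboard_frame(n = 4, lo_bin = 0, hi_bin = 31)
  p <- compute_glcm(fr, glcm_params(n_levels = 32, angles = c(0, 90)))
  expect_equal(glcm_contrast(p), 31^2)
})

test_that("checkerboard contrast increases strictly with level separation", {
  prev <- -1
  for (sep in seq(1, 31, by = 3)) {
    fr <- checkerboard_frame(n = 8, lo_bin = 0, hi_bin = sep)
    ctr <- glcm_contrast(compute_glcm(fr, glcm_params(angles = c(0, 90))))
    expect_gt(ctr, prev)
    prev <- ctr
  }
})

test_that("GLCM is normalized and symmetric on random frames", {
  for (seed in 1:100) {
    fr <- random_frame(seed, masked = seed %% 2 == 0)
    p <- compute_glcm(fr, glcm_params())
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_equal(p, t(p))
    expect_true(all(p >= 0))
  }
})

test_that("contrast is invariant under a whole-bin grey shift", {
  set.seed(7)
  vals <- matrix(sample(0:200, 32 * 32, replace = TRUE), 32, 32)
  ctr1 <- glcm_contrast(compute_glcm(grey_frame(vals), glcm_params()))
  ctr2 <- glcm_contrast(compute_glcm(grey_frame(vals + 8), glcm_params()))
  expect_equal(ctr1, ctr2)
})

test_that("compute_glcm matches brute-force pair enumeration on small images", {
  for (seed in 1:20) {
    fr <- random_frame(seed, w = 8, h = 8, masked = seed > 10)
    for (pars in list(glcm_params(),
                      glcm_params(n_levels = 8, distance = 2, angles = c(0, 135)),
                      glcm_params(symmetric = FALSE, angles = c(45, 90)))) {
      expect_equal(unclass(compute_glcm(fr, pars)), brute_glcm(fr, pars),
                   ignore_attr = TRUE,
                   label = sprintf("seed %d", seed))
    }
  }
})

test_that("degenerate fields of view are rejected", {
  img <- array(100, dim = c(8, 8, 3))
  mask <- matrix(FALSE, 8, 8)
  mask[1, 1] <- TRUE
  expect_error(compute_glcm(new_frame(img, mask), glcm_params()),
               "degenerate field of view")
})

test_that("contrast rejects unnormalized matrices", {
  m <- matrix(1, 4, 4)
  expect_error(glcm_contrast(m), "normalized")
})
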