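test_that("the intensity CDF matches hand counts", {
  e <- as_enhanced(matrix(100, 8, 8))
  cc <- compute_cdf(e)
  expect_equal(cc$cdf[100], 0)      # level 99
  expect_equal(cc$cdf[101], 1)      # level 100
  expect_equal(cc$delta_f, 1)

  e <- as_enhanced(matrix(0:255, 16, 16))
  cc <- compute_cdf(e)
  expect_equal(cc$cdf, (1:256) / 256)

  e <- as_enhanced(matrix(c(10, 10, 20, 30), 2, 2))
  cc <- compute_cdf(e)
  expect_equal(cc$cdf[11], 0.5)   # level 10
  expect_equal(cc$cdf[21], 0.75)  # level 20
  expect_equal(cc$cdf[30], 0.75)  # level 29
  expect_equal(cc$cdf[31], 1)     # level 30
})

test_that("the CDF-distance threshold picks the maximum-distance level", {
  # the identity CDF has zero distance everywhere; tie-break gives level 0
  expect_equal(global_threshold((0:255) / 255, 1), 0)
  # a step CDF has its farthest point at the step
  step <- c(rep(0, 100), rep(1, 156))
  expect_equal(global_threshold(step, 1), 100)
})

test_that("the threshold equals an exhaustive scan on random CDFs", {
  set.seed(42)
  for (i in 1:50) {
    counts <- stats::rpois(256, lambda = stats::runif(1, 0.1, 5))
    if (sum(counts) == 0) counts[1] <- 1
    cdf <- cumsum(counts) / sum(counts)
    df <- cdf[256] - cdf[1]
    expect_identical(global_threshold(cdf, df),
                     oracle_global_threshold(cdf, df))
  }
})

test_that("the NGLCM matches hand counts and signals constant images", {
  e <- as_enhanced(matrix(50, 4, 4))
  expect_error(compute_nglcm(e), class = "fundusreg_constant_image")

  chk <- matrix(0, 8, 8)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 255
  g <- compute_nglcm(as_enhanced(chk))
  # hand count over all 8 directions on an 8x8 board: 224 of the 420
  # ordered adjacent pairs are orthogonal (colours differ), 196 are
  # diagonal (colours agree), each split equally by symmetry
  expect_equal(g$P[1, 256] + g$P[256, 1] + g$P[1, 1] + g$P[256, 256], 1)
  expect_equal(g$P[1, 256], 112 / 420, tolerance = 1e-12)
  expect_equal(g$P[1, 256], g$P[256, 1])
  expect_equal(g$P[1, 1] + g$P[256, 256], 196 / 420, tolerance = 1e-12)
  expect_equal(g$corr, (196 - 224) / 420, tolerance = 1e-12)
})

test_that("the NGLCM equals brute-force pair enumeration on random images", {
  for (seed in 1:5) {
    set.seed(seed)
    gray <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    fov <- matrix(stats::runif(64) > 0.2, 8, 8)
    fov[1:4, 1:4] <- TRUE
    e <- as_enhanced(gray, fov)
    g <- compute_nglcm(e)
    expect_equal(sum(g$P), 1, tolerance = 1e-9)
    expect_equal(g$P, t(g$P))
    expect_equal(g$P, oracle_nglcm_P(gray, fov), tolerance = 1e-12)
  }
})

test_that("background co-occurrence sums the sub-threshold block", {
  chk <- matrix(0, 8, 8)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 255
  g <- compute_nglcm(as_enhanced(chk))
  expect_equal(background_cooccurrence(g, 0), 0)
  expect_equal(background_cooccurrence(g, 256), 1)
  p_diag <- g$P[1, 1] # only the 0-0 cell lies under tau = 128
  expect_equal(background_cooccurrence(g, 128), p_diag)
})

test_that("the window count threshold floors and clamps", {
  expect_equal(window_threshold(0, 0.9, 7), 0)
  expect_equal(window_threshold(0.8, 0.9, 7), 35) # floor(0.8 * 0.9 * 49)
  expect_equal(window_threshold(0.8, -1, 7), 0)
  expect_error(window_threshold(0.5, 0.5, 4), class = "fundusreg_bad_input")
})

test_that("windowed classification matches the naive double loop", {
  for (seed in 1:4) {
    set.seed(seed)
    gray <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    fov <- matrix(TRUE, 32, 32)
    fov[1:3, ] <- FALSE
    e <- as_enhanced(gray, fov)
    m <- structure(list(tau_i = 120L, delta_f = 1, cdf = NULL, p_bg = 0.5,
                        corr = 0.8, tau_sd = sample(10:40, 1), n = 5L),
                   class = "segmentation_model")
    vm <- segment_vessels(e, m)
    expect_equal(vm$mask, oracle_segment(gray, fov, m$tau_i, m$tau_sd, m$n))
  }
})

test_that("classification is monotone in the window threshold", {
  set.seed(9)
  gray <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  e <- as_enhanced(gray)
  prev <- NULL
  for (tau_sd in c(5, 15, 25, 40)) {
    m <- structure(list(tau_i = 128L, delta_f = 1, cdf = NULL, p_bg = 0.5,
                        corr = 0.8, tau_sd = tau_sd, n = 7L),
                   class = "segmentation_model")
    cur <- segment_vessels(e, m)$mask
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("all-background input yields an empty vessel mask", {
  e <- as_enhanced(matrix(10, 16, 16))
  m <- structure(list(tau_i = 50L, delta_f = 1, cdf = NULL, p_bg = 1,
                      corr = 0.5, tau_sd = 24L, n = 7L),
                 class = "segmentation_model")
  expect_equal(sum(segment_vessels(e, m)$mask), 0)
})

test_that("vessel foreground fraction on the default fundus is anatomically plausible", {
  img <- render_fundus(generate_tree(5))
  e <- preprocess_fundus(img)
  vm <- segment_vessels(e, fit_segmentation_model(e))
  # literature places the vascular tree at roughly 10-15% of the fundus
  expect_gt(vm$foreground_fraction, 0.05)
  expect_lt(vm$foreground_fraction, 0.25)
})

test_that("segmentation models round-trip through JSON", {
  e <- as_enhanced(matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  m <- fit_segmentation_model(e, n = 5L)
  path <- tempfile(fileext = ".json")
  write_segmentation_model(m, path)
  m2 <- read_segmentation_model(path)
  expect_equal(m2$tau_i, m$tau_i)
  expect_equal(m2$tau_sd, m$tau_sd)
  expect_equal(m2$p_bg, m$p_bg, tolerance = 1e-12)
  expect_equal(m2$n, m$n)
})
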