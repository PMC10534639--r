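test_that("similarity fits recover planted parameters exactly", {
  pts <- cbind(c(10, 50, 30), c(20, 40, 90))
  expect_equal(fit_similarity(pts, pts)$T, diag(3), tolerance = 1e-12)

  src <- cbind(c(0, 10), c(0, 0))
  dst <- src + matrix(rep(c(10, -5), each = 2), 2, 2)
  T <- fit_similarity(src, dst)$T
  expect_equal(T, matrix(c(1, 0, 10, 0, 1, -5, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-12)

  true <- random_similarity(s = 1.5, theta = 30 * pi / 180, t = c(10, -5))
  src <- cbind(c(3, 80), c(7, 40))
  dst <- apply_transform(true, src)
  got <- fit_similarity(src, dst)
  expect_equal(got$T, true$T, tolerance = 1e-9)
})

test_that("affine fits are exact for 3 points and least squares beyond", {
  pts <- cbind(c(0, 10, 3), c(0, 2, 9))
  expect_equal(fit_affine(pts, pts)$T, diag(3), tolerance = 1e-12)

  shear <- transform_model(matrix(c(1, 0.3, 4, 0.1, 0.9, -2, 0, 0, 1),
                                  3, 3, byrow = TRUE), "affine")
  dst <- apply_transform(shear, pts)
  expect_equal(fit_affine(pts, dst)$T, shear$T, tolerance = 1e-9)

  set.seed(11)
  src10 <- matrix(stats::runif(20, 0, 100), 10, 2)
  A <- matrix(c(1.1, -0.2, 12, 0.15, 0.95, -8, 0, 0, 1), 3, 3, byrow = TRUE)
  dst10 <- apply_transform(transform_model(A, "affine"), src10)
  expect_equal(fit_affine(src10, dst10)$T, A, tolerance = 1e-9)
})

test_that("degenerate correspondence sets are rejected", {
  same <- cbind(c(5, 5), c(5, 5))
  expect_error(fit_similarity(same, cbind(c(0, 1), c(0, 1))),
               class = "fundusreg_degenerate")
  col3 <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_error(fit_affine(col3, col3 + 1), class = "fundusreg_degenerate")
  expect_error(fit_similarity(cbind(1, 1), cbind(1, 1)),
               class = "fundusreg_degenerate")
})

test_that("the RANSAC iteration formula matches direct evaluation", {
  expect_equal(ransac_iterations(0.99, 0, 2), 1L)
  expect_equal(ransac_iterations(0.99, 0.5, 2), 17L)
  # nondecreasing in outlier rate and in sample size
  ns <- vapply(seq(0, 0.9, by = 0.1),
               function(v) ransac_iterations(0.99, v, 2), integer(1))
  expect_true(all(diff(ns) >= 0))
  expect_gte(ransac_iterations(0.99, 0.5, 3), ransac_iterations(0.99, 0.5, 2))
  expect_error(ransac_iterations(0.99, 1, 2), class = "fundusreg_bad_input")
})

make_matchset <- function(n) {
  structure(data.frame(source = seq_len(n), target = seq_len(n),
                       distance = 0),
            class = c("match_set", "data.frame"))
}

test_that("RANSAC recovers an exact model and rejects planted outliers", {
  set.seed(21)
  true <- random_similarity(s = 1.02, theta = 5 * pi / 180, t = c(30, -12))
  src <- data.frame(x = stats::runif(10, 50, 700),
                    y = stats::runif(10, 50, 700))
  proj <- apply_transform(true, src)
  dst <- data.frame(x = proj[, 1], y = proj[, 2])
  res <- ransac_fit(make_matchset(10), src, dst, "similarity",
                    ransac_config(seed = 3))
  expect_true(res$converged)
  expect_equal(nrow(res$inliers), 10)
  expect_equal(res$model$T, true$T, tolerance = 1e-6)

  # 8 exact correspondences plus 4 scrambled ones
  src12 <- data.frame(x = stats::runif(12, 50, 700),
                      y = stats::runif(12, 50, 700))
  proj <- apply_transform(true, src12)
  dst12 <- data.frame(x = proj[, 1], y = proj[, 2])
  dst12[9:12, ] <- dst12[9:12, ] + matrix(stats::runif(8, 60, 200), 4, 2)
  res <- ransac_fit(make_matchset(12), src12, dst12, "similarity",
                    ransac_config(seed = 3))
  expect_true(res$converged)
  expect_setequal(res$inliers$source, 1:8)
  expect_equal(res$model$T, true$T, tolerance = 1e-6)
})

test_that("RANSAC reports non-convergence below the minimal sample", {
  src <- data.frame(x = 1, y = 1)
  res <- ransac_fit(make_matchset(1), src, src, "similarity")
  expect_false(res$converged)
  expect_match(res$diagnostic, "matches")
})

test_that("RANSAC is deterministic for a fixed seed", {
  set.seed(33)
  true <- random_similarity()
  src <- data.frame(x = stats::runif(15, 50, 700),
                    y = stats::runif(15, 50, 700))
  proj <- apply_transform(true, src)
  dst <- data.frame(x = proj[, 1] + stats::rnorm(15, 0, 0.5),
                    y = proj[, 2] + stats::rnorm(15, 0, 0.5))
  r1 <- ransac_fit(make_matchset(15), src, dst, "similarity",
                   ransac_config(seed = 7))
  r2 <- ransac_fit(make_matchset(15), src, dst, "similarity",
                   ransac_config(seed = 7))
  expect_identical(r1$model$T, r2$model$T)
  expect_identical(r1$inliers, r2$inliers)
})

test_that("RANSAC recovery holds across 100 seeded trials with 40% outliers", {
  ok <- 0L
  for (trial in 1:100) {
    set.seed(trial)
    true <- random_similarity()
    n_in <- 12L; n_out <- 8L # 40% outliers
    src <- data.frame(x = stats::runif(n_in + n_out, 50, 700),
                      y = stats::runif(n_in + n_out, 50, 700))
    proj <- apply_transform(true, src)
    dst <- data.frame(x = proj[, 1], y = proj[, 2])
    out_idx <- seq_len(n_out) + n_in
    dst[out_idx, ] <- dst[out_idx, ] +
      matrix(stats::runif(2 * n_out, 40, 250) *
               sample(c(-1, 1), 2 * n_out, TRUE), n_out, 2)
    res <- ransac_fit(make_matchset(n_in + n_out), src, dst, "similarity",
                      ransac_config(seed = trial))
    if (!res$converged) next
    held <- data.frame(x = stats::runif(10, 100, 650),
                       y = stats::runif(10, 100, 650))
    err <- sqrt(rowSums((apply_transform(res$model, held) -
                           apply_transform(true, held))^2))
    if (mean(err) < 0.5) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("1 px keypoint noise keeps mean control-point error within 3 px", {
  errs <- vapply(1:30, function(trial) {
    set.seed(trial + 500)
    true <- random_similarity()
    n <- 40L
    src <- data.frame(x = stats::runif(n, 50, 700),
                      y = stats::runif(n, 50, 700))
    proj <- apply_transform(true, src)
    src_n <- src + matrix(stats::rnorm(2 * n, 0, 1), n, 2)
    dst_n <- data.frame(x = proj[, 1], y = proj[, 2]) +
      matrix(stats::rnorm(2 * n, 0, 1), n, 2)
    res <- ransac_fit(make_matchset(n), src_n, dst_n, "similarity",
                      ransac_config(seed = trial))
    if (!res$converged) return(Inf)
    held <- data.frame(x = stats::runif(10, 100, 650),
                       y = stats::runif(10, 100, 650))
    mean(sqrt(rowSums((apply_transform(res$model, held) -
                         apply_transform(true, held))^2)))
  }, numeric(1))
  expect_lte(mean(errs), 3)
})

test_that("the fitted model composed with the planted inverse is identity", {
  set.seed(55)
  true <- random_similarity()
  src <- data.frame(x = stats::runif(20, 50, 700),
                    y = stats::runif(20, 50, 700))
  proj <- apply_transform(true, src)
  res <- ransac_fit(make_matchset(20), src,
                    data.frame(x = proj[, 1], y = proj[, 2]),
                    "similarity", ransac_config(seed = 1))
  comp <- res$model$T %*% solve(true$T)
  expect_equal(comp, diag(3), tolerance = 1e-6)
})

test_that("transform models round-trip through JSON", {
  m <- random_similarity(s = 1.1, theta = 0.2, t = c(3.5, -7.25))
  path <- tempfile(fileext = ".json")
  write_transform_model(m, path)
  m2 <- read_transform_model(path)
  expect_equal(m2$T, m$T, tolerance = 1e-12)
  expect_equal(m2$kind, "similarity")
})

test_that("warping with the identity reproduces the source frame", {
  fx <- disc_fundus(48, 48, r = 20)
  img <- fundus_image(fx$rgb, fx$disc)
  wp <- warp_source(img, transform_model(diag(3), "similarity"))
  expect_equal(dim(wp$rgb)[1:2], c(48L, 48L))
  expect_equal(unname(wp$offset), c(1, 1))
  expect_equal(wp$rgb, img$rgb, tolerance = 1e-9)
  expect_equal(wp$mask, img$fov_mask)
})

test_that("pure translation enlarges the canvas by the offset", {
  fx <- disc_fundus(48, 48, r = 20)
  img <- fundus_image(fx$rgb, fx$disc)
  T <- matrix(c(1, 0, 10, 0, 1, -5, 0, 0, 1), 3, 3, byrow = TRUE)
  wp <- warp_source(img, transform_model(T, "similarity"))
  expect_equal(dim(wp$mask), c(48L + 5L, 48L + 10L))
  expect_equal(unname(wp$offset), c(1, -4))
})

test_that("warping by T then its inverse returns near the original", {
  tree <- generate_tree(4, canvas = c(192L, 192L), n_roots = 3, depth = 4,
                        root_length = 40)
  img <- render_fundus(tree, fov_radius = 80)
  # soften the anti-aliased vessel edges: the round-trip property is about
  # resampling consistency, and bilinear interpolation is only faithful on
  # band-limited content
  for (ch in 1:3)
    img$rgb[, , ch] <- fundusreg:::from_ebimage(
      EBImage::gblur(fundusreg:::as_ebimage(img$rgb[, , ch]), 2))
  T <- random_similarity(s = 1, theta = 4 * pi / 180, t = c(6.3, -2.7))
  wp <- warp_source(img, T)
  # shift the warped canvas back into a fundus_image in canvas coordinates
  warped <- fundus_image(wp$rgb, wp$mask | TRUE, id = "w")
  warped$fov_mask <- wp$mask
  Tshift <- diag(3); Tshift[1, 3] <- wp$offset[["x"]] - 1
  Tshift[2, 3] <- wp$offset[["y"]] - 1
  Tback <- transform_model(solve(T$T) %*% Tshift, "similarity")
  back <- warp_source(warped, Tback, target_dim = c(192L, 192L))
  # align the back-warped canvas with the source frame via its offset
  rows <- seq_len(192) - back$offset[["y"]] + 1
  cols <- seq_len(192) - back$offset[["x"]] + 1
  common <- img$fov_mask & back$mask[rows, cols]
  # away from the rim, where mask resampling differs
  dm <- fundusreg:::from_ebimage(EBImage::distmap(
    fundusreg:::as_ebimage(img$fov_mask)))
  core <- common & dm > 6
  dif <- abs(back$rgb[rows, cols, 2] - img$rgb[, , 2])
  expect_lt(mean(dif[core]), 2)
})
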