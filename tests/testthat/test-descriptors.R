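# A textured enhanced image with keypoints well inside the frame.
textured_enhanced <- function(seed = 1, h = 64, w = 64) {
  set.seed(seed)
  g <- round(fundusreg:::clamp(
    128 + 60 * sin(outer(1:h, 1:w, function(y, x) x / 3 + y / 5)) +
      matrix(stats::rnorm(h * w, 0, 10), h, w), 0, 255))
  as_enhanced(g)
}

test_that("descriptors are 128-dimensional unit vectors", {
  e <- textured_enhanced()
  pts <- data.frame(x = c(20L, 32L, 45L), y = c(20L, 40L, 30L))
  d <- compute_descriptors(e, pts)
  expect_equal(ncol(d$vectors), 128L)
  expect_equal(nrow(d$vectors), 3L)
  expect_true(all(d$valid))
  expect_equal(unname(sqrt(rowSums(d$vectors^2))), rep(1, 3),
               tolerance = 1e-9)
  expect_true(all(d$vectors >= 0))
})

test_that("points whose window leaves the image are dropped", {
  e <- textured_enhanced()
  pts <- data.frame(x = c(5L, 32L, 60L), y = c(32L, 32L, 32L))
  d <- compute_descriptors(e, pts)
  expect_equal(d$keypoints$x, 32L)
})

test_that("a constant patch yields a flagged all-zero descriptor", {
  g <- matrix(77, 64, 64)
  d <- compute_descriptors(as_enhanced(g), data.frame(x = 32L, y = 32L))
  expect_false(d$valid[1])
  expect_true(all(d$vectors == 0))
})

test_that("descriptors are invariant to gain and offset of the patch", {
  e <- textured_enhanced(3)
  pts <- data.frame(x = 32L, y = 32L)
  d1 <- compute_descriptors(e, pts)
  e2 <- as_enhanced(e$gray * 2 + 10) # affine intensity change, no clipping
  d2 <- compute_descriptors(e2, pts)
  expect_equal(d1$vectors, d2$vectors, tolerance = 1e-12)
})

test_that("identical descriptor sets match to themselves at zero distance", {
  set.seed(4)
  v <- matrix(stats::runif(5 * 128), 5, 128)
  v <- v / sqrt(rowSums(v^2))
  ds <- list(vectors = v, keypoints = data.frame(x = 1:5, y = 1:5),
             valid = rep(TRUE, 5))
  m <- match_one_direction(ds, ds, threshold = 0.9)
  expect_equal(m$source, 1:5)
  expect_equal(m$target, 1:5)
  expect_equal(m$distance, rep(0, 5), tolerance = 1e-6)
})

test_that("matching rejects candidates without a second neighbour", {
  set.seed(5)
  v <- matrix(stats::runif(3 * 128), 3, 128)
  A <- list(vectors = v, keypoints = data.frame(x = 1:3, y = 1:3),
            valid = rep(TRUE, 3))
  B <- list(vectors = v[1, , drop = FALSE],
            keypoints = data.frame(x = 1, y = 1), valid = TRUE)
  expect_equal(nrow(match_one_direction(A, B)), 0)
})

test_that("both acceptance modes equal brute-force evaluation on a known table", {
  set.seed(6)
  va <- matrix(stats::rnorm(5 * 128), 5, 128)
  vb <- matrix(stats::rnorm(5 * 128), 5, 128)
  va <- va / sqrt(rowSums(va^2)); vb <- vb / sqrt(rowSums(vb^2))
  A <- list(vectors = va, keypoints = data.frame(x = 1:5, y = 1:5),
            valid = rep(TRUE, 5))
  B <- list(vectors = vb, keypoints = data.frame(x = 1:5, y = 1:5),
            valid = rep(TRUE, 5))
  D <- as.matrix(stats::dist(rbind(va, vb)))[1:5, 6:10]
  for (mode in c("ratio", "magnitude")) {
    for (thr in c(0.5, 0.9, 1.2)) {
      got <- match_one_direction(A, B, thr, mode)
      want <- NULL
      for (i in 1:5) {
        ord <- order(D[i, ])
        d1 <- D[i, ord[1]]; d2 <- D[i, ord[2]]
        ok <- if (mode == "ratio") d1 / d2 <= thr else d1 <= thr * 1
        if (ok) want <- rbind(want, c(i, ord[1], d1))
      }
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got$source, want[, 1])
        expect_equal(got$target, want[, 2])
        expect_equal(got$distance, unname(want[, 3]), tolerance = 1e-12)
      }
    }
  }
})

test_that("cross-checking keeps exactly the mutual pairs", {
  mk <- function(s, t) structure(
    data.frame(source = s, target = t, distance = 0),
    class = c("match_set", "data.frame"))
  expect_equal(nrow(cross_check(mk(0, 1), mk(1, 0))), 1)
  expect_equal(nrow(cross_check(mk(0, 1), mk(1, 2))), 0)
  set.seed(7)
  for (rep in 1:10) {
    ab <- mk(sample(20), sample(20))
    ba <- mk(sample(20), sample(20))
    got <- cross_check(ab, ba)
    naive <- ab[mapply(function(i, j)
      any(ba$source == j & ba$target == i), ab$source, ab$target), ]
    expect_equal(got$source, naive$source)
    expect_equal(got$target, naive$target)
    # symmetric result is one-to-one
    expect_false(any(duplicated(got$source)))
    expect_false(any(duplicated(got$target)))
  }
})

test_that("cross-checked matching is symmetric in ratio mode", {
  set.seed(8)
  mkset <- function(n) {
    v <- matrix(stats::rnorm(n * 128), n, 128)
    v <- v / sqrt(rowSums(v^2))
    list(vectors = v, keypoints = data.frame(x = seq_len(n), y = seq_len(n)),
         valid = rep(TRUE, n))
  }
  A <- mkset(12); B <- mkset(12)
  mab <- match_descriptors(A, B, 0.95)
  mba <- match_descriptors(B, A, 0.95)
  expect_equal(mab[order(mab$source), c("source", "target")],
               setNames(mba[order(mba$target), c("target", "source")],
                        c("source", "target")),
               ignore_attr = TRUE)
})

test_that("cross-checking does not decrease the true-match ratio", {
  # planted correspondences: B's first 8 vectors are noisy copies of A's
  set.seed(9)
  va <- matrix(stats::rnorm(12 * 128), 12, 128)
  va <- va / sqrt(rowSums(va^2))
  vb <- va + matrix(stats::rnorm(12 * 128, 0, 0.15), 12, 128)
  vb[9:12, ] <- matrix(stats::rnorm(4 * 128), 4, 128) # distractors
  vb <- vb / sqrt(rowSums(vb^2))
  A <- list(vectors = va, keypoints = data.frame(x = 1:12, y = 1:12),
            valid = rep(TRUE, 12))
  B <- list(vectors = vb, keypoints = data.frame(x = 1:12, y = 1:12),
            valid = rep(TRUE, 12))
  ab <- match_one_direction(A, B, 0.95)
  cc <- cross_check(ab, match_one_direction(B, A, 0.95))
  ratio <- function(m) if (nrow(m) == 0) NA else mean(m$source == m$target)
  expect_gte(ratio(cc), ratio(ab))
})
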