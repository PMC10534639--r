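# Shared fixtures and independent brute-force oracles. Every oracle here is
# a deliberately naive reimplementation used only to check the package's
# optimized code paths.

# A flat fundus frame with a centred white disc.
disc_fundus <- function(h = 64L, w = 64L, r = h / 2 - 2, value = 200) {
  rgb <- array(0, c(h, w, 3L))
  d2 <- outer((seq_len(h) - h / 2)^2, (seq_len(w) - w / 2)^2, "+")
  disc <- d2 <= r^2
  for (ch in 1:3) rgb[, , ch] <- value * disc
  list(rgb = rgb, disc = disc)
}

# Wrap a gray matrix as an enhanced_image with a full-frame FOV.
as_enhanced <- function(gray, fov = NULL) {
  gray <- as.matrix(gray)
  if (is.null(fov)) fov <- matrix(TRUE, nrow(gray), ncol(gray))
  structure(list(gray = gray, fov_mask = fov), class = "enhanced_image")
}

as_skeleton <- function(mask) {
  structure(list(mask = matrix(as.logical(mask), nrow(mask), ncol(mask))),
            class = "skeleton")
}

# Random sparse skeleton-like masks: a few random 1-px strokes.
random_skeleton <- function(seed, h = 24L, w = 24L, n_strokes = 4L) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_strokes)) {
    x <- sample(2:(w - 1), 1); y <- sample(2:(h - 1), 1)
    dir <- sample(1:8, 1)
    step <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1), c(0, -1), c(-1, -1),
                 c(-1, 0), c(-1, 1))[[dir]]
    for (k in seq_len(sample(4:10, 1))) {
      m[y, x] <- TRUE
      y <- y + step[1]; x <- x + step[2]
      if (y < 2 || y > h - 1 || x < 2 || x > w - 1) break
    }
  }
  m
}

# Random blobby binary masks for thinning tests.
random_blob_mask <- function(seed, h = 40L, w = 40L) {
  set.seed(seed)
  n <- matrix(stats::rnorm(h * w), h, w)
  k <- 5L
  sm <- fundusreg:::box_sum(n, k) / k^2
  sm > stats::quantile(sm, 0.75)
}

# --- independent oracles ------------------------------------------------

# Exhaustive scan version of the CDF-distance threshold.
oracle_global_threshold <- function(cdf, delta_f) {
  best <- -Inf; best_l <- 0L
  for (l in 0:255) {
    d <- abs(cdf[l + 1] + delta_f * (1 - l / 255) - 1) / sqrt(1 + delta_f^2)
    if (d > best + 1e-15) { best <- d; best_l <- l }
  }
  best_l
}

# Double-loop NGLCM accumulation over all ordered 8-adjacent pairs.
oracle_nglcm_P <- function(gray, fov) {
  P <- matrix(0, 256, 256)
  h <- nrow(gray); w <- ncol(gray)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!fov[y, x]) next
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > h || xx < 1 || xx > w || !fov[yy, xx]) next
      P[gray[y, x] + 1, gray[yy, xx] + 1] <-
        P[gray[y, x] + 1, gray[yy, xx] + 1] + 1
    }
  }
  P / sum(P)
}

# Per-pixel window classification, naive O(H W n^2).
oracle_segment <- function(gray, fov, tau_i, tau_sd, n) {
  h <- nrow(gray); w <- ncol(gray)
  r <- (n - 1) %/% 2
  out <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!fov[y, x]) next
    cnt <- 0
    for (dy in -r:r) for (dx in -r:r) {
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > h || xx < 1 || xx > w || !fov[yy, xx] ||
          gray[yy, xx] < tau_i) cnt <- cnt + 1
    }
    out[y, x] <- cnt <= tau_sd
  }
  out
}

# Literal per-pixel transcription of the two Zhang-Suen sub-passes.
oracle_zhang_suen <- function(m) {
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  h <- nrow(m); w <- ncol(m)
  nb <- function(mm, y, x) {
    gv <- function(yy, xx) if (yy < 1 || yy > h || xx < 1 || xx > w) 0L
      else as.integer(mm[yy, xx])
    c(gv(y - 1, x), gv(y - 1, x + 1), gv(y, x + 1), gv(y + 1, x + 1),
      gv(y + 1, x), gv(y + 1, x - 1), gv(y, x - 1), gv(y - 1, x - 1))
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      del <- NULL
      for (y in seq_len(h)) for (x in seq_len(w)) {
        if (!m[y, x]) next
        p <- nb(m, y, x) # p2..p9 clockwise from north
        B <- sum(p)
        ring <- c(p, p[1])
        A <- sum(ring[-9] == 0 & ring[-1] == 1)
        cond <- if (pass == 1)
          p[1] * p[3] * p[5] == 0 && p[3] * p[5] * p[7] == 0
        else
          p[1] * p[3] * p[7] == 0 && p[1] * p[5] * p[7] == 0
        if (B >= 2 && B <= 6 && A == 1 && cond)
          del <- rbind(del, c(y, x))
      }
      if (!is.null(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Sliding-window hit-or-miss scan over every interior pixel and stencil.
oracle_hit_or_miss_points <- function(mask, bank) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (pair in bank) {
    for (y in 2:(h - 1)) for (x in 2:(w - 1)) {
      ok <- TRUE
      for (i in 1:3) for (j in 1:3) {
        v <- mask[y + i - 2, x + j - 2]
        if (pair$b1[i, j] && !v) ok <- FALSE
        if (pair$b2[i, j] && v) ok <- FALSE
      }
      if (ok) out <- rbind(out, data.frame(x = x, y = y, pattern = pair$name))
    }
  }
  if (is.null(out)) data.frame(x = integer(), y = integer(),
                               pattern = character())
  else out
}

# Trapezoidal success-curve integration, summed term by term.
oracle_auc <- function(errors, max_threshold = 25) {
  area <- 0
  rate <- function(t) mean(errors <= t)
  for (t in seq_len(max_threshold)) {
    area <- area + (rate(t - 1) + rate(t)) / 2
  }
  area / max_threshold
}

# 8-connected component count by breadth-first flood fill.
count_components8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  ncomp <- 0L
  for (y0 in seq_len(h)) for (x0 in seq_len(w)) {
    if (!m[y0, x0] || seen[y0, x0]) next
    ncomp <- ncomp + 1L
    queue <- list(c(y0, x0)); seen[y0, x0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- p[1] + dy; xx <- p[2] + dx
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
            m[yy, xx] && !seen[yy, xx]) {
          seen[yy, xx] <- TRUE
          queue[[length(queue) + 1]] <- c(yy, xx)
        }
      }
    }
  }
  ncomp
}

# Random similarity transform for recovery experiments.
random_similarity <- function(s = NULL, theta = NULL, t = NULL) {
  s <- s %||% stats::runif(1, 0.9, 1.1)
  theta <- theta %||% stats::runif(1, -15, 15) * pi / 180
  t <- t %||% stats::runif(2, -50, 50)
  A <- s * matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
                  2, 2, byrow = TRUE)
  T <- rbind(cbind(A, t), c(0, 0, 1))
  dimnames(T) <- NULL
  transform_model(T, "similarity")
}

# Label matrix of 8-connected components (0 = background).
label_components8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (y0 in seq_len(h)) for (x0 in seq_len(w)) {
    if (!m[y0, x0] || lab[y0, x0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(y0, x0)); lab[y0, x0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- p[1] + dy; xx <- p[2] + dx
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
            m[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- cur
          queue[[length(queue) + 1]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}

# Connectivity audit of thinning: no mask component ever splits into
# several skeleton components or merges with another (the skeleton stays
# inside its component). Survival is shape-dependent — Zhang-Suen erodes
# compact hole-free blobs (observed up to ~30 px, starting from the known
# 2x2 erasure case) to nothing — so only clearly-elongated components are
# required to survive.
expect_connectivity_preserved <- function(m, sk) {
  labm <- label_components8(m)
  for (cl in seq_len(max(labm))) {
    inside <- labm == cl
    ncomp <- count_components8(sk & inside)
    expect_lte(ncomp, 1L)
    if (sum(inside) > 50) expect_equal(ncomp, 1L)
  }
  expect_true(all(sk <= m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
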