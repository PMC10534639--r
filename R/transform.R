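#' Planar transform model
#'
#' A 3x3 homogeneous matrix `T` acting on column points `(x, y, 1)` so that
#' `p_target = T %*% p_source`. `kind` is `"similarity"` (rotation, uniform
#' scale, translation; 4 degrees of freedom, minimal sample 2) or
#' `"affine"` (6 DOF, minimal sample 3).
#'
#' @param T 3x3 numeric matrix with last row (0, 0, 1).
#' @param kind `"similarity"` or `"affine"`.
#' @return Object of class `transform_model`.
#' @export
transform_model <- function(T, kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(T), all(dim(T) == c(3L, 3L)))
  if (max(abs(T[3L, ] - c(0, 0, 1))) > 1e-12)
    stopf("last row of T must be (0, 0, 1)", class = "fundusreg_bad_input")
  structure(list(kind = kind, T = T,
                 dof = if (kind == "similarity") 4L else 6L),
            class = "transform_model")
}

#' @export
print.transform_model <- function(x, ...) {
  cat(sprintf("<transform_model: %s>\n", x$kind))
  print(round(x$T, 6))
  invisible(x)
}

#' Apply a transform to points
#'
#' @param model a `transform_model` (or bare 3x3 matrix).
#' @param pts matrix or data.frame with columns (x, y).
#' @return Two-column matrix of transformed (x, y).
#' @export
apply_transform <- function(model, pts) {
  T <- if (inherits(model, "transform_model")) model$T else model
  p <- as.matrix(pts[, 1:2, drop = FALSE])
  out <- cbind(p, 1) %*% t(T)
  out[, 1:2, drop = FALSE]
}

#' Fit a similarity transform to point correspondences
#'
#' Solves for `x' = a x - b y + tx`, `y' = b x + a y + ty` by linear least
#' squares; with exactly two correspondences the solution is exact.
#'
#' @param src,dst matrices/data.frames of corresponding (x, y) points,
#'   at least 2 rows.
#' @return A `transform_model` of kind `"similarity"`.
#' @export
fit_similarity <- function(src, dst) {
  src <- as.matrix(src[, 1:2, drop = FALSE])
  dst <- as.matrix(dst[, 1:2, drop = FALSE])
  n <- nrow(src)
  if (n < 2L)
    stopf("similarity needs at least 2 correspondences",
          class = "fundusreg_degenerate")
  if (max(stats::dist(src)) < 1e-12)
    stopf("coincident source points: similarity underdetermined",
          class = "fundusreg_degenerate")
  X <- rbind(cbind(src[, 1L], -src[, 2L], 1, 0),
             cbind(src[, 2L], src[, 1L], 0, 1))
  yv <- c(dst[, 1L], dst[, 2L])
  beta <- solve(crossprod(X), crossprod(X, yv))
  a <- beta[1L]; b <- beta[2L]
  T <- matrix(c(a, -b, beta[3L],
                b, a, beta[4L],
                0, 0, 1), 3L, 3L, byrow = TRUE)
  transform_model(T, "similarity")
}

#' Fit an affine transform to point correspondences
#'
#' Exact solve for three correspondences, least squares otherwise.
#'
#' @param src,dst matrices/data.frames of corresponding (x, y) points,
#'   at least 3 rows.
#' @return A `transform_model` of kind `"affine"`.
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src[, 1:2, drop = FALSE])
  dst <- as.matrix(dst[, 1:2, drop = FALSE])
  n <- nrow(src)
  if (n < 3L)
    stopf("affine needs at least 3 correspondences",
          class = "fundusreg_degenerate")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L)
    stopf("collinear source points: affine underdetermined",
          class = "fundusreg_degenerate")
  beta <- qr.solve(X, dst) # 3 x 2: columns are (x', y') coefficients
  T <- rbind(t(beta), c(0, 0, 1))
  transform_model(T, "affine")
}

#' RANSAC iteration count for a target confidence
#'
#' `N = ceil(log(1 - p) / log(1 - (1 - v)^m))`: the number of random
#' minimal samples needed so that with probability `p` at least one of them
#' is outlier-free, when each datum is an outlier with probability `v` and
#' the model needs `m` observations.
#'
#' @param p_success target confidence (commonly 0.99).
#' @param outlier_rate outlier probability `v` in [0, 1).
#' @param sample_size minimal sample size `m` (2 similarity, 3 affine).
#' @return Integer `N >= 1`.
#' @export
ransac_iterations <- function(p_success = 0.99, outlier_rate = 0.5,
                              sample_size = 2L) {
  if (p_success <= 0 || p_success >= 1)
    stopf("p_success must lie in (0, 1)", class = "fundusreg_bad_input")
  if (outlier_rate < 0 || outlier_rate >= 1)
    stopf("outlier_rate must lie in [0, 1)", class = "fundusreg_bad_input")
  if (outlier_rate == 0) return(1L)
  w <- (1 - outlier_rate)^sample_size
  as.integer(ceiling(log(1 - p_success) / log(1 - w)))
}

#' RANSAC configuration
#'
#' @param p_success confidence that at least one sample is outlier-free.
#' @param inlier_tol reprojection error (px) below which a match counts as
#'   an inlier; default 5 at working scale.
#' @param min_sample_dist minimum pairwise distance (px) between the source
#'   points of a random sample; spreads samples to curb the leverage of
#'   landmark localization error. Default 50 at working scale.
#' @param max_iter hard cap on iterations; the effective count adapts to
#'   the best inlier ratio found so far via [ransac_iterations()].
#' @param seed integer seed controlling all sampling.
#' @return List of class `ransac_config`.
#' @export
ransac_config <- function(p_success = 0.99, inlier_tol = 5,
                          min_sample_dist = 50, max_iter = 10000L,
                          seed = 1L) {
  structure(list(p_success = p_success, inlier_tol = inlier_tol,
                 min_sample_dist = min_sample_dist,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "ransac_config")
}

#' Robust transform estimation by distance-constrained RANSAC
#'
#' Repeatedly draws minimal samples of matches whose source points are
#' pairwise at least `min_sample_dist` apart (rejection sampling with
#' bounded retries), fits the minimal model, and counts matches with
#' reprojection error at most `inlier_tol` as inliers. The best consensus
#' set (ties broken by lower mean reprojection error) is refit by least
#' squares. The iteration budget adapts to the best inlier ratio via the
#' standard confidence formula, capped at `cfg$max_iter`. Deterministic for
#' a fixed `cfg$seed`.
#'
#' @param matches a `match_set`.
#' @param kps_source,kps_target keypoint tables with columns `x`, `y`
#'   indexed by `matches$source` / `matches$target`.
#' @param kind `"similarity"` or `"affine"`.
#' @param cfg a [ransac_config()].
#' @return Object of class `registration_result`: list with `model`,
#'   `inliers` (subset of `matches`), `n_candidates`, `converged`, and
#'   `diagnostic` when not converged.
#' @export
ransac_fit <- function(matches, kps_source, kps_target,
                       kind = c("similarity", "affine"),
                       cfg = ransac_config()) {
  kind <- match.arg(kind)
  m_min <- if (kind == "similarity") 2L else 3L
  src <- cbind(kps_source$x[matches$source], kps_source$y[matches$source])
  dst <- cbind(kps_target$x[matches$target], kps_target$y[matches$target])
  n <- nrow(src)
  not_conv <- function(msg) {
    structure(list(model = NULL, inliers = matches[0, , drop = FALSE],
                   n_candidates = n, converged = FALSE, diagnostic = msg),
              class = "registration_result")
  }
  if (is.null(n) || n < m_min)
    return(not_conv(sprintf("need >= %d matches, got %d", m_min, n)))

  fitter <- if (kind == "similarity") fit_similarity else fit_affine
  best_idx <- NULL; best_count <- -1L; best_mean <- Inf
  with_seed(cfg$seed, {
    n_target <- cfg$max_iter
    it <- 0L
    min_d2 <- cfg$min_sample_dist^2
    while (it < n_target) {
      it <- it + 1L
      samp <- NULL
      for (try in seq_len(100L)) {
        cand <- sample.int(n, m_min)
        ok <- TRUE
        if (m_min > 1L) {
          dd <- stats::dist(src[cand, , drop = FALSE])^2
          ok <- all(dd >= min_d2)
        }
        if (ok) { samp <- cand; break }
      }
      if (is.null(samp)) next
      model <- tryCatch(fitter(src[samp, , drop = FALSE],
                               dst[samp, , drop = FALSE]),
                        error = function(e) NULL)
      if (is.null(model)) next
      proj <- apply_transform(model, src)
      err <- sqrt(rowSums((proj - dst)^2))
      inl <- which(err <= cfg$inlier_tol)
      cnt <- length(inl)
      if (cnt > best_count ||
          (cnt == best_count && cnt > 0L && mean(err[inl]) < best_mean)) {
        best_idx <- inl; best_count <- cnt
        best_mean <- if (cnt > 0L) mean(err[inl]) else Inf
        if (cnt >= m_min) {
          v_hat <- 1 - cnt / n
          n_target <- min(cfg$max_iter,
                          ransac_iterations(cfg$p_success, v_hat, m_min))
        }
      }
    }
  })
  if (is.null(best_idx) || best_count < m_min)
    return(not_conv("no sample satisfied the distance constraint with enough inliers"))
  model <- tryCatch(fitter(src[best_idx, , drop = FALSE],
                           dst[best_idx, , drop = FALSE]),
                    error = function(e) NULL)
  if (is.null(model)) return(not_conv("degenerate inlier set at refit"))
  structure(list(model = model,
                 inliers = {
                   out <- matches[best_idx, , drop = FALSE]
                   rownames(out) <- NULL
                   out
                 },
                 n_candidates = n, converged = TRUE, diagnostic = NULL),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<registration_result> %s, %d/%d inliers\n",
                x$model$kind, nrow(x$inliers), x$n_candidates))
  } else {
    cat(sprintf("<registration_result> not converged: %s\n", x$diagnostic))
  }
  invisible(x)
}

#' Serialize / restore a transform model as JSON
#'
#' Row-major 3x3 matrix acting on homogeneous column vectors `(x, y, 1)`,
#' 1-based pixel coordinates, `target = T %*% source`.
#'
#' @param model a `transform_model`.
#' @param path file path.
#' @return `path` invisibly; `read_transform_model` returns the model.
#' @export
write_transform_model <- function(model, path) {
  jsonlite::write_json(
    list(kind = model$kind,
         matrix = lapply(1:3, function(i) model$T[i, ])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_model
#' @export
read_transform_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  T <- if (is.matrix(x$matrix)) x$matrix else do.call(rbind, x$matrix)
  transform_model(T, x$kind)
}

#' Warp the source image into the target frame
#'
#' The output canvas is the bounding box of the target frame united with
#' the transformed source corners, so nothing is cropped. Intensities are
#' resampled by inverse mapping with bilinear interpolation; the FOV mask
#' is warped with nearest-neighbour lookup.
#'
#' @param src a [fundus_image()].
#' @param model a converged `transform_model` mapping source to target
#'   coordinates.
#' @param target_dim `c(height, width)` of the target frame.
#' @return List with `rgb` (canvas array), `mask` (logical warped FOV),
#'   and `offset`, the (x, y) of the canvas origin in target coordinates
#'   (pixel (1,1) of the canvas sits at `offset` in the target frame).
#' @export
warp_source <- function(src, model, target_dim = dim(src$fov_mask)) {
  h_t <- target_dim[1L]; w_t <- target_dim[2L]
  h_s <- nrow(src$fov_mask); w_s <- ncol(src$fov_mask)
  corners <- apply_transform(model, rbind(c(1, 1), c(w_s, 1),
                                          c(1, h_s), c(w_s, h_s)))
  x0 <- floor(min(1, corners[, 1L])); x1 <- ceiling(max(w_t, corners[, 1L]))
  y0 <- floor(min(1, corners[, 2L])); y1 <- ceiling(max(h_t, corners[, 2L]))
  wc <- as.integer(x1 - x0 + 1L); hc <- as.integer(y1 - y0 + 1L)
  xt <- rep(seq_len(wc) + x0 - 1, each = hc)
  yt <- rep(seq_len(hc) + y0 - 1, times = wc)
  Tinv <- solve(model$T)
  ps <- cbind(xt, yt, 1) %*% t(Tinv)
  xs <- ps[, 1L]; ys <- ps[, 2L]
  rgb <- array(0, c(hc, wc, 3L))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(bilinear_sample(src$rgb[, , ch], xs, ys), hc, wc)
  xn <- round(xs); yn <- round(ys)
  okm <- xn >= 1 & xn <= w_s & yn >= 1 & yn <= h_s
  mv <- logical(length(xs))
  mv[okm] <- src$fov_mask[cbind(yn[okm], xn[okm])]
  mask <- matrix(mv, hc, wc)
  list(rgb = rgb, mask = mask, offset = c(x = x0, y = y0))
}
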