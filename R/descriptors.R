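#' Gradient-orientation (HOG) descriptor at a keypoint
#'
#' Describes the 16 x 16 patch around a keypoint with the classic SIFT-style
#' layout: the patch is standardized to zero mean and unit variance (so the
#' descriptor is invariant to gain and offset of the local illumination),
#' gradients are taken by centred differences (edge-replicated at the patch
#' border), and each of the sixteen non-overlapping 4 x 4 cells contributes
#' an 8-bin histogram of gradient magnitudes by orientation (45-degree bins
#' counter-clockwise from 0 = +x, hard assignment). The 128-vector is
#' L2-normalized, clipped at 0.2 and renormalized. Patches are taken with
#' the keypoint at offset (8, 8) within the window, i.e. rows
#' `y - 8 .. y + 7` and columns `x - 8 .. x + 7`. No dominant-orientation
#' assignment is made: fundus pairs exhibit only small rotations.
#'
#' @param e an `enhanced_image`.
#' @param pts a `keypoint_set` or data.frame with integer columns `x`, `y`.
#' @return Object of class `descriptor_set`: list with `vectors` (k x 128
#'   matrix), `keypoints` (the rows of `pts` whose window fits inside the
#'   image) and `valid` (logical; `FALSE` flags all-zero descriptors from
#'   constant patches, which are excluded from matching).
#' @export
compute_descriptors <- function(e, pts) {
  g <- e$gray
  h <- nrow(g); w <- ncol(g)
  inside <- pts$x - 8L >= 1L & pts$x + 7L <= w &
    pts$y - 8L >= 1L & pts$y + 7L <= h
  pts <- pts[inside, , drop = FALSE]
  rownames(pts) <- NULL
  k <- nrow(pts)
  vec <- matrix(0, k, 128L)
  valid <- logical(k)
  for (i in seq_len(k)) {
    patch <- g[(pts$y[i] - 8L):(pts$y[i] + 7L),
               (pts$x[i] - 8L):(pts$x[i] + 7L)]
    d <- hog_patch(patch)
    if (!is.null(d)) {
      vec[i, ] <- d
      valid[i] <- TRUE
    }
  }
  structure(list(vectors = vec, keypoints = pts, valid = valid),
            class = "descriptor_set")
}

# 128-dim HOG of one 16x16 patch; NULL for a constant patch.
hog_patch <- function(patch) {
  s <- stats::sd(patch)
  if (s == 0) return(NULL)
  p <- (patch - mean(patch)) / s
  pad <- rbind(p[1L, ], p, p[16L, ])
  pad <- cbind(pad[, 1L], pad, pad[, 16L])
  gx <- (pad[2:17, 3:18] - pad[2:17, 1:16]) / 2
  gy <- (pad[3:18, 2:17] - pad[1:16, 2:17]) / 2
  mag <- sqrt(gx^2 + gy^2)
  # counter-clockwise angles with y pointing down on screen: negate gy
  ang <- atan2(-gy, gx) %% (2 * pi)
  bin <- pmin(floor(ang / (pi / 4)), 7)
  desc <- numeric(128L)
  for (cy in 0:3) for (cx in 0:3) {
    ys <- (cy * 4 + 1):(cy * 4 + 4)
    xs <- (cx * 4 + 1):(cx * 4 + 4)
    hist8 <- vapply(0:7, function(b) sum(mag[ys, xs][bin[ys, xs] == b]),
                    numeric(1))
    desc[(cy * 4 + cx) * 8 + 1:8] <- hist8
  }
  nrm <- sqrt(sum(desc^2))
  if (nrm == 0) return(NULL)
  desc <- pmin(desc / nrm, 0.2)
  desc / sqrt(sum(desc^2))
}

#' One-directional second-nearest-neighbour matching
#'
#' For each descriptor in `A`, finds its nearest and second-nearest
#' neighbours in `B` by Euclidean distance. With `mode = "ratio"` the match
#' is kept when `d1/d2 <= threshold` (distinctiveness test); with
#' `mode = "magnitude"` when `d1 <= threshold * ||b1||`, an absolute
#' criterion relative to the magnitude of the most similar vector (for
#' unit-norm descriptors this is an absolute distance threshold; 0.2 is
#' the published choice under that reading). Candidates without a second
#' neighbour (`|B| < 2`) are rejected, as are flagged all-zero descriptors
#' on either side. Distance ties break toward the lower index.
#'
#' The default ratio of 0.9 is deliberately permissive: bifurcation
#' descriptors on fundus images are few and weakly distinctive, and the
#' cross-check plus RANSAC stages downstream supply the selectivity a
#' stricter ratio would enforce here at the cost of discarding most true
#' correspondences.
#'
#' @param A,B `descriptor_set` objects (source and target).
#' @param threshold acceptance threshold; default 0.9.
#' @param mode `"ratio"` (default) or `"magnitude"`.
#' @return Object of class `match_set`: data.frame with columns `source`,
#'   `target` (row indices into the keypoint tables) and `distance`, plus a
#'   `direction` attribute.
#' @export
match_one_direction <- function(A, B, threshold = 0.9, mode = c("ratio", "magnitude")) {
  mode <- match.arg(mode)
  if (threshold <= 0)
    stopf("threshold must be positive", class = "fundusreg_bad_input")
  ia <- which(A$valid); ib <- which(B$valid)
  empty <- structure(data.frame(source = integer(), target = integer(),
                                distance = numeric()),
                     direction = "forward",
                     class = c("match_set", "data.frame"))
  if (length(ia) == 0L || length(ib) < 2L) return(empty)
  va <- A$vectors[ia, , drop = FALSE]
  vb <- B$vectors[ib, , drop = FALSE]
  # squared Euclidean distances via the Gram expansion
  d2 <- outer(rowSums(va^2), rowSums(vb^2), "+") - 2 * tcrossprod(va, vb)
  d2 <- pmax(d2, 0)
  rows <- lapply(seq_along(ia), function(r) {
    ord <- order(d2[r, ], seq_along(ib))
    d1 <- sqrt(d2[r, ord[1L]]); dd2 <- sqrt(d2[r, ord[2L]])
    ok <- if (mode == "ratio") {
      dd2 > 0 && d1 / dd2 <= threshold # d2 = 0 means ambiguous duplicates
    } else {
      nb <- sqrt(sum(vb[ord[1L], ]^2))
      d1 <= threshold * nb
    }
    if (ok) data.frame(source = ia[r], target = ib[ord[1L]], distance = d1)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  structure(out, direction = "forward", class = c("match_set", "data.frame"))
}

#' Cross-check two directional match sets
#'
#' Keeps the correspondences found in both matching directions: `(i, j)`
#' survives when `ab` maps `i -> j` and `ba` maps `j -> i`. The result is
#' symmetric and one-to-one.
#'
#' @param ab source-to-target `match_set`.
#' @param ba target-to-source `match_set` (its `source` column indexes the
#'   target image).
#' @return A `match_set` with direction `"symmetric"`.
#' @export
cross_check <- function(ab, ba) {
  key_ab <- paste(ab$source, ab$target)
  key_ba <- paste(ba$target, ba$source)
  out <- ab[key_ab %in% key_ba, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, direction = "symmetric", class = c("match_set", "data.frame"))
}

#' Match two descriptor sets with cross-checking
#'
#' Convenience wrapper running [match_one_direction()] both ways and
#' intersecting with [cross_check()].
#'
#' @inheritParams match_one_direction
#' @return A symmetric `match_set`.
#' @export
match_descriptors <- function(A, B, threshold = 0.9, mode = "ratio") {
  ab <- match_one_direction(A, B, threshold, mode)
  ba <- match_one_direction(B, A, threshold, mode)
  cross_check(ab, ba)
}

#' Write descriptors / matches as CSV
#'
#' `write_descriptors` emits one row per keypoint: `x`, `y` and the 128
#' descriptor values. `write_matches` emits matched coordinate pairs:
#' `xs, ys, xt, yt, distance`.
#'
#' @param d a `descriptor_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(d, path) {
  tab <- cbind(d$keypoints[, c("x", "y")], as.data.frame(d$vectors))
  names(tab) <- c("x", "y", paste0("v", seq_len(128L)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @param matches a `match_set`.
#' @param kA,kB keypoint tables of source and target.
#' @export
write_matches <- function(matches, kA, kB, path) {
  tab <- data.frame(xs = kA$x[matches$source], ys = kA$y[matches$source],
                    xt = kB$x[matches$target], yt = kB$y[matches$target],
                    distance = matches$distance)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
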