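#' Zhang-Suen thinning of a binary vessel mask
#'
#' Iteratively peels the mask down to a one-pixel-wide skeleton while
#' preserving 8-connectivity. With neighbours `p2..p9` clockwise from north,
#' sub-pass 1 deletes a foreground pixel when its neighbour count `B` lies
#' in 2..6, its 0-to-1 transition count `A` equals 1, and
#' `p2*p4*p6 = 0`, `p4*p6*p8 = 0`; sub-pass 2 swaps the last two conditions
#' for `p2*p4*p8 = 0`, `p2*p6*p8 = 0`. Deletions within a sub-pass are
#' simultaneous; passes repeat until no pixel changes.
#'
#' @param v a `vessel_mask` or a logical/0-1 matrix.
#' @return Object of class `skeleton`: list with `mask` (logical `H x W`).
#' @export
zhang_suen_thin <- function(v) {
  m <- if (inherits(v, "vessel_mask")) v$mask else v
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      del <- zs_deletable(m, pass)
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(mask = m), class = "skeleton")
}

# Simultaneous deletability map for one Zhang-Suen sub-pass.
zs_deletable <- function(m, pass) {
  p2 <- shift_mat(m, 1, 0)   # north neighbour value at each pixel
  p3 <- shift_mat(m, 1, -1)  # north-east
  p4 <- shift_mat(m, 0, -1)  # east
  p5 <- shift_mat(m, -1, -1) # south-east
  p6 <- shift_mat(m, -1, 0)  # south
  p7 <- shift_mat(m, -1, 1)  # south-west
  p8 <- shift_mat(m, 0, 1)   # west
  p9 <- shift_mat(m, 1, 1)   # north-west
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  A <- (p2 < p3) + (p3 < p4) + (p4 < p5) + (p5 < p6) +
    (p6 < p7) + (p7 < p8) + (p8 < p9) + (p9 < p2)
  if (pass == 1L) {
    c3 <- p2 * p4 * p6 == 0
    c4 <- p4 * p6 * p8 == 0
  } else {
    c3 <- p2 * p4 * p8 == 0
    c4 <- p2 * p6 * p8 == 0
  }
  m & B >= 2 & B <= 6 & A == 1 & c3 & c4
}

#' Default hit-or-miss structuring element bank for bifurcations
#'
#' Nine 3x3 ternary stencils describing junction patterns on a one-pixel
#' skeleton: the four rotations of the axis-aligned T junction (branches
#' along three of the four axes), the four rotations of the diagonal Y
#' junction, and the + cross. Cell values: `1` = must be skeleton (B1),
#' `0` = must be background (B2), `-1` = don't care. The centre cell is
#' always part of B1 and the stencils are mutually exclusive on the centre
#' pixel.
#'
#' The diagonal Y is encoded as two perpendicular axis branches plus the
#' opposing diagonal branch (e.g. west, south and north-east): thinning
#' prefers axis-connected branches, so a Y junction tilted 45 degrees
#' presents exactly this neighbourhood on the skeleton, while a
#' two-adjacent-diagonals pattern is rare.
#'
#' @return List of class `structuring_bank`; each element has `name`, `b1`
#'   and `b2` logical 3x3 matrices and `stencil` (the ternary matrix).
#' @export
build_structuring_bank <- function() {
  t0 <- matrix(c(-1, 0, -1,
                 1, 1, 1,
                 -1, 1, -1), 3, 3, byrow = TRUE)
  y0 <- matrix(c(-1, 0, 1,
                 1, 1, 0,
                 -1, 1, -1), 3, 3, byrow = TRUE)
  cross <- matrix(c(-1, 1, -1,
                    1, 1, 1,
                    -1, 1, -1), 3, 3, byrow = TRUE)
  rot90 <- function(s) t(s)[, 3:1] # one clockwise quarter turn
  stencils <- list(T0 = t0)
  s <- t0
  for (k in 1:3) {
    s <- rot90(s)
    stencils[[paste0("T", 90 * k)]] <- s
  }
  stencils$Y0 <- y0
  s <- y0
  for (k in 1:3) {
    s <- rot90(s)
    stencils[[paste0("Y", 90 * k)]] <- s
  }
  stencils$X0 <- cross
  bank <- lapply(names(stencils), function(nm) {
    s <- stencils[[nm]]
    list(name = nm, stencil = s, b1 = s == 1, b2 = s == 0)
  })
  structure(bank, class = "structuring_bank")
}

#' Write / read a structuring bank as JSON
#'
#' Stencils are stored as 3x3 integer matrices with values 1 (skeleton, B1),
#' 0 (background, B2) and -1 (don't care).
#'
#' @param bank a `structuring_bank`.
#' @param path file path.
#' @return `path` invisibly; `read_structuring_bank` returns the bank.
#' @export
write_structuring_bank <- function(bank, path) {
  jsonlite::write_json(
    lapply(bank, function(p) list(name = p$name, stencil = p$stencil)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_structuring_bank
#' @export
read_structuring_bank <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bank <- lapply(seq_len(nrow(raw)), function(i) {
    s <- matrix(unlist(raw$stencil[[i]]), 3, 3)
    list(name = raw$name[i], stencil = s, b1 = s == 1, b2 = s == 0)
  })
  structure(bank, class = "structuring_bank")
}

# Hit-or-miss match map of one stencil over skeleton `m`; border pixels,
# whose 3x3 neighbourhood leaves the image, are never flagged.
hit_or_miss <- function(m, pair) {
  h <- nrow(m); w <- ncol(m)
  hit <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    i <- dy + 2L; j <- dx + 2L
    if (pair$b1[i, j]) {
      hit <- hit & shift_mat(m, -dy, -dx, fill = FALSE)
    } else if (pair$b2[i, j]) {
      hit <- hit & !shift_mat(m, -dy, -dx, fill = TRUE)
    }
  }
  hit[c(1L, h), ] <- FALSE
  hit[, c(1L, w)] <- FALSE
  hit
}

#' Detect vessel bifurcations on a skeleton by hit-or-miss matching
#'
#' Flags every skeleton pixel whose 3x3 neighbourhood matches one of the
#' bank's junction stencils (erosion of the skeleton by B1 intersected with
#' erosion of its complement by B2). Detections closer than `dedupe_radius`
#' are merged to their centroid snapped to the nearest skeleton pixel.
#' Optionally, points within `rim_margin` pixels of the FOV boundary are
#' discarded: the rim produces spurious junction-like artefacts.
#'
#' @param s a `skeleton`.
#' @param bank a `structuring_bank`; default [build_structuring_bank()].
#' @param dedupe_radius merge radius in pixels (default 5).
#' @param fov_mask optional logical matrix enabling rim filtering.
#' @param rim_margin distance to the FOV edge below which points are
#'   dropped (default 9, the top-hat radius).
#' @return Object of class `keypoint_set`: a data.frame with columns `x`,
#'   `y` (integer pixel coordinates on the skeleton) and `pattern` (name of
#'   the matching stencil; merged clusters keep the first member's pattern).
#' @export
detect_bifurcations <- function(s, bank = build_structuring_bank(),
                                dedupe_radius = 5, fov_mask = NULL,
                                rim_margin = 9) {
  m <- s$mask
  flagged <- NULL
  for (pair in bank) {
    hm <- hit_or_miss(m, pair)
    if (any(hm)) {
      idx <- which(hm, arr.ind = TRUE)
      flagged <- rbind(flagged,
                       data.frame(x = idx[, 2L], y = idx[, 1L],
                                  pattern = pair$name))
    }
  }
  if (is.null(flagged)) {
    return(structure(data.frame(x = integer(), y = integer(),
                                pattern = character()),
                     class = c("keypoint_set", "data.frame")))
  }
  # stencils are mutually exclusive on the centre pixel, so no pixel repeats
  pts <- merge_close_points(flagged, dedupe_radius, m)
  if (!is.null(fov_mask)) {
    dm <- from_ebimage(EBImage::distmap(as_ebimage(fov_mask)))
    keep <- dm[cbind(pts$y, pts$x)] > rim_margin
    pts <- pts[keep, , drop = FALSE]
    rownames(pts) <- NULL
  }
  structure(pts, class = c("keypoint_set", "data.frame"))
}

# Single-linkage clustering of points within `radius`; each cluster collapses
# to its centroid snapped to the nearest skeleton pixel.
merge_close_points <- function(pts, radius, skel) {
  k <- nrow(pts)
  if (k <= 1L || radius <= 0) return(pts)
  d <- as.matrix(stats::dist(pts[, c("x", "y")]))
  comp <- seq_len(k)
  repeat {
    moved <- FALSE
    for (i in seq_len(k)) {
      near <- which(d[i, ] <= radius)
      root <- min(comp[near])
      if (any(comp[near] != root)) {
        comp[comp %in% comp[near]] <- root
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  skel_idx <- which(skel, arr.ind = TRUE)
  out <- lapply(unique(comp), function(cl) {
    members <- pts[comp == cl, , drop = FALSE]
    cx <- mean(members$x); cy <- mean(members$y)
    j <- which.min((skel_idx[, 2L] - cx)^2 + (skel_idx[, 1L] - cy)^2)
    data.frame(x = skel_idx[j, 2L], y = skel_idx[j, 1L],
               pattern = members$pattern[1L])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a keypoint set as CSV (columns x, y, pattern)
#' @param kp a `keypoint_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(kp, path) {
  utils::write.csv(as.data.frame(kp), path, row.names = FALSE)
  invisible(path)
}
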