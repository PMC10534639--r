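#' Laplacian pyramid of an image
#'
#' Level `k` (0-based octave) holds the difference between Gaussian level
#' `k` and the upsampled Gaussian level `k + 1`; the final level is the
#' lowest-resolution Gaussian image itself, so collapsing the pyramid
#' (upsample the last level, add the previous difference, repeat)
#' reconstructs the input exactly in floating point. Downsampling is a
#' Gaussian blur followed by decimation by 2 (dimensions round up);
#' upsampling is bilinear resizing back to the dimensions of the level
#' above.
#'
#' @param img numeric matrix (one channel).
#' @param octaves number of pyramid levels, >= 1.
#' @param sigma blur applied before decimation; default 1.
#' @return List of `octaves` matrices, class `laplacian_pyramid`.
#' @export
build_laplacian_pyramid <- function(img, octaves = 3L, sigma = 1) {
  img <- as.matrix(img)
  if (octaves < 1L) stopf("octaves must be >= 1", class = "fundusreg_bad_input")
  if (min(dim(img)) < 2^octaves)
    stopf("image of %d x %d is too small for %d octaves",
          nrow(img), ncol(img), octaves, class = "fundusreg_bad_input")
  gp <- gaussian_pyramid(img, octaves, sigma)
  lev <- vector("list", octaves)
  if (octaves > 1L) {
    for (k in seq_len(octaves - 1L)) {
      up <- upsample_to(gp[[k + 1L]], dim(gp[[k]]))
      lev[[k]] <- gp[[k]] - up
    }
  }
  lev[[octaves]] <- gp[[octaves]]
  structure(lev, class = "laplacian_pyramid")
}

gaussian_pyramid <- function(img, octaves, sigma = 1) {
  gp <- vector("list", octaves)
  gp[[1L]] <- img
  if (octaves > 1L) {
    for (k in 2:octaves) gp[[k]] <- downsample2(gp[[k - 1L]], sigma)
  }
  gp
}

downsample2 <- function(m, sigma = 1) {
  bl <- from_ebimage(EBImage::gblur(as_ebimage(m), sigma = sigma))
  bl[seq(1L, nrow(bl), by = 2L), seq(1L, ncol(bl), by = 2L), drop = FALSE]
}

upsample_to <- function(m, target_dim) {
  from_ebimage(EBImage::resize(as_ebimage(m), w = target_dim[2L],
                               h = target_dim[1L], filter = "bilinear"))
}

#' Collapse a Laplacian pyramid back to an image
#'
#' @param pyr a `laplacian_pyramid`.
#' @return Numeric matrix with the dimensions of level 1.
#' @export
collapse_pyramid <- function(pyr) {
  k <- length(pyr)
  acc <- pyr[[k]]
  if (k > 1L) {
    for (j in (k - 1L):1L) acc <- pyr[[j]] + upsample_to(acc, dim(pyr[[j]]))
  }
  acc
}

#' Mask-normalized Laplacian-pyramid blending of two images
#'
#' Fuses two overlapping images without a visible seam: at every pyramid
#' level the two Laplacians are combined as
#' `(L_A * M_A + L_B * M_B) / (M_A + M_B)` wherever the mask sum is
#' positive (0 elsewhere), with the masks carried down the pyramid by the
#' same blurred downsampling — binary at full resolution, fractional below,
#' which is what spreads the transition and preserves exposure without
#' overflow. The fused pyramid is collapsed, clipped to 0--255, and pixels
#' outside both input masks are set to 0. Colour images are blended per
#' channel.
#'
#' @param imgA,imgB numeric matrices or `H x W x 3` arrays (0--255).
#' @param maskA,maskB nonnegative weight matrices (typically 0/1 FOV masks).
#' @param octaves pyramid depth; default 3.
#' @return Blended image, same shape as the inputs.
#' @export
blend_pair <- function(imgA, maskA, imgB, maskB, octaves = 3L) {
  if (length(dim(imgA)) == 3L) {
    out <- array(0, dim(imgA))
    for (ch in seq_len(dim(imgA)[3L]))
      out[, , ch] <- blend_pair(imgA[, , ch], maskA, imgB[, , ch], maskB,
                                octaves)
    return(out)
  }
  stopifnot(all(dim(imgA) == dim(imgB)), all(dim(imgA) == dim(maskA)),
            all(dim(imgA) == dim(maskB)))
  maskA <- maskA * 1; maskB <- maskB * 1
  pa <- build_laplacian_pyramid(imgA, octaves)
  pb <- build_laplacian_pyramid(imgB, octaves)
  ma <- gaussian_pyramid(maskA, octaves)
  mb <- gaussian_pyramid(maskB, octaves)
  fused <- vector("list", octaves)
  for (k in seq_len(octaves)) {
    den <- ma[[k]] + mb[[k]]
    num <- pa[[k]] * ma[[k]] + pb[[k]] * mb[[k]]
    f <- num
    pos <- den > 0
    f[pos] <- num[pos] / den[pos]
    f[!pos] <- 0
    fused[[k]] <- f
  }
  out <- collapse_pyramid(structure(fused, class = "laplacian_pyramid"))
  out <- clamp(out, 0, 255)
  out[!(maskA > 0 | maskB > 0)] <- 0
  out
}

#' Checkerboard overlay diagnostic for a registered pair
#'
#' Alternates square tiles from the two images so residual misalignment is
#' visible as broken vessels at tile borders.
#'
#' @param imgA,imgB matrices or `H x W x 3` arrays of equal size.
#' @param tile tile side in pixels.
#' @return Image of the same shape.
#' @export
checkerboard_overlay <- function(imgA, imgB, tile = 64L) {
  d <- dim(imgA)[1:2]
  ys <- (seq_len(d[1L]) - 1L) %/% tile
  xs <- (seq_len(d[2L]) - 1L) %/% tile
  board <- outer(ys, xs, "+") %% 2L == 0L
  if (length(dim(imgA)) == 3L) {
    out <- imgB
    for (ch in seq_len(dim(imgA)[3L])) {
      p <- out[, , ch]; q <- imgA[, , ch]
      p[board] <- q[board]
      out[, , ch] <- p
    }
    out
  } else {
    out <- imgB
    out[board] <- imgA[board]
    out
  }
}
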