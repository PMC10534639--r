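# Internal helpers shared across the pipeline. Images are plain numeric
# matrices indexed [row = y, col = x]; points are (x, y), 1-based.

# Convert an image matrix [y, x] to an EBImage Image (which is [x, y]).
as_ebimage <- function(m) EBImage::Image(t(m))

from_ebimage <- function(img) t(EBImage::imageData(img))

#' @noRd
stopf <- function(fmt, ..., class = "fundusreg_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shift a matrix by (dy, dx), padding with `fill`.
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Integral-image sum of `m` over n x n windows centred at each pixel,
# clipped at the borders (out-of-bounds cells contribute nothing).
box_sum <- function(m, n) {
  r <- (n - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  y1 <- pmax(1L, seq_len(h) - r); y2 <- pmin(h, seq_len(h) + r)
  x1 <- pmax(1L, seq_len(w) - r); x2 <- pmin(w, seq_len(w) + r)
  S[y2 + 1L, x2 + 1L, drop = FALSE] - S[y1, x2 + 1L, drop = FALSE] -
    S[y2 + 1L, x1, drop = FALSE] + S[y1, x1, drop = FALSE]
}

# Number of in-bounds cells of an n x n window centred at each pixel.
box_count <- function(h, w, n) {
  r <- (n - 1L) %/% 2L
  ny <- pmin(h, seq_len(h) + r) - pmax(1L, seq_len(h) - r) + 1L
  nx <- pmin(w, seq_len(w) + r) - pmax(1L, seq_len(w) - r) + 1L
  outer(ny, nx)
}

# Bilinear sample of matrix m at fractional (x, y); out-of-bounds -> fill.
bilinear_sample <- function(m, x, y, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 <= w - 1 & y0 <= h - 1
  # points exactly on the last row/col sample degenerately but validly
  edge <- (x0 == w & fx == 0 & y0 >= 1 & y0 <= h) |
    (y0 == h & fy == 0 & x0 >= 1 & x0 <= w)
  ok <- ok | edge
  x0c <- clamp(x0, 1, w - 1); y0c <- clamp(y0, 1, h - 1)
  i00 <- cbind(y0c, x0c); i01 <- cbind(y0c, x0c + 1)
  i10 <- cbind(y0c + 1, x0c); i11 <- cbind(y0c + 1, x0c + 1)
  v <- (1 - fy) * ((1 - fx) * m[i00] + fx * m[i01]) +
    fy * ((1 - fx) * m[i10] + fx * m[i11])
  v[!ok] <- fill
  v
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
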