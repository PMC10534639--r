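#' Cumulative distribution of intensities inside the field of view
#'
#' @param e an `enhanced_image` from [preprocess_fundus()].
#' @return List with `cdf`, a 256-vector where `cdf[l + 1]` is the fraction
#'   of in-FOV pixels with intensity `<= l`, and `delta_f`, the CDF span
#'   `cdf[255] - cdf[0]` (difference between the cumulative probability of
#'   the highest and lowest intensity levels).
#' @export
compute_cdf <- function(e) {
  vals <- as.integer(e$gray[e$fov_mask])
  if (length(vals) == 0L)
    stopf("no pixels inside fov_mask", class = "fundusreg_empty_fov")
  counts <- tabulate(vals + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(vals)
  list(cdf = cdf, delta_f = cdf[256L] - cdf[1L])
}

#' Global background/vessel intensity threshold from the CDF
#'
#' Picks the intensity level at which the CDF curve is farthest from the
#' straight line joining its endpoints on the unit square: the level
#' maximizing `|f(l) + delta_f * (1 - l/255) - 1| / sqrt(1 + delta_f^2)`.
#' Intensity is normalized to [0, 1] inside the distance so both axes of
#' the point-to-line distance are dimensionless. Ties break toward the
#' smaller level.
#'
#' @param cdf 256-vector as produced by [compute_cdf()].
#' @param delta_f CDF span.
#' @return Integer threshold `tau_i` in 0--255. Pixels with intensity below
#'   `tau_i` are treated as background by the windowed classifier.
#' @export
global_threshold <- function(cdf, delta_f) {
  stopifnot(length(cdf) == 256L)
  l <- 0:255
  d <- abs(cdf + delta_f * (1 - l / 255) - 1) / sqrt(1 + delta_f^2)
  l[which.max(d)]
}

#' Omnidirectional normalized gray-level co-occurrence matrix
#'
#' Accumulates one count for every ordered pair of 8-adjacent pixels that
#' both lie inside the FOV (distance d = 1, all eight directions, hence a
#' symmetric matrix), normalizes to a joint probability, and computes the
#' marginal means/SDs and the co-occurrence correlation
#' `corr = sum_{x,y} P[x,y] (x - mu_x)(y - mu_y) / (sigma_x sigma_y)`.
#'
#' @param e an `enhanced_image`.
#' @return Object of class `nglcm`: list with `P` (256 x 256), `mu_x`,
#'   `mu_y`, `sigma_x`, `sigma_y`, `corr`, `d = 1`.
#' @export
compute_nglcm <- function(e) {
  g <- e$gray
  fov <- e$fov_mask
  if (sum(fov) < 2L)
    stopf("need at least 2 in-FOV pixels", class = "fundusreg_bad_input")
  counts <- numeric(65536L)
  offsets <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                  c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  h <- nrow(g); w <- ncol(g)
  for (off in offsets) {
    dy <- off[1L]; dx <- off[2L]
    ys <- max(1L, 1L + dy):min(h, h + dy)
    xs <- max(1L, 1L + dx):min(w, w + dx)
    src <- cbind(rep(ys - dy, length(xs)), rep(xs - dx, each = length(ys)))
    dst <- cbind(rep(ys, length(xs)), rep(xs, each = length(ys)))
    keep <- fov[src] & fov[dst]
    idx <- as.integer(g[src][keep]) * 256L + as.integer(g[dst][keep]) + 1L
    tab <- tabulate(idx, nbins = 65536L)
    counts <- counts + tab
  }
  total <- sum(counts)
  if (total == 0)
    stopf("no adjacent in-FOV pixel pairs", class = "fundusreg_bad_input")
  P <- matrix(counts / total, 256L, 256L, byrow = TRUE)
  lev <- 0:255
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sigma_x <- sqrt(sum((lev - mu_x)^2 * px))
  sigma_y <- sqrt(sum((lev - mu_y)^2 * py))
  if (sigma_x * sigma_y == 0)
    stopf("constant image: co-occurrence correlation undefined",
          class = "fundusreg_constant_image")
  corr <- sum(P * outer(lev - mu_x, lev - mu_y)) / (sigma_x * sigma_y)
  structure(list(P = P, mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x,
                 sigma_y = sigma_y, corr = corr, d = 1L),
            class = "nglcm")
}

#' Probability of a background pixel neighbouring a background pixel
#'
#' Sums the co-occurrence probabilities of pixel pairs whose intensities are
#' both below the global threshold.
#'
#' @param g an `nglcm`.
#' @param tau_i global intensity threshold (0--256).
#' @return `p_bg` in [0, 1].
#' @export
background_cooccurrence <- function(g, tau_i) {
  stopifnot(inherits(g, "nglcm"))
  if (tau_i <= 0) return(0)
  k <- min(as.integer(tau_i), 256L)
  sum(g$P[seq_len(k), seq_len(k)])
}

#' Window count threshold for the pixel classifier
#'
#' `tau_sd = floor(p_bg * corr * n^2)`: the largest number of
#' background-intensity pixels tolerated in an `n x n` window before its
#' centre pixel is itself called background. A negative co-occurrence
#' correlation clamps to 0, since a negative pixel count is meaningless.
#'
#' @param p_bg background co-occurrence probability.
#' @param corr NGLCM correlation.
#' @param n odd window side length, >= 3.
#' @return Integer `tau_sd` in `0..n^2`.
#' @export
window_threshold <- function(p_bg, corr, n) {
  if (n < 3 || n %% 2 == 0)
    stopf("window size n must be odd and >= 3", class = "fundusreg_bad_input")
  floor(p_bg * max(corr, 0) * n^2)
}

#' Fit the coarse segmentation model of an enhanced image
#'
#' Convenience wrapper computing the CDF, the global threshold `tau_i`, the
#' NGLCM, `p_bg` and `tau_sd` in one pass.
#'
#' @param e an `enhanced_image`.
#' @param n odd window side length; default 7.
#' @return Object of class `segmentation_model`: list with `tau_i`,
#'   `delta_f`, `cdf`, `p_bg`, `corr`, `tau_sd`, `n`.
#' @export
fit_segmentation_model <- function(e, n = 7L) {
  cc <- compute_cdf(e)
  tau_i <- global_threshold(cc$cdf, cc$delta_f)
  g <- compute_nglcm(e)
  p_bg <- background_cooccurrence(g, tau_i)
  tau_sd <- window_threshold(p_bg, g$corr, n)
  structure(list(tau_i = tau_i, delta_f = cc$delta_f, cdf = cc$cdf,
                 p_bg = p_bg, corr = g$corr, tau_sd = tau_sd,
                 n = as.integer(n)),
            class = "segmentation_model")
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf(
    "<segmentation_model> tau_i=%d  p_bg=%.4f  corr=%.4f  tau_sd=%d  n=%d\n",
    x$tau_i, x$p_bg, x$corr, x$tau_sd, x$n))
  invisible(x)
}

#' Serialize / restore a segmentation model as JSON
#'
#' @param m a `segmentation_model`.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_segmentation_model` returns the model.
#' @export
write_segmentation_model <- function(m, path) {
  jsonlite::write_json(
    list(tau_i = m$tau_i, delta_f = m$delta_f, p_bg = m$p_bg,
         corr = m$corr, tau_sd = m$tau_sd, n = m$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_segmentation_model
#' @export
read_segmentation_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(tau_i = as.integer(x$tau_i), delta_f = x$delta_f, cdf = NULL,
                 p_bg = x$p_bg, corr = x$corr, tau_sd = as.integer(x$tau_sd),
                 n = as.integer(x$n)),
            class = "segmentation_model")
}

#' Coarse vessel segmentation by windowed background counting
#'
#' Classifies every in-FOV pixel of the preprocessed image: the pixel is
#' background when its `n x n` window contains more than `tau_sd` pixels of
#' background intensity (below `tau_i`), and vessel otherwise. Windows are
#' clipped at the image border; out-of-image and out-of-FOV pixels count as
#' background (conservative near the FOV rim). Pixels outside the FOV are
#' background.
#'
#' @param e an `enhanced_image`.
#' @param m a `segmentation_model` (see [fit_segmentation_model()]).
#' @return Object of class `vessel_mask`: list with `mask` (logical
#'   `H x W`), `fov_mask`, and `foreground_fraction`, the vessel fraction
#'   inside the FOV (the literature places the vascular tree at roughly
#'   10--15% of the fundus area).
#' @export
segment_vessels <- function(e, m) {
  stopifnot(inherits(e, "enhanced_image"), inherits(m, "segmentation_model"))
  g <- e$gray; fov <- e$fov_mask
  n <- m$n
  nonbg <- (g >= m$tau_i) & fov
  cnt_nonbg <- box_sum(nonbg * 1, n)
  bg_count <- n^2 - cnt_nonbg
  mask <- (bg_count <= m$tau_sd) & fov
  structure(list(mask = mask, fov_mask = fov,
                 foreground_fraction = sum(mask) / sum(fov)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %.1f%% of FOV is vessel\n",
              nrow(x$mask), ncol(x$mask), 100 * x$foreground_fraction))
  invisible(x)
}
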