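#' Generate a random branching vessel tree
#'
#' Builds a synthetic vascular tree as straight anti-aliasable segments:
#' `n_roots` trunks leave a small circle near the canvas centre at spread
#' angles and each segment splits into two children (branch angles drawn
#' uniformly from 20--50 degrees off the parent, lengths shrinking
#' geometrically) until `depth` levels exist. Every split point is recorded
#' as a true junction, giving `n_roots * (2^(depth - 1) - 1)` junctions.
#' Segment width tapers from `width0` px at the trunk to `width_min` px at
#' the leaves. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param canvas `c(height, width)` in pixels; default 768 x 768.
#' @param n_roots number of trunk vessels; default 5.
#' @param depth branching levels, >= 1; default 5.
#' @param root_length trunk segment length in px.
#' @param length_decay child/parent length ratio.
#' @param width0,width_min trunk and leaf widths in px.
#' @return Object of class `vessel_tree`: list with `segments` (data.frame
#'   `x0, y0, x1, y1, width, level`), `junctions` (data.frame `x, y`),
#'   `canvas`, and the generator parameters.
#' @export
generate_tree <- function(seed, canvas = c(768L, 768L), n_roots = 6L,
                          depth = 6L, root_length = 120, length_decay = 0.8,
                          width0 = 6, width_min = 2) {
  if (depth < 1L) stopf("depth must be >= 1", class = "fundusreg_bad_input")
  cy <- canvas[1L] / 2; cx <- canvas[2L] / 2
  widths <- if (depth == 1L) width0 else
    seq(width0, width_min, length.out = depth)
  segs <- list(); juncs <- list()
  with_seed(seed, {
    base_ang <- seq(0, 2 * pi, length.out = n_roots + 1L)[seq_len(n_roots)] +
      stats::runif(n_roots, -0.3, 0.3)
    grow <- function(x0, y0, ang, level) {
      len <- root_length * length_decay^(level - 1)
      x1 <- x0 + len * cos(ang); y1 <- y0 + len * sin(ang)
      segs[[length(segs) + 1L]] <<- data.frame(
        x0 = x0, y0 = y0, x1 = x1, y1 = y1,
        width = widths[level], level = level)
      if (level < depth) {
        juncs[[length(juncs) + 1L]] <<- data.frame(x = x1, y = y1)
        da <- stats::runif(2, 20, 50) * pi / 180
        grow(x1, y1, ang - da[1L], level + 1L)
        grow(x1, y1, ang + da[2L], level + 1L)
      }
    }
    for (i in seq_len(n_roots)) {
      r0 <- 40
      grow(cx + r0 * cos(base_ang[i]), cy + r0 * sin(base_ang[i]),
           base_ang[i], 1L)
    }
  })
  structure(list(
    segments = do.call(rbind, segs),
    junctions = if (length(juncs)) do.call(rbind, juncs)
                else data.frame(x = numeric(), y = numeric()),
    canvas = as.integer(canvas),
    params = list(seed = seed, n_roots = n_roots, depth = depth,
                  root_length = root_length, length_decay = length_decay,
                  width0 = width0, width_min = width_min)),
    class = "vessel_tree")
}

# Rasterize the tree: per-pixel vessel coverage in [0, 1] and the coverage
# of the 1-px central reflex line along each segment axis.
rasterize_tree <- function(tree) {
  h <- tree$canvas[1L]; w <- tree$canvas[2L]
  cov <- matrix(0, h, w); ref <- matrix(0, h, w)
  for (i in seq_len(nrow(tree$segments))) {
    s <- tree$segments[i, ]
    half <- s$width / 2
    x_lo <- max(1L, floor(min(s$x0, s$x1) - half - 1))
    x_hi <- min(w, ceiling(max(s$x0, s$x1) + half + 1))
    y_lo <- max(1L, floor(min(s$y0, s$y1) - half - 1))
    y_hi <- min(h, ceiling(max(s$y0, s$y1) + half + 1))
    if (x_lo > x_hi || y_lo > y_hi) next
    xs <- x_lo:x_hi; ys <- y_lo:y_hi
    px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
    dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
    len2 <- dx^2 + dy^2
    t <- clamp(((px - s$x0) * dx + (py - s$y0) * dy) / len2, 0, 1)
    d <- sqrt((px - (s$x0 + t * dx))^2 + (py - (s$y0 + t * dy))^2)
    ci <- clamp(half + 0.5 - d, 0, 1)
    ri <- clamp(1 - d, 0, 1)
    sub <- cbind(py, px)
    cov[sub] <- pmax(cov[sub], ci)
    if (s$width >= 4) ref[sub] <- pmax(ref[sub], ri)
  }
  list(cov = cov, reflex = ref)
}

#' Render a vessel tree as a colour fundus photograph
#'
#' Composes a dark frame with a circular field of view, a reddish
#' background with a smooth radial illumination falloff, vessels that are
#' darker than background in the green channel (so the inverted green
#' channel is vessel-bright), an optional bright central vessel reflex
#' stripe along wide vessels, and Gaussian pixel noise.
#'
#' @param tree a `vessel_tree`.
#' @param fov_radius FOV disc radius in px; default 350.
#' @param illumination_gradient relative brightness drop from FOV centre to
#'   rim (0 = flat); default 0.25.
#' @param noise_sigma Gaussian noise SD in intensity levels; default 0.
#' @param exposure_gain global intensity multiplier; default 1.
#' @param reflex draw the central vessel reflex; default `TRUE`.
#' @param seed seed for the noise stream; default 0.
#' @param id image label.
#' @return A [fundus_image()] whose `fov_mask` is the exact rendered disc.
#' @export
render_fundus <- function(tree, fov_radius = 350, illumination_gradient = 0.25,
                          noise_sigma = 0, exposure_gain = 1, reflex = TRUE,
                          seed = 0L, id = "synthetic") {
  h <- tree$canvas[1L]; w <- tree$canvas[2L]
  ras <- rasterize_tree(tree)
  cov <- ras$cov
  ref <- if (reflex) ras$reflex else 0 * ras$cov
  cy <- h / 2; cx <- w / 2
  r2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
  fov <- r2 <= fov_radius^2
  illum <- 1 - illumination_gradient * r2 / fov_radius^2
  base <- c(r = 190, g = 110, b = 45)
  vess <- c(r = 30, g = 60, b = 10)
  refl <- c(r = 10, g = 30, b = 5)
  rgb <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    plane <- base[ch] * illum - vess[ch] * cov + refl[ch] * ref * (cov > 0.5)
    plane <- plane * exposure_gain
    if (noise_sigma > 0) {
      plane <- plane + with_seed(seed + ch,
                                 matrix(stats::rnorm(h * w, 0, noise_sigma),
                                        h, w))
    }
    plane[!fov] <- 0
    rgb[, , ch] <- round(clamp(plane, 0, 255))
  }
  fundus_image(rgb, fov, id = id)
}

# Chord ("lens") overlap fraction of two discs with radii r1 <= r2 at
# centre distance d: intersection area / smaller disc area.
disc_overlap_fraction <- function(d, r1, r2) {
  if (r1 > r2) { tmp <- r1; r1 <- r2; r2 <- tmp }
  if (d >= r1 + r2) return(0)
  if (d <= r2 - r1) return(1)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  (a1 + a2 - a3) / (pi * r1^2)
}

#' Generate a registrable synthetic fundus pair with ground truth
#'
#' Plants a random similarity or affine transform (scale 0.95--1.05,
#' rotation within 10 degrees, shear up to 0.05 for affine) about the
#' canvas centre, with the translation magnitude solved so the two circular
#' fields of view overlap by the requested regime: about 85% of the smaller
#' FOV for `overlap = "high"` (the >75% regime) or about 55% for `"low"`
#' (the <75% mosaicking regime). The target view is rendered from the
#' transformed tree geometry with its own camera-centred FOV — no image
#' resampling is involved, so every retinal landmark `p` of the source
#' appears exactly at `T p` in the target. Ten control points are sampled
#' uniformly in the overlap; by construction
#' `registration_error(true_model, control_points)` is exactly 0.
#'
#' @param seed integer seed controlling tree, transform, control points and
#'   noise.
#' @param kind `"similarity"` or `"affine"`.
#' @param overlap `"high"` (> 75%) or `"low"` (< 75%).
#' @param exposure_gain intensity gain applied to the target view.
#' @param noise_sigma Gaussian noise SD for both views; default 0.
#' @param reflex draw central vessel reflex; default `TRUE`.
#' @param canvas,fov_radius frame geometry, passed to the tree generator
#'   and renderer.
#' @param ... further arguments to [generate_tree()].
#' @return Object of class `synthetic_pair`: list with `source`, `target`
#'   ([fundus_image()]s), `true_model` (a `transform_model`),
#'   `junctions_source`, `junctions_target` (data.frames `x, y`),
#'   `control_points` (a `control_points` table) and `params` (including
#'   the measured FOV overlap fraction).
#' @export
make_pair <- function(seed, kind = c("similarity", "affine"),
                      overlap = c("high", "low"), exposure_gain = 1,
                      noise_sigma = 0, reflex = TRUE,
                      canvas = c(768L, 768L), fov_radius = 350, ...) {
  kind <- match.arg(kind)
  overlap <- match.arg(overlap)
  tree <- generate_tree(seed, canvas = canvas, ...)
  h <- canvas[1L]; w <- canvas[2L]
  cx <- w / 2; cy <- h / 2
  target_frac <- if (overlap == "high") 0.85 else 0.55

  draw <- with_seed(seed + 1000L, {
    s <- stats::runif(1, 0.95, 1.05)
    th <- stats::runif(1, -10, 10) * pi / 180
    A <- s * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L,
                    byrow = TRUE)
    if (kind == "affine") {
      shear <- matrix(c(1, stats::runif(1, -0.05, 0.05),
                        stats::runif(1, -0.05, 0.05), 1), 2L, 2L,
                      byrow = TRUE)
      A <- A %*% shear
    }
    phi <- stats::runif(1, 0, 2 * pi)
    list(A = A, phi = phi)
  })
  A <- draw$A
  s_eff <- sqrt(abs(det(A)))
  f <- function(d) disc_overlap_fraction(d, s_eff * fov_radius, fov_radius) -
    target_frac
  d_max <- (1 + s_eff) * fov_radius
  d_star <- stats::uniroot(f, c(0, d_max - 1e-6), tol = 1e-8)$root
  # rotation/scale about the canvas centre, then an offset of length d_star
  tvec <- c(cx, cy) - A %*% c(cx, cy) +
    d_star * c(cos(draw$phi), sin(draw$phi))
  T <- rbind(cbind(A, tvec), c(0, 0, 1))
  model <- transform_model(T, kind)
  if (max(abs(c(T[1, 3], T[2, 3]))) > max(h, w))
    stopf("requested overlap unreachable on this canvas",
          class = "fundusreg_bad_input")

  tree_t <- tree
  p0 <- apply_transform(model, cbind(tree$segments$x0, tree$segments$y0))
  p1 <- apply_transform(model, cbind(tree$segments$x1, tree$segments$y1))
  tree_t$segments$x0 <- p0[, 1L]; tree_t$segments$y0 <- p0[, 2L]
  tree_t$segments$x1 <- p1[, 1L]; tree_t$segments$y1 <- p1[, 2L]
  tree_t$segments$width <- tree$segments$width * s_eff
  jt <- apply_transform(model, tree$junctions)
  junctions_target <- data.frame(x = jt[, 1L], y = jt[, 2L])

  src <- render_fundus(tree, fov_radius = fov_radius,
                       noise_sigma = noise_sigma, reflex = reflex,
                       seed = seed + 1L, id = sprintf("S%03d_source", seed))
  tgt <- render_fundus(tree_t, fov_radius = fov_radius,
                       noise_sigma = noise_sigma, reflex = reflex,
                       exposure_gain = exposure_gain, seed = seed + 2L,
                       id = sprintf("S%03d_target", seed))

  # overlap measured on the actual FOV grids: warped-source FOV is the set
  # of target-frame pixels whose preimage lies inside the source disc
  Tinv <- solve(T)
  gx <- rep(seq_len(w), each = h); gy <- rep(seq_len(h), times = w)
  pre <- cbind(gx, gy, 1) %*% t(Tinv)
  in_src <- (pre[, 1L] - cx)^2 + (pre[, 2L] - cy)^2 <= fov_radius^2
  in_tgt <- (gx - cx)^2 + (gy - cy)^2 <= fov_radius^2
  both <- in_src & in_tgt
  measured_overlap <- sum(both) / min(sum(in_src), sum(in_tgt))

  margin2 <- (fov_radius - 20)^2
  deep <- both & (pre[, 1L] - cx)^2 + (pre[, 2L] - cy)^2 <= margin2 &
    (gx - cx)^2 + (gy - cy)^2 <= margin2
  idx <- with_seed(seed + 2000L, sample(which(deep), 10L))
  p_tgt <- cbind(gx[idx], gy[idx])
  p_src <- (cbind(p_tgt, 1) %*% t(Tinv))[, 1:2, drop = FALSE]
  cps <- structure(data.frame(x_src = p_src[, 1L], y_src = p_src[, 2L],
                              x_tgt = p_tgt[, 1L], y_tgt = p_tgt[, 2L]),
                   class = c("control_points", "data.frame"))

  structure(list(source = src, target = tgt, true_model = model,
                 junctions_source = tree$junctions,
                 junctions_target = junctions_target,
                 control_points = cps,
                 params = list(seed = seed, kind = kind, overlap = overlap,
                               target_overlap = target_frac,
                               measured_overlap = measured_overlap,
                               exposure_gain = exposure_gain,
                               noise_sigma = noise_sigma, reflex = reflex,
                               fov_radius = fov_radius, canvas = canvas)),
            class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(
    "<synthetic_pair seed=%d> %s transform, %s overlap (measured %.2f)\n",
    x$params$seed, x$params$kind, x$params$overlap,
    x$params$measured_overlap))
  invisible(x)
}

#' Write a synthetic pair to disk in a FIRE-like layout
#'
#' Creates `<dir>/<id>/` containing `source.png`, `target.png`,
#' `control_points.txt` (whitespace format, see [read_control_points()])
#' and `manifest.json` with the planted matrix and generator parameters.
#'
#' @param pair a `synthetic_pair`.
#' @param dir dataset root directory.
#' @param id pair identifier; defaults to `<S|P><seed>` by overlap regime
#'   (S-like for high overlap, P-like for low).
#' @return The pair directory, invisibly.
#' @export
write_synthetic_pair <- function(pair, dir, id = NULL) {
  id <- id %||% sprintf("%s%03d",
                        if (pair$params$overlap == "high") "S" else "P",
                        pair$params$seed)
  pd <- file.path(dir, id)
  dir.create(pd, recursive = TRUE, showWarnings = FALSE)
  write_image_png(pair$source, file.path(pd, "source.png"))
  write_image_png(pair$target, file.path(pd, "target.png"))
  write_control_points(pair$control_points,
                       file.path(pd, "control_points.txt"))
  jsonlite::write_json(
    list(id = id, kind = pair$params$kind,
         matrix = lapply(1:3, function(i) pair$true_model$T[i, ]),
         params = pair$params[setdiff(names(pair$params), "canvas")],
         canvas = pair$params$canvas),
    file.path(pd, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(pd)
}
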