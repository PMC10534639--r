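#' Default pipeline configuration
#'
#' Collects every tunable of the registration pipeline. All pixel-unit
#' defaults are defined at the working scale: images whose FOV diameter
#' exceeds `working_fov` px are downscaled before processing and the fitted
#' transform is mapped back to native resolution.
#'
#' @param n segmentation window side (odd, >= 3).
#' @param sigma preprocessing Gaussian SD (px).
#' @param tophat_radius top-hat disc radius (px).
#' @param saturate_frac contrast-stretch saturation fraction per tail.
#' @param dedupe_radius bifurcation merge radius (px).
#' @param rim_margin FOV-rim exclusion margin for keypoints (px).
#' @param match_threshold second-nearest-neighbour acceptance threshold.
#' @param match_mode `"ratio"` or `"magnitude"`.
#' @param kind transform model fitted by default.
#' @param p_success,inlier_tol,min_sample_dist,max_iter,seed RANSAC
#'   controls, see [ransac_config()].
#' @param octaves Laplacian blending depth.
#' @param working_fov working-scale FOV diameter (px).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 7L, sigma = 1.5, tophat_radius = 9,
                            saturate_frac = 0.03, dedupe_radius = 5,
                            rim_margin = 9, match_threshold = 0.9,
                            match_mode = "ratio",
                            kind = c("similarity", "affine"),
                            p_success = 0.99, inlier_tol = 5,
                            min_sample_dist = 50, max_iter = 10000L,
                            seed = 1L, octaves = 3L, working_fov = 1024) {
  kind <- match.arg(kind)
  if (n %% 2 == 0 || n < 3)
    stopf("window size n must be odd and >= 3", class = "fundusreg_bad_input")
  if (!match_mode %in% c("ratio", "magnitude"))
    stopf("match_mode must be 'ratio' or 'magnitude'",
          class = "fundusreg_bad_input")
  structure(list(n = as.integer(n), sigma = sigma,
                 tophat_radius = tophat_radius,
                 saturate_frac = saturate_frac,
                 dedupe_radius = dedupe_radius, rim_margin = rim_margin,
                 match_threshold = match_threshold, match_mode = match_mode,
                 kind = kind, p_success = p_success, inlier_tol = inlier_tol,
                 min_sample_dist = min_sample_dist,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 octaves = as.integer(octaves), working_fov = working_fov),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected; omitted keys keep their defaults; values are
#' validated by [pipeline_config()].
#'
#' @param path JSON file with a flat object of configuration fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stopf("unknown config keys: %s", paste(bad, collapse = ", "),
          class = "fundusreg_bad_input")
  do.call(pipeline_config, x)
}

# Detect keypoints and compute their descriptors for one image.
extract_features <- function(img, config) {
  e <- preprocess_fundus(img, sigma = config$sigma,
                         tophat_radius = config$tophat_radius,
                         saturate_frac = config$saturate_frac)
  model <- fit_segmentation_model(e, n = config$n)
  vm <- segment_vessels(e, model)
  sk <- zhang_suen_thin(vm)
  kp <- detect_bifurcations(sk, dedupe_radius = config$dedupe_radius,
                            fov_mask = img$fov_mask,
                            rim_margin = config$rim_margin)
  ds <- compute_descriptors(e, kp)
  list(enhanced = e, seg_model = model, vessels = vm, skeleton = sk,
       keypoints = kp, descriptors = ds)
}

# Downscale a fundus image so its FOV diameter is ~ working_fov px.
# Returns the image plus the scale factor (native = working / scale).
to_working_scale <- function(img, working_fov) {
  diam <- 2 * sqrt(sum(img$fov_mask) / pi)
  if (diam <= working_fov) return(list(img = img, scale = 1))
  sc <- working_fov / diam
  h <- round(nrow(img$fov_mask) * sc); w <- round(ncol(img$fov_mask) * sc)
  rgb <- array(0, c(h, w, 3L))
  for (ch in 1:3)
    rgb[, , ch] <- from_ebimage(EBImage::resize(as_ebimage(img$rgb[, , ch]),
                                                w = w, h = h,
                                                filter = "bilinear"))
  fov <- from_ebimage(EBImage::resize(as_ebimage(img$fov_mask * 1),
                                      w = w, h = h, filter = "none")) > 0.5
  list(img = fundus_image(rgb, fov, id = img$id),
       scale = w / ncol(img$fov_mask))
}

# Conjugate a working-scale transform back to native resolution. With
# native->working scalings p_w = s * p_n (about the origin, applied to both
# frames), T_native = S^-1 T_work S.
rescale_transform <- function(model, scale_src, scale_tgt) {
  St <- diag(c(1 / scale_tgt, 1 / scale_tgt, 1))
  Ss <- diag(c(scale_src, scale_src, 1))
  transform_model(St %*% model$T %*% Ss, model$kind)
}

#' Register a fundus image pair end to end
#'
#' Runs the full landmark pipeline on both images — preprocessing, coarse
#' vessel segmentation, skeletonization, hit-or-miss bifurcation detection,
#' HOG description, cross-checked second-nearest-neighbour matching — then
#' estimates the source-to-target transform with distance-constrained
#' RANSAC, and optionally warps and blends the pair into a mosaic.
#'
#' @param source,target [fundus_image()] objects (or file paths).
#' @param config a [pipeline_config()].
#' @param blend build the blended mosaic (slowest stage); default `TRUE`.
#' @return Object of class `fundus_registration`: list with `result` (a
#'   `registration_result`; its model maps native source to native target
#'   coordinates), `features` (per-image keypoint/descriptor bundles),
#'   `matches`, `mosaic` (blended canvas or `NULL`), `offset` (mosaic
#'   canvas origin in target coordinates) and `stages` (named vector of
#'   stage timings in seconds, plus keypoint/match/inlier counts in
#'   `counts`).
#' @export
register_pair <- function(source, target, config = pipeline_config(),
                          blend = TRUE) {
  if (is.character(source)) source <- read_fundus(source)
  if (is.character(target)) target <- read_fundus(target)
  tic <- function() proc.time()[["elapsed"]]
  stages <- c(); t0 <- tic()
  ws <- to_working_scale(source, config$working_fov)
  wt <- to_working_scale(target, config$working_fov)
  stages["rescale"] <- tic() - t0; t0 <- tic()
  fs <- extract_features(ws$img, config)
  ft <- extract_features(wt$img, config)
  stages["features"] <- tic() - t0; t0 <- tic()
  ab <- match_one_direction(fs$descriptors, ft$descriptors,
                            config$match_threshold, config$match_mode)
  ba <- match_one_direction(ft$descriptors, fs$descriptors,
                            config$match_threshold, config$match_mode)
  matches <- cross_check(ab, ba)
  stages["matching"] <- tic() - t0; t0 <- tic()
  rcfg <- ransac_config(p_success = config$p_success,
                        inlier_tol = config$inlier_tol,
                        min_sample_dist = config$min_sample_dist,
                        max_iter = config$max_iter, seed = config$seed)
  res <- ransac_fit(matches, fs$descriptors$keypoints,
                    ft$descriptors$keypoints, config$kind, rcfg)
  if (res$converged)
    res$model <- rescale_transform(res$model, ws$scale, wt$scale)
  stages["ransac"] <- tic() - t0; t0 <- tic()
  mosaic <- NULL; offset <- NULL
  if (blend && res$converged) {
    wp <- warp_source(source, res$model, dim(target$fov_mask))
    canvas_dim <- dim(wp$mask)
    tgt_rgb <- array(0, c(canvas_dim, 3L))
    tgt_mask <- matrix(FALSE, canvas_dim[1L], canvas_dim[2L])
    ys <- seq_len(nrow(target$fov_mask)) + (1 - wp$offset["y"])
    xs <- seq_len(ncol(target$fov_mask)) + (1 - wp$offset["x"])
    tgt_rgb[ys, xs, ] <- target$rgb
    tgt_mask[ys, xs] <- target$fov_mask
    mosaic <- blend_pair(wp$rgb, wp$mask * 1, tgt_rgb, tgt_mask * 1,
                         octaves = config$octaves)
    offset <- wp$offset
    stages["blend"] <- tic() - t0
  }
  structure(list(result = res,
                 features = list(source = fs, target = ft),
                 matches = matches, mosaic = mosaic, offset = offset,
                 scales = c(source = ws$scale, target = wt$scale),
                 counts = c(kp_source = nrow(fs$keypoints),
                            kp_target = nrow(ft$keypoints),
                            matches_forward = nrow(ab),
                            matches_backward = nrow(ba),
                            matches = nrow(matches),
                            inliers = nrow(res$inliers)),
                 stages = stages),
            class = "fundus_registration")
}

#' @export
print.fundus_registration <- function(x, ...) {
  cat("<fundus_registration>\n")
  print(x$counts)
  print(x$result)
  invisible(x)
}

#' Evaluate registration over a directory of image pairs
#'
#' Expects the layout written by [write_synthetic_pair()] (or any FIRE-like
#' tree): one directory per pair holding `source.png`, `target.png` and
#' `control_points.txt`. Categories are taken from the first letter of the
#' pair directory name. Pairs without ground truth are skipped with a
#' warning and reported in the `excluded` element.
#'
#' @param pairs_dir dataset root.
#' @param config a [pipeline_config()].
#' @param max_threshold success band in px; default 25.
#' @return An `evaluation_batch` (see [evaluate_batch()]) with an extra
#'   `excluded` character vector.
#' @export
evaluate_directory <- function(pairs_dir, config = pipeline_config(),
                               max_threshold = 25L) {
  dirs <- list.dirs(pairs_dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "source.png"))]
  if (length(dirs) == 0L)
    stopf("no image pairs found under '%s'", pairs_dir,
          class = "fundusreg_io_error")
  excluded <- character()
  results <- list()
  for (d in dirs) {
    id <- basename(d)
    gt <- file.path(d, "control_points.txt")
    if (!file.exists(gt)) {
      warning(sprintf("pair '%s' has no ground truth; skipped", id))
      excluded <- c(excluded, id)
      next
    }
    reg <- register_pair(file.path(d, "source.png"),
                         file.path(d, "target.png"),
                         config, blend = FALSE)
    results[[id]] <- list(id = id,
                          model = if (reg$result$converged) reg$result$model,
                          cps = read_control_points(gt))
  }
  batch <- evaluate_batch(results, max_threshold)
  batch$excluded <- excluded
  batch
}
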