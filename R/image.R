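#' Fundus image container
#'
#' Bundles an RGB intensity array with the binary field-of-view (FOV) mask
#' that marks the illuminated circular region of a fundus photograph.
#' Intensities are stored on the 0--255 scale; the mask is a logical matrix
#' of the same height and width. Points throughout the package are (x, y)
#' with x growing rightwards and y downwards, 1-based.
#'
#' @param rgb numeric array `H x W x 3`, values in 0--255.
#' @param fov_mask logical (or 0/1) matrix `H x W`; `TRUE` inside the FOV.
#'   When `NULL` it is estimated with [extract_fov_mask()].
#' @param id optional label carried through the pipeline.
#' @return An object of class `fundus_image` with elements `rgb`, `fov_mask`
#'   and `id`.
#' @seealso [read_fundus()], [extract_fov_mask()], [preprocess_fundus()]
#' @export
fundus_image <- function(rgb, fov_mask = NULL, id = "fundus") {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stopf("rgb must be an H x W x 3 array", class = "fundusreg_bad_input")
  if (is.null(fov_mask)) {
    img <- structure(list(rgb = rgb, fov_mask = NULL, id = id),
                     class = "fundus_image")
    fov_mask <- extract_fov_mask(img)
  }
  fov_mask <- matrix(as.logical(fov_mask), nrow(fov_mask), ncol(fov_mask))
  if (!identical(dim(fov_mask), dim(rgb)[1:2]))
    stopf("fov_mask dimensions do not match rgb", class = "fundusreg_bad_input")
  if (!any(fov_mask))
    stopf("field-of-view mask is empty", class = "fundusreg_empty_fov")
  structure(list(rgb = rgb, fov_mask = fov_mask, id = id),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image '%s'> %d x %d px, FOV %.1f%% of frame\n",
              x$id, nrow(x$fov_mask), ncol(x$fov_mask),
              100 * mean(x$fov_mask)))
  invisible(x)
}

#' Read a fundus photograph from disk
#'
#' Reads a PNG/JPEG/TIFF image via EBImage, rescales intensities to 0--255
#' and estimates the field-of-view mask.
#'
#' @param path image file path.
#' @param id label; defaults to the file name without extension.
#' @inheritParams extract_fov_mask
#' @return A [fundus_image()].
#' @export
read_fundus <- function(path, id = NULL, threshold_frac = 0.1) {
  if (!file.exists(path))
    stopf("cannot read image '%s'", path, class = "fundusreg_io_error")
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 2L) a <- array(rep(a, 3L), c(d[1L], d[2L], 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3]
  rgb <- aperm(a, c(2L, 1L, 3L)) * 255
  id <- id %||% sub("\\.[^.]+$", "", basename(path))
  f <- structure(list(rgb = rgb, fov_mask = NULL, id = id),
                 class = "fundus_image")
  fundus_image(rgb, extract_fov_mask(f, threshold_frac), id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fundus image (or plain matrix) as PNG
#'
#' @param x a [fundus_image()], an `H x W x 3` array or an `H x W` matrix on
#'   the 0--255 scale (logical matrices are written as 0/255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (inherits(x, "fundus_image")) x <- x$rgb
  if (inherits(x, "vessel_mask")) x <- x$mask
  if (is.logical(x)) x <- x * 255
  x <- clamp(x / 255, 0, 1)
  img <- if (length(dim(x)) == 3L) {
    EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = "Color")
  } else {
    EBImage::Image(t(x))
  }
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

#' Estimate the circular field of view of a fundus photograph
#'
#' The dark surround of a fundus photograph carries no information and must
#' be excluded from every statistic. The FOV is recovered as the largest
#' connected region brighter than `threshold_frac` of the maximum intensity,
#' morphologically closed to fill pinholes.
#'
#' @param img a [fundus_image()] (the `fov_mask` field is ignored).
#' @param threshold_frac fraction of the intensity maximum separating the
#'   illuminated disc from the dark surround; default 0.1.
#' @return Logical `H x W` matrix, `TRUE` inside the field of view.
#' @export
extract_fov_mask <- function(img, threshold_frac = 0.1) {
  gray <- (img$rgb[, , 1] + img$rgb[, , 2] + img$rgb[, , 3]) / 3
  bright <- gray > threshold_frac * 255
  if (!any(bright))
    stopf("image has no field of view (all dark)", class = "fundusreg_empty_fov")
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(bright)))
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  brush <- EBImage::makeBrush(15L, "disc")
  from_ebimage(EBImage::closing(as_ebimage(mask), brush)) > 0.5
}
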