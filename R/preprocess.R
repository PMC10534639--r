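#' Preprocess a fundus image for vessel segmentation
#'
#' Produces the vessel-bright intensity surface on which segmentation and
#' description operate. The pipeline is: invert the green channel
#' (vessels absorb green light, so `255 - G` makes them bright), zero
#' outside the FOV, Gaussian smooth, white top-hat with a disc structuring
#' element (removes smooth illumination, keeps thin bright structures), then
#' a linear contrast stretch that saturates `saturate_frac` of the in-FOV
#' pixels at each tail. Output intensities are integers in 0--255, zero
#' outside the FOV.
#'
#' @param img a [fundus_image()].
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param tophat_radius radius in pixels of the disc structuring element;
#'   structures wider than about twice this are suppressed.
#' @param saturate_frac fraction of pixels saturated at each intensity tail
#'   during the stretch; default 0.03 (3%).
#' @return An object of class `enhanced_image`: list with `gray`
#'   (integer-valued `H x W` matrix, 0--255) and `fov_mask`.
#' @export
preprocess_fundus <- function(img, sigma = 1.5, tophat_radius = 9,
                              saturate_frac = 0.03) {
  stopifnot(inherits(img, "fundus_image"))
  if (sigma <= 0) stopf("sigma must be positive", class = "fundusreg_bad_input")
  if (saturate_frac < 0 || saturate_frac >= 0.5)
    stopf("saturate_frac must lie in [0, 0.5)", class = "fundusreg_bad_input")
  fov <- img$fov_mask
  if (!any(fov)) stopf("empty fov_mask", class = "fundusreg_empty_fov")

  ig <- 255 - img$rgb[, , 2]
  ig[!fov] <- 0
  sm <- from_ebimage(EBImage::gblur(as_ebimage(ig / 255), sigma = sigma)) * 255
  sm[!fov] <- 0
  brush <- EBImage::makeBrush(2L * as.integer(tophat_radius) + 1L, "disc")
  th <- from_ebimage(EBImage::whiteTopHat(as_ebimage(sm / 255), brush)) * 255
  th[!fov] <- 0
  th <- pmax(th, 0)

  vals <- th[fov]
  lo <- stats::quantile(vals, saturate_frac, names = FALSE)
  hi <- stats::quantile(vals, 1 - saturate_frac, names = FALSE)
  gray <- if (hi > lo) clamp((th - lo) / (hi - lo) * 255, 0, 255) else th * 0
  gray <- round(gray)
  gray[!fov] <- 0
  structure(list(gray = gray, fov_mask = fov), class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image> %d x %d px, in-FOV intensity range [%d, %d]\n",
              nrow(x$gray), ncol(x$gray),
              min(x$gray[x$fov_mask]), max(x$gray[x$fov_mask])))
  invisible(x)
}
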