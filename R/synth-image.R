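# Synthetic layered section images: a bright molecular band of known
# thickness under the pial contour, over a dark granular band, emulating the
# appearance of a stained cerebellar section.  Pixel rasters are stored as
# matrices indexed [x + 1, y + 1] (EBImage convention, 0-based pixel
# coordinates with centres at integers).

#' Section image container
#'
#' @param pixels numeric matrix in `[0, 1]`, indexed `[x + 1, y + 1]`.
#' @param mm_per_px calibration (mm per pixel).
#' @param contour the bounding [section_contour] of the tissue of interest.
#' @param mask logical matrix of the tissue-of-interest, same dim as pixels.
#' @return an object of class `section_image`.
#' @export
section_image <- function(pixels, mm_per_px, contour, mask = NULL) {
  stopifnot(is.matrix(pixels), mm_per_px > 0,
            inherits(contour, "section_contour"))
  if (is.null(mask)) mask <- contour_mask(contour, dim(pixels))
  stopifnot(identical(dim(mask), dim(pixels)))
  structure(list(pixels = pixels, mm_per_px = mm_per_px,
                 contour = contour, mask = mask),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("section_image %d x %d px, %.6g mm/px, %d mask px\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_px, sum(x$mask)))
  invisible(x)
}

#' Rasterise a contour to a binary inside-mask
#'
#' @param contour a closed [section_contour].
#' @param dim raster dimensions `c(width, height)` in pixels.
#' @return logical matrix indexed `[x + 1, y + 1]`.
#' @export
contour_mask <- function(contour, dim) {
  w <- dim[1L]; h <- dim[2L]
  gx <- rep(0:(w - 1L), times = h)
  gy <- rep(0:(h - 1L), each = w)
  v <- contour$vertices
  inside <- pracma::inpolygon(gx, gy, v[, 1L], v[, 2L], boundary = TRUE)
  matrix(inside, nrow = w, ncol = h)
}

#' Generate a layered section image with known molecular-layer thickness
#'
#' Pixels outside the contour take the surface grey level; pixels inside and
#' within distance `molecular_thickness` of the contour take the (bright)
#' molecular level; the next `granular_thickness` band takes the (dark)
#' granular level; deeper pixels the interior level.  Gaussian blur and
#' pixel noise are then applied.  The true thickness is constant and
#' returned per contour vertex.
#'
#' @param contour closed, calibrated [section_contour].
#' @param molecular_thickness true band thickness `t` in mm; must be smaller
#'   than the contour's minimal inradius.
#' @param grey_levels named numeric vector `surface`, `molecular`,
#'   `granular`, `interior` in `[0, 1]`.
#' @param granular_thickness dark-band depth in mm.
#' @param blur_sd Gaussian blur sigma in px (0 = none).
#' @param noise_sd additive pixel noise sd in grey units (0 = none).
#' @param seed mandatory integer seed (used only for noise, but always
#'   required so fixtures are replicable).
#' @return list with `image` (a [section_image]) and `truth` (per-vertex
#'   thickness, mm).
#' @export
generate_layered_section_image <- function(contour, molecular_thickness,
                                           grey_levels = c(surface = 0.35,
                                                           molecular = 0.9,
                                                           granular = 0.15,
                                                           interior = 0.55),
                                           granular_thickness =
                                             2 * molecular_thickness,
                                           blur_sd = 0, noise_sd = 0, seed) {
  stopifnot(inherits(contour, "section_contour"), contour$closed,
            molecular_thickness >= 0, blur_sd >= 0, noise_sd >= 0)
  stop_if_uncalibrated(contour)
  need <- c("surface", "molecular", "granular", "interior")
  if (!all(need %in% names(grey_levels)))
    stop("grey_levels needs components: ", paste(need, collapse = ", "))
  v <- contour$vertices
  pad <- 4L
  w <- ceiling(max(v[, 1L])) + pad + 1L
  h <- ceiling(max(v[, 2L])) + pad + 1L
  mask <- contour_mask(contour, c(w, h))
  # distance (px) from each inside pixel to the nearest outside pixel
  dmap <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1), "euclidean"))
  t_px <- molecular_thickness / contour$mm_per_px
  if (t_px > 0 && max(dmap) <= t_px)
    stop("molecular_thickness exceeds the contour's minimal inradius")
  g_px <- granular_thickness / contour$mm_per_px
  px <- matrix(grey_levels[["surface"]], w, h)
  px[mask & dmap <= t_px] <- grey_levels[["molecular"]]
  px[mask & dmap > t_px & dmap <= t_px + g_px] <- grey_levels[["granular"]]
  px[mask & dmap > t_px + g_px] <- grey_levels[["interior"]]
  if (blur_sd > 0)
    px <- as.matrix(EBImage::gblur(EBImage::Image(px), sigma = blur_sd))
  if (noise_sd > 0)
    px <- px + with_seed(seed, matrix(stats::rnorm(w * h, 0, noise_sd), w, h))
  px[px < 0] <- 0; px[px > 1] <- 1
  img <- section_image(px, contour$mm_per_px, contour, mask)
  list(image = img, truth = rep(molecular_thickness, nrow(v)))
}

#' Write / read a greyscale raster as PNG
#'
#' Convenience round-trip used by the pipeline; values are clamped to
#' `[0, 1]` and quantised to 16 bits.
#'
#' @param image a [section_image] or plain `[x, y]` matrix.
#' @param path PNG path.
#' @return `path` invisibly (`write`); an `[x, y]` matrix in `[0, 1]` (`read`).
#' @export
write_section_png <- function(image, path) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  px[px < 0] <- 0; px[px > 1] <- 1
  # png::writePNG expects [row = y, col = x]
  png::writePNG(t(px), path)
  invisible(path)
}

#' @rdname write_section_png
#' @export
read_section_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- rgb_to_grey(a)
  t(a)
}

rgb_to_grey <- function(arr) {
  if (dim(arr)[3L] >= 3L)
    0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L]
  else arr[, , 1L]
}
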