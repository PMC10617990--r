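# Molecular-layer thickness from a section image and its pial contour.
# The pipeline follows the profile-line approach: preprocess the image,
# mask the tissue, relax a Laplacian potential inside the mask, descend
# its gradient from every contour vertex to build profile lines, sample
# the grey values along each line, locate the bright-to-dark boundary by
# the most negative grey gradient, and summarise the per-line thicknesses
# by their median.

#' Preprocess a section image
#'
#' Luminance conversion (for RGB input), median-filter denoising and
#' global rank-based histogram equalisation, rescaled to `[0, 1]`.  A
#' constant image is returned unchanged (equalisation of a flat image is
#' the identity).
#'
#' @param raw `[x, y]` grey matrix in any range, or `[x, y, 3]` RGB array.
#' @param denoise_radius median filter radius in px (0 disables).
#' @param equalize apply global histogram equalisation.
#' @return `[x, y]` matrix in `[0, 1]`.
#' @export
preprocess_image <- function(raw, denoise_radius = 1L, equalize = TRUE) {
  if (length(raw) == 0L) stop("empty raster")
  if (length(dim(raw)) == 3L) raw <- rgb_to_grey(raw)
  px <- as.matrix(raw)
  rng <- range(px)
  if (rng[1L] == rng[2L]) return(px)
  px <- (px - rng[1L]) / (rng[2L] - rng[1L])
  if (denoise_radius > 0)
    px <- as.matrix(EBImage::medianFilter(EBImage::Image(px),
                                          size = denoise_radius))
  if (equalize) {
    rk <- rank(px, ties.method = "average")
    px <- matrix((rk - min(rk)) / (max(rk) - min(rk)),
                 nrow(px), ncol(px))
  } else {
    rng <- range(px)
    if (rng[2L] > rng[1L]) px <- (px - rng[1L]) / (rng[2L] - rng[1L])
  }
  px
}

#' Laplacian relaxation of a masked raster
#'
#' Red-black Gauss-Seidel (optionally over-relaxed) neighbour averaging of
#' the values at `free` pixels, with all other pixels in `region` acting
#' as fixed Dirichlet boundaries; pixels outside `region` never
#' participate.  Stops when the maximum update drops below `tol` times the
#' value range, or at the iteration cap (flagged via the `converged`
#' attribute, not fatal).
#'
#' @param values numeric `[x, y]` matrix holding initial and boundary
#'   values.
#' @param free logical matrix: pixels to relax.
#' @param region logical matrix: pixels that participate (fixed boundary =
#'   `region & !free`); defaults to all pixels.
#' @param iterations iteration cap.
#' @param tol relative convergence tolerance (`Inf` returns the input
#'   after 0 iterations).
#' @param omega SOR over-relaxation factor in `[1, 2)`.
#' @return relaxed matrix with attribute `converged`.
#' @export
laplace_relax <- function(values, free, region = NULL, iterations = 500L,
                          tol = 1e-4, omega = 1.5) {
  stopifnot(identical(dim(values), dim(free)))
  if (is.null(region)) region <- matrix(TRUE, nrow(values), ncol(values))
  if (!any(free) || is.infinite(tol) || iterations < 1L) {
    attr(values, "converged") <- TRUE
    return(values)
  }
  w <- nrow(values); h <- ncol(values)
  # pad by one pixel so 4-neighbour access needs no boundary handling;
  # non-region neighbours carry value 0 and are excluded via the counts
  W <- w + 2L
  Vp <- matrix(0, W, h + 2L)
  Vp[2:(w + 1L), 2:(h + 1L)] <- values * region
  regp <- matrix(0, W, h + 2L)
  regp[2:(w + 1L), 2:(h + 1L)] <- region
  fidx <- which(free)                       # original linear indices
  xi <- ((fidx - 1L) %% w) + 1L
  yi <- ((fidx - 1L) %/% w) + 1L
  pidx <- yi * W + xi + 1L                  # padded linear indices
  nb <- cbind(pidx - 1L, pidx + 1L, pidx - W, pidx + W)
  ncnt <- regp[nb[, 1L]] + regp[nb[, 2L]] + regp[nb[, 3L]] + regp[nb[, 4L]]
  ok <- ncnt > 0
  # red-black (checkerboard) split for Gauss-Seidel/SOR sweeps
  sets <- list(which(ok & (xi + yi) %% 2L == 0L),
               which(ok & (xi + yi) %% 2L == 1L))
  rng <- diff(range(values[region]))
  if (rng == 0) rng <- 1
  converged <- FALSE
  for (it in seq_len(iterations)) {
    delta <- 0
    for (sel in sets) {
      if (!length(sel)) next
      p <- pidx[sel]
      nsum <- Vp[p - 1L] + Vp[p + 1L] + Vp[p - W] + Vp[p + W]
      new <- (1 - omega) * Vp[p] + omega * nsum / ncnt[sel]
      delta <- max(delta, max(abs(new - Vp[p])))
      Vp[p] <- new
    }
    if (delta < tol * rng) { converged <- TRUE; break }
  }
  V <- values
  V[fidx] <- Vp[pidx]
  attr(V, "converged") <- converged
  V
}

#' Relax the Laplacian potential of a section image
#'
#' The masked image is relaxed with the contour-adjacent ring of mask
#' pixels held at the (bright, surface) image values and — by default —
#' the dark pixels of the mask (below an Otsu threshold; the granular
#' layer and deeper) held as interior anchors.  The relaxed field then
#' decreases monotonically from white at the surface towards black at the
#' granular layer, and its negative gradient guides the profile lines.
#'
#' @param img a [section_image] (pixels already preprocessed).
#' @param iterations,tol,omega see [laplace_relax()].
#' @param dark_anchor keep sub-threshold mask pixels fixed (recommended);
#'   without it the field is plain partial diffusion of the masked image.
#' @return potential matrix with attribute `converged`.
#' @export
relax_laplacian <- function(img, iterations = 2000L, tol = 1e-5,
                            omega = 1.8, dark_anchor = TRUE) {
  stopifnot(inherits(img, "section_image"))
  if (!any(img$mask)) stop("empty mask")
  ring <- mask_boundary_ring(img$mask)
  free <- img$mask & !ring
  if (dark_anchor) {
    thr <- otsu_threshold(img$pixels[img$mask])
    free <- free & img$pixels >= thr
  }
  out <- laplace_relax(img$pixels, free = free,
                       region = img$mask, iterations = iterations,
                       tol = tol, omega = omega)
  if (!attr(out, "converged") && iterations > 0L && is.finite(tol))
    message("laplacian relaxation stopped at the iteration cap")
  out
}

# Otsu's between-class-variance threshold on a 256-bin histogram
otsu_threshold <- function(vals) {
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(0.5)
  br <- seq(min(vals), max(vals), length.out = 257L)
  if (br[1L] == br[257L]) return(br[1L])
  hh <- tabulate(findInterval(vals, br, all.inside = TRUE), 256L)
  w <- hh / sum(hh)
  mids <- (br[-257L] + br[-1L]) / 2
  cw <- cumsum(w); cm <- cumsum(w * mids)
  mt <- cm[256L]
  bcv <- (mt * cw - cm)^2 / (cw * (1 - cw))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

# mask pixels 4-adjacent to a non-mask pixel (or on the raster edge)
mask_boundary_ring <- function(mask) {
  w <- nrow(mask); h <- ncol(mask)
  pad <- matrix(FALSE, w + 2L, h + 2L)
  pad[2:(w + 1L), 2:(h + 1L)] <- mask
  nb <- pad[1:w, 2:(h + 1L)] & pad[3:(w + 2L), 2:(h + 1L)] &
    pad[2:(w + 1L), 1:h] & pad[2:(w + 1L), 3:(h + 2L)]
  mask & !nb
}

# vectorised bilinear interpolation on an [x, y] matrix at 0-based coords
bilinear <- function(M, x, y) {
  w <- nrow(M); h <- ncol(M)
  x <- pmin(pmax(x, 0), w - 1 - 1e-9)
  y <- pmin(pmax(y, 0), h - 1 - 1e-9)
  ix <- floor(x); iy <- floor(y)
  fx <- x - ix; fy <- y - iy
  i00 <- (ix + 1L) + w * iy
  M[i00] * (1 - fx) * (1 - fy) + M[i00 + 1L] * fx * (1 - fy) +
    M[i00 + w] * (1 - fx) * fy + M[i00 + w + 1L] * fx * fy
}

#' Trace gradient-descent profile lines from contour vertices
#'
#' From every contour vertex, follow the negative gradient of the
#' potential in fixed sub-pixel steps (bilinear interpolation), advancing
#' only while the potential decreases; once a local minimum is reached the
#' line continues straight along its last direction.  All lines are given
#' one common sample count: the 95th percentile of per-vertex descent
#' lengths, capped at `max_depth_mm` of tissue.
#'
#' @param potential relaxed potential from [relax_laplacian()].
#' @param img the [section_image].
#' @param step_px integration step in pixels.
#' @param max_depth_mm cap on profile length in mm.
#' @param length_quantile quantile of descent lengths defining the common
#'   profile length.
#' @return object of class `thickness_profiles`: matrices `x`, `y`
#'   (profiles x samples, 0-based px coords), `descent_steps`, `valid`,
#'   `step_px`, `mm_per_px`.
#' @export
trace_profiles <- function(potential, img, step_px = 0.5,
                           max_depth_mm = 2, length_quantile = 0.95) {
  stopifnot(inherits(img, "section_image"), step_px > 0)
  v <- img$contour$vertices
  np <- nrow(v)
  w <- nrow(potential); h <- ncol(potential)
  max_steps <- max(2L, ceiling(max_depth_mm / img$mm_per_px / step_px))
  # the exterior is not tissue: give it a potential above the surface
  # values so the descent direction always points into the mask
  potential[!img$mask] <- max(potential[img$mask]) + 1
  gx <- matrix(0, w, h); gy <- matrix(0, w, h)
  gx[2:(w - 1L), ] <- (potential[3:w, ] - potential[1:(w - 2L), ]) / 2
  gy[, 2:(h - 1L)] <- (potential[, 3:h] - potential[, 1:(h - 2L)]) / 2
  X <- matrix(NA_real_, np, max_steps + 1L)
  Y <- matrix(NA_real_, np, max_steps + 1L)
  px <- pmin(pmax(v[, 1L], 0), w - 1)
  py <- pmin(pmax(v[, 2L], 0), h - 1)
  X[, 1L] <- px; Y[, 1L] <- py
  pot <- bilinear(potential, px, py)
  dirx <- rep(NA_real_, np); diry <- rep(NA_real_, np)
  linear <- rep(FALSE, np)
  descent <- rep(NA_integer_, np)
  valid <- rep(TRUE, np)
  for (s in seq_len(max_steps)) {
    ggx <- -bilinear(gx, px, py)
    ggy <- -bilinear(gy, px, py)
    nrm <- sqrt(ggx^2 + ggy^2)
    zero <- nrm < 1e-12
    if (s == 1L) valid[zero] <- FALSE
    # switch to linear continuation where the gradient has died out
    newlin <- !linear & zero
    linear <- linear | newlin
    descent[newlin & is.na(descent)] <- s - 1L
    ux <- ifelse(linear, dirx, ggx / pmax(nrm, 1e-12))
    uy <- ifelse(linear, diry, ggy / pmax(nrm, 1e-12))
    ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0
    nx <- px + step_px * ux
    ny <- py + step_px * uy
    npot <- bilinear(potential, nx, ny)
    stalled <- !linear & (npot >= pot - 1e-12)
    if (any(stalled)) {
      # local minimum reached: from here continue along the last direction
      linear[stalled] <- TRUE
      descent[stalled & is.na(descent)] <- s - 1L
      nx[stalled] <- px[stalled] + step_px * ifelse(is.na(dirx[stalled]),
                                                    0, dirx[stalled])
      ny[stalled] <- py[stalled] + step_px * ifelse(is.na(diry[stalled]),
                                                    0, diry[stalled])
      npot[stalled] <- bilinear(potential, nx[stalled], ny[stalled])
    }
    keep <- !linear
    dirx[keep] <- ux[keep]; diry[keep] <- uy[keep]
    px <- nx; py <- ny; pot <- npot
    X[, s + 1L] <- px; Y[, s + 1L] <- py
  }
  descent[is.na(descent)] <- max_steps
  L <- max(2L, min(max_steps,
                   ceiling(stats::quantile(descent[valid], length_quantile,
                                           names = FALSE))))
  X <- X[, seq_len(L + 1L), drop = FALSE]
  Y <- Y[, seq_len(L + 1L), drop = FALSE]
  off <- rowSums(X < 0 | X > w - 1 | Y < 0 | Y > h - 1) > 0
  valid <- valid & !off
  structure(list(x = X, y = Y, descent_steps = descent, valid = valid,
                 step_px = step_px, mm_per_px = img$mm_per_px,
                 n_samples = L + 1L),
            class = "thickness_profiles")
}

#' @export
print.thickness_profiles <- function(x, ...) {
  cat(sprintf("thickness_profiles: %d lines x %d samples (step %.3g px), %d valid\n",
              nrow(x$x), x$n_samples, x$step_px, sum(x$valid)))
  invisible(x)
}

#' Detect the molecular/granular boundary along each profile
#'
#' Grey values are sampled from the preprocessed image along each profile
#' line (not from the potential), smoothed with a 3-sample moving average
#' and differenced; the boundary is the most negative difference (the
#' bright-to-dark transition) provided it exceeds the prominence
#' threshold, refined to the sharpest unsmoothed difference within the
#' smoothing window; ties go to the sample nearest the surface.  Thickness
#' is the arc length from the contour vertex to the boundary sample.
#'
#' @param profiles a `thickness_profiles` object.
#' @param img the [section_image] whose (preprocessed) pixels are sampled.
#' @param prominence minimum drop (grey units per step) for a boundary.
#' @param smooth moving-average window (samples, odd).
#' @return the input object with `grey` (profiles x samples),
#'   `boundary_index` (0-based sample), `thickness_mm`, and updated
#'   `valid` (profiles with no detectable drop are invalidated).
#' @export
detect_boundary <- function(profiles, img, prominence = 0.05, smooth = 3L) {
  stopifnot(inherits(profiles, "thickness_profiles"))
  np <- nrow(profiles$x); L <- profiles$n_samples
  G <- matrix(bilinear(img$pixels, as.vector(profiles$x),
                       as.vector(profiles$y)), np, L)
  Gs <- G
  if (smooth > 1L) {
    half <- (smooth - 1L) %/% 2L
    kern <- rep(1 / smooth, smooth)
    for (i in seq_len(np)) {
      padded <- c(rep(G[i, 1L], half), G[i, ], rep(G[i, L], half))
      Gs[i, ] <- stats::filter(padded, kern, sides = 2L)[(half + 1L):(half + L)]
    }
  }
  D <- Gs[, -1L, drop = FALSE] - Gs[, -L, drop = FALSE]
  bidx <- rep(NA_integer_, np)
  thick <- rep(NA_real_, np)
  valid <- profiles$valid
  half <- (smooth - 1L) %/% 2L
  Draw <- G[, -1L, drop = FALSE] - G[, -L, drop = FALSE]
  for (i in seq_len(np)) {
    if (!valid[i]) next
    d <- D[i, ]
    j <- which.min(d)              # ties: which.min takes the first
    if (!is.finite(d[j]) || d[j] > -prominence) { valid[i] <- FALSE; next }
    # refine on the unsmoothed differences near the smoothed minimum
    lo <- max(1L, j - half); hi <- min(length(d), j + half)
    j <- lo - 1L + which.min(Draw[i, lo:hi])
    bidx[i] <- j                   # 0-based boundary sample index
    thick[i] <- j * profiles$step_px * profiles$mm_per_px
  }
  profiles$grey <- G
  profiles$boundary_index <- bidx
  profiles$thickness_mm <- thick
  profiles$valid <- valid
  profiles
}

#' Per-section molecular-layer thickness
#'
#' Median of the per-profile thicknesses over valid profiles, with the
#' interquartile range and the invalid fraction.
#'
#' @param profiles output of [detect_boundary()].
#' @param min_valid minimum number of valid profiles required.
#' @return list with `thickness_mm` (median), `iqr_mm`, `n_valid`,
#'   `fraction_invalid`.
#' @export
estimate_thickness <- function(profiles, min_valid = 10L) {
  if (is.null(profiles$thickness_mm)) stop("run detect_boundary() first")
  ok <- profiles$valid & !is.na(profiles$thickness_mm)
  if (sum(ok) < min_valid)
    stop("too few valid profiles: ", sum(ok), " < ", min_valid)
  th <- profiles$thickness_mm[ok]
  list(thickness_mm = stats::median(th),
       iqr_mm = stats::IQR(th),
       n_valid = sum(ok),
       fraction_invalid = 1 - sum(ok) / length(ok))
}

#' Resolution quality control for thickness estimation
#'
#' Pixel density of the tissue mask per unit section area; sections whose
#' density falls below the threshold are excluded from thickness
#' estimation (but keep their area/length measurements).  The threshold is
#' applied inclusively: a density exactly at the threshold passes.
#'
#' @param img a [section_image].
#' @param section_area_mm2 section area in mm^2 (computed from the contour
#'   when omitted).
#' @param threshold minimum pixels per mm^2.
#' @return list with `pass`, `density`, `threshold`.
#' @export
qc_pixel_density <- function(img, section_area_mm2 = NULL, threshold = 3.5) {
  stopifnot(inherits(img, "section_image"))
  npx <- sum(img$mask)
  if (npx == 0L) stop("empty mask")
  if (is.null(section_area_mm2))
    section_area_mm2 <- abs(shoelace_area(img$contour$vertices)) *
      img$mm_per_px^2
  if (section_area_mm2 <= 0) stop("section area must be positive")
  density <- npx / section_area_mm2
  list(pass = density >= threshold, density = density,
       threshold = threshold)
}

#' Measure molecular-layer thickness of one section
#'
#' End-to-end wrapper: preprocess, relax the Laplacian potential, trace
#' profiles from a resampled contour, detect boundaries and take the
#' median.
#'
#' @param img a [section_image] with raw pixels.
#' @param spacing contour resampling spacing in mm for profile seeds.
#' @param step_px streamline step (px).
#' @param max_depth_mm profile length cap (mm).
#' @param prominence boundary-detection prominence.
#' @param iterations,tol Laplacian relaxation controls.
#' @param min_valid minimum valid profiles.
#' @return list with `estimate` (see [estimate_thickness()]) and
#'   `profiles`.
#' @export
measure_thickness <- function(img, spacing = 0.05, step_px = 0.5,
                              max_depth_mm = 2, prominence = 0.05,
                              iterations = 2000L, tol = 1e-5,
                              min_valid = 10L) {
  stopifnot(inherits(img, "section_image"))
  pre <- preprocess_image(img$pixels)
  wrk <- section_image(pre, img$mm_per_px,
                       resample_contour(img$contour, spacing), img$mask)
  pot <- relax_laplacian(wrk, iterations = iterations, tol = tol)
  prof <- trace_profiles(pot, wrk, step_px = step_px,
                         max_depth_mm = max_depth_mm)
  prof <- detect_boundary(prof, wrk)
  list(estimate = estimate_thickness(prof, min_valid = min_valid),
       profiles = prof)
}
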