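# Seeded generators for folded section contours with known ground truth.
# The fold geometry is a cosine radial perturbation of a circle,
#   rho(phi) = base_radius + amplitude * cos(k * phi) [+ nested harmonics],
# which gives closed-form control over fold count and amplitude, and a dense
# parametric curve from which true chord/arc folium geometry is computed.

#' Evaluate the run's random expression under a local seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators are pure functions of their arguments.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required; it is never defaulted")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic radial profile of the fold geometry (no noise)
fold_rho <- function(phi, base_radius, n_folds, amplitude, nested_levels) {
  rho <- rep(base_radius, length(phi))
  if (n_folds > 0 && amplitude > 0) {
    for (lev in 0:nested_levels)
      rho <- rho + (amplitude / 3^lev) * cos(n_folds * 3^lev * phi)
  }
  rho
}

#' Generate a folded closed contour with ground truth
#'
#' Produces the closed curve `rho(phi) = base_radius + amplitude*cos(k*phi)`
#' (nesting adds harmonics at `k*3^level` with amplitude divided by 3 per
#' level, emulating folds-on-folds), optionally perturbed by smooth radial
#' noise, sampled uniformly in arc length.  Alongside the contour it emits
#' per-vertex ground-truth labels (gyrus at radial maxima neighbourhoods,
#' sulcus at minima, wall between) and the true folial geometry: for each
#' pair of adjacent radial minima of the noise-free curve, the straight-line
#' chord and along-curve arc length between them.
#'
#' @param base_radius circle radius in mm.
#' @param n_folds fold count `k` (0 for a circle).
#' @param amplitude radial fold amplitude in mm; the total harmonic
#'   amplitude must stay below `base_radius` so the curve remains simple.
#' @param nested_levels integer >= 0; harmonics added on top of the base fold.
#' @param noise_sd standard deviation (mm) of smooth radial noise.
#' @param mm_per_px calibration written into the returned contour.
#' @param seed mandatory integer seed.
#' @param n_vertices number of arc-length-uniform vertices; default targets
#'   0.05 mm spacing.
#' @param label contour label.
#' @return list with `contour` (a calibrated [section_contour]), `labels`
#'   (per-vertex `"gyrus"/"sulcus"/"wall"`), `folia` (data frame of true
#'   chord/arc per folium, mm) and `params`.
#' @export
generate_folded_contour <- function(base_radius, n_folds, amplitude,
                                    nested_levels = 0L, noise_sd = 0,
                                    mm_per_px = 0.02, seed,
                                    n_vertices = NULL, label = "synthetic") {
  stopifnot(base_radius > 0, n_folds >= 0, amplitude >= 0,
            nested_levels >= 0, noise_sd >= 0, mm_per_px > 0)
  amp_total <- if (n_folds > 0) amplitude * sum(1 / 3^(0:nested_levels)) else 0
  if (amp_total + 4 * noise_sd >= base_radius)
    stop("amplitude/noise too large: contour would self-intersect")
  n_dense <- max(4096L, 64L * max(1L, n_folds) * 3^nested_levels)
  phi <- seq(0, 2 * pi, length.out = n_dense + 1L)[-(n_dense + 1L)]
  rho_det <- fold_rho(phi, base_radius, n_folds, amplitude, nested_levels)
  rho <- rho_det
  if (noise_sd > 0) {
    # smooth periodic noise: iid control points interpolated by periodic
    # spline, so curvature stays well defined at the sampling scale
    rho <- rho + with_seed(seed, {
      nctl <- max(24L, 4L * max(1L, n_folds))
      ctl <- stats::rnorm(nctl, 0, noise_sd)
      phic <- seq(0, 2 * pi, length.out = nctl + 1L)
      stats::spline(phic, c(ctl, ctl[1L]), method = "periodic",
                    xout = phi)$y
    })
  }
  xy <- cbind(rho * cos(phi), rho * sin(phi))
  # cumulative arc length of the dense polyline, then uniform resampling
  seg <- sqrt(rowSums((xy[c(2:n_dense, 1L), ] - xy)^2))
  s <- c(0, cumsum(seg))              # length n_dense + 1, closes the curve
  per <- s[n_dense + 1L]
  if (is.null(n_vertices)) n_vertices <- max(64L, round(per / 0.05))
  t_out <- seq(0, per, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  xs <- c(xy[, 1L], xy[1L, 1L]); ys <- c(xy[, 2L], xy[1L, 2L])
  vx <- stats::approx(s, xs, xout = t_out)$y
  vy <- stats::approx(s, ys, xout = t_out)$y
  phi_out <- stats::approx(s, c(phi, 2 * pi), xout = t_out)$y

  truth <- fold_ground_truth(phi_out, base_radius, n_folds, amplitude,
                             nested_levels)
  # shift into positive pixel space with a margin
  margin_mm <- 2 * mm_per_px
  vpx <- cbind(vx - min(vx) + margin_mm, vy - min(vy) + margin_mm) / mm_per_px
  ct <- section_contour(vpx, mm_per_px = mm_per_px, label = label)
  # CCW normalisation may reverse vertex order; keep truth aligned
  if (shoelace_area(cbind(vpx[, 1L], vpx[, 2L])) < 0) {
    truth$labels <- rev(truth$labels)
  }
  list(contour = ct, labels = truth$labels, folia = truth$folia,
       params = list(base_radius = base_radius, n_folds = n_folds,
                     amplitude = amplitude, nested_levels = nested_levels,
                     noise_sd = noise_sd, mm_per_px = mm_per_px, seed = seed,
                     perimeter_true = per))
}

# Ground-truth labels and folium geometry from the noise-free radial profile.
fold_ground_truth <- function(phi_out, base_radius, n_folds, amplitude,
                              nested_levels) {
  n <- length(phi_out)
  if (n_folds == 0 || amplitude == 0) {
    return(list(labels = rep("gyrus", n),
                folia = data.frame(phi_left = numeric(0),
                                   phi_right = numeric(0),
                                   chord = numeric(0), arc = numeric(0))))
  }
  ngrid <- max(8192L, 256L * n_folds * 3^nested_levels)
  pg <- seq(0, 2 * pi, length.out = ngrid + 1L)[-(ngrid + 1L)]
  rg <- fold_rho(pg, base_radius, n_folds, amplitude, nested_levels)
  nxt <- c(2:ngrid, 1L); prv <- c(ngrid, 1:(ngrid - 1L))
  ismax <- rg > rg[nxt] & rg > rg[prv]
  ismin <- rg < rg[nxt] & rg < rg[prv]
  phimax <- pg[ismax]; phimin <- pg[ismin]
  # angular half-width of the gyrus/sulcus neighbourhoods: 15% of the
  # (finest) fold period either side of the extremum
  w <- 0.15 * 2 * pi / n_folds
  circ_dist <- function(a, b) {
    d <- abs(outer(a, b, "-")) %% (2 * pi)
    pmin(d, 2 * pi - d)
  }
  dmax <- apply(circ_dist(phi_out, phimax), 1L, min)
  dmin <- apply(circ_dist(phi_out, phimin), 1L, min)
  labels <- rep("wall", length(phi_out))
  labels[dmax <= w] <- "gyrus"
  labels[dmin <= w] <- "sulcus"

  # true folium geometry between adjacent radial minima, by dense quadrature
  phimin <- sort(phimin)
  k <- length(phimin)
  folia <- data.frame(phi_left = phimin,
                      phi_right = c(phimin[-1L], phimin[1L] + 2 * pi))
  pt <- function(p) {
    r <- fold_rho(p, base_radius, n_folds, amplitude, nested_levels)
    cbind(r * cos(p), r * sin(p))
  }
  folia$chord <- sqrt(rowSums((pt(folia$phi_right) - pt(folia$phi_left))^2))
  folia$arc <- vapply(seq_len(k), function(i) {
    pp <- seq(folia$phi_left[i], folia$phi_right[i], length.out = 2048L)
    xy <- pt(pp)
    sum(sqrt(rowSums(diff(xy)^2)))
  }, numeric(1L))
  list(labels = labels, folia = folia)
}
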