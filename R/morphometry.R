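# Folding measurements on a calibrated contour: arc-length resampling,
# discrete mean curvature, multiscale curvature signatures, gyrus/sulcus/
# wall classification, folium extraction (width and perimeter), section
# metrics (area, length, gyrification index) and the buckling-wavelength
# prediction.

#' Resample a contour uniformly in arc length
#'
#' @param contour calibrated, closed [section_contour].
#' @param spacing target vertex spacing in mm; must be positive and finer
#'   than an eighth of the perimeter.
#' @return a [section_contour] with vertices equally spaced in arc length
#'   (the count is rounded so the spacing is exactly uniform).
#' @export
resample_contour <- function(contour, spacing = 0.05) {
  stopifnot(inherits(contour, "section_contour"), contour$closed)
  stop_if_uncalibrated(contour)
  per_mm <- contour_perimeter_px(contour) * contour$mm_per_px
  if (spacing <= 0 || spacing >= per_mm / 8)
    stop("spacing must be positive and < perimeter/8 (perimeter ",
         signif(per_mm, 4), " mm)")
  v <- contour$vertices
  n <- nrow(v)
  seg <- sqrt(rowSums((v[c(2:n, 1L), , drop = FALSE] - v)^2))
  s <- c(0, cumsum(seg))
  per_px <- s[n + 1L]
  n_new <- max(8L, round(per_mm / spacing))
  t_out <- seq(0, per_px, length.out = n_new + 1L)[-(n_new + 1L)]
  xs <- c(v[, 1L], v[1L, 1L]); ys <- c(v[, 2L], v[1L, 2L])
  out <- cbind(stats::approx(s, xs, xout = t_out)$y,
               stats::approx(s, ys, xout = t_out)$y)
  section_contour(out, mm_per_px = contour$mm_per_px,
                  label = contour$label)
}

#' Discrete mean curvature along a resampled contour
#'
#' Central-difference curvature `(x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)`
#' with arc-length parameterisation on the uniformly resampled chain, in
#' 1/mm; positive on locally convex arcs of a counter-clockwise contour.
#'
#' @param contour calibrated, uniformly resampled [section_contour].
#' @return object of class `curvature_signature` holding `kappa`
#'   (per-vertex curvature, 1/mm), the arc `spacing` (mm) and the contour
#'   `perimeter` (mm); the multiscale `signature` slot is filled by
#'   [multiscale_signature()].
#' @export
mean_curvature <- function(contour) {
  stopifnot(inherits(contour, "section_contour"), contour$closed)
  stop_if_uncalibrated(contour)
  v <- contour$vertices * contour$mm_per_px
  n <- nrow(v)
  seg <- sqrt(rowSums((v[c(2:n, 1L), , drop = FALSE] - v)^2))
  if (any(seg == 0)) stop("duplicate consecutive vertices")
  h <- mean(seg)
  if (stats::sd(seg) > 0.05 * h)
    warning("contour is not uniformly resampled; curvature may be biased")
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  d1 <- (v[nxt, , drop = FALSE] - v[prv, , drop = FALSE]) / (2 * h)
  d2 <- (v[nxt, , drop = FALSE] - 2 * v + v[prv, , drop = FALSE]) / h^2
  kappa <- (d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]) /
    (rowSums(d1^2))^1.5
  structure(list(kappa = kappa, spacing = h,
                 perimeter = sum(seg), n = n,
                 signature = NULL, scales = NULL),
            class = "curvature_signature")
}

#' Default smoothing scales for the multiscale signature
#'
#' A geometric progression of 10 arc-length smoothing widths from 0.5% to
#' 16% of the contour perimeter, spanning folium-scale to lobule-scale
#' structure across species sizes.
#'
#' @param perimeter contour perimeter in mm.
#' @return increasing numeric vector of 10 scales (mm).
#' @export
default_signature_scales <- function(perimeter) {
  exp(seq(log(0.005 * perimeter), log(0.16 * perimeter), length.out = 10L))
}

#' Multiscale curvature signature
#'
#' Circular Gaussian smoothing of the curvature sequence along arc length
#' at each of 10 strictly increasing scales, giving a 10-column signature
#' per vertex.  The smoothing kernel is normalised so the circular mean of
#' the curvature is conserved exactly.
#'
#' @param curv a `curvature_signature` from [mean_curvature()].
#' @param scales 10 strictly increasing smoothing sigmas in mm
#'   (default [default_signature_scales()]).
#' @return the `curvature_signature` with `signature` (n x 10) and
#'   `scales` filled.
#' @export
multiscale_signature <- function(curv, scales = NULL) {
  stopifnot(inherits(curv, "curvature_signature"))
  if (is.null(scales)) scales <- default_signature_scales(curv$perimeter)
  if (length(scales) != 10L || any(diff(scales) <= 0))
    stop("scales must be 10 strictly increasing values")
  n <- curv$n
  sig <- matrix(NA_real_, n, 10L)
  fk <- stats::fft(curv$kappa)
  # circular arc-length offsets of each sample from the kernel centre
  off <- curv$spacing * pmin(0:(n - 1L), n - (0:(n - 1L)))
  for (j in seq_along(scales)) {
    kern <- stats::dnorm(off, 0, scales[j])
    kern <- kern / sum(kern)
    sig[, j] <- Re(stats::fft(fk * stats::fft(kern), inverse = TRUE)) / n
  }
  curv$signature <- sig
  curv$scales <- scales
  curv
}

# signature column used by the rule classifier and the sulcus anchors:
# the scale whose median-centred column has the largest robust spread,
# i.e. the scale that best captures the contour's folding
rule_scale_index <- function(sig) {
  if (is.null(sig$signature)) stop("run multiscale_signature() first")
  mads <- apply(sig$signature, 2L, stats::mad)
  which.max(mads)
}

#' Classify contour vertices as gyrus, sulcus or wall
#'
#' Two modes.  `"rule"`: thresholds the median-centred smoothed curvature
#' (at the scale with the largest robust spread) at +/- `tau`, by default
#' a quarter of the column's MAD floored at 5% of the contour's mean
#' turning curvature `2*pi/perimeter` (so convex contours classify as
#' wall/gyrus only); convex beyond the threshold is gyrus, concave beyond
#' is sulcus, the rest wall.  `"forest"`: a random forest trained on seeded synthetic
#' rosette fixtures with ground-truth labels (see
#' [train_fold_classifier()]), applied to the median-centred, MAD-scaled
#' signature.
#'
#' @param sig a `curvature_signature` with the 10-column signature.
#' @param mode `"rule"` or `"forest"`.
#' @param tau rule-mode threshold in 1/mm (default `0.25 * mad`).
#' @param forest optional [train_fold_classifier()] result; when absent, a
#'   default forest is trained once per session and cached.
#' @return character vector of per-vertex classes.
#' @export
classify_vertices <- function(sig, mode = c("rule", "forest"), tau = NULL,
                              forest = NULL) {
  mode <- match.arg(mode)
  if (is.null(sig$signature)) stop("run multiscale_signature() first")
  if (mode == "rule") {
    s <- sig$signature[, rule_scale_index(sig)]
    s <- s - stats::median(s)
    if (is.null(tau))
      tau <- max(0.25 * stats::mad(s), 0.05 * 2 * pi / sig$perimeter)
    cls <- rep("wall", length(s))
    cls[s > tau] <- "gyrus"
    cls[s < -tau] <- "sulcus"
    return(cls)
  }
  if (is.null(forest)) forest <- cached_fold_classifier()
  as.character(stats::predict(forest,
    newdata = as.data.frame(signature_features(sig))))
}

# classifier features: each signature column centred on its median and
# scaled by its MAD, making the features invariant to contour size and to
# the baseline curvature of the unfolded envelope
signature_features <- function(sig) {
  S <- sig$signature
  floor_sc <- 0.05 * 2 * pi / sig$perimeter  # guards flat (convex) inputs
  Z <- vapply(seq_len(ncol(S)), function(j) {
    md <- stats::median(S[, j]); sc <- max(stats::mad(S[, j]), floor_sc)
    (S[, j] - md) / sc
  }, numeric(nrow(S)))
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  Z
}

.foliametry_env <- new.env(parent = emptyenv())

cached_fold_classifier <- function() {
  if (is.null(.foliametry_env$forest))
    .foliametry_env$forest <- train_fold_classifier()
  .foliametry_env$forest
}

#' Train the gyrus/sulcus/wall random forest
#'
#' Training corpus: seeded rosette fixtures spanning fold counts 4..20,
#' relative amplitudes 0.03..0.2, radial noise up to 5% of the amplitude
#' and 0 or 1 nesting level, labelled by the generator's ground truth.
#' Signature columns are median-centred and MAD-scaled per contour, so the
#' features are invariant to overall contour size and to the baseline
#' curvature of the unfolded envelope.
#'
#' @param n_fixtures number of training contours.
#' @param seed classifier and corpus seed.
#' @param ntree random-forest size.
#' @return a `randomForest` classifier over the 10 signature columns.
#' @export
train_fold_classifier <- function(n_fixtures = 200L, seed = 42L,
                                  ntree = 200L) {
  grid <- with_seed(seed, data.frame(
    k = sample(4:20, n_fixtures, replace = TRUE),
    rel_amp = stats::runif(n_fixtures, 0.03, 0.2),
    noise = stats::runif(n_fixtures, 0, 0.05),
    nest = sample(0:1, n_fixtures, replace = TRUE),
    seed = sample.int(1e6, n_fixtures)))
  feats <- vector("list", n_fixtures)
  labs <- vector("list", n_fixtures)
  for (i in seq_len(n_fixtures)) {
    g <- grid[i, ]
    fc <- generate_folded_contour(base_radius = 10, n_folds = g$k,
                                  amplitude = g$rel_amp * 10,
                                  nested_levels = g$nest,
                                  noise_sd = g$noise * g$rel_amp * 10,
                                  mm_per_px = 0.05, seed = g$seed,
                                  n_vertices = 768L)
    sig <- suppressWarnings(multiscale_signature(mean_curvature(fc$contour)))
    feats[[i]] <- signature_features(sig)
    labs[[i]] <- fc$labels
  }
  Xf <- do.call(rbind, feats)
  yf <- factor(unlist(labs), levels = c("gyrus", "sulcus", "wall"))
  with_seed(seed, randomForest::randomForest(
    x = as.data.frame(Xf), y = yf, ntree = ntree))
}

#' Extract folia from classified vertices
#'
#' Each maximal circular run of sulcus vertices contributes one anchor:
#' its most negative mid-scale-curvature vertex (ties broken by lowest
#' index).  Consecutive anchors enclosing at least one gyrus vertex bound
#' one folium; arcs without an interior gyrus vertex are merged into the
#' following arc.  Folial width is the Euclidean distance between the two
#' anchors, folial perimeter the arc length between them, both in mm; the
#' per-section summary is the median over folia.
#'
#' @param contour calibrated resampled [section_contour].
#' @param classes per-vertex classes from [classify_vertices()].
#' @param sig the `curvature_signature` used for classification (supplies
#'   anchor curvature).
#' @return object of class `folium_set`: data frame `folia` with columns
#'   `left`, `right` (anchor vertex indices), `width`, `perimeter`, plus
#'   `median_width`, `median_perimeter`, `n_folia` and `unfolded` flag.
#' @export
extract_folia <- function(contour, classes, sig) {
  stopifnot(inherits(contour, "section_contour"))
  stop_if_uncalibrated(contour)
  n <- nrow(contour$vertices)
  stopifnot(length(classes) == n)
  curv <- if (!is.null(sig$signature))
    sig$signature[, rule_scale_index(sig)] else sig$kappa
  runs <- circular_runs(classes == "sulcus")
  if (length(runs) < 2L) {
    return(structure(list(folia = data.frame(left = integer(0),
                                             right = integer(0),
                                             width = numeric(0),
                                             perimeter = numeric(0)),
                          median_width = NA_real_,
                          median_perimeter = NA_real_,
                          n_folia = 0L, unfolded = TRUE),
                     class = "folium_set"))
  }
  anchors <- vapply(runs, function(ix) ix[which.min(curv[ix])], integer(1L))
  anchors <- sort(anchors)
  v <- contour$vertices * contour$mm_per_px
  seg <- sqrt(rowSums((v[c(2:n, 1L), , drop = FALSE] - v)^2))
  cum <- c(0, cumsum(seg))               # arc length from vertex 1
  arc_between <- function(i, j) {        # forward arc i -> j (circular)
    if (j > i) cum[j] - cum[i] else cum[n + 1L] - cum[i] + cum[j]
  }
  gyrus_between <- function(i, j) {      # any gyrus strictly inside (i, j)
    ix <- if (j > i + 1L) (i + 1L):(j - 1L)
    else if (j <= i) c(if (i < n) (i + 1L):n, if (j > 1L) 1:(j - 1L))
    else integer(0)
    any(classes[ix] == "gyrus")
  }
  k <- length(anchors)
  left <- integer(0); right <- integer(0)
  L <- anchors[1L]
  for (a in c(anchors[-1L], anchors[1L])) {
    if (gyrus_between(L, a)) {
      left <- c(left, L); right <- c(right, a)
      L <- a
    } # else: merge this arc into the following one
  }
  folia <- data.frame(left = left, right = right)
  folia$width <- sqrt(rowSums((v[folia$right, , drop = FALSE] -
                                 v[folia$left, , drop = FALSE])^2))
  folia$perimeter <- mapply(arc_between, folia$left, folia$right)
  structure(list(folia = folia,
                 median_width = stats::median(folia$width),
                 median_perimeter = stats::median(folia$perimeter),
                 n_folia = nrow(folia), unfolded = nrow(folia) == 0L),
            class = "folium_set")
}

#' @export
print.folium_set <- function(x, ...) {
  if (x$unfolded) cat("folium_set: unfolded contour (0 folia)\n")
  else cat(sprintf(
    "folium_set: %d folia, median width %.4g mm, median perimeter %.4g mm\n",
    x$n_folia, x$median_width, x$median_perimeter))
  invisible(x)
}

# maximal circular runs of TRUE in a logical vector, as index vectors
circular_runs <- function(flag) {
  n <- length(flag)
  if (!any(flag)) return(list())
  if (all(flag)) return(list(seq_len(n)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(function(s, e) s:e, starts[r$values], ends[r$values])
  # merge a wrap-around run
  if (flag[1L] && flag[n] && length(runs) > 1L) {
    runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
    runs[[length(runs)]] <- NULL
  }
  runs
}

#' Section area, length and gyrification index
#'
#' Area by the shoelace formula and perimeter of the pial contour, both
#' calibrated to mm; the gyrification index is the ratio of the contour
#' perimeter to the perimeter of its convex hull (the idealised unfolded
#' envelope adopted here).
#'
#' @param contour calibrated, simple, closed [section_contour].
#' @param check_simple verify non-self-intersection first.
#' @return object of class `section_metrics` with `area` (mm^2), `length`
#'   (mm) and `gyrification`.
#' @export
section_metrics <- function(contour, check_simple = TRUE) {
  stopifnot(inherits(contour, "section_contour"), contour$closed)
  stop_if_uncalibrated(contour)
  if (check_simple && !is_simple_polygon(contour$vertices))
    stop("contour polygon is self-intersecting")
  v <- contour$vertices
  area <- abs(shoelace_area(v)) * contour$mm_per_px^2
  len <- contour_perimeter_px(contour) * contour$mm_per_px
  hull <- v[grDevices::chull(v), , drop = FALSE]
  nh <- nrow(hull)
  hlen <- sum(sqrt(rowSums((hull[c(2:nh, 1L), , drop = FALSE] -
                              hull)^2))) * contour$mm_per_px
  structure(list(area = area, length = len, gyrification = len / hlen),
            class = "section_metrics")
}

#' @export
print.section_metrics <- function(x, ...) {
  cat(sprintf("area %.4f mm^2, length %.4f mm, g = %.4f\n",
              x$area, x$length, x$gyrification))
  invisible(x)
}

#' Predicted buckling wavelength of a growing cortical layer
#'
#' The thin-layer buckling prediction `lambda = 2 pi t (mu / (3 mu_s))^(1/3)`
#' relating folding wavelength to the thickness `t` of the expanding layer
#' and the layer/substrate stiffness ratio `mu/mu_s`.
#'
#' @param t expanding-layer thickness in mm (>= 0).
#' @param stiffness_ratio `mu / mu_s` (> 0), 1 when layer and substrate
#'   are equally stiff.
#' @return object of class `wavelength_model` with fields `t`,
#'   `stiffness_ratio` and `lambda` (mm).
#' @export
predicted_folding_wavelength <- function(t, stiffness_ratio = 1) {
  if (!is.numeric(t) || any(t < 0)) stop("t must be >= 0")
  if (!is.numeric(stiffness_ratio) || any(stiffness_ratio <= 0))
    stop("stiffness_ratio must be > 0")
  lambda <- 2 * pi * t * (stiffness_ratio / 3)^(1 / 3)
  structure(list(t = t, stiffness_ratio = stiffness_ratio,
                 lambda = lambda),
            class = "wavelength_model")
}

#' @export
print.wavelength_model <- function(x, ...) {
  cat(sprintf("predicted folding wavelength %.4g mm (t = %.4g mm, mu/mu_s = %.4g)\n",
              x$lambda, x$t, x$stiffness_ratio))
  invisible(x)
}

#' Full morphometry of one calibrated contour
#'
#' Convenience wrapper: resample, curvature, multiscale signature,
#' classification, folium extraction and section metrics in one call.
#'
#' @param contour calibrated closed [section_contour].
#' @param spacing resampling spacing in mm.
#' @param scales signature scales (default [default_signature_scales()]).
#' @param classifier `"rule"` or `"forest"`.
#' @param tau rule-mode threshold override.
#' @return list with `metrics` ([section_metrics]), `folia`
#'   ([extract_folia]), `classes`, `signature`, and the resampled contour.
#' @export
measure_contour <- function(contour, spacing = 0.05, scales = NULL,
                            classifier = "rule", tau = NULL) {
  rc <- resample_contour(contour, spacing)
  sig <- multiscale_signature(mean_curvature(rc), scales)
  cls <- classify_vertices(sig, mode = classifier, tau = tau)
  fol <- extract_folia(rc, cls, sig)
  list(metrics = section_metrics(rc, check_simple = FALSE), folia = fol,
       classes = cls, signature = sig, contour = rc)
}
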