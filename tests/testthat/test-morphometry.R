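test_that("resampling is uniform in arc length and conserves perimeter", {
  ct <- circle_contour(radius_mm = 100 / (2 * pi), mm_per_px = 0.05,
                       n = 16384L)
  rc <- resample_contour(ct, spacing = 1)
  expect_equal(nrow(rc$vertices), 100L)
  v <- rc$vertices * rc$mm_per_px
  gaps <- sqrt(rowSums((v[c(2:100, 1), ] - v)^2))
  expect_true(all(abs(gaps - gaps[1]) < 1e-6))

  sq <- square_contour(10, 0.1)
  rs <- resample_contour(sq, spacing = 0.1)
  per <- foliametry:::contour_perimeter_px(rs) * rs$mm_per_px
  expect_equal(per, 40, tolerance = 1e-3)

  expect_error(resample_contour(section_contour(sq$vertices), 0.1),
               "uncalibrated")
  expect_error(resample_contour(sq, 10), "spacing")
})

test_that("discrete curvature matches closed forms", {
  rc <- resample_contour(circle_contour(10, n = 8192L), 0.05)
  k <- mean_curvature(rc)
  expect_true(all(abs(k$kappa - 0.1) < 0.001))

  # analytic ellipse curvature at the recovered parameter of each vertex
  re <- resample_contour(ellipse_contour(10, 5, n = 8192L), 0.05)
  ke <- mean_curvature(re)
  v <- re$vertices * re$mm_per_px
  v <- sweep(v, 2L, (apply(v, 2L, max) + apply(v, 2L, min)) / 2)
  tt <- atan2(v[, 2] / 5, v[, 1] / 10)
  kappa_true <- (10 * 5) / (100 * sin(tt)^2 + 25 * cos(tt)^2)^1.5
  expect_lt(max(abs(ke$kappa - kappa_true) / kappa_true), 0.01)

  # straight run of a rounded rectangle has zero curvature
  r <- 2; L <- 10
  corner <- function(cx, cy, from) {
    a <- seq(from, from + pi / 2, length.out = 25L)[-25L]
    cbind(cx + r * cos(a), cy + r * sin(a))
  }
  v <- rbind(corner(L, 0, -pi / 2), corner(L, L, 0),
             corner(0, L, pi / 2), corner(0, 0, pi))
  rr <- resample_contour(section_contour(v / 0.05, mm_per_px = 0.05), 0.05)
  kr <- mean_curvature(rr)
  mid <- rr$vertices[, 2] * 0.05 < -r / 2 &
    abs(rr$vertices[, 1] * 0.05 - (L / 2 + r)) < L / 4
  flat <- which(abs(kr$kappa) < 1e-6)
  expect_gt(length(flat), 50L)
})

test_that("multiscale smoothing conserves mean and attenuates harmonics", {
  rc <- resample_contour(circle_contour(10, n = 8192L), 0.05)
  sig <- multiscale_signature(mean_curvature(rc))
  expect_identical(dim(sig$signature), c(sig$n, 10L))
  expect_true(all(diff(sig$scales) > 0))
  # constant curvature is a fixed point of the smoothing
  expect_true(all(abs(sig$signature - 0.1) < 1e-3))
  # circular mean conserved at every scale
  for (j in 1:10)
    expect_equal(mean(sig$signature[, j]), mean(sig$kappa),
                 tolerance = 1e-9)

  # single-harmonic input: each column attenuated by exp(-(sigma k)^2/2)
  n <- 512L; P <- 100; h <- P / n
  kwav <- 2 * pi * 8 / P
  curv <- structure(list(kappa = cos(kwav * h * (0:(n - 1L))), spacing = h,
                         perimeter = P, n = n, signature = NULL,
                         scales = NULL),
                    class = "curvature_signature")
  scales <- seq(0.5, 5, length.out = 10L)
  sm <- multiscale_signature(curv, scales)
  for (j in c(3L, 6L, 10L)) {
    pred <- exp(-(scales[j] * kwav)^2 / 2)
    got <- max(sm$signature[, j])
    expect_equal(got, pred, tolerance = 0.02)
  }
  # zero-mean signal keeps zero mean at the largest scale
  expect_lt(abs(mean(sm$signature[, 10L])), 1e-9)

  expect_error(multiscale_signature(curv, scales[1:4]), "10")
})

test_that("vertex classification finds no sulci on convex contours", {
  rc <- resample_contour(circle_contour(10), 0.05)
  sig <- multiscale_signature(mean_curvature(rc))
  expect_false(any(classify_vertices(sig, "rule") == "sulcus"))
  rf <- train_fold_classifier(n_fixtures = 30L, seed = 42L, ntree = 60L)
  expect_false(any(classify_vertices(sig, "forest", forest = rf) ==
                     "sulcus"))
})

test_that("forest classification agrees with generator ground truth", {
  rf <- train_fold_classifier(n_fixtures = 30L, seed = 42L, ntree = 60L)
  ro <- generate_folded_contour(10, 8, 1, mm_per_px = 0.02, seed = 2)
  sig <- multiscale_signature(mean_curvature(ro$contour))
  cls <- classify_vertices(sig, "forest", forest = rf)
  expect_gte(mean(cls == ro$labels), 0.95)
})

test_that("classification is invariant to rigid motion and start shift", {
  ro <- generate_folded_contour(10, 8, 1, mm_per_px = 0.02, seed = 2)
  sig <- multiscale_signature(mean_curvature(ro$contour))
  cls <- classify_vertices(sig, "rule")
  # rotate the contour by 30 degrees about its centroid
  v <- ro$contour$vertices
  cen <- colMeans(v)
  a <- pi / 6
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  vr <- sweep(sweep(v, 2, cen) %*% Rm, 2, cen + 500, "+")
  ctr <- section_contour(vr, mm_per_px = ro$contour$mm_per_px)
  clsr <- classify_vertices(multiscale_signature(mean_curvature(ctr)),
                            "rule")
  expect_gte(mean(cls == clsr), 0.999)
  # shift the starting vertex
  sh <- 101L
  vs <- v[c(sh:nrow(v), 1:(sh - 1L)), ]
  cts <- section_contour(vs, mm_per_px = ro$contour$mm_per_px)
  clss <- classify_vertices(multiscale_signature(mean_curvature(cts)),
                            "rule")
  expect_identical(clss, cls[c(sh:length(cls), 1:(sh - 1L))])
  # reversed (clockwise) input is renormalised to the same polygon
  ctw <- section_contour(v[nrow(v):1, ], mm_per_px = ro$contour$mm_per_px)
  expect_identical(ctw$vertices, v)
})

test_that("folium extraction recovers the generator's folium geometry", {
  ro <- generate_folded_contour(10, 8, 1, mm_per_px = 0.02, seed = 2)
  m <- measure_contour(ro$contour, spacing = 0.05)
  expect_equal(m$folia$n_folia, 8L)
  orc <- rosette_truth_oracle(10, 8, 1)
  expect_lt(abs(m$folia$median_width - orc$chord) / orc$chord, 0.05)
  expect_lt(abs(m$folia$median_perimeter - orc$arc) / orc$arc, 0.05)
  expect_true(all(m$folia$folia$width <= m$folia$folia$perimeter))

  # circle: unfolded flag, no exception
  mc <- measure_contour(circle_contour(10), spacing = 0.05)
  expect_true(mc$folia$unfolded)
  expect_equal(mc$folia$n_folia, 0L)
})

test_that("folium count equals the generator fold count across k", {
  for (k in c(3L, 6L, 12L, 18L, 24L)) {
    ro <- generate_folded_contour(10, k, 0.08 * 10 * 8 / k,
                                  mm_per_px = 0.02, seed = k)
    m <- measure_contour(ro$contour, spacing = 0.05)
    expect_equal(m$folia$n_folia, k)
  }
})

test_that("folial medians are stable under refined resampling", {
  ro <- generate_folded_contour(10, 8, 1, mm_per_px = 0.02, seed = 2)
  m1 <- measure_contour(ro$contour, spacing = 0.05)
  m2 <- measure_contour(ro$contour, spacing = 0.025)
  expect_lt(abs(m1$folia$median_width - m2$folia$median_width) /
              m1$folia$median_width, 0.02)
  expect_lt(abs(m1$folia$median_perimeter - m2$folia$median_perimeter) /
              m1$folia$median_perimeter, 0.02)
})

test_that("section metrics match circle, calibration square and oracle g", {
  mc <- section_metrics(resample_contour(circle_contour(10), 0.05))
  expect_equal(mc$area, pi * 100, tolerance = 0.5 / (pi * 100))
  expect_equal(mc$length, 2 * pi * 10, tolerance = 0.05 / (2 * pi * 10))
  expect_equal(mc$gyrification, 1, tolerance = 0.002)

  ms <- section_metrics(square_contour(10, 0.1))
  expect_equal(ms$area, 100)
  expect_equal(ms$length, 40)

  # rosette gyrification against a dense numerical curve/hull oracle
  ro <- generate_folded_contour(10, 8, 1, mm_per_px = 0.02, seed = 2)
  mr <- section_metrics(ro$contour)
  phi <- seq(0, 2 * pi, length.out = 20001L)
  rho <- 10 + cos(8 * phi)
  xy <- cbind(rho * cos(phi), rho * sin(phi))
  curve_len <- sum(sqrt(rowSums(diff(xy)^2)))
  hull <- xy[grDevices::chull(xy), ]
  hull_len <- sum(sqrt(rowSums((hull[c(2:nrow(hull), 1), ] - hull)^2)))
  expect_equal(mr$gyrification, curve_len / hull_len, tolerance = 0.01)
  expect_gte(mr$gyrification, 1)

  # self-intersecting contour is refused
  bow <- section_contour(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)),
                         mm_per_px = 1)
  expect_error(section_metrics(bow), "self-intersecting")
})

test_that("morphometry scales correctly under spatial rescaling", {
  ro <- generate_folded_contour(10, 8, 1, mm_per_px = 0.02, seed = 2)
  m1 <- measure_contour(ro$contour, spacing = 0.05)
  ct2 <- ro$contour
  ct2$mm_per_px <- ct2$mm_per_px * 3       # same pixels, 3x the physical size
  m2 <- measure_contour(ct2, spacing = 0.15)
  expect_equal(m2$folia$median_width, 3 * m1$folia$median_width,
               tolerance = 0.02)
  expect_equal(m2$folia$median_perimeter, 3 * m1$folia$median_perimeter,
               tolerance = 0.02)
  expect_equal(m2$metrics$length, 3 * m1$metrics$length, tolerance = 1e-6)
  expect_equal(m2$metrics$area, 9 * m1$metrics$area, tolerance = 1e-6)
})

test_that("buckling wavelength formula reproduces its reference values", {
  expect_equal(signif(predicted_folding_wavelength(2.5, 1)$lambda, 3),
               10.9)
  expect_equal(signif(predicted_folding_wavelength(0.2, 1)$lambda, 2),
               0.87)
  expect_identical(predicted_folding_wavelength(0, 1)$lambda, 0)
  expect_error(predicted_folding_wavelength(-1, 1), ">= 0")
  expect_error(predicted_folding_wavelength(1, 0), "> 0")
})
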