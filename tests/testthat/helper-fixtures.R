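# Shared in-code fixtures: parametric contours with known geometry and
# small trees.  All fixtures are built at test time; nothing is stored.

circle_contour <- function(radius_mm = 10, mm_per_px = 0.05, n = 1024L,
                           label = "circle") {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r_px <- radius_mm / mm_per_px
  v <- cbind(r_px * cos(phi) + r_px + 2, r_px * sin(phi) + r_px + 2)
  section_contour(v, mm_per_px = mm_per_px, label = label)
}

ellipse_contour <- function(a_mm = 10, b_mm = 5, mm_per_px = 0.05,
                            n = 2048L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  v <- cbind(a_mm * cos(phi), b_mm * sin(phi)) / mm_per_px
  v <- sweep(v, 2L, apply(v, 2L, min)) + 2
  section_contour(v, mm_per_px = mm_per_px, label = "ellipse")
}

square_contour <- function(side_mm = 10, mm_per_px = 0.1) {
  s <- side_mm / mm_per_px
  v <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)) + 2
  section_contour(v, mm_per_px = mm_per_px, label = "square")
}

star_tree <- function(n, bl = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# dense parametric oracle for the rosette: exact radial minima, chord by
# direct evaluation, arc by adaptive quadrature (independent of the
# generator's polyline machinery)
rosette_truth_oracle <- function(base_radius, k, amplitude) {
  rho <- function(p) base_radius + amplitude * cos(k * p)
  pt <- function(p) c(rho(p) * cos(p), rho(p) * sin(p))
  phimin <- (2 * seq_len(k) - 1) * pi / k
  chord <- sqrt(sum((pt(phimin[2L]) - pt(phimin[1L]))^2))
  ds <- function(p) sqrt(rho(p)^2 + (-amplitude * k * sin(k * p))^2)
  arc <- stats::integrate(ds, phimin[1L], phimin[2L],
                          rel.tol = 1e-10)$value
  list(chord = chord, arc = arc)
}

# memoised layered-disk fixture shared by the thickness and acceptance
# suites
.disk_cache <- new.env(parent = emptyenv())
disk_image <- function(t_mm, mm_per_px = 0.01, radius = 1.8, blur = 1,
                       noise = 0.02, seed = 5) {
  key <- paste(t_mm, mm_per_px, radius, blur, noise, seed, sep = "|")
  if (is.null(.disk_cache[[key]])) {
    ct <- generate_folded_contour(radius, 0, 0, mm_per_px = mm_per_px,
                                  seed = 1)$contour
    .disk_cache[[key]] <- generate_layered_section_image(
      ct, t_mm, blur_sd = blur, noise_sd = noise, seed = seed)
  }
  .disk_cache[[key]]
}

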