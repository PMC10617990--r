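#' Closed section contour
#'
#' A `section_contour` is an ordered chain of (x, y) vertices in image pixel
#' coordinates (origin top-left, x rightward, y downward, 0-based), together
#' with an optional mm-per-pixel calibration.  It is the unit of all contour
#' morphometry.  On construction the vertex order is normalised so that the
#' shoelace signed area is positive (counter-clockwise by the package's
#' convention), consecutive duplicate vertices are rejected, and closed
#' contours may be checked for self-intersection.
#'
#' @param vertices two-column numeric matrix of (x, y) vertex coordinates in
#'   pixels; at least 3 rows.
#' @param mm_per_px millimetres per pixel; `NA` marks an uncalibrated
#'   contour, which measurement operations refuse.
#' @param label free-text label (e.g. `"cerebellum"`).
#' @param closed logical; closed contours are treated as simple polygons.
#' @param check_simple logical; if `TRUE`, verify the closed polygon does not
#'   self-intersect (O(n^2) test, decimated above 3000 vertices).
#' @return an object of class `section_contour` with fields `vertices`,
#'   `mm_per_px`, `label`, `closed`.
#' @export
section_contour <- function(vertices, mm_per_px = NA_real_, label = "",
                            closed = TRUE, check_simple = FALSE) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || any(!is.finite(vertices)))
    stop("contour vertices must be finite numeric coordinates")
  if (ncol(vertices) != 2L)
    stop("contour vertices must be a two-column (x, y) matrix")
  if (nrow(vertices) < 3L)
    stop("degenerate polygon: a contour needs at least 3 vertices")
  dimnames(vertices) <- list(NULL, c("x", "y"))
  d <- vertices - vertices[c(2:nrow(vertices), 1L), , drop = FALSE]
  dup <- rowSums(d^2) == 0
  if (closed && any(dup)) {
    # drop an exactly repeated closing vertex; reject interior duplicates
    if (sum(dup) == 1L && dup[nrow(vertices)]) {
      vertices <- vertices[-nrow(vertices), , drop = FALSE]
      if (nrow(vertices) < 3L)
        stop("degenerate polygon: a contour needs at least 3 vertices")
    } else stop("contour has identical consecutive vertices")
  } else if (!closed && any(dup[-length(dup)]))
    stop("contour has identical consecutive vertices")
  if (closed && shoelace_area(vertices) < 0)
    vertices <- vertices[nrow(vertices):1L, , drop = FALSE]
  if (closed && check_simple && !is_simple_polygon(vertices))
    stop("contour polygon is self-intersecting (not simple)")
  if (!is.na(mm_per_px) && mm_per_px <= 0)
    stop("mm_per_px must be positive")
  structure(list(vertices = vertices, mm_per_px = as.numeric(mm_per_px),
                 label = as.character(label), closed = isTRUE(closed)),
            class = "section_contour")
}

#' @export
print.section_contour <- function(x, ...) {
  cat(sprintf("section_contour '%s': %d vertices, %s, %s\n", x$label,
              nrow(x$vertices), if (x$closed) "closed" else "open",
              if (is_calibrated(x)) sprintf("%.6g mm/px", x$mm_per_px)
              else "uncalibrated"))
  if (x$closed)
    cat(sprintf("  area %.6g px^2, perimeter %.6g px\n",
                shoelace_area(x$vertices), contour_perimeter_px(x)))
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for the package's counter-clockwise orientation convention.
#'
#' @param vertices two-column matrix of vertices (pixels or mm).
#' @return signed area in squared input units.
#' @export
shoelace_area <- function(vertices) {
  x <- vertices[, 1L]; y <- vertices[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

contour_perimeter_px <- function(contour) {
  v <- contour$vertices
  nxt <- if (contour$closed) c(2:nrow(v), 1L) else c(2:nrow(v), nrow(v))
  sum(sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2)))
}

#' @rdname section_contour
#' @param x a `section_contour`.
#' @export
is_calibrated <- function(x) !is.na(x$mm_per_px) && x$mm_per_px > 0

stop_if_uncalibrated <- function(contour) {
  if (!is_calibrated(contour))
    stop("contour is uncalibrated: run calibrate_scale() first")
  invisible(contour)
}

# O(n^2) segment-pair intersection test; decimated for very dense chains.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n > 3000L) v <- v[unique(round(seq(1L, n, length.out = 3000L))), ,
                        drop = FALSE]
  n <- nrow(v)
  a <- v; b <- v[c(2:n, 1L), , drop = FALSE]
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # skip adjacent edges (share a vertex), incl. the wrap-around pair
  keep <- ij[, 2L] - ij[, 1L] > 1L & !(ij[, 1L] == 1L & ij[, 2L] == n)
  ij <- ij[keep, , drop = FALSE]
  if (nrow(ij) == 0L) return(TRUE)
  p1 <- a[ij[, 1L], , drop = FALSE]; p2 <- b[ij[, 1L], , drop = FALSE]
  p3 <- a[ij[, 2L], , drop = FALSE]; p4 <- b[ij[, 2L], , drop = FALSE]
  crs <- function(o, u, w)
    (u[, 1L] - o[, 1L]) * (w[, 2L] - o[, 2L]) -
    (u[, 2L] - o[, 2L]) * (w[, 1L] - o[, 1L])
  d1 <- crs(p3, p4, p1); d2 <- crs(p3, p4, p2)
  d3 <- crs(p1, p2, p3); d4 <- crs(p1, p2, p4)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Attach a millimetre scale to a contour
#'
#' Histological sections carry a scale bar; dividing its labelled physical
#' length by its pixel length gives the section's mm-per-pixel factor.
#' Vertices are kept in pixel units; measurement operations apply the factor.
#'
#' @param contour a `section_contour`.
#' @param scalebar_px scale-bar length in pixels (> 0).
#' @param scalebar_mm scale-bar physical length in mm (> 0).
#' @return the contour with `mm_per_px = scalebar_mm / scalebar_px`.
#' @export
calibrate_scale <- function(contour, scalebar_px, scalebar_mm) {
  stopifnot(inherits(contour, "section_contour"))
  if (!is.numeric(scalebar_px) || length(scalebar_px) != 1L ||
      !is.finite(scalebar_px) || scalebar_px <= 0)
    stop("scalebar_px must be a positive scalar")
  if (!is.numeric(scalebar_mm) || length(scalebar_mm) != 1L ||
      !is.finite(scalebar_mm) || scalebar_mm <= 0)
    stop("scalebar_mm must be a positive scalar")
  contour$mm_per_px <- scalebar_mm / scalebar_px
  contour
}

#' Read a contour annotation file
#'
#' Annotation files are JSON documents of the form
#' `{"annotations": [{"label": ..., "points": [[x, y], ...]}, ...]}` with
#' coordinates in image pixels.  The polygon with the requested label is
#' returned normalised to counter-clockwise orientation and marked
#' uncalibrated.
#'
#' @param path path to the JSON annotation file.
#' @param label label of the polygon to extract.
#' @param check_simple verify the polygon is simple (default `TRUE`).
#' @return a `section_contour`.
#' @export
read_contour_annotation <- function(path, label, check_simple = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(doc$annotations)) stop("no 'annotations' array in ", path)
  labels <- vapply(doc$annotations, function(a)
    as.character(a$label %||% ""), character(1L))
  hit <- which(labels == label)
  if (length(hit) == 0L)
    stop("label '", label, "' not found; available: ",
         paste(labels, collapse = ", "))
  pts <- doc$annotations[[hit[1L]]]$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  pts <- as.matrix(pts)
  if (!is.numeric(pts)) stop("non-numeric coordinates in polygon '", label, "'")
  if (nrow(pts) < 3L) stop("degenerate polygon '", label,
                           "': fewer than 3 vertices")
  section_contour(pts, label = label, check_simple = check_simple)
}

#' Write contour annotations
#'
#' Inverse of [read_contour_annotation()]; coordinates are serialised with
#' full double precision so a read-back reproduces the vertices.
#'
#' @param contours a `section_contour` or list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_contour_annotation <- function(contours, path) {
  if (inherits(contours, "section_contour")) contours <- list(contours)
  ann <- lapply(contours, function(ct)
    list(label = ct$label, points = unname(ct$vertices)))
  jsonlite::write_json(list(annotations = ann), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
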