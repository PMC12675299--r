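#' Canonicalize four perimeter points into a simple quadrilateral
#'
#' Plaque outlines are recorded as four points along the perimeter, in no
#' particular order. Sorting the points counter-clockwise by angle about
#' their centroid always yields a simple (non-self-intersecting)
#' quadrilateral, whatever order they were clicked in.
#'
#' @param points A 4x2 numeric matrix (columns x, y, in micrometres).
#' @return A 4x2 matrix of the same points in counter-clockwise order,
#'   starting from the smallest angle.
#' @export
canonical_quadrilateral <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 4 || ncol(points) != 2) {
    abort("`points` must be a 4x2 numeric matrix.")
  }
  if (anyNA(points) || any(!is.finite(points))) {
    abort("Perimeter points must be finite.")
  }
  if (anyDuplicated(points)) {
    abort("Degenerate plaque: duplicated perimeter points.")
  }
  ctr <- colMeans(points)
  ang <- atan2(points[, 2] - ctr[2], points[, 1] - ctr[1])
  if (anyDuplicated(ang)) {
    abort("Degenerate plaque: two perimeter points are collinear with the centroid.")
  }
  out <- points[order(ang), , drop = FALSE]
  if (abs(shoelace_area(out)) < sqrt(.Machine$double.eps)) {
    abort("Degenerate plaque: perimeter points are collinear.")
  }
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

shoelace_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]) / 2
}

#' Area of a simple polygon
#'
#' Absolute shoelace area; invariant to vertex order reversal.
#'
#' @param poly An n x 2 numeric matrix of vertices (micrometres).
#' @return Area in square micrometres.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) abort("A polygon needs at least 3 vertices.")
  a <- abs(shoelace_area(poly))
  if (a <= 0) abort("Degenerate polygon: zero area.")
  a
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' @param x,y Coordinates of the query points (vectors of equal length).
#' @param poly An n x 2 vertex matrix of a simple polygon.
#' @return Logical vector, `TRUE` where the point is inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) abort("Degenerate polygon: fewer than 3 vertices.")
  if (abs(shoelace_area(poly)) <= 0) abort("Degenerate polygon: zero area.")
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

# squared distance from points (px, py) to segment (ax,ay)-(bx,by), vectorized
dist2_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 > 0) ((px - ax) * dx + (py - ay) * dy) / len2 else 0
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  (px - qx)^2 + (py - qy)^2
}

#' Distance from cell centroids to a plaque edge
#'
#' The plaque boundary is the closed outline through the four canonical
#' perimeter points. Centroids on or inside the boundary have distance 0;
#' outside, the distance is the minimum Euclidean distance to the four
#' boundary segments.
#'
#' @param x,y Centroid coordinates (micrometres), vectors of equal length.
#' @param plaque A 4x2 perimeter matrix; canonicalized internally.
#' @return Non-negative distances in micrometres.
#' @export
distance_to_plaque_edge <- function(x, y, plaque) {
  quad <- canonical_quadrilateral(plaque)
  d2 <- rep(Inf, length(x))
  for (i in 1:4) {
    j <- if (i == 4) 1 else i + 1
    d2 <- pmin(d2, dist2_point_segment(x, y, quad[i, 1], quad[i, 2],
                                       quad[j, 1], quad[j, 2]))
  }
  d <- sqrt(d2)
  d[point_in_polygon(x, y, quad)] <- 0
  d
}

plaque_vertex_list <- function(plaques) {
  stopifnot(is.data.frame(plaques))
  need <- c("plaque_id", paste0(rep(c("x", "y"), 4), rep(1:4, each = 2)))
  missing <- setdiff(need, names(plaques))
  if (length(missing)) {
    abort(paste0("Plaque table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  lapply(seq_len(nrow(plaques)), function(i) {
    canonical_quadrilateral(matrix(as.numeric(plaques[i, need[-1]]),
                                   ncol = 2, byrow = TRUE))
  })
}

#' Nearest plaque for each cell centroid
#'
#' @param cells Data frame with `cell_id`, `x_um`, `y_um`.
#' @param plaques Plaque table with `plaque_id` and perimeter columns
#'   `x1,y1,...,x4,y4` (micrometres).
#' @return Tibble `cell_id`, `nearest_plaque_id`, `distance_um`. Ties in
#'   distance go to the smallest `plaque_id`.
#' @export
nearest_plaque <- function(cells, plaques) {
  if (nrow(plaques) == 0) {
    abort("No plaques given; request distal-only summaries explicitly instead.")
  }
  quads <- plaque_vertex_list(plaques)
  ord <- order(plaques$plaque_id)
  dmat <- vapply(ord, function(i) {
    distance_to_plaque_edge(cells$x_um, cells$y_um, quads[[i]])
  }, numeric(nrow(cells)))
  dmat <- matrix(dmat, nrow = nrow(cells))
  best <- max.col(-dmat, ties.method = "first")  # first = smallest plaque_id
  tibble::tibble(
    cell_id = cells$cell_id,
    nearest_plaque_id = plaques$plaque_id[ord][best],
    distance_um = dmat[cbind(seq_len(nrow(cells)), best)]
  )
}

#' Classify plaque proximity of a cell
#'
#' Cells within `cutoff_um` of the nearest plaque edge are
#' `"plaque_associated"`; cells strictly further are `"distal"`. The
#' boundary (distance exactly equal to the cutoff) belongs to the
#' plaque-associated class.
#'
#' @param distance_um Non-negative distances in micrometres.
#' @param cutoff_um Distance cutoff in micrometres (default 15; use 5 for
#'   the process-contact analogue).
#' @return Character vector of labels.
#' @export
classify_proximity <- function(distance_um, cutoff_um = 15) {
  if (any(is.na(distance_um)) || any(distance_um < 0)) {
    abort("Distances must be non-negative and non-missing.")
  }
  ifelse(distance_um <= cutoff_um, "plaque_associated", "distal")
}

#' Proximity classification of all cells within a region
#'
#' Computes each cell's distance to the nearest plaque edge and labels
#' cells inside the region polygon as plaque-associated or distal. Cells
#' outside the region keep their distance but get no label (`NA`), and are
#' excluded from downstream group comparisons.
#'
#' @param cells Data frame with `cell_id`, `x_um`, `y_um`.
#' @param plaques Plaque table (`plaque_id`, `x1..y4`).
#' @param region Region polygon as an n x 2 vertex matrix, or `NULL` to
#'   treat every cell as in-region.
#' @param cutoff_um Proximity cutoff in micrometres (default 15).
#' @return Tibble with `cell_id`, `nearest_plaque_id`, `distance_um`,
#'   `in_region`, `label`.
#' @export
compute_proximity <- function(cells, plaques, region = NULL, cutoff_um = 15) {
  np <- nearest_plaque(cells, plaques)
  in_region <- if (is.null(region)) {
    rep(TRUE, nrow(cells))
  } else {
    point_in_polygon(cells$x_um, cells$y_um, region)
  }
  np$in_region <- in_region
  np$label <- ifelse(in_region, classify_proximity(np$distance_um, cutoff_um),
                     NA_character_)
  class(np) <- c("plaquemap_proximity", class(np))
  attr(np, "cutoff_um") <- cutoff_um
  np
}

#' Per-plaque counts and plaque-free distal density
#'
#' Counts plaque-associated cells per nearest plaque and computes the
#' distal cell density over the region area with plaque areas removed (the
#' areal analogue of normalizing distal counts to tissue volume minus
#' total plaque volume).
#'
#' @param records Proximity records from [compute_proximity()].
#' @param plaques Plaque table.
#' @param region Region polygon vertex matrix.
#' @return List with `per_plaque` (tibble `plaque_id`, `n_associated`) and
#'   `distal` (tibble `n_distal`, `free_area_um2`, `density_per_um2`).
#' @export
summarize_proximity <- function(records, plaques, region) {
  rec <- dplyr::filter(records, .data$in_region)
  region_area <- polygon_area(region)
  plaque_area <- sum(vapply(plaque_vertex_list(plaques), polygon_area, 0))
  free_area <- region_area - plaque_area
  if (free_area <= 0) {
    abort("Region area does not exceed total plaque area; check units.")
  }
  assoc <- dplyr::count(
    dplyr::filter(rec, .data$label == "plaque_associated"),
    .data$nearest_plaque_id, name = "n_associated"
  )
  per_plaque <- dplyr::left_join(
    tibble::tibble(plaque_id = sort(plaques$plaque_id)),
    dplyr::rename(assoc, plaque_id = "nearest_plaque_id"),
    by = "plaque_id"
  )
  per_plaque$n_associated[is.na(per_plaque$n_associated)] <- 0L
  n_distal <- sum(rec$label == "distal")
  list(
    per_plaque = per_plaque,
    distal = tibble::tibble(
      n_distal = n_distal,
      free_area_um2 = free_area,
      density_per_um2 = n_distal / free_area
    )
  )
}
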