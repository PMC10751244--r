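# Planar polygon utilities and the Voronoi/Lloyd cell mosaic.
#
# Coordinate convention (used package-wide): origin at the top-left corner of
# the field, x to the right, y down, all lengths in micrometres.  Polygons are
# closed polylines stored as n x 2 matrices (columns x_um, y_um) whose last
# vertex repeats the first.

#' Polygon area by the shoelace formula
#'
#' @param poly closed polyline, an n x 2 matrix (last vertex == first).
#' @return area in squared input units (always >= 0).
#' @export
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Polygon perimeter (polyline length)
#'
#' @inheritParams poly_area
#' @return total edge length.
#' @export
poly_perimeter <- function(poly) {
  d <- diff(poly)
  sum(sqrt(rowSums(d^2)))
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple closed polygon.
#'
#' @inheritParams poly_area
#' @return length-2 numeric (x, y).
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly[-n, , drop = FALSE]))
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  c(cx, cy)
}

# Clip a convex polygon (open vertex list, no repeated last vertex) by the
# half-plane {p : dot(p - m, d) <= 0} using Sutherland-Hodgman.
clip_halfplane <- function(verts, m, d) {
  if (nrow(verts) == 0L) return(verts)
  s <- as.vector((verts[, 1] - m[1]) * d[1] + (verts[, 2] - m[2]) * d[2])
  n <- nrow(verts)
  nxt <- c(2:n, 1L)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- nxt[i]
    pi_in <- s[i] <= 0; pj_in <- s[j] <= 0
    if (pi_in) out <- rbind(out, verts[i, ])
    if (xor(pi_in, pj_in)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, verts[i, ] + t * (verts[j, ] - verts[i, ]))
    }
  }
  out
}

# Voronoi cell of seed `p` among `seeds`, clipped to the field rectangle.
# Returns an open vertex list (counter-clockwise in screen coordinates).
voronoi_cell <- function(p, seeds, field_size_um) {
  verts <- rbind(c(0, 0), c(field_size_um[1], 0), field_size_um,
                 c(0, field_size_um[2]))
  for (k in seq_len(nrow(seeds))) {
    q <- seeds[k, ]
    if (all(q == p)) next
    verts <- clip_halfplane(verts, (p + q) / 2, q - p)
    if (nrow(verts) < 3L) break
  }
  verts
}

#' Generate a cell mosaic by Lloyd-relaxed Voronoi tessellation
#'
#' Emulates the roughly isotropic, convex cell outlines of an endothelial
#' monolayer: `n_cells` seed points are drawn uniformly in the field, their
#' Voronoi diagram is clipped to the field rectangle, and two Lloyd iterations
#' (seeds moved to cell centroids) regularize the cell sizes.
#'
#' @param n_cells number of cells (>= 1).
#' @param field_size_um field width and height in micrometres (length 1 or 2).
#' @param seed integer RNG seed; identical seeds give identical mosaics.
#' @param lloyd_iters number of Lloyd relaxation steps (default 2).
#' @return list of closed polylines (n x 2 matrices, last vertex == first),
#'   one per cell; their areas sum to the field area.
#' @export
generate_cell_mosaic <- function(n_cells, field_size_um = c(100, 100),
                                 seed = 1L, lloyd_iters = 2L) {
  if (length(field_size_um) == 1L) field_size_um <- rep(field_size_um, 2)
  stopifnot(all(field_size_um > 0))
  if (n_cells < 1L) stop("empty scene: n_cells must be >= 1")
  if (n_cells == 1L) {
    W <- field_size_um[1]; H <- field_size_um[2]
    return(list(rbind(c(0, 0), c(W, 0), c(W, H), c(0, H), c(0, 0))))
  }
  seeds <- local_seed(seed, {
    cbind(stats::runif(n_cells, 0, field_size_um[1]),
          stats::runif(n_cells, 0, field_size_um[2]))
  })
  for (it in seq_len(lloyd_iters)) {
    cells <- lapply(seq_len(n_cells), function(i)
      voronoi_cell(seeds[i, ], seeds, field_size_um))
    seeds <- t(vapply(cells, function(v)
      poly_centroid(rbind(v, v[1, ])), numeric(2)))
  }
  lapply(seq_len(n_cells), function(i) {
    v <- voronoi_cell(seeds[i, ], seeds, field_size_um)
    colnames(v) <- c("x_um", "y_um")
    rbind(v, v[1, , drop = FALSE])
  })
}

# Arc-length parametrization: point and unit tangent at arc position s
# (measured from the first vertex, wrapping around) on a closed polyline.
point_on_polyline <- function(poly, s) {
  d <- diff(poly)
  len <- sqrt(rowSums(d^2))
  keep <- len > 0
  d <- d[keep, , drop = FALSE]; len <- len[keep]
  starts <- poly[-nrow(poly), , drop = FALSE][keep, , drop = FALSE]
  total <- sum(len)
  s <- s %% total
  cum <- cumsum(len)
  i <- findInterval(s, cum) + 1L # segment index
  i[i > length(len)] <- length(len)
  off <- s - c(0, cum)[i]
  tang <- d / len
  list(point = starts[i, , drop = FALSE] + tang[i, , drop = FALSE] * off,
       tangent = tang[i, , drop = FALSE])
}

#' Minimum distance from points to a closed polyline
#'
#' @param pts m x 2 matrix of query points.
#' @param poly closed polyline (n x 2, last vertex == first).
#' @return numeric vector of length m.
#' @export
dist_to_polyline <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1
  dmin <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(a))) {
    t <- ((pts[, 1] - a[k, 1]) * ab[k, 1] + (pts[, 2] - a[k, 2]) * ab[k, 2]) / len2[k]
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[k, 1] + t * ab[k, 1])
    dy <- pts[, 2] - (a[k, 2] + t * ab[k, 2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
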