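# Junctional "zippering" metrics: VE-cadherin coverage of the cell perimeter,
# fragment count per 100 um of vessel, and the cumulative distribution of
# fragment lengths.  Zippering (button -> zipper transition) shows up as
# higher coverage, fewer fragments per 100 um, and a right-shifted length CDF.

#' Assign fragments to a cell perimeter
#'
#' A fragment is junctional for a cell when its centroid lies within
#' `tolerance_um` of the cell's perimeter polyline; all others are
#' pan-cellular.
#'
#' @param fragments data frame with columns `id`, `centroid_x_um`,
#'   `centroid_y_um` and a length column (`length_um` or
#'   `length_skeleton_um`).
#' @param polyline closed cell perimeter (n x 2 matrix, last vertex ==
#'   first).
#' @param tolerance_um assignment tolerance in micrometres (default 1).
#' @param cell_id identifier recorded in the annotation.
#' @return a `cell_junction_annotation`: `cell_id`, `perimeter_um`,
#'   `fragments` (the junctional subset, with `dist_um` added), and
#'   `n_pan_cellular`.
#' @export
assign_fragments_to_perimeter <- function(fragments, polyline,
                                          tolerance_um = 1, cell_id = 1L) {
  stopifnot(tolerance_um > 0)
  if (!isTRUE(all.equal(polyline[1, ], polyline[nrow(polyline), ],
                        check.attributes = FALSE))) {
    stop("perimeter polyline must be closed (last vertex == first)")
  }
  perim <- poly_perimeter(polyline)
  if (perim <= 0) stop("zero-length perimeter")
  d <- if (nrow(fragments) > 0) {
    dist_to_polyline(cbind(fragments$centroid_x_um, fragments$centroid_y_um),
                     polyline)
  } else numeric(0)
  keep <- d <= tolerance_um
  junc <- fragments[keep, , drop = FALSE]
  junc$dist_um <- d[keep]
  structure(list(cell_id = cell_id, perimeter_um = perim,
                 polyline = polyline, fragments = junc,
                 n_pan_cellular = sum(!keep)),
            class = "cell_junction_annotation")
}

#' VE-cadherin coverage of a cell perimeter
#'
#' `100 * sum(junctional fragment lengths) / cell perimeter`.  Coverage above
#' 100 is possible only when assigned fragments overlap along the perimeter;
#' such annotations are flagged via the `overlap_flag` attribute.
#'
#' @param annotation a `cell_junction_annotation`.
#' @param length_col which length column to sum; the skeleton (geodesic)
#'   length follows junction curvature and is the default for coverage.
#' @return coverage percentage (>= 0), with attribute `overlap_flag`.
#' @export
coverage_percent <- function(annotation,
                             length_col = c("length_skeleton_um", "length_um")) {
  stopifnot(inherits(annotation, "cell_junction_annotation"))
  length_col <- match.arg(length_col)
  if (annotation$perimeter_um <= 0) stop("zero perimeter")
  lens <- annotation$fragments[[length_col]]
  if (is.null(lens)) lens <- annotation$fragments$length_um
  cov <- 100 * sum(lens) / annotation$perimeter_um
  attr(cov, "overlap_flag") <- cov > 100
  cov
}

#' Fragments per 100 micrometres of vessel
#'
#' @param n fragment count.
#' @param vessel_length_um vessel (or perimeter) length in micrometres (> 0).
#' @return count per 100 um.
#' @export
fragments_per_100um <- function(n, vessel_length_um) {
  if (vessel_length_um <= 0) stop("vessel length must be > 0")
  stopifnot(n >= 0)
  100 * n / vessel_length_um
}

#' Empirical cumulative distribution of fragment lengths
#'
#' Right-continuous step CDF over the sorted unique lengths.
#'
#' @param lengths numeric vector of fragment lengths (>= 1 value).
#' @return data frame `length_um`, `cumulative_fraction`, with the underlying
#'   [stats::ecdf()] attached as attribute `ecdf`.
#' @export
cumulative_length_frequency <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) == 0L) stop("no lengths supplied")
  f <- stats::ecdf(lengths)
  x <- sort(unique(lengths))
  out <- data.frame(length_um = x, cumulative_fraction = f(x))
  attr(out, "ecdf") <- f
  out
}

#' Per-cell junction metrics for a segmented scene
#'
#' Assigns shape-measured fragments to each cell perimeter and reports
#' coverage, fragment count, and fragments per 100 um of perimeter.
#'
#' @param shapes fragment table from [shape_table()].
#' @param polygons list of closed cell perimeters.
#' @param tolerance_um assignment tolerance (default 1 um).
#' @param length_col length column used for coverage sums.
#' @return data frame: cell_id, perimeter_um, n_fragments, coverage_pct,
#'   fragments_per_100um, overlap_flag.
#' @export
junction_metrics <- function(shapes, polygons, tolerance_um = 1,
                             length_col = c("length_skeleton_um", "length_um")) {
  length_col <- match.arg(length_col)
  # nearest-perimeter ownership: each fragment assigned to at most one cell
  n <- nrow(shapes)
  dmat <- vapply(polygons, function(p)
    dist_to_polyline(cbind(shapes$centroid_x_um, shapes$centroid_y_um), p),
    numeric(n))
  dmat <- matrix(dmat, nrow = n)
  owner <- if (n > 0) apply(dmat, 1L, which.min) else integer(0)
  rows <- lapply(seq_along(polygons), function(ci) {
    mine <- shapes[owner == ci, , drop = FALSE]
    ann <- assign_fragments_to_perimeter(mine, polygons[[ci]],
                                         tolerance_um, cell_id = ci)
    cov <- coverage_percent(ann, length_col)
    data.frame(cell_id = ci, perimeter_um = ann$perimeter_um,
               n_fragments = nrow(ann$fragments),
               coverage_pct = as.numeric(cov),
               fragments_per_100um = fragments_per_100um(
                 nrow(ann$fragments), ann$perimeter_um),
               overlap_flag = attr(cov, "overlap_flag"))
  })
  do.call(rbind, rows)
}
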