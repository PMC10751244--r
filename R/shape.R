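# Shape descriptors consumed by the four-category classifier: circularity,
# best-fit-ellipse aspect ratio, and fragment length (maximum caliper or
# skeleton geodesic).

#' Circularity of a fragment mask
#'
#' `4 * pi * area / perimeter^2`, the particle-analysis standard: 1 for a
#' circle, approaching 0 for elongated shapes.  Values above 1 arising from
#' discretization are clipped to 1; a degenerate object with zero estimated
#' perimeter is defined as circularity 1.
#'
#' @param mask logical matrix, one fragment (TRUE = object pixel).
#' @param perimeter_mode "weighted" (corner-corrected boundary estimator,
#'   default) or "crack" (raw pixel-edge count; oracle mode, biased low in
#'   circularity).
#' @return circularity in `[0, 1]`.
#' @export
circularity <- function(mask, perimeter_mode = c("weighted", "crack")) {
  perimeter_mode <- match.arg(perimeter_mode)
  a <- sum(mask)
  if (a == 0L) stop("empty mask")
  p <- perimeter_px(mask, perimeter_mode)
  if (p <= 0) return(1)
  min(4 * pi * a / p^2, 1)
}

# Eigenvalues of the second-central-moment (covariance) matrix of the pixel
# centers of a mask, largest first.
mask_moments <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  n <- length(idx)
  mu_rr <- sum((rr - mean(rr))^2) / n
  mu_cc <- sum((cc - mean(cc))^2) / n
  mu_rc <- sum((rr - mean(rr)) * (cc - mean(cc))) / n
  tr <- mu_rr + mu_cc
  det <- mu_rr * mu_cc - mu_rc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  c(lambda1 = tr / 2 + disc, lambda2 = tr / 2 - disc)
}

#' Aspect ratio of a fragment mask
#'
#' Major/minor axis-length ratio of the best-fit ellipse from the second
#' central moments of the pixel set; rotation-invariant, always >= 1.  The
#' minor axis is floored at one pixel so single-pixel or one-row objects are
#' well defined (a lone pixel has aspect ratio 1).
#'
#' @inheritParams circularity
#' @return aspect ratio (dimensionless, >= 1).
#' @export
aspect_ratio <- function(mask) {
  if (!any(mask)) stop("empty mask")
  lam <- mask_moments(mask)
  major <- 4 * sqrt(lam[["lambda1"]])
  minor <- max(4 * sqrt(lam[["lambda2"]]), 1) # floor: one pixel
  max(major, 1) / minor
}

#' Fragment length
#'
#' Two length measures are offered.  `major_axis` (default) is the maximum
#' caliper (Feret) diameter — the largest pixel-center distance plus one pixel
#' of end caps — which equals the true length for straight bars and the
#' diameter for puncta, and gives the chord for curved fragments.  `skeleton`
#' is the geodesic length of the Zhang-Suen skeleton plus one pixel, which
#' follows curvature and is therefore the more faithful measure for coverage
#' sums along curved junctions (it slightly undershoots for wide objects,
#' whose skeleton retracts by about half a width at each end).
#'
#' @inheritParams circularity
#' @param pixel_size_um pixel size in micrometres.
#' @param mode "major_axis" or "skeleton".
#' @return length in micrometres.
#' @export
fragment_length <- function(mask, pixel_size_um,
                            mode = c("major_axis", "skeleton")) {
  mode <- match.arg(mode)
  if (!any(mask)) stop("empty mask")
  if (mode == "major_axis") {
    idx <- which(mask)
    nr <- nrow(mask)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    pts <- cbind(cc, rr)
    h <- grDevices::chull(pts)
    hp <- pts[h, , drop = FALSE]
    d2 <- 0
    if (nrow(hp) > 1L) {
      for (i in seq_len(nrow(hp) - 1L)) {
        d2 <- max(d2, (hp[-(1:i), 1] - hp[i, 1])^2 + (hp[-(1:i), 2] - hp[i, 2])^2)
      }
    }
    (sqrt(d2) + 1) * pixel_size_um # +1 px: end-cap half-pixels
  } else {
    skel <- skeletonize(mask)
    (skeleton_length_px(skel) + 1) * pixel_size_um
  }
}

#' Compute shape descriptors for every fragment in a segmentation
#'
#' Appends circularity, aspect ratio and both length measures to the
#' per-field fragment table.
#'
#' @param seg a `fov_segmentation` from [segment_fov()].
#' @return the fragment table with added columns `circularity`,
#'   `aspect_ratio`, `length_um` (major-axis mode) and `length_skeleton_um`.
#' @export
shape_table <- function(seg) {
  stopifnot(inherits(seg, "fov_segmentation"))
  labels <- seg$labels
  px <- pixel_size(labels)
  tab <- seg$table
  n <- nrow(tab)
  circ <- ar <- len <- lens <- numeric(n)
  for (i in seq_len(n)) {
    mask <- crop_mask(labels, tab$id[i])
    circ[i] <- circularity(mask)
    ar[i] <- aspect_ratio(mask)
    len[i] <- fragment_length(mask, px, "major_axis")
    lens[i] <- fragment_length(mask, px, "skeleton")
  }
  tab$circularity <- circ
  tab$aspect_ratio <- ar
  tab$length_um <- len
  tab$length_skeleton_um <- lens
  tab
}

# Extract the bounding-box-cropped logical mask of one labelled object.
crop_mask <- function(labels, id) {
  idx <- which(labels == id)
  nr <- nrow(labels)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  sub <- matrix(FALSE, diff(range(rr)) + 1L, diff(range(cc)) + 1L)
  sub[cbind(rr - min(rr) + 1L, cc - min(cc) + 1L)] <- TRUE
  sub
}
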