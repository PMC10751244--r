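# Image-to-objects stage: tile a calibrated field of view into 20 x 20-um
# blocks and segment each block into labelled VE-cadherin fragments by
# per-block Otsu thresholding and 8-connected component labelling.

#' Segmentation configuration
#'
#' @param min_area_px minimum object size in pixels; smaller components are
#'   discarded (single-pixel noise suppression).
#' @param range_epsilon blocks whose intensity dynamic range is below this are
#'   treated as empty (no foreground), guarding Otsu against thresholding pure
#'   background noise (a noise-only block has range about 8 * noise_sd).
#' @param floor_frac threshold floor, as a fraction of the block's dynamic
#'   range above its minimum.  Otsu's threshold is unreliable when the
#'   foreground occupies well under 1 percent of a block (it then splits the
#'   background noise instead); the effective threshold is
#'   `max(otsu, min + floor_frac * range)`.
#' @param connectivity 4 or 8 (default) neighbour connectivity.
#' @return a `segment_config` list.
#' @export
segment_config <- function(min_area_px = 3L, range_epsilon = 0.5,
                           floor_frac = 0.45, connectivity = 8L) {
  stopifnot(min_area_px >= 1, range_epsilon >= 0,
            floor_frac >= 0, floor_frac < 1, connectivity %in% c(4L, 8L))
  structure(list(min_area_px = as.integer(min_area_px),
                 range_epsilon = range_epsilon, floor_frac = floor_frac,
                 connectivity = as.integer(connectivity)),
            class = "segment_config")
}

#' Crop a field of view into blocks
#'
#' Tiles the image into `block_size_um` x `block_size_um` blocks (edge blocks
#' may be smaller), the unit at which thresholding operates.
#'
#' @param image a `calibrated_image`.
#' @param block_size_um block edge length in micrometres (default 20).
#' @return list of blocks; each block carries `pixels` (sub-image),
#'   `origin_um` (top-left corner), `origin_px` (1-based row/col offset),
#'   `block_id`, and the pixel size.
#' @export
crop_blocks <- function(image, block_size_um = 20) {
  px <- pixel_size(image) # errors when calibration is missing
  stopifnot(block_size_um > 0)
  bpx <- max(1L, round(block_size_um / px))
  nr <- nrow(image); nc <- ncol(image)
  row_starts <- seq(1L, nr, by = bpx)
  col_starts <- seq(1L, nc, by = bpx)
  blocks <- list()
  id <- 0L
  for (r0 in row_starts) for (c0 in col_starts) {
    id <- id + 1L
    rs <- r0:min(r0 + bpx - 1L, nr)
    cs <- c0:min(c0 + bpx - 1L, nc)
    blocks[[id]] <- structure(
      list(pixels = unclass(image)[rs, cs, drop = FALSE],
           origin_px = c(row = r0, col = c0),
           origin_um = c(x = (c0 - 1L) * px, y = (r0 - 1L) * px),
           block_id = id, pixel_size_um = px),
      class = "fov_block")
  }
  blocks
}

#' Segment one block into labelled fragments
#'
#' Foreground is `intensity > Otsu threshold` computed within the block;
#' blocks whose dynamic range is below `range_epsilon` yield no fragments.
#' Connected components smaller than `min_area_px` are removed.  Labels are a
#' deterministic function of the pixel data.
#'
#' @param block a block from [crop_blocks()].
#' @param config a [segment_config()].
#' @return a `block_segmentation`: `labels` (integer matrix, 0 = background),
#'   and `table`, a data frame with one row per fragment (id, area_um2,
#'   perimeter_um, centroid_x_um, centroid_y_um, border flag, block_id).
#' @export
segment_fragments <- function(block, config = segment_config()) {
  stopifnot(inherits(block, "fov_block"))
  px <- block$pixel_size_um
  m <- block$pixels
  rng <- range(m)
  if (diff(rng) < config$range_epsilon) {
    labels <- matrix(0L, nrow(m), ncol(m))
  } else {
    thr <- max(otsu_threshold(m), rng[1] + config$floor_frac * diff(rng))
    labels <- label_components(m > thr, config$connectivity)
  }
  labels <- drop_small(labels, config$min_area_px)
  structure(list(labels = labels,
                 table = fragment_table(labels, block, px)),
            class = "block_segmentation")
}

drop_small <- function(labels, min_area_px) {
  if (!any(labels > 0L)) return(labels)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_area_px)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- relab[labels[labels > 0L]]
  out
}

fragment_table <- function(labels, block, px) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) == 0L) {
    return(data.frame(id = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), border = logical(0),
                      block_id = integer(0)))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  rows <- lapply(ids, function(i) {
    mask <- labels == i
    idx <- which(mask)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    data.frame(
      id = i,
      area_um2 = length(idx) * px^2,
      perimeter_um = perimeter_px(mask) * px,
      centroid_x_um = block$origin_um[["x"]] + (mean(cc) - 0.5) * px,
      centroid_y_um = block$origin_um[["y"]] + (mean(rr) - 0.5) * px,
      border = any(rr == 1L) || any(rr == nr) || any(cc == 1L) || any(cc == nc),
      block_id = block$block_id)
  })
  do.call(rbind, rows)
}

#' Segment a whole field of view
#'
#' [crop_blocks()] + [segment_fragments()] per block, merged into one
#' per-field fragment table with globally unique ids.
#'
#' @param image a `calibrated_image`.
#' @param block_size_um block edge length in micrometres.
#' @param config a [segment_config()].
#' @param fov field-of-view identifier recorded in the table.
#' @return a `fov_segmentation`: `labels` (full-field label
#'   `calibrated_image`), `table` (fov, block_id, id, area_um2, perimeter_um,
#'   centroid_x_um, centroid_y_um, border), and `blocks` (per-block
#'   segmentations).
#' @export
segment_fov <- function(image, block_size_um = 20, config = segment_config(),
                        fov = 1L) {
  blocks <- crop_blocks(image, block_size_um)
  segs <- lapply(blocks, segment_fragments, config = config)
  merged <- merge_fragment_tables(segs, fov = fov)
  labels <- matrix(0L, nrow(image), ncol(image))
  offset <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; lab <- segs[[i]]$labels
    n_here <- max(lab, 0L)
    if (n_here > 0L) {
      rs <- b$origin_px[["row"]] + seq_len(nrow(lab)) - 1L
      cs <- b$origin_px[["col"]] + seq_len(ncol(lab)) - 1L
      sub <- labels[rs, cs, drop = FALSE]
      sub[lab > 0L] <- lab[lab > 0L] + offset
      labels[rs, cs] <- sub
    }
    offset <- offset + n_here
  }
  structure(list(labels = calibrated_image(labels, pixel_size(image)),
                 table = merged, blocks = segs),
            class = "fov_segmentation")
}

#' Merge per-block fragment tables for one field of view
#'
#' Concatenates block tables, renumbering fragment ids to be globally unique
#' within the field.  Objects split by block borders remain separate rows and
#' keep their border-touching flag, so they can be excluded in sensitivity
#' analyses.
#'
#' @param segmentations list of `block_segmentation` objects from one FOV.
#' @param fov field-of-view identifier.
#' @return single data frame; zero rows for an empty field.
#' @export
merge_fragment_tables <- function(segmentations, fov = 1L) {
  tabs <- lapply(segmentations, `[[`, "table")
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) == 0L) {
    tab <- fragment_table(matrix(0L, 1, 1),
                          structure(list(origin_um = c(x = 0, y = 0),
                                         block_id = 0L), class = "fov_block"),
                          1)
  }
  tab$id <- seq_len(nrow(tab))
  cbind(fov = rep(fov, nrow(tab)), tab)
}
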