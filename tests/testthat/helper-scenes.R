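# Shared fixture builders: all synthetic, generated at test time.

# axis-aligned rectangle mask of L x W micrometres at the given pixel size
mk_rect_mask <- function(length_um, width_um, px = 0.1) {
  matrix(TRUE, max(1L, round(width_um / px)), max(1L, round(length_um / px)))
}

# disk mask of the given radius in pixels, padded with background
mk_disk_mask <- function(r_px, pad = 10L) {
  n <- 2L * r_px + 2L * pad
  cc <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) (i - cc)^2 + (j - cc)^2 <= r_px^2)
}

# small, fast scene: 50 x 50 um, 4 cells
small_scene_spec <- function(seed = 1L, n_bars = 16L, n_puncta = 8L,
                             noise_sd = 0.05, blur_sigma_um = 0.2,
                             bar_len = 3, punctum_junctional = FALSE) {
  scene_spec(field_size_um = c(50, 50), pixel_size_um = 0.1, n_cells = 4L,
             mix = rbind(
               fragment_mix("bar", n_bars, bar_len, 0.5, 0.5, 1),
               fragment_mix("punctum", n_puncta, 1, 0.15, intensity = 1,
                            junctional = punctum_junctional)),
             blur_sigma_um = blur_sigma_um, noise_sd = noise_sd,
             background = 0.1, seed = seed)
}

# index of the nearest ground-truth fragment for each measured fragment
match_to_truth <- function(shapes, truth) {
  vapply(seq_len(nrow(shapes)), function(i) {
    which.min((truth$fragments$x_um - shapes$centroid_x_um[i])^2 +
              (truth$fragments$y_um - shapes$centroid_y_um[i])^2)
  }, integer(1))
}

# Jaccard overlap between one truth object and the union of found labels
# that lie mostly (>= 50%) inside it; per-block segmentation legitimately
# splits boundary-crossing objects, so recovery is judged on the union.
recovery_jaccard <- function(truth_mask, found_labels) {
  ids <- setdiff(unique(found_labels[truth_mask]), 0L)
  ids <- ids[vapply(ids, function(id) {
    f <- found_labels == id
    sum(f & truth_mask) / sum(f) >= 0.5
  }, logical(1))]
  if (length(ids) == 0L) return(0)
  f <- matrix(found_labels %in% ids, nrow(found_labels))
  sum(f & truth_mask) / sum(f | truth_mask)
}

# Jaccard overlap between one truth label and the best-matching found label
best_jaccard <- function(truth_mask, found_labels) {
  ids <- setdiff(unique(found_labels[truth_mask]), 0L)
  if (length(ids) == 0L) return(0)
  max(vapply(ids, function(id) {
    f <- found_labels == id
    sum(f & truth_mask) / sum(f | truth_mask)
  }, numeric(1)))
}
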