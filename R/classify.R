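# Four-category fragment shape classifier: aspect-ratio quartile bins crossed
# with fixed circularity bins, then per-field-of-view category percentages.
#
# Category 1: aspect ratio above the upper quartile (Q3), circularity 0-0.25
# Category 2: aspect ratio Q2-Q3, circularity 0.25-0.5
# Category 3: aspect ratio Q1-Q2, circularity 0.5-0.75
# Category 4: aspect ratio below Q1, circularity 0.75-1
# High categories are short round fragments (turnover puncta); low categories
# are elongated junctional segments.

#' Aspect-ratio quartile boundaries of a reference population
#'
#' Quartiles are computed with linear-interpolation quantiles.  The scope of
#' the reference population (all fragments of a comparison cohort pooled, or
#' per field of view) is recorded with the boundaries, because the bins only
#' support a between-group comparison when both groups share them.
#'
#' @param aspect_ratios numeric vector of fragment aspect ratios (>= 4 values).
#' @param scope "cohort" (default) or "per_fov"; descriptive only.
#' @return a `quartile_boundaries` object with `q1`, `q2`, `q3`, `n`, `scope`.
#' @export
compute_quartiles <- function(aspect_ratios, scope = c("cohort", "per_fov")) {
  scope <- match.arg(scope)
  aspect_ratios <- aspect_ratios[!is.na(aspect_ratios)]
  if (length(aspect_ratios) < 4L) {
    stop("insufficient population: need >= 4 aspect-ratio values")
  }
  q <- stats::quantile(aspect_ratios, c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  structure(list(q1 = q[1], q2 = q[2], q3 = q[3],
                 n = length(aspect_ratios), scope = scope),
            class = "quartile_boundaries")
}

#' @export
print.quartile_boundaries <- function(x, ...) {
  cat(sprintf("<quartile_boundaries> Q1 = %.3f, Q2 = %.3f, Q3 = %.3f (n = %d, scope = %s)\n",
              x$q1, x$q2, x$q3, x$n, x$scope))
  invisible(x)
}

#' Classify fragments into the four shape categories
#'
#' Circularity bins are `(0, 0.25], (0.25, 0.5], (0.5, 0.75], (0.75, 1]`
#' (bins 1-4; circularity exactly 0 falls in bin 1).  Aspect-ratio bins are
#' `(Q3, Inf), (Q2, Q3], (Q1, Q2], [min, Q1]` (bins 1-4; boundary ties fall
#' in the lower-aspect-ratio, higher-category bin).  In lenient mode (the
#' default) the category is the circularity bin and disagreement between the
#' two bin indices is only flagged, so every fragment is counted; in strict
#' mode a fragment is `unclassified` (NA) unless both indices agree.
#'
#' @param shapes data frame with columns `circularity` and `aspect_ratio`
#'   (e.g. from [shape_table()]).
#' @param quartiles a `quartile_boundaries` from [compute_quartiles()].
#' @param mode "lenient" (default) or "strict".
#' @return `shapes` with added columns `circ_bin`, `ar_bin`, `discordant`,
#'   and `category` (integer 1-4, NA when unclassified).
#' @export
classify_fragments <- function(shapes, quartiles, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(quartiles, "quartile_boundaries"))
  circ <- shapes$circularity
  ar <- shapes$aspect_ratio
  if (any(circ < 0 | circ > 1, na.rm = TRUE)) {
    stop("circularity outside [0, 1]")
  }
  circ_bin <- findInterval(circ, c(0, 0.25, 0.5, 0.75),
                           left.open = TRUE, rightmost.closed = FALSE)
  circ_bin[circ == 0] <- 1L
  ar_bin <- ifelse(ar > quartiles$q3, 1L,
                   ifelse(ar > quartiles$q2, 2L,
                          ifelse(ar > quartiles$q1, 3L, 4L)))
  discordant <- circ_bin != ar_bin
  category <- if (mode == "lenient") circ_bin else
    ifelse(discordant, NA_integer_, circ_bin)
  shapes$circ_bin <- as.integer(circ_bin)
  shapes$ar_bin <- as.integer(ar_bin)
  shapes$discordant <- discordant
  shapes$category <- as.integer(category)
  attr(shapes, "classify_mode") <- mode
  shapes
}

#' Single-fragment classification
#'
#' Scalar convenience wrapper around [classify_fragments()].
#'
#' @param circularity,aspect_ratio scalar shape descriptors.
#' @inheritParams classify_fragments
#' @return integer category 1-4, or NA (unclassified, strict mode only).
#' @export
classify_fragment <- function(circularity, aspect_ratio, quartiles,
                              mode = c("lenient", "strict")) {
  df <- classify_fragments(
    data.frame(circularity = circularity, aspect_ratio = aspect_ratio),
    quartiles, mode)
  df$category
}

#' Per-field-of-view category percentages
#'
#' Percentages are computed on the total number of fragments in the field.
#' Unclassified fragments (strict mode) are included in the total and
#' reported separately, so the four category percentages plus the
#' unclassified percentage always sum to 100.
#'
#' @param categories integer vector of category labels (1-4 or NA) for one
#'   field of view.
#' @param fov field-of-view identifier.
#' @return a one-row data frame: fov, n, n_cat1..n_cat4, pct_cat1..pct_cat4,
#'   pct_unclassified, discordance_rate (NA unless `discordant` attribute
#'   supplied via the `discordant` argument).
#' @param discordant optional logical vector flagging discordant joint bins.
#' @export
fov_percentages <- function(categories, fov = 1L, discordant = NULL) {
  n <- length(categories)
  if (n == 0L) stop(sprintf("FOV %s has no classified fragments; percentages undefined", fov))
  counts <- vapply(1:4, function(k) sum(categories == k, na.rm = TRUE), integer(1))
  out <- data.frame(fov = fov, n = n,
                    n_cat1 = counts[1], n_cat2 = counts[2],
                    n_cat3 = counts[3], n_cat4 = counts[4],
                    pct_cat1 = 100 * counts[1] / n,
                    pct_cat2 = 100 * counts[2] / n,
                    pct_cat3 = 100 * counts[3] / n,
                    pct_cat4 = 100 * counts[4] / n,
                    pct_unclassified = 100 * sum(is.na(categories)) / n,
                    discordance_rate = if (is.null(discordant)) NA_real_ else
                      mean(discordant))
  out
}

#' Compare a category percentage between two cohorts
#'
#' Inputs are per-animal mean percentages (fields of view averaged within
#' each animal first, matching per-mouse reporting); the comparison is the
#' one-tailed Wilcoxon rank-sum test by default.
#'
#' @param groupA,groupB numeric vectors of per-animal mean percentages.
#' @param alternative "greater" (A > B), "less", or "two_sided"; the
#'   direction must be declared by the caller.
#' @return a `test_result` from [rank_sum_test()].
#' @export
cohort_compare <- function(groupA, groupB,
                           alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  rank_sum_test(groupA, groupB, alternative)
}

#' Aggregate field-of-view percentages to animal means
#'
#' @param fov_table data frame of [fov_percentages()] rows.
#' @param animal vector mapping each row to an animal id.
#' @return data frame of per-animal means of the percentage columns.
#' @export
animal_means <- function(fov_table, animal) {
  stopifnot(nrow(fov_table) == length(animal))
  cols <- grep("^pct_", names(fov_table), value = TRUE)
  agg <- stats::aggregate(fov_table[cols], by = list(animal = animal), FUN = mean)
  agg
}
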