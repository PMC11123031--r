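#' Sum member-metabolite counts into pathway feature vectors
#'
#' Each pathway category is represented by the element-wise sum of the raw
#' atom-color counts of its member metabolites: the pathway's value for an
#' atom color is the number of occurrences of that substructure across all
#' compounds in the category. The pathway matrix therefore starts with
#' exactly the same column set as the metabolite matrix.
#'
#' @param metabolites A [feature_matrix()] of raw (pre-normalization) counts.
#' @param membership A [pathway_membership()]; every member id must exist in
#'   `metabolites`.
#' @return A [feature_matrix()] with one row per pathway (in the
#'   membership's stable order) and `entity_kind = "pathway"`.
#' @export
sum_pathway_counts <- function(metabolites, membership) {
  stopifnot(inherits(metabolites, "feature_matrix"),
            inherits(membership, "pathway_membership"))
  check_membership_ids(membership, metabolites)
  vals <- t(vapply(membership, function(ids) {
    colSums(metabolites$values[ids, , drop = FALSE])
  }, numeric(ncol(metabolites$values))))
  rownames(vals) <- names(membership)
  colnames(vals) <- feature_names(metabolites)
  feature_matrix(vals, metabolites$bond_level, entity_kind = "pathway")
}

#' Normalize counts to proportions within each bond-inclusion level
#'
#' For every entry and every group of features sharing a bond-inclusion
#' level, each raw count is divided by the group's total (the denominator
#' includes the focal feature). A group totaling 10,000 with a focal count
#' of 1,000 yields 0.1. This makes entries with different overall sizes —
#' small compounds vs. large pathway categories — directly comparable.
#' Groups whose total is zero map to all zeros rather than NaN: an entry
#' with no substructures at a bond level carries no proportional signal.
#'
#' @param m A [feature_matrix()] of non-negative values.
#' @return A [feature_matrix()] of the same shape with values in \[0, 1\];
#'   every (entry, bond-level) group sums to exactly 1 (positive raw total)
#'   or 0 (zero raw total).
#' @export
normalize_within_bond_level <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- m$values
  for (lv in unique(m$bond_level)) {
    idx <- which(m$bond_level == lv)
    sub <- vals[, idx, drop = FALSE]
    tot <- rowSums(sub)
    pos <- tot > 0
    sub[pos, ] <- sub[pos, , drop = FALSE] / tot[pos]
    sub[!pos, ] <- 0
    vals[, idx] <- sub
  }
  feature_matrix(vals, m$bond_level, m$entity_kind)
}

#' Remove duplicate feature columns
#'
#' Two columns are duplicates iff their full value vectors are exactly
#' equal; at the stage where this runs (after proportion normalization)
#' values are exact rationals of integer counts, so exact equality is
#' reproducible and no tolerance is used. The earliest column of each
#' duplicate class is kept; kept-column order preserves input order.
#'
#' @param m A [feature_matrix()].
#' @return A list: `matrix` (the de-duplicated [feature_matrix()]),
#'   `removed` (character vector of dropped column names), `keep_map`
#'   (named character vector: removed name -> kept representative name).
#' @export
deduplicate_columns <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- m$values
  # %.17g keys give exact double identity through text
  keys <- vapply(seq_len(ncol(vals)), function(j) {
    paste(sprintf("%.17g", vals[, j]), collapse = ",")
  }, character(1))
  first <- match(keys, keys)
  keep <- which(first == seq_along(keys))
  removed_idx <- which(first != seq_along(keys))
  keep_map <- stats::setNames(colnames(vals)[first[removed_idx]],
                              colnames(vals)[removed_idx])
  list(matrix = fm_subset_cols(m, keep),
       removed = colnames(vals)[removed_idx],
       keep_map = keep_map)
}

#' Fit and/or apply per-feature min-max scaling
#'
#' With `ranges = NULL`, per-column minima and maxima are fit from `m` and
#' the transform `(x - min) / (max - min)` is applied; constant columns map
#' to 0. With fitted `ranges` supplied, they are applied as-is and the
#' result is clipped to \[0, 1\] (new data may exceed the training range).
#'
#' @param m A [feature_matrix()].
#' @param ranges Optional `scaling_ranges` from a previous fit; must cover
#'   every column of `m`.
#' @return A list: `matrix` (scaled [feature_matrix()]) and `ranges`
#'   (class `scaling_ranges`: named `min` and `max` vectors).
#' @export
min_max_scale <- function(m, ranges = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- m$values
  if (is.null(ranges)) {
    mins <- apply(vals, 2, min)
    maxs <- apply(vals, 2, max)
    ranges <- structure(list(min = mins, max = maxs), class = "scaling_ranges")
  } else {
    stopifnot(inherits(ranges, "scaling_ranges"))
    missing <- setdiff(colnames(vals), names(ranges$min))
    if (length(missing)) {
      stop_pathpair(sprintf("supplied ranges lack column(s): %s",
                            paste(utils::head(missing, 5), collapse = ", ")),
                    "pathpair_range_error")
    }
  }
  mins <- ranges$min[colnames(vals)]
  maxs <- ranges$max[colnames(vals)]
  span <- maxs - mins
  out <- sweep(vals, 2, mins, "-")
  const <- span == 0
  span[const] <- 1
  out <- sweep(out, 2, span, "/")
  out[, const] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  list(matrix = feature_matrix(out, m$bond_level, m$entity_kind),
       ranges = ranges)
}
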