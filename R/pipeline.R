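#' Run the feature-engineering pipeline from raw counts to pair dataset
#'
#' Convenience wrapper over the individual stages, in the canonical order:
#' sum member counts into pathway vectors, proportion-normalize both
#' matrices within bond-inclusion levels, de-duplicate the pathway
#' columns, and cross-join into labeled metabolite-pathway pairs. The
#' full (non-de-duplicated, normalized) pathway matrix is also returned —
#' it is the input the autoencoder needs, since encoder inputs must all
#' have the same width.
#'
#' Pathway vectors are computed from all metabolites, including any later
#' held out of a training split; set `from_train_only` and supply
#' `train_ids` to restrict the summation to training metabolites instead.
#'
#' @param metabolites Raw-count [feature_matrix()].
#' @param membership A [pathway_membership()].
#' @param from_train_only If `TRUE`, pathway sums use only `train_ids`.
#' @param train_ids Metabolite ids for `from_train_only`.
#' @return A list: `pairs` (the `pair_dataset`), `metabolites_norm`,
#'   `pathways_full` (normalized, not de-duplicated), `pathways_dedup`,
#'   `removed`, `keep_map`.
#' @export
build_pair_dataset <- function(metabolites, membership,
                               from_train_only = FALSE, train_ids = NULL) {
  memb_for_sums <- membership
  if (from_train_only) {
    if (is.null(train_ids)) {
      stop_pathpair("`from_train_only` requires `train_ids`",
                    "pathpair_validation_error")
    }
    memb_for_sums <- pathway_membership(lapply(membership, intersect,
                                               y = train_ids))
  }
  pathways_raw <- sum_pathway_counts(metabolites, memb_for_sums)
  pathways_full <- normalize_within_bond_level(pathways_raw)
  dd <- deduplicate_columns(pathways_full)
  metabolites_norm <- normalize_within_bond_level(metabolites)
  pairs <- cross_join(metabolites_norm, dd$matrix, membership)
  list(pairs = pairs, metabolites_norm = metabolites_norm,
       pathways_full = pathways_full, pathways_dedup = dd$matrix,
       removed = dd$removed, keep_map = dd$keep_map)
}
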