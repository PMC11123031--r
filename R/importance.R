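#' Aggregate per-iteration feature importances with a softmax
#'
#' Features whose raw gain score is 0 in every iteration are excluded
#' entirely. Within each iteration a softmax over the remaining features'
#' raw scores (`exp(s_f) / sum_g exp(s_g)`; a feature missing from an
#' iteration contributes raw 0 before the softmax) converts raw gains into
#' importances relative to every other feature; the mean across iterations
#' gives each feature's overall relative importance. Ranks are 1..n by
#' descending mean, ties broken by feature name. Where the same atom color
#' exists as both a metabolite and a pathway feature, the counterpart's
#' rank is cross-referenced.
#'
#' @param per_iteration List (one element per CV iteration) of named
#'   numeric vectors: feature name -> raw gain score. Names carry the
#'   `metabolite::` / `pathway::` prefix used by pair datasets.
#' @return An `importance_table` data.frame: `feature_name`, `entity_kind`,
#'   `atom_color`, `mean_relative_importance`, `rank`, `counterpart_rank`
#'   (NA when the other kind's feature is absent or excluded).
#' @export
aggregate_importance <- function(per_iteration) {
  per_iteration <- Filter(Negate(is.null), per_iteration)
  if (length(per_iteration) == 0L) {
    stop_pathpair("no iterations to aggregate", "pathpair_aggregation_error")
  }
  all_feats <- unique(unlist(lapply(per_iteration, names)))
  raw <- vapply(per_iteration, function(v) {
    out <- stats::setNames(numeric(length(all_feats)), all_feats)
    out[names(v)] <- v
    out
  }, numeric(length(all_feats)))
  raw <- matrix(raw, nrow = length(all_feats),
                dimnames = list(all_feats, NULL))
  keep <- rowSums(raw != 0) > 0
  if (!any(keep)) {
    stop_pathpair("all features scored 0 in every iteration",
                  "pathpair_aggregation_error")
  }
  raw <- raw[keep, , drop = FALSE]
  rel <- apply(raw, 2, function(s) {
    e <- exp(s - max(s))
    e / sum(e)
  })
  rel <- matrix(rel, nrow = nrow(raw), dimnames = dimnames(raw))
  mean_rel <- rowMeans(rel)
  nm <- names(mean_rel)
  ord <- order(-mean_rel, nm)
  tbl <- data.frame(feature_name = nm[ord],
                    entity_kind = ifelse(startsWith(nm[ord], "pathway::"),
                                         "pathway", "metabolite"),
                    atom_color = sub("^(metabolite|pathway)::", "", nm[ord]),
                    mean_relative_importance = unname(mean_rel[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  other <- ifelse(tbl$entity_kind == "pathway", "metabolite", "pathway")
  counterpart <- paste0(other, "::", tbl$atom_color)
  tbl$counterpart_rank <- tbl$rank[match(counterpart, tbl$feature_name)]
  class(tbl) <- c("importance_table", "data.frame")
  tbl
}

#' @export
print.importance_table <- function(x, n = 10L, ...) {
  cat(sprintf("<importance_table> %d features (%d pathway, %d metabolite)\n",
              nrow(x), sum(x$entity_kind == "pathway"),
              sum(x$entity_kind == "metabolite")))
  print.data.frame(utils::head(x, n))
  invisible(x)
}

#' Correlation between paired metabolite and pathway importances
#'
#' For every atom color retained as both a metabolite feature and a
#' pathway feature, pairs the two mean relative importances and reports
#' their Pearson and Spearman correlations — a check on whether an atom
#' color that matters for describing pathways also matters for describing
#' metabolites. Pairs where either side was excluded (all-zero importance
#' or de-duplicated away) are dropped.
#'
#' @param table An `importance_table` from [aggregate_importance()].
#' @return A list: `pearson`, `spearman` (NaN with a warning when one side
#'   is constant), `n_pairs`.
#' @export
importance_correlation <- function(table) {
  stopifnot(inherits(table, "importance_table"))
  met <- table[table$entity_kind == "metabolite", ]
  pat <- table[table$entity_kind == "pathway", ]
  shared <- intersect(met$atom_color, pat$atom_color)
  if (length(shared) < 3L) {
    stop_pathpair("need >= 3 atom colors present as both metabolite and pathway features",
                  "pathpair_insufficient_pairs_error")
  }
  x <- met$mean_relative_importance[match(shared, met$atom_color)]
  y <- pat$mean_relative_importance[match(shared, pat$atom_color)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("one side of the importance pairing is constant; correlation undefined")
    return(list(pearson = NaN, spearman = NaN, n_pairs = length(shared)))
  }
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"),
       n_pairs = length(shared))
}
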