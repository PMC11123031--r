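#' Cross-join metabolite and pathway feature vectors into labeled pairs
#'
#' Forms the Cartesian product of metabolite rows and pathway rows: one
#' pair entry per combination, ordered metabolite-major, whose feature
#' vector is the metabolite's features followed by the pathway's features
#' and whose binary label is 1 iff the metabolite is annotated to that
#' pathway category. Pair rows are held lazily as (metabolite index,
#' pathway index) so memory stays linear in the two input matrices;
#' [pair_features()] materializes any subset on demand.
#'
#' @param metabolites,pathways [feature_matrix()] objects (metabolite and
#'   pathway kinds).
#' @param membership A [pathway_membership()] defining the labels; it may
#'   reference only ids present in the two matrices.
#' @return A `pair_dataset`: row count `n_metabolites * n_pathways`,
#'   feature width `ncol(metabolites) + ncol(pathways)`, feature names
#'   prefixed `metabolite::` / `pathway::`.
#' @export
cross_join <- function(metabolites, pathways, membership) {
  stopifnot(inherits(metabolites, "feature_matrix"),
            inherits(pathways, "feature_matrix"),
            inherits(membership, "pathway_membership"))
  met_ids <- entry_ids(metabolites)
  path_ids <- entry_ids(pathways)
  if (length(intersect(met_ids, path_ids))) {
    stop_pathpair("metabolite and pathway identifiers collide",
                  "pathpair_naming_error")
  }
  check_membership_ids(membership, metabolites)
  unknown <- setdiff(names(membership), path_ids)
  if (length(unknown)) {
    stop_pathpair(sprintf("membership references unknown pathway(s): %s",
                          paste(unknown, collapse = ", ")),
                  "pathpair_reference_error")
  }
  nm <- length(met_ids)
  np <- length(path_ids)
  met_idx <- rep(seq_len(nm), each = np)
  path_idx <- rep.int(seq_len(np), nm)
  label <- integer(nm * np)
  for (p in names(membership)) {
    j <- match(p, path_ids)
    i <- match(membership[[p]], met_ids)
    label[(i - 1L) * np + j] <- 1L
  }
  structure(list(metabolites = metabolites, pathways = pathways,
                 met_idx = met_idx, path_idx = path_idx, label = label,
                 feature_names = c(paste0("metabolite::", feature_names(metabolites)),
                                   paste0("pathway::", feature_names(pathways)))),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset> %d pairs (%d metabolites x %d pathways as built)\n",
              length(x$label), nrow(x$metabolites$values),
              nrow(x$pathways$values)))
  cat(sprintf("  feature width: %d; positives: %d (%.1f%%)\n",
              length(x$feature_names), sum(x$label),
              100 * mean(x$label)))
  invisible(x)
}

#' Number of pair rows / pair feature width
#' @param ds A `pair_dataset`.
#' @return `n_pairs()`: integer row count. `pair_width()`: integer
#'   concatenated feature width.
#' @export
n_pairs <- function(ds) length(ds$label)

#' @rdname n_pairs
#' @export
pair_width <- function(ds) length(ds$feature_names)

#' Materialize the concatenated feature rows of a pair dataset
#'
#' @param ds A `pair_dataset`.
#' @param rows Optional integer row indices; default all rows.
#' @return Numeric matrix `length(rows) x pair_width(ds)` with the pair
#'   feature names as colnames.
#' @export
pair_features <- function(ds, rows = NULL) {
  rows <- rows %||% seq_along(ds$label)
  out <- cbind(ds$metabolites$values[ds$met_idx[rows], , drop = FALSE],
               ds$pathways$values[ds$path_idx[rows], , drop = FALSE])
  dimnames(out) <- list(NULL, ds$feature_names)
  out
}

#' Pair-level identifiers and labels
#' @param ds A `pair_dataset`.
#' @param rows Optional row indices.
#' @return A data.frame with `metabolite_id`, `pathway_id`, `label`.
#' @export
pair_info <- function(ds, rows = NULL) {
  rows <- rows %||% seq_along(ds$label)
  data.frame(metabolite_id = entry_ids(ds$metabolites)[ds$met_idx[rows]],
             pathway_id = entry_ids(ds$pathways)[ds$path_idx[rows]],
             label = ds$label[rows], stringsAsFactors = FALSE)
}

pair_subset <- function(ds, rows) {
  structure(list(metabolites = ds$metabolites, pathways = ds$pathways,
                 met_idx = ds$met_idx[rows], path_idx = ds$path_idx[rows],
                 label = ds$label[rows], feature_names = ds$feature_names),
            class = "pair_dataset")
}

#' Plan a stratified Monte-Carlo train/test split
#'
#' Strata are (pathway, label) combinations, so every pathway's positives
#' are represented in every test set — a requirement for per-pathway
#' metric reporting. The evaluation protocol repeats independent random
#' splits (Monte-Carlo cross-validation), not disjoint k-folds.
#'
#' @param test_fraction Fraction of rows assigned to test, in (0, 1).
#'   Default 0.2.
#' @param seed Integer seed; splits are deterministic given it.
#' @return A `split_plan`.
#' @export
split_plan <- function(test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  structure(list(test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified train/test split of a pair dataset
#'
#' Per-stratum test counts follow the largest-remainder method so the
#' global test size is `round(test_fraction * n)` while each stratum's
#' count differs from `test_fraction * size` by at most 1; every stratum of
#' size >= 2 is represented in both splits.
#'
#' @param ds A `pair_dataset`.
#' @param plan A [split_plan()].
#' @return A list with `train` and `test` pair datasets: disjoint, covering
#'   `ds`, with no duplicated test rows.
#' @export
stratified_split <- function(ds, plan) {
  stopifnot(inherits(ds, "pair_dataset"), inherits(plan, "split_plan"))
  stratum <- paste(ds$path_idx, ds$label, sep = "\r")
  sizes <- table(stratum)
  if (any(sizes < 2L)) {
    bad <- names(sizes)[sizes < 2L]
    stop_pathpair(sprintf(
      paste("stratification requires >= 2 rows per (pathway, label) stratum;",
            "%d stratum(s) have a single row. Merge sparse pathways or add",
            "metabolites before splitting."), length(bad)),
      "pathpair_stratification_error")
  }
  n <- length(ds$label)
  target <- round(plan$test_fraction * n)
  exact <- as.numeric(sizes) * plan$test_fraction
  base <- floor(exact)
  frac <- exact - base
  # keep both splits populated per stratum
  base <- pmin(pmax(base, 1L), as.numeric(sizes) - 1L)
  deficit <- target - sum(base)
  ord <- order(frac, decreasing = TRUE)
  counts <- base
  if (deficit > 0) {
    for (k in ord) {
      if (deficit == 0) break
      if (counts[k] < sizes[k] - 1L) { counts[k] <- counts[k] + 1L; deficit <- deficit - 1L }
    }
  } else if (deficit < 0) {
    for (k in rev(ord)) {
      if (deficit == 0) break
      if (counts[k] > 1L) { counts[k] <- counts[k] - 1L; deficit <- deficit + 1L }
    }
  }
  test_rows <- with_seed(plan$seed, {
    unlist(lapply(seq_along(sizes), function(k) {
      rows <- which(stratum == names(sizes)[k])
      rows[sample.int(length(rows), counts[k])]
    }), use.names = FALSE)
  })
  test_rows <- sort(test_rows)
  train_rows <- setdiff(seq_len(n), test_rows)
  list(train = pair_subset(ds, train_rows),
       test = pair_subset(ds, test_rows))
}

#' Balance a training set by duplicating positive entries
#'
#' Every positive row is replicated `k = floor(n_neg / n_pos)` times (its
#' original occurrence plus `k - 1` copies), the largest equal whole-number
#' duplication for which the positive proportion stays at or just under
#' 50%. Negatives are untouched and the set of distinct rows never changes.
#' Test sets must never pass through this operation: duplicated test
#' entries make results overly optimistic.
#'
#' @param train A `pair_dataset` containing at least one positive and one
#'   negative row.
#' @return The oversampled `pair_dataset` (unchanged when `k = 1`).
#' @export
oversample_positives <- function(train) {
  stopifnot(inherits(train, "pair_dataset"))
  pos <- which(train$label == 1L)
  neg <- which(train$label == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_pathpair("oversampling needs both classes present",
                  "pathpair_balance_error")
  }
  k <- max(1L, length(neg) %/% length(pos))
  if (k == 1L) return(train)
  rows <- c(seq_along(train$label), rep(pos, k - 1L))
  pair_subset(train, rows)
}
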