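#' Construct a feature matrix of atom-color counts or derived values
#'
#' The common currency of the pipeline: a dense non-negative matrix whose
#' rows are entries (metabolites or pathway categories) and whose columns are
#' atom-color features. Each feature carries a bond-inclusion level — the
#' neighborhood depth at which the atom color is defined (0 = element only,
#' 1 = one bond out, ...) — which drives the within-level proportion
#' normalization.
#'
#' @param values Numeric matrix, entries x features, with unique non-empty
#'   rownames (entry identifiers) and colnames (atom-color names). All values
#'   must be finite and non-negative.
#' @param bond_level Integer vector of bond-inclusion levels, one per column;
#'   either unnamed (positional) or named by column name.
#' @param entity_kind `"metabolite"` or `"pathway"`; the kind of entry the
#'   rows represent.
#' @return An object of class `feature_matrix`: a list with elements
#'   `values`, `bond_level` (named integer vector) and `entity_kind`.
#' @examples
#' m <- feature_matrix(
#'   matrix(c(1, 2, 3, 4), 2, 2,
#'          dimnames = list(c("m1", "m2"), c("C0", "O0"))),
#'   bond_level = c(0L, 0L))
#' dim(m)
#' @export
feature_matrix <- function(values, bond_level,
                           entity_kind = c("metabolite", "pathway")) {
  entity_kind <- match.arg(entity_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_pathpair("`values` must be a numeric matrix", "pathpair_validation_error")
  }
  if (nrow(values) < 1L) {
    stop_pathpair("feature matrix must have at least one entry",
                  "pathpair_validation_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_pathpair("`values` must carry rownames (entry ids) and colnames (feature names)",
                  "pathpair_validation_error")
  }
  if (anyDuplicated(rownames(values))) {
    stop_pathpair("duplicate entry ids", "pathpair_validation_error")
  }
  if (anyDuplicated(colnames(values))) {
    stop_pathpair("duplicate feature names", "pathpair_validation_error")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_pathpair("feature values must be finite and >= 0",
                  "pathpair_validation_error")
  }
  bond_level <- as.integer(bond_level)
  if (is.null(names(bond_level))) {
    if (length(bond_level) != ncol(values)) {
      stop_pathpair("`bond_level` must give a level for every column",
                    "pathpair_metadata_error")
    }
    names(bond_level) <- colnames(values)
  } else {
    missing <- setdiff(colnames(values), names(bond_level))
    if (length(missing)) {
      stop_pathpair(sprintf("no bond level for feature(s): %s",
                            paste(utils::head(missing, 5), collapse = ", ")),
                    "pathpair_metadata_error")
    }
    bond_level <- bond_level[colnames(values)]
  }
  if (anyNA(bond_level) || any(bond_level < 0L)) {
    stop_pathpair("bond levels must be non-negative integers",
                  "pathpair_metadata_error")
  }
  structure(list(values = values, bond_level = bond_level,
                 entity_kind = entity_kind),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d %s entries x %d atom-color features\n",
              nrow(x$values), x$entity_kind, ncol(x$values)))
  lv <- table(x$bond_level)
  cat("  bond levels:",
      paste(sprintf("L%s:%d", names(lv), as.integer(lv)), collapse = " "), "\n")
  invisible(x)
}

entry_ids <- function(m) rownames(m$values)
feature_names <- function(m) colnames(m$values)

# Subset a feature_matrix by column index/names, keeping metadata in step.
fm_subset_cols <- function(m, j) {
  feature_matrix(m$values[, j, drop = FALSE], m$bond_level[j], m$entity_kind)
}
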