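#' Read a feature matrix from disk
#'
#' Two on-disk layouts are supported. `"csv"` is a plain comma-separated
#' UTF-8 table: header row of feature names, first column the entry id.
#' `"feather"` is the Arrow feather (IPC) binary format with the entry id in
#' a leading `.entry_id` column; it round-trips doubles exactly. Both
#' layouts carry feature metadata in a JSON sidecar `<path>.meta.json`
#' mapping each feature name to its bond level, plus the entity kind, so the
#' pipeline never has to parse bond levels out of atom-color name syntax.
#'
#' @param path File path. The sidecar is looked up at `<path>.meta.json`.
#' @param fmt `"csv"` or `"feather"`.
#' @return A validated [feature_matrix()] with column order as stored.
#' @seealso [write_feature_matrix()]
#' @export
read_feature_matrix <- function(path, fmt = c("csv", "feather")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) {
    stop_pathpair(sprintf("no such file: %s", path), "pathpair_io_error")
  }
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop_pathpair(sprintf("missing metadata sidecar: %s", meta_path),
                  "pathpair_metadata_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$bond_level) || is.null(meta$entity_kind)) {
    stop_pathpair("sidecar must contain `bond_level` and `entity_kind`",
                  "pathpair_metadata_error")
  }
  if (fmt == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
    if (nrow(df) == 0L || ncol(df) < 2L) {
      stop_pathpair("feature matrix file is empty", "pathpair_validation_error")
    }
    ids <- as.character(df[[1L]])
    vals <- df[, -1L, drop = FALSE]
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_pathpair("the `arrow` package is required for feather format",
                    "pathpair_io_error")
    }
    df <- as.data.frame(arrow::read_feather(path))
    if (nrow(df) == 0L) {
      stop_pathpair("feature matrix file is empty", "pathpair_validation_error")
    }
    ids <- as.character(df[[".entry_id"]])
    vals <- df[, setdiff(names(df), ".entry_id"), drop = FALSE]
  }
  not_num <- !vapply(vals, is.numeric, logical(1))
  if (any(not_num)) {
    stop_pathpair(sprintf("non-numeric feature column(s): %s",
                          paste(names(vals)[not_num], collapse = ", ")),
                  "pathpair_validation_error")
  }
  missing_meta <- setdiff(names(vals), names(meta$bond_level))
  if (length(missing_meta)) {
    stop_pathpair(sprintf("sidecar lacks bond level for column(s): %s",
                          paste(missing_meta, collapse = ", ")),
                  "pathpair_metadata_error")
  }
  values <- as.matrix(vals)
  rownames(values) <- ids
  feature_matrix(values,
                 bond_level = unlist(meta$bond_level)[colnames(values)],
                 entity_kind = meta$entity_kind)
}

#' Write a feature matrix (and its metadata sidecar) to disk
#'
#' CSV output reproduces values to at least 1e-12 on round trip (17
#' significant digits are printed); feather output round-trips exactly.
#'
#' @param m A [feature_matrix()].
#' @param path Output file path; `<path>.meta.json` is written alongside.
#' @param fmt `"csv"` or `"feather"`.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(m, path, fmt = c("csv", "feather")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(m, "feature_matrix"))
  meta <- list(entity_kind = m$entity_kind,
               bond_level = as.list(m$bond_level))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  if (fmt == "csv") {
    df <- data.frame(entry_id = entry_ids(m), check.names = FALSE)
    vals <- m$values
    df <- cbind(df, as.data.frame(vals, check.names = FALSE))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    # %.17g round-trips IEEE doubles through text
    writeLines(paste(c("entry_id", colnames(vals)), collapse = ","), con)
    for (i in seq_len(nrow(vals))) {
      writeLines(paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])),
                       collapse = ","), con)
    }
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_pathpair("the `arrow` package is required for feather format",
                    "pathpair_io_error")
    }
    df <- data.frame(.entry_id = entry_ids(m), check.names = FALSE)
    df <- cbind(df, as.data.frame(m$values, check.names = FALSE))
    arrow::write_feather(df, path)
  }
  invisible(path)
}

#' Read a pathway-membership map from JSON
#'
#' The file is a JSON object mapping pathway-category name to a list of
#' member metabolite identifiers, e.g. `{"Amino acid metabolism":
#' ["C00025", "C00037"]}`. Members are deduplicated (set semantics) and
#' pathways are ordered lexicographically so downstream row order is stable.
#'
#' @param path JSON file path.
#' @return A `pathway_membership`: a named list of unique character vectors.
#' @export
read_pathway_membership <- function(path) {
  if (!file.exists(path)) {
    stop_pathpair(sprintf("no such file: %s", path), "pathpair_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pathway_membership(raw)
}

#' Construct a pathway-membership map
#'
#' @param x Named list: pathway name -> character vector of metabolite ids.
#' @return A `pathway_membership` with sorted pathway names and deduplicated
#'   member sets.
#' @export
pathway_membership <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    stop_pathpair("membership must be a named list of member-id vectors",
                  "pathpair_validation_error")
  }
  x <- lapply(x, function(v) unique(as.character(v)))
  empty <- vapply(x, length, integer(1)) == 0L
  if (any(empty)) {
    stop_pathpair(sprintf("pathway(s) with empty member set: %s",
                          paste(names(x)[empty], collapse = ", ")),
                  "pathpair_validation_error")
  }
  x <- x[order(names(x))]
  structure(x, class = "pathway_membership")
}

#' @export
print.pathway_membership <- function(x, ...) {
  cat(sprintf("<pathway_membership> %d pathway categories\n", length(x)))
  sizes <- vapply(x, length, integer(1))
  cat("  member counts:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Write a pathway-membership map to JSON
#'
#' @param membership A `pathway_membership`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pathway_membership <- function(membership, path) {
  stopifnot(inherits(membership, "pathway_membership"))
  jsonlite::write_json(unclass(membership), path)
  invisible(path)
}

# Check that every referenced metabolite id exists in the companion matrix.
check_membership_ids <- function(membership, metabolites) {
  known <- entry_ids(metabolites)
  for (p in names(membership)) {
    missing <- setdiff(membership[[p]], known)
    if (length(missing)) {
      stop_pathpair(sprintf(
        "pathway '%s' references unknown metabolite id(s): %s",
        p, paste(utils::head(missing, 5), collapse = ", ")),
        "pathpair_reference_error")
    }
  }
  invisible(TRUE)
}
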