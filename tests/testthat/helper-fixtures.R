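# Small fixtures built in code.

# A counts matrix with named entries/features and per-column bond levels.
make_fm <- function(values, bond_level, entity_kind = "metabolite",
                    ids = NULL, feats = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(ids %||% 1))
  rownames(values) <- ids %||% paste0("m", seq_len(nrow(values)))
  colnames(values) <- feats %||% paste0("f", seq_len(ncol(values)))
  feature_matrix(values, bond_level, entity_kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random non-negative count matrix for property tests.
random_fm <- function(n = 6, k = 5, levels = NULL, seed = 1,
                      entity_kind = "metabolite") {
  set.seed(seed)
  vals <- matrix(rpois(n * k, 3), n, k,
                 dimnames = list(paste0("m", seq_len(n)),
                                 paste0("f", seq_len(k))))
  feature_matrix(vals, levels %||% rep(0L, k), entity_kind)
}

# Toy pair dataset: nm metabolites x np pathways, every pathway gets
# `per_path` members, so every (pathway, label) stratum is populated.
toy_pairs <- function(nm = 6, np = 4, per_path = 2, k = 3, seed = 1) {
  set.seed(seed)
  met <- random_fm(nm, k, seed = seed)
  path_vals <- matrix(runif(np * k), np, k,
                      dimnames = list(paste0("P", seq_len(np)),
                                      paste0("f", seq_len(k))))
  paths <- feature_matrix(path_vals, rep(0L, k), "pathway")
  memb <- pathway_membership(setNames(
    lapply(seq_len(np), function(j) {
      paste0("m", sample.int(nm, per_path))
    }), paste0("P", seq_len(np))))
  cross_join(met, paths, memb)
}

# A linearly separable two-feature pair dataset: label decided by the
# metabolite's first feature being above 5.
separable_pairs <- function(n = 40) {
  vals <- cbind(f1 = rep(c(1, 9), each = n / 2), f2 = runif(n))
  rownames(vals) <- paste0("m", seq_len(n))
  met <- feature_matrix(vals, c(0L, 0L), "metabolite")
  paths <- feature_matrix(matrix(0.5, 1, 2, dimnames = list("P1", c("f1", "f2"))),
                          c(0L, 0L), "pathway")
  memb <- pathway_membership(list(P1 = paste0("m", (n / 2 + 1):n)))
  cross_join(met, paths, memb)
}
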