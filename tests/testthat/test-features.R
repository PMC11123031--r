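test_that("bond-level proportion normalization matches the worked example", {
  # one entry; a 0-bond group totaling 10,000 with a focal carbon count of 1,000
  m <- make_fm(matrix(c(1000, 6000, 3000, 7), 1, 4), c(0L, 0L, 0L, 1L),
               ids = "P", feats = c("C0", "H0", "O0", "C1"))
  norm <- normalize_within_bond_level(m)
  expect_identical(norm$values[1, "C0"], 0.1)
  # a single nonzero feature in its group becomes exactly 1
  expect_identical(norm$values[1, "C1"], 1)
})

test_that("normalized bond-level groups sum to 1 (or 0 for empty groups)", {
  for (seed in 1:5) {
    m <- random_fm(n = 7, k = 9, levels = rep(c(0L, 1L, 2L), each = 3),
                   seed = seed)
    m$values[3, m$bond_level == 1L] <- 0  # plant an all-zero group
    norm <- normalize_within_bond_level(m)
    expect_true(all(norm$values >= 0 & norm$values <= 1))
    for (lv in unique(m$bond_level)) {
      raw_tot <- rowSums(m$values[, m$bond_level == lv, drop = FALSE])
      norm_tot <- rowSums(norm$values[, m$bond_level == lv, drop = FALSE])
      expect_equal(norm_tot, ifelse(raw_tot > 0, 1, 0),
                   ignore_attr = TRUE)
    }
  }
})

test_that("normalization is invariant to per-entry scaling of raw counts", {
  m <- random_fm(n = 4, k = 6, levels = rep(c(0L, 1L), each = 3), seed = 2)
  scaled_vals <- m$values
  scaled_vals[2, ] <- scaled_vals[2, ] * 7.5
  m2 <- feature_matrix(scaled_vals, m$bond_level, m$entity_kind)
  expect_equal(normalize_within_bond_level(m)$values[2, ],
               normalize_within_bond_level(m2)$values[2, ])
})

test_that("pathway sums equal member-wise column sums and are additive", {
  met <- make_fm(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE), c(0L, 0L),
                 ids = c("m1", "m2"))
  both <- sum_pathway_counts(met, pathway_membership(list(P = c("m1", "m2"))))
  expect_equal(both$values["P", ], c(f1 = 4, f2 = 6))
  single <- sum_pathway_counts(met, pathway_membership(list(P = "m2")))
  expect_equal(single$values["P", ], met$values["m2", ])
  expect_identical(both$entity_kind, "pathway")

  # additivity: disjoint halves sum to the whole
  met2 <- random_fm(8, 5, seed = 3)
  ids <- rownames(met2$values)
  whole <- sum_pathway_counts(met2, pathway_membership(list(P = ids)))
  halves <- sum_pathway_counts(met2, pathway_membership(
    list(A = ids[1:4], B = ids[5:8])))
  expect_equal(whole$values["P", ],
               halves$values["A", ] + halves$values["B", ])

  expect_error(
    sum_pathway_counts(met, pathway_membership(list(P = "mX"))),
    class = "pathpair_reference_error")
})

test_that("column de-duplication keeps the earliest column of each class", {
  vals <- cbind(c1 = c(1, 2), c2 = c(3, 4), c3 = c(1, 2))
  rownames(vals) <- c("m1", "m2")
  dd <- deduplicate_columns(feature_matrix(vals, rep(0L, 3), "pathway"))
  expect_identical(colnames(dd$matrix$values), c("c1", "c2"))
  expect_identical(dd$removed, "c3")
  expect_identical(dd$keep_map, c(c3 = "c1"))
})

test_that("de-duplication agrees with an all-pairs oracle and is idempotent", {
  # oracle: O(k^2) scan for the earliest exactly-equal column
  oracle_keep <- function(vals) {
    k <- ncol(vals)
    keep <- rep(TRUE, k)
    for (j in 2:k) {
      for (i in 1:(j - 1)) {
        if (identical(vals[, i], vals[, j])) { keep[j] <- FALSE; break }
      }
    }
    keep
  }
  for (seed in 1:20) {
    set.seed(seed)
    vals <- matrix(sample(0:1, 12 * 8, replace = TRUE), 12, 8,
                   dimnames = list(paste0("m", 1:12), paste0("c", 1:8)))
    m <- feature_matrix(vals, rep(0L, 8), "pathway")
    dd <- deduplicate_columns(m)
    expect_identical(colnames(dd$matrix$values),
                     colnames(vals)[oracle_keep(vals)])
    again <- deduplicate_columns(dd$matrix)
    expect_identical(again$matrix$values, dd$matrix$values)
    expect_length(again$removed, 0L)
  }
})

test_that("min-max scaling maps ranges to [0, 1] with degenerate rules", {
  m <- make_fm(matrix(c(0, 5, 10, 7, 7, 7), 3, 2), c(0L, 0L),
               ids = c("a", "b", "c"), feats = c("x", "const"))
  sc <- min_max_scale(m)
  expect_equal(unname(sc$matrix$values[, "x"]), c(0, 0.5, 1))
  expect_equal(unname(sc$matrix$values[, "const"]), c(0, 0, 0))

  # reuse fitted ranges on out-of-range data: clipped to [0, 1]
  m2 <- make_fm(matrix(c(20, 0, 7, 7), 2, 2), c(0L, 0L),
                ids = c("d", "e"), feats = c("x", "const"))
  sc2 <- min_max_scale(m2, sc$ranges)
  expect_equal(unname(sc2$matrix$values[, "x"]), c(1, 0))

  bad <- make_fm(matrix(1:2, 1, 2), c(0L, 0L), ids = "a",
                 feats = c("x", "unseen"))
  expect_error(min_max_scale(bad, sc$ranges), class = "pathpair_range_error")
})
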