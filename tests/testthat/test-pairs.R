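test_that("cross join enumerates every (metabolite, pathway) combination", {
  met <- make_fm(matrix(1:6, 3, 2), c(0L, 0L), ids = c("m1", "m2", "m3"))
  paths <- make_fm(matrix(7:10, 2, 2), c(0L, 0L), ids = c("p1", "p2"),
                   entity_kind = "pathway")
  memb <- pathway_membership(list(p1 = "m1", p2 = c("m1", "m2", "m3")))
  ds <- cross_join(met, paths, memb)

  expect_identical(n_pairs(ds), 6L)
  expect_identical(pair_width(ds), 4L)
  # oracle: exhaustive enumeration, metabolite-major
  info <- pair_info(ds)
  expect_identical(info$metabolite_id, rep(c("m1", "m2", "m3"), each = 2))
  expect_identical(info$pathway_id, rep(c("p1", "p2"), 3))
  expect_identical(info$label, c(1L, 1L, 0L, 1L, 0L, 1L))
  expect_identical(sum(info$label), sum(lengths(memb)))

  X <- pair_features(ds)
  expect_identical(colnames(X),
                   c("metabolite::f1", "metabolite::f2",
                     "pathway::f1", "pathway::f2"))
  expect_equal(X[4, ], c(`metabolite::f1` = 2, `metabolite::f2` = 5,
                         `pathway::f1` = 8, `pathway::f2` = 10))

  # single member pair
  one <- cross_join(make_fm(matrix(1, 1, 1), 0L, ids = "m1"),
                    make_fm(matrix(2, 1, 1), 0L, ids = "p1",
                            entity_kind = "pathway"),
                    pathway_membership(list(p1 = "m1")))
  expect_identical(n_pairs(one), 1L)
  expect_identical(one$label, 1L)

  # id collision between a metabolite and a pathway
  clash <- make_fm(matrix(2, 1, 1), 0L, ids = "m1", entity_kind = "pathway")
  expect_error(cross_join(met, clash, pathway_membership(list(m1 = "m2"))),
               class = "pathpair_naming_error")
})

test_that("positive pair count equals the total membership size", {
  for (seed in 1:5) {
    ds <- toy_pairs(nm = 10, np = 5, per_path = 3, seed = seed)
    memb_sizes <- tapply(pair_info(ds)$label, pair_info(ds)$pathway_id, sum)
    expect_identical(sum(ds$label), 5L * 3L)
    expect_true(all(memb_sizes == 3L))
  }
})

test_that("stratified splits are deterministic, disjoint and proportionate", {
  ds <- toy_pairs(nm = 6, np = 4, per_path = 2, seed = 3)  # 24 rows
  plan <- split_plan(0.25, seed = 42)
  sp1 <- stratified_split(ds, plan)
  sp2 <- stratified_split(ds, plan)
  key <- function(d) paste(d$met_idx, d$path_idx)
  expect_identical(key(sp1$test), key(sp2$test))

  # across many seeds: exact cover, no duplicated test rows, per-stratum
  # proportions within one row of the target
  for (seed in 1:300) {
    sp <- stratified_split(ds, split_plan(0.25, seed))
    expect_identical(sort(c(key(sp$train), key(sp$test))), sort(key(ds)))
    expect_identical(anyDuplicated(key(sp$test)), 0L)
    # size-2 positive strata are forced to 1 test row each, so the global
    # test size can exceed round(0.25 * 24) by at most one row per stratum
    expect_lte(abs(length(sp$test$label) - 6L), 2L)
    strat <- paste(ds$path_idx, ds$label)
    test_strat <- paste(sp$test$path_idx, sp$test$label)
    for (s in unique(strat)) {
      expect_lte(abs(sum(test_strat == s) - 0.25 * sum(strat == s)), 1)
      expect_gte(sum(test_strat == s), 1L)  # both splits populated
    }
  }

  # exact divisibility: every stratum contributes exactly its share
  big <- toy_pairs(nm = 20, np = 2, per_path = 10, seed = 5)  # strata of 10
  spb <- stratified_split(big, split_plan(0.2, 1))
  expect_identical(length(spb$test$label), 8L)
  strat_b <- paste(spb$test$path_idx, spb$test$label)
  expect_true(all(table(strat_b) == 2L))

  # stratum of size 1 is rejected with a remediation message
  met <- make_fm(matrix(1:4, 2, 2), c(0L, 0L), ids = c("m1", "m2"))
  paths <- make_fm(matrix(1:2, 1, 2), c(0L, 0L), ids = "p1",
                   entity_kind = "pathway")
  tiny <- cross_join(met, paths, pathway_membership(list(p1 = "m1")))
  expect_error(stratified_split(tiny, plan),
               class = "pathpair_stratification_error")
})

test_that("positive oversampling duplicates whole copies up to 50%", {
  build <- function(n_pos, n_neg) {
    nm <- n_pos + n_neg
    met <- random_fm(nm, 2, seed = 1)
    paths <- make_fm(matrix(1:2, 1, 2), c(0L, 0L), ids = "p1",
                     entity_kind = "pathway")
    memb <- pathway_membership(list(p1 = paste0("m", seq_len(n_pos))))
    cross_join(met, paths, memb)
  }
  # 10 positives, 90 negatives -> k = 9, exactly 50%
  over <- oversample_positives(build(10, 90))
  expect_identical(sum(over$label == 1L), 90L)
  expect_identical(sum(over$label == 0L), 90L)
  expect_equal(mean(over$label), 0.5)

  # 30 positives, 70 negatives -> k = 2 -> 60/70
  over2 <- oversample_positives(build(30, 70))
  expect_identical(sum(over2$label == 1L), 60L)
  expect_identical(sum(over2$label == 0L), 70L)
  expect_lte(mean(over2$label), 0.5)
  # maximal under equal duplication: one more copy each would exceed 50%
  expect_gt((60 + 30) / (90 + 70), 0.5)

  # balanced input unchanged (k = 1)
  bal <- build(50, 50)
  expect_identical(oversample_positives(bal)$label, bal$label)

  # multiplicities change, the set of distinct rows does not
  key <- function(d) paste(d$met_idx, d$path_idx)
  expect_setequal(unique(key(over)), unique(key(build(10, 90))))

  # single-class input is rejected
  ds10 <- build(10, 90)
  allpos <- pathpair:::pair_subset(ds10, which(ds10$label == 1L))
  expect_error(oversample_positives(allpos), class = "pathpair_balance_error")
})
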