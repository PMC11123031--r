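test_that("metrics agree with the closed-form contingency oracle", {
  # independent oracle: direct arithmetic on (tp, fp, tn, fn)
  oracle <- function(tp, fp, tn, fn) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    list(accuracy = (tp + tn) / (tp + fp + tn + fn),
         precision = prec, recall = rec,
         f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
         mcc = if (den > 0) (tp * tn - fp * fn) / den else 0)
  }
  for (tp in 0:5) for (fp in 0:5) for (tn in 0:5) for (fn in 0:5) {
    if (tp + fp + tn + fn == 0) next
    pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
    truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
    got <- compute_metrics(pred, truth)
    want <- oracle(tp, fp, tn, fn)
    for (m in names(want)) expect_equal(got[[m]], want[[m]])
  }
})

test_that("metric conventions and the 351/651 contingency check hold", {
  # TP=4, TN=90, FP=3, FN=3 -> MCC = 351/651
  pred <- c(rep(1, 4), rep(1, 3), rep(0, 90), rep(0, 3))
  truth <- c(rep(1, 4), rep(0, 3), rep(0, 90), rep(1, 3))
  expect_equal(compute_metrics(pred, truth)$mcc, 351 / 651)

  perfect <- compute_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_identical(perfect$mcc, 1)
  expect_identical(perfect$f1, 1)

  allneg <- compute_metrics(c(0, 0, 0), c(1, 0, 1))
  expect_identical(allneg$mcc, 0)
  expect_identical(allneg$precision, 0)

  expect_error(compute_metrics(c(1, 0), c(1)), class = "pathpair_shape_error")
})

test_that("run_cv stores one row per metric per iteration and per pathway", {
  ds <- toy_pairs(nm = 20, np = 3, per_path = 6, seed = 8)
  store <- results_store()
  cv <- run_cv(classifier_spec("gbt", list(nrounds = 10L), seed = 1), ds,
               n_iterations = 3, plan = split_plan(0.25, 7), store = store)
  expect_length(cv$metrics, 3L)
  overall <- store$cv_results[store$cv_results$pathway == "overall", ]
  expect_identical(nrow(overall), 3L * 5L)       # 5 metrics x 3 iterations
  per_path <- store$cv_results[store$cv_results$pathway != "overall", ]
  expect_identical(nrow(per_path), 3L * 3L)      # 3 pathways x 3 iterations
  # stored values match the returned objects
  m1 <- cv$metrics[[1]]
  got <- overall[overall$iteration == 1, ]
  expect_equal(got$value[match("mcc", got$metric_name)], m1$mcc)
})

test_that("tuning returns a singleton space and prefers a dominant config", {
  ds <- toy_pairs(nm = 30, np = 3, per_path = 8, seed = 4)
  single <- tune("gbt", search_space(nrounds = param_choice(list(15L))),
                 ds, n_trials = 2, cv_per_trial = 2,
                 plan = split_plan(0.25, 1), sampler_seed = 1)
  expect_identical(single$best_params$nrounds, 15L)

  # a planted-signal set where more boosting rounds strictly dominate
  sim <- simulate_pathway_data(sim_config(n_metabolites = 80L, n_pathways = 4L,
                                          features_per_level = c("0" = 6L, "1" = 14L),
                                          signatures_per_pathway = 2L,
                                          seed = 5))
  built <- build_pair_dataset(sim$metabolites, sim$membership)
  res <- tune("gbt", search_space(nrounds = param_choice(list(1L, 120L))),
              ds = built$pairs, n_trials = 10, cv_per_trial = 5,
              plan = split_plan(0.25, 2), sampler_seed = 3)
  expect_identical(res$best_params$nrounds, 120L)
  expect_identical(res$trials$median_mcc[res$best_trial],
                   res$best_median_mcc)
  # trial medians recompute from their definition
  expect_equal(median(c(0.2, 0.4, 0.6)), 0.4)
})

test_that("importance aggregation matches a brute-force softmax oracle", {
  # all-equal scores over k features -> 1/k each
  flat <- aggregate_importance(list(c(a = 2, b = 2, c = 2, d = 2)))
  expect_equal(flat$mean_relative_importance, rep(0.25, 4))

  # two identical iterations -> mean equals either one
  one <- aggregate_importance(list(c(a = 1, b = 3)))
  two <- aggregate_importance(list(c(a = 1, b = 3), c(a = 1, b = 3)))
  expect_equal(two$mean_relative_importance, one$mean_relative_importance)

  # random scores vs direct recomputation, with an ever-zero feature
  set.seed(6)
  iters <- lapply(1:3, function(i) {
    s <- c(runif(4), 0)
    names(s) <- c("metabolite::x", "pathway::x", "metabolite::y",
                  "pathway::z", "metabolite::dead")
    s
  })
  got <- aggregate_importance(iters)
  expect_false("metabolite::dead" %in% got$feature_name)
  raw <- sapply(iters, function(v) v[setdiff(names(iters[[1]]), "metabolite::dead")])
  want <- rowMeans(apply(raw, 2, function(s) exp(s) / sum(exp(s))))
  expect_equal(got$mean_relative_importance[match(names(want), got$feature_name)],
               unname(want))
  # per-iteration softmax sums to 1, so means sum to 1
  expect_equal(sum(got$mean_relative_importance), 1)
  # ranks descend with ties broken by name
  expect_identical(got$rank, seq_len(nrow(got)))
  expect_true(all(diff(got$mean_relative_importance) <= 0))
  # paired ranks cross-reference the same atom color of the other kind
  x_rows <- got[got$atom_color == "x", ]
  expect_identical(sort(x_rows$counterpart_rank), sort(x_rows$rank))

  expect_error(aggregate_importance(list()),
               class = "pathpair_aggregation_error")
})

test_that("importance correlation pairs shared atom colors correctly", {
  mk_table <- function(met_scores, path_scores) {
    iters <- list(c(setNames(met_scores, paste0("metabolite::", names(met_scores))),
                    setNames(path_scores, paste0("pathway::", names(path_scores)))))
    aggregate_importance(iters)
  }
  # pathway importances exactly equal to metabolite importances -> r = 1
  s <- c(a = 1, b = 2, c = 4)
  tbl <- mk_table(s, s)
  cc <- importance_correlation(tbl)
  expect_equal(cc$pearson, 1)
  expect_equal(cc$spearman, 1)
  expect_identical(cc$n_pairs, 3L)

  # one side constant -> NaN with a warning
  tbl2 <- mk_table(c(a = 1, b = 2, c = 4), c(a = 3, b = 3, c = 3))
  expect_warning(cc2 <- importance_correlation(tbl2), "constant")
  expect_true(is.nan(cc2$pearson))

  # fewer than 3 shared atom colors -> error
  tbl3 <- mk_table(c(a = 1, b = 2, c = 3), c(a = 1, d = 2, e = 3))
  expect_error(importance_correlation(tbl3),
               class = "pathpair_insufficient_pairs_error")

  # independent importances: correlation is small with high frequency
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    t4 <- mk_table(setNames(runif(100), paste0("c", 1:100)),
                   setNames(runif(100), paste0("c", 1:100)))
    if (abs(importance_correlation(t4)$pearson) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})
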