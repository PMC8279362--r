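# Fabricate an experiment_result with prescribed per-level, per-repeat
# micro-Q values (entropy optional) to exercise the verdict logic without
# running the pipeline.
fabricate_result <- function(design, q_train, q_indep, q_test = q_train,
                             ent_test = NULL, n_repeats = 4, noise = 0.002) {
  set.seed(83)
  lv <- as.character(seq_along(q_train))
  if (is.null(ent_test)) ent_test <- rep(2.5, length(lv))
  per_repeat <- do.call(rbind, lapply(seq_along(lv), function(i) {
    data.frame(level = lv[i], repeat_index = seq_len(n_repeats),
               q_train = q_train[i] + rnorm(n_repeats, 0, noise),
               q_test = q_test[i] + rnorm(n_repeats, 0, noise),
               q_indep = q_indep[i] + rnorm(n_repeats, 0, noise),
               gap = NA)
  }))
  per_repeat$gap <- per_repeat$q_train - per_repeat$q_indep
  levels_tab <- data.frame(level = lv, q_train = q_train, q_test = q_test,
                           q_indep = q_indep, ent_test = ent_test,
                           gap = q_train - q_indep)
  structure(list(design = design, ladder = as.list(lv), summary = NULL,
                 levels = levels_tab, per_repeat = per_repeat,
                 n_repeats = n_repeats),
            class = "experiment_result")
}

test_that("flat accuracies pass no-effect verdicts and fail trend verdicts", {
  flat <- fabricate_result("inter_query", q_train = rep(0.8, 4), q_indep = rep(0.7, 4))
  v <- trend_tests(flat)
  expect_true(v$train_unaffected$pass)
  expect_true(v$independent_unaffected$pass)

  flat2 <- fabricate_result("inner_query", q_train = rep(0.8, 4), q_indep = rep(0.7, 4))
  v2 <- trend_tests(flat2)
  expect_false(v2$gap_drop_significant$pass)
})

test_that("a monotone shrinking gap passes the inner-homology verdicts", {
  shrink <- fabricate_result("inner_query",
                             q_train = c(0.85, 0.82, 0.79, 0.76),
                             q_indep = rep(0.70, 4))
  v <- trend_tests(shrink)
  expect_true(v$gap_monotone_decreasing$pass)
  expect_true(v$gap_drop_significant$pass)
  expect_lt(v$gap_monotone_decreasing$spearman, 0)
})

test_that("query_reference and reference_redundancy verdicts read their registered statistics", {
  f4 <- fabricate_result("query_reference",
                         q_train = c(0.85, 0.80, 0.74),
                         q_test = c(0.80, 0.75, 0.70),
                         q_indep = rep(0.70, 3))
  v4 <- trend_tests(f4)
  expect_true(v4$train_drops$pass)
  expect_true(v4$test_drops$pass)
  expect_true(v4$independent_stable$pass)

  f5 <- fabricate_result("reference_redundancy",
                         q_train = c(0.75, 0.76, 0.77, 0.78),
                         q_test = c(0.70, 0.72, 0.73, 0.75),
                         q_indep = c(0.70, 0.70, 0.705, 0.71),
                         ent_test = c(1.1, 1.5, 1.9, 2.3))
  v5 <- trend_tests(f5)
  expect_true(v5$entropy_increases_each_step$pass)
  expect_true(v5$independent_not_reduced$pass)
  expect_true(v5$entropy_accuracy_corr_positive$pass)

  f13 <- fabricate_result("reference_size",
                          q_train = c(0.75, 0.80, 0.85),
                          q_indep = c(0.65, 0.67, 0.69))
  expect_true(all(vapply(trend_tests(f13), `[[`, TRUE, "pass")))
})

test_that("verdicts demand enough levels and repeats", {
  tiny <- fabricate_result("inner_query", q_train = c(0.8, 0.75), q_indep = c(0.7, 0.7),
                           n_repeats = 2)
  expect_error(trend_tests(tiny), "repeats")
})

test_that("a degenerate one-level ladder runs reproducibly end to end", {
  u <- test_universe(40)
  base <- layout_spec(reference_size = 60, train_size = 10, test_size = 10,
                      independent_size = 6, inner_cutoff_query = 0.9,
                      reference_inner_cutoff = 0.9, n_repeats = 2, seed = 91)
  cfg <- pipeline_config(ensemble = ensemble_config(2, "tree"))
  r1 <- run_ladder("inner_query", u, base, ladder = list(0.9), config = cfg)
  r2 <- run_ladder("inner_query", u, base, ladder = list(0.9), config = cfg)
  expect_equal(nrow(r1$per_repeat), 2)
  expect_identical(r1$levels, r2$levels)
  expect_equal(r1$levels$gap, r1$levels$q_train - r1$levels$q_indep)
  # every measure present for every group
  expect_true(all(c("q_train", "q_test", "q_indep", "sov_train", "ent_indep") %in%
                    names(r1$per_repeat)))
})

test_that("size exhaustion surfaces with design and level context", {
  u <- test_universe(12)
  base <- layout_spec(reference_size = 20, train_size = 200, test_size = 5,
                      independent_size = 4, n_repeats = 1, seed = 1)
  expect_error(
    run_ladder("inner_query", u, base, ladder = list(0.9),
               config = pipeline_config(ensemble = ensemble_config(1, "tree"))),
    "design inner_query, level 0.9")
})

test_that("the strategy comparison runs both layouts and reports verified cutoffs", {
  u <- test_universe(40)
  base <- layout_spec(reference_size = 20, train_size = 8, test_size = 8,
                      independent_size = 6, n_repeats = 2, seed = 131)
  cfg <- pipeline_config(ensemble = ensemble_config(2, "tree"))
  chk <- strategy_check(u, base, cutoff = 0.3, config = cfg, n_repeats = 2)
  expect_equal(chk$cutoffs$rigorous$inner_cutoff_query, 0.3)
  expect_equal(chk$cutoffs$rigorous$query_reference_cutoff, 0.3)
  expect_equal(chk$cutoffs$conventional$inter_cutoff_train_test, "All")
  expect_equal(nrow(chk$rigorous$per_repeat), 2)
  expect_equal(chk$gap_rigorous, mean(chk$rigorous$per_repeat$gap))
  expect_type(chk$rigorous_gap_not_larger, "logical")
})
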