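#' Configuration of the SSP pipeline stages shared by all experiments
#'
#' Bundles the profile-search and predictor settings one experiment run
#' needs.  The ladder experiments default to a light 10-member forest of
#' small networks so that multi-level multi-repeat designs stay desk-scale;
#' `ensemble_config()`'s own defaults (60 members, 30 hidden units) are the
#' full-size study configuration.
#'
#' @param window Feature window (odd, default 5).
#' @param max_hits,min_identity Hit-list cap and identity floor of
#'   [search_homologs()].
#' @param beta,background PSSM pseudocount weight and background.
#' @param ensemble An [ensemble_config()].
#' @param scoring An [identity_scoring()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 5, max_hits = 500, min_identity = 0.25,
                            beta = 1, background = rep(1 / 20, 20),
                            ensemble = ensemble_config(n_members = 10,
                                                       ann_size = 6,
                                                       ann_maxit = 50,
                                                       ann_decay = 0.01),
                            scoring = identity_scoring()) {
  structure(list(window = window, max_hits = max_hits,
                 min_identity = min_identity, beta = beta,
                 background = background, ensemble = ensemble,
                 scoring = scoring),
            class = "pipeline_config")
}

#' Run the full SSP pipeline on one layout
#'
#' Verifies the layout's declared homology constraints (fail-fast), builds
#' PSSM profiles for every query against its assigned reference set, trains
#' the ensemble on the training queries and evaluates all three groups.
#'
#' @param layout An `ssp_layout` from [build_layout()].
#' @param config A [pipeline_config()].
#' @param seed Training seed (defaults to the layout's sampling seed).
#' @param verify Re-check the layout with the all-pairs oracle first.
#' @return Named numeric vector: per group (train/test/indep) the micro-Q,
#'   weighted SOV and length-weighted mean profile entropy, plus
#'   `gap` = train minus independent micro-Q.
#' @export
run_ssp_experiment <- function(layout, config = pipeline_config(),
                               seed = layout$seed, verify = TRUE) {
  if (verify) verify_layout(layout, config$scoring)
  ref_of <- function(role) layout$reference[[layout$assignment[[role]]]]
  groups <- list(train = layout$train, test = layout$test,
                 independent = layout$independent)
  profiles <- lapply(names(groups), function(g)
    build_profiles(groups[[g]], ref_of(g), config$max_hits, config$min_identity,
                   config$beta, config$background, config$scoring))
  names(profiles) <- names(groups)

  enc_train <- encode_dataset(layout$train, profiles$train, config$window)
  model <- train_ensemble(enc_train$x, enc_train$y, config$ensemble, seed = seed)

  out <- numeric(0)
  for (g in names(groups)) {
    d <- groups[[g]]
    pred <- predict_dataset(model, d, profiles[[g]], config$window)
    rep_ <- score_predictions(pred, d$records$ss3, d$records$id)
    ent <- weighted_mean_entropy(profiles[[g]])
    tag <- c(train = "train", test = "test", independent = "indep")[[g]]
    out[paste0("q_", tag)] <- attr(rep_, "micro_q")
    out[paste0("sov_", tag)] <- attr(rep_, "weighted_sov")
    out[paste0("ent_", tag)] <- ent
  }
  out["gap"] <- out["q_train"] - out["q_indep"]
  out
}

ladder_designs <- c("inter_query", "inner_query", "reference_isolation", "query_reference", "reference_redundancy", "reference_size")

# Apply one ladder level to the base spec according to the design.
spec_at_level <- function(design, base_spec, level) {
  s <- base_spec
  switch(design,
    inter_query = { s$inter_cutoff_train_test <- level },
    inner_query = { s$inner_cutoff_query <- level },
    reference_isolation = { s$n_reference_sets <- as.integer(level) },
    query_reference = { s$query_reference_cutoff <- level },
    reference_redundancy = { s$reference_inner_cutoff <- level },
    reference_size = { s$reference_size <- as.integer(level) },
    stop("unknown design: ", design))
  validate_layout_spec(s)
  s
}

default_ladders <- list(
  inter_query = list(1.0, 0.9, 0.6, 0.4, 0.2),
  inner_query = list(0.9, 0.6, 0.4, 0.2),
  reference_isolation = list(1L, 2L, 3L),
  query_reference = list("All", 0.5, 0.2),
  reference_redundancy = list(1.0, 0.9, 0.6, 0.3),
  reference_size = list(250L, 500L, 1000L))

#' Run one experiment family over its homology (or size) ladder
#'
#' The designs mirror the experiment families of the study:
#' \describe{
#'   \item{inter_query}{inter-query homology between train and test varies}
#'   \item{inner_query}{inner-query homology within train/test varies}
#'   \item{reference_isolation}{1-3 isolated reference sets}
#'   \item{query_reference}{query-reference homology varies}
#'   \item{reference_redundancy}{reference inner homology varies}
#'   \item{reference_size}{reference size varies}
#' }
#' Each level builds its layouts, runs the pipeline for every repeat and
#' aggregates mean and sample sd of every measure.
#'
#' @param design One of the names above.
#' @param universe A [seq_dataset()].
#' @param base_spec A [layout_spec()]; the design's ladder field is
#'   overwritten per level.
#' @param ladder List of levels (defaults per design).
#' @param config A [pipeline_config()].
#' @param n_repeats Override of `base_spec$n_repeats`.
#' @return Object of class `experiment_result`: list with `design`,
#'   `ladder`, `summary` (one row per level x measure), `levels` (one row
#'   per level with the headline measures and the overfit gap) and
#'   `per_repeat`.
#' @export
run_ladder <- function(design, universe, base_spec = layout_spec(),
                       ladder = default_ladders[[design]],
                       config = pipeline_config(),
                       n_repeats = base_spec$n_repeats) {
  design <- match.arg(design, ladder_designs)
  stopifnot(length(ladder) >= 1)
  level_lab <- vapply(ladder, format, "")
  res <- lapply(seq_along(ladder), function(li) {
    spec <- spec_at_level(design, base_spec, ladder[[li]])
    rr <- tryCatch(
      run_repeats(universe, spec, function(layout, seed_r)
        run_ssp_experiment(layout, config, seed = seed_r), n_repeats,
        config$scoring),
      error = function(e) stop("design ", design, ", level ", level_lab[li],
                               ": ", conditionMessage(e), call. = FALSE))
    rr
  })
  per_repeat <- do.call(rbind, lapply(seq_along(res), function(li)
    cbind(level = level_lab[li], res[[li]]$per_repeat)))
  summary <- do.call(rbind, lapply(seq_along(res), function(li)
    cbind(level = level_lab[li], res[[li]]$summary)))
  levels_tab <- do.call(rbind, lapply(seq_along(res), function(li) {
    s <- res[[li]]$summary
    g <- function(m) s$mean[s$measure == m]
    data.frame(level = level_lab[li],
               q_train = g("q_train"), q_test = g("q_test"), q_indep = g("q_indep"),
               sov_train = g("sov_train"), sov_test = g("sov_test"),
               sov_indep = g("sov_indep"),
               ent_train = g("ent_train"), ent_test = g("ent_test"),
               ent_indep = g("ent_indep"),
               gap = g("q_train") - g("q_indep"))
  }))
  structure(list(design = design, ladder = ladder, summary = summary,
                 levels = levels_tab, per_repeat = per_repeat,
                 base_spec = base_spec, n_repeats = n_repeats),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result '%s'> %d levels x %d repeats\n",
              x$design, length(x$ladder), x$n_repeats))
  print(x$levels, digits = 3, row.names = FALSE)
  invisible(x)
}

repeat_values <- function(result, measure, level) {
  pr <- result$per_repeat
  pr[[measure]][pr$level == level]
}

#' Pre-registered qualitative verdicts for an experiment result
#'
#' Each design has named verdicts operationalising the study's qualitative
#' discoveries: "no effect" means the per-level means of a measure span
#' less than 2 percentage points and the extreme levels do not differ
#' significantly ([compare_groups()], alpha 0.05); trends use rank
#' correlations, significance of extreme-level differences, or per-step
#' monotonicity as documented per design.
#'
#' @param result An `experiment_result` with >= 3 levels (>= 2 for reference_size)
#'   and >= 3 repeats.
#' @param alpha Significance level.
#' @return Named list: each verdict carries `pass` (logical) plus its
#'   supporting statistics.
#' @export
trend_tests <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "experiment_result"))
  lv <- result$levels$level
  if (length(lv) < 2) stop("need at least 2 ladder levels")
  if (result$n_repeats < 3) stop("need at least 3 repeats for significance tests")
  first <- lv[1]; last <- lv[length(lv)]
  cmp <- function(measure) compare_groups(repeat_values(result, measure, first),
                                          repeat_values(result, measure, last),
                                          alpha)
  range_of <- function(measure) {
    m <- result$levels[[measure]]
    max(m) - min(m)
  }
  no_effect <- function(measure) {
    ct <- cmp(measure)
    list(pass = range_of(measure) < 0.02 && ct$p_value > alpha,
         range = range_of(measure), extreme_test = ct$test,
         extreme_p = ct$p_value)
  }
  switch(result$design,
    inter_query = list(
      train_unaffected = no_effect("q_train"),
      test_unaffected = no_effect("q_test"),
      independent_unaffected = no_effect("q_indep")),
    inner_query = {
      gaps <- result$levels$gap
      rho <- if (sd(gaps) == 0) 0 else
        pearson_corr(rank(seq_along(gaps)), rank(gaps))
      g1 <- repeat_values(result, "gap", first)
      g2 <- repeat_values(result, "gap", last)
      # matched repeats: a repeat seed reuses the same reference draw at
      # every level of a query-source ladder, so the drop is tested pairwise
      tt <- t.test(g1, g2, paired = TRUE)
      d <- mean(g1) - mean(g2)
      list(gap_monotone_decreasing = list(pass = rho < 0, spearman = rho,
                                          gaps = gaps),
           gap_drop_significant = list(pass = d > 0 && tt$p.value < alpha,
                                       drop = d, test = "paired t",
                                       p = tt$p.value))
    },
    reference_isolation = {
      pairs <- utils::combn(lv, 2, simplify = FALSE)
      per_group <- lapply(c("q_train", "q_test", "q_indep"), function(m) {
        ps <- vapply(pairs, function(pr)
          compare_groups(repeat_values(result, m, pr[1]),
                         repeat_values(result, m, pr[2]), alpha)$p_value, 0)
        list(pass = all(ps > alpha), min_p = min(ps))
      })
      names(per_group) <- c("train_unchanged", "test_unchanged", "independent_unchanged")
      per_group
    },
    query_reference = {
      ct_train <- cmp("q_train"); ct_test <- cmp("q_test")
      d_train <- mean(repeat_values(result, "q_train", first)) -
                 mean(repeat_values(result, "q_train", last))
      d_test <- mean(repeat_values(result, "q_test", first)) -
                mean(repeat_values(result, "q_test", last))
      list(
        train_drops = list(pass = d_train > 0 && ct_train$p_value < alpha,
                           drop = d_train, p = ct_train$p_value,
                           test = ct_train$test),
        test_drops = list(pass = d_test > 0 && ct_test$p_value < alpha,
                          drop = d_test, p = ct_test$p_value,
                          test = ct_test$test),
        independent_stable = no_effect("q_indep"))
    },
    reference_redundancy = {
      ents <- result$levels$ent_test
      ct <- cmp("q_indep")
      dec <- mean(repeat_values(result, "q_indep", last)) <
             mean(repeat_values(result, "q_indep", first))
      r <- pearson_corr(result$levels$ent_test, result$levels$q_test)
      list(
        entropy_increases_each_step = list(pass = all(diff(ents) > 0),
                                           entropies = ents),
        independent_not_reduced = list(
          pass = !(dec && ct$p_value < alpha),
          p = ct$p_value, test = ct$test),
        entropy_accuracy_corr_positive = list(pass = r > 0, r = r))
    },
    reference_size = {
      inc <- function(measure) {
        m <- result$levels[[measure]]
        list(pass = all(diff(m) > 0), means = m)
      }
      list(train_increases = inc("q_train"),
           test_increases = inc("q_test"),
           independent_increases = inc("q_indep"))
    },
    stop("no registered verdicts for design ", result$design))
}

#' Compare the proposed all-low-homology strategy with a conventional layout
#'
#' The proposed evaluation strategy reduces every homology relation (within
#' and between query sets, and between queries and reference) to the same
#' low cutoff; the conventional layout leaves inter-set homology unreduced
#' and keeps query sets redundant.  Both are run over the same repeats and
#' the overfit gap (train minus independent micro-Q) is compared pairwise.
#'
#' @param universe A [seq_dataset()].
#' @param base_spec A [layout_spec()] supplying sizes/repeats/seed.
#' @param cutoff The rigorous cutoff (default 0.3, the strategy's
#'   recommended level).
#' @param config A [pipeline_config()].
#' @param n_repeats Repeats (defaults to `base_spec$n_repeats`).
#' @return List with the two per-repeat tables, mean gaps, the layouts'
#'   declared cutoffs, and verdict `rigorous_gap_not_larger`.
#' @export
strategy_check <- function(universe, base_spec = layout_spec(),
                           cutoff = 0.3, config = pipeline_config(),
                           n_repeats = base_spec$n_repeats) {
  rig <- base_spec
  rig$inner_cutoff_query <- cutoff
  rig$inter_cutoff_train_test <- cutoff
  rig$query_reference_cutoff <- cutoff
  rig$reference_inner_cutoff <- cutoff
  conv <- base_spec
  conv$inner_cutoff_query <- 0.9
  conv$inter_cutoff_train_test <- "All"
  conv$query_reference_cutoff <- "All"
  conv$reference_inner_cutoff <- 0.9
  run1 <- run_repeats(universe, rig, function(l, s)
    run_ssp_experiment(l, config, seed = s), n_repeats, config$scoring)
  run2 <- run_repeats(universe, conv, function(l, s)
    run_ssp_experiment(l, config, seed = s), n_repeats, config$scoring)
  gap_r <- run1$per_repeat$gap
  gap_c <- run2$per_repeat$gap
  list(rigorous = run1, conventional = run2,
       cutoffs = list(rigorous = rig[c("inner_cutoff_query", "inter_cutoff_train_test",
                                       "query_reference_cutoff", "reference_inner_cutoff")],
                      conventional = conv[c("inner_cutoff_query", "inter_cutoff_train_test",
                                            "query_reference_cutoff", "reference_inner_cutoff")]),
       gap_rigorous = mean(gap_r), gap_conventional = mean(gap_c),
       rigorous_gap_not_larger = mean(gap_r) <= mean(gap_c))
}
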