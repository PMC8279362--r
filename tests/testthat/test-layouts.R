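small_spec <- function(...) {
  args <- list(reference_size = 60, train_size = 12, test_size = 12,
               independent_size = 8, n_repeats = 2, seed = 31)
  do.call(layout_spec, utils::modifyList(args, list(...)))
}

test_that("layouts with no reduction sample exact disjoint sets", {
  u <- test_universe(40)
  lay <- build_layout(u, small_spec())
  expect_equal(n_seqs(lay$reference[[1]]), 60)
  expect_equal(n_seqs(lay$train), 12)
  expect_equal(n_seqs(lay$test), 12)
  expect_equal(n_seqs(lay$independent), 8)
  ids <- c(lay$reference[[1]]$records$id, lay$train$records$id,
           lay$test$records$id, lay$independent$records$id)
  expect_false(any(duplicated(ids)))
  expect_true(verify_layout(lay))
  # deterministic given the seed
  lay2 <- build_layout(u, small_spec())
  expect_identical(lay2$train$records$id, lay$train$records$id)
})

test_that("three reference sets are pairwise disjoint and equally sized", {
  u <- test_universe(40)
  lay <- build_layout(u, small_spec(n_reference_sets = 3, reference_size = 40))
  expect_length(lay$reference, 3)
  sizes <- vapply(lay$reference, n_seqs, 0)
  expect_equal(sizes, rep(40, 3))
  ids <- unlist(lapply(lay$reference, function(r) r$records$id))
  expect_false(any(duplicated(ids)))
  # roles map to distinct sets
  expect_equal(unname(lay$assignment), 1:3)
})

test_that("declared homology cutoffs are verified by the all-pairs oracle", {
  u <- test_universe(40)
  lay <- build_layout(u, small_spec(train_size = 8, test_size = 8,
                                    reference_size = 50,
                                    inner_cutoff_query = 0.5,
                                    inter_cutoff_train_test = 0.5,
                                    query_reference_cutoff = 0.35,
                                    reference_inner_cutoff = 0.9))
  expect_lt(max_inner_identity(lay$train), 0.5)
  expect_lt(max_inner_identity(lay$test), 0.5)
  expect_lt(max_cross_identity(lay$train, lay$test), 0.5)
  expect_lt(max_cross_identity(lay$train, lay$reference[[1]]), 0.35)
  expect_lt(max_cross_identity(lay$test, lay$reference[[1]]), 0.35)
  expect_lt(max_inner_identity(lay$reference[[1]]), 0.9)
  expect_true(verify_layout(lay, check_reference_inner = TRUE))
})

test_that("independent proteins come from withheld families with only distant relatives in the pool", {
  u <- test_universe(40)
  spec <- small_spec()
  lay <- build_layout(u, spec)
  ind_fams <- lay$independent$records$family_id
  expect_false(any(lay$train$records$family_id %in% ind_fams))
  expect_false(any(lay$test$records$family_id %in% ind_fams))
  ref_rel <- lay$reference[[1]]$records[
    lay$reference[[1]]$records$family_id %in% ind_fams, ]
  if (nrow(ref_rel)) {
    ids <- vapply(seq_len(nrow(ref_rel)), function(i) {
      rep_ <- lay$independent$records[
        lay$independent$records$family_id == ref_rel$family_id[i], ][1, ]
      pairwise_identity(rep_, ref_rel[i, ])$identity
    }, 0)
    expect_true(all(ids < spec$novelty_cutoff))
  }
  # strict family withholding when relatives are disabled
  lay2 <- build_layout(u, small_spec(independent_relatives = FALSE, seed = 32))
  expect_false(any(lay2$reference[[1]]$records$family_id %in%
                     lay2$independent$records$family_id))
})

test_that("unsatisfiable sizes raise a size-exhaustion error naming the constraint", {
  u <- test_universe(12)
  expect_error(build_layout(u, layout_spec(reference_size = 5000, train_size = 5,
                                           test_size = 5, independent_size = 4,
                                           seed = 3)),
               "size exhaustion: reference_size")
  expect_error(build_layout(u, layout_spec(reference_size = 20, train_size = 500,
                                           test_size = 5, independent_size = 4,
                                           seed = 3)),
               "size exhaustion: train_size")
  err <- tryCatch(build_layout(u, layout_spec(independent_size = 50, seed = 3)),
                  error = identity)
  expect_s3_class(err, "homssp_size_exhaustion")
})

test_that("repeats aggregate with mean and sample sd, deterministically", {
  u <- test_universe(40)
  spec <- small_spec()
  const <- function(layout, seed) c(a = 1, b = n_seqs(layout$train))
  rr <- run_repeats(u, spec, const, n_repeats = 3)
  expect_equal(nrow(rr$per_repeat), 3)
  expect_equal(rr$summary$sd, c(0, 0))
  one <- run_repeats(u, spec, const, n_repeats = 1)
  expect_true(all(is.na(one$summary$sd)))
  # same master seed -> identical aggregate table
  probe <- function(layout, seed) c(first_id = as.numeric(
    gsub("\\D", "", layout$train$records$id[1])))
  r1 <- run_repeats(u, spec, probe, n_repeats = 2)
  r2 <- run_repeats(u, spec, probe, n_repeats = 2)
  expect_identical(r1$per_repeat, r2$per_repeat)
  # fresh sampling per repeat
  expect_false(identical(r1$per_repeat$first_id[1], r1$per_repeat$first_id[2]))
})
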