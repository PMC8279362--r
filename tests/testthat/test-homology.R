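test_that("pairwise identity reproduces hand-checked alignments", {
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIK")$identity, 1)
  expect_equal(pairwise_identity("AAAA", "CCCC")$identity, 0)
  r <- pairwise_identity("ACDEF", "ACDFF")
  expect_equal(r$n_matches, 4)
  expect_equal(r$denominator, 5)
  expect_equal(r$identity, 0.8)
  expect_error(pairwise_identity("", "ACD"), "non-empty")
})

test_that("identity is symmetric, bounded, and 1 on self", {
  set.seed(3)
  seqs <- replicate(12, random_protein(sample(40:90, 1)))
  for (i in 1:6) {
    a <- sample(seqs, 1); b <- sample(seqs, 1)
    ia <- pairwise_identity(a, b)$identity
    ib <- pairwise_identity(b, a)$identity
    expect_equal(ia, ib)
    expect_gte(ia, 0); expect_lte(ia, 1)
    expect_equal(pairwise_identity(a, a)$identity, 1)
  }
})

test_that("alignment scores agree with the Biostrings aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(9)
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  sm <- matrix(-2L, 20, 20, dimnames = list(aa, aa))
  diag(sm) <- 4L  # quarter-grid x4: match 1, mismatch -0.5
  sc <- identity_scoring(match = 1, mismatch = -0.5, gap = -1)
  for (i in 1:12) {
    a <- random_protein(sample(30:80, 1))
    b <- if (i %% 2) random_protein(sample(30:80, 1)) else
      substitute_positions(a, sample(nchar(a), sample(5:20, 1)))
    mine <- pairwise_identity(a, b, sc)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sm, gapOpening = 0, gapExtension = 4,
      type = "global", scoreOnly = FALSE)
    expect_equal(mine$score * 4, Biostrings::score(aln))
    # same optimal score; our tie-break maximises matches among optima
    expect_gte(mine$n_matches, Biostrings::nmatch(aln))
  }
})

test_that("within-dataset reduction satisfies the all-pairs post-condition", {
  set.seed(13)
  u <- test_universe(12)
  d <- seq_dataset(u$records[sample(nrow(u$records), 40), ], "sub")
  for (cutoff in c(0.9, 0.5, 0.3)) {
    r <- reduce_within(d, cutoff)
    expect_lt(max_inner_identity(r), cutoff)
    expect_equal(r$declared_inner_cutoff, cutoff)
    # fixed point: already-reduced input returned unchanged
    r2 <- reduce_within(r, cutoff)
    expect_equal(r2$records$id, r$records$id)
  }
})

test_that("reduction collapses duplicates and keeps A plus C in a 0.92 chain", {
  set.seed(17)
  a <- random_protein(100)
  b <- substitute_positions(a, sample(100, 8))
  cc <- substitute_positions(b, setdiff(sample(100, 16), which(
    strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))[1:8])
  d <- strings_dataset(c(a, b, cc), ids = c("A", "B", "C"))
  expect_gte(pairwise_identity(a, b)$identity, 0.9)
  expect_gte(pairwise_identity(b, cc)$identity, 0.9)
  expect_lt(pairwise_identity(a, cc)$identity, 0.9)
  r <- reduce_within(d, 0.9)
  expect_setequal(r$records$id, c("A", "C"))
  expect_lt(max_inner_identity(r), 0.9)

  dup <- strings_dataset(c(a, a), ids = c("x", "y"))
  expect_equal(n_seqs(reduce_within(dup, 0.9)), 1)
})

test_that("lowering the cutoff never keeps more sequences", {
  set.seed(19)
  u <- test_universe(12)
  d <- seq_dataset(u$records[sample(nrow(u$records), 50), ], "mono")
  kept <- vapply(c(0.95, 0.7, 0.5, 0.3, 0.2),
                 function(co) n_seqs(reduce_within(d, co)), 0)
  expect_true(all(diff(kept) <= 0))
})

test_that("between-dataset reduction removes exactly the over-cutoff records", {
  u <- test_universe(12)
  set.seed(23)
  ra <- sample(nrow(u$records), 25)
  a <- seq_dataset(u$records[ra, ], "A")
  b <- seq_dataset(u$records[sample(setdiff(seq_len(nrow(u$records)), ra), 25), ], "B")
  b2 <- reduce_between(b, a, 0.4)
  if (n_seqs(b2) > 0)
    expect_lt(max_cross_identity(b2, a), 0.4)
  # A untouched; empty A leaves B alone
  empty <- seq_dataset(u$records[0, ], "E")
  expect_equal(n_seqs(reduce_between(b, empty, 0.4)), n_seqs(b))
  # B identical to A vanishes at any cutoff (self-identity 1)
  expect_equal(n_seqs(reduce_between(a, a, 1.0)), 0)
})

test_that("two-way reduction is symmetric-clean and idempotent", {
  u <- test_universe(12)
  set.seed(29)
  for (i in 1:5) {
    ra <- sample(nrow(u$records), 20)
    rb <- sample(setdiff(seq_len(nrow(u$records)), ra), 20)
    a <- seq_dataset(u$records[ra, ], "A")
    b <- seq_dataset(u$records[rb, ], "B")
    tw <- reduce_two_way(a, b, 0.4)
    if (n_seqs(tw$a) && n_seqs(tw$b))
      expect_lt(max_cross_identity(tw$a, tw$b), 0.4)
    tw2 <- reduce_two_way(tw$a, tw$b, 0.4)
    expect_equal(tw2$a$records$id, tw$a$records$id)
    expect_equal(tw2$b$records$id, tw$b$records$id)
  }
})

test_that("homology levels All and NR100 behave as labelled", {
  a <- random_protein(60)
  d <- strings_dataset(c(a, a, substitute_positions(a, 1:30)), ids = c("p", "q", "r"))
  expect_equal(n_seqs(apply_homology_level(d, "All")), 3)
  nr <- apply_homology_level(d, "NR100")
  expect_equal(n_seqs(nr), 2)
  expect_error(apply_homology_level(d, "NR90"), "homology level")
})
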