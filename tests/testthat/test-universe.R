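test_that("config validation rejects malformed universes", {
  expect_error(universe_config(length_range = c(10, 50)), "min >= 30")
  expect_error(universe_config(family_sizes = c(0, 2)), "positive")
  bad <- default_aa_propensity(); bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(universe_config(aa_propensity = bad), "sum to 1")
  expect_error(universe_config(identity_ladder = c(1, .9, .8, .7, .6, 1.2)),
               "in \\(0, 1\\]")
})

test_that("ancestors respect length, alphabet and segment minima", {
  cfg <- universe_config(n_families = 2, ss_noise_prob = 0, ss_flip_prob = 0)
  set.seed(31)
  for (i in 1:15) {
    a <- sample_ancestor(cfg, id = paste0("a", i))
    expect_equal(nchar(a$residues), nchar(a$ss8))
    expect_gte(a$length, cfg$length_range[1])
    expect_lte(a$length, cfg$length_range[2])
    expect_false(grepl(sprintf("[^%s]", AA_ALPHABET), a$residues))
    expect_false(grepl("[^HETSC]", a$ss8))  # generator emits H/E + coil sublabels
    # segment minima on the 3-state projection
    r <- rle(strsplit(a$ss3, "")[[1]])
    mins <- c(H = 4, E = 2, C = 1)
    expect_true(all(r$lengths >= mins[r$values]))
  }
})

test_that("helix segment lengths follow the configured geometric mean", {
  cfg <- universe_config(n_families = 2,
                         ss_segment_length_means = c(H = 10, E = 5, C = 5),
                         ss_noise_prob = 0, ss_flip_prob = 0)
  set.seed(37)
  lens <- integer(0)
  while (length(lens) < 1000) {
    a <- sample_ancestor(cfg)
    r <- rle(strsplit(a$ss3, "")[[1]])
    # interior segments only: first/last may be truncated
    keep <- r$values == "H" & seq_along(r$values) > 1 &
      seq_along(r$values) < length(r$values)
    lens <- c(lens, r$lengths[keep])
  }
  expect_lt(abs(mean(lens) - 10) / 10, 0.15)
})

test_that("mutated homologs hit their identity targets", {
  cfg <- universe_config(n_families = 2)
  set.seed(41)
  parent <- sample_ancestor(cfg, id = "p")
  same <- mutate_homolog(parent, 1.0, cfg)
  expect_identical(same$residues, parent$residues)
  for (target in c(0.9, 0.6, 0.4)) {
    child <- mutate_homolog(parent, target, cfg)
    expect_equal(nchar(child$residues), nchar(parent$residues))
    realized <- pairwise_identity(parent, child)$identity
    expect_gte(realized, target - cfg$substitution_identity_tolerance)
    expect_lte(realized, target + cfg$substitution_identity_tolerance)
  }
  expect_error(mutate_homolog(parent, 1.3, cfg), "target_identity")
})

test_that("universe generation is deterministic and correctly structured", {
  cfg <- universe_config(n_families = 10, family_sizes = rep(5L, 10),
                         identity_ladder = c(1, .9, .7, .5, .3),
                         family_size = 5, seed = 99)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_identical(u1$records, u2$records)
  expect_equal(n_seqs(u1), 50)
  expect_equal(length(unique(u1$records$family_id)), 10)
  expect_false(any(duplicated(u1$records$id)))
  expect_false(any(grepl(sprintf("[^%s]", SS8_ALPHABET), u1$records$ss8)))
})

test_that("realized within-family identities bracket the ladder targets", {
  u <- test_universe(8, uniform = TRUE)
  cfg <- universe_config(n_families = 8, family_sizes = rep(6L, 8), seed = 7)
  tol <- cfg$substitution_identity_tolerance
  for (f in unique(u$records$family_id)[1:4]) {
    fam <- u$records[u$records$family_id == f, ]
    anc <- fam[fam$target_identity == 1, ][1, ]
    for (i in which(fam$target_identity < 1)) {
      realized <- pairwise_identity(anc, fam[i, ])$identity
      expect_lte(abs(realized - fam$target_identity[i]), tol + 1e-9)
    }
  }
})

test_that("cross-family identities sit well below the ladder", {
  u <- test_universe(12)
  anc <- u$records[u$records$target_identity == 1, ]
  anc <- anc[!duplicated(anc$family_id), ][1:10, ]
  m <- identity_matrix(seq_dataset(anc, "anc"))
  diag(m) <- NA
  expect_lt(median(m, na.rm = TRUE), min(universe_config()$identity_ladder))
})

test_that("datasets round-trip through paired FASTA files", {
  u <- test_universe(8, uniform = TRUE)
  d <- seq_dataset(u$records[1:10, ], "rt")
  fa <- tempfile(fileext = ".fasta"); ss <- tempfile(fileext = ".ssa")
  write_dataset_fasta(d, fa, ss)
  back <- read_dataset_fasta(fa, ss, name = "rt")
  expect_equal(back$records$id, d$records$id)
  expect_equal(back$records$residues, d$records$residues)
  expect_equal(back$records$ss8, d$records$ss8)
  expect_equal(back$records$ss3, d$records$ss3)
  expect_equal(back$records$family_id, d$records$family_id)
  # mismatched pairing is rejected
  d2 <- seq_dataset(u$records[11:20, ], "other")
  ss2 <- tempfile(fileext = ".ssa")
  write_dataset_fasta(d2, tempfile(fileext = ".fa"), ss2)
  expect_error(read_dataset_fasta(fa, ss2), "not paired")
})
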