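# Independent oracles used across the suite.  These are deliberately written
# from first principles, structurally unlike the package implementations.

# SOV'99, transcribed directly from the definition: per state, enumerate
# observed/predicted segment pairs as explicit position sets.
ref_sov99 <- function(pred, true) {
  stopifnot(nchar(pred) == nchar(true))
  runs <- function(s) {
    v <- strsplit(s, "")[[1]]
    idx <- split(seq_along(v), cumsum(c(TRUE, v[-1] != v[-length(v)])))
    lapply(idx, function(i) list(state = v[i[1]], pos = i))
  }
  obs <- runs(true)
  prd <- runs(pred)
  num <- 0
  den <- 0
  for (s1 in obs) {
    partners <- Filter(function(s2) s2$state == s1$state &&
                         length(intersect(s1$pos, s2$pos)) > 0, prd)
    if (length(partners) == 0) {
      den <- den + length(s1$pos)
      next
    }
    for (s2 in partners) {
      minov <- length(intersect(s1$pos, s2$pos))
      maxov <- length(union(s1$pos, s2$pos))
      delta <- min(maxov - minov, minov,
                   floor(length(s1$pos) / 2), floor(length(s2$pos) / 2))
      num <- num + (minov + delta) / maxov * length(s1$pos)
      den <- den + length(s1$pos)
    }
  }
  if (den == 0) 0 else 100 * num / den
}

# Residue-level Q by brute concatenation.
ref_micro_q <- function(preds, trues) {
  p <- strsplit(paste(preds, collapse = ""), "")[[1]]
  t_ <- strsplit(paste(trues, collapse = ""), "")[[1]]
  mean(p == t_)
}

# Random state strings for metric tests.
random_ss3 <- function(n, min_len = 5, max_len = 40) {
  vapply(seq_len(n), function(i)
    paste(sample(c("H", "E", "C"), sample(min_len:max_len, 1),
                 replace = TRUE, prob = c(.35, .25, .4)), collapse = ""), "")
}

random_protein <- function(len) {
  paste(sample(strsplit(homssp::AA_ALPHABET, "")[[1]], len, replace = TRUE),
        collapse = "")
}

# Substitute k positions of a sequence (uniform replacement, never the
# original letter); used to build identity chains without the package's
# mutate_homolog.
substitute_positions <- function(seq, pos) {
  aa <- strsplit(homssp::AA_ALPHABET, "")[[1]]
  v <- strsplit(seq, "")[[1]]
  for (i in pos) v[i] <- sample(setdiff(aa, v[i]), 1)
  paste(v, collapse = "")
}

# Small memoised universes so expensive generation happens once per run.
.test_env <- new.env()
test_universe <- function(n_families = 40, seed = 7, uniform = FALSE) {
  key <- paste0("u", n_families, "_", seed, "_", uniform)
  if (is.null(.test_env[[key]])) {
    cfg <- if (uniform)
      universe_config(n_families = n_families,
                      family_sizes = rep(6L, n_families), seed = seed)
    else universe_config(n_families = n_families, seed = seed)
    .test_env[[key]] <- generate_universe(cfg)
  }
  .test_env[[key]]
}

# Dataset wrapper for raw residue strings (labels all-coil placeholders).
strings_dataset <- function(seqs, name = "tmp", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(seqs))
  seq_dataset(data.frame(id = ids, residues = seqs,
                         ss8 = vapply(nchar(seqs), function(L)
                           paste(rep("C", L), collapse = ""), ""),
                         family_id = ids, stringsAsFactors = FALSE),
              name = name)
}
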