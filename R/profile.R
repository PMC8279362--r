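#' Search a reference set for homologs of a query
#'
#' Exhaustive pairwise-identity scan of the reference (the desk-scale
#' stand-in for a database search tool): hits are reference sequences with
#' identity >= `min_identity` to the query, sorted by identity descending
#' (ties by id), truncated to `max_hits`.  The truncation mirrors the
#' bounded hit list of profile search tools, which is what couples
#' reference-set redundancy to profile diversity.
#'
#' @param query A record (row/list with `$residues`, `$id`) or residue string.
#' @param reference A [seq_dataset()].
#' @param max_hits Hit-list cap (default 500).
#' @param min_identity Identity floor for a hit (default 0.25).
#' @param scoring An [identity_scoring()].
#' @param identities Optional precomputed identity vector of the query to
#'   every reference record (used by batch drivers to avoid recomputation).
#' @return A data frame of hits: `id`, `identity`, `residues` (possibly
#'   zero rows).
#' @export
search_homologs <- function(query, reference, max_hits = 500, min_identity = 0.25,
                            scoring = identity_scoring(), identities = NULL) {
  if (n_seqs(reference) == 0) stop("reference dataset is empty")
  q <- as_residues(query)
  if (is.null(identities)) {
    identities <- as.vector(identity_cross_cpp(
      q, reference$records$residues,
      scoring$match, scoring$mismatch, scoring$gap))
  }
  stopifnot(length(identities) == n_seqs(reference))
  sel <- which(identities >= min_identity)
  hits <- data.frame(id = reference$records$id[sel],
                     identity = identities[sel],
                     residues = reference$records$residues[sel],
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$identity, hits$id), , drop = FALSE]
  if (nrow(hits) > max_hits) hits <- hits[seq_len(max_hits), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Shannon entropy of a probability vector
#'
#' `S = -sum(p * log2(p))` with `0 * log2(0)` defined as 0.  For a 20-state
#' profile column the value lies in `[0, log2(20)]`.
#'
#' @param p Non-negative numeric vector summing to 1.
#' @return Entropy in bits.
#' @export
entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("entropy expects a probability vector (non-negative, summing to 1)")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Build a PSSM profile for a query from its hit list
#'
#' Per query position, observed counts accumulate the query residue plus
#' every hit residue aligned to that position (gap-aligned hits contribute
#' nothing); probabilities are background pseudocount-smoothed,
#' `p = (c + beta * b) / (sum(c) + beta)`, log-odds are `log2(p / b)` in
#' bits, and each column's Shannon entropy is reported together with their
#' mean.
#'
#' @param query Record or residue string.
#' @param hits Hit table from [search_homologs()] (or any data frame with a
#'   `residues` column; zero-row for a hitless profile).
#' @param beta Total pseudocount weight (default 1); `beta = 0` gives raw
#'   frequencies.
#' @param background Length-20 background distribution (default uniform).
#' @param scoring An [identity_scoring()] (hit alignments are recomputed for
#'   the count accumulation).
#' @return An object of class `pssm_profile`: list with `query_id`, `probs`
#'   and `log_odds` (L x 20), `position_entropy` (length L), `mean_entropy`,
#'   `n_hits`, `length`.
#' @export
build_pssm <- function(query, hits, beta = 1,
                       background = rep(1 / 20, 20),
                       scoring = identity_scoring()) {
  q <- as_residues(query)
  L <- nchar(q)
  if (L == 0) stop("empty query")
  if (length(background) != 20 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop("background must be a positive 20-vector summing to 1")
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  hit_seqs <- if (is.null(hits) || nrow(hits) == 0) character(0) else hits$residues
  counts <- if (length(hit_seqs)) {
    profile_counts_cpp(q, hit_seqs, AA_ALPHABET,
                       scoring$match, scoring$mismatch, scoring$gap)
  } else {
    matrix(0L, nrow = 20, ncol = L)
  }
  qi <- match(strsplit(q, "")[[1]], aa)
  counts[cbind(qi, seq_len(L))] <- counts[cbind(qi, seq_len(L))] + 1L
  tot <- colSums(counts)
  probs <- t((counts + beta * background) / rep(tot + beta, each = 20))
  colnames(probs) <- aa
  log_odds <- log2(probs / rep(background, each = L))
  pos_ent <- apply(probs, 1, entropy)
  structure(
    list(query_id = as_seq_id(query, "query"), probs = probs,
         log_odds = log_odds, position_entropy = pos_ent,
         mean_entropy = mean(pos_ent), n_hits = length(hit_seqs), length = L),
    class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile '%s'> L=%d, hits=%d, mean entropy %.3f bits\n",
              x$query_id, x$length, x$n_hits, x$mean_entropy))
  invisible(x)
}

#' Build profiles for every sequence of a query set
#'
#' Batch driver: one identity scan of queries against the reference, then
#' [search_homologs()] + [build_pssm()] per query.  Records with an id
#' present in the reference never hit themselves (self-hits are dropped) so
#' that a dataset can be profiled against a superset pool.
#'
#' @param queries,reference [seq_dataset()]s.
#' @inheritParams search_homologs
#' @inheritParams build_pssm
#' @return A named list of `pssm_profile` objects, one per query record.
#' @export
build_profiles <- function(queries, reference, max_hits = 500, min_identity = 0.25,
                           beta = 1, background = rep(1 / 20, 20),
                           scoring = identity_scoring()) {
  idm <- identity_cross_cpp(queries$records$residues, reference$records$residues,
                            scoring$match, scoring$mismatch, scoring$gap)
  out <- lapply(seq_len(n_seqs(queries)), function(i) {
    rec <- queries$records[i, ]
    ids <- idm[i, ]
    ids[reference$records$id == rec$id] <- -1  # no self-hits
    hits <- search_homologs(rec, reference, max_hits, min_identity,
                            scoring, identities = ids)
    build_pssm(rec, hits, beta, background, scoring)
  })
  names(out) <- queries$records$id
  out
}

#' Length-weighted mean profile entropy
#'
#' `sum(len_q * mean_entropy_q) / sum(len_q)` over a collection of profiles:
#' the per-protein weight is its sequence length.
#'
#' @param profiles List of `pssm_profile` objects.
#' @return Scalar entropy in bits.
#' @export
weighted_mean_entropy <- function(profiles) {
  if (!length(profiles)) stop("empty profile collection")
  lens <- vapply(profiles, function(p) p$length, 0)
  ents <- vapply(profiles, function(p) p$mean_entropy, 0)
  sum(lens * ents) / sum(lens)
}

#' Transform an HMM integer score to a probability
#'
#' Profile HMM tools store emission scores as non-negative integers `h`
#' related to probabilities by `p = 2^(-h / 1000)`; this converts such
#' scores for use as PSSM probability columns.
#'
#' @param h Non-negative numeric vector of HMM scores.
#' @return Probabilities in (0, 1].
#' @export
hmm_to_prob <- function(h) {
  if (any(h < 0)) stop("HMM scores must be non-negative")
  2^(-h / 1000)
}

#' Write a profile as CSV
#'
#' Tabular export: one row per position with the query residue, the 20
#' probability columns, the 20 log-odds columns and the position entropy.
#'
#' @param profile A `pssm_profile`.
#' @param query Record or residue string the profile belongs to.
#' @param path Output file.
#' @return Invisibly, the written data frame.
#' @export
write_profile_csv <- function(profile, query, path) {
  res <- strsplit(as_residues(query), "")[[1]]
  df <- data.frame(pos = seq_len(profile$length), residue = res,
                   profile$probs,
                   setNames(as.data.frame(profile$log_odds),
                            paste0("lod_", colnames(profile$log_odds))),
                   entropy = profile$position_entropy, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
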