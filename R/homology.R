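#' Alignment scoring scheme for identity computation
#'
#' Pairwise identity is computed from a global alignment with linear gap
#' penalties; identity is the number of identical aligned pairs divided by
#' the length of the shorter sequence, the convention of CD-HIT-style
#' clustering tools.  The default gap penalty of -2 keeps the identity of
#' unrelated sequences low (~0.12 for typical protein compositions): a
#' cheaper gap (-1) lets the aligner "gap-dance" unrelated pairs up to ~0.2
#' apparent identity, which would make sub-25% identity cutoffs
#' unsatisfiable on any dataset.  Constants must lie on a 0.25 grid.
#'
#' @param match,mismatch,gap Scoring constants (per aligned pair / gap column).
#' @return A list of class `identity_scoring`.
#' @export
identity_scoring <- function(match = 1, mismatch = 0, gap = -2) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap),
            length(match) == 1, length(mismatch) == 1, length(gap) == 1)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "identity_scoring")
}

as_residues <- function(x) {
  if (is.character(x) && length(x) == 1) return(x)
  if (is.list(x) && !is.null(x$residues)) return(x$residues)
  stop("expected a residue string or a record with a $residues field")
}

as_seq_id <- function(x, default) {
  if (is.list(x) && !is.null(x$id)) as.character(x$id) else default
}

#' Pairwise sequence identity
#'
#' Optimal global alignment (see [identity_scoring()]) between two sequences;
#' among equally optimal alignments the one with the most identical aligned
#' pairs is used.  Identity = matches / length of the shorter sequence, so it
#' lies in `[0, 1]` and is symmetric in its arguments.
#'
#' @param a,b Residue strings, or records (rows/lists) with `$residues` (and
#'   optionally `$id`).
#' @param scoring An [identity_scoring()].
#' @return A list with `id_a`, `id_b`, `identity`, `n_matches`, `denominator`
#'   and the alignment `score`.
#' @export
pairwise_identity <- function(a, b, scoring = identity_scoring()) {
  ra <- as_residues(a)
  rb <- as_residues(b)
  if (nchar(ra) == 0 || nchar(rb) == 0)
    stop("pairwise identity requires non-empty sequences")
  res <- nw_identity_cpp(ra, rb, scoring$match, scoring$mismatch, scoring$gap)
  list(id_a = as_seq_id(a, "a"), id_b = as_seq_id(b, "b"),
       identity = res$identity, n_matches = res$n_matches,
       denominator = res$denominator, score = res$score)
}

#' All-pairs identity matrix
#'
#' Exhaustive pairwise identity within one dataset or across two datasets.
#' This is the post-condition oracle behind every homology-reduction
#' guarantee: independent of the greedy clustering code, it simply scans all
#' pairs.
#'
#' @param a A [seq_dataset()] (or character vector of residue strings).
#' @param b Optional second dataset; if `NULL`, the within-`a` matrix is
#'   returned (diagonal 1).
#' @param scoring An [identity_scoring()].
#' @return Numeric identity matrix with sequence ids as dimnames.
#' @export
identity_matrix <- function(a, b = NULL, scoring = identity_scoring()) {
  sa <- if (inherits(a, "seq_dataset")) a$records$residues else as.character(a)
  na <- if (inherits(a, "seq_dataset")) a$records$id else names(a)
  if (is.null(b)) {
    m <- identity_self_cpp(sa, scoring$match, scoring$mismatch, scoring$gap)
    dimnames(m) <- list(na, na)
  } else {
    sb <- if (inherits(b, "seq_dataset")) b$records$residues else as.character(b)
    nb <- if (inherits(b, "seq_dataset")) b$records$id else names(b)
    m <- identity_cross_cpp(sa, sb, scoring$match, scoring$mismatch, scoring$gap)
    dimnames(m) <- list(na, nb)
  }
  m
}

#' Maximum pairwise identity within a dataset
#'
#' @param d A [seq_dataset()].
#' @param scoring An [identity_scoring()].
#' @return The largest off-diagonal pairwise identity (0 for fewer than two
#'   sequences).
#' @export
max_inner_identity <- function(d, scoring = identity_scoring()) {
  if (n_seqs(d) < 2) return(0)
  m <- identity_matrix(d, scoring = scoring)
  diag(m) <- 0
  max(m)
}

#' Maximum pairwise identity between two datasets
#' @param a,b [seq_dataset()]s.
#' @param scoring An [identity_scoring()].
#' @return Largest identity over all cross pairs (0 if either is empty).
#' @export
max_cross_identity <- function(a, b, scoring = identity_scoring()) {
  if (n_seqs(a) == 0 || n_seqs(b) == 0) return(0)
  max(identity_matrix(a, b, scoring = scoring))
}

# Canonical greedy order: length descending, ties by id lexicographic
# (C collation for reproducibility across locales).
greedy_order <- function(records) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old))
  Sys.setlocale("LC_COLLATE", "C")
  order(-records$length, records$id)
}

#' Within-dataset homology reduction
#'
#' Greedy incremental clustering in the style of CD-HIT: records are visited
#' longest-first (ties by id); a record is kept iff its identity to every
#' already-kept record is below `cutoff`.  The output therefore satisfies the
#' all-pairs post-condition `max_inner_identity(result) < cutoff`.
#'
#' @param d A [seq_dataset()].
#' @param cutoff Identity cutoff in (0, 1].
#' @param scoring An [identity_scoring()].
#' @return A reduced [seq_dataset()] in kept (greedy) order with
#'   `declared_inner_cutoff` set.
#' @export
reduce_within <- function(d, cutoff, scoring = identity_scoring()) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (n_seqs(d) == 0)
    return(derive_dataset(d, d$records, sprintf("reduce_within(%.3g): empty", cutoff),
                          declared_inner_cutoff = cutoff))
  ord <- greedy_order(d$records)
  recs <- d$records[ord, , drop = FALSE]
  keep <- greedy_keep_cpp(recs$residues, cutoff,
                          scoring$match, scoring$mismatch, scoring$gap)
  derive_dataset(d, recs[keep, , drop = FALSE],
                 sprintf("reduce_within(cutoff=%.3g): kept %d of %d",
                         cutoff, sum(keep), nrow(recs)),
                 declared_inner_cutoff = cutoff)
}

#' One-way inter-dataset homology reduction
#'
#' Removes from `b` every record whose identity to any record of `a` is
#' `>= cutoff`; `a` is untouched.
#'
#' @param b Dataset to be reduced.
#' @param a Dataset reduced against.
#' @param cutoff Identity cutoff in (0, 1].
#' @param scoring An [identity_scoring()].
#' @return The reduced version of `b` (original record order preserved).
#' @export
reduce_between <- function(b, a, cutoff, scoring = identity_scoring()) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (n_seqs(a) == 0 || n_seqs(b) == 0)
    return(derive_dataset(b, b$records,
                          sprintf("reduce_between(vs '%s', cutoff=%.3g): nothing to compare",
                                  a$name, cutoff)))
  keep <- keep_between_cpp(b$records$residues, a$records$residues, cutoff,
                           scoring$match, scoring$mismatch, scoring$gap)
  derive_dataset(b, b$records[keep, , drop = FALSE],
                 sprintf("reduce_between(vs '%s', cutoff=%.3g): kept %d of %d",
                         a$name, cutoff, sum(keep), n_seqs(b)))
}

#' Two-way inter-dataset homology reduction
#'
#' First `B' = B - A` (drop records of `b` with identity >= cutoff to `a`),
#' then `A' = A - B'`.  The returned pair has no cross pair at or above the
#' cutoff, and re-applying the procedure removes nothing (idempotence).
#' One-way reduction alone does not guarantee the symmetric property when the
#' reducing tool is heuristic, which is why the second pass exists.
#'
#' @param a,b [seq_dataset()]s.
#' @param cutoff Identity cutoff in (0, 1].
#' @param scoring An [identity_scoring()].
#' @return A list with elements `a` and `b` (reduced in that order).
#' @export
reduce_two_way <- function(a, b, cutoff, scoring = identity_scoring()) {
  stopifnot(cutoff > 0, cutoff <= 1)
  b2 <- reduce_between(b, a, cutoff, scoring)
  a2 <- reduce_between(a, b2, cutoff, scoring)
  list(a = a2, b = b2)
}

#' Remove exact duplicate sequences ("NR100")
#'
#' Keeps the first record (in greedy order) of every identical residue
#' string.  This is the "no duplicates" homology level between no reduction
#' at all ("All") and numeric identity cutoffs.
#'
#' @param d A [seq_dataset()].
#' @return Deduplicated [seq_dataset()].
#' @export
deduplicate_exact <- function(d) {
  if (n_seqs(d) == 0) return(d)
  ord <- greedy_order(d$records)
  recs <- d$records[ord, , drop = FALSE]
  keep <- !duplicated(recs$residues)
  derive_dataset(d, recs[keep, , drop = FALSE],
                 sprintf("deduplicate_exact: kept %d of %d", sum(keep), nrow(recs)))
}

#' Apply a homology level to a dataset
#'
#' Homology levels are written the way benchmark papers label them: `"All"`
#' (no reduction), `"NR100"` (exact-duplicate removal only) or a numeric
#' identity cutoff in (0, 1].
#'
#' @param d A [seq_dataset()].
#' @param level `"All"`, `"NR100"`, or a numeric cutoff.
#' @param scoring An [identity_scoring()].
#' @return The (possibly) reduced dataset.
#' @export
apply_homology_level <- function(d, level, scoring = identity_scoring()) {
  if (identical(level, "All")) return(d)
  if (identical(level, "NR100")) return(deduplicate_exact(d))
  if (is.numeric(level) && length(level) == 1) return(reduce_within(d, level, scoring))
  stop("homology level must be 'All', 'NR100' or a numeric cutoff, got: ",
       deparse(level))
}
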