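#' Construct a labelled-sequence dataset
#'
#' A `seq_dataset` is the basic container of the package: a named, role-tagged
#' collection of labelled protein sequences.  Records are rows of a data frame
#' with columns `id`, `residues`, `ss8`, `ss3`, `family_id` and `length`.
#' The 3-state labels are always the image of the 8-state labels under the
#' H,G,I -> H; E,B -> E; T,S,C -> C mapping and are (re)derived on
#' construction.
#'
#' @param records Data frame with at least `id`, `residues`, `ss8` and
#'   `family_id` columns. `ss3` and `length` are derived.
#' @param name Dataset name (free text, used in provenance).
#' @param role One of `"reference"`, `"train"`, `"test"`, `"independent"`,
#'   `"universe"`.
#' @param declared_inner_cutoff Optional fraction: a promise that all pairwise
#'   identities within the dataset are below this cutoff (verifiable with
#'   [max_inner_identity()]).
#' @param provenance Character vector audit trail (sources, cutoffs, seeds).
#' @return An object of class `seq_dataset`.
#' @export
seq_dataset <- function(records, name, role = "universe",
                        declared_inner_cutoff = NULL,
                        provenance = character()) {
  role <- match.arg(role, c("reference", "train", "test", "independent", "universe"))
  stopifnot(is.data.frame(records))
  required <- c("id", "residues", "ss8", "family_id")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  records$id <- as.character(records$id)
  records$residues <- as.character(records$residues)
  records$ss8 <- as.character(records$ss8)
  records$family_id <- as.character(records$family_id)
  if (anyDuplicated(records$id))
    stop("duplicate sequence ids in dataset '", name, "'")
  if (nrow(records)) {
    if (any(nchar(records$residues) == 0L))
      stop("empty residue strings are not allowed")
    bad_aa <- grepl(sprintf("[^%s]", AA_ALPHABET), records$residues)
    if (any(bad_aa))
      stop("illegal residue letters in: ", paste(head(records$id[bad_aa]), collapse = ", "))
    bad_ss <- grepl(sprintf("[^%s]", SS8_ALPHABET), records$ss8)
    if (any(bad_ss))
      stop("illegal 8-state letters in: ", paste(head(records$id[bad_ss]), collapse = ", "))
    if (any(nchar(records$residues) != nchar(records$ss8)))
      stop("residue and ss8 strings must have equal lengths")
  }
  records$ss3 <- ss8_to_ss3(records$ss8)
  records$length <- nchar(records$residues)
  rownames(records) <- NULL
  structure(
    list(name = name, role = role, records = records,
         declared_inner_cutoff = declared_inner_cutoff,
         provenance = provenance),
    class = "seq_dataset")
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat(sprintf("<seq_dataset '%s'> role=%s, n=%d", x$name, x$role, nrow(x$records)))
  if (!is.null(x$declared_inner_cutoff))
    cat(sprintf(", inner identity < %.2f", x$declared_inner_cutoff))
  cat("\n")
  if (length(x$provenance))
    cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' Number of sequences in a dataset
#' @param d A [seq_dataset()].
#' @return Integer count.
#' @export
n_seqs <- function(d) nrow(d$records)

# Internal: make a derived dataset, preserving provenance.
derive_dataset <- function(d, records, note, name = d$name, role = d$role,
                           declared_inner_cutoff = d$declared_inner_cutoff) {
  seq_dataset(records, name = name, role = role,
              declared_inner_cutoff = declared_inner_cutoff,
              provenance = c(d$provenance, note))
}

#' Write a dataset as paired FASTA files
#'
#' Sequences go to `seq_path` as plain FASTA; the 8-state labels go to
#' `ss_path` in the same FASTA layout (same ids, label strings as sequence
#' lines), so the pair can be inspected with any FASTA tool.
#'
#' @param d A [seq_dataset()].
#' @param seq_path,ss_path Output file paths.
#' @return Invisibly, `d`.
#' @export
write_dataset_fasta <- function(d, seq_path, ss_path) {
  hdr <- paste(d$records$id, d$records$family_id)
  seqs <- Biostrings::AAStringSet(setNames(d$records$residues, hdr))
  lbls <- Biostrings::BStringSet(setNames(d$records$ss8, hdr))
  Biostrings::writeXStringSet(seqs, seq_path)
  Biostrings::writeXStringSet(lbls, ss_path)
  invisible(d)
}

#' Read a dataset from paired FASTA files
#'
#' Validates that the two files carry the same ids in the same order and that
#' every label string matches its sequence in length and alphabet.
#'
#' @param seq_path,ss_path Paths written by [write_dataset_fasta()] (or any
#'   FASTA pair following the same convention).
#' @param name,role Passed to [seq_dataset()].
#' @return A [seq_dataset()]. Family ids are taken from the text after the
#'   first space of the FASTA header if present, otherwise set to the id.
#' @export
read_dataset_fasta <- function(seq_path, ss_path, name = basename(seq_path),
                               role = "universe") {
  seqs <- Biostrings::readAAStringSet(seq_path)
  lbls <- Biostrings::readBStringSet(ss_path)
  sid <- sub("\\s.*$", "", names(seqs))
  lid <- sub("\\s.*$", "", names(lbls))
  if (length(sid) != length(lid) || any(sid != lid))
    stop("sequence and label FASTA files are not paired (ids differ)")
  fam <- ifelse(grepl("\\s", names(seqs)), sub("^\\S+\\s+", "", names(seqs)), sid)
  seq_dataset(
    data.frame(id = sid, residues = as.character(seqs),
               ss8 = as.character(lbls), family_id = fam,
               stringsAsFactors = FALSE),
    name = name, role = role,
    provenance = sprintf("read from %s + %s", seq_path, ss_path))
}
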