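# Build the synthetic protein universe and record its basic structure:
# family sizes, realized within-family identities, and the unrelated-pair
# identity background that every homology cutoff must clear.
source("analysis/00_common.R")

u <- study_universe()
say("universe: %d sequences in %d families", n_seqs(u),
    length(unique(u$records$family_id)))

# a 30-family excerpt as paired FASTA (the full universe is regenerated
# deterministically from the config, so only an inspectable sample is kept)
excerpt <- seq_dataset(u$records[u$records$family_id %in% sprintf("F%04d", 1:30), ],
                       "universe_excerpt")
write_dataset_fasta(excerpt, file.path(RESULTS_DIR, "universe_excerpt.fasta"),
                    file.path(RESULTS_DIR, "universe_excerpt.ss8"))

fam_sizes <- table(table(u$records$family_id))
say("family-size spectrum: %s",
    paste(sprintf("%sx%s", names(fam_sizes), fam_sizes), collapse = " "))

# realized identity of each member to its family ancestor, first 40 families
recs <- u$records[u$records$family_id %in% sprintf("F%04d", 1:40), ]
rows <- do.call(rbind, lapply(split(recs, recs$family_id), function(fam) {
  anc <- fam[fam$target_identity == 1, ][1, ]
  do.call(rbind, lapply(seq_len(nrow(fam)), function(i)
    data.frame(family = fam$family_id[i], id = fam$id[i],
               target = fam$target_identity[i],
               realized = pairwise_identity(anc, fam[i, ])$identity)))
}))
write.csv(rows, file.path(RESULTS_DIR, "universe_identities.csv"), row.names = FALSE)
say("identity control: max |realized - target| = %.3f (tolerance 0.03)",
    max(abs(rows$realized - rows$target)))

# unrelated background: ancestors of distinct families
anc <- u$records[u$records$target_identity == 1, ]
anc <- anc[!duplicated(anc$family_id), ][1:60, ]
m <- identity_matrix(seq_dataset(anc, "ancestors"))
bg <- m[upper.tri(m)]
say("unrelated-pair identity: median %.3f, 95th pct %.3f, max %.3f",
    median(bg), quantile(bg, 0.95), max(bg))
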