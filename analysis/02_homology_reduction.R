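# Exercise the homology-reduction machinery on the universe: the kept-count
# ladder of within-dataset reduction, and the two-way inter-dataset
# procedure with its all-pairs post-condition and idempotence.
source("analysis/00_common.R")

u <- study_universe()

ladder <- c(0.95, 0.9, 0.8, 0.6, 0.5, 0.4, 0.3, 0.25)
sub <- seq_dataset(u$records[u$records$family_id %in% sprintf("F%04d", 1:120), ],
                   "subuniverse")
tab <- do.call(rbind, lapply(ladder, function(co) {
  r <- reduce_within(sub, co)
  data.frame(cutoff = co, kept = n_seqs(r),
             max_inner = max_inner_identity(r))
}))
write.csv(tab, file.path(RESULTS_DIR, "reduction_ladder.csv"), row.names = FALSE)
say("within-reduction of %d sequences:", n_seqs(sub))
print(tab, row.names = FALSE)
stopifnot(all(tab$max_inner < tab$cutoff), all(diff(tab$kept) <= 0))

set.seed(7)
ids <- sample(n_seqs(u), 60)
a <- seq_dataset(u$records[ids[1:30], ], "A")
b <- seq_dataset(u$records[ids[31:60], ], "B")
tw <- reduce_two_way(a, b, 0.4)
say("two-way at 0.4: A %d -> %d, B %d -> %d, max cross %.3f",
    n_seqs(a), n_seqs(tw$a), n_seqs(b), n_seqs(tw$b),
    max_cross_identity(tw$a, tw$b))
tw2 <- reduce_two_way(tw$a, tw$b, 0.4)
stopifnot(identical(tw2$a$records$id, tw$a$records$id),
          identical(tw2$b$records$id, tw$b$records$id))
say("re-applying the two-way procedure removed nothing (idempotent).")
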