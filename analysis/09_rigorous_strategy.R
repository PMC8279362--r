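# The proposed evaluation strategy: reduce every homology relation (within
# and between query sets, query-to-reference) to a single low cutoff (0.3),
# and compare its overfit gap against a conventional high-homology layout.
source("analysis/00_common.R")

u <- study_universe()
chk <- strategy_check(u, study_spec(reference_size = 250), cutoff = 0.3,
                      config = study_config(), n_repeats = 3)
say("rigorous layout:     gap %.4f (train %.3f, independent %.3f)",
    chk$gap_rigorous,
    mean(chk$rigorous$per_repeat$q_train),
    mean(chk$rigorous$per_repeat$q_indep))
say("conventional layout: gap %.4f (train %.3f, independent %.3f)",
    chk$gap_conventional,
    mean(chk$conventional$per_repeat$q_train),
    mean(chk$conventional$per_repeat$q_indep))
say("rigorous gap not larger: %s", chk$rigorous_gap_not_larger)
write.csv(rbind(cbind(layout = "rigorous", chk$rigorous$per_repeat),
                cbind(layout = "conventional", chk$conventional$per_repeat)),
          file.path(RESULTS_DIR, "strategy_comparison.csv"), row.names = FALSE)
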