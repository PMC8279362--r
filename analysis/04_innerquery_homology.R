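# Does the homology WITHIN each query set inflate apparent accuracy?  The
# overfit gap (training minus independent micro-Q) should shrink as the
# inner-set identity cutoff drops.
source("analysis/00_common.R")

u <- study_universe()
r <- run_ladder("inner_query", u, study_spec(), ladder = list(0.9, 0.5, 0.2),
                config = study_config(), n_repeats = 6)
print(r)
save_result(r, "inner_query")
v <- trend_tests(r)
say("gap monotone decreasing: %s (Spearman %.2f)",
    v$gap_monotone_decreasing$pass, v$gap_monotone_decreasing$spearman)
say("gap(0.9) - gap(0.2) = %.4f, %s p = %.4f",
    v$gap_drop_significant$drop, v$gap_drop_significant$test,
    v$gap_drop_significant$p)
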