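# The homology between the query sets and the PSSM reference dataset is the
# main driver of apparent accuracy: reducing it should pull training and
# testing accuracy down toward the independent level, which itself stays put.
source("analysis/00_common.R")

u <- study_universe()
r <- run_ladder("query_reference", u, study_spec(reference_size = 300),
                ladder = list("All", 0.5, 0.2), config = study_config(),
                n_repeats = 6)
print(r)
save_result(r, "query_reference")
v <- trend_tests(r)
say("train drops: %s (%.4f, p %.4f); test drops: %s (%.4f, p %.4f); independent range %.4f",
    v$train_drops$pass, v$train_drops$drop, v$train_drops$p,
    v$test_drops$pass, v$test_drops$drop, v$test_drops$p,
    v$independent_stable$range)
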