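# Redundancy within the PSSM reference dataset caps profile diversity: as
# the reference inner cutoff drops, hit lists become more diverse, profile
# Shannon entropy rises, and accuracy should rise with it (positive
# entropy-accuracy correlation).
source("analysis/00_common.R")

u <- study_universe()
r <- run_ladder("reference_redundancy", u, study_spec(reference_size = 300),
                ladder = list(1.0, 0.9, 0.6, 0.3), config = study_config(),
                n_repeats = 3)
print(r)
save_result(r, "reference_redundancy")
v <- trend_tests(r)
say("test-set entropy by level: %s",
    paste(round(v$entropy_increases_each_step$entropies, 3), collapse = " "))
say("entropy increases at every step: %s", v$entropy_increases_each_step$pass)
say("independent accuracy not reduced: %s (p %.3f)",
    v$independent_not_reduced$pass, v$independent_not_reduced$p)
say("Pearson r(entropy, test micro-Q) = %.3f", v$entropy_accuracy_corr_positive$r)
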