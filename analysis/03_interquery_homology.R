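# Does the homology BETWEEN the training and testing query sets change SSP
# accuracy?  The inter-set identity cutoff ladder runs from none (exact
# duplicates allowed across sets) down to 0.2 while everything else is held
# fixed.
source("analysis/00_common.R")

u <- study_universe()
r <- run_ladder("inter_query", u, study_spec(), ladder = list(1.0, 0.9, 0.6, 0.4, 0.2),
                config = study_config(), n_repeats = 3)
print(r)
save_result(r, "inter_query")
v <- trend_tests(r)
for (nm in names(v))
  say("%s: %s (range %.4f, p %.3f)", nm, ifelse(v[[nm]]$pass, "yes", "NO"),
      v[[nm]]$range, v[[nm]]$extreme_p)
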