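# Does sharing one PSSM reference set between training and evaluation leak
# information?  Compare one shared reference set against two or three
# isolated sets (one per role).
source("analysis/00_common.R")

u <- study_universe()
r <- run_ladder("reference_isolation", u, study_spec(reference_size = 300),
                ladder = list(1L, 2L, 3L), config = study_config(),
                n_repeats = 3)
print(r)
save_result(r, "reference_isolation")
v <- trend_tests(r)
for (nm in names(v))
  say("%s: %s (min pairwise p %.3f)", nm,
      ifelse(v[[nm]]$pass, "no significant difference", "DIFFERS"),
      v[[nm]]$min_p)
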