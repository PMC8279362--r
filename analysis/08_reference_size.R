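# Reference-set size: a larger reference raises accuracy in every group, but
# it raises apparent accuracy faster when the query sets are redundant --
# the overfit gap grows with reference size, and faster at high inner-query
# homology.
source("analysis/00_common.R")

u <- study_universe()
sizes <- list(250L, 500L, 1000L)
r_high <- run_ladder("reference_size", u, study_spec(inner_cutoff_query = 0.9),
                     ladder = sizes, config = study_config())
r_low <- run_ladder("reference_size", u, study_spec(inner_cutoff_query = 0.2),
                    ladder = sizes, config = study_config())
print(r_high); print(r_low)
save_result(r_high, "reference_size__inner90")
save_result(r_low, "reference_size__inner20")

v <- trend_tests(r_high)
say("micro-Q increases with size (inner 0.9): train %s, test %s, independent %s",
    v$train_increases$pass, v$test_increases$pass, v$independent_increases$pass)

gap_growth <- function(r) {
  g <- r$levels$gap
  g[length(g)] - g[1]
}
contrast <- gap_growth(r_high) - gap_growth(r_low)
say("gap growth 250->1000: %.4f at inner 0.9 vs %.4f at inner 0.2 (interaction %.4f)",
    gap_growth(r_high), gap_growth(r_low), contrast)
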