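# Shared settings of the analysis drivers.  Each numbered script is a thin
# narrative wrapper over the package; all computation lives in homssp.
library(homssp)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Study universe: 300 families (~1800 sequences) with the heavy-tailed
# family-size pattern; desk-scale stand-in for a structural database.
study_universe <- function(seed = 20150101) {
  generate_universe(universe_config(n_families = 300, seed = seed))
}

# Desk-scale layout defaults used across the experiment drivers.
study_spec <- function(...) {
  args <- list(reference_size = 500, train_size = 30, test_size = 30,
               independent_size = 20, inner_cutoff_query = 0.9,
               reference_inner_cutoff = 0.9, n_repeats = 4, seed = 101)
  do.call(layout_spec, utils::modifyList(args, list(...)))
}

study_config <- function() pipeline_config()

save_result <- function(result, stem) {
  write.csv(result$levels, file.path(RESULTS_DIR, paste0(stem, "_levels.csv")),
            row.names = FALSE)
  write.csv(result$per_repeat, file.path(RESULTS_DIR, paste0(stem, "_repeats.csv")),
            row.names = FALSE)
  invisible(result)
}

say <- function(...) cat(sprintf(...), "\n")
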