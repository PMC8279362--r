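# Base-learner comparison (reduced scope): bootstrapped forests of neural
# networks and decision trees, and their pooled committee, on one
# conventional layout.
source("analysis/00_common.R")

u <- study_universe()
lay <- build_layout(u, study_spec())
ref <- lay$reference[[1]]
profs <- list(train = build_profiles(lay$train, ref),
              test = build_profiles(lay$test, ref),
              independent = build_profiles(lay$independent, ref))
enc <- homssp:::encode_dataset(lay$train, profs$train)

evaluate <- function(model, nm) {
  out <- sapply(c("train", "test", "independent"), function(g) {
    d <- lay[[g]]
    pred <- homssp:::predict_dataset(model, d, profs[[g]])
    attr(score_predictions(pred, d$records$ss3), "micro_q")
  })
  say("%-12s train %.3f  test %.3f  independent %.3f", nm,
      out["train"], out["test"], out["independent"])
  out
}

ann <- train_ensemble(enc$x, enc$y,
                      ensemble_config(5, "ann", ann_size = 6, ann_maxit = 50,
                                      ann_decay = 0.01), seed = 11)
tree <- train_ensemble(enc$x, enc$y, ensemble_config(5, "tree"), seed = 12)
res <- rbind(ann = evaluate(ann, "ANN forest"),
             tree = evaluate(tree, "tree forest"),
             combined = evaluate(combine_ensembles(list(ann, tree)), "combined"))
write.csv(data.frame(learner = rownames(res), res),
          file.path(RESULTS_DIR, "learner_comparison.csv"), row.names = FALSE)
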