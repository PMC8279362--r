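make_profile <- function(seq) build_pssm(seq, NULL, beta = 1)

test_that("windowed encoding has the documented geometry", {
  set.seed(61)
  rec <- list(id = "t", residues = random_protein(30),
              ss3 = paste(sample(c("H", "E", "C"), 30, TRUE), collapse = ""))
  enc <- encode_features(rec, make_profile(rec$residues), window = 5)
  expect_equal(dim(enc$x), c(30, 205))
  pad_cols <- grep("_pad$", colnames(enc$x))
  expect_equal(sum(enc$x[1, pad_cols]), 2)   # first residue: two padded slots
  expect_equal(sum(enc$x[2, pad_cols]), 1)
  expect_equal(sum(enc$x[15, pad_cols]), 0)  # interior: none
  expect_equal(sum(enc$x[30, pad_cols]), 2)
  expect_equal(as.character(enc$y), strsplit(rec$ss3, "")[[1]])
  expect_error(encode_features(rec, make_profile(random_protein(10))),
               "length")
  expect_error(encode_features(rec, make_profile(rec$residues), window = 4),
               "odd")
})

toy_problem <- function(n = 400, seed = 67) {
  set.seed(seed)
  x <- matrix(runif(n * 10), n, 10)
  y <- factor(ifelse(x[, 1] > 0.5, "H", "C"), levels = c("H", "E", "C"))
  list(x = x, y = y)
}

test_that("ensembles learn a separable toy problem and stay deterministic", {
  tp <- toy_problem()
  cfg <- ensemble_config(n_members = 5, base_learner = "tree")
  m <- train_ensemble(tp$x, tp$y, cfg, seed = 2)
  pred <- predict(m, tp$x)
  expect_gte(mean(pred$labels == as.character(tp$y)), 0.99)
  expect_equal(length(pred$labels), nrow(tp$x))
  expect_true(all(pred$labels %in% levels(tp$y)))
  # seeded determinism of the full train-predict path
  m2 <- train_ensemble(tp$x, tp$y, cfg, seed = 2)
  expect_identical(predict(m2, tp$x)$labels, pred$labels)
})

test_that("a degenerate single-class training set is rejected", {
  tp <- toy_problem()
  expect_error(train_ensemble(tp$x, factor(rep("H", nrow(tp$x)),
                                           levels = c("H", "E", "C"))),
               "single class")
})

test_that("one full-sample member equals the base learner trained directly", {
  tp <- toy_problem(250)
  cfg <- ensemble_config(n_members = 1, base_learner = "ann",
                         sample_fraction = 1, replace = FALSE,
                         feature_fraction = 1, ann_size = 3, ann_maxit = 50)
  ens <- train_ensemble(tp$x, tp$y, cfg, seed = 5)
  direct <- homssp:::with_seed(5, homssp:::fit_base_learner(tp$x, droplevels(tp$y), cfg))
  p_ens <- predict(ens, tp$x)$labels
  p_dir <- homssp:::predict_base_learner(direct, tp$x, "ann", levels(droplevels(tp$y)))
  expect_identical(p_ens, as.character(p_dir))
})

constant_member <- function(label, p = 10) {
  # a root-only tree whose overwhelming majority class makes it constant
  other <- setdiff(c("H", "E", "C"), label)[1]
  xm <- homssp:::ensure_colnames(matrix(runif(20 * p), 20, p))
  df <- data.frame(.y = factor(c(rep(label, 19), other), levels = c("H", "E", "C")),
                   xm, check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., df, method = "class",
                      control = rpart::rpart.control(minsplit = 100, xval = 0))
  list(model = fit, features = seq_len(p), type = "tree")
}

fake_ensemble <- function(members, p = 10) {
  structure(list(members = members, levels = c("H", "E", "C"),
                 n_features = p, config = ensemble_config(n_members = 1),
                 seed = 1), class = "ssp_ensemble")
}

test_that("votes tie toward coil and pool across combined ensembles", {
  x <- matrix(runif(50), 5, 10)
  eH <- fake_ensemble(list(constant_member("H")))
  eC <- fake_ensemble(list(constant_member("C")))
  # 1-vs-1 tie H/C resolves to C
  both <- combine_ensembles(list(eH, eC))
  expect_equal(predict(both, x)$labels, rep("C", 5))
  # 30 always-H + 30 always-C members: still all-C by the tie-break
  big <- combine_ensembles(list(
    fake_ensemble(replicate(30, constant_member("H"), simplify = FALSE)),
    fake_ensemble(replicate(30, constant_member("C"), simplify = FALSE))))
  expect_equal(predict(big, x)$labels, rep("C", 5))
  # combining a model with itself changes nothing
  tp <- toy_problem(200)
  m <- train_ensemble(tp$x, tp$y, ensemble_config(3, "tree"), seed = 3)
  expect_identical(predict(combine_ensembles(list(m, m)), tp$x)$labels,
                   predict(m, tp$x)$labels)
  expect_error(predict(m, tp$x[, 1:5]), "feature width")
})

test_that("mixed-learner forests run end-to-end above the majority baseline", {
  set.seed(71)
  n <- 600
  x <- matrix(runif(n * 12), n, 12)
  y <- factor(ifelse(x[, 1] + 0.3 * x[, 2] > 0.8, "H",
                     ifelse(x[, 3] > 0.6, "E", "C")), levels = c("H", "E", "C"))
  ann <- train_ensemble(x, y, ensemble_config(3, "ann", ann_size = 3,
                                              ann_maxit = 40), seed = 11)
  tree <- train_ensemble(x, y, ensemble_config(3, "tree"), seed = 12)
  mix <- combine_ensembles(list(ann, tree))
  acc <- mean(predict(mix, x)$labels == as.character(y))
  expect_gt(acc, max(table(y)) / length(y))
})

test_that("models survive a save/load round trip", {
  tp <- toy_problem(150)
  m <- train_ensemble(tp$x, tp$y, ensemble_config(2, "tree"), seed = 4)
  f <- tempfile(fileext = ".rds")
  save_ensemble(m, f)
  m2 <- load_ensemble(f)
  expect_identical(predict(m2, tp$x)$labels, predict(m, tp$x)$labels)
})
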