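#' Encode windowed per-residue features
#'
#' For every position i the encodings of positions i-w..i+w (window size
#' 2w+1, default 5) are concatenated.  Each window slot contributes the 20
#' profile probabilities, the 20-letter one-hot of the residue, and one
#' terminus-pad flag which is 1 exactly when the slot falls outside the
#' sequence (profile and one-hot are zero there).  Width is therefore
#' `window * 41` (205 for the default window).
#'
#' @param seq Record (row/list with `$residues`, `$ss3`, `$ss8`) or residue
#'   string.
#' @param profile A `pssm_profile` of the same length.
#' @param window Odd window size (default 5).
#' @param label_states `"ss3"` (default) or `"ss8"`: which labels to attach.
#' @return A list with `x` (L x window*41 feature matrix) and `y` (factor of
#'   per-residue labels, `NULL` when the record carries none).
#' @export
encode_features <- function(seq, profile, window = 5, label_states = c("ss3", "ss8")) {
  label_states <- match.arg(label_states)
  if (window %% 2 != 1 || window < 1) stop("window must be odd and positive")
  res <- as_residues(seq)
  L <- nchar(res)
  if (profile$length != L)
    stop("profile length does not match sequence length")
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  one_hot <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, aa))
  one_hot[cbind(seq_len(L), match(strsplit(res, "")[[1]], aa))] <- 1
  half <- window %/% 2
  blocks <- lapply(-half:half, function(off) {
    idx <- seq_len(L) + off
    inside <- idx >= 1 & idx <= L
    block <- matrix(0, nrow = L, ncol = 41)
    block[inside, 1:20] <- profile$probs[idx[inside], , drop = FALSE]
    block[inside, 21:40] <- one_hot[idx[inside], , drop = FALSE]
    block[!inside, 41] <- 1
    colnames(block) <- paste0("o", off, "_", c(aa, paste0("aa", aa), "pad"))
    block
  })
  x <- do.call(cbind, blocks)
  y <- NULL
  if (is.list(seq) && !is.null(seq[[label_states]])) {
    lvl <- strsplit(if (label_states == "ss3") SS3_ALPHABET else SS8_ALPHABET, "")[[1]]
    y <- factor(strsplit(seq[[label_states]], "")[[1]], levels = lvl)
  }
  list(x = x, y = y)
}

# Stack encoded features for all records of a dataset, given its profiles.
encode_dataset <- function(d, profiles, window = 5, label_states = "ss3") {
  enc <- lapply(seq_len(n_seqs(d)), function(i) {
    rec <- d$records[i, ]
    encode_features(rec, profiles[[rec$id]], window, label_states)
  })
  list(x = do.call(rbind, lapply(enc, `[[`, "x")),
       y = factor(unlist(lapply(enc, function(e) as.character(e$y))),
                  levels = levels(enc[[1]]$y)),
       lengths = d$records$length, ids = d$records$id)
}

#' Ensemble configuration
#'
#' The prediction model is a "random forest" of bootstrapped base learners:
#' every member is trained on a bootstrap resample of residues and a random
#' subset of features, and prediction is by majority vote with ties broken
#' toward coil.
#'
#' @param n_members Number of members (study default 60; ladder experiments
#'   use a lighter 10-member forest).
#' @param base_learner `"ann"` (single-hidden-layer neural network),
#'   `"tree"` (decision tree) or `"svm"` (support vector machine).
#' @param sample_fraction Fraction of residues resampled per member
#'   (default 1: a classical bootstrap, ~63.2% unique rows).
#' @param replace Sample with replacement (default TRUE).
#' @param feature_fraction Fraction of feature columns per member.
#' @param ann_size Hidden units of the neural-network learner.
#' @param ann_decay,ann_maxit nnet regularisation and iteration cap.
#' @param svm_cost,svm_gamma e1071::svm parameters (gamma NULL = 1/ncol).
#' @param tree_cp rpart complexity parameter.
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 60, base_learner = c("ann", "tree", "svm"),
                            sample_fraction = 1, replace = TRUE,
                            feature_fraction = 0.7,
                            ann_size = 30, ann_decay = 0.1, ann_maxit = 100,
                            svm_cost = 1, svm_gamma = NULL, tree_cp = 0.002) {
  stopifnot(n_members >= 1, sample_fraction > 0, sample_fraction <= 1,
            feature_fraction > 0, feature_fraction <= 1)
  structure(list(n_members = n_members,
                 base_learner = match.arg(base_learner),
                 sample_fraction = sample_fraction, replace = replace,
                 feature_fraction = feature_fraction,
                 ann_size = ann_size, ann_decay = ann_decay, ann_maxit = ann_maxit,
                 svm_cost = svm_cost, svm_gamma = svm_gamma, tree_cp = tree_cp),
            class = "ensemble_config")
}

ensure_colnames <- function(x) {
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

fit_base_learner <- function(x, y, config) {
  x <- ensure_colnames(x)
  switch(config$base_learner,
    ann = {
      ymat <- nnet::class.ind(y)
      nnet::nnet(x, ymat, size = config$ann_size, decay = config$ann_decay,
                 maxit = config$ann_maxit, softmax = TRUE, trace = FALSE,
                 MaxNWts = 100000)
    },
    tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = config$tree_cp,
                                                  xval = 0))
    },
    svm = {
      e1071::svm(x, y, cost = config$svm_cost,
                 gamma = if (is.null(config$svm_gamma)) 1 / ncol(x) else config$svm_gamma,
                 kernel = "radial")
    })
}

predict_base_learner <- function(model, x, config_type, levels_) {
  x <- ensure_colnames(x)
  lab <- switch(config_type,
    ann = {
      p <- predict(model, x, type = "raw")
      colnames(p)[max.col(p, ties.method = "first")]
    },
    tree = {
      df <- data.frame(x, check.names = FALSE)
      as.character(predict(model, df, type = "class"))
    },
    svm = as.character(predict(model, x)))
  factor(lab, levels = levels_)
}

#' Train a bootstrapped voting ensemble
#'
#' Each member sees a resample of `sample_fraction * n` residues (with
#' replacement by default) and a random `feature_fraction` subset of feature
#' columns; resamples are redrawn (up to 20 times) if they lose a class.
#' Deterministic given `seed`.  When `sample_fraction = 1`,
#' `replace = FALSE` and `feature_fraction = 1`, a member is the base
#' learner trained on the untouched data.
#'
#' @param x Feature matrix (rows = residues).
#' @param y Factor of labels (at least 2 classes present).
#' @param config An [ensemble_config()].
#' @param seed Integer training seed.
#' @return Object of class `ssp_ensemble`.
#' @export
train_ensemble <- function(x, y, config = ensemble_config(), seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("degenerate training set: a single class is present")
  n <- nrow(x)
  p <- ncol(x)
  full_levels <- levels(y)
  members <- with_seed(seed, lapply(seq_len(config$n_members), function(m) {
    feat <- if (config$feature_fraction < 1)
      sort(sample.int(p, max(1, round(config$feature_fraction * p))))
    else seq_len(p)
    take_all <- config$sample_fraction == 1 && !config$replace
    for (try in 1:20) {
      rows <- if (take_all) seq_len(n)
              else sample.int(n, max(2, round(config$sample_fraction * n)),
                              replace = config$replace)
      if (nlevels(droplevels(y[rows])) >= 2) break
    }
    model <- fit_base_learner(x[rows, feat, drop = FALSE], y[rows], config)
    list(model = model, features = feat, type = config$base_learner)
  }))
  structure(list(members = members, levels = full_levels, n_features = p,
                 config = config, seed = seed),
            class = "ssp_ensemble")
}

#' @export
print.ssp_ensemble <- function(x, ...) {
  types <- table(vapply(x$members, `[[`, "", "type"))
  cat(sprintf("<ssp_ensemble> %d members (%s), %d features, classes {%s}\n",
              length(x$members),
              paste(sprintf("%s x%d", names(types), types), collapse = ", "),
              x$n_features, paste(x$levels, collapse = ",")))
  invisible(x)
}

#' Predict with a voting ensemble
#'
#' Per-residue majority vote over the members; ties are broken toward coil
#' (`"C"`) when coil is among the tied classes, otherwise toward the
#' alphabetically first tied class.
#'
#' @param object An `ssp_ensemble`.
#' @param x Feature matrix with the training feature width.
#' @param ... Unused.
#' @return A list with `labels` (character vector) and `votes` (matrix of
#'   per-class vote fractions).
#' @export
predict.ssp_ensemble <- function(object, x, ...) {
  if (ncol(x) != object$n_features)
    stop("feature width ", ncol(x), " does not match training width ",
         object$n_features)
  lv <- object$levels
  votes <- matrix(0L, nrow = nrow(x), ncol = length(lv),
                  dimnames = list(NULL, lv))
  for (mem in object$members) {
    pred <- predict_base_learner(mem$model, x[, mem$features, drop = FALSE],
                                 mem$type, lv)
    idx <- cbind(seq_len(nrow(x)), as.integer(pred))
    votes[idx] <- votes[idx] + 1L
  }
  labels <- apply(votes, 1, function(v) {
    top <- which(v == max(v))
    if (length(top) > 1 && "C" %in% lv[top]) return("C")
    lv[top[1]]
  })
  list(labels = labels, votes = votes / length(object$members))
}

# Predict a whole dataset: returns one predicted label string per record.
predict_dataset <- function(model, d, profiles, window = 5, label_states = "ss3") {
  enc <- encode_dataset(d, profiles, window, label_states)
  pred <- predict(model, enc$x)$labels
  ends <- cumsum(d$records$length)
  starts <- ends - d$records$length + 1
  vapply(seq_along(ends), function(i)
    paste(pred[starts[i]:ends[i]], collapse = ""), "")
}

#' Pool several ensembles into one voting committee
#'
#' Members of all models vote jointly (e.g. 30 ANN + 30 tree members).
#' Models must share the class alphabet and feature width.
#'
#' @param models List of `ssp_ensemble` objects.
#' @return A pooled `ssp_ensemble`.
#' @export
combine_ensembles <- function(models) {
  stopifnot(length(models) >= 1)
  ref <- models[[1]]
  for (m in models[-1]) {
    if (!identical(m$levels, ref$levels))
      stop("ensembles use different class alphabets")
    if (m$n_features != ref$n_features)
      stop("ensembles use different feature widths")
  }
  structure(list(members = do.call(c, lapply(models, `[[`, "members")),
                 levels = ref$levels, n_features = ref$n_features,
                 config = ref$config, seed = ref$seed),
            class = "ssp_ensemble")
}

#' Save / load an ensemble model
#'
#' Single-file archive via R serialisation.
#' @param model An `ssp_ensemble`.
#' @param path Archive path.
#' @return `save_ensemble`: invisibly `path`; `load_ensemble`: the model.
#' @export
save_ensemble <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) readRDS(path)

#' Write predictions in a vertical per-residue format
#'
#' One line per residue: index, residue, predicted state and the per-class
#' vote fractions — the layout SSP tools conventionally emit.
#'
#' @param seq Record or residue string.
#' @param labels Predicted label string.
#' @param votes Per-class vote matrix (rows = residues).
#' @param path Output file.
#' @return Invisibly, the data frame written.
#' @export
write_predictions <- function(seq, labels, votes, path) {
  res <- strsplit(as_residues(seq), "")[[1]]
  df <- data.frame(pos = seq_along(res), residue = res,
                   pred = strsplit(labels, "")[[1]],
                   round(votes, 4), check.names = FALSE)
  write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(df)
}
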