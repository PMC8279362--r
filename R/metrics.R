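#' Map 8-state secondary structure labels to 3 states
#'
#' The common convention: H, G, I -> H (helix); E, B -> E (strand);
#' T, S, C -> C (coil).  Total and deterministic; idempotent on strings that
#' already use only H, E and C.
#'
#' @param ss8 Character vector of 8-state label strings.
#' @return Character vector of 3-state label strings.
#' @export
ss8_to_ss3 <- function(ss8) {
  bad <- grepl(sprintf("[^%s]", SS8_ALPHABET), ss8)
  if (any(bad))
    stop("illegal 8-state symbol in: ", paste(head(ss8[bad]), collapse = ", "))
  chartr("HGIEBTSC", "HHHEECCC", ss8)
}

split_states <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Per-protein Q accuracy
#'
#' Fraction of positions at which the predicted state equals the observed
#' state.
#'
#' @param pred,true State strings of equal length over the same alphabet.
#' @return A list with `n_correct`, `length` and `q`.
#' @export
q_accuracy <- function(pred, true) {
  if (nchar(pred) != nchar(true))
    stop("predicted and observed strings must have equal length")
  p <- split_states(pred)
  t_ <- split_states(true)
  n_correct <- sum(p == t_)
  list(n_correct = n_correct, length = nchar(true), q = n_correct / nchar(true))
}

# Segments of one state string: data.frame(state, start, end, len)
ss_segments <- function(s) {
  r <- rle(split_states(s))
  end <- cumsum(r$lengths)
  data.frame(state = r$values, start = end - r$lengths + 1L, end = end,
             len = r$lengths, stringsAsFactors = FALSE)
}

#' Segment overlap (SOV) score
#'
#' The SOV'99 measure: for every observed segment `s1` of a state and every
#' predicted segment `s2` of the same state that overlaps it, the pair
#' contributes `(minov + delta) / maxov * len(s1)`, where `minov` is the
#' length of their intersection, `maxov` the length of their union and
#' `delta = min(maxov - minov, minov, floor(len(s1)/2), floor(len(s2)/2))`
#' the boundary-shift allowance.  The normaliser counts `len(s1)` once per
#' overlapping pair, and once for observed segments with no overlapping
#' partner.  States are pooled (a single sum over all states).
#'
#' @param pred,true State strings of equal length.
#' @param states Character vector of states to score (defaults to the states
#'   present in `true`).
#' @return SOV score in `[0, 100]`; identical strings score 100.
#' @export
sov <- function(pred, true, states = NULL) {
  if (nchar(pred) != nchar(true))
    stop("predicted and observed strings must have equal length")
  seg_t <- ss_segments(true)
  seg_p <- ss_segments(pred)
  if (is.null(states)) states <- unique(seg_t$state)
  total <- 0
  n_norm <- 0
  for (st in states) {
    s1s <- seg_t[seg_t$state == st, , drop = FALSE]
    s2s <- seg_p[seg_p$state == st, , drop = FALSE]
    if (!nrow(s1s)) next
    for (i in seq_len(nrow(s1s))) {
      s1 <- s1s[i, ]
      ov <- which(s2s$start <= s1$end & s2s$end >= s1$start)
      if (!length(ov)) {
        n_norm <- n_norm + s1$len
        next
      }
      for (j in ov) {
        s2 <- s2s[j, ]
        minov <- min(s1$end, s2$end) - max(s1$start, s2$start) + 1L
        maxov <- max(s1$end, s2$end) - min(s1$start, s2$start) + 1L
        delta <- min(maxov - minov, minov, s1$len %/% 2L, s2$len %/% 2L)
        total <- total + (minov + delta) / maxov * s1$len
        n_norm <- n_norm + s1$len
      }
    }
  }
  if (n_norm == 0) return(0)
  100 * total / n_norm
}

#' Length-weighted average SOV over a set of proteins
#'
#' `sum(len_q * SOV_q) / sum(len_q)`: each protein's SOV is weighted by its
#' sequence length, so long proteins are not underweighted relative to a
#' plain mean over proteins.
#'
#' @param scores Data frame with columns `length` and `sov` (one row per
#'   protein), e.g. the per-protein table of [score_predictions()].
#' @return Weighted SOV in `[0, 100]`.
#' @export
weighted_sov <- function(scores) {
  if (!nrow(scores)) stop("empty score set")
  sum(scores$length * scores$sov) / sum(scores$length)
}

#' Residue-level (micro-average) Q over a set of proteins
#'
#' `sum(Nres_a(q)) / sum(len_q)`: the residue is the unit, equivalent to
#' concatenating all proteins and counting correct positions, which prevents
#' small proteins from being overweighted.
#'
#' @param scores Data frame with columns `n_correct` and `length`.
#' @return Fraction in `[0, 1]`.
#' @export
micro_q <- function(scores) {
  if (!nrow(scores)) stop("empty score set")
  sum(scores$n_correct) / sum(scores$length)
}

#' Score a set of predictions against observed labels
#'
#' @param pred Character vector of predicted state strings.
#' @param true Character vector of observed state strings (same order).
#' @param ids Optional protein ids.
#' @return An object of class `eval_report`: a per-protein data frame
#'   (`id`, `length`, `n_correct`, `q`, `sov`) with aggregate attributes
#'   `micro_q` and `weighted_sov`.
#' @export
score_predictions <- function(pred, true, ids = NULL) {
  stopifnot(length(pred) == length(true))
  if (is.null(ids)) ids <- paste0("q", seq_along(pred))
  rows <- lapply(seq_along(pred), function(i) {
    qa <- q_accuracy(pred[i], true[i])
    data.frame(id = ids[i], length = qa$length, n_correct = qa$n_correct,
               q = qa$q, sov = sov(pred[i], true[i]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(tab, class = c("eval_report", "data.frame"),
            micro_q = micro_q(tab), weighted_sov = weighted_sov(tab))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d proteins, micro-Q=%.4f, weighted SOV=%.2f\n",
              nrow(x), attr(x, "micro_q"), attr(x, "weighted_sov")))
  invisible(x)
}

#' Two-group significance cascade
#'
#' The testing cascade used throughout the experiments: Shapiro-Wilk
#' normality on each sample; if both pass at `alpha`, an F test for equality
#' of variances decides between Student's t (equal variances) and Welch's t;
#' if either sample is non-normal the Wilcoxon rank-sum test is used instead.
#' Degenerate constant samples short-circuit: equal constants give p = 1,
#' different constants p = 0.
#'
#' @param x,y Numeric samples, each of size >= 3.
#' @param alpha Significance level for the auxiliary normality/variance
#'   decisions (default 0.05).
#' @return A list with `test` (name of the test that produced the p-value),
#'   `p_value`, `statistic` and the auxiliary p-values.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3)
    stop("each sample must have at least 3 values")
  if (sd(x) == 0 && sd(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(test = "degenerate (constant samples)",
                p_value = if (equal) 1 else 0,
                statistic = 0, shapiro_x = NA, shapiro_y = NA, f_test = NA))
  }
  sw_x <- if (sd(x) > 0) shapiro.test(x)$p.value else 0
  sw_y <- if (sd(y) > 0) shapiro.test(y)$p.value else 0
  if (sw_x > alpha && sw_y > alpha) {
    fp <- var.test(x, y)$p.value
    equal_var <- fp > alpha
    tt <- t.test(x, y, var.equal = equal_var)
    list(test = if (equal_var) "Student's t" else "Welch's t",
         p_value = tt$p.value, statistic = unname(tt$statistic),
         shapiro_x = sw_x, shapiro_y = sw_y, f_test = fp)
  } else {
    wt <- wilcox.test(x, y, exact = FALSE)
    list(test = "Wilcoxon rank-sum", p_value = wt$p.value,
         statistic = unname(wt$statistic),
         shapiro_x = sw_x, shapiro_y = sw_y, f_test = NA)
  }
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient r.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("samples must have equal length")
  if (length(x) < 3) stop("at least 3 paired values are required")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance sample")
  cor(x, y, method = "pearson")
}
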