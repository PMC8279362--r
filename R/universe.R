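#' Default per-state amino-acid propensity table
#'
#' A 3 x 20 row-stochastic matrix (rows H, E, C; columns the 20 residues)
#' giving the probability of each residue within helix, strand and coil
#' segments.  State-typical residues (helix: A E K L M Q R; strand:
#' C F I T V W Y; coil: D G N P S) carry four-fold weight, which yields
#' moderately discriminative compositions without collapsing row entropy —
#' enough signal for a windowed classifier to beat the majority class, while
#' unrelated sequences still look compositionally alike.
#'
#' @return A 3 x 20 numeric matrix with rows summing to 1.
#' @export
default_aa_propensity <- function() {
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  w <- matrix(1, nrow = 3, ncol = 20, dimnames = list(c("H", "E", "C"), aa))
  w["H", c("A", "E", "K", "L", "M", "Q", "R")] <- 4
  w["E", c("C", "F", "I", "T", "V", "W", "Y")] <- 4
  w["C", c("D", "G", "N", "P", "S")] <- 4
  w / rowSums(w)
}

#' Configuration of the synthetic protein universe
#'
#' The generator emulates the homology structure of a structural database:
#' `n_families` ancestral proteins, each expanded into `family_size` members
#' whose identities to the ancestor follow `identity_ladder`.  Secondary
#' structure comes from a semi-Markov segment process over three macro
#' states (helix-, strand-, coil-like) with geometric segment lengths;
#' residues are drawn per position from the state's propensity row.
#'
#' @param n_families Number of independent families.
#' @param family_size Nominal members per family: the mean of the default
#'   `family_sizes` pattern.
#' @param family_sizes Integer vector of per-family sizes, recycled across
#'   families.  The default heavy-tailed pattern (1, 1, 2, 4, 10, 18; mean 6)
#'   emulates the family-size distribution of real sequence databases, where
#'   a minority of large families contributes most of the redundancy —
#'   the feature that couples dataset homology reduction to profile quality.
#'   Members of a family cycle through the `identity_ladder` slots, so large
#'   families contain exact duplicates and near-duplicate pairs while small
#'   families are ancestor-only.  Use `rep(family_size, n_families)` for a
#'   uniform universe.
#' @param length_range Two integers, min/max ancestor length (min >= 30).
#'   The default narrow band (110-130) keeps the shorter-sequence identity
#'   denominator from inflating the apparent identity of unrelated pairs.
#' @param identity_ladder Target identities of the members to their ancestor,
#'   each in (0, 1]; members cycle through these slots, so families larger
#'   than the ladder repeat it.  The default spans 1.0 down to 0.28 on a
#'   dense grid: real databases contain a *continuum* of redundancy, and the
#'   near-cutoff pairs (e.g. mutual identity ~0.87 surviving an NR90
#'   reduction) are what couples homology cutoffs to dataset redundancy.
#' @param ss_segment_length_means Named numeric: mean segment length per
#'   3-state class (minimum segment lengths helix 4, strand 2, coil 1).
#' @param aa_propensity 3 x 20 row-stochastic matrix (rows H, E, C).
#' @param substitution_identity_tolerance Allowed deviation of realized from
#'   target identity (measured by [pairwise_identity()]).
#' @param ss_flip_prob Probability that a substituted position's label flips
#'   to a coil sub-label (label noise; keeps prediction imperfectly
#'   learnable).
#' @param ss_noise_prob Baseline per-position probability that an ancestor's
#'   label flips to a coil sub-label after the residue is drawn (assignment
#'   ambiguity, as real 8-state assigners disagree on a few percent of
#'   positions).  Without it, ancestors would carry systematically cleaner
#'   labels than deep family mutants, making the independent set (family
#'   representatives) artificially easy relative to train/test.
#' @param seed Integer seed; the universe is a deterministic function of the
#'   full configuration.
#' @return A list of class `universe_config`.
#' @export
universe_config <- function(n_families = 400,
                            family_size = 6,
                            family_sizes = c(1L, 1L, 2L, 4L, 10L, 18L),
                            length_range = c(110, 130),
                            identity_ladder = c(1.0, 0.95, 0.90, 0.85, 0.80, 0.75,
                                                0.70, 0.60, 0.50, 0.40, 0.30, 0.28),
                            ss_segment_length_means = c(H = 8, E = 5, C = 6),
                            aa_propensity = default_aa_propensity(),
                            substitution_identity_tolerance = 0.03,
                            ss_flip_prob = 0.1,
                            ss_noise_prob = 0.03,
                            seed = 20150101) {
  cfg <- structure(
    list(n_families = n_families, family_size = family_size,
         family_sizes = rep_len(as.integer(family_sizes), n_families),
         length_range = length_range, identity_ladder = identity_ladder,
         ss_segment_length_means = ss_segment_length_means,
         aa_propensity = aa_propensity,
         substitution_identity_tolerance = substitution_identity_tolerance,
         ss_flip_prob = ss_flip_prob, ss_noise_prob = ss_noise_prob,
         seed = seed),
    class = "universe_config")
  validate_universe_config(cfg)
  cfg
}

validate_universe_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(n_families) || n_families < 1) stop("n_families must be >= 1")
    if (!is.numeric(family_size) || family_size < 1) stop("family_size must be >= 1")
    if (any(family_sizes < 1)) stop("family_sizes must be positive")
    if (length(length_range) != 2 || length_range[1] < 30 ||
        length_range[2] < length_range[1])
      stop("length_range must be (min, max) with min >= 30")
    if (any(identity_ladder <= 0 | identity_ladder > 1))
      stop("identities must lie in (0, 1]")
    if (!all(c("H", "E", "C") %in% names(ss_segment_length_means)))
      stop("ss_segment_length_means needs names H, E, C")
    min_seg <- c(H = 4, E = 2, C = 1)
    if (any(ss_segment_length_means[names(min_seg)] < min_seg))
      stop("segment length means must be >= the minimum segment lengths (H 4, E 2, C 1)")
    if (!is.matrix(aa_propensity) || !all(dim(aa_propensity) == c(3, 20)))
      stop("aa_propensity must be a 3 x 20 matrix")
    if (any(abs(rowSums(aa_propensity) - 1) > 1e-9))
      stop("aa_propensity rows must sum to 1")
    if (substitution_identity_tolerance <= 0 || substitution_identity_tolerance >= 1)
      stop("substitution_identity_tolerance must be in (0, 1)")
    if (ss_flip_prob < 0 || ss_flip_prob > 1) stop("ss_flip_prob must be in [0, 1]")
    if (ss_noise_prob < 0 || ss_noise_prob > 1) stop("ss_noise_prob must be in [0, 1]")
  })
  invisible(cfg)
}

MIN_SEGMENT <- c(H = 4L, E = 2L, C = 1L)
COIL_SUBLABELS <- c("T", "S", "C")

# Draw one segment length: minimum + geometric overhang with the configured
# mean.
draw_segment_length <- function(state, means) {
  m <- MIN_SEGMENT[[state]]
  mu <- means[[state]]
  extra <- if (mu > m) rgeom(1, 1 / (mu - m + 1)) else 0L
  m + extra
}

next_state <- function(state) {
  # leave the current macro state; helices and strands relax mostly through
  # coil, coil splits evenly between the structured states
  switch(state,
         H = sample(c("E", "C"), 1, prob = c(0.35, 0.65)),
         E = sample(c("H", "C"), 1, prob = c(0.35, 0.65)),
         C = sample(c("H", "E"), 1))
}

sub_labels <- function(state, len) {
  switch(state,
         H = rep("H", len),
         E = rep("E", len),
         C = sample(COIL_SUBLABELS, len, replace = TRUE))
}

#' Sample an ancestral labelled protein
#'
#' Generates the secondary structure by a semi-Markov process over the three
#' macro states (helix -> 8-state H, strand -> E, coil -> uniform T/S/C),
#' then draws each residue from the state's propensity row.  Uses the
#' current RNG state; seed externally (or via [generate_universe()]).
#'
#' @param config A [universe_config()].
#' @param id,family_id Identifiers for the new record.
#' @return A one-row data frame (id, residues, ss8, ss3, family_id, length).
#' @export
sample_ancestor <- function(config, id = "anc", family_id = id) {
  validate_universe_config(config)
  target_len <- sample(config$length_range[1]:config$length_range[2], 1)
  states <- character(0)
  ss8 <- character(0)
  state <- sample(c("H", "E", "C"), 1)
  while (length(ss8) < target_len) {
    len <- draw_segment_length(state, config$ss_segment_length_means)
    ss8 <- c(ss8, sub_labels(state, len))
    states <- c(states, rep(state, len))
    state <- next_state(state)
  }
  if (length(ss8) > target_len) {
    # truncate the final segment; if the stub violates its minimum segment
    # length, relabel it as coil (minimum 1)
    keep <- seq_len(target_len)
    ss8 <- ss8[keep]
    states <- states[keep]
    last <- states[target_len]
    nz <- which(states != last)
    run <- (if (length(nz)) max(nz) + 1L else 1L):target_len  # trailing run of `last`
    if (length(run) < MIN_SEGMENT[[last]]) {
      states[run] <- "C"
      ss8[run] <- sample(COIL_SUBLABELS, length(run), replace = TRUE)
    }
  }
  aa <- colnames(config$aa_propensity)
  if (is.null(aa)) aa <- strsplit(AA_ALPHABET, "")[[1]]
  residues <- vapply(states, function(st)
    sample(aa, 1, prob = config$aa_propensity[st, ]), "")
  if (config$ss_noise_prob > 0) {
    noisy <- which(runif(target_len) < config$ss_noise_prob)
    if (length(noisy))
      ss8[noisy] <- sample(COIL_SUBLABELS, length(noisy), replace = TRUE)
  }
  data.frame(id = id, residues = paste(residues, collapse = ""),
             ss8 = paste(ss8, collapse = ""),
             ss3 = ss8_to_ss3(paste(ss8, collapse = "")),
             family_id = family_id, length = target_len,
             stringsAsFactors = FALSE)
}

#' Mutate a protein to a target sequence identity
#'
#' Point substitutions at uniformly random positions, the replacement drawn
#' from the local state's propensity row excluding the original residue; no
#' indels, so the child has its parent's length.  Each substituted position
#' flips its label to a coil sub-label with probability `ss_flip_prob`
#' (structure drifts slightly where sequence drifts).  After the initial
#' draw, substitutions are added or reverted until the realized identity
#' (per [pairwise_identity()]) is within the configured tolerance of the
#' target.
#'
#' @param parent One-row record (as from [sample_ancestor()]).
#' @param target_identity Fraction in (0, 1].
#' @param config A [universe_config()].
#' @param id Id for the child.
#' @param scoring [identity_scoring()] used when verifying the realized
#'   identity.
#' @return A one-row data frame like the parent's.
#' @export
mutate_homolog <- function(parent, target_identity, config, id = paste0(parent$id, "_m"),
                           scoring = identity_scoring()) {
  if (!is.numeric(target_identity) || target_identity <= 0 || target_identity > 1)
    stop("target_identity must lie in (0, 1]")
  validate_universe_config(config)
  res <- strsplit(parent$residues, "")[[1]]
  ss8 <- strsplit(parent$ss8, "")[[1]]
  ss3 <- strsplit(parent$ss3, "")[[1]]
  L <- length(res)
  aa <- colnames(config$aa_propensity)
  if (is.null(aa)) aa <- strsplit(AA_ALPHABET, "")[[1]]

  substitute_at <- function(res, ss8, pos) {
    for (i in pos) {
      row <- config$aa_propensity[ss3[i], ]
      keep <- aa != res[i]
      res[i] <- sample(aa[keep], 1, prob = row[keep])
      if (runif(1) < config$ss_flip_prob && !(ss8[i] %in% COIL_SUBLABELS))
        ss8[i] <- sample(COIL_SUBLABELS, 1)
    }
    list(res = res, ss8 = ss8)
  }

  k <- round((1 - target_identity) * L)
  touched <- if (k > 0) sample.int(L, k) else integer(0)
  out <- substitute_at(res, ss8, touched)
  tol <- config$substitution_identity_tolerance
  # realized identity can exceed the Hamming target when the aligner finds
  # extra gapped matches; add substitutions (at fresh positions) until back
  # inside the band
  for (iter in 1:25) {
    realized <- pairwise_identity(parent$residues,
                                  paste(out$res, collapse = ""), scoring)$identity
    if (realized <= target_identity + tol && realized >= target_identity - tol) break
    if (realized > target_identity + tol) {
      free <- setdiff(seq_len(L), touched)
      if (!length(free)) break
      extra <- sample(free, min(length(free), ceiling((realized - target_identity) * L / 2)))
      touched <- c(touched, extra)
      out <- substitute_at(out$res, out$ss8, extra)
    } else {
      # overshot low (rare): revert some substituted positions to the parent
      revert <- sample(touched, min(length(touched),
                                    ceiling((target_identity - realized) * L / 2)))
      out$res[revert] <- res[revert]
      out$ss8[revert] <- ss8[revert]
      touched <- setdiff(touched, revert)
    }
  }
  ss8_str <- paste(out$ss8, collapse = "")
  data.frame(id = id, residues = paste(out$res, collapse = ""),
             ss8 = ss8_str, ss3 = ss8_to_ss3(ss8_str),
             family_id = parent$family_id, length = L,
             stringsAsFactors = FALSE)
}

#' Generate the synthetic protein universe
#'
#' `n_families` ancestors, each expanded to `family_size` members at the
#' identities of `identity_ladder` (a target of 1 reproduces the ancestor
#' itself).  Deterministic given the configuration: the same config (and
#' seed) always yields a byte-identical universe, and the caller's RNG state
#' is left untouched.
#'
#' @param config A [universe_config()].
#' @return A [seq_dataset()] with role `"universe"`; records carry a
#'   `target_identity` column (identity target to the family ancestor).
#' @export
generate_universe <- function(config = universe_config()) {
  validate_universe_config(config)
  with_seed(config$seed, {
    fams <- lapply(seq_len(config$n_families), function(f) {
      fam_id <- sprintf("F%04d", f)
      fam_size <- config$family_sizes[f]
      anc <- sample_ancestor(config, id = sprintf("%s_m1", fam_id), family_id = fam_id)
      rows <- vector("list", fam_size)
      for (m in seq_len(fam_size)) {
        slot <- (m - 1L) %% length(config$identity_ladder) + 1L
        target <- config$identity_ladder[slot]
        r <- if (target >= 1) {
          a <- anc
          a$id <- sprintf("%s_m%d", fam_id, m)
          a
        } else {
          mutate_homolog(anc, target, config, id = sprintf("%s_m%d", fam_id, m))
        }
        r$target_identity <- target
        rows[[m]] <- r
      }
      do.call(rbind, rows)
    })
    seq_dataset(do.call(rbind, fams),
                name = sprintf("universe(seed=%d)", config$seed),
                role = "universe",
                provenance = sprintf(
                  "generate_universe: %d families (%d sequences), lengths %d-%d, seed %d",
                  config$n_families, sum(config$family_sizes),
                  config$length_range[1], config$length_range[2], config$seed))
  })
}
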