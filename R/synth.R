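HYDROPHOBIC <- c("I", "L", "V", "F", "A", "M")

hydrophobic_weights <- function(core = 0.78) {
  w <- setNames(rep((1 - core) / (20 - length(HYDROPHOBIC)), 20), AMINO_ACIDS)
  w[HYDROPHOBIC] <- core / length(HYDROPHOBIC)
  w
}

#' Specification of a synthetic domain-alignment fixture
#'
#' Defines everything the deterministic generators need: alignment shape,
#' planted SP/TM segments (alignment-column spans), residue composition
#' inside and outside planted spans, gap rate, the predictor battery and
#' its per-residue error rates, and the seed fixing all randomness.
#'
#' Defaults emulate a typical curated seed alignment audited by the
#' reference predictor battery: 30 sequences, 120 columns, one planted
#' 21-column transmembrane helix, 5 TM predictors and 2 SP predictors
#' with per-residue sensitivity 0.9 and false-positive rate 0.05, and a
#' 5 percent gap rate outside planted spans (planted spans are kept
#' gap-free so the planted signal is column-aligned).  The default depth
#' of 30 is chosen so the per-column binomial test has near-certain
#' rejection probability at the battery's sensitivity (at depth n the
#' test rejects at k >= k_min(n); P(Bin(30, 0.9) >= 20) ~ 0.9999,
#' whereas at depth 20 the rejection probability is only ~0.99 and a
#' planted column misses a predictor often enough to blur the fixture).
#'
#' @param n_sequences,n_columns alignment dimensions.
#' @param segments data.frame with `category` ("TM"/"SP"), `start`,
#'   `end` columns, or `NULL` for a background-only alignment.  SP spans
#'   must start at column 1.
#' @param gap_rate per-residue gap probability outside planted spans.
#' @param n_tm_predictors,n_sp_predictors predictor roster sizes.
#' @param sensitivity per-residue probability that a predictor calls a
#'   planted residue positive.
#' @param fp_rate per-residue probability of a positive call outside
#'   planted spans.
#' @param hydrophobic_core total composition weight on I/L/V/F/A/M inside
#'   planted spans.
#' @param seed integer seed fixing all randomness.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_sequences = 30L, n_columns = 120L,
                       segments = data.frame(category = "TM",
                                             start = 41L, end = 61L),
                       gap_rate = 0.05,
                       n_tm_predictors = 5L, n_sp_predictors = 2L,
                       sensitivity = 0.9, fp_rate = 0.05,
                       hydrophobic_core = 0.78, seed = 1L) {
  if (is.null(segments))
    segments <- data.frame(category = character(0),
                           start = integer(0), end = integer(0))
  segments$category <- validate_category(segments$category)
  stopifnot(n_sequences >= 1L, n_columns >= 1L,
            gap_rate >= 0, gap_rate < 1,
            sensitivity >= 0, sensitivity <= 1,
            fp_rate >= 0, fp_rate <= 1,
            abs(seed) < .Machine$integer.max)
  if (nrow(segments) > 0L) {
    if (any(segments$start < 1L) || any(segments$end > n_columns) ||
        any(segments$end < segments$start))
      stop("planted segment spans must lie within the alignment")
    if (any(segments$category == "SP" & segments$start != 1L))
      stop("planted SP spans must start at column 1 (N-terminal)")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 n_columns = as.integer(n_columns), segments = segments,
                 gap_rate = gap_rate,
                 n_tm_predictors = as.integer(n_tm_predictors),
                 n_sp_predictors = as.integer(n_sp_predictors),
                 sensitivity = sensitivity, fp_rate = fp_rate,
                 hydrophobic_core = hydrophobic_core,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

planted_columns <- function(spec, category = NULL) {
  seg <- spec$segments
  if (!is.null(category)) seg <- seg[seg$category == category, , drop = FALSE]
  if (nrow(seg) == 0L) return(integer(0))
  unique(unlist(mapply(seq, seg$start, seg$end, SIMPLIFY = FALSE)))
}

#' Generate a synthetic domain alignment with planted SP/TM blocks
#'
#' Columns inside planted spans are drawn from a hydrophobic-enriched
#' composition (I/L/V/F/A/M); all other columns from a uniform background
#' composition, with gaps inserted independently at the spec's gap rate.
#' Byte-identical on rerun with the same spec.
#'
#' @param spec a [synth_spec()].
#' @return An [msa] with rows `seq1..seqN`.
#' @export
make_alignment <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  wh <- hydrophobic_weights(spec$hydrophobic_core)
  planted <- planted_columns(spec)
  mat <- matrix("", spec$n_sequences, spec$n_columns)
  for (j in seq_len(spec$n_columns)) {
    w <- if (j %in% planted) wh else rep(1 / 20, 20)
    mat[, j] <- sample(AMINO_ACIDS, spec$n_sequences, replace = TRUE, prob = w)
    if (!(j %in% planted) && spec$gap_rate > 0) {
      gap <- runif(spec$n_sequences) < spec$gap_rate
      mat[gap, j] <- "-"
    }
  }
  msa(paste0("seq", seq_len(spec$n_sequences)),
      apply(mat, 1L, paste0, collapse = ""))
}

#' Generate predictor masks for a synthetic alignment
#'
#' For every predictor of the battery and every row, each residue whose
#' alignment column lies inside a planted span of the predictor's
#' category is called positive with probability `sensitivity`; every
#' other residue with probability `fp_rate`; calls are independent across
#' rows and predictors.  Uses a seed derived from the spec's, so
#' alignment and masks are jointly reproducible yet independent draws.
#'
#' @param m the [msa] generated from `spec` (or any alignment of the
#'   same row ids).
#' @param spec the [synth_spec()].
#' @return A [mask_set()] with predictors `tm1..tmD`, `sp1..spD`.
#' @export
make_masks <- function(m, spec) {
  stopifnot(inherits(m, "msa"), inherits(spec, "synth_spec"))
  set.seed(spec$seed + 1000003L)
  manifest <- data.frame(
    predictor_id = c(sprintf("tm%d", seq_len(spec$n_tm_predictors)),
                     sprintf("sp%d", seq_len(spec$n_sp_predictors))),
    category = c(rep("TM", spec$n_tm_predictors),
                 rep("SP", spec$n_sp_predictors)))
  planted <- list(TM = planted_columns(spec, "TM"),
                  SP = planted_columns(spec, "SP"))
  runs <- list()
  for (i in seq_along(m$ids)) {
    cols <- m$pos2col[[i]]
    for (p in seq_len(nrow(manifest))) {
      category <- manifest$category[p]
      inside <- cols %in% planted[[category]]
      prob <- ifelse(inside, spec$sensitivity, spec$fp_rate)
      calls <- as.integer(runif(length(cols)) < prob)
      r <- rle(calls)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- r$values == 1L
      if (any(keep))
        runs[[length(runs) + 1L]] <- data.frame(
          sequence_id = m$ids[i],
          predictor_id = manifest$predictor_id[p],
          category = category, start = starts[keep], end = ends[keep])
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(sequence_id = character(0), predictor_id = character(0),
               category = character(0), start = integer(0), end = integer(0))
  mask_set(runs, manifest, ungapped_lengths(m))
}

#' Specification of a synthetic profile-HMM fixture
#'
#' A two-block toy domain model emulating an SP/TM-contaminated family:
#' an N-terminal hydrophobic (flagged) block whose match states favour
#' I/L/V/F/A/M — alignable by composition alone — followed by an
#' information-rich globular block whose match states each favour one
#' specific residue.  Delete transitions are cheap, so an unrelated
#' query carrying only a hydrophobic run can traverse the globular block
#' as one long deletion at small cost, reproducing the mechanism by
#' which SP/TM matches alone lift false hits over the gathering
#' threshold.
#'
#' @param n_flagged,n_globular block lengths (model nodes).
#' @param GA gathering score threshold, bits; the default is a typical
#'   curated threshold low enough that a clean hydrophobic-block match
#'   can reach it.
#' @param n_members,n_decoys fixture sequence counts.
#' @param specificity match probability of the favoured residue in
#'   globular nodes.
#' @param hydrophobic_core composition weight on I/L/V/F/A/M in flagged
#'   nodes.
#' @param flank_length random null-composition residues added on both
#'   sides of member sequences and upstream of the decoy run.
#' @param decoy_tail residues left downstream of the decoy's hydrophobic
#'   run.  Decoys emulate unrelated proteins whose TM anchor sits near
#'   the C-terminus, so the model's globular block spans (almost) none of
#'   the query and is traversed as one long cheap deletion — the "single
#'   large gap with marginal influence on the total score" mechanism of
#'   hydrophobic false hits.
#' @param seed integer seed.
#' @return A list of class `profile_spec`.
#' @export
profile_spec <- function(n_flagged = 40L, n_globular = 40L, GA = 20,
                         n_members = 30L, n_decoys = 30L,
                         specificity = 0.6, hydrophobic_core = 0.78,
                         flank_length = 10L, decoy_tail = 2L, seed = 1L) {
  stopifnot(n_flagged >= 1L, n_globular >= 1L, n_members >= 1L,
            n_decoys >= 0L, specificity > 0.05, specificity <= 1,
            abs(seed) < .Machine$integer.max)
  structure(list(n_flagged = as.integer(n_flagged),
                 n_globular = as.integer(n_globular), GA = GA,
                 n_members = as.integer(n_members),
                 n_decoys = as.integer(n_decoys),
                 specificity = specificity,
                 hydrophobic_core = hydrophobic_core,
                 flank_length = as.integer(flank_length),
                 decoy_tail = as.integer(decoy_tail),
                 seed = as.integer(seed)),
            class = "profile_spec")
}

#' Generate a toy contaminated profile HMM with members and decoys
#'
#' Builds the model described by [profile_spec()], flags its hydrophobic
#' block in a [model_region_mask()], and samples member sequences (drawn
#' from the match emission distributions of both blocks) and decoy
#' sequences (a hydrophobic run matching only the flagged block, with
#' null-composition residues elsewhere).  Deterministic given the spec.
#'
#' @param pspec a [profile_spec()].
#' @return List with `hmm`, `mask`, `members`, `decoys` (named character
#'   vectors) and `pspec`.
#' @export
make_profile <- function(pspec) {
  stopifnot(inherits(pspec, "profile_spec"))
  set.seed(pspec$seed + 2000003L)
  M <- pspec$n_flagged + pspec$n_globular
  wh <- hydrophobic_weights(pspec$hydrophobic_core)
  null <- rep(1 / 20, 20)
  probs <- matrix(0, M, 20L, dimnames = list(NULL, AMINO_ACIDS))
  for (s in seq_len(pspec$n_flagged)) probs[s, ] <- wh
  # globular specificity lives on polar/charged positions, so a purely
  # hydrophobic run can never masquerade as the globular block
  favoured <- sample(setdiff(AMINO_ACIDS, HYDROPHOBIC),
                     pspec$n_globular, replace = TRUE)
  for (i in seq_len(pspec$n_globular)) {
    w <- setNames(rep((1 - pspec$specificity) / 19, 20), AMINO_ACIDS)
    w[favoured[i]] <- pspec$specificity
    probs[pspec$n_flagged + i, ] <- w
  }
  transitions <- matrix(rep(c(0, -2, -1, -1, -1, -1, -0.1, -Inf, -Inf),
                            each = M), nrow = M)
  colnames(transitions) <- TRANSITION_NAMES
  transitions[1L, "bm"] <- 0
  transitions[M, "me"] <- 0
  hmm <- profile_hmm(log2(probs / rep(null, each = M)),
                     transitions = transitions, GA = pspec$GA,
                     evd_mu = pspec$GA - 8, evd_lambda = 0.693,
                     null = null, name = "synthetic_contaminated")
  mask <- model_region_mask(M, ranges = data.frame(start = 1L,
                                                   end = pspec$n_flagged))
  draw <- function(p) sample(AMINO_ACIDS, 1L, prob = p)
  flank <- function(n) paste(sample(AMINO_ACIDS, n, replace = TRUE),
                             collapse = "")
  members <- vapply(seq_len(pspec$n_members), function(i) {
    core <- paste(apply(probs, 1L, draw), collapse = "")
    paste0(flank(pspec$flank_length), core, flank(pspec$flank_length))
  }, "")
  decoys <- vapply(seq_len(pspec$n_decoys), function(i) {
    run <- paste(sample(AMINO_ACIDS, pspec$n_flagged, replace = TRUE,
                        prob = wh), collapse = "")
    paste0(flank(pspec$flank_length), run, flank(pspec$decoy_tail))
  }, "")
  list(hmm = hmm,
       mask = mask,
       members = setNames(members, sprintf("member%d", seq_along(members))),
       decoys = setNames(decoys, sprintf("decoy%d",
                                         seq_len(pspec$n_decoys))),
       pspec = pspec)
}
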