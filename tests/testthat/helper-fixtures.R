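# Shared fixtures and independent reference implementations ("oracles").
# The oracles deliberately avoid the package's own code paths: they
# enumerate or sum directly, so agreement is evidence, not tautology.

toy_msa <- function() {
  msa(c("s1", "s2", "s3"),
      c("ACDEFGHIKL", "ACDEF-HIKL", "AC.EFGHIKL"))
}

# Build a mask_set straight from explicit 0/1 call vectors:
# calls[[sequence_id]][[predictor_id]]
masks_from_calls <- function(calls, categories, seq_lengths) {
  runs <- list()
  for (sid in names(calls))
    for (pid in names(calls[[sid]])) {
      r <- rle(calls[[sid]][[pid]])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values == 1L
      if (any(keep))
        runs[[length(runs) + 1L]] <- data.frame(
          sequence_id = sid, predictor_id = pid,
          category = categories[[pid]], start = starts[keep],
          end = ends[keep])
    }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(sequence_id = character(0), predictor_id = character(0),
               category = character(0), start = integer(0), end = integer(0))
  manifest <- data.frame(predictor_id = names(categories),
                         category = unlist(categories))
  mask_set(runs, manifest, seq_lengths)
}

# Perfect masks marking the given column span in every row, D predictors.
perfect_masks <- function(m, span, D = 5L, category = "TM",
                          prefix = tolower(category)) {
  categories <- setNames(as.list(rep(category, D)),
                         paste0(prefix, seq_len(D)))
  calls <- lapply(seq_along(m$ids), function(i) {
    cols <- m$pos2col[[i]]
    v <- as.integer(cols >= span[1] & cols <= span[2])
    lapply(categories, function(x) v)
  })
  names(calls) <- m$ids
  masks_from_calls(calls, categories, ungapped_lengths(m))
}

# Summation oracle for the binomial upper tail under p = 1/2.
tail_by_summation <- function(n, k) {
  if (n == 0) return(1)
  sum(choose(n, k:n)) / 2^n
}

# --- independent column-state reference for the consensus detector ----
# Recomputes, column by column and with explicit loops, the counts,
# binomial tails, positives and segment runs of one category.
reference_positive_columns <- function(m, ms, category,
                                       alpha = 0.05, epsilon = 1e-4) {
  preds <- ms$roster[[category]]
  ncol <- m$n_columns
  positive <- logical(ncol)
  L <- numeric(ncol)
  for (j in seq_len(ncol)) {
    lj <- 0
    rejected_any <- FALSE
    for (p in preds) {
      n <- 0L; k <- 0L
      for (i in seq_along(m$ids)) {
        ch <- substr(m$seqs[i], j, j)
        if (ch != "-") {
          n <- n + 1L
          pos <- sum(strsplit(substr(m$seqs[i], 1, j), "")[[1]] != "-")
          if (ms$calls[[m$ids[i]]][[p]][pos] == 1L) k <- k + 1L
        }
      }
      pv <- tail_by_summation(n, k)
      if (n > 0 && pv <= alpha) {
        rejected_any <- TRUE
        lj <- lj + log(max(k / n, epsilon))
      } else lj <- lj + log(epsilon)
    }
    L[j] <- lj
    positive[j] <- rejected_any
  }
  list(positive = positive, L = L)
}

# --- brute-force Viterbi oracle -------------------------------------
# Enumerates every legal single-traversal path (begin at any node with
# finite entry, end at any node with finite exit, match > insert/delete
# interleavings) and returns the maximal score.
brute_viterbi <- function(hmm, seq) {
  x <- domaudit:::encode_sequence(seq)
  L <- length(x)
  M <- hmm$M
  tr <- hmm$transitions
  me <- hmm$match_emit
  ie <- hmm$insert_emit
  best <- -Inf
  step <- function(state, s, t, sc) {
    if (!is.finite(sc)) return()
    if (state == "M") {
      cand <- sc + tr[s, "me"]
      if (cand > best) best <<- cand
      if (s < M) {
        if (t < L) step("M", s + 1L, t + 1L,
                        sc + tr[s, "mm"] + me[s + 1L, x[t + 1L]])
        step("D", s + 1L, t, sc + tr[s, "md"])
        if (t < L) step("I", s, t + 1L,
                        sc + tr[s, "mi"] + ie[s, x[t + 1L]])
      }
    } else if (state == "I") {
      if (t < L) {
        step("M", s + 1L, t + 1L, sc + tr[s, "im"] + me[s + 1L, x[t + 1L]])
        step("I", s, t + 1L, sc + tr[s, "ii"] + ie[s, x[t + 1L]])
      }
    } else {
      if (s < M) {
        if (t < L) step("M", s + 1L, t + 1L,
                        sc + tr[s, "dm"] + me[s + 1L, x[t + 1L]])
        step("D", s + 1L, t, sc + tr[s, "dd"])
      }
    }
  }
  for (t0 in seq_len(L))
    for (s0 in seq_len(M))
      if (is.finite(tr[s0, "bm"]))
        step("M", s0, t0, tr[s0, "bm"] + me[s0, x[t0]])
  unname(best)
}

# Compare the DP against the enumeration, including the degenerate case
# where no legal traversal exists (model longer than the query).
expect_viterbi_matches_oracle <- function(hmm, sq, info = NULL) {
  expected <- brute_viterbi(hmm, sq)
  if (!is.finite(expected)) {
    expect_error(viterbi_hmmls(hmm, sq), "no finite-scoring", info = info)
  } else {
    expect_equal(viterbi_hmmls(hmm, sq)$score, expected,
                 tolerance = 1e-12, info = info)
  }
}

# Random small profile for fuzzing; entry at node 1 and exit at node M
# always open, occasionally extra entries/exits.
random_hmm <- function(M, extra_ports = FALSE) {
  tr <- cbind(mm = runif(M, -1, 0), mi = runif(M, -3, -0.5),
              md = runif(M, -3, -0.5), im = runif(M, -2, 0),
              ii = runif(M, -2, 0), dm = runif(M, -2, 0),
              dd = runif(M, -2, 0), bm = rep(-Inf, M), me = rep(-Inf, M))
  tr[1, "bm"] <- 0
  tr[M, "me"] <- 0
  if (extra_ports && M > 1) {
    tr[sample(M, 1), "bm"] <- runif(1, -2, 0)
    tr[sample(M, 1), "me"] <- runif(1, -2, 0)
  }
  profile_hmm(matrix(rnorm(M * 20, 0, 1.5), M, 20),
              matrix(rnorm(M * 20, -0.3, 0.5), M, 20),
              tr, GA = 0, evd_mu = 0, evd_lambda = 0.5)
}

random_aa_string <- function(L) {
  paste(sample(c(domaudit:::AMINO_ACIDS, "X"), L, replace = TRUE,
               prob = c(rep(1, 20), 0.5)), collapse = "")
}
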