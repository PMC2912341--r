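PROFILE_ALPHABET <- c(AMINO_ACIDS, "X")
TRANSITION_NAMES <- c("mm", "mi", "md", "im", "ii", "dm", "dd", "bm", "me")

#' Construct a plan7-style profile HMM
#'
#' A minimal single-hit profile: M match nodes with match and insert
#' emission log-odds (bits, relative to the null model), per-node
#' transition log-odds, per-node begin-entry (`bm`) and end-exit (`me`)
#' scores, a gathering score `GA` and Gumbel (extreme value distribution)
#' parameters for E-values.  There is no multi-hit (J) state: each query
#' is scored for a single traversal of the model, global with respect to
#' the model and local with respect to the sequence.
#'
#' The unknown residue X scores 0 bits against every match and insert
#' state (neutral under the null).
#'
#' @param match_emit,insert_emit numeric matrices, `M x 20` (columns in
#'   the order ACDEFGHIKLMNPQRSTVWY) or `M x 21` including an X column;
#'   bits.  An X column of zeros is appended when absent.
#' @param transitions numeric `M x 9` matrix with columns `mm, mi, md,
#'   im, ii, dm, dd, bm, me`: transitions leaving node s (`mm` =
#'   M_s -> M_(s+1), ..., `dd` = D_s -> D_(s+1)), plus entry B -> M_s and
#'   exit M_s -> E.  `-Inf` forbids a transition.  When `NULL`, a default
#'   topology is built: free match-to-match chain, mild insert/delete
#'   penalties, entry only at node 1 and exit only at node M (global in
#'   the model).
#' @param GA gathering score threshold, bits.
#' @param evd_mu,evd_lambda Gumbel location and slope for [evalue()].
#' @param null background residue frequencies (informational; emission
#'   scores are already log-odds).
#' @param name model identifier.
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(match_emit, insert_emit = NULL, transitions = NULL,
                        GA = 0, evd_mu = 0, evd_lambda = 0.693,
                        null = rep(1 / 20, 20), name = "model") {
  match_emit <- pad_x(as.matrix(match_emit))
  M <- nrow(match_emit)
  if (M < 1L) stop("model must have at least one node")
  if (is.null(insert_emit))
    insert_emit <- matrix(0, nrow = M, ncol = 21L)
  insert_emit <- pad_x(as.matrix(insert_emit))
  if (nrow(insert_emit) != M) stop("insert_emit must have M rows")
  if (is.null(transitions)) {
    transitions <- matrix(rep(c(0, -2, -2, -1, -1, -1, -1, -Inf, -Inf),
                              each = M), nrow = M)
    transitions[1L, 8L] <- 0       # enter at node 1
    transitions[M, 9L] <- 0        # leave at node M
  }
  transitions <- as.matrix(transitions)
  if (!all(dim(transitions) == c(M, 9L)))
    stop("transitions must be an M x 9 matrix")
  colnames(transitions) <- TRANSITION_NAMES
  if (all(!is.finite(transitions[, "bm"])))
    stop("model has no begin entry (all bm = -Inf)")
  if (all(!is.finite(transitions[, "me"])))
    stop("model has no end exit (all me = -Inf)")
  if (!is.finite(GA)) stop("GA must be finite")
  evd_mu <- if (is.null(evd_mu) || is.na(evd_mu)) NA_real_ else
    as.numeric(evd_mu)
  evd_lambda <- if (is.null(evd_lambda) || is.na(evd_lambda)) NA_real_ else
    as.numeric(evd_lambda)
  if (!is.na(evd_lambda) && evd_lambda <= 0)
    stop("evd_lambda must be positive")
  structure(list(name = name, M = M, alphabet = PROFILE_ALPHABET,
                 match_emit = match_emit, insert_emit = insert_emit,
                 transitions = transitions, GA = GA,
                 evd_mu = evd_mu, evd_lambda = evd_lambda, null = null),
            class = "profile_hmm")
}

pad_x <- function(m) {
  if (ncol(m) == 20L) m <- cbind(m, 0)
  if (ncol(m) != 21L)
    stop("emission matrices need 20 (or 21, with X) columns")
  colnames(m) <- PROFILE_ALPHABET
  m
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM '", x$name, "': M = ", x$M, ", GA = ", x$GA,
      ", EVD(mu = ", x$evd_mu, ", lambda = ", x$evd_lambda, ")\n", sep = "")
  invisible(x)
}

#' Read a profile HMM
#'
#' Two formats: the package's native JSON profile (written by
#' [write_profile()]; lossless round-trip), and a best-effort subset of
#' the HMMER2 ASCII save-file format (header keys `LENG`, `GA`, `EVD`
#' plus the three per-node score lines; integer scores are converted to
#' bits by dividing by 1000, `*` denotes a forbidden transition).
#'
#' @param path file path.
#' @param format `"native-json"` or `"hmmer2"`.
#' @return A [profile_hmm()].
#' @export
read_profile <- function(path, format = c("native-json", "hmmer2")) {
  format <- match.arg(format)
  if (format == "native-json") {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    num <- function(m) {
      m <- as.matrix(m)
      m[m == "-Inf"] <- -Inf
      storage.mode(m) <- "double"
      m
    }
    return(profile_hmm(num(o$match_emit), num(o$insert_emit),
                       num(o$transitions), GA = o$GA,
                       evd_mu = o$evd_mu, evd_lambda = o$evd_lambda,
                       null = as.numeric(o$null), name = o$name))
  }
  read_hmmer2(path)
}

#' Write a profile HMM in the native JSON format
#' @param hmm a [profile_hmm()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  enc <- function(m) {
    m <- as.matrix(m)
    mode(m) <- "character"   # keep -Inf representable in JSON
    m
  }
  jsonlite::write_json(
    list(name = hmm$name, M = hmm$M,
         match_emit = enc(hmm$match_emit),
         insert_emit = enc(hmm$insert_emit),
         transitions = enc(hmm$transitions),
         GA = hmm$GA, evd_mu = hmm$evd_mu, evd_lambda = hmm$evd_lambda,
         null = hmm$null),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

read_hmmer2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  score1k <- function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    v[tok == "*"] <- -Inf
    if (any(is.na(v))) stop("unparseable score token(s): ",
                            paste(tok[is.na(v)], collapse = " "))
    v / 1000
  }
  kv <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    strsplit(trimws(hit[1L]), "[ \t]+")[[1L]][-1L]
  }
  leng <- as.integer(kv("LENG")[1L])
  if (is.na(leng)) stop("missing or malformed LENG header")
  ga <- suppressWarnings(as.numeric(kv("GA")[1L]))
  evd <- suppressWarnings(as.numeric(kv("EVD")))
  name <- kv("NAME")[1L]
  hmm_at <- grep("^HMM\\b", lines)
  if (length(hmm_at) == 0L) stop("no HMM score section found")
  body <- lines[(hmm_at[1L] + 2L):length(lines)]   # skip transition header
  match_emit <- matrix(0, leng, 20L)
  insert_emit <- matrix(0, leng, 20L)
  transitions <- matrix(-Inf, leng, 9L)
  node <- 0L
  i <- 1L
  while (i <= length(body) && node < leng) {
    tok <- strsplit(trimws(body[i]), "[ \t]+")[[1L]]
    if (length(tok) >= 21L &&
        !is.na(suppressWarnings(as.integer(tok[1L]))) &&
        as.integer(tok[1L]) == node + 1L) {
      node <- node + 1L
      match_emit[node, ] <- score1k(tok[2L:21L])
      itok <- strsplit(trimws(body[i + 1L]), "[ \t]+")[[1L]]
      if (length(itok) < 20L)
        stop("malformed insert line at node ", node,
             " (line ", hmm_at[1L] + 2L + i, ")")
      insert_emit[node, ] <- score1k(itok[1L:20L])
      ttok <- strsplit(trimws(body[i + 2L]), "[ \t]+")[[1L]]
      if (length(ttok) < 9L)
        stop("malformed transition line at node ", node,
             " (line ", hmm_at[1L] + 3L + i, ")")
      transitions[node, ] <- score1k(ttok[1L:9L])
      i <- i + 3L
    } else i <- i + 1L
  }
  if (node != leng)
    stop("expected ", leng, " node blocks, found ", node)
  profile_hmm(match_emit, insert_emit, transitions,
              GA = if (is.na(ga)) 0 else ga,
              evd_mu = if (length(evd) >= 1L) evd[1L] else NA_real_,
              evd_lambda = if (length(evd) >= 2L) evd[2L] else NA_real_,
              name = if (is.na(name) || is.null(name)) "model" else name)
}

encode_sequence <- function(seq) {
  if (length(seq) == 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1L]]
  seq <- toupper(seq)
  seq[seq %in% c("B", "Z", "U", "O")] <- "X"
  idx <- match(seq, PROFILE_ALPHABET)
  idx[is.na(idx)] <- 21L   # anything else scored as X
  idx
}

#' Viterbi alignment, global in the model and local in the sequence
#'
#' Finds the highest-scoring single traversal of the model (entering at a
#' node with finite begin score, leaving at a node with finite end score;
#' with the default topology, node 1 to node M) placed anywhere within
#' the query: flanking residues outside the matched span are emitted by
#' the null model and cost 0 bits.  Ties are broken deterministically:
#' predecessor preference match > delete > insert, and among equal-scoring
#' end cells the earliest sequence position, then the earliest node, wins.
#'
#' @param hmm a [profile_hmm()].
#' @param seq query: a single string or character vector of residues
#'   (B/Z/U/O and unknown letters are scored as X).
#' @return A `viterbi_alignment`: list with `score` (bits), `path`
#'   (data.frame `state` in M/I/D, `node`, `pos`; `pos` is `NA` for
#'   delete states), `model_span`, `seq_span`.
#' @export
viterbi_hmmls <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  x <- encode_sequence(seq)
  L <- length(x)
  if (L < 1L) stop("empty query sequence")
  M <- hmm$M
  tr <- hmm$transitions
  NEG <- -Inf
  VM <- matrix(NEG, M, L); VI <- matrix(NEG, M, L); VD <- matrix(NEG, M, L)
  PM <- matrix(0L, M, L); PI <- matrix(0L, M, L); PD <- matrix(0L, M, L)
  # predecessor codes: 0 = begin, 1 = match, 2 = delete, 3 = insert
  for (t in seq_len(L)) {
    for (s in seq_len(M)) {
      best <- tr[s, "bm"]; who <- 0L
      if (s > 1L && t > 1L) {
        cand <- c(VM[s - 1L, t - 1L] + tr[s - 1L, "mm"],
                  VD[s - 1L, t - 1L] + tr[s - 1L, "dm"],
                  VI[s - 1L, t - 1L] + tr[s - 1L, "im"])
        for (w in 1:3) if (cand[w] > best) { best <- cand[w]; who <- w }
      }
      VM[s, t] <- hmm$match_emit[s, x[t]] + best
      PM[s, t] <- who
      if (t > 1L) {
        ci <- c(VM[s, t - 1L] + tr[s, "mi"], VI[s, t - 1L] + tr[s, "ii"])
        if (ci[1L] >= ci[2L]) { VI[s, t] <- ci[1L]; PI[s, t] <- 1L }
        else { VI[s, t] <- ci[2L]; PI[s, t] <- 3L }
        VI[s, t] <- VI[s, t] + hmm$insert_emit[s, x[t]]
      }
      if (s > 1L) {
        cd <- c(VM[s - 1L, t] + tr[s - 1L, "md"], VD[s - 1L, t] + tr[s - 1L, "dd"])
        if (cd[1L] >= cd[2L]) { VD[s, t] <- cd[1L]; PD[s, t] <- 1L }
        else { VD[s, t] <- cd[2L]; PD[s, t] <- 2L }
      }
    }
  }
  end_scores <- VM + tr[, "me"]
  best <- -Inf; bs <- NA_integer_; bt <- NA_integer_
  for (t in seq_len(L)) for (s in seq_len(M))
    if (end_scores[s, t] > best) { best <- end_scores[s, t]; bs <- s; bt <- t }
  if (!is.finite(best))
    stop("no finite-scoring traversal of the model exists for this query")
  # traceback
  path <- list()
  s <- bs; t <- bt; st <- "M"
  repeat {
    path[[length(path) + 1L]] <-
      list(state = st, node = s, pos = if (st == "D") NA_integer_ else t)
    if (st == "M") {
      w <- PM[s, t]
      if (w == 0L) break
      st <- c("M", "D", "I")[w]; s <- s - 1L; t <- t - 1L
    } else if (st == "I") {
      w <- PI[s, t]
      st <- if (w == 1L) "M" else "I"
      t <- t - 1L
    } else {                        # D
      w <- PD[s, t]
      st <- if (w == 1L) "M" else "D"
      s <- s - 1L
    }
  }
  path <- do.call(rbind, lapply(rev(path), as.data.frame))
  structure(
    list(score = best, path = path,
         model_span = c(path$node[1L], path$node[nrow(path)]),
         seq_span = c(min(path$pos, na.rm = TRUE),
                      max(path$pos, na.rm = TRUE)),
         residues = x),
    class = "viterbi_alignment")
}

#' @export
print.viterbi_alignment <- function(x, ...) {
  cat(sprintf("Viterbi hit: %.3f bits; model %d-%d; sequence %d-%d; path %d states\n",
              x$score, x$model_span[1L], x$model_span[2L],
              x$seq_span[1L], x$seq_span[2L], nrow(x$path)))
  invisible(x)
}

#' Gumbel E-value of a bit score
#'
#' Expected number of hits at least this good in a database of `N`
#' sequences under the model's extreme value distribution:
#' `E = N * (1 - exp(-exp(-lambda * (score - mu))))`, clamped to `[0, N]`.
#'
#' @param score_bits bit score (vectorised).
#' @param N database size (number of sequences).
#' @param mu,lambda Gumbel location and slope (`lambda > 0`).
#' @return E-value(s).
#' @export
evalue <- function(score_bits, N, mu, lambda) {
  if (is.na(lambda) || lambda <= 0) stop("lambda must be positive")
  if (N < 1) stop("database size must be >= 1")
  p <- -expm1(-exp(-lambda * (score_bits - mu)))
  pmin(pmax(N * p, 0), N)
}
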