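#' Per-residue SP/TM prediction masks from multiple predictors
#'
#' The canonical input of the consensus detector: for each (sequence,
#' predictor) pair, a binary vector with one call per ungapped residue.
#' Third-party predictor scores are deliberately not modelled; only the
#' positive/negative call per residue enters the statistics, each call
#' being a Bernoulli indicator.
#'
#' @param runs data.frame with columns `sequence_id`, `predictor_id`,
#'   `category` (`"TM"` or `"SP"`), `start`, `end` (1-based inclusive
#'   residue coordinates of a positive run).  Overlapping runs of the same
#'   mask are merged.  A registered pair with no runs is an all-zero mask.
#' @param manifest data.frame with columns `predictor_id`, `category`:
#'   the predictor roster.  Every sequence is assumed audited by every
#'   registered predictor of each category.
#' @param seq_lengths named integer vector of ungapped sequence lengths
#'   (e.g. [ungapped_lengths()] of the alignment the masks belong to).
#' @param full_length logical; if `TRUE`, sequences are declared
#'   full-length and SP masks are checked to consist of a single
#'   N-terminal run starting at residue 1.  The default `FALSE` treats
#'   rows as domain fragments, where the true N-terminus may be missing
#'   upstream of the fragment, so an SP run may begin anywhere.
#' @return A `mask_set` object: list with `calls` (nested list
#'   `[[sequence_id]][[predictor_id]]` of 0/1 integer vectors), `roster`
#'   (list `TM`/`SP` of predictor ids), `n_predictors` (named vector,
#'   `D_TM` and `D_SP`), `seq_lengths`, `category` of each predictor.
#' @export
mask_set <- function(runs, manifest, seq_lengths, full_length = FALSE) {
  manifest$category <- validate_category(manifest$category)
  if (anyDuplicated(manifest$predictor_id))
    stop("duplicate predictor_id in manifest")
  roster <- split(as.character(manifest$predictor_id), manifest$category)
  roster <- lapply(roster, unname)
  for (cat in c("TM", "SP")) if (is.null(roster[[cat]])) roster[[cat]] <- character(0)
  if (is.null(names(seq_lengths)) || anyDuplicated(names(seq_lengths)))
    stop("seq_lengths must be uniquely named")
  predcat <- setNames(as.character(manifest$category),
                      as.character(manifest$predictor_id))

  calls <- lapply(seq_lengths, function(L) {
    lapply(setNames(nm = names(predcat)), function(p) integer(L))
  })

  if (nrow(runs) > 0) {
    runs$category <- validate_category(runs$category)
    for (r in seq_len(nrow(runs))) {
      sid <- as.character(runs$sequence_id[r])
      pid <- as.character(runs$predictor_id[r])
      s <- runs$start[r]; e <- runs$end[r]
      if (!sid %in% names(seq_lengths))
        stop("mask run for unknown sequence '", sid, "'")
      if (!pid %in% names(predcat))
        stop("mask run for predictor '", pid, "' not in manifest")
      if (predcat[[pid]] != runs$category[r])
        stop("predictor '", pid, "' registered as ", predcat[[pid]],
             " but run declared ", runs$category[r])
      L <- seq_lengths[[sid]]
      if (is.na(s) || is.na(e) || s < 1 || e < s)
        stop("invalid run coordinates [", s, ", ", e, "] for (",
             sid, ", ", pid, "): 1-based, start <= end required")
      if (e > L)
        stop("run end ", e, " exceeds length ", L, " of sequence '", sid, "'")
      calls[[sid]][[pid]][s:e] <- 1L
    }
  }

  if (full_length) {
    for (sid in names(calls))
      for (pid in roster$SP) {
        v <- calls[[sid]][[pid]]
        ones <- which(v == 1L)
        if (length(ones) &&
            !(ones[1L] == 1L && all(diff(ones) == 1L)))
          stop("full-length SP mask (", sid, ", ", pid,
               ") must be a single N-terminal run starting at residue 1")
      }
  }

  structure(
    list(calls = calls, roster = roster,
         n_predictors = c(TM = length(roster$TM), SP = length(roster$SP)),
         seq_lengths = seq_lengths, predictor_category = predcat,
         full_length = full_length),
    class = "mask_set")
}

validate_category <- function(x) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), c("TM", "SP"))
  if (length(bad))
    stop("unknown category token(s): ", paste(bad, collapse = ", "),
         " (expected TM or SP)")
  x
}

#' @export
print.mask_set <- function(x, ...) {
  cat("Prediction mask set: ", length(x$calls), " sequences; predictors: TM = {",
      paste(x$roster$TM, collapse = ", "), "}, SP = {",
      paste(x$roster$SP, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Read prediction masks from a run-list TSV and a manifest TSV
#'
#' The run list has header columns `sequence_id`, `predictor_id`,
#' `category`, `start`, `end`; the manifest has `predictor_id`,
#' `category`.  See [mask_set()] for semantics.
#'
#' @param runs_path path to the tab-separated run list (may have 0 rows).
#' @param manifest_path path to the predictor roster TSV.
#' @inheritParams mask_set
#' @return A `mask_set`.
#' @export
read_masks <- function(runs_path, manifest_path, seq_lengths,
                       full_length = FALSE) {
  runs <- read.delim(runs_path, stringsAsFactors = FALSE)
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "predictor_id", "category", "start", "end")
  if (!all(need %in% names(runs)))
    stop("run list must have columns: ", paste(need, collapse = ", "))
  mask_set(runs, manifest, seq_lengths, full_length = full_length)
}

#' Write a mask set as a run-list TSV
#' @param ms a `mask_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_masks <- function(ms, path) {
  stopifnot(inherits(ms, "mask_set"))
  rows <- list()
  for (sid in names(ms$calls))
    for (pid in names(ms$calls[[sid]])) {
      v <- ms$calls[[sid]][[pid]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values == 1L
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = sid, predictor_id = pid,
          category = ms$predictor_category[[pid]],
          start = starts[keep], end = ends[keep])
    }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = character(0), predictor_id = character(0),
               category = character(0), start = integer(0), end = integer(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Project per-residue predictor calls onto alignment columns
#'
#' For every column j and every predictor d of the requested category,
#' counts the column depth n_j (non-gap residues) and the number k_dj of
#' rows whose residue at column j is both present (non-gap) and called
#' positive by predictor d.  These are the binomial counts of the
#' per-column consensus test.
#'
#' @param m an [msa].
#' @param ms a [mask_set()]; every row of `m` must have a mask for every
#'   registered predictor of `category` (a missing mask is an error, not
#'   an implicit zero).
#' @param category `"TM"` or `"SP"`.
#' @return List with `n` (integer vector of column depths, length
#'   `n_columns`) and `k` (integer matrix, predictors x columns, rownames
#'   the predictor ids).
#' @export
project_to_columns <- function(m, ms, category = c("TM", "SP")) {
  stopifnot(inherits(m, "msa"), inherits(ms, "mask_set"))
  category <- match.arg(category)
  preds <- ms$roster[[category]]
  if (length(preds) == 0L)
    stop("no predictors registered for category ", category)
  nongap <- m$mat != "-"
  n <- colSums(nongap)
  k <- matrix(0L, nrow = length(preds), ncol = m$n_columns,
              dimnames = list(preds, NULL))
  for (i in seq_along(m$ids)) {
    sid <- m$ids[i]
    if (!sid %in% names(ms$calls))
      stop("no masks for alignment row '", sid, "'")
    cols <- m$pos2col[[i]]           # columns holding residues 1..L
    L <- length(cols)
    for (p in preds) {
      v <- ms$calls[[sid]][[p]]
      if (is.null(v))
        stop("missing mask for (", sid, ", ", p, ")")
      if (length(v) != L)
        stop("mask length ", length(v), " for (", sid, ", ", p,
             ") does not match ungapped length ", L)
      pos <- which(v == 1L)
      if (length(pos)) k[p, cols[pos]] <- k[p, cols[pos]] + 1L
    }
  }
  list(n = as.integer(n), k = k, category = category)
}
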