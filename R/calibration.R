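#' False-positive / false-negative rate table over score cutoffs
#'
#' Given segment scores for a labelled negative set (e.g. structural
#' helices, where any retained prediction is false) and a labelled
#' positive set (genuine membrane helices or signal peptides), tabulates
#' for each candidate cutoff the number and percentage of negatives
#' retained (false positives, `score >= cutoff`, ties counted as FP to
#' match the retention rule) and positives discarded (false negatives,
#' `score < cutoff`).
#'
#' @param neg_scores,pos_scores numeric score vectors, both non-empty.
#' @param cutoffs candidate cutoffs (any order; reported descending).
#' @return data.frame of class `rate_table` with columns `cutoff`, `n_fp`,
#'   `fp_rate`, `n_fn`, `fn_rate` (percentages rounded to 2 decimals) and
#'   attributes `n_neg_total`, `n_pos_total`.
#' @export
rate_table <- function(neg_scores, pos_scores, cutoffs) {
  if (length(neg_scores) == 0L || length(pos_scores) == 0L)
    stop("both score sets must be non-empty")
  if (length(cutoffs) == 0L) stop("no cutoffs supplied")
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  n_fp <- vapply(cutoffs, function(c) sum(neg_scores >= c), 0L)
  n_fn <- vapply(cutoffs, function(c) sum(pos_scores < c), 0L)
  out <- data.frame(
    cutoff = cutoffs, n_fp = n_fp,
    fp_rate = round(100 * n_fp / length(neg_scores), 2L),
    n_fn = n_fn,
    fn_rate = round(100 * n_fn / length(pos_scores), 2L))
  attr(out, "n_neg_total") <- length(neg_scores)
  attr(out, "n_pos_total") <- length(pos_scores)
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Select the most permissive cutoff meeting a false-positive target
#'
#' Returns the lowest cutoff in the table whose false-positive rate is
#' strictly below `max_fp_rate` (percent).  Lower cutoffs retain more
#' segments, so this is the most sensitive setting still meeting the
#' error target.
#'
#' @param table a [rate_table()].
#' @param max_fp_rate maximal tolerated FP rate, percent.
#' @return The selected cutoff (a single number).
#' @export
select_cutoff <- function(table, max_fp_rate = 5) {
  stopifnot(inherits(table, "rate_table"), nrow(table) > 0L)
  ok <- table$fp_rate < max_fp_rate
  if (!any(ok))
    stop("no cutoff attains a false-positive rate below ", max_fp_rate, "%")
  min(table$cutoff[ok])
}

#' Segment scores for a single sequence (no alignment available)
#'
#' The degenerate depth-1 path used to benchmark cutoffs on sequence
#' databases: with a single sequence the binomial consensus test has no
#' power, so it is bypassed and the column probability is taken directly
#' as the predictor's binary call floored at `epsilon`.  Everything
#' downstream (delineation, TM fragment bridging, SP span rule, scoring,
#' cutoffs) is identical to the alignment path.
#'
#' @param calls matrix of 0/1 calls, predictors x residues (a list of
#'   equal-length vectors is accepted), all of one category.
#' @param category `"TM"` or `"SP"`.
#' @param config an [audit_config()].
#' @return List of `detected_segment`s with scores and retention flags;
#'   empty when nothing is called.
#' @export
single_sequence_scores <- function(calls, category = c("TM", "SP"),
                                   config = audit_config()) {
  category <- match.arg(category)
  if (is.list(calls)) calls <- do.call(rbind, calls)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (any(is.na(calls)) || any(!calls %in% c(0L, 1L)))
    stop("calls must be 0/1")
  p_hat <- pmax(calls, config$epsilon)
  L <- colSums(log(p_hat))
  positive <- apply(calls == 1L, 2L, any)
  raw <- runs_of(positive)
  if (nrow(raw) == 0L) return(list())
  segs <- if (category == "TM") {
    proj <- list(n = rep(1L, ncol(calls)), k = calls, category = "TM")
    lapply(merge_tm_fragments(raw, proj), function(g)
      new_segment("TM", g$start, g$end, g$fragments, L))
  } else {
    list(sp_segment_span(raw, L))
  }
  apply_cutoffs(segs, config$tm_cutoff, config$sp_cutoff)
}

#' Project expected annotation error over a domain library census
#'
#' Given the census of a domain library audit (total domains, domains
#' flagged with TM or SP content, total retained TM helices) and the
#' calibrated false-positive rates of the segment cutoffs, computes the
#' derived quantities used to summarise library-scale contamination: the
#' fraction of problematic domains, the mean number of TM helices per
#' flagged domain, and the expected numbers of wrongly flagged helices
#' and domains implied by the FP rates.
#'
#' @param n_domains total domains in the library.
#' @param n_problematic domains flagged with any retained SP/TM segment.
#' @param n_tm_domains,n_sp_domains domains with retained TM / SP content.
#' @param n_tm_helices total retained TM helices across the library.
#' @param tm_fp_rate,sp_fp_rate calibrated FP rates of the cutoffs used,
#'   in percent.
#' @return List with `pct_problematic`, `pct_tm_domains`,
#'   `pct_sp_domains`, `tm_helices_per_domain`,
#'   `expected_fp_helices_per_domain`, `expected_wrong_tm_domains`,
#'   `expected_wrong_sp_domains`.
#' @export
library_error_projection <- function(n_domains, n_problematic,
                                     n_tm_domains, n_sp_domains,
                                     n_tm_helices,
                                     tm_fp_rate, sp_fp_rate) {
  stopifnot(n_domains > 0, n_tm_domains >= 0, n_sp_domains >= 0)
  helices_per <- if (n_tm_domains > 0) n_tm_helices / n_tm_domains else NA_real_
  list(
    pct_problematic = 100 * n_problematic / n_domains,
    pct_tm_domains = 100 * n_tm_domains / n_domains,
    pct_sp_domains = 100 * n_sp_domains / n_domains,
    tm_helices_per_domain = helices_per,
    expected_fp_helices_per_domain = tm_fp_rate / 100 * helices_per,
    expected_wrong_tm_domains = tm_fp_rate / 100 * n_tm_domains,
    expected_wrong_sp_domains = sp_fp_rate / 100 * n_sp_domains)
}
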