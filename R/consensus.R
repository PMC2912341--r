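#' Exact one-sided binomial tail probability under the fair-coin null
#'
#' The type I error of calling an alignment column an SP/TM residue: the
#' probability P(K >= k) for K ~ Binomial(n, 1/2), where n is the column
#' depth (non-gap sequences) and k the number of positive predictor
#' calls.  Under this null every predictor call is an unbiased coin, so
#' small tails indicate genuine consensus.  Returns 1 when `n = 0`.
#'
#' @param n column depth (number of non-gap residues), vectorised.
#' @param k number of positive calls, `0 <= k <= n`, vectorised.
#' @return Numeric tail probabilities in `[0, 1]`.
#' @examples
#' binomial_tail(5, 5)   # 1/32
#' binomial_tail(10, 9)  # 11/1024
#' @export
binomial_tail <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  if (any(is.na(n) | is.na(k)) || any(n < 0) || any(k < 0) || any(k > n))
    stop("require 0 <= k <= n")
  ifelse(n == 0, 1, pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

#' Per-column consensus hypothesis test
#'
#' Rejects the fair-coin null when the exact binomial tail is at most
#' `alpha`.  On rejection the expected number of positive predictions for
#' the column is estimated by the observed count `k`; otherwise it is set
#' to zero.  Because the smallest attainable tail is `(1/2)^n`, no column
#' of an alignment with 4 or fewer sequences can ever be rejected at
#' `alpha = 0.05`: the test requires alignments of 5 sequences or more.
#'
#' @inheritParams binomial_tail
#' @param alpha significance level in (0, 1).
#' @return List with `rejected` (logical) and `E_hat` (numeric), vectorised.
#' @export
column_test <- function(n, k, alpha = 0.05) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  p <- binomial_tail(n, k)
  rejected <- p <= alpha
  list(rejected = rejected, E_hat = ifelse(rejected, as.numeric(k), 0))
}

#' Estimated column probability with a logarithm floor
#'
#' The probability that the column represents a residue of a true SP/TM
#' segment, estimated as `E_hat / n` and floored at `epsilon` so that
#' downstream logarithms stay finite.
#'
#' @param E_hat expected positive predictions (0 when the null stands).
#' @param n column depth, `n >= 1`.
#' @param epsilon floor in (0, 1).
#' @return `p_hat` in `[epsilon, 1]`, vectorised.
#' @export
column_probability <- function(E_hat, n, epsilon = 1e-4) {
  if (any(n < 1)) stop("column probability undefined for empty columns (n = 0)")
  pmax(E_hat / n, epsilon)
}

#' Total log probability of a column over all predictors
#'
#' Sum of natural logarithms of the per-predictor column probabilities;
#' lies in `[D * log(epsilon), 0]` for `D` predictors.
#'
#' @param p_hat numeric vector of per-predictor column probabilities.
#' @return A single number `L_j <= 0`.
#' @export
column_log_probability <- function(p_hat) {
  if (length(p_hat) == 0L) stop("empty predictor set")
  sum(log(p_hat))
}

#' Per-column consensus statistics for one category
#'
#' Runs the binomial test for every (column, predictor) pair of a
#' projection and assembles the column log probabilities and the positive
#' indicator.  A column is positive when at least one predictor's null
#' hypothesis is rejected there; all-gap columns are never positive.
#'
#' @param proj output of [project_to_columns()].
#' @param alpha significance level of the per-column test.
#' @param epsilon probability floor of [column_probability()].
#' @return List of class `column_stats`: `n`, `k`, `p_value`, `rejected`,
#'   `E_hat`, `p_hat` (predictor x column matrices), `L` (numeric vector),
#'   `positive` (logical vector), `category`, `D`.
#' @export
column_stats <- function(proj, alpha = 0.05, epsilon = 1e-4) {
  k <- proj$k
  D <- nrow(k)
  nmat <- matrix(proj$n, nrow = D, ncol = length(proj$n), byrow = TRUE)
  p_value <- matrix(binomial_tail(nmat, k), nrow = D,
                    dimnames = dimnames(k))
  rejected <- p_value <= alpha
  E_hat <- ifelse(rejected, k, 0)
  p_hat <- matrix(epsilon, nrow = D, ncol = ncol(k), dimnames = dimnames(k))
  ok <- nmat >= 1
  p_hat[ok] <- pmax(E_hat[ok] / nmat[ok], epsilon)
  L <- colSums(log(p_hat))
  positive <- apply(rejected, 2L, any) & proj$n > 0
  structure(list(n = proj$n, k = k, p_value = p_value, rejected = rejected,
                 E_hat = E_hat, p_hat = p_hat, L = L, positive = positive,
                 category = proj$category, D = D,
                 alpha = alpha, epsilon = epsilon),
            class = "column_stats")
}

#' Maximal runs of positive columns
#'
#' A contiguous run of positive columns is a raw predicted TM (or SP)
#' segment.
#'
#' @param positive logical vector over columns (or a `column_stats`
#'   object, whose `positive` element is used).
#' @return data.frame with `start`, `end` (1-based inclusive columns);
#'   zero rows when nothing is positive.
#' @export
delineate_segments <- function(positive) {
  if (inherits(positive, "column_stats")) positive <- positive$positive
  runs_of(positive)
}

runs_of <- function(x) {
  x <- as.logical(x)
  if (length(x) == 0L || !any(x))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Bridge TM segments fragmented by alignment gaps
#'
#' Small alignment gaps can split one transmembrane helix into several
#' raw segments.  The raw per-predictor calls arbitrate which fragments
#' belong together: per predictor a union indicator marks columns where
#' any sequence carries a positive call, and a composite indicator keeps
#' only columns on which all predictors active in that covered block
#' agree.  The union preserves continuity within a helix; the
#' intersection maintains separation between helices.  Two raw segments
#' overlapping the same composite run are united into one segment whose
#' fragment list is kept for weighted scoring.
#'
#' @param raw data.frame of raw segments from [delineate_segments()].
#' @param proj the [project_to_columns()] result the raw segments came
#'   from (TM category).
#' @return List of segments, each a list with `start`, `end` and
#'   `fragments` (data.frame of the member raw runs).
#' @export
merge_tm_fragments <- function(raw, proj) {
  n_col <- length(proj$n)
  if (nrow(raw) == 0L) return(list())
  I_u <- proj$k >= 1L                     # predictor x column union indicator
  any_u <- apply(I_u, 2L, any)
  blocks <- runs_of(any_u)
  I_c <- rep(FALSE, n_col)
  for (b in seq_len(nrow(blocks))) {
    cols <- blocks$start[b]:blocks$end[b]
    active <- which(rowSums(I_u[, cols, drop = FALSE]) > 0L)
    I_c[cols] <- colSums(!I_u[active, cols, drop = FALSE]) == 0L
  }
  cruns <- runs_of(I_c)
  # group raw segments by the composite run they overlap (if any)
  group <- integer(nrow(raw))
  for (s in seq_len(nrow(raw))) {
    hit <- which(cruns$start <= raw$end[s] & cruns$end >= raw$start[s])
    group[s] <- if (length(hit)) hit[1L] else -s   # unmatched stay alone
  }
  lapply(unname(split(seq_len(nrow(raw)), group)), function(idx) {
    frs <- raw[idx, , drop = FALSE]
    frs <- frs[order(frs$start), , drop = FALSE]
    rownames(frs) <- NULL
    list(start = min(frs$start), end = max(frs$end), fragments = frs)
  })
}

#' Average log probability of a detected segment
#'
#' For a single fragment the score is the arithmetic mean of the column
#' log probabilities over its predicted columns.  For a fragment-merged
#' segment it is the weighted average of the fragment means, each weighted
#' by its predicted-column count — equivalently the mean over the union of
#' predicted columns (restored linker columns between fragments do not
#' contribute).
#'
#' @param fragments data.frame with `start`, `end` of predicted runs.
#' @param L numeric vector of column log probabilities for the whole
#'   alignment.
#' @return The segment score, a number `<= 0`.
#' @export
score_segment <- function(fragments, L) {
  cols <- unlist(mapply(seq, fragments$start, fragments$end,
                        SIMPLIFY = FALSE))
  cols <- unique(cols)
  if (length(cols) == 0L) stop("segment has zero predicted columns")
  mean(L[cols])
}

new_segment <- function(category, start, end, fragments, L,
                        score = NULL, span_score = FALSE) {
  n_pred <- sum(fragments$end - fragments$start + 1L)
  if (is.null(score))
    score <- if (span_score) mean(L[start:end]) else score_segment(fragments, L)
  structure(list(category = category, start_col = start, end_col = end,
                 fragments = fragments, n_pred_columns = n_pred,
                 score = score, retained = NA),
            class = "detected_segment")
}

#' @export
print.detected_segment <- function(x, ...) {
  cat(sprintf("%s segment %d-%d (%d fragment%s, %d predicted columns), psi = %.3f%s\n",
              x$category, x$start_col, x$end_col, nrow(x$fragments),
              if (nrow(x$fragments) == 1L) "" else "s", x$n_pred_columns,
              x$score,
              if (is.na(x$retained)) "" else if (x$retained) ", retained"
              else ", discarded"))
  invisible(x)
}

#' Collapse raw signal-peptide segments to the N-terminal span
#'
#' Fragmented SP predictions are assumed to come from a single signal
#' peptide, so one segment is reported spanning column 1 through the
#' C-terminal boundary of the most C-terminal fragment, scored by the
#' plain mean of the column log probabilities over that whole span.
#'
#' @param raw data.frame of raw SP segments (>= 1 row).
#' @param L column log probabilities.
#' @return A single `detected_segment` of category `"SP"`.
#' @export
sp_segment_span <- function(raw, L) {
  if (nrow(raw) == 0L) stop("no raw SP segments to span")
  new_segment("SP", 1L, max(raw$end), raw[order(raw$start), , drop = FALSE],
              L, span_score = TRUE)
}

#' Concatenate nearby TM helices into TM regions
#'
#' Adjacent retained TM helices separated by fewer than `linker_max`
#' alignment columns are concatenated into one TM region, on the grounds
#' that the smallest known globular domains exceed 40 residues, so
#' shorter inter-helix stretches are mere linkers.  A gap of exactly
#' `linker_max` keeps the helices in separate regions.
#'
#' @param segments list of retained TM `detected_segment`s, ordered by
#'   start column.
#' @param linker_max strict upper bound (in columns) for a linker.
#' @return List of regions, each a list with `start`, `end`, `helices`
#'   (indices into `segments`).
#' @export
concatenate_tm_regions <- function(segments, linker_max = 40) {
  if (length(segments) == 0L) return(list())
  ord <- order(vapply(segments, `[[`, 0L, "start_col"))
  segments <- segments[ord]
  regions <- list()
  cur <- list(start = segments[[1L]]$start_col, end = segments[[1L]]$end_col,
              helices = ord[1L])
  for (i in seq_along(segments)[-1L]) {
    gap <- segments[[i]]$start_col - cur$end - 1L
    if (gap < linker_max) {
      cur$end <- max(cur$end, segments[[i]]$end_col)
      cur$helices <- c(cur$helices, ord[i])
    } else {
      regions[[length(regions) + 1L]] <- cur
      cur <- list(start = segments[[i]]$start_col,
                  end = segments[[i]]$end_col, helices = ord[i])
    }
  }
  regions[[length(regions) + 1L]] <- cur
  regions
}

#' Retain or discard segments by score cutoff
#'
#' A segment is retained when its average log probability is at least the
#' cutoff of its category (ties retained); discarded segments have their
#' columns zeroed in the positive indicator.
#'
#' @param segments list of `detected_segment`s.
#' @param tm_cutoff,sp_cutoff retention cutoffs.
#' @return The segments with `retained` set.
#' @export
apply_cutoffs <- function(segments, tm_cutoff = -12, sp_cutoff = -1) {
  lapply(segments, function(s) {
    s$retained <- s$score >= if (s$category == "TM") tm_cutoff else sp_cutoff
    s
  })
}

#' Configuration of the consensus detector
#'
#' @param alpha per-column binomial test significance level.
#' @param epsilon column-probability floor (keeps logs finite).
#' @param tm_cutoff,sp_cutoff segment retention cutoffs on the average
#'   log probability (calibrated so that false-positive rates stay below
#'   5 percent on labelled helix/signal-peptide benchmarks).
#' @param linker_max TM region concatenation bound, in columns.
#' @return A named list of class `audit_config`.
#' @export
audit_config <- function(alpha = 0.05, epsilon = 1e-4,
                         tm_cutoff = -12, sp_cutoff = -1, linker_max = 40) {
  stopifnot(alpha > 0, alpha < 1, epsilon > 0, epsilon < 1, linker_max > 0)
  structure(list(alpha = alpha, epsilon = epsilon, tm_cutoff = tm_cutoff,
                 sp_cutoff = sp_cutoff, linker_max = linker_max),
            class = "audit_config")
}

#' Audit a domain alignment for SP/TM contamination
#'
#' The full consensus pipeline for every category with registered
#' predictors: project masks onto columns, test each column, delineate
#' raw segments, bridge TM fragments (or take the SP N-terminal span),
#' score, apply cutoffs and concatenate retained TM helices into regions.
#' The domain is flagged problematic for a category when at least one
#' segment of that category survives its cutoff.
#'
#' @param m an [msa].
#' @param ms a [mask_set()] covering every row of `m`.
#' @param config an [audit_config()].
#' @param domain_id identifier used in reports.
#' @return A `domain_audit` object: `segments` (all, with retention
#'   flags), `tm_problematic`, `sp_problematic`, `tm_regions`,
#'   `domain_score` (per category: predicted-column-weighted mean over
#'   retained segments, `NA` when none), `cumulative_predicted_length`,
#'   `indicator` (per category logical vector after zeroing discarded
#'   segments) and the per-category `column_stats`.
#' @export
audit_domain <- function(m, ms, config = audit_config(),
                         domain_id = "domain") {
  stopifnot(inherits(m, "msa"), inherits(ms, "mask_set"))
  segments <- list()
  stats_by_cat <- list()
  indicator <- list()
  for (category in c("TM", "SP")) {
    if (length(ms$roster[[category]]) == 0L) next
    proj <- project_to_columns(m, ms, category)
    st <- column_stats(proj, alpha = config$alpha, epsilon = config$epsilon)
    stats_by_cat[[category]] <- st
    raw <- delineate_segments(st)
    segs <- if (nrow(raw) == 0L) {
      list()
    } else if (category == "TM") {
      lapply(merge_tm_fragments(raw, proj), function(g)
        new_segment("TM", g$start, g$end, g$fragments, st$L))
    } else {
      list(sp_segment_span(raw, st$L))
    }
    segs <- apply_cutoffs(segs, config$tm_cutoff, config$sp_cutoff)
    ind <- st$positive
    for (s in segs)
      if (!s$retained) ind[s$start_col:s$end_col] <- FALSE
    indicator[[category]] <- ind
    segments <- c(segments, segs)
  }
  retained <- Filter(function(s) isTRUE(s$retained), segments)
  cat_of <- vapply(retained, `[[`, "", "category")
  domain_score <- sapply(c(TM = "TM", SP = "SP"), function(category) {
    rs <- retained[cat_of == category]
    if (length(rs) == 0L) return(NA_real_)
    w <- vapply(rs, `[[`, 0L, "n_pred_columns")
    sum(w * vapply(rs, `[[`, 0, "score")) / sum(w)
  })
  tm_regions <- concatenate_tm_regions(retained[cat_of == "TM"],
                                       config$linker_max)
  structure(
    list(domain_id = domain_id, segments = segments,
         tm_problematic = any(cat_of == "TM"),
         sp_problematic = any(cat_of == "SP"),
         tm_regions = tm_regions,
         domain_score = domain_score,
         cumulative_predicted_length =
           sum(vapply(retained, `[[`, 0L, "n_pred_columns")),
         indicator = indicator, column_stats = stats_by_cat,
         config = config),
    class = "domain_audit")
}

#' @export
print.domain_audit <- function(x, ...) {
  cat("Domain audit: ", x$domain_id, "\n", sep = "")
  cat("  TM problematic: ", x$tm_problematic,
      "; SP problematic: ", x$sp_problematic, "\n", sep = "")
  for (s in x$segments) {
    cat("  ")
    print(s)
  }
  invisible(x)
}

#' Tabular audit report
#'
#' One row per detected segment (retained or not), in the format written
#' by the command-line `detect` workflow.
#'
#' @param audit a `domain_audit`.
#' @return data.frame with columns `domain_id`, `category`, `start`,
#'   `end`, `n_fragments`, `n_pred_columns`, `score`, `retained`.
#' @export
audit_report <- function(audit) {
  stopifnot(inherits(audit, "domain_audit"))
  if (length(audit$segments) == 0L)
    return(data.frame(domain_id = character(0), category = character(0),
                      start = integer(0), end = integer(0),
                      n_fragments = integer(0), n_pred_columns = integer(0),
                      score = numeric(0), retained = logical(0)))
  do.call(rbind, lapply(audit$segments, function(s)
    data.frame(domain_id = audit$domain_id, category = s$category,
               start = s$start_col, end = s$end_col,
               n_fragments = nrow(s$fragments),
               n_pred_columns = s$n_pred_columns,
               score = s$score, retained = s$retained)))
}
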