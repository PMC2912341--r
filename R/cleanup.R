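#' Remove detected SP/TM segment columns from an alignment
#'
#' Produces the "cleanup" alignment: all columns inside the retained
#' segments' spans (including restored linker columns between merged
#' fragments — the segment is removed as a unit) are deleted and the
#' coordinate maps rebuilt.  Rows left without any residue are dropped
#' with a warning.
#'
#' @param m an [msa].
#' @param segments list of retained `detected_segment`s (or a
#'   `domain_audit`, whose retained segments are used), or a data.frame
#'   with `start`, `end` columns.
#' @return The stripped [msa].
#' @export
strip_columns <- function(m, segments) {
  stopifnot(inherits(m, "msa"))
  spans <- segment_spans(segments)
  if (nrow(spans) == 0L) return(m)
  if (any(spans$start < 1L) || any(spans$end > m$n_columns))
    stop("segment span outside alignment columns 1..", m$n_columns)
  drop_cols <- unique(unlist(mapply(seq, spans$start, spans$end,
                                    SIMPLIFY = FALSE)))
  keep <- setdiff(seq_len(m$n_columns), drop_cols)
  if (length(keep) == 0L)
    stop("stripping would remove every column of the alignment")
  mat <- m$mat[, keep, drop = FALSE]
  rows <- apply(mat != "-", 1L, any)
  if (!all(rows))
    warning("dropping ", sum(!rows), " row(s) left all-gap: ",
            paste(m$ids[!rows], collapse = ", "))
  if (!any(rows))
    stop("stripping would leave no rows with residues")
  msa(m$ids[rows], apply(mat[rows, , drop = FALSE], 1L, paste0, collapse = ""))
}

segment_spans <- function(segments) {
  if (inherits(segments, "domain_audit"))
    segments <- Filter(function(s) isTRUE(s$retained), segments$segments)
  if (is.data.frame(segments))
    return(segments[, c("start", "end"), drop = FALSE])
  if (length(segments) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = vapply(segments, `[[`, 0L, "start_col"),
             end = vapply(segments, `[[`, 0L, "end_col"))
}

#' Subset prediction masks to the residues surviving a column strip
#'
#' Companion of [strip_columns()]: drops, from every mask, the calls of
#' residues whose alignment columns were removed, and drops rows that
#' the strip removed, so the cleaned alignment can be re-audited with
#' consistent masks.
#'
#' @param ms the [mask_set()] of the original alignment.
#' @param m the original [msa] the spans refer to.
#' @param segments same value passed to [strip_columns()].
#' @return A `mask_set` matching the stripped alignment.
#' @export
strip_mask_columns <- function(ms, m, segments) {
  stopifnot(inherits(ms, "mask_set"), inherits(m, "msa"))
  spans <- segment_spans(segments)
  drop_cols <- if (nrow(spans) == 0L) integer(0) else
    unique(unlist(mapply(seq, spans$start, spans$end, SIMPLIFY = FALSE)))
  out <- ms
  for (i in seq_along(m$ids)) {
    sid <- m$ids[i]
    keep_pos <- which(!(m$pos2col[[i]] %in% drop_cols))
    if (length(keep_pos) == 0L) {
      out$calls[[sid]] <- NULL
      out$seq_lengths <- out$seq_lengths[names(out$seq_lengths) != sid]
      next
    }
    out$calls[[sid]] <- lapply(out$calls[[sid]], `[`, keep_pos)
    out$seq_lengths[[sid]] <- length(keep_pos)
  }
  out
}

#' Summary record of a cleanup operation
#'
#' @param audit the `domain_audit` whose retained segments were stripped.
#' @param before,after the alignment before and after [strip_columns()].
#' @return One-row data.frame: `domain_id`, `columns_before`,
#'   `columns_removed`, `columns_after`, `rows_dropped`, `segments`
#'   (semicolon-joined `category:start-end` list).
#' @export
cleanup_report <- function(audit, before, after) {
  stopifnot(inherits(audit, "domain_audit"),
            inherits(before, "msa"), inherits(after, "msa"))
  retained <- Filter(function(s) isTRUE(s$retained), audit$segments)
  data.frame(
    domain_id = audit$domain_id,
    columns_before = before$n_columns,
    columns_removed = before$n_columns - after$n_columns,
    columns_after = after$n_columns,
    rows_dropped = length(before$ids) - length(after$ids),
    segments = paste(vapply(retained, function(s)
      sprintf("%s:%d-%d", s$category, s$start_col, s$end_col), ""),
      collapse = ";"))
}
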