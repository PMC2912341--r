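#' Flag a set of model nodes as the SP/TM region
#'
#' The validated SP/TM block of a domain model, given as node ranges
#' (1-based inclusive, e.g. the TM block spanning nodes 102-177 of a
#' 177-node model); the complement is the globular (non-SP/TM) part.
#'
#' @param M model length.
#' @param ranges data.frame with `start`, `end` node columns, or `NULL`
#'   for an empty mask.
#' @param nodes alternatively, an explicit integer node set.
#' @param category `"TM"` or `"SP"` (annotation only).
#' @return Object of class `model_region_mask` with `M`, sorted `nodes`,
#'   and `category`.
#' @export
model_region_mask <- function(M, ranges = NULL, nodes = NULL,
                              category = "TM") {
  if (!is.null(ranges) && nrow(ranges) > 0L) {
    if (any(ranges$start < 1L) || any(ranges$end < ranges$start))
      stop("invalid node range (1-based, start <= end)")
    nodes <- c(nodes, unlist(mapply(seq, ranges$start, ranges$end,
                                    SIMPLIFY = FALSE)))
  }
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) && (min(nodes) < 1L || max(nodes) > M))
    stop("mask references nodes outside 1..", M)
  structure(list(M = M, nodes = nodes,
                 category = validate_category(category)),
            class = "model_region_mask")
}

#' Read model region masks from a TSV
#'
#' Columns: `domain_id`, `category`, `start_node`, `end_node` (1-based
#' inclusive).  Multiple rows per domain accumulate into one mask.
#'
#' @param path file path.
#' @param M named integer vector of model lengths per domain_id (or a
#'   single length when one domain).
#' @return Named list of `model_region_mask` objects, one per domain.
#' @export
read_region_masks <- function(path, M) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain_id", "category", "start_node", "end_node")
  if (!all(need %in% names(df)))
    stop("region mask file must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(df$domain_id)) {
    rows <- df[df$domain_id == id, ]
    len <- if (length(M) == 1L && is.null(names(M))) M else M[[id]]
    out[[id]] <- model_region_mask(
      len, ranges = data.frame(start = rows$start_node, end = rows$end_node),
      category = rows$category[1L])
  }
  out
}

path_terms <- function(aln, hmm) {
  # one row per additive score term of the Viterbi path:
  # value, owner node, constant flag
  p <- aln$path
  x <- aln$residues
  tr <- hmm$transitions
  n <- nrow(p)
  terms <- vector("list", 2L * n + 2L)
  k <- 0L
  add <- function(value, node, const = FALSE) {
    k <<- k + 1L
    terms[[k]] <<- c(value = as.numeric(value)[1L], node = node,
                     const = as.numeric(const))
  }
  add(tr[p$node[1L], "bm"], p$node[1L], const = TRUE)       # begin entry
  for (i in seq_len(n)) {
    if (i > 1L) {                                           # transition i-1 -> i
      ps <- p$state[i - 1L]; pn <- p$node[i - 1L]; cs <- p$state[i]
      name <- paste0(tolower(ps), tolower(cs))              # mm, mi, md, im, ii, dm, dd
      add(tr[pn, name], pn)                                 # departure node owns it
    }
    if (p$state[i] == "M") add(hmm$match_emit[p$node[i], x[p$pos[i]]], p$node[i])
    else if (p$state[i] == "I") add(hmm$insert_emit[p$node[i], x[p$pos[i]]], p$node[i])
  }
  add(tr[p$node[n], "me"], p$node[n], const = TRUE)         # end exit
  do.call(rbind, terms[seq_len(k)])
}

#' Decompose a Viterbi hit score into region-specific parts
#'
#' Every position-specific term of the optimal path (match/insert
#' emissions and the transition leaving each node) is attributed to its
#' model node; terms at nodes flagged by the region mask sum to the
#' SP/TM-specific score `S_TM`, terms at unflagged nodes to the
#' non-SP/TM score `S_NG`, and the position-independent begin-entry and
#' end-exit terms to `S_const`.  Additivity
#' `S_NG + S_TM + S_const = S_total` is exact by construction.
#'
#' @param aln a `viterbi_alignment` from [viterbi_hmmls()], produced with
#'   `hmm`.
#' @param hmm the [profile_hmm()] that produced `aln`.
#' @param mask a [model_region_mask()] on the nodes of `hmm`.
#' @return Object of class `score_partition`: list with `S_total`,
#'   `S_NG`, `S_TM`, `S_const` (bits).
#' @export
partition_score <- function(aln, hmm, mask) {
  stopifnot(inherits(aln, "viterbi_alignment"),
            inherits(hmm, "profile_hmm"),
            inherits(mask, "model_region_mask"))
  if (mask$M != hmm$M)
    stop("mask is defined for a model of length ", mask$M,
         ", hmm has length ", hmm$M)
  tm <- path_terms(aln, hmm)
  flagged <- tm[, "node"] %in% mask$nodes & tm[, "const"] == 0
  unflagged <- !(tm[, "node"] %in% mask$nodes) & tm[, "const"] == 0
  structure(list(
    S_total = aln$score,
    S_NG = sum(tm[unflagged, "value"]),
    S_TM = sum(tm[flagged, "value"]),
    S_const = sum(tm[tm[, "const"] == 1, "value"])),
    class = "score_partition")
}

#' @export
print.score_partition <- function(x, ...) {
  cat(sprintf("Score partition: total %.3f = NG %.3f + TM/SP %.3f + const %.3f (bits)\n",
              x$S_total, x$S_NG, x$S_TM, x$S_const))
  invisible(x)
}

#' Split the gathering threshold into SP/TM and non-SP/TM parts
#'
#' The proportion between the SP/TM-specific and non-SP/TM-specific score
#' contributions observed over the seed sequences of a model is assumed
#' to persist for true hits scoring near the gathering threshold GA.
#' Each seed i is scored and partitioned; a per-seed scaling factor
#' `c_i = (GA - S_const_i) / (S_NG_i + S_TM_i)` rescales its
#' position-specific score to the threshold (so that
#' `c_i * (S_NG_i + S_TM_i) + S_const_i = GA` exactly).  The expected
#' SP/TM share of the threshold is the sample mean
#' `G_TM = mean_i(c_i * S_TM_i)` and the non-SP/TM gathering threshold is
#' `G_NG = GA - G_TM`.
#'
#' @param hmm a [profile_hmm()].
#' @param seeds character vector of seed sequences (named, ideally).
#' @param mask a [model_region_mask()].
#' @param GA gathering score; defaults to the model's.
#' @return Object of class `gathering_partition`: `GA`, `G_TM`, `G_NG`,
#'   `seed_table` (per-seed S parts and c_i), `S_TM_mean`, `S_NG_mean`.
#'   Seeds whose position-specific score sums to zero are excluded with a
#'   warning; an error is raised when none remain.
#' @export
gathering_partition <- function(hmm, seeds, mask, GA = hmm$GA) {
  stopifnot(inherits(hmm, "profile_hmm"), length(seeds) >= 1L)
  ids <- names(seeds)
  if (is.null(ids)) ids <- paste0("seed", seq_along(seeds))
  parts <- lapply(seeds, function(s)
    partition_score(viterbi_hmmls(hmm, s), hmm, mask))
  tab <- data.frame(
    sequence_id = ids,
    S_total = vapply(parts, `[[`, 0, "S_total"),
    S_NG = vapply(parts, `[[`, 0, "S_NG"),
    S_TM = vapply(parts, `[[`, 0, "S_TM"),
    S_const = vapply(parts, `[[`, 0, "S_const"))
  denom <- tab$S_NG + tab$S_TM
  keep <- denom != 0
  if (!all(keep))
    warning("excluding ", sum(!keep),
            " seed(s) with zero position-specific score: ",
            paste(tab$sequence_id[!keep], collapse = ", "))
  if (!any(keep))
    stop("all seeds have zero position-specific score; cannot scale to GA")
  tab$c <- ifelse(keep, (GA - tab$S_const) / denom, NA_real_)
  G_TM <- mean(tab$c[keep] * tab$S_TM[keep])
  structure(list(GA = GA, G_TM = G_TM, G_NG = GA - G_TM,
                 seed_table = tab,
                 S_TM_mean = mean(tab$S_TM[keep]),
                 S_NG_mean = mean(tab$S_NG[keep])),
            class = "gathering_partition")
}

#' @export
print.gathering_partition <- function(x, ...) {
  cat(sprintf("Gathering partition: GA = %.2f, G_TM = %.2f, G_NG = %.2f (%d seeds)\n",
              x$GA, x$G_TM, x$G_NG, nrow(x$seed_table)))
  invisible(x)
}

#' Classify a domain hit by total and non-SP/TM score
#'
#' A hit is a true positive when both its total score reaches the
#' gathering threshold and its non-SP/TM part reaches `G_NG`.  A hit
#' below GA whose non-SP/TM part still reaches `G_NG` is a recoverable
#' false negative (the SP/TM block acted as a penalty).  A hit at or
#' above GA whose non-SP/TM part falls short of `G_NG` was carried over
#' the threshold solely by the SP/TM match: the annotation is
#' unjustified.  Hits failing both bounds get no call.
#'
#' @param partition a [partition_score()] result.
#' @param GA gathering threshold.
#' @param G_NG non-SP/TM gathering threshold, from
#'   [gathering_partition()].
#' @return Object of class `hit_classification`: `verdict` (one of
#'   `"true_positive"`, `"false_negative"`, `"unjustified"`,
#'   `"no_call"`) plus the supporting numbers.
#' @export
classify_hit <- function(partition, GA, G_NG) {
  stopifnot(inherits(partition, "score_partition"),
            is.finite(GA), is.finite(G_NG))
  pass_total <- partition$S_total >= GA
  pass_ng <- partition$S_NG >= G_NG
  verdict <- if (pass_total && pass_ng) "true_positive"
  else if (!pass_total && pass_ng) "false_negative"
  else if (pass_total) "unjustified"
  else "no_call"
  structure(list(verdict = verdict, S_total = partition$S_total,
                 S_NG = partition$S_NG, GA = GA, G_NG = G_NG),
            class = "hit_classification")
}

#' Classify a set of query sequences against a model
#'
#' Convenience wrapper: estimates `G_NG` from the seeds, then scores,
#' partitions and classifies each query.
#'
#' @param hmm a [profile_hmm()].
#' @param mask a [model_region_mask()].
#' @param seeds seed sequences for the gathering partition.
#' @param queries named character vector of query sequences.
#' @param GA gathering threshold; defaults to the model's.
#' @return List with `gathering` (the [gathering_partition()]) and
#'   `report`: data.frame `sequence_id`, `S_total`, `S_NG`, `S_TM`,
#'   `S_const`, `GA`, `G_NG`, `verdict`.
#' @export
classification_report <- function(hmm, mask, seeds, queries, GA = hmm$GA) {
  gp <- gathering_partition(hmm, seeds, mask, GA = GA)
  ids <- names(queries)
  if (is.null(ids)) ids <- paste0("query", seq_along(queries))
  rows <- lapply(seq_along(queries), function(i) {
    part <- partition_score(viterbi_hmmls(hmm, queries[[i]]), hmm, mask)
    cls <- classify_hit(part, GA, gp$G_NG)
    data.frame(sequence_id = ids[i], S_total = part$S_total,
               S_NG = part$S_NG, S_TM = part$S_TM, S_const = part$S_const,
               GA = GA, G_NG = gp$G_NG, verdict = cls$verdict)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = character(0), S_total = numeric(0),
               S_NG = numeric(0), S_TM = numeric(0), S_const = numeric(0),
               GA = numeric(0), G_NG = numeric(0), verdict = character(0))
  list(gathering = gp, report = report)
}

#' Rescore a query against the model with the SP/TM block excised
#'
#' Builds the sub-model consisting of the unflagged nodes only: flagged
#' nodes and their incident transitions are removed and each pair of
#' consecutive surviving nodes is rejoined using the upstream (donor)
#' node's own outgoing transitions — the minimal-perturbation splice.
#' Insert states of removed nodes are dropped.  If the excision removed
#' the begin-entry (or end-exit) node, entry (exit) is re-anchored at the
#' first (last) surviving node at zero cost, preserving the
#' global-in-model contract.  The E-value, when requested, is computed
#' with the ORIGINAL model's extreme-value parameters.
#'
#' @param hmm a [profile_hmm()].
#' @param mask a [model_region_mask()]; must leave at least one node.
#' @param seq query sequence.
#' @param db_size database size for the E-value; `NULL` skips it.
#' @return List with `score` (bits), `evalue` (or `NULL`), `alignment`
#'   (the `viterbi_alignment` on the sub-model) and `submodel`.
#' @export
rescore_without_region <- function(hmm, mask, seq, db_size = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"), inherits(mask, "model_region_mask"))
  keep <- setdiff(seq_len(hmm$M), mask$nodes)
  if (length(keep) == 0L) stop("mask flags every node; nothing to rescore")
  sub <- hmm
  sub$M <- length(keep)
  sub$match_emit <- hmm$match_emit[keep, , drop = FALSE]
  sub$insert_emit <- hmm$insert_emit[keep, , drop = FALSE]
  sub$transitions <- hmm$transitions[keep, , drop = FALSE]
  if (all(!is.finite(sub$transitions[, "bm"])))
    sub$transitions[1L, "bm"] <- 0
  if (all(!is.finite(sub$transitions[, "me"])))
    sub$transitions[sub$M, "me"] <- 0
  sub$name <- paste0(hmm$name, "_cleanup")
  aln <- viterbi_hmmls(sub, seq)
  ev <- if (!is.null(db_size)) {
    if (is.na(hmm$evd_mu) || is.na(hmm$evd_lambda))
      stop("E-value requested but the model has no EVD parameters")
    evalue(aln$score, db_size, hmm$evd_mu, hmm$evd_lambda)
  }
  list(score = aln$score, evalue = ev, alignment = aln, submodel = sub)
}
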