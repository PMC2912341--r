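#' @importFrom stats pbinom rbinom runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

AMINO_ACIDS <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
GAP_CHARS <- c("-", ".")

#' Multiple sequence alignment with column/residue coordinate maps
#'
#' Constructs the container used throughout the package for domain seed
#' alignments: a rectangular gapped residue matrix plus, for every row, the
#' bijection between alignment columns and ungapped residue positions.
#' Columns and residue positions are 1-based inclusive everywhere in the
#' package's interfaces and reports.
#'
#' Input is normalised: `.` and `-` are both accepted as gaps (Pfam
#' full-alignment dialect) and stored as `-`; lowercase residues are
#' uppercased.  Non-standard residues (B, Z, U, O) are preserved here and
#' only mapped to X by scoring code.
#'
#' @param ids character vector of unique row identifiers.
#' @param seqs character vector of aligned sequences, all the same length.
#' @return An object of class `msa` with elements `ids`, `seqs` (normalised
#'   aligned strings), `mat` (character matrix, rows = sequences),
#'   `n_columns`, `col2pos` (list of integer vectors, `NA` at gap columns)
#'   and `pos2col` (list of integer vectors over ungapped positions).
#' @examples
#' m <- msa(c("a", "b"), c("AC-DE", "A.CDE"))
#' m$n_columns
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length")
  if (length(ids) == 0L)
    stop("alignment must contain at least one row")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1L]][1L]
    stop("ragged alignment: row '", bad, "' has length ",
         widths[ids == bad][1L], ", expected ", widths[1L])
  }
  if (widths[1L] < 1L)
    stop("alignment must have at least one column")
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  nongap <- mat != "-"
  col2pos <- pos2col <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cp <- cumsum(nongap[i, ])
    cp[!nongap[i, ]] <- NA_integer_
    col2pos[[i]] <- as.integer(cp)
    pos2col[[i]] <- which(nongap[i, ])
  }
  names(col2pos) <- names(pos2col) <- ids
  structure(
    list(ids = ids, seqs = seqs, mat = mat, n_columns = ncol(mat),
         col2pos = col2pos, pos2col = pos2col),
    class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x$ids), " rows x ",
      x$n_columns, " columns\n", sep = "")
  show <- head(x$ids, 5L)
  for (id in show) {
    s <- x$seqs[match(id, x$ids)]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-15s %s\n", id, s))
  }
  if (length(x$ids) > 5L) cat("  ...\n")
  invisible(x)
}

#' Number of non-gap residues in an alignment column
#'
#' The column depth n_j: the number of sequences contributing a residue
#' (not a gap) at column `j`.  This is the binomial sample size of the
#' per-column consensus test.
#'
#' @param m an [msa] object.
#' @param j column index, 1-based.
#' @return Integer count in `[0, nrow]`.
#' @export
column_depth <- function(m, j) {
  stopifnot(inherits(m, "msa"))
  if (length(j) != 1L || is.na(j) || j < 1L || j > m$n_columns)
    stop("column index out of range [1, ", m$n_columns, "]: ", j)
  sum(m$mat[, j] != "-")
}

#' Ungapped length of each alignment row
#' @param m an [msa] object.
#' @return Named integer vector of ungapped sequence lengths.
#' @export
ungapped_lengths <- function(m) {
  stopifnot(inherits(m, "msa"))
  setNames(lengths(m$pos2col), m$ids)
}

#' Read a domain alignment
#'
#' Reads Stockholm (minimal dialect: sequence lines, `#` annotation lines
#' ignored, `//` terminator) or aligned FASTA.  `.` and `-` are both
#' treated as gaps; case is normalised to upper.
#'
#' @param path file path (or, for FASTA, anything
#'   [Biostrings::readBStringSet] accepts).
#' @param format `"stockholm"` or `"aligned-fasta"`.
#' @return An [msa] object.
#' @export
read_alignment <- function(path, format = c("aligned-fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path)
    return(msa(names(set), as.character(set)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  ids <- character(0)
  parts <- list()
  for (ln in lines) {
    if (ln == "" || startsWith(ln, "#")) next
    if (ln == "//") break
    tok <- strsplit(ln, "[ \t]+")[[1L]]
    if (length(tok) != 2L)
      stop("malformed Stockholm sequence line: '", ln, "'")
    id <- tok[1L]
    k <- match(id, ids)
    if (is.na(k)) {       # interleaved blocks append to existing rows
      ids <- c(ids, id)
      parts[[length(ids)]] <- tok[2L]
    } else {
      parts[[k]] <- c(parts[[k]], tok[2L])
    }
  }
  if (length(ids) == 0L)
    stop("no sequence rows found in Stockholm input")
  msa(ids, vapply(parts, paste0, "", collapse = ""))
}

#' Write a domain alignment
#'
#' Output uses `-` for gaps and uppercase residues.  Stockholm output is
#' the minimal dialect (header, one line per row, `//` terminator);
#' round-trips with [read_alignment()].
#'
#' @param m an [msa] object.
#' @param path output file path.
#' @param format `"stockholm"` or `"aligned-fasta"`.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(m, path, format = c("aligned-fasta", "stockholm")) {
  stopifnot(inherits(m, "msa"))
  format <- match.arg(format)
  if (format == "aligned-fasta") {
    set <- Biostrings::BStringSet(setNames(m$seqs, m$ids))
    Biostrings::writeXStringSet(set, path, width = 60L)
  } else {
    w <- max(nchar(m$ids)) + 2L
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# STOCKHOLM 1.0", con)
    writeLines(sprintf(paste0("%-", w, "s%s"), m$ids, m$seqs), con)
    writeLines("//", con)
  }
  invisible(path)
}
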