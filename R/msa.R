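## Alignment summaries: consensus, conservation profile (the grey-strip
## statistic), and information-content logo matrices.

normalize_gapped <- function(s) {
  s <- chartr("T.", "U-", toupper(s))
  gsub("[^ACGUX-]", "X", s)
}

#' Construct an alignment object from gapped sequences
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (alphabet A/C/G/U/X/-; T and '.' are normalised on input).
#' @return Object of class `rna_alignment`: list with `ids`, `seqs`,
#'   `n_rows`, `n_cols`.
#' @export
as_alignment <- function(seqs) {
  if (length(seqs) < 2L) stop("an alignment needs at least 2 rows")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("row", seq_along(seqs))
  seqs <- vapply(unname(seqs), normalize_gapped, character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("row length mismatch: ", ids[which(lens != lens[1])[1]])
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                 n_rows = length(seqs), n_cols = unname(lens[1])),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("RNA alignment: %d rows x %d columns\n", x$n_rows, x$n_cols))
  invisible(x)
}

#' Read a multiple sequence alignment from file
#'
#' Aligned FASTA is read with Biostrings; Clustal with the Biostrings
#' Clustal parser. The alphabet is normalised (T to U, '.' to '-', other
#' non-ACGU symbols to X) and row order is preserved.
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return An `rna_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  seqs <- if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    ## the amino-acid alphabet admits A/C/G/T/U/X/- so nucleotide text
    ## parses without alphabet errors
    as.character(Biostrings::readAAMultipleAlignment(path, format = "clustal"))
  }
  as_alignment(seqs)
}

## n_rows x n_cols character matrix of an alignment.
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), ""))
}

## Per-column counts of A, C, G, U (4 x n_cols).
base_counts <- function(m) {
  apply(m, 2, function(col) {
    c(A = sum(col == "A"), C = sum(col == "C"),
      G = sum(col == "G"), U = sum(col == "U"))
  })
}

#' Majority consensus of an alignment
#'
#' Per column, the most frequent base (A/C/G/U) wins if its fraction among
#' non-gap symbols reaches `threshold`, else N. Columns that are majority
#' gap (> 0.5) emit '-' (`gap_policy = "mark"`) or are dropped
#' (`"drop"`). Ties are broken by the fixed base order A < C < G < U and
#' recorded. The placeholder X counts toward the non-gap denominator but
#' cannot win a column.
#'
#' @param aln an `rna_alignment`.
#' @param threshold winning-fraction threshold in `[0, 1]`.
#' @param gap_policy `"mark"` or `"drop"`.
#' @return Object of class `consensus_result`: list with `sequence`,
#'   `threshold`, `fraction` (per emitted column, winning fraction among
#'   non-gap symbols; NA for gap columns), `tie` (logical), `gap_policy`,
#'   `kept_columns` (0-based original indices of emitted columns).
#' @export
consensus <- function(aln, threshold = 0.5, gap_policy = c("mark", "drop")) {
  stopifnot(inherits(aln, "rna_alignment"))
  gap_policy <- match.arg(gap_policy)
  m <- alignment_matrix(aln)
  cnt <- base_counts(m)
  n_gap <- colSums(m == "-")
  n_nongap <- aln$n_rows - n_gap

  chars <- character(aln$n_cols)
  frac <- rep(NA_real_, aln$n_cols)
  tie <- logical(aln$n_cols)
  gapcol <- n_gap / aln$n_rows > 0.5
  for (j in seq_len(aln$n_cols)) {
    if (gapcol[j]) { chars[j] <- "-"; next }
    counts <- cnt[, j]
    top <- max(counts)
    if (top == 0L) { chars[j] <- "N"; frac[j] <- 0; next }  # all-X column
    winners <- names(counts)[counts == top]
    tie[j] <- length(winners) > 1L
    f <- top / n_nongap[j]
    frac[j] <- f
    chars[j] <- if (f >= threshold) winners[1] else "N"
  }
  keep <- if (gap_policy == "drop") which(!gapcol) else seq_len(aln$n_cols)
  structure(
    list(sequence = paste(chars[keep], collapse = ""), threshold = threshold,
         fraction = frac[keep], tie = tie[keep], gap_policy = gap_policy,
         kept_columns = keep - 1L),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus (threshold %.2f, gaps: %s):\n%s\n",
              x$threshold, x$gap_policy, x$sequence))
  invisible(x)
}

#' Per-column conservation profile
#'
#' The statistic behind the grey conservation strip: for each column, the
#' count of the most frequent base (A/C/G/U) divided by the number of
#' rows. Gap-only columns score 0.
#'
#' @param aln an `rna_alignment`.
#' @return Numeric vector in `[0, 1]`, one value per column.
#' @export
conservation_profile <- function(aln) {
  stopifnot(inherits(aln, "rna_alignment"))
  m <- alignment_matrix(aln)
  apply(base_counts(m), 2, max) / aln$n_rows
}

#' Information-content logo matrix of an alignment
#'
#' Per column, over the non-gap A/C/G/U symbols: information content
#' `2 - H` bits (H = Shannon entropy of the base frequencies), minus the
#' small-sample correction `e_n = 3 / (2 ln 2 n)` when enabled, floored
#' at 0. Letter heights are `frequency x info`.
#'
#' @param aln an `rna_alignment`.
#' @param small_sample_correction logical; default applies the correction
#'   for alignments of fewer than 50 rows.
#' @return data.frame with columns col0 (0-based column), A, C, G, U
#'   (letter heights in bits) and info (column information content).
#' @export
logo <- function(aln, small_sample_correction = NULL) {
  stopifnot(inherits(aln, "rna_alignment"))
  if (is.null(small_sample_correction))
    small_sample_correction <- aln$n_rows < 50L
  m <- alignment_matrix(aln)
  cnt <- base_counts(m)
  n <- colSums(cnt)
  out <- data.frame(col0 = seq_len(aln$n_cols) - 1L,
                    A = 0, C = 0, G = 0, U = 0, info = 0)
  for (j in seq_len(aln$n_cols)) {
    if (n[j] == 0L) next
    p <- cnt[, j] / n[j]
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    e_n <- if (small_sample_correction) 3 / (2 * log(2) * n[j]) else 0
    info <- max(0, 2 - h - e_n)
    out[j, c("A", "C", "G", "U")] <- p * info
    out$info[j] <- info
  }
  out
}
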