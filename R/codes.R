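#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide classes (RNA alphabet). Concrete letters denote
## singletons; R/Y are the purine/pyrimidine classes, M the amino bases,
## N any base. The placeholder X (non-ACGU input) matches nothing.
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"),
  M = c("A", "C"), K = c("G", "U"),
  S = c("C", "G"), W = c("A", "U"),
  B = c("C", "G", "U"), D = c("A", "G", "U"),
  H = c("A", "C", "U"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "U")
)

RNA_BASES <- c("A", "C", "G", "U")

## Generating patterns of the built-in codon repertoires.  PGC is Eigen's
## primaeval RNY code; Ex1 extends it by frame-shift reading (RNY+NYR+YRN),
## Ex2 by first/third-position transversions (RNY+YNY+RNR); SGC is all 64.
REPERTOIRE_PATTERNS <- list(
  PGC = "RNY",
  Ex1 = c("RNY", "NYR", "YRN"),
  Ex2 = c("RNY", "YNY", "RNR"),
  SGC = "NNN"
)

#' Base set denoted by an IUPAC pattern symbol
#'
#' @param letter single IUPAC nucleotide letter (RNA alphabet).
#' @return Character vector: the subset of A/C/G/U the symbol denotes.
#' @examples
#' iupac_base_set("R")  # purines
#' iupac_base_set("M")  # amino bases A, C
#' @export
iupac_base_set <- function(letter) {
  stopifnot(is.character(letter), length(letter) == 1L, nchar(letter) == 1L)
  set <- IUPAC_CLASSES[[toupper(letter)]]
  if (is.null(set)) stop("unknown IUPAC symbol: ", letter)
  set
}

#' Normalise a raw nucleotide string to the RNA working alphabet
#'
#' Case-folds, replaces every T by U, and replaces any character outside
#' A/C/G/T/U by the placeholder X. A triplet containing X is a non-member
#' of every repertoire, so ambiguity codes in genome-scale FASTA stream
#' through without raising. Length is preserved.
#'
#' @param raw non-empty character scalar.
#' @return Uppercase RNA string over A/C/G/U/X.
#' @examples
#' normalize_sequence("gattaca")  # "GAUUACA"
#' normalize_sequence("ACN")      # "ACX"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    stop("empty sequence")
  s <- chartr("T", "U", toupper(raw))
  gsub("[^ACGU]", "X", s)
}

#' All 64 codons in lexicographic order
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  g <- expand.grid(b3 = RNA_BASES, b2 = RNA_BASES, b1 = RNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

#' Does a codon match a 3-symbol IUPAC pattern?
#'
#' True iff each base lies in the base set of the corresponding pattern
#' symbol. Codons containing the placeholder X never match.
#'
#' @param codon character vector of 3-letter RNA codons.
#' @param pattern single 3-letter IUPAC pattern, e.g. "RNY" or "AAM".
#' @return Logical vector, one element per codon.
#' @examples
#' pattern_matches("GCC", "RNY")  # TRUE
#' pattern_matches("UUC", "RNY")  # FALSE: U is not a purine
#' @export
pattern_matches <- function(codon, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) != 3L)
    stop("pattern must be a single 3-letter IUPAC string")
  if (!all(nchar(codon) == 3L)) stop("codons must have exactly 3 bases")
  sets <- lapply(strsplit(pattern, "")[[1]], iupac_base_set)
  ok <- rep(TRUE, length(codon))
  for (pos in 1:3)
    ok <- ok & substr(codon, pos, pos) %in% sets[[pos]]
  ok
}

#' Build a codon repertoire from its generating patterns
#'
#' The four built-in repertoires are `PGC` (the 16 RNY triplets), `Ex1`
#' (RNY+NYR+YRN, 48 triplets, the frame-shift route), `Ex2` (RNY+YNY+RNR,
#' 48 triplets, the transversion route) and `SGC` (all 64). A custom
#' repertoire can be built by passing `patterns` with any label.
#'
#' @param name repertoire label; one of the built-ins unless `patterns`
#'   is supplied.
#' @param patterns optional character vector of 3-letter IUPAC patterns
#'   overriding the built-in set.
#' @return An object of class `code_repertoire`: list with `name`,
#'   `patterns`, and `members` (lexicographically sorted codons).
#' @examples
#' length(build_repertoire("PGC")$members)  # 16
#' @export
build_repertoire <- function(name, patterns = NULL) {
  if (is.null(patterns)) {
    patterns <- REPERTOIRE_PATTERNS[[name]]
    if (is.null(patterns))
      stop("unknown repertoire '", name, "'; supply patterns= for a custom code")
  }
  codons <- all_codons()
  member <- Reduce(`|`, lapply(patterns, function(p) pattern_matches(codons, p)))
  structure(
    list(name = name, patterns = patterns, members = codons[member]),
    class = "code_repertoire"
  )
}

#' @export
print.code_repertoire <- function(x, ...) {
  cat("Codon repertoire", x$name, "\n")
  cat("  patterns:", paste(x$patterns, collapse = " + "), "\n")
  cat("  members: ", length(x$members), "codons\n")
  invisible(x)
}

#' Repertoire memberships of a codon
#'
#' @param codon single 3-letter codon (may contain X).
#' @return Character vector: subset of c("PGC","Ex1","Ex2","SGC") whose
#'   member sets contain the codon. A codon containing X returns an empty
#'   vector (it belongs to no repertoire).
#' @examples
#' codon_memberships("AUG")  # Ex1, Ex2, SGC
#' codon_memberships("UGG")  # Ex1, SGC
#' @export
codon_memberships <- function(codon) {
  stopifnot(length(codon) == 1L, nchar(codon) == 3L)
  if (grepl("X", codon)) return(character(0))
  if (!all(strsplit(codon, "")[[1]] %in% RNA_BASES))
    stop("invalid codon: ", codon)
  names(REPERTOIRE_PATTERNS)[vapply(
    REPERTOIRE_PATTERNS,
    function(p) any(vapply(p, function(q) pattern_matches(codon, q), logical(1))),
    logical(1)
  )]
}

#' Stop codons contained in a repertoire
#'
#' @param repertoire a `code_repertoire`.
#' @return Character vector: intersection of the repertoire with the three
#'   stop codons UAA, UGA, UAG.
#' @export
stop_codon_audit <- function(repertoire) {
  stopifnot(inherits(repertoire, "code_repertoire"))
  intersect(repertoire$members, c("UAA", "UGA", "UAG"))
}

## Standard genetic code (NCBI table 1) on the RNA alphabet, taken from
## Biostrings; "*" marks stop codons.
standard_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), chartr("T", "U", names(gc)))
}

#' Per-codon table: patterns matched, amino acid, repertoire memberships
#'
#' One row per codon of the standard code, with the amino acid it encodes
#' (one-letter, "*" for stop) and logical membership columns for each
#' built-in repertoire. This is the serialisable "show the codes" surface.
#'
#' @return data.frame with columns codon, amino_acid, patterns, PGC, Ex1,
#'   Ex2, SGC, sorted lexicographically by codon.
#' @export
codon_code_table <- function() {
  codons <- all_codons()
  gc <- standard_code()
  pats <- unique(unlist(REPERTOIRE_PATTERNS))
  matched <- vapply(codons, function(cd) {
    paste(pats[vapply(pats, function(p) pattern_matches(cd, p), logical(1))],
          collapse = ",")
  }, character(1))
  out <- data.frame(
    codon = codons,
    amino_acid = unname(gc[codons]),
    patterns = unname(matched),
    stringsAsFactors = FALSE
  )
  for (nm in names(REPERTOIRE_PATTERNS))
    out[[nm]] <- codons %in% build_repertoire(nm)$members
  out
}

#' Amino-acid level repertoire membership audit
#'
#' For each amino acid (plus STOP), the set of repertoires containing at
#' least one of its codons, by direct set membership. Tyrosine is commonly
#' described in the code-evolution literature as encoded only by the
#' transversion-route extended code, yet its codons UAU/UAC satisfy both
#' the YRN and YNY patterns; the row is flagged in `note` rather than
#' forced to the literature assignment.
#'
#' @param detail if TRUE, return the per-codon table instead
#'   (see [codon_code_table()]).
#' @return data.frame with columns amino_acid, PGC, Ex1, Ex2, SGC
#'   (logical), codes (comma string of repertoires), note.
#' @export
amino_acid_code_table <- function(detail = FALSE) {
  tab <- codon_code_table()
  if (detail) return(tab)
  tab$amino_acid[tab$amino_acid == "*"] <- "STOP"
  aas <- sort(unique(tab$amino_acid))
  rows <- lapply(aas, function(aa) {
    sub <- tab[tab$amino_acid == aa, , drop = FALSE]
    memb <- vapply(names(REPERTOIRE_PATTERNS), function(nm) any(sub[[nm]]),
                   logical(1))
    data.frame(amino_acid = aa,
               PGC = memb[["PGC"]], Ex1 = memb[["Ex1"]],
               Ex2 = memb[["Ex2"]], SGC = memb[["SGC"]],
               codes = paste(names(memb)[memb], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$note <- ""
  out$note[out$amino_acid == "Y"] <-
    paste("set membership places Tyr codons (UAU/UAC) in both extended",
          "codes, although Tyr is often listed as exclusive to the",
          "transversion-route code")
  out
}
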