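## Coordinate conventions: 0-based half-open [start, end) everywhere.

## Fragments of one fixed-frame scan: maximal runs of member triplets.
## Returns data.frame(frame, start, end) in ascending start order.
scan_frame <- function(residues, members, frame) {
  n <- nchar(residues)
  starts0 <- seq.int(frame, n - 3L, by = 3L)
  if (n - frame < 3L || length(starts0) == 0L)
    return(data.frame(frame = integer(0), start = integer(0), end = integer(0)))
  trip <- substring(residues, starts0 + 1L, starts0 + 3L)
  ok <- trip %in% members
  r <- rle(ok)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    frame = rep.int(frame, length(keep)),
    start = starts0[starts_i[keep]],
    end = starts0[ends_i[keep]] + 3L
  )
}

#' Decompose a sequence into repertoire-member triplet runs
#'
#' Scans non-overlapping triplets and keeps maximal runs whose triplets all
#' belong to the repertoire; triplets outside the repertoire (including any
#' containing the placeholder X) are discarded. Fragments keep their true
#' coordinates on the parent, so they can be reassembled in original order.
#'
#' @param seq RNA string (see [normalize_sequence()]); may also be a named
#'   length-1 character vector, in which case the name becomes the id.
#' @param repertoire a `code_repertoire` or a built-in repertoire name.
#' @param frames frame policy: `"union"` (default; fragments from all three
#'   fixed frames, coverage counts the union of residue positions),
#'   `"best"` (the fixed frame maximising coverage, ties to the lowest
#'   frame), or a fixed frame 0, 1 or 2.
#' @param id sequence identifier carried into the result.
#' @return Object of class `decomposition`: list with `id`, `residues`,
#'   `code`, `frame_policy`, `fragments` (data.frame frame/start/end,
#'   0-based half-open), `covered_positions`, `coverage`.
#' @examples
#' d <- decompose("GAUCACCUCC", "Ex2", frames = 0)
#' d$coverage  # 0.9: GAU, CAC, CUC are all members; trailing C unscanned
#' @export
decompose <- function(seq, repertoire, frames = "union", id = NULL) {
  if (is.character(repertoire)) repertoire <- build_repertoire(repertoire)
  stopifnot(inherits(repertoire, "code_repertoire"))
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  residues <- unname(seq[1])
  n <- nchar(residues)

  policy <- if (is.numeric(frames)) {
    stopifnot(frames %in% 0:2)
    sprintf("fixed(%d)", frames)
  } else match.arg(frames, c("union", "best"))

  frags <- if (n < 3L) {
    data.frame(frame = integer(0), start = integer(0), end = integer(0))
  } else if (is.numeric(frames)) {
    scan_frame(residues, repertoire$members, as.integer(frames))
  } else {
    per_frame <- lapply(0:2, scan_frame, residues = residues,
                        members = repertoire$members)
    if (policy == "best") {
      cov <- vapply(per_frame, function(f) sum(f$end - f$start), numeric(1))
      per_frame[[which.max(cov)]]  # which.max ties -> lowest frame
    } else do.call(rbind, per_frame)
  }
  frags <- frags[order(frags$start, frags$frame), , drop = FALSE]
  rownames(frags) <- NULL

  covered <- if (nrow(frags) == 0L) integer(0) else
    sort(unique(unlist(Map(seq.int, frags$start, frags$end - 1L))))
  structure(
    list(id = id, residues = residues, code = repertoire$name,
         frame_policy = policy, fragments = frags,
         covered_positions = length(covered),
         coverage = if (n == 0L) 0 else length(covered) / n),
    class = "decomposition"
  )
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("Decomposition of '%s' under %s (%s): %d fragment(s), coverage %.3f\n",
              x$id, x$code, x$frame_policy, nrow(x$fragments), x$coverage))
  invisible(x)
}

## Sorted unique covered residue positions (0-based) of a decomposition.
covered_positions_of <- function(d) {
  if (nrow(d$fragments) == 0L) return(integer(0))
  sort(unique(unlist(Map(seq.int, d$fragments$start, d$fragments$end - 1L))))
}

#' Reassemble the fragments of a decomposition in original gene order
#'
#' Concatenates fragment subsequences in ascending start order; under the
#' union policy residues covered by more than one frame are emitted once,
#' in ascending position order.
#'
#' @param d a `decomposition`.
#' @return Named character scalar (name = parent id); empty string for an
#'   empty decomposition.
#' @export
reassemble <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  pos <- covered_positions_of(d)
  out <- if (length(pos) == 0L) "" else
    paste(strsplit(d$residues, "")[[1]][pos + 1L], collapse = "")
  stats::setNames(out, d$id)
}

## Compile an IUPAC pattern into a regular expression character-class
## string; the classes contain only A/C/G/U so the placeholder X never
## matches.
iupac_regex <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(l) {
    set <- iupac_base_set(l)
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Find all occurrences of an IUPAC motif in a sequence
#'
#' Overlapping occurrences are reported, left to right.
#'
#' @param seq RNA string.
#' @param pattern IUPAC motif string (e.g. "GAGGAAMGUCC").
#' @return data.frame with columns start, end (0-based half-open); zero
#'   rows when there is no occurrence or the pattern is longer than the
#'   sequence.
#' @examples
#' find_motif("GAUCACCUCC", "CCUCC")  # one hit at [5, 10)
#' @export
find_motif <- function(seq, pattern) {
  residues <- unname(seq[1])
  if (nchar(pattern) > nchar(residues) || nchar(pattern) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  rx <- paste0("(?=", iupac_regex(pattern), ")")  # lookahead: overlaps allowed
  m <- gregexpr(rx, residues, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + nchar(pattern))
}

#' Built-in library of functional RNA motifs
#'
#' The anti-Shine-Dalgarno core and two organism-specific 3'-end contexts,
#' the universally conserved SRP-RNA helix-8 decamer, the RNase P RNA
#' signature (M = amino base, A or C), and the tRNA CCA acceptor end.
#'
#' @return data.frame with columns name, pattern, source_note.
#' @export
builtin_motifs <- function() {
  data.frame(
    name = c("ANTI_SD_CORE", "ANTI_SD_ECOK12", "ANTI_SD_MEJAN",
             "SRP_HELIX8", "RNAP_SIGNATURE", "TRNA_ACCEPTOR_END"),
    pattern = c("CCUCC", "GAUCACCUCC", "AUCACCUCCU",
                "GAAGCAGCCA", "GAGGAAMGUCC", "CCA"),
    source_note = c(
      "minimal anti-Shine-Dalgarno core at the 16S rRNA 3' end",
      "anti-SD context at the E. coli K-12 16S rRNA 3' end",
      "anti-SD context at the M. jannaschii 16S rRNA 3' end",
      "helix-8 decamer conserved across SRP-RNAs (B. subtilis form)",
      "RNase P RNA signature 5'-GAG-GAAM-GUCC-3'; M = amino base A/C",
      "unpaired CCA acceptor end of mature tRNAs"),
    stringsAsFactors = FALSE
  )
}

#' Score recovery of motif occurrences by one or more codon repertoires
#'
#' For every occurrence of every motif, computes the fraction of its
#' residue positions covered by the decomposition of the full parent
#' sequence under each repertoire, and assigns a status: `full`
#' (fraction 1), `none` (fraction 0) or `partial`.
#'
#' @param seq RNA string.
#' @param motifs data.frame with columns name, pattern (as from
#'   [builtin_motifs()]), or a single IUPAC pattern string.
#' @param codes character vector of repertoire names, or list of
#'   `code_repertoire` objects.
#' @param frames frame policy passed to [decompose()].
#' @param id sequence identifier.
#' @return data.frame with columns motif, start, end, code, fraction,
#'   status; zero rows when no motif occurs.
#' @examples
#' motif_recovery("GAUCACCUCC", "CCUCC", c("Ex1", "Ex2"))
#' @export
motif_recovery <- function(seq, motifs, codes = c("Ex1", "Ex2"),
                           frames = "union", id = NULL) {
  if (is.character(motifs))
    motifs <- data.frame(name = motifs, pattern = motifs,
                         stringsAsFactors = FALSE)
  reps <- lapply(codes, function(cd)
    if (is.character(cd)) build_repertoire(cd) else cd)
  decomps <- lapply(reps, function(r) decompose(seq, r, frames = frames, id = id))
  cov_sets <- lapply(decomps, covered_positions_of)

  rows <- list()
  for (mi in seq_len(nrow(motifs))) {
    occ <- find_motif(seq, motifs$pattern[mi])
    if (nrow(occ) == 0L) next
    for (oi in seq_len(nrow(occ))) {
      span <- seq.int(occ$start[oi], occ$end[oi] - 1L)
      for (ci in seq_along(reps)) {
        frac <- sum(span %in% cov_sets[[ci]]) / length(span)
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motifs$name[mi], start = occ$start[oi], end = occ$end[oi],
          code = reps[[ci]]$name, fraction = frac,
          status = if (frac == 1) "full" else if (frac == 0) "none" else "partial",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), code = character(0),
                      fraction = numeric(0), status = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
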