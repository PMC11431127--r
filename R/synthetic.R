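## Seeded generators for every input the pipeline consumes: code-biased
## sequences with triplet provenance, motif-planted sequences, diverged
## families with true alignments, fold-prone hairpins, and toy helical
## coordinate sets. All generators are pure functions of their parameters
## and seed.

#' Generate a sequence of triplets drawn from a codon repertoire
#'
#' Each triplet is drawn uniformly from the repertoire with probability
#' `purity`, otherwise uniformly from its complement among the 64 codons.
#' The provenance of every triplet is recorded so planted truth can be
#' recovered without re-generation.
#'
#' @param repertoire a `code_repertoire` or built-in name.
#' @param n_triplets number of triplets (sequence length is 3x this).
#' @param purity probability in `[0, 1]` of an in-repertoire draw.
#' @param seed integer seed.
#' @return List with `seq` (RNA string), `triplets`, `from_repertoire`
#'   (logical per triplet), `repertoire`, `seed`.
#' @examples
#' x <- gen_code_sequence("PGC", 10, seed = 1)
#' decompose(x$seq, "PGC", frames = 0)$coverage  # 1 by construction
#' @export
gen_code_sequence <- function(repertoire, n_triplets, purity = 1, seed = 1) {
  if (is.character(repertoire)) repertoire <- build_repertoire(repertoire)
  stopifnot(n_triplets >= 1, purity >= 0, purity <= 1)
  complement <- setdiff(all_codons(), repertoire$members)
  if (length(complement) == 0L && purity < 1)
    stop("repertoire covers all 64 codons; purity < 1 is impossible")
  withr::with_seed(seed, {
    from_rep <- stats::runif(n_triplets) < purity
    trips <- character(n_triplets)
    trips[from_rep] <- sample(repertoire$members, sum(from_rep), replace = TRUE)
    trips[!from_rep] <- sample(complement, sum(!from_rep), replace = TRUE)
    list(seq = paste(trips, collapse = ""), triplets = trips,
         from_repertoire = from_rep, repertoire = repertoire$name, seed = seed)
  })
}

#' Plant a concrete motif instance into a sequence
#'
#' @param seq RNA string.
#' @param motif concrete motif string (no ambiguity letters).
#' @param pos 0-based position of the first motif residue.
#' @return List with `seq` (modified string) and `record` (list with
#'   `start`, `end` 0-based half-open, `original` replaced text).
#' @export
plant_motif <- function(seq, motif, pos) {
  residues <- unname(seq[1])
  if (pos < 0 || pos + nchar(motif) > nchar(residues))
    stop("motif does not fit at position ", pos)
  original <- substr(residues, pos + 1L, pos + nchar(motif))
  substr(residues, pos + 1L, pos + nchar(motif)) <- motif
  list(seq = residues,
       record = list(start = pos, end = pos + nchar(motif),
                     original = original))
}

#' Evolve a family of sequences from an ancestor with a true alignment
#'
#' Each member is derived independently: per ancestor site, substitution
#' with probability `mu` (uniform over the three alternatives), deletion
#' with probability `iota`, and a single-base insertion after the site
#' with probability `iota`. The true alignment is built from the edit
#' records: one column per ancestor site plus one insertion column per
#' site boundary used by any member; stripping gaps from row i reproduces
#' member i exactly.
#'
#' @param ancestor RNA string.
#' @param n number of members (>= 2).
#' @param mu per-site substitution rate in `[0, 0.5]`.
#' @param iota per-site indel rate in `[0, 0.5]`.
#' @param seed integer seed.
#' @param planted_motifs optional record of (name, interval) truths to
#'   carry along.
#' @return Object of class `synthetic_family`: list with `ancestor`,
#'   `members` (named character), `true_alignment` (`rna_alignment`),
#'   `params`, `planted_motifs`.
#' @export
evolve_family <- function(ancestor, n, mu = 0.1, iota = 0, seed = 1,
                          planted_motifs = NULL) {
  residues <- unname(ancestor[1])
  L <- nchar(residues)
  stopifnot(n >= 2, mu >= 0, mu <= 0.5, iota >= 0, iota <= 0.5, L >= 1)
  anc <- strsplit(residues, "")[[1]]
  withr::with_seed(seed, {
    ## site_chars[m, i]: member m's residue at ancestor site i ("-" if
    ## deleted); ins_chars[m, i]: single base inserted after site i ("")
    site_chars <- matrix("", n, L)
    ins_chars <- matrix("", n, L)
    for (m in seq_len(n)) {
      res <- anc
      subst <- stats::runif(L) < mu
      for (i in which(subst))
        res[i] <- sample(setdiff(RNA_BASES, anc[i]), 1)
      res[anc == "X"] <- "X"  # placeholders never mutate
      del <- stats::runif(L) < iota
      res[del] <- "-"
      site_chars[m, ] <- res
      ins <- stats::runif(L) < iota
      ins_chars[m, ins] <- sample(RNA_BASES, sum(ins), replace = TRUE)
    }
  })
  ## assemble the true alignment column by column
  cols <- list()
  for (i in seq_len(L)) {
    cols[[length(cols) + 1L]] <- site_chars[, i]
    if (any(ins_chars[, i] != ""))
      cols[[length(cols) + 1L]] <-
        ifelse(ins_chars[, i] == "", "-", ins_chars[, i])
  }
  rows <- apply(do.call(cbind, cols), 1, paste, collapse = "")
  ids <- sprintf("member%02d", seq_len(n))
  aln <- as_alignment(stats::setNames(rows, ids))
  members <- stats::setNames(gsub("-", "", rows), ids)
  structure(
    list(ancestor = residues, members = members, true_alignment = aln,
         params = list(n = n, mu = mu, iota = iota, seed = seed),
         planted_motifs = planted_motifs),
    class = "synthetic_family"
  )
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf(
    "Synthetic family: %d members from a %d-nt ancestor (mu %.3g, iota %.3g, seed %d)\n",
    length(x$members), nchar(x$ancestor), x$params$mu, x$params$iota,
    x$params$seed))
  invisible(x)
}

#' Generate a perfect hairpin sequence G^k A^L C^k
#'
#' Folds into a stem of k GC pairs around an L-residue loop under the
#' internal engine (for L >= min_loop); a k = 1 stem is a lone pair and is
#' pruned to score 0.
#'
#' @param stem_len k >= 1 stem pairs.
#' @param loop_len L >= 3 loop residues.
#' @return RNA string of length 2k + L.
#' @export
gen_hairpin <- function(stem_len, loop_len) {
  stopifnot(stem_len >= 1)
  if (loop_len < 3) stop("loop_len must be at least 3 (unfoldable loop)")
  paste0(strrep("G", stem_len), strrep("A", loop_len), strrep("C", stem_len))
}

#' Generate ideal helical coordinates
#'
#' Points on a regular helix (defaults loosely shaped like an A-form RNA
#' backbone trace): point k at angle `k * twist` on a circle of radius
#' `radius`, rising `rise` per step. Consecutive-point distances are
#' constant.
#'
#' @param n number of points (>= 3).
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @return A `coord_set`.
#' @export
gen_helix_coords <- function(n, rise = 2.8, twist = 32.7, radius = 9.4) {
  stopifnot(n >= 3)
  k <- seq_len(n) - 1
  theta <- k * twist * pi / 180
  coord_set(cbind(radius * cos(theta), radius * sin(theta), k * rise),
            id = sprintf("helix%d", n), atom_source = "synthetic")
}

#' Perturb coordinates with i.i.d. Gaussian noise
#'
#' @param coords a `coord_set` or n x 3 matrix.
#' @param sigma noise standard deviation per coordinate, Angstrom.
#' @param seed integer seed.
#' @return A `coord_set` with the same labels.
#' @export
perturb_coords <- function(coords, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  cs <- if (inherits(coords, "coord_set")) coords else coord_set(coords)
  pts <- withr::with_seed(seed,
    cs$points + matrix(stats::rnorm(length(cs$points), 0, sigma),
                       nrow(cs$points), 3))
  coord_set(pts, labels = cs$labels, id = paste0(cs$id, "_noise"),
            atom_source = cs$atom_source)
}
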