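## Internal secondary-structure engine: weighted base-pair maximisation
## (Nussinov-style dynamic programme) over nested structures with a
## minimum hairpin-loop size, followed by a single pruning pass that
## removes lone (unstacked) pairs. Scores are negated pair-weight sums in
## arbitrary units (<= 0), standing in for a free-energy scale; a
## thermodynamic engine can be plugged in through the `engine` argument
## of fold().

## 5x5 pairing-weight lookup over A/C/G/U/X. Unordered pairs; X pairs
## with nothing.
pair_weight_matrix <- function(weights = c(GC = 3, AU = 2, GU = 1)) {
  ab <- c(RNA_BASES, "X")
  W <- matrix(0, 5, 5, dimnames = list(ab, ab))
  for (nm in names(weights)) {
    b <- strsplit(nm, "")[[1]]
    W[b[1], b[2]] <- W[b[2], b[1]] <- unname(weights[nm])
  }
  W
}

## Maximum summed pair weight over nested structures; O(n^3) with a
## vectorised inner loop. Returns the DP matrix.
nussinov_dp <- function(wp, n, min_loop) {
  N <- matrix(0, n, n)
  if (n < min_loop + 2L) return(N)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in 1:(n - span)) {
      j <- i + span
      ks <- i:(j - min_loop - 1L)
      w <- wp[ks, j]
      best <- N[i, j - 1L]
      cand <- which(w > 0)
      if (length(cand)) {
        left_full <- if (length(ks) > 1L) c(0, N[i, ks[1]:(ks[length(ks)] - 1L)]) else 0
        vals <- left_full[cand] + w[cand] + N[cbind(ks[cand] + 1L, j - 1L)]
        best <- max(best, vals)
      }
      N[i, j] <- best
    }
  }
  N
}

## Recover one optimal pair set from the DP matrix (iterative stack;
## deterministic: the unpaired-j branch is preferred on ties, then the
## lowest pairing partner).
nussinov_traceback <- function(N, wp, n, min_loop) {
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    if (N[i, j] == N[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1L)) {
      if (wp[k, j] <= 0) next
      left <- if (k > i) N[i, k - 1L] else 0
      if (left + wp[k, j] + N[k + 1L, j - 1L] == N[i, j]) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  pairs
}

## Single pruning pass: a pair survives iff it has a stacked neighbour
## (i+1, j-1) or (i-1, j+1) in the *original* optimal pair set.
prune_lone_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  key <- paste(pairs[, 1], pairs[, 2])
  stacked <- paste(pairs[, 1] + 1L, pairs[, 2] - 1L) %in% key |
             paste(pairs[, 1] - 1L, pairs[, 2] + 1L) %in% key
  pairs[stacked, , drop = FALSE]
}

dot_bracket <- function(pairs, n) {
  s <- rep(".", n)
  if (nrow(pairs)) {
    s[pairs[, 1]] <- "("
    s[pairs[, 2]] <- ")"
  }
  paste(s, collapse = "")
}

#' Fold an RNA sequence with the internal weighted base-pair engine
#'
#' Maximises the summed pair weight (default GC = 3, AU = 2, GU wobble =
#' 1) over nested structures with hairpin loops of at least `min_loop`
#' unpaired bases, then prunes isolated pairs (no stacked neighbour) in a
#' single pass and recomputes the score from the surviving pairs.
#'
#' @param seq RNA string over A/C/G/U/X (X pairs with nothing).
#' @param min_loop minimum number of unpaired bases enclosed by a pair.
#' @param weights named pairing weights; names are unordered base pairs.
#' @param engine optional drop-in engine: a function `f(seq, min_loop)`
#'   returning a list with at least `structure` (dot-bracket) and `score`;
#'   when supplied it replaces the internal engine entirely, so a
#'   thermodynamic folder can be used for the same comparisons.
#' @return Object of class `fold_result`: list with `structure`
#'   (dot-bracket), `pairs` (matrix of 0-based i < j), `score` (post-
#'   pruning, <= 0), `dp_score` (pre-pruning optimum), `engine`.
#' @examples
#' fold("GGGAAACCC")$score  # -9: three stacked GC pairs
#' @export
fold <- function(seq, min_loop = 3, weights = c(GC = 3, AU = 2, GU = 1),
                 engine = NULL) {
  residues <- unname(seq[1])
  n <- nchar(residues)
  if (is.function(engine)) {
    res <- engine(residues, min_loop)
    stopifnot(is.list(res), !is.null(res$structure), !is.null(res$score))
    res$engine <- if (!is.null(res$engine)) res$engine else "external"
    class(res) <- "fold_result"
    return(res)
  }
  if (n < min_loop + 2L)
    return(structure(list(structure = strrep(".", n),
                          pairs = matrix(integer(0), ncol = 2,
                                         dimnames = list(NULL, c("i", "j"))),
                          score = 0, dp_score = 0, engine = "nussinov"),
                     class = "fold_result"))
  bases <- strsplit(residues, "")[[1]]
  W <- pair_weight_matrix(weights)
  idx <- match(bases, rownames(W))
  idx[is.na(idx)] <- 5L  # anything unexpected behaves like X
  wp <- W[idx, idx, drop = FALSE]
  N <- nussinov_dp(wp, n, min_loop)
  pairs <- nussinov_traceback(N, wp, n, min_loop)
  kept <- prune_lone_pairs(pairs)
  score <- if (nrow(kept)) -sum(wp[kept]) else 0
  kept0 <- kept - 1L
  colnames(kept0) <- c("i", "j")
  structure(list(structure = dot_bracket(kept, n), pairs = kept0,
                 score = score, dp_score = -N[1, n], engine = "nussinov"),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n")
  cat(sprintf("score %g (%s engine, %d pairs)\n", x$score, x$engine,
              nrow(x$pairs)))
  invisible(x)
}

#' Shuffle the nucleotides of a sequence (seeded Fisher-Yates)
#'
#' Uniform random permutation of the residues: length and mononucleotide
#' composition are preserved while any biological order is destroyed.
#'
#' @param seq RNA string.
#' @param seed integer seed; the same (seq, seed) always yields the same
#'   permutation.
#' @param dinucleotide if TRUE, shuffle non-overlapping dinucleotide
#'   blocks instead of single residues (sensitivity analysis; an odd
#'   trailing residue stays last).
#' @return Shuffled string.
#' @export
shuffle_sequence <- function(seq, seed, dinucleotide = FALSE) {
  residues <- unname(seq[1])
  if (nchar(residues) == 0L) stop("empty sequence")
  chars <- strsplit(residues, "")[[1]]
  withr::with_seed(seed, {
    if (dinucleotide) {
      nb <- length(chars) %/% 2L
      blocks <- vapply(seq_len(nb), function(b)
        paste(chars[(2 * b - 1):(2 * b)], collapse = ""), character(1))
      tail <- if (length(chars) %% 2L) chars[length(chars)] else ""
      paste0(paste(sample(blocks), collapse = ""), tail)
    } else paste(sample(chars), collapse = "")
  })
}

#' Generate shuffled null controls for a sequence
#'
#' @param seq RNA string.
#' @param n number of controls (the analysis default is three).
#' @param base_seed seed of the first control; control k uses
#'   `base_seed + k - 1`.
#' @param id parent identifier; controls are named `<id>_shuf1`, ...
#' @return Named character vector of n shuffled sequences. Warns if any
#'   two controls are identical (expected only for very short or
#'   homogeneous input).
#' @export
make_controls <- function(seq, n = 3, base_seed = 1, id = NULL) {
  stopifnot(n >= 1)
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  out <- vapply(seq_len(n), function(k)
    shuffle_sequence(seq, seed = base_seed + k - 1L), character(1))
  names(out) <- paste0(id, "_shuf", seq_len(n))
  if (anyDuplicated(out) && nchar(unname(seq[1])) >= 20L)
    warning("duplicate shuffled controls for '", id, "'")
  out
}

#' Classify biological-vs-control stability from score arithmetic
#'
#' `delta = bio - control_mean`. `delta <= -1` is `BIO_MORE_STABLE`,
#' `delta >= 1` is `CONTROL_MORE_STABLE`; within the open near-tie band
#' (|delta| < 1, the "less than one unit" rule) the label records which
#' side is lower: `NEAR_TIE_CONTROL_LOWER` when the control mean is
#' strictly below the biological score, `NEAR_TIE_CONTROL_HIGHER`
#' otherwise (exact ties included).
#'
#' @param bio biological fold score.
#' @param control_mean mean fold score of the shuffled controls.
#' @return Category string.
#' @export
mfe_category <- function(bio, control_mean) {
  delta <- bio - control_mean
  if (delta <= -1) "BIO_MORE_STABLE"
  else if (delta >= 1) "CONTROL_MORE_STABLE"
  else if (control_mean < bio) "NEAR_TIE_CONTROL_LOWER"
  else "NEAR_TIE_CONTROL_HIGHER"
}

#' Compare folding stability of a sequence against shuffled controls
#'
#' Folds the biological sequence and `n_shuffles` seeded nucleotide
#' shuffles with the same engine and parameters, averages the control
#' scores, and classifies the difference (see [mfe_category()]).
#'
#' @inheritParams fold
#' @param n_shuffles number of shuffled controls.
#' @param base_seed seed of the first control.
#' @param id sequence identifier for the report.
#' @return Object of class `mfe_report`: list with `sequence_id`,
#'   `bio_mfe`, `control_mfes`, `control_mean`, `delta`, `category`,
#'   `seeds`, `engine`.
#' @export
mfe_compare <- function(seq, n_shuffles = 3, base_seed = 1, min_loop = 3,
                        weights = c(GC = 3, AU = 2, GU = 1), engine = NULL,
                        id = NULL) {
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  bio <- fold(seq, min_loop = min_loop, weights = weights, engine = engine)
  controls <- make_controls(seq, n = n_shuffles, base_seed = base_seed, id = id)
  ctrl_scores <- vapply(controls, function(s)
    fold(s, min_loop = min_loop, weights = weights, engine = engine)$score,
    numeric(1))
  cm <- mean(ctrl_scores)
  structure(
    list(sequence_id = id, bio_mfe = bio$score,
         control_mfes = unname(ctrl_scores), control_mean = cm,
         delta = bio$score - cm, category = mfe_category(bio$score, cm),
         seeds = base_seed + seq_len(n_shuffles) - 1L, engine = bio$engine),
    class = "mfe_report"
  )
}

#' @export
print.mfe_report <- function(x, ...) {
  cat(sprintf("%s: bio %g vs control mean %g (delta %g) -> %s\n",
              x$sequence_id, x$bio_mfe, x$control_mean, x$delta, x$category))
  invisible(x)
}
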