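## Rigid-body structure comparison: one point per nucleotide, Kabsch
## least-squares superposition, and a length-normalised TM-style score
## with the >= 0.45 same-family convention.

#' Construct a coordinate set
#'
#' @param points numeric matrix (n x 3) of coordinates in Angstrom.
#' @param labels residue labels (default 1..n).
#' @param id identifier.
#' @param atom_source which atom the points came from.
#' @return Object of class `coord_set`.
#' @export
coord_set <- function(points, labels = NULL, id = "coords",
                      atom_source = "synthetic") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 3, all(is.finite(points)))
  if (is.null(labels)) labels <- as.character(seq_len(nrow(points)))
  structure(list(id = id, points = unname(points), labels = labels,
                 atom_source = atom_source),
            class = "coord_set")
}

#' @export
print.coord_set <- function(x, ...) {
  cat(sprintf("coord_set '%s': %d points (%s)\n", x$id, nrow(x$points),
              paste(unique(x$atom_source), collapse = "/")))
  invisible(x)
}

#' Read one-point-per-nucleotide coordinates from a PDB file
#'
#' Uses the bio3d PDB reader and keeps one atom per residue: the selected
#' atom (C3' by default, both C3' and C3* spellings accepted), falling
#' back to the alternate atom (P) for residues where it is absent.
#' Chain and insertion codes are preserved in the labels.
#'
#' @param path PDB file with ATOM records.
#' @param atom `"C3'"` or `"P"`; the other serves as fallback.
#' @return A `coord_set`; `atom_source` records, per point, which atom was
#'   used.
#' @export
read_coords <- function(path, atom = c("C3'", "P")) {
  atom <- match.arg(atom)
  fallback <- if (atom == "C3'") "P" else "C3'"
  spellings <- function(a) if (a == "C3'") c("C3'", "C3*") else a
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no nucleotide coordinates")
  ins <- at$insert
  ins[is.na(ins)] <- ""
  res_key <- paste(at$chain, at$resno, ins, sep = "|")
  keys <- unique(res_key)
  rows <- vapply(keys, function(k) {
    idx <- which(res_key == k)
    hit <- idx[at$elety[idx] %in% spellings(atom)]
    if (length(hit) == 0L) hit <- idx[at$elety[idx] %in% spellings(fallback)]
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }, integer(1))
  used <- !is.na(rows)
  if (!any(used)) stop("no nucleotide coordinates")
  rows <- rows[used]
  pts <- cbind(at$x[rows], at$y[rows], at$z[rows])
  src <- ifelse(at$elety[rows] %in% spellings(atom), atom,
                paste0(fallback, " (fallback)"))
  coord_set(pts, labels = keys[used],
            id = sub("\\.pdb$", "", basename(path)), atom_source = src)
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation of B that minimises the RMSD
#' to A over matched points (reflections are corrected via the SVD
#' determinant sign).
#'
#' @param A,B numeric matrices (n x 3), n >= 3, matched row-by-row.
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3; transformed B is
#'   `B %*% t(rotation) + translation`), `rmsd` (Angstrom), and
#'   `degenerate` (TRUE when 3 collinear points make the rotation
#'   non-unique; a valid optimum is still returned).
#' @export
kabsch <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, ncol(B) == 3, nrow(A) >= 3)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bt <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - Bt)^2)))
  ## 3 collinear points leave a rotation degree of freedom; flag but
  ## still return the (non-unique) optimum
  degenerate <- nrow(A) == 3 && (qr(Ac)$rank < 2 || qr(Bc)$rank < 2)
  structure(list(rotation = R, translation = as.numeric(ca - cb %*% t(R)),
                 rmsd = rmsd, degenerate = isTRUE(degenerate)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition: rmsd %.4f A%s\n", x$rmsd,
              if (x$degenerate) " (degenerate: collinear triple)" else ""))
  invisible(x)
}

## Length-dependent distance scale, floored at 1 A for short chains.
tm_d0 <- function(L) max(0.6 * sqrt(L - 0.5) - 2.5, 1.0)

#' TM-style structural similarity score
#'
#' Iterative refinement: superpose the template onto the target over the
#' current pair subset (initially all corresponded pairs), compute
#' per-pair distances d_i, score
#' `tm = (1/L_norm) * sum(1 / (1 + (d_i/d0)^2))` over all corresponded
#' pairs, then re-select the pairs with d_i < d0 for the next
#' superposition; iterate to a fixed point (at most 20 rounds) and report
#' the maximum score over rounds. `L_norm` is the target length and
#' `d0 = max(0.6 * sqrt(L_norm - 0.5) - 2.5, 1)` Angstrom.
#'
#' @param target,template `coord_set` objects (or n x 3 matrices).
#' @param correspondence two-column matrix of (target, template) indices
#'   (1-based); default is the identity mapping, which requires equal
#'   lengths.
#' @return Object of class `tm_result`: list with `tm`, `L_norm`, `d0`,
#'   `n_aligned`, `same_family` (tm >= 0.45), `rounds`.
#' @export
tm_score <- function(target, template, correspondence = NULL) {
  P <- if (inherits(target, "coord_set")) target$points else as.matrix(target)
  Q <- if (inherits(template, "coord_set")) template$points else as.matrix(template)
  if (is.null(correspondence)) {
    if (nrow(P) != nrow(Q))
      stop("different lengths: supply an explicit correspondence")
    correspondence <- cbind(seq_len(nrow(P)), seq_len(nrow(P)))
  }
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) < 3L) stop("need at least 3 corresponded pairs")
  stopifnot(max(correspondence[, 1]) <= nrow(P),
            max(correspondence[, 2]) <= nrow(Q))
  L <- nrow(P)
  d0 <- tm_d0(L)
  tp <- P[correspondence[, 1], , drop = FALSE]
  tq <- Q[correspondence[, 2], , drop = FALSE]

  subset <- seq_len(nrow(correspondence))
  best <- 0
  rounds <- 0L
  for (it in seq_len(20L)) {
    rounds <- it
    sup <- kabsch(tp[subset, , drop = FALSE], tq[subset, , drop = FALSE])
    moved <- tq %*% t(sup$rotation) +
      matrix(sup$translation, nrow(tq), 3, byrow = TRUE)
    d <- sqrt(rowSums((tp - moved)^2))
    best <- max(best, sum(1 / (1 + (d / d0)^2)) / L)
    nxt <- which(d < d0)
    if (length(nxt) < 3L || identical(nxt, subset)) break
    subset <- nxt
  }
  structure(list(tm = best, L_norm = L, d0 = d0,
                 n_aligned = nrow(correspondence),
                 same_family = best >= 0.45, rounds = rounds),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("TM = %.5f (L_norm %d, d0 %.2f A, %d pairs) -> %s\n",
              x$tm, x$L_norm, x$d0, x$n_aligned,
              if (x$same_family) "same family (>= 0.45)" else "below 0.45"))
  invisible(x)
}

#' Same-family call from a TM score
#'
#' @param tm score in (0, 1].
#' @return TRUE iff `tm >= 0.45`.
#' @export
family_call <- function(tm) {
  if (!is.numeric(tm) || length(tm) != 1L || is.na(tm) || tm <= 0 || tm > 1)
    stop("tm must lie in (0, 1]")
  tm >= 0.45
}
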