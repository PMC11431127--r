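## Independent reference implementations used as oracles. These are
## deliberately naive (loops, exhaustive enumeration, grid search) and
## share no code with the package internals they check.

## Per-position set lookup for a codon against an IUPAC triple.
oracle_pattern_match <- function(codon, pattern) {
  classes <- list(
    A = "A", C = "C", G = "G", U = "U",
    R = c("A", "G"), Y = c("C", "U"), M = c("A", "C"), K = c("G", "U"),
    S = c("C", "G"), W = c("A", "U"), B = c("C", "G", "U"),
    D = c("A", "G", "U"), H = c("A", "C", "U"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "U"))
  cb <- strsplit(codon, "")[[1]]
  pb <- strsplit(pattern, "")[[1]]
  all(vapply(1:3, function(i) cb[i] %in% classes[[pb[i]]], logical(1)))
}

## Quadratic reference decomposition for one fixed frame: walk triplets
## one by one, open/close fragments explicitly.
oracle_decompose_fixed <- function(seq, members, frame) {
  n <- nchar(seq)
  frags <- list()
  cur_start <- NA
  pos <- frame
  while (pos + 3 <= n) {
    trip <- substr(seq, pos + 1, pos + 3)
    if (trip %in% members) {
      if (is.na(cur_start)) cur_start <- pos
    } else if (!is.na(cur_start)) {
      frags[[length(frags) + 1]] <- c(cur_start, pos)
      cur_start <- NA
    }
    pos <- pos + 3
  }
  if (!is.na(cur_start)) frags[[length(frags) + 1]] <- c(cur_start, pos)
  if (length(frags) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, frags)
  data.frame(start = m[, 1], end = m[, 2])
}

## Exhaustive maximum over all nested structures: enumerate every set of
## non-crossing pairs satisfying the loop constraint and score it.
oracle_max_weight <- function(seq, min_loop = 3,
                              weights = c(GC = 3, AU = 2, GU = 1)) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  wt <- function(i, j) {
    key <- paste0(sort(c(bases[i], bases[j])), collapse = "")
    w <- c(CG = unname(weights["GC"]), AU = unname(weights["AU"]),
           GU = unname(weights["GU"]))
    if (key %in% names(w)) unname(w[key]) else 0
  }
  best <- 0
  rec <- function(i, j) {
    ## returns max weight of [i, j] by explicit branching on position i
    if (i >= j) return(0)
    if (j - i <= min_loop) return(0)
    res <- rec(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      w <- wt(i, k)
      if (w > 0) res <- max(res, w + rec(i + 1, k - 1) + rec(k + 1, j))
    }
    res
  }
  rec(1, n)
}

## Single-superposition TM oracle: one least-squares fit over all pairs
## (inline SVD, no package code), no pair re-selection.
oracle_tm_single <- function(P, Q) {
  ca <- colMeans(P); cb <- colMeans(Q)
  Pc <- sweep(P, 2, ca); Qc <- sweep(Q, 2, cb)
  s <- svd(t(Qc) %*% Pc)
  d <- sign(det(s$v %*% t(s$u))); if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- Qc %*% t(R)
  dist <- sqrt(rowSums((Pc - moved)^2))
  L <- nrow(P)
  d0 <- max(0.6 * sqrt(L - 0.5) - 2.5, 1.0)
  sum(1 / (1 + (dist / d0)^2)) / L
}

## Dense rotation-grid + local-refinement RMSD oracle (Euler angles).
oracle_best_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    a <- ang[1]; b <- ang[2]; c <- ang[3]
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((Ac - Bc %*% t(rotmat(ang)))^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  bgrid <- seq(0, pi, length.out = 7)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in bgrid) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  opt <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

## Random RNA string of length n (seeded).
random_rna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "U"), n, TRUE),
                               collapse = ""))
}

## Random proper rotation matrix (seeded).
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(9), 3)
    q <- qr(M)
    R <- qr.Q(q)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}
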