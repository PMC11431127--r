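## Small PDB text fixture written at test time: 5 residues with C3'
## atoms, one residue missing C3' but carrying P.
write_toy_pdb <- function(path, drop_c3_res = NULL) {
  helix <- gen_helix_coords(5)$points
  lines <- character(0)
  serial <- 0
  for (r in 1:5) {
    for (atom in c("P", "C3'")) {
      if (atom == "C3'" && r %in% drop_c3_res) next
      serial <- serial + 1
      xyz <- helix[r, ] + if (atom == "P") 0.5 else 0
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        serial, atom, "  G", "A", r, xyz[1], xyz[2], xyz[3], 1.0, 0.0))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("PDB reading picks one atom per residue with P fallback", {
  pdb <- write_toy_pdb(tempfile(fileext = ".pdb"))
  cs <- read_coords(pdb)
  expect_s3_class(cs, "coord_set")
  expect_equal(nrow(cs$points), 5)
  expect_true(all(cs$atom_source == "C3'"))

  pdb2 <- write_toy_pdb(tempfile(fileext = ".pdb"), drop_c3_res = 3)
  cs2 <- read_coords(pdb2)
  expect_equal(nrow(cs2$points), 5)
  expect_equal(sum(grepl("fallback", cs2$atom_source)), 1)

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_coords(empty), "no nucleotide coordinates")
})

test_that("Kabsch superposition recovers rigid transforms exactly", {
  A <- gen_helix_coords(10)$points
  expect_lt(kabsch(A, A)$rmsd, 1e-10)
  expect_equal(kabsch(A, A)$rotation, diag(3), tolerance = 1e-8)

  R <- random_rotation(4)
  B <- A %*% t(R) + matrix(c(5, -3, 12), 10, 3, byrow = TRUE)
  sup <- kabsch(A, B)
  expect_lt(sup$rmsd, 1e-8)
  expect_equal(sup$rotation %*% t(sup$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
  ## the returned transform actually moves B onto A
  moved <- B %*% t(sup$rotation) +
    matrix(sup$translation, 10, 3, byrow = TRUE)
  expect_equal(moved, A, tolerance = 1e-6)
})

test_that("Kabsch rmsd matches a dense rotation-grid brute force on small toys", {
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  bent <- square; bent[3, ] <- bent[3, ] + c(0, 0, 1)
  expect_equal(kabsch(square, bent)$rmsd, oracle_best_rmsd(square, bent),
               tolerance = 1e-3)
  for (s in 1:5) {
    A <- withr::with_seed(s, matrix(stats::rnorm(18), 6, 3))
    B <- withr::with_seed(s + 50, A + matrix(stats::rnorm(18, 0, 0.3), 6, 3))
    expect_equal(kabsch(A, B)$rmsd, oracle_best_rmsd(A, B), tolerance = 1e-3)
  }
})

test_that("collinear 3-point input is flagged degenerate but still answered", {
  line <- cbind(0:2, 0, 0)
  sup <- kabsch(line, line)
  expect_true(sup$degenerate)
  expect_lt(sup$rmsd, 1e-10)
})

test_that("TM score is 1 for identical and rigidly moved structures", {
  h <- gen_helix_coords(30)
  expect_equal(tm_score(h, h)$tm, 1.0, tolerance = 1e-12)
  R <- random_rotation(7)
  moved <- coord_set(h$points %*% t(R) +
                       matrix(c(-4, 9, 2), 30, 3, byrow = TRUE))
  res <- tm_score(h, moved)
  expect_equal(res$tm, 1.0, tolerance = 1e-8)
  expect_true(res$same_family)
  expect_equal(res$L_norm, 30)
  expect_equal(res$d0, max(0.6 * sqrt(30 - 0.5) - 2.5, 1))
})

test_that("TM score is invariant under rigid transforms of either input", {
  h <- gen_helix_coords(25)
  noisy <- perturb_coords(h, sigma = 1.5, seed = 2)
  base_tm <- tm_score(h, noisy)$tm
  for (s in 1:5) {
    R <- random_rotation(100 + s)
    t_ <- withr::with_seed(200 + s, stats::rnorm(3, 0, 10))
    move <- function(cs) coord_set(cs$points %*% t(R) +
                                     matrix(t_, nrow(cs$points), 3, byrow = TRUE))
    expect_equal(tm_score(move(h), noisy)$tm, base_tm, tolerance = 1e-6)
    expect_equal(tm_score(h, move(noisy))$tm, base_tm, tolerance = 1e-6)
  }
})

test_that("iterative TM agrees with the single-superposition oracle at sigma 1", {
  h <- gen_helix_coords(30)
  diffs <- vapply(1:10, function(s) {
    noisy <- perturb_coords(h, sigma = 1, seed = 300 + s)
    got <- tm_score(h, noisy)$tm
    want <- oracle_tm_single(h$points, noisy$points)
    expect_gte(got, want - 1e-12)   # pair re-selection can only help
    got - want
  }, numeric(1))
  ## agreement holds in expectation; single seeds can gain a little more
  ## from refinement
  expect_lt(mean(abs(diffs)), 0.02)
  expect_true(all(abs(diffs) < 0.05))
})

test_that("TM decreases with noise magnitude in expectation", {
  h <- gen_helix_coords(30)
  tm_at <- function(sigma) vapply(1:10, function(s)
    tm_score(h, perturb_coords(h, sigma, seed = 400 + s))$tm, numeric(1))
  t05 <- tm_at(0.5); t1 <- tm_at(1); t2 <- tm_at(2); t4 <- tm_at(4)
  expect_gt(mean(t05), mean(t1))
  expect_gt(mean(t1), mean(t2))
  expect_gt(mean(t2), mean(t4))
  expect_gte(mean(tm_score(h, perturb_coords(h, 1, seed = 1))$tm >
               tm_score(h, perturb_coords(h, 4, seed = 1))$tm), 1)
})

test_that("family call has a sharp boundary at 0.45 and validates range", {
  expect_true(family_call(0.45))
  expect_false(family_call(0.449))
  expect_true(family_call(1.0))
  expect_error(family_call(0))
  expect_error(family_call(1.2))
  expect_error(tm_score(gen_helix_coords(3)$points[1:2, ],
                        gen_helix_coords(3)$points[1:2, ]))
})
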