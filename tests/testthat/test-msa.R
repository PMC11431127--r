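make_aln <- function(...) as_alignment(c(...))

test_that("alignment construction validates and normalises", {
  a <- make_aln(r1 = "ACGU", r2 = "ACGU", r3 = "ACGU")
  expect_equal(a$n_rows, 3)
  expect_equal(a$n_cols, 4)
  expect_error(as_alignment(c(a = "ACGU")), "at least 2 rows")
  expect_error(as_alignment(c(a = "ACGU", b = "ACG")),
               "row length mismatch: b")
  ## T -> U, '.' -> '-', stray symbols -> X
  a2 <- make_aln(x = "acgt", y = ".?gu")
  expect_equal(unname(a2$seqs), c("ACGU", "-XGU"))
})

test_that("aligned FASTA and Clustal files round-trip through the readers", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 first", "AC-GUACGUACG", ">s2", "ACGGUACG-ACG",
               ">s3", "ACGGUACGUACG"), fa)
  a <- read_alignment(fa, "fasta")
  expect_equal(a$n_rows, 3)
  expect_equal(a$n_cols, 12)
  expect_equal(a$ids[1], "s1 first")

  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "s1   ACGUACGUACGU", "s2   ACGUAC..ACGU", "",
               "s1   ACGU", "s2   ACGU"), cl)
  b <- read_alignment(cl, "clustal")
  expect_equal(b$n_rows, 2)
  expect_equal(b$n_cols, 16)
  expect_equal(substr(b$seqs[["s2"]], 7, 8), "--")  # '.' gaps normalised

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGU", ">b", "ACGUA"), ragged)
  expect_error(read_alignment(ragged, "fasta"), "row length mismatch: b")
})

test_that("consensus follows the majority rule with ties and gap policy", {
  ident <- make_aln(a = "GAUUACA", b = "GAUUACA", c = "GAUUACA")
  expect_equal(consensus(ident)$sequence, "GAUUACA")

  tied <- make_aln(a = "A", b = "A", c = "C", d = "C")
  cs <- consensus(tied, threshold = 0.5)
  expect_equal(cs$sequence, "A")    # tie broken by base order A < C
  expect_true(cs$tie[1])
  expect_equal(cs$fraction[1], 0.5)

  gappy <- make_aln(a = "AG", b = "-G", c = "-G")
  expect_equal(consensus(gappy, gap_policy = "mark")$sequence, "-G")
  dropped <- consensus(gappy, gap_policy = "drop")
  expect_equal(dropped$sequence, "G")
  expect_equal(dropped$kept_columns, 1L)

  ## below-threshold plurality gives N; threshold 0 gives plurality;
  ## threshold 1 requires unanimity
  mixed <- make_aln(a = "A", b = "A", c = "C", d = "G")
  expect_equal(consensus(mixed, threshold = 0.75)$sequence, "N")
  expect_equal(consensus(mixed, threshold = 0)$sequence, "A")
  expect_equal(consensus(make_aln(a = "A", b = "A", c = "A"),
                         threshold = 1)$sequence, "A")
  expect_equal(consensus(make_aln(a = "A", b = "A", c = "C"),
                         threshold = 1)$sequence, "N")
})

test_that("conservation profile is the max-base fraction over rows", {
  a <- make_aln(r1 = "AAAA", r2 = "ACA-", r3 = "AG--", r4 = "AU--")
  expect_equal(conservation_profile(a), c(1, 0.25, 0.5, 0.25))
  gaps <- make_aln(r1 = "-", r2 = "-")
  expect_equal(conservation_profile(gaps), 0)
})

test_that("logo information content matches the closed forms", {
  allg <- as_alignment(stats::setNames(rep("G", 10), paste0("r", 1:10)))
  lg_off <- logo(allg, small_sample_correction = FALSE)
  expect_equal(lg_off$info, 2.0)
  expect_equal(lg_off$G, 2.0)
  expect_equal(lg_off$A + lg_off$C + lg_off$U, 0)

  lg_on <- logo(allg, small_sample_correction = TRUE)
  expect_equal(lg_on$info, 2 - 3 / (2 * log(2) * 10), tolerance = 1e-12)

  unif <- make_aln(a = "A", b = "C", c = "G", d = "U")
  expect_equal(logo(unif, small_sample_correction = FALSE)$info, 0)

  ## correction defaults on below 50 rows, off at 50+
  big <- as_alignment(stats::setNames(rep("G", 50), paste0("r", 1:50)))
  expect_equal(logo(big)$info, 2.0)
  expect_lt(logo(allg)$info, 2.0)
})

test_that("logo heights are non-negative, sum to info, and info stays in [0,2]", {
  for (s in 1:10) {
    fam <- evolve_family(random_rna(40, seed = s), n = 8, mu = 0.2,
                         iota = 0.05, seed = s)
    lg <- logo(fam$true_alignment)
    expect_true(all(lg$info >= 0 & lg$info <= 2))
    expect_true(all(lg[, c("A", "C", "G", "U")] >= 0))
    expect_equal(rowSums(lg[, c("A", "C", "G", "U")]), lg$info,
                 tolerance = 1e-12)
  }
})

test_that("duplicating a row never decreases any column's max-base fraction", {
  fam <- evolve_family(random_rna(30, seed = 3), n = 6, mu = 0.3, seed = 3)
  aln <- fam$true_alignment
  ## duplicate the row that carries each column's current majority? A
  ## weaker but sufficient check: duplicate each row in turn and compare
  ## winning fractions among non-gap symbols
  frac_nongap <- function(a) {
    m <- do.call(rbind, strsplit(unname(a$seqs), ""))
    apply(m, 2, function(col) {
      ng <- col[col != "-"]
      if (!length(ng)) return(0)
      max(table(factor(ng, levels = c("A", "C", "G", "U"))))
    })
  }
  base_max <- frac_nongap(aln)
  for (i in seq_len(aln$n_rows)) {
    dup <- as_alignment(c(aln$seqs, stats::setNames(aln$seqs[i], "dup")))
    expect_true(all(frac_nongap(dup) >= base_max))
  }
})

test_that("mean conservation decreases with the substitution rate", {
  anc <- random_rna(300, seed = 99)
  mean_cons <- function(mu) {
    mean(vapply(1:6, function(s)
      mean(conservation_profile(
        evolve_family(anc, n = 20, mu = mu, iota = 0, seed = s)$true_alignment)),
      numeric(1)))
  }
  c0 <- mean_cons(0); c1 <- mean_cons(0.1); c5 <- mean_cons(0.5)
  expect_equal(c0, 1.0)
  expect_gt(c0, c1)
  expect_gt(c1, c5)
})
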