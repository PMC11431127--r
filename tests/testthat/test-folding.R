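test_that("DP optimum equals exhaustive enumeration on short random sequences", {
  for (s in 1:60) {
    n <- sample(4:12, 1)
    seq <- random_rna(n, seed = 7000 + s)
    f <- fold(seq)
    expect_equal(-f$dp_score, oracle_max_weight(seq), info = seq)
  }
})

test_that("canonical examples fold as expected", {
  f <- fold("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$score, -9)
  expect_equal(nrow(f$pairs), 3)

  expect_equal(fold("AAAA")$score, 0)
  expect_equal(fold("AAAA")$structure, "....")
  expect_equal(fold("GC")$score, 0)

  h <- fold(gen_hairpin(6, 4))
  expect_equal(h$score, -18)
  expect_equal(nrow(h$pairs), 6)
  expect_equal(h$structure, "((((((....))))))")
})

test_that("lone pairs are pruned; pruning keeps structures valid and nested", {
  lone <- fold(gen_hairpin(1, 3))
  expect_equal(lone$score, 0)
  expect_equal(lone$structure, ".....")
  for (s in 1:20) {
    seq <- random_rna(sample(10:40, 1), seed = 8000 + s)
    f <- fold(seq)
    expect_lte(abs(f$score), abs(f$dp_score))
    p <- f$pairs
    if (nrow(p) > 0) {
      expect_true(all(p[, 2] - p[, 1] > 3))                 # min loop
      expect_false(anyDuplicated(c(p)) > 0)                 # one pair/pos
      ## non-crossing: for any two pairs, nested or disjoint
      if (nrow(p) > 1) for (a in 1:(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
        i <- p[a, ]; j <- p[b, ]
        crossing <- (i[1] < j[1] && j[1] < i[2] && i[2] < j[2]) ||
                    (j[1] < i[1] && i[1] < j[2] && j[2] < i[2])
        expect_false(crossing)
      }
      ## every surviving pair Watson-Crick or wobble
      bases <- strsplit(seq, "")[[1]]
      for (a in seq_len(nrow(p))) {
        pr <- paste0(sort(bases[p[a, ] + 1]), collapse = "")
        expect_true(pr %in% c("CG", "AU", "GU"))
      }
      ## dot-bracket consistent with the pair list
      expect_equal(sum(strsplit(f$structure, "")[[1]] == "("), nrow(p))
    }
  }
})

test_that("fold score has no 5'/3' bias: reverse-complement symmetry (WC weights)", {
  wc <- c(GC = 3, AU = 2)  # wobble off: GU maps to AC under revcomp
  revcomp <- function(s) chartr("ACGU", "UGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (s in 1:15) {
    seq <- random_rna(sample(8:30, 1), seed = 9000 + s)
    expect_equal(fold(seq, weights = wc)$dp_score,
                 fold(revcomp(seq), weights = wc)$dp_score, info = seq)
  }
  ## with wobble weights the symmetry genuinely fails: a GU pair maps to
  ## an unpairable AC under reverse complement
  expect_equal(fold("GAAAU")$dp_score, -1)
  expect_equal(fold(revcomp("GAAAU"))$dp_score, 0)
})

test_that("shuffling preserves composition, is seeded, and fixes degenerate input", {
  seq <- random_rna(50, seed = 1)
  sh <- shuffle_sequence(seq, seed = 11)
  expect_equal(sort(strsplit(sh, "")[[1]]), sort(strsplit(seq, "")[[1]]))
  expect_identical(sh, shuffle_sequence(seq, seed = 11))
  expect_false(identical(sh, shuffle_sequence(seq, seed = 12)))
  expect_equal(shuffle_sequence("AAAA", seed = 3), "AAAA")
  ## dinucleotide mode preserves dinucleotide multiset
  sh2 <- shuffle_sequence(seq, seed = 5, dinucleotide = TRUE)
  blocks <- function(x) sort(substring(x, seq(1, 49, 2), seq(2, 50, 2)))
  expect_equal(blocks(sh2), blocks(seq))
})

test_that("controls are seeded, suffixed, and pairwise distinct for rich input", {
  seq <- random_rna(60, seed = 2)
  ctrl <- make_controls(seq, base_seed = 100, id = "x")
  expect_length(ctrl, 3)
  expect_equal(names(ctrl), c("x_shuf1", "x_shuf2", "x_shuf3"))
  expect_equal(anyDuplicated(ctrl), 0)
  expect_identical(ctrl, make_controls(seq, base_seed = 100, id = "x"))
  expect_length(make_controls(seq, n = 1, base_seed = 1), 1)
})

test_that("stability categories partition the (bio, control) plane", {
  expect_equal(mfe_category(-10, -5), "BIO_MORE_STABLE")
  expect_equal(mfe_category(-5, -10), "CONTROL_MORE_STABLE")
  expect_equal(mfe_category(-5, -5.5), "NEAR_TIE_CONTROL_LOWER")
  expect_equal(mfe_category(-5.5, -5), "NEAR_TIE_CONTROL_HIGHER")
  expect_equal(mfe_category(-5, -5), "NEAR_TIE_CONTROL_HIGHER")
  ## closed boundary at |delta| = 1
  expect_equal(mfe_category(-6, -5), "BIO_MORE_STABLE")
  expect_equal(mfe_category(-4, -5), "CONTROL_MORE_STABLE")
  ## totality: exactly one label for a sweep of deltas
  for (b in seq(-8, 0, by = 0.25)) for (m in seq(-8, 0, by = 0.25))
    expect_length(mfe_category(b, m), 1)
})

test_that("mfe_compare wiring: stated-arithmetic example and seed capture", {
  rep <- mfe_compare(gen_hairpin(6, 4), base_seed = 21, id = "hp")
  expect_equal(rep$bio_mfe, -18)
  expect_equal(rep$control_mean, mean(rep$control_mfes))
  expect_equal(rep$delta, rep$bio_mfe - rep$control_mean)
  expect_equal(rep$seeds, 21:23)
  expect_equal(rep$category, mfe_category(rep$bio_mfe, rep$control_mean))
  ## a perfect stem is destroyed by shuffling: planted hairpin wins
  expect_equal(rep$category, "BIO_MORE_STABLE")
})

test_that("planted hairpins beat their shuffles in almost every seeding", {
  hp <- gen_hairpin(6, 4)
  wins <- vapply(1:40, function(s)
    mfe_compare(hp, base_seed = s * 3)$category == "BIO_MORE_STABLE",
    logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("a drop-in external engine is honoured end to end", {
  flat <- function(seq, min_loop) list(structure = strrep(".", nchar(seq)),
                                       score = -nchar(seq), engine = "flat")
  f <- fold("GGGAAACCC", engine = flat)
  expect_equal(f$score, -9)
  expect_equal(f$engine, "flat")
  rep <- mfe_compare("GGGAAACCC", engine = flat, base_seed = 1)
  expect_equal(rep$delta, 0)  # length-only engine: all scores equal
  expect_equal(rep$engine, "flat")
})
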