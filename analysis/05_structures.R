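#!/usr/bin/env Rscript
## Structural comparison on toy helical coordinate sets: TM-style score
## under rigid transforms and increasing coordinate noise, with the
## same-family call at 0.45.

suppressMessages(library(exgcrna))
dir.create("results", showWarnings = FALSE)
seed <- 20260926

helix <- gen_helix_coords(30)
message("Ideal 30-point helix; d0 = ",
        round(tm_score(helix, helix)$d0, 3), " A")

rows <- list()
for (sigma in c(0, 0.5, 1, 2, 4)) {
  tms <- vapply(1:10, function(s)
    tm_score(helix, perturb_coords(helix, sigma, seed = seed + s))$tm,
    numeric(1))
  rows[[length(rows) + 1]] <- data.frame(
    sigma = sigma, mean_tm = mean(tms), sd_tm = sd(tms),
    same_family_rate = mean(tms >= 0.45))
}
noise <- do.call(rbind, rows)
print(noise)
message("TM falls monotonically with noise; at sigma = 0 the score is ",
        "exactly 1 and the same-family call always fires.")

R <- withr::with_seed(seed, {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
})
moved <- coord_set(helix$points %*% t(R) +
                     matrix(c(12, -4, 7), 30, 3, byrow = TRUE))
sup <- kabsch(helix$points, moved$points)
message(sprintf("Rigidly moved copy: Kabsch rmsd %.2e A, TM %.5f",
                sup$rmsd, tm_score(helix, moved)$tm))

write.table(noise, "results/tm_vs_noise.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Wrote results/tm_vs_noise.tsv")
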