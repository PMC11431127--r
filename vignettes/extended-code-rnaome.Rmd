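---
title: "Decomposing RNA under ancestral codon repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing RNA under ancestral codon repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exgcrna)
```

## The model

A widely discussed account of genetic-code evolution starts from a
primaeval code (PGC) of the 16 triplets matching the pattern RNY — purine,
any base, pyrimidine — and reaches the standard code (SGC, all 64 triplets)
through two complementary routes. Reading RNY strings out of frame adds the
patterns NYR and YRN, giving the 48-triplet extended code Ex1; transversions
in the first or third position add YNY and RNR instead, giving the
48-triplet extended code Ex2. The two extended codes share 32 triplets
(RNY itself plus RYR and RYR's pyrimidine mirror YRY) and jointly cover all
64; only Ex1 contains the three stop codons UAA/UGA/UAG.

`exgcrna` asks, for a given RNA sequence: which parts of it *could* have
been encoded at each evolutionary stage? The operational answer is a
**decomposition**: scan the sequence as non-overlapping triplets, discard
triplets outside the chosen repertoire, and keep the maximal runs of member
triplets as coordinate-preserving fragments. Derived quantities are the
coverage (fraction of residues inside fragments), the recovery status of
known functional motifs (the fraction of a motif occurrence covered by
fragments), the folding stability of the reassembled fragments relative to
shuffled controls, per-column summaries of alignments of such fragments, and
a TM-style comparison of reconstructed 3D coordinate sets.

## Reading frames

Nothing fixes a reading frame for non-coding RNA, so `decompose()` supports
three policies. `fixed(f)` scans triplets starting at offset `f` in
`{0, 1, 2}`; `best` keeps the fixed frame with the highest coverage (ties to
the lowest frame); `union`, the default, reports the fragments of all three
fixed scans and counts each residue once. Union is deliberately permissive:
it plays the role of the low-stringency fragment-recovery step of a
database-search pipeline while remaining exact and coordinate-true. The
policy is recorded in every output so downstream readers can tell which
convention produced a number. Coordinates are 0-based half-open throughout;
trailing sub-triplet remainders of a frame are never counted as covered, and
motif-recovery fractions count residue positions, not triplets.

Non-ACGU input characters become the placeholder `X` rather than raising an
error, and any triplet containing `X` is a non-member of every repertoire —
ambiguity codes in genome-scale FASTA simply stream through as uncovered
positions.

## The motif library

Six built-in motifs cover the functional signatures the decomposition
analysis targets: the minimal anti-Shine–Dalgarno core `CCUCC` and its
two organism-specific 3'-end contexts `GAUCACCUCC` and `AUCACCUCCU`, the
universally conserved SRP-RNA helix-8 decamer `GAAGCAGCCA`, the RNase P RNA
signature `GAGGAAMGUCC` (IUPAC `M` = A or C, the amino bases), and the tRNA
acceptor end `CCA`. Matching is plain IUPAC class matching with overlaps
allowed; `X` never matches. On the worked anti-SD context `GAUCACCUCC` the
union-frame decomposition covers positions `[0, 7)` under Ex1 and the whole
string under Ex2, so the core occurrence at `[5, 10)` is recovered at
fraction 2/5 by Ex1 and fully by Ex2 — the same asymmetry holds for the
RNase P signature under both readings of `M`.

## The folding engine and the control comparison

The secondary-structure engine is a weighted base-pair maximiser: a
Nussinov-style dynamic programme over nested structures with hairpin loops
of at least `min_loop = 3` unpaired bases, pair weights GC = 3, AU = 2,
GU = 1, and a score equal to minus the summed weight of the optimal pair
set. After the optimum is found, isolated pairs — pairs with neither
stacked neighbour `(i+1, j-1)` nor `(i-1, j+1)` in the optimal set — are
removed in a single pass and the score is recomputed from the survivors
(the pass is not iterated, so a pair whose only partner was itself pruned
survives; this keeps the rule simple and order-independent). The engine is
a stand-in on a deliberately abstract energy scale, not a thermodynamic
model; `fold(engine =)` accepts any drop-in function returning a structure
and score, so a thermodynamic folder can be substituted without touching
the comparison logic.

Stability is judged against **thrice-shuffled controls**: seeded uniform
permutations of the nucleotides, which preserve length and mononucleotide
composition while destroying order (a dinucleotide-preserving mode exists
behind a flag for sensitivity analysis). The category rules operate on
`delta = bio - mean(controls)`: `BIO_MORE_STABLE` at `delta <= -1`,
`CONTROL_MORE_STABLE` at `delta >= 1`, and inside the open band
`|delta| < 1` ("less than one unit") a near-tie label recording whether the
control mean is strictly lower or not; an exact tie is reported as
`NEAR_TIE_CONTROL_HIGHER`. Seeds are mandatory and recorded in every
report; no hidden RNG state is used anywhere.

Two numerical notes. First, the weight model is symmetric for Watson–Crick
pairs under reverse complementation, but a GU wobble pair maps to an
unpairable AC, so fold scores are only reverse-complement invariant when
wobble pairs carry no weight; the property suite checks the invariance in
the Watson–Crick-only model and documents the wobble counterexample.
Second, traceback ties prefer leaving the 3'-most base unpaired, making the
reported structure deterministic.

## Alignment summaries

Alignments are inputs, not something the package computes. The consensus is
simple extended majority: per column, the most frequent base among non-gap
symbols wins when its fraction reaches the threshold (default 0.5),
otherwise `N`; majority-gap columns are marked `-` or dropped; ties break by
the fixed order A < C < G < U and are flagged. The placeholder `X` counts in
the non-gap denominator but cannot win a column — a column of only `X`
yields `N`. The conservation profile is the max-base count over the number
of rows, a deliberately simple statistic for the grey conservation strip
(gap-only columns score 0; heavy gapping therefore reads as low
conservation, which is the intended visual semantics). Logos follow the
classic information-content convention: column information `2 - H` bits,
minus the small-sample correction `3 / (2 ln 2 n)` when enabled (default: on
below 50 rows), floored at zero, with letter heights `frequency x info`.

## Structure comparison

Coordinate sets are one point per nucleotide (C3' by default, falling back
to P), read from PDB ATOM records via `bio3d`. Superposition is standard
Kabsch least squares with reflection correction. The similarity score is a
TM-style iteration: superpose on the current pair subset, score all
corresponded pairs as `sum(1 / (1 + (d_i/d0)^2)) / L_norm`, re-select the
pairs within `d0`, and repeat to a fixed point (at most 20 rounds),
reporting the maximum. `L_norm` is the **target** length and
`d0 = max(0.6 sqrt(L_norm - 0.5) - 2.5, 1)` Å, the published RNA
convention with a 1 Å floor for short chains; exact parity with any
particular web server is not claimed. The correspondence is an explicit
input (identity by default when lengths match) — no structural alignment
search is performed. Scores of at least 0.45 are called same-family.

## The synthetic generators

The generators replace a multi-genome input corpus with controlled
truth-known data, sized so every statistical check runs in seconds:

* `gen_code_sequence()` draws triplets uniformly from a repertoire (with
  probability `purity`, default 1) or its complement. Uniform draws give
  closed-form cross-code expectations — a pure-Ex1 sequence has expected
  fixed-frame Ex2 coverage `32/48 ≈ 0.667` — which the tests verify at
  2000 triplets with a binomial-scale tolerance of 0.03.
* `plant_motif()` overwrites a window with a concrete motif instance and
  records the interval and the replaced text.
* `evolve_family()` derives members by per-site substitution (rate `mu`),
  deletion and single-base insertion (rate `iota` each), and constructs the
  exact true alignment from the edit records; indels are single-base so the
  alignment is trivially constructible and gap-stripping reproduces the
  members. Default family sizes in the analyses are 15–20 members of
  250–300 nt over substitution rates 0–0.5, a range wide enough to order
  conservation statistics monotonically.
* `gen_hairpin()` emits `G^k A^L C^k`, whose optimal structure under the
  internal engine is a k-pair GC stem (score `-3k`; a k = 1 stem is a lone
  pair and prunes to 0).
* `gen_helix_coords()` places points on a regular helix (defaults rise
  2.8 Å, twist 32.7°, radius 9.4 Å, loosely shaped like an A-form backbone
  trace) and `perturb_coords()` adds seeded i.i.d. Gaussian noise.

What the generators do **not** emulate: codon-usage bias, base
modification, covariation between paired positions, realistic indel length
distributions, and genuinely homologous 3D folds. Passing tests on this
material therefore demonstrates the correctness of the computations and the
detectability of planted signal, not biological conclusions about real
RNAomes.

## The report

`run_report()` ties the stages together: for every sequence and every
configured repertoire it records coverage and fragment counts, folds the
**reassembled fragment concatenation** (matching the idea of analysing the
per-code reconstruction; `fold_scope = "raw"` switches to the full
sequence), compares it against seeded shuffles, and scores the motif
library. Control seeds are derived deterministically from the master seed
and the row index, and the JSON sidecar written by `write_report()` records
every parameter needed to recompute any cell. Regeneration with the same
seed is byte-identical.

## Known limitations

The energy scale is internal, so stability categories are comparable within
an engine but not against published thermodynamic values. The union frame
policy is this package's construction and is flagged in output metadata.
The conservation statistic and the consensus rule are simple conventions
chosen for transparency, not reimplementations of any particular suite.
Tyrosine's placement in both extended codes follows strict set membership
and is flagged in the amino-acid table where the literature convention
differs. TM scores here are for toy, point-per-residue models; they are not
comparable to scores between experimentally determined structures.
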