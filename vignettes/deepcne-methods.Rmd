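---
title: "Statistical methods behind deepcne"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind deepcne}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

deepcne detects conserved non-coding elements (CNEs): short stretches of
regulatory DNA that remain alignable between genomes separated by very
large evolutionary distances.  At such distances a single whole-genome
comparison is hopeless — any alignment strong enough to clear a
genome-scale significance threshold has long since decayed — so the
package combines three ideas:

1. **Calibrated E-values.**  Every alignment score is converted to an
   expected count of equal-or-better chance alignments, using Gumbel
   (extreme-value) parameters fitted to the actual scoring scheme and
   search engine.
2. **A cascade of searches with shrinking search spaces.**  Regions
   conserved between close relatives are carried forward as the *query*
   for a search against a more distant genome.  Because the E-value is
   proportional to the product of query and target lengths, shrinking
   the query makes borderline similarities significant without changing
   the alignments themselves.
3. **Gene-context rescue.**  A candidate too weak for the strict
   threshold is still accepted if its flanking genes in query and
   target are known homologs — chance alignments have no reason to land
   next to homologous genes.

This vignette explains how each part works and how the package verifies
them.  The companion README shows the end-to-end pipeline; here we focus
on the statistics.

```{r load}
library(deepcne)
```

## Scoring schemes

Alignments are scored with a nucleotide substitution matrix plus affine
gap costs.  The default scheme is match +5, mismatch −4, gap open −10,
gap extension −4, chosen for distant, A+T-rich genomes:

```{r scheme}
sch <- scoring_scheme()
sch$substitution_matrix
c(gap_open = sch$gap_open, gap_extend = sch$gap_extend)
```

`N` characters take the worst mismatch score against everything and are
excluded from seeding, so masked or ambiguous sequence can never anchor
or inflate an alignment.

## Gumbel statistics and E-values

For local alignment of random sequences, the number of distinct
alignments scoring at least $s$ is approximately Poisson with mean

$$E(s) = K \, m \, n \, e^{-\lambda s}$$

where $m$ and $n$ are the query and target lengths and $\lambda, K$
depend on the scoring scheme and the background base composition.  For
*ungapped* alignment $\lambda$ is available analytically as the unique
positive root of $\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$; the package
exposes this via `solve_lambda_ungapped()`.  For a uniform base
composition and a ±1 match/mismatch matrix the root is exactly
$\ln 3 \approx 1.0986$, which makes a convenient analytic anchor:

```{r lambda-analytic}
pm1 <- scoring_scheme(match = 1, mismatch = -1, gap_open = NA)
solve_lambda_ungapped(pm1, gc_content = 0.5)
log(3)
```

For *gapped* alignment no closed form exists, so `calibrate_gumbel()`
estimates $(\lambda, K)$ by simulation against random sequences of the
requested base composition.  The calibration runs in three passes:

1. **Pilot.**  A small set of exact (dynamic-programming) alignments of
   random sequence pairs gives a rough Gumbel fit by the method of
   moments, which sets sensible score floors for the later passes.
2. **λ from exact island scores.**  The tail decay rate is estimated
   from the distinct locally-optimal alignment ("island") scores of
   exact alignments: if island scores above a floor $s_0$ are
   geometric on the score lattice, then
   $\hat\lambda = \log(1 + 1/\overline{s - s_0})$.  Using the *exact*
   optimum here matters — a heuristic engine misses a score-dependent
   fraction of weak alignments, which flattens the apparent tail and
   biases $\lambda$ downward.
3. **K at the operating point.**  With $\lambda$ fixed, $K$ is set so
   that the *heuristic engine's* observed island counts at a
   realistically high score floor match the Poisson model:
   $\hat K = \bar c \, e^{\lambda s_1} / (mn)$.  Any residual
   sensitivity loss of the seed-and-extend engine is thereby absorbed
   into $K$, so reported E-values describe what the engine actually
   finds.

```{r calibrate, eval = FALSE}
gum <- calibrate_gumbel(sch, gc_content = 0.40, seed = 1L)
gum
#> Gumbel parameters: lambda = 0.192, K = 0.21
```

The decisive check of a calibration is the **reversed-sequence
control**: align real queries against a *reversed* (not
reverse-complemented) target.  Reversal preserves length and
composition but destroys homology, so every hit is a chance hit, and a
correct calibration must yield, on average, about $t$ hits at
$E \le t$ — independent of the search-space size, because $m n$ appears
in the E-value itself.  `reversed_control()` packages this check and
the pipeline runs it automatically.

## The search engine

`local_align()` is a seed-and-extend local aligner:

* **Two-hit seeding.**  Candidate diagonals need either two
  non-overlapping exact word matches (word length 6 by default) on the
  same diagonal within a 64-base window, or a single long run.  This
  drastically cuts extension work in large searches while keeping
  sensitivity for genuinely similar regions.
* **X-drop gapped extension** from each trigger, with affine gaps.
* **Exact fallback.**  Small problems (few enough dynamic-programming
  cells) are solved exactly with full Smith–Waterman, so small searches
  are optimal by construction.  The test suite verifies that the
  heuristic path reproduces exact optimal scores on planted homologies
  and agrees with `Biostrings::pairwiseAlignment()` on random pairs.

Searches may cover both strands of the target; the effective search
space (and hence every E-value) is doubled accordingly.

## The cascade

The E-value formula is where the cascade gets its power.  Suppose two
close genomes share 1 Mb of conserved regions found in a first-stage
comparison.  A second-stage search that uses only those regions as the
query against a distant 174 Mb genome has its E-values reduced by a
factor of 174 relative to an all-vs-all comparison — the same alignment
score becomes two orders of magnitude more significant, with no change
to the alignment itself.

`staged_search()` implements one stage: it extracts the query subset
(`search_space()` records lengths and the reduction factor), runs the
aligner, converts scores to E-values with the calibrated parameters,
and maps hit coordinates back to the full genome.  `run_pipeline()`
chains stages according to a configurable plan: stage 1 compares the
two closest genomes in full, `merge_hits_to_regions()` +
`subtract_annotated()` turn the hits into a masked set of conserved
non-coding regions, and later stages search those regions against
progressively more distant genomes.

Masking matters because coding sequence is both more conserved and less
interesting here: exons, UTRs, structural-RNA genes and pseudogenes
(see `default_excluded_categories()`) are subtracted from the conserved
regions before they are carried forward, so the cascade spends its
search space on candidate regulatory DNA only.

## Acceptance rules

`accept_candidates()` applies a two-tier decision to every candidate:

* $E \le$ `strict_evalue` (default $10^{-4}$): accepted outright.
* `strict_evalue` $< E \le$ `relaxed_evalue` (default 10): accepted
  only if the nearest gene to the query hit and the nearest gene to the
  target hit are known homologs (`is_homolog()` on an orthology table).
  Otherwise the candidate is recorded with reason
  `nearest_genes_not_homologous`.
* $E >$ `relaxed_evalue`: rejected with reason `evalue_above_relaxed`.

The relaxed path is what makes marginal E-values (say, $E \approx 0.5$,
meaning half a chance hit expected genome-wide) usable: the probability
that a chance hit additionally lands next to the correct homologous
gene pair is small enough to tip the balance.

## Annotating accepted elements

Accepted elements are classified by `classify_element()` with a fixed
precedence: *promoter* (overlapping a TSS window) beats *utr3* beats
*intron* (wholly contained) beats the default *enhancer*.
`relative_geometry()` reports upstream/downstream position in the
gene's reading direction and whether query and target elements have the
same relative orientation — a single consistent inversion across
species is itself evidence of a real, orientation-tolerant element.

`scan_boxes()` searches aligned element sequences for short
transcription-factor binding boxes (E-box `CANNTG`, CCAAT, CArG
`CCWWWWWWGG`, a Wnt response element `CTTTG`) and reports perfectly
and near-perfectly conserved occurrences, with IUPAC degeneracy and
strand conventions per motif (CCAAT is scanned on both strands, so a
forward-text `ATTGG` is reported as a reverse-strand CCAAT; the E-box
and CArG are palindromic so only the forward strand is scanned; the
Wnt element is forward-only).

## The synthetic truth set

Because no real pair of genomes comes with known regulatory elements,
the package ships a generator (`fixture_config()` + `build_truth_set()`)
that *plants* the truth: three species are evolved from common
ancestral sequence with realistic divergence, each gene locus carrying
upstream/intronic/downstream regulatory elements under stronger
constraint than the background.  The fixture also plants traps:

* **confounder elements** present in only one species — any "conserved"
  hit on them is a false positive;
* neutral background — strict-threshold hits there are false positives;
* exactly **one inverted element** in the third species — the pipeline
  must report that flip and no others.

`score_truth()` compares pipeline output against the planted truth and
reports recall, confounder hits, background hits and orientation flips.
Because every sequence is generated from a seed, the whole
benchmark is reproducible and text-only.

## Reproducing the numbers

The acceptance script runs the full set of checks (reversed-sequence
control calibration, analytic λ anchors, aligner-vs-reference
agreement, cascade reduction factors, fixture recall, acceptance-rule
semantics, motif semantics) and writes the computed quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

See the README for the expected contents and runtimes.
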