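---
title: "Predicting conserved small RNAs from TSS maps and intrinsic terminators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting conserved small RNAs from TSS maps and intrinsic terminators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaflow)
```

## The problem and the model

Bacterial small regulatory RNAs (sRNAs) are short non-protein-coding
transcripts, here taken as 45–350 nt, that act mostly post-transcriptionally.
Purely computational genome-wide screens must guess which intergenic
sequences are transcribed at all; differential RNA-Seq (dRNA-Seq) removes
that guess by mapping every active transcription start site (TSS). srnaflow
implements the resulting predictive scheme for organisms with such a TSS
map, with heterocystous cyanobacteria as the motivating system:

1. **Orphan TSS selection.** A TSS supported by at least `min_reads` reads
   in some sequencing library and lying in an intergenic region — not
   inside any gene, and more than `ntss_distance` (200) nt upstream of the
   nearest same-strand gene start — is an *nTSS*, a plausible sRNA promoter.
   TSSs inside same-strand genes (iTSS), inside opposite-strand genes
   (aTSS), or gene-associated (gTSS) are excluded. Both boundaries of a gene
   count as inside it.
2. **Terminator pairing.** Transcription of an sRNA typically ends at a
   Rho-independent terminator: an RNA hairpin followed by a uridine-rich
   tract. Every same-strand terminator whose hairpin lies fully downstream
   of an nTSS defines a putative transcript from the TSS through the
   hairpin, excluding the poly-U tail. Transcripts outside the
   `[min_len, max_len]` = [45, 350] nt window are discarded, and for each
   TSS only the shortest surviving transcript is kept, since RNA polymerase
   most likely stops at the first terminator it meets. Several TSSs may
   legitimately share one terminator.
3. **Family collapse.** Near-identical genomic copies and TSS clusters
   feeding one terminator are collapsed: an undirected graph connects two
   candidates when their sequences are near-identical (local alignment
   identity ≥ 0.95 over ≥ 0.90 of the shorter sequence) *or* when they share
   a terminator, and families are the connected components (single
   linkage). One representative is chosen per family: the member with the
   most reads or, among members whose read totals are within a factor of 2
   of the maximum, the member with the most homologs.
4. **Conservation profiling.** Each candidate is searched against a panel
   of related genomes. A genome carries a homolog when at least one local
   hit covers at least `min_query_coverage` = 35% of the query; presence is
   binary per genome, whatever the number of hits, and multi-contig
   assemblies are searched contig by contig. Candidates whose homologs fall
   only in a designated clade (here: heterocystous strains) are flagged
   clade-exclusive.
5. **Small-ORF screen.** Strong cross-genome conservation of a candidate
   sometimes reflects a hidden protein: homolog sets are aligned and
   scanned for small ORFs whose substitution pattern is biased toward the
   third (mostly synonymous) codon position.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 8 | reads (max over libraries) supporting a TSS |
| `ntss_distance` | 200 nt | upstream margin that makes a TSS gene-associated |
| `min_len`, `max_len` | 45, 350 nt | transcript window, hairpin included, poly-U excluded |
| `min_query_coverage` | 0.35 | fraction of the query a homology hit must span |
| `max_evalue` | 10 | e-value cutoff for imported BLAST hits only |
| `table_min_homologs` | 11 | clade table shows "more than 10" in-clade homologs |
| `map_min_homologs` | 10 | presence map shows "at least 10" total homologs |
| `reads_similarity_factor` | 2 | read totals within 2x count as similar |
| `orf_alpha` | 0.05 | significance level of the ORF permutation test |
| `min_alignment_seqs` | 4 | alignment rows required ("more than three") |

Two display thresholds coexist deliberately: the clade-exclusive table
requires *more than* 10 in-clade homologs while the presence map shows
candidates with *at least* 10 total homologs; both are configurable because
the two surfaces serve different purposes (a shortlist versus an overview).

The read threshold is applied to the **maximum** single-library count, not
the sum: a TSS active in only one condition should not be penalized for
being silent in the others. This choice is configurable in spirit by
pre-aggregating the table.

## Design choices in the open spots

* **Window before shortest.** The size window is applied before the
  shortest-segment rule. The alternative — nearest terminator first, window
  second — silently drops a TSS whose nearest terminator is closer than 45
  nt even when a perfectly good in-window terminator follows; it remains
  available via `shortest_after_window = FALSE`.
* **Downstream means the whole hairpin.** A hairpin straddling the TSS
  cannot terminate that transcript, so `hairpin_lo >= position` (forward)
  is required, not merely hairpin end past the TSS.
* **Ties in pairing.** Equal-length segments prefer the higher-scoring
  terminator, then the more compact hairpin; ties in representative choice
  fall back to higher reads, then the lexicographically smallest id. All
  tie-breaks are deterministic so runs are reproducible.
* **Gene-boundary TSSs** count as internal (`start <= pos <= end`).
* **Circular replicons.** Origin-spanning segments are not formed; the
  flag is carried but only documents the topology.
* **Family criterion.** "Near-identical copies" is concretized as ≥95%
  identity over ≥90% of the shorter sequence under match +1 / mismatch −1 /
  gap −2 local alignment. Merging same-terminator candidates in the same
  connected-components pass is equivalent to performing the two collapses
  sequentially, because single-linkage closure is order-independent.

## Built-in stand-ins for external tools

The pipeline treats terminator calling, homology search and multiple
alignment as exchangeable backends. External results are imported through
their standard formats (TransTermHP report text, 12-column BLAST tabular,
aligned FASTA). The built-in backends exist so the pipeline and its tests
run with zero external dependencies; each is deliberately simple enough to
verify against brute-force oracles:

* **Terminator detector** (`predict_terminators()`): perfect hairpin stems
  only (pairs G-C = 3, A-U = 2, G-U = 1; no mismatches or bulges), stem
  4–18 bp, loop 3–10 nt, hairpin score ≥ 12, then a 7 nt tail window with
  ≥ 4 U's and a U at tail position 1 or 2. Thresholds were chosen so a
  canonical terminator (≥6 bp GC stem, U6 tail) always passes. No
  free-energy model; mismatch-free stems make the detector less sensitive
  than TransTermHP, which is acceptable because the default path is the
  parser.
* **Homology search** (`seed_extend_search()`): exact 11-mer seeds on both
  subject strands, ungapped extension with match +1 / mismatch −2 and
  X-drop 12, overlapping hits merged best-first. Score thresholds replace
  e-values; the 35% query-coverage rule is the operative filter anyway, as
  the default BLASTn e-value of 10 is nearly vacuous at these lengths.
  Because extension is ungapped, sensitivity degrades for indel-rich
  homologs; the panel generator is substitution-only for the same reason.
* **Multiple aligner** (`center_star_align()`): center-star with the
  center chosen by shared 6-mer counts, global alignment match +1 /
  mismatch −1 / gap −2, merged under once-a-gap-always-a-gap.
* **Coding statistic** (`scan_conserved_orfs()`): replaces a full
  phylogenetic codon model with the signal at its core — substitutions in a
  real protein-coding region accumulate at the third codon position. With
  per-codon-position substitution counts `n1, n2, n3` against the reference
  (gap or ambiguous columns skipped), the score is `S = n3/(n1+n2+n3)`, and
  its null distribution comes from shuffling the column order within the
  ORF span; `p = (1 + #{S_perm >= S_obs})/(B + 1)`. ORFs with fewer than 5
  substitutions are reported conserved-but-untestable with `p = 1` rather
  than assigned a meaningless score. A Shine–Dalgarno-like AGGAGG hexamer
  (≤1 mismatch) 4–13 nt upstream of the ATG/GTG start is reported as RBS
  evidence. Published p-values from tree-aware codon models are not
  reproducible by this statistic; only the qualitative coding/non-coding
  call at the same significance level is comparable.

## What the synthetic generator emulates

`simulate_dataset()` produces a complete, fully reproducible dataset from a
seed: a multi-replicon genome (41% GC, typical of the motivating organisms)
with planted sRNA loci (45–350 nt, strong GC stem-loop terminators with U7
tails), decoy genes, decoy terminators, and decoy TSSs of three classes
that each exercise one filter — sub-threshold read support, position inside
a gene, and no terminator within the size window. A genome panel carries
substitution-mutated copies of the planted loci, a configurable fraction of
them restricted to the designated clade, and optionally a small ORF with an
RBS whose homolog copies mutate preferentially at third codon positions.

Placement is blockwise with at least 400 nt between elements. That spacing
is what makes the ground truth exact: planted loci stay intergenic, decoy
"no-terminator" TSSs really have no terminator within 350 nt, and no decoy
terminator can shadow a planted one under the shortest-segment rule.

Real data are messier in ways the generator deliberately omits: overlapping
features, processed 5' ends, indel divergence between homologs, chance
hairpins inside transcribed regions, and compositional heterogeneity. A
green test suite on synthetic data therefore demonstrates that the
algorithmic contracts hold, not that the biological error rates on a real
genome are zero — on real inputs the precision of the scheme is bounded by
the quality of the TSS annotation and the terminator prediction, exactly as
for the original analysis.

## Numerical and scale choices

Default simulated conditions are two 25 kb replicons, 8 planted loci, 12
decoy TSSs, a 12-genome panel with a 6-genome clade, and 5% per-site
homolog divergence; the test suite uses smaller instances (single 14 kb
replicon, 3 loci, 6-genome panel) where many seeds are iterated. Property
checks compare against brute-force oracles at the sizes where brute force
is exact and fast: pairing instances up to 50×50, clustering instances up
to 40 segments, local-alignment pairs up to 300 nt, permutation toys of 12
columns (495 enumerable label subsets). The permutation test uses B = 1000
by default (resolution ~0.001); seeded so results are reproducible.

Degenerate inputs are defined, not special-cased: an empty panel gives
all-zero profiles, a TSS with no downstream terminator yields no segment,
an alignment with no start codon yields no ORF calls, and ambiguous bases
(N) never match, pair, or count as substitutions.

## Known limitations

* No gapped extension in the built-in homology backend; diverged homologs
  with indels are undercounted relative to BLASTn.
* No bulged or mismatched stems in the built-in terminator detector.
* Origin-spanning candidates on circular replicons are not formed.
* The coding statistic ignores phylogenetic non-independence of the
  homolog rows; closely related carriers inflate substitution counts less
  than independent ones would.

## A worked run

```{r example, eval = FALSE}
d <- tempfile()
ds <- simulate_dataset(sim_params(seed = 7), d)
res <- run_predict(file.path(d, "genome.fasta"), file.path(d, "tss.tsv"),
                   genes = file.path(d, "genes.gff3"),
                   terminators = file.path(d, "terminators.txt"),
                   panel = file.path(d, "panel"),
                   clade_file = file.path(d, "clade.txt"))
glance(res)                                   # stage counts
tidy(res)                                     # one row per entry
evaluate_predictions(ds$truth, res$segments, res$profiles)
autoplot(res$profiles, min_homologs = 4)      # presence map
```
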