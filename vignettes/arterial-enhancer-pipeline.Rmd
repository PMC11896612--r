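---
title: "Characterizing arterial endothelial enhancers with artenh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing arterial endothelial enhancers with artenh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artenh)
```

## The problem

Arterial endothelial cells (ECs) express a characteristic gene programme
(*Efnb2*, *Cxcr4*, *Gja5*, *Unc5b*, ...) whose cis-regulatory control is
poorly mapped. Candidate enhancers are nominated from chromatin evidence —
open chromatin (ATAC-seq, DNaseI hypersensitivity), EP300 co-activator
binding, and H3K27Ac/H3K4Me1 histone modification — but most marked
regions have no independent enhancer activity in vivo. `artenh`
implements the downstream analysis of such a screen: cross-species
candidate calling, motif scanning with conservation tiers, peak-based
binding calls, reporter-assay activity classification, and class-wise
summaries.

## The putative-enhancer rule

Candidate regions over a locus are the merged union of all mark intervals
(marks closer than the merge gap, default 500 bp, are fused). The
deterministic merge is a surrogate for by-eye region selection in a
genome browser; the original visual procedure cannot be reproduced
exactly, which is why the packaged worked examples for the published
tables supply evidence matrices directly rather than re-deriving regions
from signal.

A candidate is **putative** when

- the neighbouring gene is transcribed in the human EC datasets (open
  chromatin/H3K4Me3 at the promoter, an input here) and the region
  carries ≥ 1 mark in both mouse and human EC datasets, or
- the gene is poorly transcribed in human ECs and the region carries
  marks in ≥ 2 distinct mouse datasets (the relaxed rule; we read "two
  enhancer marks" as two datasets, not two intervals of one track).

Overlap means ≥ 1 bp everywhere; the source analysis never quantifies a
minimum overlap, and 1 bp is the weakest assumption. Marks whose
enrichment extends to many non-EC cell types still count but are
propagated with a `nonspecific` flag. Human datasets are queried through
an explicit orthology block map (source span → target span, TSV) rather
than a chain-file liftover engine: the screen's own orthology came from
browser alignments, and a block map keeps the pipeline self-contained.
Regions that map to no block record every human dataset as absent with an
`unmapped` note.

## Enhancer naming

Enhancers are named `<gene><sign><kb>`: the distance from the enhancer
midpoint to the TSS, rounded to the nearest kb (ties away from zero),
signed by transcription orientation (`-` upstream, `+` downstream; a
zero-kb distance renders `+0`). Whether distance should be measured to
the midpoint or the nearest edge is not specified by the convention we
follow; the midpoint is symmetric under representation of the span and is
what we adopt. Names therefore deviate from the exact base-pair distance
by < 500 bp.

## Motif scanning and conservation tiers

Cores are scanned with IUPAC consensi on both strands
(`Biostrings::matchPattern`, consensus codes expanded, sequence letters
literal — an `N` in the sequence matches only an `N` consensus position).
All overlapping hits are reported; summaries use existence (the `M`/`m`
encoding), not counts, so no greedy masking is needed.

The default consensus set carries ETS `HGGAAR` and RBPJ `TGGGAA` from the
source analysis; the remaining families (SOX `WWCAAW`, FOX `RYAAAYA`,
MEF2 `CTAWWWWTAG`, NR2F2 `TGACCT`, KLF4 `GGGGNGGGG`, TCF/LEF `CTTTGWW`,
SMAD `GGCGCC`) are standard literature consensi. They are deliberate
placeholders — the screen's own motif table is not published in machine-
readable form — and every function accepts a user motif TSV
(`read_motifs()`); the `provenance` attribute marks which set is in use.
Note that some standard consensi (MEF2, SMAD) are IUPAC palindromes, so
any concrete instance matches both strands by construction.

A FOX hit immediately 5′ of an ETS hit on the same strand with ≤ 2 bp gap
(configurable) is a FOX:ETS composite; its FOX half does not count as an
independent FOX site. The composite geometry is our own precise reading
of the compound element; the source analysis states no numeric criterion.

Conservation is classified against a per-enhancer alignment (aligned
multi-FASTA, reference species first). Let `D_e` be the species whose row
covers ≥ 50% of the core with non-gap bases (the enhancer's conservation
depth) and `D_m` the species whose bases at the hit's columns still match
the consensus (gaps fail). The tier is **strong** when human ∈ `D_m` and
`D_e ⊆ D_m` ("conserved to the same depth as the surrounding sequence"
made precise as a subset relation), **weak** when human matches but some
aligning species does not, **none** when the human row fails. The 50%
coverage threshold is a design choice: it separates a species that merely
aligns patchily from one genuinely carrying the orthologous enhancer, and
tier calls are insensitive to it in the synthetic tests because simulated
rows either align fully or not at all.

## Binding and co-occupancy

An enhancer is bound by a TF when its span overlaps any peak (≥ 1 bp; no
summit extension, no reciprocal-overlap requirement — deposited peak
spans are used as-is). Status `C` requires any corresponding motif, and a
weak (`m`) motif suffices: the status encoding does not restrict
correspondence to strong motifs. `peakset_overlap_fraction()` reports,
for a reference peak set, the fraction of its peaks overlapped by each
query set, by their union, and by all jointly; bounds
(`joint ≤ each ≤ union`) are property-tested. Recomputing the published
SOX17 co-occupancy percentages requires the deposited CUT&RUN peak data
and is supported but not packaged.

## Activity classification

An enhancer is active when GFP-positive embryos exceed 5% of injected
embryos, *strictly* — exactly 5.0% is inactive, following the wording
"more than 5%". The weak category (faint GFP or GFP limited to a few
ECs) is qualitative and enters as an input flag splitting actives into
`active_strong`/`active_weak`; it is never computed from counts. A
vein-restricted enhancer remains "active" under this rule —
arteriovenous pattern is carried by a separate label, not by the activity
rule. Whether the denominator should exclude dead or uninjectable embryos
is unknowable from printed counts; counts are taken as printed.

## Class summaries and the enrichment contrast

`tabulate_status()` counts, per TF family and enhancer class, the
enhancers whose status falls in a chosen set (`{M}`, `{M, m}`, `{C}`,
`{C, c}`), stored as `(k, n)`. `enrichment_contrast()` formalizes
"over-represented" as a two-sided exact hypergeometric test (summation of
equally-or-less-probable tables) with a sample odds ratio, Haldane 0.5
correction when a cell is zero; the source analysis reports raw fractions
only, so the test is explicitly labelled an extension, and raw p-values
are reported without a multiplicity policy. In silico labels are opaque
strings matched exactly ("Arterial enhancer", "Common EC enhancer",
"Arterial TSS", "Common EC TSS", "Uncalled"); no re-derivation from
signal is attempted.

## The synthetic cohort

`generate_locus()`/`generate_cohort()` emulate the screen's input side
with exact ground truth:

- a random-background locus (GC 0.45) with planted enhancer cores;
- concrete motif instances written in at specified positions/strands,
  with cores *scrubbed* of incidental consensus matches (randomized
  single-base substitutions outside planted spans, iterated until the
  recovered hit set equals the plant specification);
- per-dataset mark intervals covering planted spans, plus noise marks
  that avoid planted spans and each other by more than the merge gap, so
  noise stays single-dataset and cannot fabricate evidence;
- a six-species ladder (mouse, human, dog, cow, opossum, chicken) with
  geometrically increasing substitution rates (0.10–0.42) standing in
  for a vertebrate alignment; orthologous rows preserve or disrupt each
  motif instance exactly per its planted tier. Substitution is per-base
  without indels inside cores, so alignment columns are trivial — tier
  logic, not aligner behaviour, is under test;
- peaks jittered around planted spans (sd 50 bp, clamped to keep ≥ 1 bp
  overlap) and binomial assay counts at planted activity rates
  (arterial 0.5, pan-EC 0.3, decoys/inactive 0.01 or 0; 100 injected
  embryos per assay, the scale of the real screen).

The default cohort plants 8 loci named for the screen's arterial genes
with 41 putative enhancers in total plus one single-mark decoy per locus;
three loci are flagged poorly transcribed in human to exercise the
relaxed rule. Fixed seeds give byte-identical bundles.

What the simulator does *not* emulate: signal-level data (everything is
already intervals), indels and rearrangement in alignments, correlated
noise between datasets, and partial peak/mark overlap at region
boundaries. Passing the synthetic truth-recovery tests therefore shows
the decision logic is implemented exactly as specified, not that the
rules themselves are robust to real-data ambiguity — that evidence comes
from the packaged table-derived checks.

Problem sizes were chosen for fast, deterministic test runs: 64 kb loci,
6 enhancers + 1 decoy per locus, 2 noise marks per track, and n = 500
injections where a binomial tail bound is asserted.

## Numerical and degenerate-input choices

- Coordinates are BED-convention 0-based half-open at every I/O
  boundary and converted once to 1-based `GRanges` internally.
- Rounding in names: nearest kb, ties away from zero.
- `n_injected = 0` is an error, not an inactive call.
- Empty reference peak sets error; empty query sets give fraction 0.
- Candidate merging with `merge_gap = g` fuses marks separated by ≤ g bp.
- Ties and ordering: hits sort by start then strand; tables are invariant
  to input order (property-tested).

## Known limitations

- The default motif consensi are placeholders; published per-family
  tallies are only reproducible with the original motif definitions
  supplied as a TSV.
- The orthology block map does not model inversions or split blocks.
- The candidate-construction surrogate cannot reproduce a by-eye screen
  region-for-region; published counts that depend on it (e.g. "over 110
  regions considered") are not recomputable.
- The exact enrichment test is an extension, not a reproduction.
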