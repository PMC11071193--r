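---
title: "Methods: alignment-based curation of TE consensus sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-based curation of TE consensus sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tecurate)
```

This vignette documents the models, rules and numerical choices behind
`tecurate`, in the spirit of a methods section: what each step assumes,
which knobs exist, and what the simulation-based tests do and do not
demonstrate.

## The curation loop

A draft consensus is refined by a mine–extend–align–rebuild loop:

1. **Copy mining** (`find_copies`). An internal seed-and-extend local
   search: exact k-mer seeds (`k = 11`, sampled every third query
   position), grouped into candidate windows by diagonal (±40) and
   positional gap (≤ 400 bp), each window then locally aligned to the
   query with affine gaps (match +1, mismatch −2, gap open 5, gap
   extend 1). Hits report identity, coordinates, strand and score in the
   common 12-column tabular dialect; minus strand is encoded by
   `sstart > send`. An imported hit table may replace the internal search,
   preserving fidelity to workflows that ran the search externally.
2. **Selection and extension** (`select_and_extend`). The best 20 hits by
   bit score (ties: longer alignment, then contig and coordinate — the
   ordering is fixed so reruns are reproducible) are each extended by
   2000 bp per side, clipped at contig bounds, never merged: one hit, one
   interval. `extract_oriented` reverse-complements minus-strand
   intervals so every copy is in consensus orientation.
3. **Star alignment** (`build_star_msa`). Each copy is aligned to the
   anchor (the current consensus) globally with free end gaps, and the
   pairwise alignments are projected onto anchor coordinates. Copy
   insertions become anchor-gap column blocks sized by the largest
   insertion at that anchor position; flank overhangs are stacked against
   the nearest aligned column (left overhangs right-justified, right
   overhangs left-justified), so homologous flanking sequence occupies
   comparable columns. Alignments that clip up to 30 anchor-edge
   positions still stack at the terminal block: a noisy anchor terminus
   otherwise scatters the overhangs across blocks.
4. **Consensus calls** (`column_consensus`, `indel_consensus`). Columns
   with no gap among covering rows are called by the majority rule with
   IUPAC fallback: gap if gaps exceed half the rows; a base if its
   frequency among non-gap rows strictly exceeds `majority_frac` (0.5);
   otherwise the IUPAC code of all bases at frequency ≥ `minor_frac`
   (0.25); `N` if none qualifies. `N` characters count toward depth but
   never win. Runs of gap-containing columns are treated as
   insertion/deletion *events*: each row's residue count in the region is
   its length class, the plurality class wins, ties go to the shorter
   (deletion-favouring) length, and the winning rows' residues are
   column-called. Because independent events at adjacent but
   non-overlapping column ranges must not be conflated, a maximal gappy
   run is first split into overlap-connected components of per-row gap
   intervals.
5. **Placeholders** (`unresolved_placeholder`). A region is unresolvable
   when no length class reaches `complexity_frac` (1/3) of the informative
   rows, or when more than `max_length_classes` (4) *recurrent* classes
   (support ≥ 2) occur; singleton lengths are treated as noise rather than
   independent events, since with a dozen decayed copies nearly every
   wide region otherwise accumulates five distinct lengths and would be
   needlessly voided. An unresolvable region contributes exactly ten `N`
   characters regardless of width — a fixed-size scar marking "something
   is here that the copies cannot resolve".
6. **Termini** (`detect_termini`). Column depth (non-gap copies) and
   agreement (top-base frequency) are scanned from each end with a
   15-column window over *informative* columns only (depth ≥ `min_depth`,
   default 3) — shallow columns are lone-copy insertions whose single row
   trivially agrees with itself, so they may neither qualify nor break a
   window. A window qualifies when 80% of its informative columns reach
   `agreement_min` (0.7); boundaries are then refined column-by-column.
   The anchor row is excluded throughout, so a draft cannot vote for its
   own termini.
7. **TSD-aware polishing.** Conserved target-site context (such as Tc4's
   `C·TNA·G`) is indistinguishable from element sequence by agreement
   alone and gets absorbed into the detected termini. A small boundary
   search (up to 14 columns inward, 14 outward per side) therefore scores
   every candidate boundary pair by cross-copy support for an exact
   suffix/prefix duplication between the copies' flanks. Three rules make
   this search safe, each forced by a concrete failure mode:
   * *exact matches only* — with a mismatch tolerance, an off-by-one
     boundary yields a systematic wrong-length call in every copy;
   * *length-first ranking among candidates at ≥ 70% of the best
     support* — outward shifts truncate the true duplication
     symmetrically and would otherwise win on support with a shorter
     match, while low-support longer flukes must not outrank a
     well-supported truth;
   * *reverse-complement-palindrome rejection* — a boundary placed inside
     a terminal inverted repeat manufactures a unanimous "duplication"
     which is provably always an rc-palindrome; real TSDs essentially
     never are (per copy, a duplicated site is palindromic only by
     chance).
8. **Iteration** (`curate`). A single anchored pass cannot extend beyond
   the draft's own span, and justified overhang stacking drifts across
   indels, so the loop re-anchors: each round appends to the next anchor a
   *probe* — the plurality base of flank columns adjacent to the detected
   termini, stopping where three informative columns in a row fall below
   0.5 agreement. The next round's dynamic-programming alignment then pins
   that region down properly, and termini detection trims whatever the
   realignment exposes as junk. Rounds continue until the trimmed
   consensus is reproduced (or `max_rounds = 8`). Later rounds realign
   only a window of each copy around its previous aligned span
   (±300 bp), which keeps the loop fast without changing results. The
   curated version is appended to the alignment next to the original row
   (`id.vN` labels), so the file itself carries the version history.

## Hallmarks

* `find_tir` / `find_ltr` locally align the two terminal regions (against
  the reverse complement for TIRs). Arms must reach `min_len` (8 / 80),
  satisfy the mismatch or identity threshold (20% / 80%), start within
  `max_offset` of their terminus (30 / 50) — and, for TIRs, reach a net
  alignment score of `min_len`, which suppresses the mismatch-studded
  chance matches abundant in random sequence (false-positive rate ≈ 1%
  at defaults, measured over seeded random 1 kb sequences).
* `find_tsd` calls, per copy, the longest suffix of the left flank equal
  to the prefix of the right flank (one mismatch tolerated from 8 bp).
  The consensus length is the plurality across copies, ties to the
  shorter. The motif and the target-site model are called with laxer
  thresholds than the sequence consensus (single base above 0.8, else the
  code of everything ≥ 0.05): a site model describes the *set* of
  acceptable duplications, so minor variants are included rather than
  out-voted — this is what turns `TAA/TCA/TGA/TTA` into `TNA` rather than
  some accidental three-base code.
* `fit_target_site_model` extends the motif with flanking context and
  trims uninformative (`N`) outer positions, reconstructing the
  pre-insertion site with the cut annotated, e.g. `C|TNA|G`; a fully
  random context degenerates to the bare core.
* `boundary_logo` reports per-position base frequencies and information
  content (`2 + Σ f·log2 f`, in bits) over 15 positions before the 5'
  TIR and 11 after the 3' TIR, anchored at the outermost TIR base. No
  small-sample correction is applied; with few copies the expected
  background IC is visibly above zero.

## Classification and library comparison

Classification follows a fixed precedence: imported homology evidence
(e-value ≤ 1e−5 and consensus coverage ≥ 0.5) donates its label; else
structure (TIR + TSD → `DNA/Unknown`, LTR pair → `LTR/Unknown` — a
structural call never invents a superfamily); else `Unknown`. Every rule
fired is recorded in a decision trace; conflicts resolve in favour of
homology and are noted. Nomenclature validation checks `Class/Superfamily`
labels against an extensible vocabulary and suggests corrections within
edit distance 2 (case-insensitive, since case errors like `DNA/Hat` are
the common mistake).

`compare_libraries` aligns every pair across two libraries, summing
fragmented local alignments per pair (alignment-length-weighted identity).
The `80-80-80` preset demands ≥ 80 bp aligned, ≥ 80% identity and ≥ 80%
coverage; coverage is measured against the shorter sequence, which the
source rules leave unspecified. The subfamily preset `95-80-98` is read
here as (identity 95%, coverage 0.8, minimum span 98 bp) by analogy with
the family rule's ordering; the cited rule's exact reading is ambiguous,
so the triple is overridable.

## Annotation statistics

`kimura2p` implements `K = −½·ln(1−2p−q) − ¼·ln(1−2q)` and errors outside
its domain ("saturated divergence"). Landscapes bin masked bp by top-level
category and 1% divergence bins `[k, k+1)`, pooling ≥ 49% into the last
bin, **without** overlap resolution (standard landscape semantics:
column totals equal masked bp). `masked_summary` *does* flatten overlaps —
per base, the highest-scoring annotation wins — so genome percentages
cannot exceed 100. Divergence defaults to the `.out` table's `pct_div`;
recomputation from alignment rows via `divergence_from_pair` is available,
without CpG adjustment. The activity filter counts subfamilies with at
least `min_copies` (10) annotations at `pct_div ≤ max_div`; the default
`max_div = 0` is exact, with the threshold exposed because annotations
that round their divergences may need a small epsilon.

## The simulator and what the tests show

`simulate_genome` implants family copies into a random background:
insertion sites match the family's target-site pattern when given (the
bracketed core is duplicated on both sides, mirroring central-TSD elements
like Tc4) or are random with `tsd_len` bases duplicated. Copies decay
under a two-rate substitution process (per-site probability `d`,
transition fraction `κ/(κ+1)`, default `κ = 2`) — deliberately
K2P-compatible so that distance recovery is a closed loop — plus small
indels at 0.1× the substitution rate with geometric lengths (mean 2), 5'
truncation with probability `truncation_prob`, and random strand. Element
generation and genome assembly use different random generators
(Mersenne-Twister vs L'Ecuyer-CMRG) so that equal seeds can never leak
element sequence into the background. Everything is bit-reproducible
under a seed.

The default family — 800 bp element, 12 bp TIRs, 4–8 bp TSD, 15 copies at
8% expected divergence, 10% of copies truncated, one family per ~95 kb
genome with insertion points ≥ 5 kb apart — defines the standard study
conditions used by the recovery benchmark (`recovery_benchmark`, 50
independent families; drafts are the central 70% of the truth plus 2%
noise, emulating a truncated automated consensus). The acceptance
script reports, under these conditions, the fraction of families with
curated consensus ≥ 95% identical over ≥ 95% of the truth, termini within
10 bp, exact TSD length, and a correct structural class.

What this does *not* show: the background is compositionally uniform (no
GC structure, no satellite arrays), families are not nested, copies of
different ages are not mixed within a family, and drafts are degraded
truths rather than genuinely chimeric assemblies. Passing the benchmark
demonstrates the machinery is correct and calibrated under its stated
model, not that real libraries curate themselves; real alignments still
warrant eyes on the MSA, which is why every result keeps its alignment,
flanks and version history.

## Degenerate inputs and edge behaviour

Empty copy sets, sub-seed-length queries, ragged alignments, saturated
divergences and coordinate violations raise errors naming the problem.
Zero hits is an empty result, not an error. Copies whose flanks are too
short for a logo are excluded with a warning; fewer than three flanked
copies disables TSD polishing (nothing to compare). The review ledger
refuses illegal state transitions and self-acceptance, and its FNV-1a
hash chain makes edits, deletions and reorderings detectable.
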