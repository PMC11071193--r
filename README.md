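# tecurate

Alignment-based curation of transposable element (TE) consensus libraries
in R.

Automated repeat finders (RepeatModeler and kin) emit draft consensus
sequences that are routinely truncated, chimeric or unclassified —
especially in taxa far from any curated repeat database. The remedy the TE
community relies on is *manual curation*: mine the genomic copies of each
draft, extend them with flanking sequence, align them, rebuild a
majority-rule consensus, locate the element's true termini and its
structural hallmarks (terminal inverted repeats, long terminal repeats,
target site duplications), and only then classify and compare. `tecurate`
packages this workflow for R users — curators, teachers of curation, and
anyone needing reproducible repeat-library QC — together with the
annotation statistics used to read the results (Kimura 2-parameter repeat
landscapes, masked-fraction tables, the "at least 10 copies at 0%
divergence" activity filter) and a peer-review ledger with hash-chained
version history.

At its core are three operations:

* **Copy mining** — a seed-and-extend local search (exact 11-mers,
  diagonal chaining, affine-gap extension; +1/−2 match/mismatch, 5/1 gap
  open/extend) finds genomic copies of a draft; the best 20 hits are
  extended by 2 kb on both sides and extracted in consensus orientation.
  Hit tables from an external search can be imported instead.
* **Consensus building** — copies are star-aligned onto the current
  consensus; each column is called by the majority rule with IUPAC
  fallback (a base wins above 50% of non-gap rows; otherwise the ambiguity
  code of all bases at ≥ 25%); insertion/deletion regions are resolved as
  independent events by plurality of length classes, with a fixed
  10-`N` placeholder where no length class is credible; the alignable part
  and the element termini are detected from column depth and agreement and
  polished by cross-copy TSD support. The loop re-anchors on each new
  consensus until it stabilises, so a truncated draft grows back to the
  full element.
* **Hallmarks and classification** — TIR/LTR detection on the consensus,
  per-copy TSD calls with a plurality summary and an IUPAC target-site
  model (e.g. Tc4's `C|TNA|G`, whose central `TNA` alone is duplicated),
  boundary sequence logos, RepeatMasker-style nomenclature validation, and
  library comparison under the 80-80-80 family and 95-80-98 subfamily
  rules.

A simulator generates genomes with implanted TE families (controlled copy
number, K2P-compatible divergence, truncation, TIRs/LTRs, TSDs and
target-site patterns) plus truth tables, so the entire toolchain is
testable offline.

## Worked example

Simulate a genome with one implanted family, degrade the true element into
a RepeatModeler-style draft, and run the curation loop:

```r
library(tecurate)

spec <- family_spec(name = "fam1", tsd_len = 6, seed = 7)   # 800 bp, TIRs
sim  <- simulate_genome(spec, background_len = 90000, seed = 7,
                        min_separation = 5000)
draft <- degrade_element(sim$elements[["fam1"]], seed = 7)  # 560 bp draft
rec   <- consensus_record("fam1_draft", draft)

cur <- curate_in_genome(rec, sim$genome)   # mine -> extend -> curate
cur
#> <te_curation> fam1_draft: 800 bp after 4 round(s), columns [301,1171)
cur$hallmarks
#> <hallmark_report>
#>   TIR: 12 bp, 0 mismatch(es)
#>   LTR: none
#>   TSD: length 6, motif NNNNNV
#>   target site: |NNNNNV|NH
classify(cur$record, cur$hallmarks)$label
#> [1] "DNA/Unknown"
```

The 560 bp draft is restored to the full 800 bp element (100% identical to
the implanted truth here), the 12 bp terminal inverted repeats are found,
and the 6 bp target site duplication is recovered at its exact length —
its motif is almost entirely `N` because this family inserts at random
sites, so the duplicated bases differ between copies and the site model
correctly reports no sequence preference. TIR plus TSD yields a
structural classification as a DNA transposon; the superfamily is left
`Unknown` until homology evidence is supplied.

Annotation statistics work from RepeatMasker `.out` tables (or the
simulator's truth projection):

```r
rows <- project_truth_to_out(sim$truth, sim$genome)
masked_summary(rows, genome_size = nchar(sim$genome[[1]]))
#>   category    bp  percent
#> 1      DNA 11004 10.88492
#> ...
landscape(rows, genome_size = nchar(sim$genome[[1]]))   # K2P landscape
active_subfamilies(rows, min_copies = 10, max_div = 0)  # activity filter
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/tecurate` (subcommands `simulate`, `mine`, `curate`,
`hallmarks`, `compare`, `validate-lib`, `landscape`, `summary`, `active`).

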