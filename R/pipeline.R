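## Convenience drivers composing the modules into the standard
## "Blast-Extend-Extract" curation loop.

#' Mine, extend and extract the copies of a draft consensus
#'
#' Runs the search-extend-extract steps: locate genomic copies (internal
#' seed-and-extend search, or an imported hit table), keep the best `n`,
#' extend each by `flank` bp, and extract oriented sequences.
#'
#' @param record draft [consensus_record()].
#' @param genome named character vector of contigs.
#' @param n number of best hits to keep (default 20).
#' @param flank extension on each side in bp (default 2000).
#' @param hits optional imported hit table (bypasses the internal search).
#' @param min_len,min_identity optional hit filters applied before ranking
#'   (defaults: none).
#' @return list with `hits`, `intervals` and `copies` (named oriented
#'   sequences).
#' @export
mine_copies <- function(record, genome, n = 20L, flank = 2000L,
                        hits = NULL, min_len = 0L, min_identity = 0) {
  if (is.null(hits)) hits <- find_copies(record, genome)
  hits <- hits[hits$aln_length >= min_len &
                 hits$identity >= min_identity, , drop = FALSE]
  iv <- select_and_extend(hits, n = n, flank = flank,
                          contig_lengths = nchar(genome))
  copies <- if (nrow(iv) > 0L) extract_oriented(genome, iv)
            else character(0)
  list(hits = hits, intervals = iv, copies = copies)
}

#' Alignment-based agreement of a curated consensus with its true element
#'
#' Overlap-aligns the consensus to the truth and reports identity over the
#' aligned region (IUPAC-compatible positions count as matches, since an
#' ambiguity code denotes observed polymorphism), the fraction of the truth
#' covered, and the worst end offset (missing truth bases plus spurious
#' consensus bases at either terminus).
#'
#' @param consensus consensus sequence (string or [consensus_record()]).
#' @param truth the true element sequence.
#' @return list with `identity` (percent), `coverage` (fraction) and
#'   `boundary_error` (bp).
#' @export
consensus_accuracy <- function(consensus, truth) {
  cseq <- if (is(consensus, "consensus_record")) consensus$sequence
          else toupper(as.character(consensus))
  pa <- .align(cseq, truth, type = "overlap")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ok <- ap != "-" & as_ != "-"
  matches <- sum(iupac_compatible(ap[ok], as_[ok]))
  ps <- IRanges::start(pa@pattern@range); pe <- IRanges::end(pa@pattern@range)
  ss <- IRanges::start(pa@subject@range); se <- IRanges::end(pa@subject@range)
  err5 <- (ss - 1L) + (ps - 1L)
  err3 <- (nchar(truth) - se) + (nchar(cseq) - pe)
  list(identity = 100 * matches / length(ap),
       coverage = (se - ss + 1L) / nchar(truth),
       boundary_error = max(err5, err3))
}

#' Recovery benchmark over simulated families
#'
#' Simulates `n_families` independent genomes, each carrying one TE family
#' under the standard study conditions (800 bp element with 12 bp TIRs and
#' a 4-8 bp TSD, 15 copies, 8% expected divergence, 10% of copies
#' 5'-truncated), degrades each true element into a draft (central 70%
#' fragment, 2% noise), runs the full mine-extend-curate-hallmarks loop,
#' and scores the result against the truth.
#'
#' @param n_families number of simulated families (default 50).
#' @param seed base RNG seed; family f uses derived seeds below 2^31.
#' @param n,flank mining parameters (defaults 20 and 2000).
#' @return data frame with one row per family: `identity`, `coverage`,
#'   `boundary_error`, `tsd_true`, `tsd_called`, `class_called`,
#'   `len_raw`, `len_curated`, `len_true`.
#' @export
recovery_benchmark <- function(n_families = 50L, seed = 1L, n = 20L,
                               flank = 2000L) {
  out <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fseed <- (seed * 1000L + f) %% 2147483647L
    tsd_len <- 4L + (fseed %% 5L)
    spec <- family_spec(name = sprintf("fam%03d", f), tsd_len = tsd_len,
                        seed = fseed)
    sim <- simulate_genome(spec, background_len = 90000L, seed = fseed,
                           min_separation = 5000L)
    truth_el <- sim$elements[[1]]
    draft <- degrade_element(truth_el, seed = fseed)
    rec <- consensus_record(paste0(spec$name, "_draft"), draft)
    # a family whose curation fails outright counts as unrecovered
    cur <- tryCatch(curate_in_genome(rec, sim$genome, n = n, flank = flank),
                    error = function(e) NULL)
    if (is.null(cur)) {
      out[[f]] <- data.frame(identity = 0, coverage = 0,
                             boundary_error = NA_integer_,
                             tsd_true = tsd_len, tsd_called = NA_integer_,
                             class_called = NA_character_,
                             len_raw = nchar(draft), len_curated = NA,
                             len_true = nchar(truth_el))
      next
    }
    acc <- consensus_accuracy(cur$record, truth_el)
    cl <- classify(cur$record, cur$hallmarks)
    out[[f]] <- data.frame(identity = acc$identity,
                           coverage = acc$coverage,
                           boundary_error = acc$boundary_error,
                           tsd_true = tsd_len,
                           tsd_called = cur$hallmarks$tsd$length,
                           class_called = cl$label,
                           len_raw = nchar(draft),
                           len_curated = nchar(cur$record$sequence),
                           len_true = nchar(truth_el))
  }
  do.call(rbind, out)
}

#' Run the full curation loop for one consensus in a genome
#'
#' [mine_copies()] followed by [curate()] and [hallmark_report()].
#'
#' @param record draft [consensus_record()].
#' @param genome named character vector of contigs.
#' @param n,flank,hits see [mine_copies()].
#' @param ... curation parameters passed to [curate()].
#' @return a `te_curation` (see [curate()]) with an extra `hallmarks`
#'   component, or `NULL` when no copies are found.
#' @export
curate_in_genome <- function(record, genome, n = 20L, flank = 2000L,
                             hits = NULL, ...) {
  mined <- mine_copies(record, genome, n = n, flank = flank, hits = hits)
  if (length(mined$copies) == 0L) return(NULL)
  # hit span within each oriented copy focuses the first alignment round
  iv <- mined$intervals
  lo <- ifelse(iv$strand == "+", iv$hit_start - iv$start,
               iv$end - iv$hit_end) + 1L
  hi <- ifelse(iv$strand == "+", iv$hit_end - iv$start,
               iv$end - iv$hit_start)
  cur <- curate(record, mined$copies, focus = cbind(lo, hi), ...)
  cur$hallmarks <- hallmark_report(cur)
  cur$mined <- mined
  cur
}
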