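## "Blast-Extend" half of the curation loop: locate genomic copies of a
## draft consensus, pick the best N, extend flanks, extract oriented copies.
## The internal search is seed-and-extend: exact k-mer seeds, diagonal
## chaining, then local alignment (affine gaps: match +1, mismatch -2,
## gap open 5, gap extend 1) of the consensus against each candidate window.

#' Find genomic copies of a consensus sequence
#'
#' Seed-and-extend local search of a consensus against a genome on both
#' strands. Callers who ran an external search can bypass this and feed an
#' imported hit table (see [read_hits()]) straight to [select_and_extend()].
#'
#' @param consensus a [consensus_record()] or plain sequence string.
#' @param genome named character vector of contigs (see [read_genome()]).
#' @param k exact seed length (default 11).
#' @param min_score minimum local alignment score to report (default 20).
#' @param band_width diagonal tolerance when chaining seeds (default 40).
#' @param max_seed_gap maximum genomic gap between chained seeds (default 400).
#' @param seed_stride spacing between seed start positions on the query
#'   (default 3; 1 uses every k-mer). Stride trades a little seeding
#'   sensitivity for speed; any copy sharing one conserved seed k-mer is
#'   still found, because the alignment step re-extends over the full hit.
#' @return hit table (data frame, 12-column dialect; `sstart > send` encodes
#'   minus strand), ordered by bit score descending, then contig, then start.
#'   Zero hits give an empty data frame.
#' @export
find_copies <- function(consensus, genome, k = 11L, min_score = 20,
                        band_width = 40L, max_seed_gap = 400L,
                        seed_stride = 3L) {
  if (is(consensus, "consensus_record")) {
    qid <- consensus$id
    qseq <- consensus$sequence
  } else {
    qid <- "query"
    qseq <- toupper(as.character(consensus))
  }
  qlen <- nchar(qseq)
  if (qlen < k)
    stop("consensus shorter than seed length k=", k)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") qseq else .revcomp(qseq)
    # seeds with ambiguity codes cannot be exact-matched; skip them
    starts <- seq.int(1L, nchar(q) - k + 1L, by = seed_stride)
    kmers <- substring(q, starts, starts + k - 1L)
    keep <- grepl("^[ACGT]+$", kmers)
    if (!any(keep)) next
    qpos <- starts[keep]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
    win_ctg <- character(0)
    win_lo <- integer(0)
    regions <- character(0)
    for (ctg in names(genome)) {
      sseq <- genome[[ctg]]
      seed_hits <- .seed_positions(pd, qpos, sseq)
      if (nrow(seed_hits) == 0L) next
      windows <- .chain_seeds(seed_hits, nchar(q), nchar(sseq),
                              band_width, max_seed_gap)
      for (w in windows) {
        win_ctg <- c(win_ctg, ctg)
        win_lo <- c(win_lo, w[1])
        regions <- c(regions, substr(sseq, w[1], w[2]))
      }
    }
    if (length(regions) == 0L) next
    # one vectorized local alignment of all candidate windows vs the query
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(regions), Biostrings::DNAString(q),
      type = "local", substitutionMatrix = .submat(1, -2),
      gapOpening = 5, gapExtension = 1)
    scores <- pa@score
    alens <- nchar(as.character(Biostrings::alignedPattern(pa)))
    nmm <- Biostrings::nmismatch(pa)
    nma <- Biostrings::nmatch(pa)
    gaps <- .count_gap_opens(pa)
    rs <- pa@pattern@range      # window (genome) side
    qs <- pa@subject@range      # query side
    for (i in which(scores >= min_score)) {
      h <- list(score = scores[i], aln_length = alens[i],
                mismatches = nmm[i], gap_opens = gaps[i],
                qstart = IRanges::start(qs)[i],
                qend = IRanges::end(qs)[i],
                sstart = win_lo[i] + IRanges::start(rs)[i] - 1L,
                send = win_lo[i] + IRanges::end(rs)[i] - 1L,
                identity = 100 * nma[i] / alens[i])
      hits[[length(hits) + 1L]] <- .hit_row(qid, win_ctg[i], h, strand,
                                            qlen = qlen)
    }
  }
  out <- if (length(hits)) unique(do.call(rbind, hits)) else
    stats::setNames(data.frame(matrix(ncol = 12, nrow = 0)), .HIT_COLS)
  names(out) <- .HIT_COLS
  ord <- order(-out$bitscore, out$subject, pmin(out$sstart, out$send))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact k-mer match positions of query kmers in subject, via PDict
.seed_positions <- function(pd, qpos, sseq) {
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(sseq))
  starts <- IRanges::start(m)
  n_per <- lengths(starts)
  data.frame(q = rep(qpos, n_per), s = unlist(starts, use.names = FALSE))
}

# group seeds into candidate windows by diagonal band + positional gap
.chain_seeds <- function(seeds, qlen, slen, band_width, max_seed_gap) {
  seeds$diag <- seeds$s - seeds$q
  seeds <- seeds[order(seeds$diag, seeds$s), ]
  n <- nrow(seeds)
  new_grp <- c(TRUE, (diff(seeds$diag) > band_width) |
                 (abs(diff(seeds$s)) > max_seed_gap))
  grp <- cumsum(new_grp)
  wins <- lapply(split(seeds, grp), function(g) {
    s_lo <- max(1L, min(g$s) - min(g$q) - 16L)
    s_hi <- min(slen, max(g$s) + (qlen - max(g$q)) + 16L)
    c(s_lo, s_hi)
  })
  # merge overlapping windows to avoid redundant alignments
  wins <- wins[order(vapply(wins, `[`, 0, 1))]
  merged <- list()
  for (w in wins) {
    nlast <- length(merged)
    if (nlast && w[1] <= merged[[nlast]][2]) {
      merged[[nlast]][2] <- max(merged[[nlast]][2], w[2])
    } else merged[[length(merged) + 1L]] <- w
  }
  merged
}

.extend_window <- function(q, sseq, w, min_score) {
  region <- substr(sseq, w[1], w[2])
  pa <- .align(q, region, type = "local")
  sc <- pa@score
  if (sc < min_score) return(NULL)
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  nm <- Biostrings::nmismatch(pa)
  list(score = sc, aln_length = alen, mismatches = nm,
       gap_opens = .count_gap_opens(pa),
       qstart = IRanges::start(pa@pattern@range),
       qend = IRanges::end(pa@pattern@range),
       sstart = w[1] + IRanges::start(pa@subject@range) - 1L,
       send = w[1] + IRanges::end(pa@subject@range) - 1L,
       identity = 100 * Biostrings::nmatch(pa) / alen)
}

# gap opens per alignment (vectorized over a PairwiseAlignments object)
.count_gap_opens <- function(pa) {
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  one <- function(x) {
    g <- gregexpr("-+", x)[[1]]
    if (g[1] == -1L) 0L else length(g)
  }
  vapply(p, one, 0L, USE.NAMES = FALSE) +
    vapply(s, one, 0L, USE.NAMES = FALSE)
}

.hit_row <- function(qid, ctg, h, strand, qlen) {
  if (strand == "+") {
    qs <- h$qstart; qe <- h$qend; ss <- h$sstart; se <- h$send
  } else {
    # query coordinates reported on the original (plus) consensus
    qs <- qlen - h$qend + 1L; qe <- qlen - h$qstart + 1L
    ss <- h$send; se <- h$sstart
  }
  data.frame(query = qid, subject = ctg,
             identity = round(h$identity, 2), aln_length = h$aln_length,
             mismatches = h$mismatches, gap_opens = h$gap_opens,
             qstart = qs, qend = qe, sstart = ss, send = se,
             evalue = 0, bitscore = h$score)
}

#' Select the best hits and extend their flanks
#'
#' Ranks hits by bit score (ties: longer alignment, then contig, then
#' coordinate), keeps the best `n`, and extends each hit span by `flank`
#' bases on both sides, clipped to the contig. Overlapping intervals are not
#' merged: each hit stays one interval. Duplicated coordinate triples
#' (contig, start, end) are dropped.
#'
#' @param hits hit table from [find_copies()] or [read_hits()].
#' @param n number of hits to keep (default 20).
#' @param flank extension in bp on each side (default 2000).
#' @param contig_lengths named integer vector of contig lengths.
#' @return data frame of intervals: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `score`, plus the originating hit span
#'   `hit_start`/`hit_end` (0-based half-open).
#' @export
select_and_extend <- function(hits, n = 20L, flank = 2000L, contig_lengths) {
  stopifnot(n >= 1L, flank >= 0L)
  if (nrow(hits) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), hit_start = integer(),
                      hit_end = integer()))
  lo <- pmin(hits$sstart, hits$send)
  hi <- pmax(hits$sstart, hits$send)
  ord <- order(-hits$bitscore, -hits$aln_length, hits$subject, lo)
  hits <- hits[ord, ]; lo <- lo[ord]; hi <- hi[ord]
  keep <- !duplicated(data.frame(hits$subject, lo, hi))
  hits <- hits[keep, ]; lo <- lo[keep]; hi <- hi[keep]
  m <- min(n, nrow(hits))
  hits <- hits[seq_len(m), ]; lo <- lo[seq_len(m)]; hi <- hi[seq_len(m)]
  clen <- contig_lengths[hits$subject]
  if (any(is.na(clen))) stop("hit contig missing from contig_lengths")
  data.frame(contig = hits$subject,
             start = pmax(0L, lo - 1L - flank),
             end = pmin(as.integer(clen), hi + flank),
             strand = hit_strand(hits),
             score = hits$bitscore,
             hit_start = lo - 1L, hit_end = hi)
}

#' Extract oriented copy sequences for a set of intervals
#'
#' Minus-strand intervals are reverse-complemented so every copy is in the
#' consensus orientation. Labels are `contig:start-end(strand)` with 0-based
#' half-open coordinates and can be parsed back with
#' [parse_interval_label()].
#'
#' @param genome named character vector of contigs.
#' @param intervals data frame from [select_and_extend()].
#' @return named character vector of sequences.
#' @export
extract_oriented <- function(genome, intervals) {
  out <- character(nrow(intervals))
  labs <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    ctg <- intervals$contig[i]
    if (!ctg %in% names(genome)) stop("unknown contig: ", ctg)
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < 0L || e > nchar(genome[[ctg]]) || s >= e)
      stop("interval outside contig ", ctg, ": [", s, ",", e, ")")
    seq <- substr(genome[[ctg]], s + 1L, e)
    if (intervals$strand[i] == "-") seq <- .revcomp(seq)
    out[i] <- seq
    labs[i] <- sprintf("%s:%d-%d(%s)", ctg, s, e, intervals$strand[i])
  }
  stats::setNames(out, labs)
}

#' Parse an interval label back to its coordinates
#'
#' @param label label(s) of the form `contig:start-end(strand)`.
#' @return data frame with `contig`, `start`, `end`, `strand`.
#' @export
parse_interval_label <- function(label) {
  m <- regmatches(label,
                  regexec("^(.+):([0-9]+)-([0-9]+)\\(([+-])\\)$", label))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad)) stop("unparseable interval label: ", label[bad][1])
  data.frame(contig = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             strand = vapply(m, `[`, "", 5L))
}
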