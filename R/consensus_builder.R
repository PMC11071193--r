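## "Extract/curate" half of the loop: anchored star MSA, majority-rule IUPAC
## consensus with indel-event handling and 10-N placeholders, detection of
## the alignable part and element termini, and length comparison.

new_te_msa <- function(labels, seqs, anchor = 1L) {
  stopifnot(length(labels) == length(seqs),
            length(unique(nchar(seqs))) == 1L,
            anchor >= 1L, anchor <= length(seqs))
  structure(list(labels = labels, seqs = unname(seqs),
                 anchor = as.integer(anchor)),
            class = "te_msa")
}

#' @export
print.te_msa <- function(x, ...) {
  cat(sprintf("<te_msa> %d rows x %d columns (anchor: %s)\n",
              length(x$seqs), nchar(x$seqs[1]), x$labels[x$anchor]))
  invisible(x)
}

#' Number of rows / columns of an alignment
#' @param msa a `te_msa`.
#' @return integer.
#' @export
msa_nrow <- function(msa) length(msa$seqs)

#' @rdname msa_nrow
#' @export
msa_ncol <- function(msa) nchar(msa$seqs[1])

# character matrix view (rows x columns)
.msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
}

# per-row coverage span: first/last non-gap column (NA when empty)
.row_spans <- function(M) {
  t(apply(M != "-", 1L, function(v) {
    w <- which(v)
    if (length(w)) c(w[1], w[length(w)]) else c(NA_integer_, NA_integer_)
  }))
}

#' Build a star alignment of copies anchored on a consensus
#'
#' Each copy is pairwise-aligned to the anchor (global with free end gaps,
#' affine gap penalties) and the pairwise alignments are projected onto the
#' anchor's coordinate system. Copy insertions relative to the anchor become
#' anchor-gap column blocks whose width is the largest insertion at that
#' anchor position; flank overhangs are stacked against the nearest aligned
#' anchor column (left overhangs right-justified, right overhangs
#' left-justified) so flank columns remain comparable across copies.
#'
#' @param anchor a [consensus_record()] or sequence string; becomes row 1.
#' @param copies named character vector of copy sequences in consensus
#'   orientation (see [extract_oriented()]).
#' @return a `te_msa` with the anchor as first row.
#' @export
build_star_msa <- function(anchor, copies) {
  if (is(anchor, "consensus_record")) {
    alab <- paste0(anchor$id, ".v", anchor$version)
    aseq <- anchor$sequence
  } else {
    alab <- "anchor"
    aseq <- toupper(as.character(anchor))
  }
  if (length(copies) == 0L) stop("empty copy set")
  if (is.null(names(copies)))
    names(copies) <- paste0("copy", seq_along(copies))
  L <- nchar(aseq)
  copies <- toupper(copies)
  # one vectorized overlap alignment of all copies against the anchor
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(copies), Biostrings::DNAString(aseq),
    type = "overlap", substitutionMatrix = .submat(1, -2),
    gapOpening = 5, gapExtension = 1)
  ap_all <- as.character(Biostrings::alignedPattern(pa))
  as_all <- as.character(Biostrings::alignedSubject(pa))
  ps <- IRanges::start(pa@pattern@range); pe <- IRanges::end(pa@pattern@range)
  ss <- IRanges::start(pa@subject@range); se <- IRanges::end(pa@subject@range)
  proj <- lapply(seq_along(copies), function(i) {
    .project_copy(copies[[i]], L,
                  pstart = ps[i], pend = pe[i],
                  sstart = ss[i], send = se[i],
                  ap = strsplit(ap_all[i], "")[[1]],
                  as_ = strsplit(as_all[i], "")[[1]])
  })
  # block j sits after anchor position j (block 0 precedes the anchor)
  W <- integer(L + 1L)
  for (p in proj) {
    has <- which(nzchar(p$ins)) - 1L
    for (j in has) W[j + 1L] <- max(W[j + 1L], nchar(p$ins[j + 1L]))
  }
  ncol_total <- L + sum(W)
  render <- function(at, ins, rjust) {
    out <- character(0)
    for (j in 0:L) {
      if (W[j + 1L] > 0L) {
        s <- ins[j + 1L]
        pad <- strrep("-", W[j + 1L] - nchar(s))
        out <- c(out, if (rjust[j + 1L]) paste0(pad, s) else paste0(s, pad))
      }
      if (j < L) out <- c(out, at[j + 1L])
    }
    paste(out, collapse = "")
  }
  anchor_row <- render(strsplit(aseq, "")[[1]],
                       rep("", L + 1L), rep(FALSE, L + 1L))
  copy_rows <- vapply(proj, function(p) render(p$at, p$ins, p$rjust), "")
  new_te_msa(c(alab, names(copies)), c(anchor_row, unname(copy_rows)),
             anchor = 1L)
}

# project one copy's pairwise alignment onto anchor coordinates.
# edge_clip: when the alignment clips no more than this many anchor-edge
# positions (a mismatching anchor terminus makes most copies clip a base
# or two, each at its own offset), the overhang still goes to the terminal
# block so that shared flanking sequence stays stacked across copies
.project_copy <- function(copy, L, pstart, pend, sstart, send, ap, as_,
                          edge_clip = 30L) {
  at <- rep("-", L)
  ins <- rep("", L + 1L)
  rjust <- rep(FALSE, L + 1L)
  cur <- sstart - 1L            # last anchor position consumed
  for (k in seq_along(ap)) {
    if (as_[k] != "-") {
      cur <- cur + 1L
      at[cur] <- ap[k]
    } else if (ap[k] != "-") {
      ins[cur + 1L] <- paste0(ins[cur + 1L], ap[k])
    }
  }
  if (pstart > 1L) {            # left overhang abuts first aligned column
    j <- if (sstart - 1L <= edge_clip) 0L else sstart - 1L
    ins[j + 1L] <- paste0(substr(copy, 1L, pstart - 1L), ins[j + 1L])
    rjust[j + 1L] <- TRUE
  }
  if (pend < nchar(copy)) {     # right overhang
    j <- if (L - send <= edge_clip) L else send
    ins[j + 1L] <- paste0(ins[j + 1L],
                          substr(copy, pend + 1L, nchar(copy)))
  }
  list(at = at, ins = ins, rjust = rjust)
}

#' Majority-rule IUPAC consensus call for one alignment column
#'
#' The call follows the majority rule with IUPAC fallback: if gaps exceed
#' half the rows the column is a gap; otherwise a base whose frequency among
#' non-gap rows strictly exceeds `majority_frac` wins; otherwise the IUPAC
#' code of all bases at frequency `>= minor_frac`; if no base qualifies,
#' `N`. `N` characters count toward depth but never toward a base call.
#'
#' @param profile named counts over `A`, `C`, `G`, `T`, `N` and `-` (a
#'   `table` or named numeric vector; absent names count zero).
#' @param majority_frac strict majority threshold (default 0.5).
#' @param minor_frac inclusion threshold for ambiguity codes (default 0.25).
#' @param min_depth minimum non-gap depth (default 3); a shallower column is
#'   outside the alignable part and is an error here.
#' @return single character: a base, an IUPAC code, `N`, or `-`.
#' @export
column_consensus <- function(profile, majority_frac = 0.5,
                             minor_frac = 0.25, min_depth = 3) {
  counts <- stats::setNames(rep(0, 6), c("A", "C", "G", "T", "N", "-"))
  p <- unlist(as.list(profile))
  if (length(p) == 0L || sum(p) == 0) stop("empty profile")
  bad <- setdiff(names(p), names(counts))
  if (length(bad)) stop("unexpected profile characters: ",
                        paste(bad, collapse = ","))
  counts[names(p)] <- counts[names(p)] + p
  total <- sum(counts)
  gaps <- counts[["-"]]
  if (gaps > total / 2) return("-")
  depth <- total - gaps
  if (depth < min_depth)
    stop("column depth ", depth, " below min_depth ", min_depth)
  freq <- counts[c("A", "C", "G", "T")] / depth
  if (max(freq) > majority_frac) return(names(freq)[which.max(freq)])
  keep <- names(freq)[freq >= minor_frac]
  if (length(keep) == 0L) return("N")
  iupac_code(keep)
}

# plurality decision over indel length classes; ties go to the shorter
# (deletion-favouring) length. A region is complex (10-N placeholder) when
# no class reaches complexity_frac of the rows, or when more than
# max_length_classes recurrent classes (support >= 2; singletons are noise,
# not independent events) are present
.plurality_length <- function(lengths, complexity_frac = 1 / 3,
                              max_length_classes = 4L) {
  tab <- table(lengths)
  classes <- as.integer(names(tab))
  n <- length(lengths)
  top <- max(tab)
  complex <- (top < complexity_frac * n) ||
    (sum(tab >= 2L) > max_length_classes)
  winners <- classes[tab == top]
  list(length = min(winners), complex = complex)
}

# split a maximal gappy column run into overlap-connected components of
# per-row gap intervals (independent indel events)
.split_gap_run <- function(M, spans, rng) {
  iv <- list()
  for (r in seq_len(nrow(M))) {
    if (is.na(spans[r, 1])) next
    inside <- rng[rng >= spans[r, 1] & rng <= spans[r, 2]]
    if (length(inside) == 0L) next
    isgap <- M[r, inside] == "-"
    if (!any(isgap)) next
    rr <- rle(isgap)
    endp <- cumsum(rr$lengths)
    startp <- endp - rr$lengths + 1L
    for (i in which(rr$values))
      iv[[length(iv) + 1L]] <- c(inside[startp[i]], inside[endp[i]])
  }
  if (length(iv) == 0L) return(list(rng))
  iv <- iv[order(vapply(iv, `[`, 0L, 1L))]
  comps <- list()
  cur <- iv[[1]]
  for (i in seq_along(iv)[-1]) {
    if (iv[[i]][1] <= cur[2]) cur[2] <- max(cur[2], iv[[i]][2])
    else {
      comps[[length(comps) + 1L]] <- cur
      cur <- iv[[i]]
    }
  }
  comps[[length(comps) + 1L]] <- cur
  # cover any run columns that fall outside all components (gaps there come
  # only from rows not spanning the region); attach them as their own piece
  covered <- unlist(lapply(comps, function(c) c[1]:c[2]))
  rest <- setdiff(rng, covered)
  out <- lapply(comps, function(c) c[1]:c[2])
  if (length(rest)) {
    grp <- cumsum(c(TRUE, diff(rest) != 1L))
    out <- c(out, unname(split(rest, grp)))
  }
  out[order(vapply(out, min, 0L))]
}

# informative rows for a column region: span covers the whole region
.region_rows <- function(spans, region) {
  which(!is.na(spans[, 1]) & spans[, 1] <= min(region) &
          spans[, 2] >= max(region))
}

#' Majority-rule consensus of an insertion/deletion region
#'
#' Within a maximal run of gap-containing columns, each row's number of
#' placed residues is treated as one realisation of an independent
#' insertion/deletion event; the plurality length class wins (ties resolved
#' toward the shorter, deletion-favouring length) and the consensus keeps
#' that many positions, called by [column_consensus()] over the winning
#' rows. Regions too complex to resolve get a fixed placeholder of ten `N`s
#' (see [unresolved_placeholder()]).
#'
#' @param msa a `te_msa`.
#' @param region integer vector of column indices (a maximal gap run).
#' @param complexity_frac minimum fraction of informative rows the winning
#'   length class must reach (default 1/3).
#' @param max_length_classes maximum number of distinct length classes
#'   before the region is declared complex (default 4).
#' @param ... thresholds passed to [column_consensus()].
#' @return list with `length` (kept residue count, `NA` when complex),
#'   `complex` flag and `consensus` (the region's consensus string; ten `N`s
#'   when complex).
#' @export
indel_consensus <- function(msa, region, complexity_frac = 1 / 3,
                            max_length_classes = 4L, ...) {
  M <- .msa_matrix(msa)
  M <- M[-msa$anchor, , drop = FALSE]
  spans <- .row_spans(M)
  .region_call(M, spans, region, complexity_frac, max_length_classes, ...)
}

.region_call <- function(M, spans, region, complexity_frac = 1 / 3,
                         max_length_classes = 4L, ...) {
  rows <- .region_rows(spans, region)
  if (length(rows) == 0L)
    return(list(length = NA_integer_, complex = FALSE, consensus = ""))
  lens <- apply(M[rows, region, drop = FALSE] != "-", 1L, sum)
  dec <- .plurality_length(lens, complexity_frac, max_length_classes)
  if (dec$complex)
    return(list(length = NA_integer_, complex = TRUE,
                consensus = strrep("N", 10L)))
  k <- dec$length
  if (k == 0L)
    return(list(length = 0L, complex = FALSE, consensus = ""))
  win <- rows[lens == k]
  resid <- vapply(win, function(r) {
    paste(M[r, region][M[r, region] != "-"], collapse = "")
  }, "")
  cons <- paste(vapply(seq_len(k), function(j) {
    column_consensus(table(substr(resid, j, j)), min_depth = 1, ...)
  }, ""), collapse = "")
  list(length = k, complex = FALSE, consensus = cons)
}

#' Placeholder for an unresolvable indel region
#'
#' When no indel length class reaches `complexity_frac` of the informative
#' rows, or more than `max_length_classes` distinct lengths occur, the
#' region cannot be unambiguously solved and the consensus receives exactly
#' ten `N` characters regardless of region width.
#'
#' @inheritParams indel_consensus
#' @return the 10-character placeholder string, or `NULL` when the region is
#'   resolvable.
#' @export
unresolved_placeholder <- function(msa, region, complexity_frac = 1 / 3,
                                   max_length_classes = 4L) {
  res <- indel_consensus(msa, region, complexity_frac, max_length_classes)
  if (isTRUE(res$complex)) strrep("N", 10L) else NULL
}

# per-column depth (non-gap count) and agreement (top-base frequency);
# residues only occur inside a row's span, so no cover mask is needed
.column_stats <- function(M, spans) {
  depth <- colSums(M != "-")
  top <- pmax(colSums(M == "A"), colSums(M == "C"),
              colSums(M == "G"), colSums(M == "T"))
  agree <- ifelse(depth > 0L, top / depth, 0)
  list(depth = depth, agree = agree)
}

# logical matrix: does row r's span cover column j
.cover_matrix <- function(M, spans) {
  lo <- ifelse(is.na(spans[, 1]), ncol(M) + 1L, spans[, 1])
  hi <- ifelse(is.na(spans[, 2]), 0L, spans[, 2])
  (col(M) >= lo) & (col(M) <= hi)
}

#' Detect the alignable part (element termini) of a copy alignment
#'
#' Scans columns from each end inward with a sliding window; the alignable
#' part starts at the first window whose mean copy depth reaches
#' `min_depth` and whose mean column agreement (top-base frequency among
#' non-gap copy rows) reaches `agreement_min`, then the boundary is refined
#' column-by-column. Column statistics exclude the anchor row so the draft
#' consensus cannot vote for its own termini.
#'
#' @param msa a `te_msa` built from flank-extended copies.
#' @param window sliding window width in columns (default 15).
#' @param min_depth minimum mean depth (default 3).
#' @param agreement_min minimum mean top-base frequency (default 0.7).
#' @return integer vector `c(start, end)`: a half-open 1-based column range;
#'   the element occupies columns `start` to `end - 1`.
#' @export
detect_termini <- function(msa, window = 15L, min_depth = 3,
                           agreement_min = 0.7) {
  M <- .msa_matrix(msa)
  M <- M[-msa$anchor, , drop = FALSE]
  spans <- .row_spans(M)
  st <- .column_stats(M, spans)
  # the scan runs over informative columns only (depth >= min_depth):
  # shallow columns are lone-copy insertions whose single row trivially
  # "agrees" with itself, and must neither qualify nor break a window
  idx <- which(st$depth >= min_depth)
  if (length(idx) == 0L) stop("no alignable core")
  ok <- st$agree[idx] >= agreement_min
  w <- min(window, length(idx))
  # a window of informative columns qualifies when 80% of them agree
  run <- stats::filter(as.numeric(ok), rep(1, w), sides = 1)
  qual <- which(!is.na(run) & run >= 0.8 * w) - w + 1L  # window starts
  if (length(qual) == 0L) stop("no alignable core")
  i <- qual[1]
  j <- qual[length(qual)] + w - 1L
  # refine: push outward over agreeing columns, then trim failing ones
  while (i > 1L && ok[i - 1L]) i <- i - 1L
  while (j < length(idx) && ok[j + 1L]) j <- j + 1L
  while (i <= j && !ok[i]) i <- i + 1L
  while (j >= i && !ok[j]) j <- j - 1L
  if (i > j) stop("no alignable core")
  c(start = idx[i], end = idx[j] + 1L)
}

# longest suffix(left)/prefix(right) match; one mismatch tolerated for
# matches of 8 bp or more (unless tolerant = FALSE); character vectors for
# speed
.tsd_call_vec <- function(lchars, rchars, min_len = 2L, max_len = 20L,
                          tolerant = TRUE) {
  kmax <- min(max_len, length(lchars), length(rchars))
  if (kmax < min_len) return(list(length = 0L, tsd = ""))
  nl <- length(lchars)
  for (k in seq(kmax, min_len)) {
    a <- lchars[(nl - k + 1L):nl]
    b <- rchars[seq_len(k)]
    mm <- sum(a != b)
    if (mm == 0L || (tolerant && k >= 8L && mm <= 1L))
      return(list(length = k, tsd = paste(b, collapse = "")))
  }
  list(length = 0L, tsd = "")
}

.tsd_call <- function(left, right, min_len = 2L, max_len = 20L) {
  .tsd_call_vec(strsplit(left, "")[[1]], strsplit(right, "")[[1]],
                min_len, max_len)
}

# per-copy flank strings at given boundary columns (left of s / right of e)
.copy_flanks_at <- function(M, spans, s, e, tail_len = Inf) {
  n <- nrow(M)
  lapply(seq_len(n), function(r) {
    if (is.na(spans[r, 1])) return(list(left = "", core = "", right = ""))
    chars <- M[r, ]
    lcols <- seq_len(s - 1L)
    rcols <- if (e <= ncol(M)) e:ncol(M) else integer(0)
    left <- paste(chars[lcols][chars[lcols] != "-"], collapse = "")
    right <- paste(chars[rcols][chars[rcols] != "-"], collapse = "")
    core <- paste(chars[s:(e - 1L)][chars[s:(e - 1L)] != "-"],
                  collapse = "")
    if (is.finite(tail_len)) {
      left <- substr(left, max(1L, nchar(left) - tail_len + 1L),
                     nchar(left))
      right <- substr(right, 1L, tail_len)
    }
    list(left = left, core = core, right = right)
  })
}

# TSD-aware boundary polish: small column shifts of each terminus are
# scored by cross-copy target-site-duplication support; needed because a
# conserved target-site context would otherwise be absorbed into the
# element. Shifts are inward up to in_max and outward up to out_max.
.polish_termini <- function(M, spans, s, e, min_len = 2L, max_len = 20L,
                            in_max = 14L, out_max = 14L) {
  nc <- ncol(M)
  shifts <- seq(-out_max, in_max)
  tail_len <- max_len + 4L
  # per-row residue columns/characters, so flank tails are cheap to slice
  rows <- lapply(seq_len(nrow(M)), function(r) {
    nz <- which(M[r, ] != "-")
    list(cols = nz, chars = M[r, nz])
  })
  left_tail <- function(row, s2) {
    i <- findInterval(s2 - 1L, row$cols)
    if (i == 0L) return(character(0))
    row$chars[max(1L, i - tail_len + 1L):i]
  }
  right_head <- function(row, e2) {
    n <- length(row$cols)
    i <- findInterval(e2 - 1L, row$cols) + 1L
    if (i > n) return(character(0))
    row$chars[i:min(n, i + tail_len - 1L)]
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_rc_palindrome <- function(x) {
    chars <- strsplit(x, "")[[1]]
    all(chars %in% names(comp)) &&
      identical(chars, rev(unname(comp[chars])))
  }
  # score = (copies supporting the plurality TSD length, that length);
  # compared lexicographically so a longer consistent duplication wins at
  # equal support, and ties fall back to the smallest boundary shift
  score_at <- function(s2, e2) {
    if (s2 < 1L || e2 > nc + 1L || e2 - s2 < 50L) return(c(-1L, 0L))
    # exact matches only: with a tolerance, an off-by-one boundary yields
    # a systematic (wrong) k+1 call that would outscore the true boundary
    calls <- lapply(rows, function(row) {
      if (length(row$cols) == 0L) return(list(length = 0L, tsd = ""))
      .tsd_call_vec(left_tail(row, s2), right_head(row, e2),
                    min_len, max_len, tolerant = FALSE)
    })
    lens <- vapply(calls, `[[`, 0L, "length")
    pos <- lens[lens >= min_len]
    if (length(pos) == 0L) return(c(0L, 0L))
    tab <- table(pos)
    supp <- max(tab)
    len <- max(as.integer(names(tab))[tab == supp])
    # a boundary placed inside a terminal inverted repeat manufactures a
    # unanimous "duplication" that is always a reverse-complement
    # palindrome; real target site duplications essentially never are
    strs <- vapply(calls[lens == len], `[[`, "", "tsd")
    if (mean(vapply(strs, is_rc_palindrome, TRUE)) > 0.5)
      return(c(0L, 0L))
    c(supp, len)
  }
  # polishing needs flanking sequence to compare: with (near) flankless
  # copies any coincidental prefix/suffix repeat of the element itself
  # would be unanimously "supported", so bail out instead
  flanked <- sum(vapply(rows, function(row) {
    length(left_tail(row, s)) >= min_len &&
      length(right_head(row, e)) >= min_len
  }, TRUE))
  if (flanked < 3L) return(c(start = s, end = e))
  # candidate ranking is length-first among well-supported boundaries: an
  # outward shift truncates the duplication symmetrically and so always
  # yields a shorter but unanimous match, which must not outrank the true
  # (longest) one; support breaks remaining ties, then the smallest shift
  cand <- list()
  for (aL in shifts) for (aR in shifts) {
    sc <- score_at(s + aL, e - aR)
    if (sc[1] >= 3L)
      cand[[length(cand) + 1L]] <-
        c(supp = sc[1], len = sc[2], aL = aL, aR = aR,
          shift = abs(aL) + abs(aR))
  }
  if (length(cand) == 0L) return(c(start = s, end = e))
  cm <- do.call(rbind, cand)
  eligible <- cm[cm[, "supp"] >= max(3, ceiling(0.7 * max(cm[, "supp"]))), ,
                 drop = FALSE]
  ord <- order(-eligible[, "len"], -eligible[, "supp"],
               eligible[, "shift"], abs(eligible[, "aL"]))
  best <- eligible[ord[1], ]
  c(start = s + best[["aL"]], end = e - best[["aR"]])
}

#' Curate a consensus against its genomic copies
#'
#' One curation step: build the anchored star alignment, detect the element
#' termini, polish them with target-site-duplication support, and derive a
#' new majority-rule consensus with indel-event handling and 10-N
#' placeholders. Because a single anchored pass cannot extend past the
#' draft's own span, the procedure iterates (re-anchoring on each new
#' consensus) until the sequence stabilises or `max_rounds` is reached,
#' mirroring iterative manual practice. Later rounds re-align only a window
#' of each copy around its previous aligned span, for speed.
#'
#' @param anchor the draft [consensus_record()] (or sequence string).
#' @param copies named character vector of flank-extended copy sequences in
#'   consensus orientation.
#' @param window,min_depth,agreement_min see [detect_termini()].
#' @param majority_frac,minor_frac see [column_consensus()].
#' @param complexity_frac,max_length_classes see [indel_consensus()].
#' @param tsd_polish apply TSD-aware terminus polishing (default TRUE).
#' @param max_rounds maximum re-anchoring rounds (default 8).
#' @param realign_margin copy window margin, bp, for later rounds
#'   (default 300).
#' @param focus optional n-copies x 2 matrix of 1-based `[lo, hi]` windows
#'   locating each copy's element region (e.g. from hit coordinates); the
#'   first round then aligns only `lo - 2 * realign_margin` to
#'   `hi + 2 * realign_margin` of each copy instead of the whole sequence.
#' @return object of class `te_curation`: list with `record` (the new
#'   [consensus_record()], version incremented, status `curated`), `msa`
#'   (final alignment with the curated version appended as an extra row),
#'   `termini` (column range), `flanks` (per-copy left flank, element core
#'   and right flank sequences, for hallmark detection) and `rounds`.
#' @export
curate <- function(anchor, copies, window = 15L, min_depth = 3,
                   agreement_min = 0.7, majority_frac = 0.5,
                   minor_frac = 0.25, complexity_frac = 1 / 3,
                   max_length_classes = 4L, tsd_polish = TRUE,
                   max_rounds = 8L, realign_margin = 300L, focus = NULL) {
  if (length(copies) == 0L) stop("empty copy set")
  if (is(anchor, "consensus_record")) rec0 <- anchor
  else rec0 <- consensus_record("consensus", toupper(as.character(anchor)))
  if (is.null(names(copies)))
    names(copies) <- paste0("copy", seq_along(copies))
  cur_seq <- rec0$sequence
  anchor_seq <- cur_seq
  win_lo <- rep(1L, length(copies))
  win_hi <- nchar(copies)
  if (!is.null(focus)) {
    stopifnot(nrow(focus) == length(copies))
    win_lo <- pmax(1L, as.integer(focus[, 1]) - 2L * realign_margin)
    win_hi <- pmin(nchar(copies),
                   as.integer(focus[, 2]) + 2L * realign_margin)
  }
  used_lo <- win_lo
  used_hi <- win_hi
  res <- NULL
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    used_lo <- win_lo
    used_hi <- win_hi
    sub <- substr(copies, win_lo, win_hi)
    names(sub) <- names(copies)
    msa <- build_star_msa(consensus_record(rec0$id, anchor_seq,
                                           version = rec0$version),
                          sub)
    # polishing is deferred to a final pass once the sequence is stable
    res <- .consensus_pass(msa, window, min_depth, agreement_min,
                           majority_frac, minor_frac, complexity_frac,
                           max_length_classes, tsd_polish = FALSE)
    new_seq <- res$consensus
    # update per-copy realignment windows from this round's core spans
    spans <- res$core_spans_in_copy
    new_lo <- pmax(1L, used_lo + spans[, 1] - 1L - realign_margin)
    new_hi <- pmin(nchar(copies), used_lo + spans[, 2] - 1L +
                     realign_margin)
    degenerate <- spans[, 2] < spans[, 1]
    win_lo <- ifelse(degenerate, used_lo, new_lo)
    win_hi <- ifelse(degenerate, used_hi, new_hi)
    stable <- identical(new_seq, cur_seq)
    cur_seq <- new_seq
    if (stable || rounds >= max_rounds) break
    # re-anchor on the probed consensus so the next round's alignment can
    # pin down flanking sequence that justified stacking only approximates
    anchor_seq <- paste0(res$probe_left, new_seq, res$probe_right)
  }
  if (tsd_polish) {
    res <- .consensus_pass(res$msa, window, min_depth, agreement_min,
                           majority_frac, minor_frac, complexity_frac,
                           max_length_classes, tsd_polish = TRUE)
    cur_seq <- res$consensus
  }
  new_rec <- consensus_record(rec0$id, cur_seq,
                              classification = rec0$classification,
                              version = rec0$version + 1L,
                              status = "curated", curator = rec0$curator)
  # reattach full flank sequence beyond the realignment window
  flanks <- res$flanks
  for (i in seq_along(copies)) {
    lo <- used_lo[i]; hi <- used_hi[i]
    if (lo > 1L)
      flanks[[i]]$left <- paste0(substr(copies[[i]], 1L, lo - 1L),
                                 flanks[[i]]$left)
    if (hi < nchar(copies[[i]]))
      flanks[[i]]$right <- paste0(flanks[[i]]$right,
                                  substr(copies[[i]], hi + 1L,
                                         nchar(copies[[i]])))
  }
  names(flanks) <- names(copies)
  msa_out <- snapshot_version(new_rec, res$msa, gapped = res$gapped)
  structure(list(record = new_rec, msa = msa_out,
                 termini = res$termini, flanks = flanks,
                 rounds = rounds),
            class = "te_curation")
}

#' @export
print.te_curation <- function(x, ...) {
  cat(sprintf("<te_curation> %s: %d bp after %d round(s), columns [%d,%d)\n",
              x$record$id, nchar(x$record$sequence), x$rounds,
              x$termini[1], x$termini[2]))
  invisible(x)
}

# one full consensus pass over an existing MSA
.consensus_pass <- function(msa, window, min_depth, agreement_min,
                            majority_frac, minor_frac, complexity_frac,
                            max_length_classes, tsd_polish) {
  Mall <- .msa_matrix(msa)
  M <- Mall[-msa$anchor, , drop = FALSE]
  spans <- .row_spans(M)
  term <- detect_termini(msa, window, min_depth, agreement_min)
  s <- term[[1]]; e <- term[[2]]
  if (tsd_polish) {
    pol <- .polish_termini(M, spans, s, e)
    s <- pol[[1]]; e <- pol[[2]]
  }
  cols <- s:(e - 1L)
  cover <- .cover_matrix(M, spans)
  base_cnt <- vapply(c("A", "C", "G", "T", "N"),
                     function(b) colSums(M == b), numeric(ncol(M)))
  gap_cnt <- colSums((M == "-") & cover)
  # a column is gappy when a covering copy row has a gap there
  gappy <- gap_cnt[cols] > 0L
  runs <- rle(gappy)
  pieces <- character(0)
  proj <- rep("-", ncol(M))
  idx <- 1L
  segments <- list()
  for (r in seq_along(runs$lengths)) {
    rng <- cols[idx:(idx + runs$lengths[r] - 1L)]
    if (!runs$values[r]) {
      segments[[length(segments) + 1L]] <- list(gap = FALSE, cols = rng)
    } else {
      # indel events are independent: split the gappy run into
      # overlap-connected components of per-row gap intervals, so that
      # adjacent but non-overlapping events stay separate regions
      for (comp in .split_gap_run(M, spans, rng))
        segments[[length(segments) + 1L]] <- list(gap = TRUE, cols = comp)
    }
    idx <- idx + runs$lengths[r]
  }
  for (seg in segments) {
    rng <- seg$cols
    if (!seg$gap) {
      piece <- vapply(rng, function(j) {
        if (sum(base_cnt[j, ]) < min_depth) return("")
        column_consensus(c(base_cnt[j, ], "-" = gap_cnt[j]),
                         majority_frac, minor_frac, min_depth)
      }, "")
      keep <- piece != "" & piece != "-"
      proj[rng[keep]] <- piece[keep]
      pieces <- c(pieces, paste(piece[keep], collapse = ""))
    } else {
      rc <- .region_call(M, spans, rng, complexity_frac,
                         max_length_classes,
                         majority_frac = majority_frac,
                         minor_frac = minor_frac)
      pieces <- c(pieces, rc$consensus)
      k <- nchar(rc$consensus)
      if (k > 0L) {
        fill <- min(k, length(rng))
        proj[rng[seq_len(fill)]] <-
          strsplit(rc$consensus, "")[[1]][seq_len(fill)]
      }
    }
  }
  consensus <- paste(pieces, collapse = "")
  if (!nzchar(consensus)) stop("no alignable core")
  # provisional probe consensus just outside the alignable part: plurality
  # base of adjacent flank columns. Appended to the next round's anchor it
  # lets the aligner anchor flanking copy sequence properly (justified
  # stacking drifts over indels), and is trimmed again if it proves junk.
  # The probe stops where column support collapses (three informative
  # columns in a row below 0.5 agreement): probing into unrelated flank
  # sequence would disrupt the terminal alignment instead of helping it
  probe_strip <- function(cols) {
    depth_ok <- rowSums(base_cnt[cols, c("A", "C", "G", "T"),
                                 drop = FALSE]) >= min_depth
    out <- character(0)
    fails <- 0L
    for (i in seq_along(cols)) {
      j <- cols[i]
      if (!depth_ok[i]) next
      cnt <- base_cnt[j, c("A", "C", "G", "T")]
      if (max(cnt) / sum(cnt) < 0.5) {
        fails <- fails + 1L
        if (fails >= 3L) break
        next
      }
      fails <- 0L
      out <- c(out, names(cnt)[which.max(cnt)])
    }
    out
  }
  probe_len <- 50L
  probe_left <- if (s > 1L)
    paste(rev(probe_strip(rev(seq(max(1L, s - probe_len), s - 1L)))),
          collapse = "")
  else ""
  probe_right <- if (e <= ncol(M))
    paste(probe_strip(seq(e, min(ncol(M), e + probe_len - 1L))),
          collapse = "")
  else ""
  flanks <- .copy_flanks_at(M, spans, s, e)
  # where the core sits within each (windowed) copy sequence
  core_spans <- t(vapply(seq_len(nrow(M)), function(r) {
    lf <- nchar(flanks[[r]]$left)
    c(lf + 1L, lf + nchar(flanks[[r]]$core))
  }, integer(2)))
  list(consensus = consensus, termini = c(start = s, end = e),
       flanks = flanks, core_spans_in_copy = core_spans,
       probe_left = probe_left, probe_right = probe_right,
       msa = msa, gapped = paste(proj, collapse = ""))
}

#' Compare consensus lengths before and after curation
#'
#' @param before,after two `te_library` objects matched by record id.
#' @return list with `table` (per-id `len_before`, `len_after`, `delta`),
#'   `median_delta`, and `unmatched` ids present in only one library.
#' @export
length_comparison <- function(before, after) {
  ids <- intersect(names(before), names(after))
  unmatched <- union(setdiff(names(before), ids),
                     setdiff(names(after), ids))
  if (length(unmatched))
    warning("unmatched ids excluded: ", paste(unmatched, collapse = ", "))
  lb <- vapply(before[ids], function(r) nchar(r$sequence), 0L)
  la <- vapply(after[ids], function(r) nchar(r$sequence), 0L)
  tab <- data.frame(id = ids, len_before = lb, len_after = la,
                    delta = la - lb, row.names = NULL)
  list(table = tab, median_delta = stats::median(tab$delta),
       unmatched = unmatched)
}
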