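## Structural hallmark detection: terminal inverted repeats (TIRs), long
## terminal repeats (LTRs), target site duplications (TSDs, including
## incomplete/central ones such as Tc4's TNA), and boundary sequence logos.

#' Find terminal inverted repeats
#'
#' Locally aligns the 5' end region against the reverse complement of the
#' 3' end region. A TIR is reported when the best arm alignment is at least
#' `min_len` long, its mismatch fraction is at most `max_mismatch_frac`,
#' and both arms start within `max_offset` of their terminus.
#'
#' @param element element sequence (string or [consensus_record()]).
#' @param min_len minimum arm length (default 8).
#' @param max_mismatch_frac maximum mismatch fraction in the arm alignment
#'   (default 0.2).
#' @param max_offset maximum distance of an arm from its terminus
#'   (default 30).
#' @return `NULL`, or a list with `arm5`/`arm3` (0-based half-open intervals
#'   on the element), `length` and `mismatches`.
#' @export
find_tir <- function(element, min_len = 8L, max_mismatch_frac = 0.2,
                     max_offset = 30L) {
  seq <- if (is(element, "consensus_record")) element$sequence
         else toupper(as.character(element))
  L <- nchar(seq)
  if (L < 2L * min_len) return(NULL)
  w <- min(L %/% 2L, max_offset + 50L)
  left <- substr(seq, 1L, w)
  right <- substr(seq, L - w + 1L, L)
  pa <- .align(left, .revcomp(right), type = "local",
               match = 1, mismatch = -1, gap_open = 3, gap_ext = 1)
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  if (alen < min_len) return(NULL)
  # the arm's net alignment score must also reach min_len, which filters
  # the mismatch-studded chance matches abundant in random sequence
  if (pa@score < min_len) return(NULL)
  mm <- Biostrings::nmismatch(pa)
  if (mm / alen > max_mismatch_frac) return(NULL)
  p1 <- IRanges::start(pa@pattern@range)   # in left region, 1-based
  p2 <- IRanges::end(pa@pattern@range)
  s1 <- IRanges::start(pa@subject@range)   # in revcomp(right region)
  s2 <- IRanges::end(pa@subject@range)
  # map revcomp coordinates back onto the element's 3' end
  arm3_start <- L - w + (w - s2 + 1L) - 1L  # 0-based
  arm3_end <- L - w + (w - s1 + 1L)
  if (p1 - 1L > max_offset) return(NULL)
  if (L - arm3_end > max_offset) return(NULL)
  list(arm5 = c(p1 - 1L, p2), arm3 = c(arm3_start, arm3_end),
       length = alen, mismatches = mm)
}

#' Find long terminal repeats
#'
#' Best direct-repeat match between the 5' and 3' terminal regions; a pair
#' is reported when the aligned span is at least `min_len`, identity is at
#' least `min_identity`, and both copies start within `max_offset` of their
#' terminus.
#'
#' @param element element sequence (string or [consensus_record()]).
#' @param min_len minimum LTR length (default 80).
#' @param min_identity minimum identity (default 0.8).
#' @param max_offset maximum distance from each terminus (default 50).
#' @return `NULL`, or a list with `ltr5`/`ltr3` (0-based half-open
#'   intervals), `length` and `identity`.
#' @export
find_ltr <- function(element, min_len = 80L, min_identity = 0.8,
                     max_offset = 50L) {
  seq <- if (is(element, "consensus_record")) element$sequence
         else toupper(as.character(element))
  L <- nchar(seq)
  if (L < 2L * min_len) return(NULL)
  w <- min(L %/% 2L, max_offset + 2000L)
  left <- substr(seq, 1L, w)
  right <- substr(seq, L - w + 1L, L)
  pa <- .align(left, right, type = "local",
               match = 1, mismatch = -1, gap_open = 3, gap_ext = 1)
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  if (alen < min_len) return(NULL)
  ident <- Biostrings::nmatch(pa) / alen
  if (ident < min_identity) return(NULL)
  p1 <- IRanges::start(pa@pattern@range); p2 <- IRanges::end(pa@pattern@range)
  s1 <- IRanges::start(pa@subject@range); s2 <- IRanges::end(pa@subject@range)
  off3 <- L - (L - w + s2)           # distance of 3' copy end from terminus
  if (p1 - 1L > max_offset || off3 > max_offset) return(NULL)
  list(ltr5 = c(p1 - 1L, p2),
       ltr3 = c(L - w + s1 - 1L, L - w + s2),
       length = alen, identity = ident)
}

.as_flank_list <- function(copies_with_flanks) {
  stopifnot(is.list(copies_with_flanks), length(copies_with_flanks) >= 1L)
  lapply(copies_with_flanks, function(f) {
    stopifnot(all(c("left", "core", "right") %in% names(f)))
    list(left = toupper(f$left), core = toupper(f$core),
         right = toupper(f$right))
  })
}

#' Find target site duplications across copies
#'
#' For every copy, the longest suffix of the left flank equal to the prefix
#' of the right flank (one mismatch tolerated for calls of 8 bp or more) is
#' called as its TSD. The consensus TSD length is the plurality length
#' across copies (0 means no duplication, reported as `"none"`), and the
#' motif is the IUPAC column consensus of the calls at that length. Copies
#' at identical loci (duplicate names) are collapsed first.
#'
#' @param copies_with_flanks named list of per-copy
#'   `list(left=, core=, right=)` flank/element sequences, e.g.
#'   the `flanks` component of [curate()].
#' @param min_len,max_len TSD length bounds (defaults 2 and 20).
#' @param motif_majority,motif_minor motif-call thresholds: a position is a
#'   single base only when that base reaches `motif_majority` of the calls,
#'   otherwise the IUPAC code of every base at frequency `>= motif_minor`
#'   (defaults 0.8 and 0.05). A site model describes the set of observed
#'   duplications, so minor variants are included rather than out-voted.
#' @return list with `calls` (per-copy data frame: `tsd`, `length`),
#'   `length` (consensus length, 0 when none) and `motif` (IUPAC string or
#'   `"none"`).
#' @export
find_tsd <- function(copies_with_flanks, min_len = 2L, max_len = 20L,
                     motif_majority = 0.8, motif_minor = 0.05) {
  fl <- .as_flank_list(copies_with_flanks)
  if (!is.null(names(fl)) && anyDuplicated(names(fl)))
    fl <- fl[!duplicated(names(fl))]
  calls <- lapply(fl, function(f) .tsd_call(f$left, f$right,
                                            min_len, max_len))
  lens <- vapply(calls, `[[`, 0L, "length")
  tab <- table(lens)
  top <- as.integer(names(tab))[tab == max(tab)]
  cons_len <- min(top)                 # tie -> shorter (conservative)
  motif <- "none"
  if (cons_len > 0L) {
    strs <- vapply(calls[lens == cons_len], `[[`, "", "tsd")
    motif <- iupac_motif(strs, majority_frac = motif_majority,
                         minor_frac = motif_minor)
  }
  list(calls = data.frame(copy = if (is.null(names(fl)))
                            seq_along(fl) else names(fl),
                          tsd = vapply(calls, `[[`, "", "tsd"),
                          length = lens, row.names = NULL),
       length = cons_len, motif = motif)
}

#' Reconstruct the pre-insertion target-site model
#'
#' Extends the consensus TSD motif with flanking context: the bases of the
#' left flank immediately before the TSD and of the right flank immediately
#' after it. Uninformative (`N`) context positions are trimmed from the
#' outside, so a fully random context degenerates to the core alone. The
#' duplicated core is counted once, reconstructing the pre-insertion target
#' with the transposase cut annotated as `left|core|right` (e.g. Tc4's
#' `C|TNA|G`, whose central TNA alone is duplicated).
#'
#' @param tsd result of [find_tsd()].
#' @param copies_with_flanks as in [find_tsd()].
#' @param context number of context positions on each side (default 2).
#' @param motif_majority,motif_minor see [find_tsd()].
#' @return list with `pattern` (`left|core|right`, or `"none"` for a
#'   zero-length TSD), `core`, `left`, `right`.
#' @export
fit_target_site_model <- function(tsd, copies_with_flanks, context = 2L,
                                  motif_majority = 0.8,
                                  motif_minor = 0.05) {
  if (tsd$length == 0L)
    return(list(pattern = "none", core = "", left = "", right = ""))
  fl <- .as_flank_list(copies_with_flanks)
  keep <- tsd$calls$length == tsd$length
  lefts <- character(0); rights <- character(0)
  for (i in which(keep)) {
    lf <- fl[[i]]$left; rf <- fl[[i]]$right
    lctx <- substr(lf, max(1L, nchar(lf) - tsd$length - context + 1L),
                   nchar(lf) - tsd$length)
    rctx <- substr(rf, tsd$length + 1L,
                   min(nchar(rf), tsd$length + context))
    if (nchar(lctx) == context) lefts <- c(lefts, lctx)
    if (nchar(rctx) == context) rights <- c(rights, rctx)
  }
  left <- if (length(lefts))
    iupac_motif(lefts, majority_frac = motif_majority,
                minor_frac = motif_minor) else ""
  right <- if (length(rights))
    iupac_motif(rights, majority_frac = motif_majority,
                minor_frac = motif_minor) else ""
  left <- sub("^N+", "", left)     # trim uninformative outer context
  right <- sub("N+$", "", right)
  list(pattern = paste0(left, "|", tsd$motif, "|", right),
       core = tsd$motif, left = left, right = right)
}

#' Position frequency/information logos of element boundaries
#'
#' Builds base-frequency and information-content profiles over the
#' `upstream` positions immediately before the 5' TIR arm and the
#' `downstream` positions immediately after the 3' TIR arm (windows are
#' anchored at the outermost TIR base; with `tir_arms = NULL` the element
#' boundaries themselves anchor the windows). Copies with insufficient
#' flank are excluded with a warning. Information content is
#' `2 + sum(f * log2(f))` bits per position, uncorrected for small samples.
#'
#' @param copies_with_flanks as in [find_tsd()].
#' @param tir_arms optional TIR report from [find_tir()]; its `arm5` start
#'   offset and `arm3` end offset shift the windows into the element.
#' @param upstream,downstream window widths (defaults 15 and 11).
#' @return list with `logo5` and `logo3`, each a list of `freq` (4 x width
#'   matrix, columns sum to 1) and `ic` (bits, in `[0, 2]`).
#' @export
boundary_logo <- function(copies_with_flanks, tir_arms = NULL,
                          upstream = 15L, downstream = 11L) {
  fl <- .as_flank_list(copies_with_flanks)
  off5 <- if (!is.null(tir_arms)) tir_arms$arm5[1] else 0L
  off3 <- if (!is.null(tir_arms))
    nchar(fl[[1]]$core) - tir_arms$arm3[2] else 0L
  win5 <- character(0); win3 <- character(0)
  short <- 0L
  for (f in fl) {
    l5 <- paste0(f$left, substr(f$core, 1L, off5))
    r3 <- if (off3 > 0L) paste0(substr(f$core,
                                       nchar(f$core) - off3 + 1L,
                                       nchar(f$core)), f$right)
          else f$right
    if (nchar(l5) < upstream || nchar(r3) < downstream) {
      short <- short + 1L
      next
    }
    win5 <- c(win5, substr(l5, nchar(l5) - upstream + 1L, nchar(l5)))
    win3 <- c(win3, substr(r3, 1L, downstream))
  }
  if (short > 0L) warning(short, " cop(ies) with short flanks excluded")
  if (length(win5) == 0L) stop("no copies with sufficient flank")
  list(logo5 = .logo(win5, upstream), logo3 = .logo(win3, downstream))
}

.logo <- function(windows, width) {
  M <- do.call(rbind, strsplit(windows, ""))
  freq <- vapply(seq_len(width), function(j) {
    cnt <- tabulate(match(M[, j], c("A", "C", "G", "T")), 4L)
    if (sum(cnt) == 0) rep(0.25, 4) else cnt / sum(cnt)
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  ic <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  list(freq = freq, ic = ic)
}

#' Full hallmark report for a curated family
#'
#' Convenience wrapper running [find_tir()], [find_ltr()], [find_tsd()] and
#' [fit_target_site_model()] on a curation result.
#'
#' @param curation a `te_curation` from [curate()], or a list with
#'   `record` and `flanks`.
#' @param ... threshold overrides passed to the detectors.
#' @return object of class `hallmark_report`: list with `tir`, `ltr`,
#'   `tsd`, `target_site_model`.
#' @export
hallmark_report <- function(curation, ...) {
  rec <- curation$record
  tir <- find_tir(rec)
  ltr <- find_ltr(rec)
  tsd <- find_tsd(curation$flanks)
  model <- fit_target_site_model(tsd, curation$flanks)
  structure(list(tir = tir, ltr = ltr, tsd = tsd,
                 target_site_model = model),
            class = "hallmark_report")
}

#' @export
print.hallmark_report <- function(x, ...) {
  cat("<hallmark_report>\n")
  cat("  TIR:", if (is.null(x$tir)) "none" else
    sprintf("%d bp, %d mismatch(es)", x$tir$length, x$tir$mismatches), "\n")
  cat("  LTR:", if (is.null(x$ltr)) "none" else
    sprintf("%d bp, %.0f%% identity", x$ltr$length,
            100 * x$ltr$identity), "\n")
  cat("  TSD:", if (x$tsd$length == 0L) "none" else
    sprintf("length %d, motif %s", x$tsd$length, x$tsd$motif), "\n")
  cat("  target site:", x$target_site_model$pattern, "\n")
  invisible(x)
}
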