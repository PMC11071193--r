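## Annotation-derived statistics: Kimura 2-parameter divergence, repeat
## landscapes, per-category masked fractions, and the putatively-active
## subfamily filter.

#' Kimura 2-parameter distance
#'
#' `K = -1/2 ln(1 - 2p - q) - 1/4 ln(1 - 2q)` where `p` and `q` are the
#' observed transition and transversion proportions.
#'
#' @param p transition proportion (A<->G, C<->T).
#' @param q transversion proportion.
#' @return K (substitutions per site); vectorized.
#' @export
kimura2p <- function(p, q) {
  if (any(p < 0 | q < 0)) stop("p and q must be non-negative")
  if (any(1 - 2 * p - q <= 0 | 1 - 2 * q <= 0))
    stop("saturated divergence: K2P undefined for these (p, q)")
  -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
}

.PURINES <- c("A", "G")

#' Transition/transversion proportions and K2P distance of an aligned pair
#'
#' Counts transitions (A<->G, C<->T) and transversions over columns where
#' both rows carry an unambiguous base; gap and IUPAC-ambiguous columns are
#' excluded from the denominator.
#'
#' @param a,b equal-length gapped sequence strings.
#' @return list with `p`, `q`, `K`, and `sites` (comparable columns).
#' @export
divergence_from_pair <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("rows must have equal length")
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("zero comparable columns")
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  ts <- diff & ((ca %in% .PURINES) == (cb %in% .PURINES))
  p <- sum(ts) / n
  q <- sum(diff & !ts) / n
  list(p = p, q = q, K = kimura2p(p, q), sites = n)
}

.top_category <- function(classification) {
  sub("/.*$", "", classification)
}

#' Repeat landscape: masked bp by category and divergence bin
#'
#' Each annotation row contributes its masked length (`qend - qbegin + 1`)
#' to the half-open divergence bin `[k, k+1)` of its top-level category
#' (the text before `/` in the classification); divergences of 50% or more
#' pool into the last bin. No overlap resolution is applied — standard
#' landscape semantics (see [masked_summary()] for flattened totals).
#'
#' @param rows annotation data frame from [read_rm_out()].
#' @param genome_size assembly size in bp.
#' @param bin_width divergence bin width in percent (default 1).
#' @param divergence divergence values to bin; defaults to `rows$pct_div`.
#' @return object of class `landscape_matrix`: a categories x bins matrix
#'   of masked bp with `genome_size` attribute; see
#'   [landscape_percent()].
#' @export
landscape <- function(rows, genome_size, bin_width = 1,
                      divergence = rows$pct_div) {
  stopifnot(genome_size > 0)
  if (any(divergence < 0)) stop("negative divergence")
  nbins <- ceiling(50 / bin_width)
  bins <- pmin(floor(divergence / bin_width), nbins - 1L) + 1L
  cats <- sort(unique(.top_category(rows$repeat_classification)))
  if (length(cats) == 0L) cats <- "Unknown"
  M <- matrix(0, nrow = length(cats), ncol = nbins,
              dimnames = list(cats,
                              paste0("[", (seq_len(nbins) - 1) * bin_width,
                                     ",", seq_len(nbins) * bin_width, ")")))
  if (nrow(rows) > 0L) {
    bp <- rows$qend - rows$qbegin + 1L
    cat_i <- match(.top_category(rows$repeat_classification), cats)
    for (i in seq_len(nrow(rows)))
      M[cat_i[i], bins[i]] <- M[cat_i[i], bins[i]] + bp[i]
  }
  structure(M, genome_size = genome_size, class = "landscape_matrix")
}

#' Landscape as percent of genome
#' @param x a `landscape_matrix`.
#' @return matrix of percentages.
#' @export
landscape_percent <- function(x) {
  100 * unclass(x) / attr(x, "genome_size")
}

#' @export
print.landscape_matrix <- function(x, ...) {
  cat(sprintf("<landscape_matrix> %d categories x %d bins, %.3f%% of %s bp masked\n",
              nrow(x), ncol(x), 100 * sum(x) / attr(x, "genome_size"),
              format(attr(x, "genome_size"), big.mark = ",")))
  invisible(x)
}

#' Plot a repeat landscape
#'
#' Stacked bar chart of percent of genome masked per divergence bin,
#' coloured by category (base graphics).
#'
#' @param x a `landscape_matrix`.
#' @param max_div right edge of the plotted divergence range (default 50).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.landscape_matrix <- function(x, max_div = 50, ...) {
  P <- landscape_percent(x)
  keep <- seq_len(min(ncol(P), max_div))
  graphics::barplot(P[, keep, drop = FALSE], col = seq_len(nrow(P)) + 1,
                    border = NA, names.arg = keep - 1,
                    xlab = "Kimura divergence from consensus (%)",
                    ylab = "percent of genome", legend.text = rownames(P),
                    ...)
  invisible(x)
}

#' Masked base pairs and genome percentages per category
#'
#' With `resolve_overlaps` (the default), overlapping annotations on the
#' same contig are flattened so each base counts once, assigned to the
#' highest-scoring row covering it; summed percentages then cannot exceed
#' 100. The categories of the main summary table (DNA, LINE, SINE, LTR,
#' Unknown) are always present, any others observed are appended, and a
#' `total` row closes the table.
#'
#' @param rows annotation data frame from [read_rm_out()].
#' @param genome_size assembly size in bp.
#' @param resolve_overlaps flatten overlapping intervals (default TRUE).
#' @return data frame with `category`, `bp`, `percent`.
#' @export
masked_summary <- function(rows, genome_size, resolve_overlaps = TRUE) {
  stopifnot(genome_size > 0)
  main <- c("DNA", "LINE", "SINE", "LTR", "Unknown")
  bp <- stats::setNames(rep(0, length(main)), main)
  if (nrow(rows) > 0L) {
    cat_all <- .top_category(rows$repeat_classification)
    if (resolve_overlaps) {
      for (ctg in unique(rows$query)) {
        sel <- which(rows$query == ctg)
        sel <- sel[order(-rows$score[sel])]      # higher score wins per base
        taken <- IRanges::IRanges()
        for (i in sel) {
          r <- IRanges::IRanges(rows$qbegin[i], rows$qend[i])
          free <- IRanges::setdiff(r, taken)
          w <- sum(IRanges::width(free))
          if (w > 0) {
            cc <- cat_all[i]
            if (!cc %in% names(bp)) bp[cc] <- 0
            bp[cc] <- bp[cc] + w
          }
          taken <- IRanges::union(taken, r)
        }
      }
    } else {
      agg <- tapply(rows$qend - rows$qbegin + 1L, cat_all, sum)
      for (cc in names(agg))
        bp[cc] <- if (cc %in% names(bp)) bp[cc] + agg[[cc]] else agg[[cc]]
    }
  }
  bp <- bp[!is.na(bp)]
  out <- data.frame(category = c(names(bp), "total"),
                    bp = c(unname(bp), sum(bp)), row.names = NULL)
  out$percent <- 100 * out$bp / genome_size
  out
}

#' Count putatively active subfamilies
#'
#' A subfamily (unique repeat name) is putatively active when it has at
#' least `min_copies` annotated copies at divergence `<= max_div` percent
#' from its consensus. Counts are aggregated by top-level category.
#'
#' @param rows annotation data frame from [read_rm_out()].
#' @param min_copies minimum copy count (default 10).
#' @param max_div maximum percent divergence (default 0, i.e. identical
#'   copies only; raise by a rounding epsilon if the annotation rounds).
#' @return list with `counts` (data frame: `category`, `n_subfamilies`)
#'   and `subfamilies` (qualifying names).
#' @export
active_subfamilies <- function(rows, min_copies = 10L, max_div = 0) {
  hit <- rows[rows$pct_div <= max_div, , drop = FALSE]
  tab <- table(hit$repeat_name)
  qual <- names(tab)[tab >= min_copies]
  if (length(qual) == 0L)
    return(list(counts = data.frame(category = character(),
                                    n_subfamilies = integer()),
                subfamilies = character()))
  cls <- vapply(qual, function(nm) {
    .top_category(rows$repeat_classification[rows$repeat_name == nm][1])
  }, "")
  cnt <- table(cls)
  list(counts = data.frame(category = names(cnt),
                           n_subfamilies = as.integer(cnt),
                           row.names = NULL),
       subfamilies = qual)
}
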