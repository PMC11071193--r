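## Synthetic TE families and genomes with truth annotations, so every other
## module is testable without downloads. The substitution process is
## K2P-compatible (two rates, transition:transversion ratio kappa) so that
## divergence recovery by kimura2p is a closed-loop check.

#' Specify a synthetic TE family
#'
#' Defaults describe a typical desk-scale study family: an 800 bp DNA
#' transposon with 12 bp terminal inverted repeats, a 6 bp target site
#' duplication, 15 genomic copies at 8% expected divergence, 10% of copies
#' 5'-truncated.
#'
#' @param name family name.
#' @param length element length in bp.
#' @param classification `Class/Superfamily` label.
#' @param tir_len terminal inverted repeat arm length (0 = none).
#' @param ltr_len long terminal repeat length (0 = none); mutually
#'   exclusive with `tir_len`.
#' @param tsd_len target site duplication length (0 = none).
#' @param target_site_pattern optional IUPAC insertion-site pattern with
#'   the duplicated core bracketed, e.g. `C[TNA]G` (core length must equal
#'   `tsd_len`).
#' @param copy_number number of genomic copies.
#' @param divergence expected substitutions per site per copy.
#' @param kappa transition:transversion ratio (default 2).
#' @param truncation_prob probability a copy is 5'-truncated (default 0.1).
#' @param truncation_range fraction of the element removed from the 5' end
#'   of a truncated copy, drawn uniformly (default `c(0.2, 0.8)`).
#' @param indel_factor small-indel rate as a multiple of the substitution
#'   rate (default 0.1); indel lengths are geometric with mean 2.
#' @param seed RNG seed for the family's element sequence.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(name = "fam1", length = 800L,
                        classification = "DNA/Unknown", tir_len = 12L,
                        ltr_len = 0L, tsd_len = 6L,
                        target_site_pattern = NULL, copy_number = 15L,
                        divergence = 0.08, kappa = 2,
                        truncation_prob = 0.1,
                        truncation_range = c(0.2, 0.8),
                        indel_factor = 0.1, seed = 1L) {
  if (tir_len > 0L && ltr_len > 0L)
    stop("tir_len and ltr_len are mutually exclusive")
  if (length < 2L * max(tir_len, ltr_len) + 10L)
    stop("element too short for its terminal repeats")
  if (!is.null(target_site_pattern)) {
    core <- sub("^.*\\[(.*)\\].*$", "\\1", target_site_pattern)
    if (!grepl("\\[.*\\]", target_site_pattern))
      stop("target_site_pattern must bracket the duplicated core")
    if (nchar(core) != tsd_len)
      stop("bracketed core length (", nchar(core),
           ") must equal tsd_len (", tsd_len, ")")
  }
  structure(list(name = name, length = as.integer(length),
                 classification = classification,
                 tir_len = as.integer(tir_len),
                 ltr_len = as.integer(ltr_len),
                 tsd_len = as.integer(tsd_len),
                 target_site_pattern = target_site_pattern,
                 copy_number = as.integer(copy_number),
                 divergence = divergence, kappa = kappa,
                 truncation_prob = truncation_prob,
                 truncation_range = truncation_range,
                 indel_factor = indel_factor, seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate the true element sequence of a family
#'
#' Random sequence with the specified terminal structure planted: the last
#' `tir_len` bases are the reverse complement of the first (TIR), or the
#' first `ltr_len` bases are repeated at the end (LTR). Deterministic under
#' the spec's seed.
#'
#' @param spec a [family_spec()].
#' @return the element sequence (string).
#' @export
simulate_family <- function(spec) {
  stopifnot(is(spec, "family_spec"))
  .with_seed(spec$seed, {
    seq <- .rand_dna(spec$length)
    if (spec$tir_len > 0L) {
      arm <- substr(seq, 1L, spec$tir_len)
      substr(seq, spec$length - spec$tir_len + 1L, spec$length) <-
        .revcomp(arm)
    } else if (spec$ltr_len > 0L) {
      ltr <- substr(seq, 1L, spec$ltr_len)
      substr(seq, spec$length - spec$ltr_len + 1L, spec$length) <- ltr
    }
    seq
  })
}

# K2P-style decay of one copy: per-site substitution probability d with
# transition fraction kappa/(kappa+1), plus small indels; returns the
# mutated sequence and the realized substitution fraction
.mutate_copy <- function(seq, d, kappa, indel_factor) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  sub_sites <- which(runif(L) < d)
  for (i in sub_sites) {
    b <- chars[i]
    if (!b %in% c("A", "C", "G", "T")) next
    if (runif(1) < kappa / (kappa + 1)) {
      chars[i] <- c(A = "G", G = "A", C = "T", T = "C")[[b]]
    } else {
      tv <- setdiff(c("A", "C", "G", "T"),
                    c(b, c(A = "G", G = "A", C = "T", T = "C")[[b]]))
      chars[i] <- sample(tv, 1L)
    }
  }
  realized <- length(sub_sites) / L
  n_indel <- rbinom(1L, L, d * indel_factor)
  if (n_indel > 0L) {
    for (k in seq_len(n_indel)) {
      pos <- sample(length(chars), 1L)
      len <- 1L + rgeom(1L, 0.5)
      if (runif(1) < 0.5) {   # deletion
        chars <- chars[-(pos:min(length(chars), pos + len - 1L))]
      } else {                # insertion
        chars <- append(chars, sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), after = pos)
      }
      if (length(chars) < 10L) break
    }
  }
  list(seq = paste(chars, collapse = ""), divergence = realized)
}

#' Simulate a genome with implanted TE family copies
#'
#' Copies are inserted into a random background at sites matching the
#' family's target-site pattern when one is given (the bracketed core is
#' duplicated on both sides of the insertion), or at random sites whose
#' `tsd_len` bases are duplicated. Each copy is independently decayed by
#' the two-rate substitution process, optionally 5'-truncated, and placed
#' on a random strand. A truth table records every copy.
#'
#' @param families list of [family_spec()]s (or a single one).
#' @param background_len background length in bp before insertions.
#' @param seed RNG seed for background, placement and decay.
#' @param min_separation minimum distance between insertion points
#'   (default 1000 bp).
#' @param contig name of the single contig emitted (default `"ctg1"`).
#' @return list with `genome` (named character vector), `truth` (data
#'   frame: `contig`, `start`, `end` 0-based half-open, `strand`, `family`,
#'   `divergence`, `tsd`, `truncated`), `elements` (named vector of true
#'   element sequences) and `specs`.
#' @export
simulate_genome <- function(families, background_len = 50000L, seed = 1L,
                            min_separation = 1000L, contig = "ctg1") {
  if (is(families, "family_spec")) families <- list(families)
  elements <- vapply(families, simulate_family, "")
  names(elements) <- vapply(families, `[[`, "", "name")
  .with_seed(seed, kind = "L'Ecuyer-CMRG", {
    bg <- .rand_dna(background_len)
    plan <- list()
    used <- integer(0)
    for (fi in seq_along(families)) {
      sp <- families[[fi]]
      if (!is.null(sp$target_site_pattern)) {
        pat <- gsub("\\[|\\]", "", sp$target_site_pattern)
        left_len <- nchar(sub("\\[.*$", "", sp$target_site_pattern))
        m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                      Biostrings::DNAString(bg),
                                      fixed = FALSE)
        sites <- IRanges::start(m)
        if (length(sites) == 0L)
          stop("no sites match pattern ", sp$target_site_pattern)
        sites <- sample(sites)
        pos <- integer(0)
        for (s in sites) {
          ip <- s + left_len + sp$tsd_len - 1L  # insert after the core
          if (all(abs(ip - used) >= min_separation) &&
              ip > 100L && ip < background_len - 100L) {
            pos <- c(pos, ip)
            used <- c(used, ip)
            if (length(pos) == sp$copy_number) break
          }
        }
        if (length(pos) < sp$copy_number)
          stop("not enough separated pattern sites for ", sp$name)
      } else {
        # spaced sampling: k sorted uniform draws shifted apart by the
        # minimum separation, retried against other families' sites
        lo <- 100L + sp$tsd_len
        hi <- background_len - 100L
        k <- sp$copy_number
        if (hi - (k - 1L) * min_separation <= lo)
          stop("could not place all copies of ", sp$name,
               "; increase background_len")
        pos <- NULL
        for (try in 1:50) {
          u <- sort(runif(k, lo, hi - (k - 1L) * min_separation))
          cand <- as.integer(round(u + (seq_len(k) - 1L) * min_separation))
          if (all(vapply(cand, function(ip)
            all(abs(ip - used) >= min_separation), TRUE))) {
            pos <- cand
            break
          }
        }
        if (is.null(pos))
          stop("could not place all copies of ", sp$name,
               "; increase background_len")
        used <- c(used, pos)
      }
      for (ip in pos) {
        mut <- .mutate_copy(elements[[sp$name]], sp$divergence,
                            sp$kappa, sp$indel_factor)
        cseq <- mut$seq
        truncated <- runif(1) < sp$truncation_prob
        if (truncated) {
          cut <- floor(nchar(cseq) *
                         runif(1, sp$truncation_range[1],
                               sp$truncation_range[2]))
          cseq <- substr(cseq, cut + 1L, nchar(cseq))
        }
        strand <- sample(c("+", "-"), 1L)
        tsd <- if (sp$tsd_len > 0L)
          substr(bg, ip - sp$tsd_len + 1L, ip) else ""
        plan[[length(plan) + 1L]] <-
          list(ip = ip, family = sp$name,
               seq = if (strand == "-") .revcomp(cseq) else cseq,
               tsd = tsd, strand = strand,
               divergence = mut$divergence, truncated = truncated)
      }
    }
    plan <- plan[order(vapply(plan, `[[`, 0L, "ip"))]
    pieces <- character(0)
    truth <- list()
    prev <- 0L
    offset <- 0L
    for (p in plan) {
      pieces <- c(pieces, substr(bg, prev + 1L, p$ip), p$seq, p$tsd)
      start0 <- p$ip + offset              # 0-based element start
      truth[[length(truth) + 1L]] <-
        data.frame(contig = contig, start = start0,
                   end = start0 + nchar(p$seq), strand = p$strand,
                   family = p$family, divergence = p$divergence,
                   tsd = p$tsd, truncated = p$truncated)
      offset <- offset + nchar(p$seq) + nchar(p$tsd)
      prev <- p$ip
    }
    pieces <- c(pieces, substr(bg, prev + 1L, background_len))
    genome <- stats::setNames(paste(pieces, collapse = ""), contig)
    list(genome = genome, truth = do.call(rbind, truth),
         elements = elements, specs = families)
  })
}

#' Project a truth table onto the .out annotation dialect
#'
#' Emits one annotation row per implanted copy with `pct_div` set to the
#' realized per-copy divergence (in percent, one decimal as in the file
#' dialect), so annotation statistics are testable without any masking
#' engine.
#'
#' @param truth truth table from [simulate_genome()].
#' @param genome the genome it describes (for the `qleft` fields).
#' @param classifications named vector mapping family name to
#'   classification (defaults to `DNA/Unknown`).
#' @return annotation data frame in the layout of [read_rm_out()].
#' @export
project_truth_to_out <- function(truth, genome,
                                 classifications = NULL) {
  clen <- nchar(genome[[1]])
  cls <- function(fam) {
    if (!is.null(classifications) && fam %in% names(classifications))
      classifications[[fam]] else "DNA/Unknown"
  }
  n <- nrow(truth)
  data.frame(score = rep(1000, n),
             pct_div = round(truth$divergence * 100, 1),
             pct_del = rep(0, n), pct_ins = rep(0, n),
             query = truth$contig,
             qbegin = truth$start + 1L, qend = truth$end,
             qleft = clen - truth$end,
             strand = truth$strand,
             repeat_name = truth$family,
             repeat_classification = vapply(truth$family, cls, ""),
             rbegin = rep(1L, n),
             rend = truth$end - truth$start,
             rleft = rep(0L, n), id = as.character(seq_len(n)))
}

#' Extract implanted copies with flanks using the truth table
#'
#' Returns every implanted copy in consensus orientation with `flank` bp of
#' genomic context on each side, labelled by locus.
#'
#' @param sim result of [simulate_genome()].
#' @param flank context width in bp (default 60).
#' @param family restrict to one family name (default: all).
#' @return named character vector of oriented sequences.
#' @export
truth_copies <- function(sim, flank = 60L, family = NULL) {
  tr <- sim$truth
  if (!is.null(family)) tr <- tr[tr$family == family, , drop = FALSE]
  g <- sim$genome
  out <- character(nrow(tr))
  labs <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    s <- max(0L, tr$start[i] - flank)
    e <- min(nchar(g[[tr$contig[i]]]), tr$end[i] + flank)
    seq <- substr(g[[tr$contig[i]]], s + 1L, e)
    if (tr$strand[i] == "-") seq <- .revcomp(seq)
    out[i] <- seq
    labs[i] <- sprintf("%s:%d-%d(%s)", tr$contig[i], s, e, tr$strand[i])
  }
  stats::setNames(out, labs)
}

#' Degrade an element into an automated-style draft consensus
#'
#' Emulates the typical defects of an automatically generated raw
#' consensus: truncation to a central fragment and light sequence noise.
#' Useful as the starting anchor when exercising the curation loop.
#'
#' @param element true element sequence.
#' @param keep_frac central fraction retained (default 0.7).
#' @param divergence substitution rate of the noise (default 0.02).
#' @param seed RNG seed.
#' @return the draft sequence (string).
#' @export
degrade_element <- function(element, keep_frac = 0.7, divergence = 0.02,
                            seed = 1L) {
  .with_seed(seed, {
    L <- nchar(element)
    keep <- floor(L * keep_frac)
    off <- floor((L - keep) / 2)
    frag <- substr(element, off + 1L, off + keep)
    .mutate_copy(frag, divergence, kappa = 2, indel_factor = 0)$seq
  })
}
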