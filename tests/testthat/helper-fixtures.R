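# shared fixtures and small independent oracles

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# independent re-statement of the majority/IUPAC column rule, written as a
# literal walk through the rule table (the implementation is count-based)
oracle_column_call <- function(a, c, g, t, n = 0, gap = 0,
                               majority = 0.5, minor = 0.25) {
  total <- a + c + g + t + n + gap
  stopifnot(total > 0)
  if (gap > total / 2) return("-")
  depth <- total - gap
  counts <- c(A = a, C = c, G = g, T = t)
  freqs <- counts / depth
  top <- names(freqs)[order(-freqs)][1]
  if (freqs[[top]] > majority) return(top)
  keep <- names(freqs)[freqs >= minor]
  if (length(keep) == 0) return("N")
  code_table <- c(A = "A", C = "C", G = "G", T = "T",
                  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K",
                  AC = "M", CGT = "B", AGT = "D", ACT = "H", ACG = "V",
                  ACGT = "N")
  code_table[[paste(sort(keep), collapse = "")]]
}

# independent indel-region decision: plurality with shorter-wins ties;
# complex when the top class is under a third of rows or more than four
# recurrent (>= 2 rows) length classes occur
oracle_indel_call <- function(lengths) {
  counts <- table(lengths)
  top <- max(counts)
  winners <- as.integer(names(counts)[counts == top])
  list(length = min(winners),
       complex = top < length(lengths) / 3 || sum(counts >= 2) > 4)
}

# a tiny aligned-FASTA family with known structure, for MSA-level tests:
# rows must be equal length, anchor first
make_msa <- function(seqs, labels = NULL, anchor = 1L) {
  if (is.null(labels)) labels <- paste0("row", seq_along(seqs))
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", labels, "\n", seqs), path)
  read_msa(path, anchor = anchor)
}

# genome with one implanted family under compact conditions, for fast tests
small_sim <- function(seed = 1, ...) {
  spec <- family_spec(seed = seed, ...)
  simulate_genome(spec, background_len = 90000L, seed = seed,
                  min_separation = 5000L)
}
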