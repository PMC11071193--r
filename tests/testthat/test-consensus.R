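test_that("star alignment projects copies onto anchor coordinates", {
  msa <- build_star_msa("ACGTACGT", c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(msa_ncol(msa), 8L)
  expect_false(any(grepl("-", msa$seqs, fixed = TRUE)))

  # one copy with a central 3 bp insertion -> 3 anchor-gap columns
  anchor <- rand_seq(30, seed = 4)
  with_ins <- paste0(substr(anchor, 1, 15), "TTT", substr(anchor, 16, 30))
  msa2 <- build_star_msa(anchor, c(a = with_ins, b = anchor))
  expect_equal(msa_ncol(msa2), 33L)
  anchor_row <- msa2$seqs[msa2$anchor]
  expect_equal(lengths(regmatches(anchor_row, gregexpr("-", anchor_row))),
               3L)
  # degapping recovers each input sequence
  expect_equal(gsub("-", "", msa2$seqs[2]), with_ins)

  expect_error(build_star_msa("ACGT", character(0)), "empty")
})

test_that("copies at 5% divergence align near their simulated identity", {
  set.seed(31)
  anchor <- rand_seq(500)
  mutate <- function(s, d) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < d)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  copies <- vapply(1:10, function(i) mutate(anchor, 0.05), "")
  names(copies) <- paste0("c", 1:10)
  msa <- build_star_msa(anchor, copies)
  M <- do.call(rbind, strsplit(msa$seqs, ""))
  idents <- vapply(2:11, function(r) mean(M[r, ] == M[1, ]), 0)
  expect_gt(mean(idents), 0.93)
  expect_lt(mean(idents), 0.97)
})

test_that("column consensus follows the majority/IUPAC rule table", {
  expect_equal(column_consensus(c(A = 3, G = 1)), "A")
  expect_equal(column_consensus(c(A = 2, G = 2)), "R")
  expect_equal(column_consensus(c(A = 1, C = 1, G = 1, T = 1)), "N")
  # gaps above half the rows silence the column
  expect_equal(column_consensus(c(A = 2, "-" = 5), min_depth = 1), "-")
  # N rows count toward depth but never win
  expect_equal(column_consensus(c(A = 2, N = 2), min_depth = 1), "A")
  expect_error(column_consensus(c(A = 0)), "empty")
  expect_error(column_consensus(c(A = 2), min_depth = 3), "depth")
})

test_that("column consensus matches brute-force enumeration to depth 6", {
  for (total in 1:6) {
    combos <- expand.grid(a = 0:total, c = 0:total, g = 0:total,
                          t = 0:total, gap = 0:total)
    combos <- combos[rowSums(combos) == total, ]
    for (i in seq_len(nrow(combos))) {
      cc <- combos[i, ]
      prof <- c(A = cc$a, C = cc$c, G = cc$g, T = cc$t, "-" = cc$gap)
      expect_equal(
        column_consensus(prof, min_depth = 1),
        oracle_column_call(cc$a, cc$c, cc$g, cc$t, gap = cc$gap),
        info = paste(prof, collapse = ","))
    }
  }
})

test_that("indel regions resolve by plurality with shorter-wins ties", {
  # anchor + rows; region = columns 5..9 (a 5-column gap block)
  mk <- function(fill_counts) {
    rows <- vapply(fill_counts, function(k) {
      paste0("ACGT", strrep("G", k), strrep("-", 5 - k), "TTAA")
    }, "")
    make_msa(c("ACGTGGGGGTTAA", rows))
  }
  # 6 rows place 0 residues, 2 rows place 5 -> deletion wins
  res <- indel_consensus(mk(c(0, 0, 0, 0, 0, 0, 5, 5)), 5:9)
  expect_equal(res$length, 0L)
  expect_false(res$complex)
  # 4 rows place 3, 3 rows place 0 -> length 3
  res2 <- indel_consensus(mk(c(3, 3, 3, 3, 0, 0, 0)), 5:9)
  expect_equal(res2$length, 3L)
  expect_equal(res2$consensus, "GGG")
  # tie 2 vs 4 -> shorter
  res3 <- indel_consensus(mk(c(2, 2, 2, 4, 4, 4)), 5:9)
  expect_equal(res3$length, 2L)
})

test_that("indel decisions match brute-force enumeration up to 6 rows", {
  set.seed(11)
  for (rep in 1:300) {
    n <- sample(2:6, 1)
    lens <- sample(0:5, n, replace = TRUE)
    msa <- make_msa(c("ACGTGGGGGTTAA",
                      vapply(lens, function(k) {
                        paste0("ACGT", strrep("G", k), strrep("-", 5 - k),
                               "TTAA")
                      }, "")))
    got <- indel_consensus(msa, 5:9)
    want <- oracle_indel_call(lens)
    expect_equal(got$complex, want$complex,
                 info = paste(lens, collapse = ","))
    if (!want$complex)
      expect_equal(got$length, want$length,
                   info = paste(lens, collapse = ","))
  }
})

test_that("unresolvable regions get exactly ten Ns", {
  mk <- function(fill_counts, width = 12L) {
    rows <- vapply(fill_counts, function(k) {
      paste0("ACGT", strrep("G", k), strrep("-", width - k), "TTAA")
    }, "")
    make_msa(c(paste0("ACGT", strrep("G", width), "TTAA"), rows))
  }
  region <- 5:16
  # five distinct singleton lengths: no class reaches a third
  expect_equal(unresolved_placeholder(mk(c(0, 2, 4, 7, 11)), region),
               "NNNNNNNNNN")
  res <- indel_consensus(mk(c(0, 2, 4, 7, 11)), region)
  expect_true(res$complex)
  expect_equal(res$consensus, "NNNNNNNNNN")
  # a clear plurality resolves instead
  expect_null(unresolved_placeholder(mk(c(3, 3, 3, 0, 1, 2)), region))
  expect_equal(indel_consensus(mk(c(3, 3, 3, 0, 1, 2)), region)$length, 3L)
  # full agreement never triggers the placeholder
  expect_null(unresolved_placeholder(mk(c(4, 4, 4, 4)), region))
})

test_that("termini detection finds the alignable part", {
  # identical full-length rows: the whole alignment is alignable
  rows <- rep(rand_seq(60, seed = 2), 4)
  msa <- make_msa(c(rows[1], rows))
  expect_equal(unname(detect_termini(msa)), c(1L, 61L))

  # two copies cannot satisfy min_depth 3
  msa2 <- make_msa(c(rows[1], rows[1], rows[1]))  # anchor + 2 copies
  expect_error(detect_termini(msa2, min_depth = 3), "no alignable core")

  # shared core with random flanks: detected within 10 columns of truth
  set.seed(13)
  core <- rand_seq(300)
  copies <- vapply(1:10, function(i) {
    paste0(rand_seq(2000), core, rand_seq(2000))
  }, "")
  names(copies) <- paste0("c", 1:10)
  msa3 <- build_star_msa(core, copies)
  term <- detect_termini(msa3)
  anchor_cols <- which(strsplit(msa3$seqs[1], "")[[1]] != "-")
  expect_lte(abs(term[[1]] - anchor_cols[1]), 10L)
  expect_lte(abs(term[[2]] - (anchor_cols[300] + 1L)), 10L)
})

test_that("curation recovers a simulated element from a truncated draft", {
  sim <- small_sim(seed = 17)
  el <- sim$elements[[1]]
  draft <- degrade_element(el, seed = 17)
  expect_lt(nchar(draft), nchar(el))
  cur <- curate_in_genome(consensus_record("fam_draft", draft), sim$genome)
  expect_s3_class(cur, "te_curation")
  expect_equal(cur$record$version, 2L)
  expect_equal(cur$record$status, "curated")
  acc <- consensus_accuracy(cur$record, el)
  expect_gte(acc$identity, 95)
  expect_gte(acc$coverage, 0.95)
  # curation must lengthen a truncated draft
  expect_gt(nchar(cur$record$sequence), nchar(draft))
  # the consensus is pure IUPAC, no gaps
  expect_match(cur$record$sequence, "^[ACGTRYSWKMBDHVN]+$")
  # the curated version is kept alongside the original in the alignment
  expect_true(paste0("fam_draft.v2") %in% cur$msa$labels)
})

test_that("curating a perfect consensus against identical copies is a no-op", {
  el <- rand_seq(400, seed = 23)
  copies <- stats::setNames(rep(el, 5), paste0("c", 1:5))
  cur <- curate(consensus_record("perfect", el), copies)
  expect_equal(cur$record$sequence, el)
})

test_that("length comparison pairs records and reports the median shift", {
  before <- te_library(list(consensus_record("a", rand_seq(500, seed = 1)),
                            consensus_record("b", rand_seq(300, seed = 2))))
  after_same <- before
  lc <- length_comparison(before, after_same)
  expect_true(all(lc$table$delta == 0))

  after <- te_library(list(consensus_record("a", rand_seq(1500, seed = 3)),
                           consensus_record("c", rand_seq(100, seed = 4))))
  expect_warning(lc2 <- length_comparison(before, after), "unmatched")
  expect_equal(lc2$table$delta, 1000L)
  expect_setequal(lc2$unmatched, c("b", "c"))
})
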