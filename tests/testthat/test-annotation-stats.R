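test_that("K2P distance matches independent evaluation on a grid", {
  expect_equal(kimura2p(0, 0), 0)
  # frozen values from high-precision evaluation of the closed form
  expect_equal(kimura2p(0.1, 0.05), 0.17018117, tolerance = 1e-7)
  expect_equal(kimura2p(0, 0.15), 0.17042820, tolerance = 1e-7)
  # log1p-based independent evaluation across the domain
  for (p in seq(0, 0.4, by = 0.02)) for (q in seq(0, 0.4, by = 0.02)) {
    if (1 - 2 * p - q > 1e-9 && 1 - 2 * q > 1e-9) {
      oracle <- -0.5 * log1p(-(2 * p + q)) - 0.25 * log1p(-2 * q)
      expect_equal(kimura2p(p, q), oracle, tolerance = 1e-9)
    }
  }
  expect_error(kimura2p(0.5, 0.2), "saturated")
  expect_error(kimura2p(-0.1, 0), "non-negative")
})

test_that("K2P always exceeds the raw difference proportion", {
  for (p in seq(0, 0.35, by = 0.05)) for (q in seq(0, 0.35, by = 0.05)) {
    if (1 - 2 * p - q > 0.01 && 1 - 2 * q > 0.01) {
      K <- kimura2p(p, q)
      expect_gte(K, p + q)
      if (p + q > 0) expect_gt(K, p + q)
    }
  }
})

test_that("pairwise divergence counts transitions and transversions", {
  d0 <- divergence_from_pair("ACGT", "ACGT")
  expect_equal(c(d0$p, d0$q, d0$K), c(0, 0, 0))

  # 100 columns with 10 transitions only
  a <- strrep("A", 50)
  b <- paste0(strrep("G", 10), strrep("A", 40))
  a2 <- paste0(a, strrep("C", 50))
  b2 <- paste0(b, strrep("C", 50))
  d <- divergence_from_pair(a2, b2)
  expect_equal(d$p, 0.1)
  expect_equal(d$q, 0)
  expect_equal(d$K, -0.5 * log(0.8), tolerance = 1e-9)

  # ambiguous and gap columns are excluded from the denominator
  d2 <- divergence_from_pair("ANC-G", "AGCTG")
  expect_equal(d2$sites, 3L)
  expect_error(divergence_from_pair("NN", "NN"), "zero comparable")
  expect_error(divergence_from_pair("ACG", "AC"), "equal length")
})

test_that("landscape bins masked bp by category and divergence", {
  rows <- data.frame(score = 100, pct_div = 3.4, pct_del = 0, pct_ins = 0,
                     query = "ctg1", qbegin = 1001L, qend = 1100L,
                     qleft = 0L, strand = "+", repeat_name = "fam1",
                     repeat_classification = "DNA/hAT", rbegin = 1L,
                     rend = 100L, rleft = 0L, id = NA)
  L <- landscape(rows, genome_size = 10000)
  P <- landscape_percent(L)
  expect_equal(unname(P["DNA", "[3,4)"]), 1.0)
  expect_equal(sum(L), 100)

  # divergences of 50+ pool into the last bin
  rows$pct_div <- 73
  L2 <- landscape(rows, genome_size = 10000)
  expect_equal(unname(unclass(L2)["DNA", "[49,50)"]), 100)
  rows$pct_div <- -1
  expect_error(landscape(rows, genome_size = 10000), "negative")
})

test_that("landscape agrees with brute-force binning on 1000 random rows", {
  set.seed(83)
  n <- 1000
  cats <- c("DNA/hAT", "DNA/TcMar", "LINE/L1", "LTR/Gypsy", "Unknown")
  qb <- sample(1:100000, n)
  len <- sample(50:2000, n, replace = TRUE)
  rows <- data.frame(score = 100, pct_div = runif(n, 0, 60),
                     pct_del = 0, pct_ins = 0, query = "ctg1",
                     qbegin = qb, qend = qb + len - 1L, qleft = 0L,
                     strand = "+",
                     repeat_name = paste0("f", sample(1:50, n, TRUE)),
                     repeat_classification = sample(cats, n, TRUE),
                     rbegin = 1L, rend = len, rleft = 0L, id = NA)
  L <- landscape(rows, genome_size = 2e6)
  # conservation: cells sum to total masked bp, no overlap resolution
  expect_equal(sum(L), sum(rows$qend - rows$qbegin + 1))
  # brute force, one row at a time
  brute <- matrix(0, nrow = nrow(L), ncol = 50,
                  dimnames = list(rownames(L), colnames(L)))
  for (i in seq_len(n)) {
    cat_i <- sub("/.*$", "", rows$repeat_classification[i])
    bin <- min(floor(rows$pct_div[i]), 49) + 1
    brute[cat_i, bin] <- brute[cat_i, bin] + rows$qend[i] - rows$qbegin[i] + 1
  }
  expect_equal(unclass(L), brute, ignore_attr = TRUE)
})

test_that("masked summary flattens overlaps by score priority", {
  mk_row <- function(qb, qe, cls, score = 100) {
    data.frame(score = score, pct_div = 1, pct_del = 0, pct_ins = 0,
               query = "ctg1", qbegin = qb, qend = qe, qleft = 0L,
               strand = "+", repeat_name = "f",
               repeat_classification = cls, rbegin = 1L,
               rend = qe - qb + 1L, rleft = 0L, id = NA)
  }
  rows <- rbind(mk_row(101, 200, "DNA/hAT"), mk_row(301, 400, "DNA/hAT"))
  ms <- masked_summary(rows, genome_size = 10000)
  expect_equal(ms$bp[ms$category == "DNA"], 200)
  expect_equal(ms$percent[ms$category == "DNA"], 2.0)

  # full overlap: the higher-scoring row's category takes the bases once
  ov <- rbind(mk_row(101, 200, "DNA/hAT", score = 100),
              mk_row(101, 200, "LINE/L1", score = 50))
  ms2 <- masked_summary(ov, genome_size = 10000)
  expect_equal(ms2$bp[ms2$category == "DNA"], 100)
  expect_equal(ms2$bp[ms2$category == "LINE"], 0)
  expect_equal(ms2$bp[ms2$category == "total"], 100)

  # without resolution the same rows double-count
  ms3 <- masked_summary(ov, genome_size = 10000, resolve_overlaps = FALSE)
  expect_equal(ms3$bp[ms3$category == "total"], 200)

  empty <- mk_row(1, 1, "DNA/hAT")[0, ]
  ms4 <- masked_summary(empty, genome_size = 10000)
  expect_true(all(ms4$bp == 0))
})

test_that("masked totals never exceed the genome after overlap resolution", {
  set.seed(89)
  n <- 300
  qb <- sample(1:5000, n, replace = TRUE)
  len <- sample(100:800, n, replace = TRUE)
  rows <- data.frame(score = runif(n, 10, 1000), pct_div = 1, pct_del = 0,
                     pct_ins = 0, query = "ctg1", qbegin = qb,
                     qend = qb + len - 1L, qleft = 0L, strand = "+",
                     repeat_name = "f",
                     repeat_classification = sample(c("DNA/hAT", "LINE/L1"),
                                                    n, TRUE),
                     rbegin = 1L, rend = len, rleft = 0L, id = NA)
  gsize <- 7000
  ms <- masked_summary(rows, genome_size = gsize)
  expect_lte(ms$bp[ms$category == "total"], gsize)
  expect_lte(ms$percent[ms$category == "total"], 100)
})

test_that("active subfamily filter applies the copy and divergence bounds", {
  mk <- function(name, cls, divs) {
    data.frame(score = 100, pct_div = divs, pct_del = 0, pct_ins = 0,
               query = "ctg1", qbegin = 1L, qend = 100L, qleft = 0L,
               strand = "+", repeat_name = name,
               repeat_classification = cls, rbegin = 1L, rend = 100L,
               rleft = 0L, id = NA)
  }
  # exactly 10 copies at 0.0 qualifies ("at least 10" is inclusive)
  rows <- rbind(mk("famA", "DNA/hAT", rep(0, 10)),
                mk("famB", "DNA/hAT", c(rep(0, 9), rep(2.1, 50))),
                mk("famC", "LTR/Gypsy", rep(0, 12)))
  res <- active_subfamilies(rows)
  expect_setequal(res$subfamilies, c("famA", "famC"))
  expect_equal(res$counts$n_subfamilies[res$counts$category == "DNA"], 1L)
  expect_equal(res$counts$n_subfamilies[res$counts$category == "LTR"], 1L)
})

test_that("active counts equal brute-force enumeration on a mixed fixture", {
  set.seed(97)
  rows_list <- lapply(1:20, function(i) {
    n <- sample(3:30, 1)
    divs <- round(runif(n, 0, 3) * sample(0:1, n, replace = TRUE), 1)
    data.frame(score = 100, pct_div = divs, pct_del = 0, pct_ins = 0,
               query = "ctg1", qbegin = 1L, qend = 100L, qleft = 0L,
               strand = "+", repeat_name = paste0("sf", i),
               repeat_classification = sample(c("DNA/hAT", "LINE/L1",
                                                "Unknown"), 1),
               rbegin = 1L, rend = 100L, rleft = 0L, id = NA)
  })
  rows <- do.call(rbind, rows_list)
  res <- active_subfamilies(rows, min_copies = 10, max_div = 0)
  brute <- character(0)
  for (sf in unique(rows$repeat_name)) {
    if (sum(rows$pct_div[rows$repeat_name == sf] <= 0) >= 10)
      brute <- c(brute, sf)
  }
  expect_setequal(res$subfamilies, brute)
  expect_equal(sum(res$counts$n_subfamilies), length(brute))
})
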