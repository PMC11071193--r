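test_that("perfect and near-perfect TIRs are found, direct repeats are not", {
  set.seed(41)
  mid <- rand_seq(200)
  el <- paste0("CAGTGC", mid, revcomp("CAGTGC"))
  tir <- find_tir(el, min_len = 6)
  expect_false(is.null(tir))
  expect_equal(tir$arm5, c(0L, 6L))
  expect_equal(tir$arm3, c(nchar(el) - 6L, nchar(el)))
  expect_equal(tir$mismatches, 0L)

  # one mismatch in a 10 bp arm is tolerated and reported
  arm <- "ACGGATCCGT"
  arm3 <- revcomp(arm)
  substr(arm3, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                substr(arm3, 5, 5))[1]
  el2 <- paste0(arm, rand_seq(300), arm3)
  tir2 <- find_tir(el2)
  expect_false(is.null(tir2))
  expect_equal(tir2$mismatches, 1L)

  # an LTR-style element has no terminal *inverted* repeat
  ltr <- rand_seq(150)
  el3 <- paste0(ltr, rand_seq(400), ltr)
  expect_null(find_tir(el3, min_len = 20))
})

test_that("TIR detection has a low false-positive rate on random sequence", {
  fp <- 0L
  for (s in 1:100) {
    if (!is.null(find_tir(rand_seq(1000, seed = s)))) fp <- fp + 1L
  }
  expect_lte(fp, 5L)
})

test_that("LTR pairs are found by identity and position", {
  set.seed(43)
  ltr <- rand_seq(150)
  el <- paste0(ltr, rand_seq(600), ltr)
  res <- find_ltr(el)
  expect_false(is.null(res))
  expect_equal(res$identity, 1.0)
  expect_equal(res$length, 150L)
  expect_equal(res$ltr5, c(0L, 150L))

  # terminal inverted (not direct) repeats do not qualify
  el2 <- paste0(ltr, rand_seq(600), revcomp(ltr))
  expect_null(find_ltr(el2))

  # ~85% identity 200 bp repeats still qualify at the 0.8 threshold
  ltr2 <- rand_seq(200)
  decayed <- strsplit(ltr2, "")[[1]]
  idx <- sample(200, 30)
  for (i in idx) decayed[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                              decayed[i]), 1)
  el3 <- paste0(ltr2, rand_seq(600), paste(decayed, collapse = ""))
  res3 <- find_ltr(el3)
  expect_false(is.null(res3))
  expect_gte(res3$identity, 0.8)
})

test_that("TSDs are called per copy and summarised by plurality", {
  set.seed(47)
  mk_copy <- function(tsd) {
    list(left = paste0(rand_seq(30), tsd), core = rand_seq(100),
         right = paste0(tsd, rand_seq(30)))
  }
  tsd <- "ACGTACGT"
  copies <- lapply(1:5, function(i) mk_copy(tsd))
  res <- find_tsd(copies)
  expect_equal(res$length, 8L)
  expect_true(all(res$calls$tsd[res$calls$length == 8] == tsd))

  # no duplication: plurality length 0, motif "none"
  none <- lapply(1:5, function(i) {
    list(left = rand_seq(30), core = rand_seq(100), right = rand_seq(30))
  })
  res0 <- find_tsd(none)
  expect_equal(res0$length, 0L)
  expect_equal(res0$motif, "none")

  # degenerate central position collapses to N in the motif
  quartet <- lapply(c("TAA", "TCA", "TGA", "TTA"), mk_copy)
  res3 <- find_tsd(quartet)
  expect_equal(res3$length, 3L)
  expect_equal(res3$motif, "TNA")
})

test_that("the target-site model reconstructs conserved context", {
  set.seed(53)
  # Tc4-style: conserved C..G around a duplicated TNA core
  mk <- function(center) {
    tsd <- paste0("T", center, "A")
    list(left = paste0(rand_seq(20), "C", tsd), core = rand_seq(80),
         right = paste0(tsd, "G", rand_seq(20)))
  }
  copies <- lapply(c("A", "C", "G", "T", "A", "C", "G", "T"), mk)
  tsd <- find_tsd(copies)
  expect_equal(tsd$length, 3L)
  expect_equal(tsd$motif, "TNA")
  model <- fit_target_site_model(tsd, copies)
  expect_equal(model$pattern, "C|TNA|G")

  # random context degenerates to the core alone
  mk2 <- function() {
    tsd <- "GATC"
    list(left = paste0(rand_seq(22), tsd), core = rand_seq(80),
         right = paste0(tsd, rand_seq(22)))
  }
  copies2 <- replicate(10, mk2(), simplify = FALSE)
  tsd2 <- find_tsd(copies2)
  model2 <- fit_target_site_model(tsd2, copies2)
  expect_equal(model2$pattern, "|GATC|")

  # zero-length TSD -> no model
  none <- list(calls = data.frame(), length = 0L, motif = "none")
  expect_equal(fit_target_site_model(none, copies2)$pattern, "none")
})

test_that("boundary logos have valid frequencies and information content", {
  set.seed(59)
  copies <- lapply(1:50, function(i) {
    list(left = paste0(rand_seq(20), "G"),  # G fixed at position -1
         core = rand_seq(60), right = rand_seq(20))
  })
  logos <- boundary_logo(copies, upstream = 15, downstream = 11)
  expect_equal(dim(logos$logo5$freq), c(4L, 15L))
  expect_equal(unname(colSums(logos$logo5$freq)), rep(1, 15))
  expect_true(all(logos$logo5$ic >= 0 & logos$logo5$ic <= 2 + 1e-9))
  expect_true(all(logos$logo3$ic >= 0 & logos$logo3$ic <= 2 + 1e-9))
  # the fixed G column carries the full 2 bits
  expect_equal(logos$logo5$ic[[15]], 2)

  # uniform random flanks: mean IC near zero (small-sample bias only)
  big <- lapply(1:1000, function(i) {
    list(left = rand_seq(15), core = rand_seq(30), right = rand_seq(11))
  })
  logos2 <- boundary_logo(big)
  expect_lt(mean(logos2$logo5$ic), 0.02)

  # short-flank copies are excluded with a warning
  mixed <- c(copies[1:5], list(list(left = "ACG", core = rand_seq(60),
                                    right = rand_seq(20))))
  expect_warning(boundary_logo(mixed), "excluded")
})

test_that("information content decreases with column entropy", {
  ic_of <- function(freq) {
    f <- freq[freq > 0]
    2 + sum(f * log2(f))
  }
  skewed <- c(0.97, 0.01, 0.01, 0.01)
  milder <- c(0.7, 0.1, 0.1, 0.1)
  flat <- c(0.25, 0.25, 0.25, 0.25)
  expect_gt(ic_of(skewed), ic_of(milder))
  expect_gt(ic_of(milder), ic_of(flat))
  expect_equal(ic_of(flat), 0)
})

test_that("TIR windows anchor the logo at the outermost TIR base", {
  set.seed(61)
  # element with the TIR starting 2 bp inside: logo window shifts inward
  lead <- "AT"
  arm <- "ACGGATCCGT"
  core_mid <- rand_seq(100)
  el <- paste0(lead, arm, core_mid, revcomp(arm))
  tir <- find_tir(el, min_len = 10)
  expect_equal(tir$arm5[1], 2L)
  copies <- lapply(1:4, function(i) {
    list(left = rand_seq(20), core = el, right = rand_seq(20))
  })
  logos <- boundary_logo(copies, tir_arms = tir)
  # last window position is the base immediately before the TIR: the 'T'
  expect_equal(unname(logos$logo5$freq["T", 15]), 1)
})
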