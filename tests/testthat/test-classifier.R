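test_that("nomenclature validation accepts good labels, corrects near-misses", {
  expect_true(validate_name("DNA/hAT")$ok)
  expect_true(validate_name("DNA/TcMar-Tc4")$ok)
  expect_true(validate_name("Unknown")$ok)
  expect_true(validate_name("LINE/RTE-BovB")$ok)

  v <- validate_name("DNA/Hat")
  expect_false(v$ok)
  expect_equal(v$suggestion, "DNA/hAT")

  v2 <- validate_name("LTR/Gipsy")
  expect_false(v2$ok)
  expect_equal(v2$suggestion, "LTR/Gypsy")

  v3 <- validate_name("DNa/hAT")
  expect_false(v3$ok)
  expect_equal(v3$suggestion, "DNA/hAT")

  expect_false(validate_name("Frob/Quux")$ok)
})

test_that("classification precedence: homology, then structure, then Unknown", {
  rec <- consensus_record("x", rand_seq(300, seed = 1))
  tir <- list(arm5 = c(0L, 10L), arm3 = c(290L, 300L), length = 10L,
              mismatches = 0L)
  tsd <- list(calls = NULL, length = 8L, motif = "ACGTACGT")
  hm_dna <- structure(list(tir = tir, ltr = NULL, tsd = tsd,
                           target_site_model = NULL),
                      class = "hallmark_report")
  res <- classify(rec, hm_dna)
  expect_equal(res$label, "DNA/Unknown")
  expect_equal(res$tier, "structure")

  hm_ltr <- structure(list(tir = NULL,
                           ltr = list(ltr5 = c(0, 150), ltr3 = c(450, 600),
                                      length = 150L, identity = 1),
                           tsd = list(length = 0L),
                           target_site_model = NULL),
                      class = "hallmark_report")
  expect_equal(classify(rec, hm_ltr)$label, "LTR/Unknown")

  hom <- data.frame(subject = "Tc4_CE", classification = "DNA/TcMar-Tc4",
                    identity = 85, coverage = 0.8, evalue = 1e-30)
  res2 <- classify(rec, hm_dna, hom)
  expect_equal(res2$label, "DNA/TcMar-Tc4")
  expect_equal(res2$tier, "homology")

  # homology below thresholds is ignored
  weak <- data.frame(subject = "s", classification = "LINE/L1",
                     identity = 80, coverage = 0.2, evalue = 1e-3)
  expect_equal(classify(rec, hm_dna, weak)$tier, "structure")

  # conflicting homology wins and the conflict is traced
  conflict <- data.frame(subject = "s", classification = "LINE/L1",
                         identity = 90, coverage = 0.9, evalue = 1e-40)
  res3 <- classify(rec, hm_dna, conflict)
  expect_equal(res3$label, "LINE/L1")
  expect_true(any(grepl("conflict", res3$trace)))

  res4 <- classify(rec, NULL, NULL)
  expect_equal(res4$label, "Unknown")
  expect_equal(res4$tier, "none")
})

test_that("classification is deterministic and the trace explains the label", {
  rec <- consensus_record("x", rand_seq(300, seed = 2))
  hom <- data.frame(subject = c("a", "b"),
                    classification = c("DNA/hAT", "LINE/L1"),
                    identity = c(90, 95), coverage = c(0.9, 0.6),
                    evalue = c(1e-20, 1e-10))
  r1 <- classify(rec, NULL, hom)
  r2 <- classify(rec, NULL, hom)
  expect_identical(r1, r2)
  expect_true(any(grepl(r1$label, r1$trace, fixed = TRUE)))
})

test_that("80-80-80 and 95-80-98 rules separate families and subfamilies", {
  set.seed(71)
  base <- rand_seq(500)
  mutate <- function(s, d) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < d)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  libA <- te_library(list(consensus_record("a1", base),
                          consensus_record("a2", rand_seq(400))))
  libB <- te_library(list(
    consensus_record("b_same", base),                 # identical
    consensus_record("b_family", mutate(base, 0.10)), # ~90% identity
    consensus_record("b_far", mutate(base, 0.30)),    # ~70% identity
    consensus_record("b_unrel", rand_seq(450))))

  fam <- compare_libraries(libA, libB, rule = "80-80-80")
  expect_true(all(c("b_same", "b_family") %in% fam$pairs$b))
  expect_false("b_far" %in% fam$pairs$b)
  expect_false("b_unrel" %in% fam$pairs$b)
  expect_true("b_far" %in% fam$orphans_b)

  sub <- compare_libraries(libA, libB, rule = "95-80-98")
  expect_true("b_same" %in% sub$pairs$b)
  expect_false("b_family" %in% sub$pairs$b)

  # two unrelated species libraries share nothing under the family rule
  libC <- te_library(lapply(1:3, function(i)
    consensus_record(paste0("c", i), rand_seq(400))))
  libD <- te_library(lapply(1:3, function(i)
    consensus_record(paste0("d", i), rand_seq(400))))
  none <- compare_libraries(libC, libD, rule = "80-80-80")
  expect_equal(nrow(none$pairs), 0L)
  expect_length(none$orphans_b, 3L)
})

test_that("library comparison is symmetric at the pair level", {
  set.seed(73)
  base <- rand_seq(400)
  mutate <- function(s, d) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < d)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  libA <- te_library(list(consensus_record("a1", base),
                          consensus_record("a2", rand_seq(300))))
  libB <- te_library(list(consensus_record("b1", mutate(base, 0.05)),
                          consensus_record("b2", rand_seq(350))))
  ab <- compare_libraries(libA, libB)
  ba <- compare_libraries(libB, libA)
  expect_setequal(paste(ab$pairs$a, ab$pairs$b),
                  paste(ba$pairs$b, ba$pairs$a))
})

test_that("renaming prefixes ids, logs the change, and refuses collisions", {
  lib <- te_library(list(consensus_record("rnd-1_family-5", "ACGTACGTACGT"),
                         consensus_record("rnd-1_family-7", "ACGTTACGTACG")))
  res <- rename_library(lib, "droMel", curator = "ada")
  expect_equal(names(res$library),
               c("droMel_rnd-1_family-5", "droMel_rnd-1_family-7"))
  expect_equal(res$entries$old_name, c("rnd-1_family-5", "rnd-1_family-7"))
  # ledger restores old names
  expect_equal(sub("^droMel_", "", res$entries$new_name),
               res$entries$old_name)

  expect_error(rename_library(lib, "2bad"), "invalid prefix")
  # identical post-rename ids must error (construct by hand)
  lib2 <- te_library(list(consensus_record("x", "ACGT")))
  dup <- c(lib2, lib2)
  class(dup) <- "te_library"
  names(dup) <- c("x", "x")
  expect_error(rename_library(dup, "p"), "collision")
})
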