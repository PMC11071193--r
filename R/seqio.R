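## Readers/writers for every format the toolkit touches.
## Internal coordinates are 0-based half-open; the .out and hit-table file
## dialects are 1-based inclusive and are converted only at this boundary
## (AnnotationRow/HitRow keep the file's 1-based fields, as documented).

#' Create a TE consensus record
#'
#' The basic unit of a repeat library: one consensus sequence with its
#' RepeatMasker-style classification, version and curation status.
#'
#' @param id record identifier (e.g. `droMel_rnd-1_family-5`).
#' @param sequence DNA sequence over the IUPAC alphabet; lower case is
#'   accepted and upper-cased, `U` is mapped to `T`.
#' @param classification `Class/Superfamily` label or `"Unknown"`.
#' @param version integer version, starts at 1.
#' @param status one of `raw`, `curated`, `in_review`, `accepted`, `returned`.
#' @param curator,reviewer optional names.
#' @return object of class `consensus_record`.
#' @export
consensus_record <- function(id, sequence, classification = "Unknown",
                             version = 1L, status = "raw",
                             curator = NA_character_,
                             reviewer = NA_character_) {
  sequence <- chartr("u", "t", sequence)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  if (!.is_iupac_seq(sequence))
    stop("sequence of '", id, "' contains non-IUPAC characters")
  if (version < 1L) stop("version must be >= 1")
  status <- match.arg(status,
                      c("raw", "curated", "in_review", "accepted", "returned"))
  structure(list(id = id, classification = classification,
                 sequence = sequence, version = as.integer(version),
                 status = status, curator = curator, reviewer = reviewer),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("<consensus_record> %s#%s  v%d  %s  %d bp\n",
              x$id, x$classification, x$version, x$status,
              nchar(x$sequence)))
  invisible(x)
}

#' Bundle consensus records into a TE library
#'
#' @param records list of [consensus_record()] objects.
#' @return object of class `te_library` (a named list of records).
#' @export
te_library <- function(records) {
  if (is(records, "consensus_record")) records <- list(records)
  stopifnot(all(vapply(records, is, TRUE, "consensus_record")))
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicated record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(stats::setNames(records, ids), class = "te_library")
}

#' @export
print.te_library <- function(x, ...) {
  cat(sprintf("<te_library> %d record(s)\n", length(x)))
  for (r in head(x, 10)) {
    cat(sprintf("  %s#%s (%d bp, v%d)\n", r$id, r$classification,
                nchar(r$sequence), r$version))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Read a TE library from FASTA
#'
#' Headers follow the RepeatMasker library convention
#' `name#Class/Superfamily`; a header without `#` yields classification
#' `"Unknown"` with a warning.
#'
#' @param path FASTA file.
#' @return a `te_library`.
#' @export
read_te_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  recs <- lapply(seq_along(ss), function(i) {
    h <- strsplit(headers[i], "\\s+")[[1]][1]
    if (grepl("#", h, fixed = TRUE)) {
      parts <- strsplit(h, "#", fixed = TRUE)[[1]]
      id <- parts[1]; cls <- parts[2]
    } else {
      warning("header '", h, "' has no '#' classification; set to Unknown")
      id <- h; cls <- "Unknown"
    }
    consensus_record(id, as.character(ss[[i]]), classification = cls)
  })
  te_library(recs)
}

#' Write a TE library to FASTA
#'
#' @param lib a `te_library` (or list of records).
#' @param path output file; sequences wrap at 60 columns.
#' @return `path`, invisibly.
#' @export
write_te_fasta <- function(lib, path) {
  if (!is(lib, "te_library")) lib <- te_library(lib)
  seqs <- vapply(lib, `[[`, "", "sequence")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- vapply(lib, function(r) paste0(r$id, "#", r$classification), "")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a genome assembly from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences (upper case).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  g
}

#' Write a genome to FASTA
#' @param genome named character vector of contigs.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

## ---- RepeatMasker .out dialect ------------------------------------------

.RM_HEADER <- c(
  "   SW   perc perc perc  query      position in query           matching       repeat              position in  repeat",
  "score   div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
  "")

#' Read a RepeatMasker .out annotation table
#'
#' Parses the classic `.out` dialect: a 3-line header, whitespace-separated
#' records, parenthesized "(left)" fields, minus strand encoded as `C` with
#' the repeat begin/left columns swapped. Returned coordinates keep the
#' file's 1-based inclusive convention.
#'
#' @param path `.out` file.
#' @return data frame with one row per annotation: `score`, `pct_div`,
#'   `pct_del`, `pct_ins`, `query`, `qbegin`, `qend`, `qleft`, `strand`
#'   (`+`/`-`), `repeat_name`, `repeat_classification`, `rbegin`, `rend`,
#'   `rleft`, `id`.
#' @export
read_rm_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) >= 3L) lines <- lines[-(1:3)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(score = numeric(), pct_div = numeric(),
                      pct_del = numeric(), pct_ins = numeric(),
                      query = character(), qbegin = integer(),
                      qend = integer(), qleft = integer(),
                      strand = character(), repeat_name = character(),
                      repeat_classification = character(),
                      rbegin = integer(), rend = integer(),
                      rleft = integer(), id = character()))
  }
  unparen <- function(x) as.integer(sub("^\\((.*)\\)$", "\\1", x))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # 14 mandatory fields; optional trailing ID and '*' tolerated
    if (length(f) < 14L || length(f) > 16L)
      stop("malformed .out record at data line ", i, ": expected 14-16 ",
           "fields, got ", length(f))
    strand_raw <- f[9]
    if (!strand_raw %in% c("+", "C"))
      stop("malformed .out record at data line ", i, ": bad strand '",
           strand_raw, "'")
    if (strand_raw == "+") {
      rbegin <- as.integer(f[12]); rend <- as.integer(f[13])
      rleft <- unparen(f[14])
    } else {
      rleft <- unparen(f[12]); rend <- as.integer(f[13])
      rbegin <- as.integer(f[14])
    }
    id <- if (length(f) >= 15L && f[15] != "*") f[15] else NA_character_
    data.frame(score = as.numeric(f[1]), pct_div = as.numeric(f[2]),
               pct_del = as.numeric(f[3]), pct_ins = as.numeric(f[4]),
               query = f[5], qbegin = as.integer(f[6]),
               qend = as.integer(f[7]), qleft = unparen(f[8]),
               strand = if (strand_raw == "+") "+" else "-",
               repeat_name = f[10], repeat_classification = f[11],
               rbegin = rbegin, rend = rend, rleft = rleft, id = id)
  })
  out <- do.call(rbind, rows)
  bad <- which(out$qbegin > out$qend | out$pct_div < 0)
  if (length(bad))
    stop("invalid coordinates/divergence at data line ", bad[1])
  out
}

#' Write annotation rows in the .out dialect
#'
#' Inverse of [read_rm_out()]: re-encodes minus strand as `C` with swapped
#' repeat begin/left fields and parenthesizes the "left" columns.
#'
#' @param rows data frame as returned by [read_rm_out()].
#' @param path output file.
#' @export
write_rm_out <- function(rows, path) {
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$strand == "+") {
      rep3 <- c(r$rbegin, r$rend, paste0("(", r$rleft, ")"))
      s <- "+"
    } else {
      rep3 <- c(paste0("(", r$rleft, ")"), r$rend, r$rbegin)
      s <- "C"
    }
    paste(format(r$score, trim = TRUE), sprintf("%.1f", r$pct_div),
          sprintf("%.1f", r$pct_del), sprintf("%.1f", r$pct_ins),
          r$query, r$qbegin, r$qend, paste0("(", r$qleft, ")"), s,
          r$repeat_name, r$repeat_classification,
          rep3[1], rep3[2], rep3[3],
          if (is.na(r$id)) "" else r$id)
  }, "")
  writeLines(c(.RM_HEADER, body), path)
  invisible(path)
}

## ---- 12-column tabular hit format ---------------------------------------

.HIT_COLS <- c("query", "subject", "identity", "aln_length", "mismatches",
               "gap_opens", "qstart", "qend", "sstart", "send",
               "evalue", "bitscore")

#' Read a 12-column tabular hit table
#'
#' The common tab-separated search-output dialect: query, subject, percent
#' identity, alignment length, mismatches, gap opens, 1-based inclusive
#' query and subject coordinates, e-value, bit score. `sstart > send`
#' encodes a minus-strand hit.
#'
#' @param path tab-separated file, no header.
#' @return data frame with columns `query`, `subject`, `identity`,
#'   `aln_length`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = .HIT_COLS)
  if (any(df$identity < 0 | df$identity > 100))
    stop("identity out of [0,100]")
  df
}

#' Write a hit table
#' @param hits data frame as returned by [read_hits()] or [find_copies()].
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand of a hit row
#' @param hits hit data frame.
#' @return character vector of `+`/`-`.
#' @export
hit_strand <- function(hits) ifelse(hits$sstart <= hits$send, "+", "-")

## ---- aligned FASTA (MSA) ------------------------------------------------

#' Read an aligned FASTA multiple alignment
#'
#' @param path aligned FASTA; all rows must have equal length.
#' @param anchor label (or index) of the anchor row; defaults to the first.
#' @return a `te_msa` object; see [build_star_msa()].
#' @export
read_msa <- function(path, anchor = 1L) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0L) stop("no FASTA records in ", path)
  labels <- sub("^>", "", lines[idx])
  starts <- idx + 1L
  ends <- c(idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    toupper(paste(lines[starts[i]:ends[i]], collapse = ""))
  }, "")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged MSA: rows have unequal lengths")
  if (is.character(anchor)) anchor <- match(anchor, labels)
  new_te_msa(labels, seqs, anchor = as.integer(anchor))
}

#' Write a multiple alignment as aligned FASTA
#' @param msa a `te_msa`.
#' @param path output file.
#' @export
write_msa <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(msa$labels)) {
    writeLines(paste0(">", msa$labels[i]), con)
    s <- msa$seqs[i]
    writeLines(substring(s, seq(1, nchar(s), 60),
                         pmin(seq(60, nchar(s) + 59, 60), nchar(s))), con)
  }
  invisible(path)
}

## ---- curation ledger TSV ------------------------------------------------

.LEDGER_COLS <- c("consensus_id", "version", "old_name", "new_name",
                  "curator", "reviewer", "status", "comment", "timestamp",
                  "prev_hash", "hash")

#' Read a curation ledger
#'
#' @param path TSV with the fixed ledger header.
#' @return data frame of ledger entries in file order.
#' @export
read_ledger <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (!identical(names(df), .LEDGER_COLS))
    stop("not a ledger file: header mismatch")
  df$version <- as.integer(df$version)
  key <- paste(df$consensus_id, df$version, df$status)
  if (anyDuplicated(key))
    stop("duplicated ledger key (consensus_id, version, status): ",
         key[duplicated(key)][1])
  df
}

#' Write a curation ledger
#' @param ledger data frame of entries.
#' @param path output file.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger[, .LEDGER_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
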