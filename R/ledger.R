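## Curation bookkeeping: the peer-review state machine and basic version
## control mirroring a shared curation table plus in-file consensus
## versioning. Entries are hash-chained so history tampering is detectable.

# legal transitions of the peer-review state machine
.TRANSITIONS <- list(
  raw = c(curate = "curated"),
  curated = c(submit = "in_review"),
  in_review = c(accept = "accepted", return = "returned"),
  returned = c(recurate = "curated"),
  accepted = character(0)          # terminal
)

# FNV-1a 64-bit hash (implemented here to keep the ledger dependency-free);
# state is kept as four 16-bit limbs so all arithmetic is exact in doubles
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  a <- c(0x2325, 0x8422, 0x9ce4, 0xcbf2)    # 0xcbf29ce484222325
  m <- c(0x01b3, 0x0000, 0x0100, 0x0000)    # 0x00000100000001b3
  for (b in bytes) {
    a[1] <- bitwXor(a[1], b)
    r <- numeric(4)
    for (i in 1:4) for (j in 1:(5L - i)) {
      r[i + j - 1L] <- r[i + j - 1L] + a[i] * m[j]
    }
    carry <- 0
    for (k in 1:4) {
      v <- r[k] + carry
      r[k] <- v %% 65536
      carry <- v %/% 65536
    }
    a <- r
  }
  sprintf("%04x%04x%04x%04x", a[4], a[3], a[2], a[1])
}

#' Create a ledger entry
#'
#' @param consensus_id record id.
#' @param version record version.
#' @param old_name,new_name name change recorded by this entry (equal when
#'   no rename happened).
#' @param curator,reviewer actor names.
#' @param status resulting review status.
#' @param comment free-text note.
#' @param timestamp ISO-8601 UTC; defaults to now.
#' @param prev_hash hash of the previous entry (chain head uses `"0"`).
#' @return one-row data frame with the entry's own chain hash filled in.
#' @export
ledger_entry <- function(consensus_id, version = 1L,
                         old_name = consensus_id, new_name = consensus_id,
                         curator = NA_character_, reviewer = NA_character_,
                         status = "raw", comment = "",
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC"),
                         prev_hash = "0") {
  payload <- paste(consensus_id, version, old_name, new_name,
                   curator, reviewer, status, comment, timestamp,
                   prev_hash, sep = "\x1f")
  data.frame(consensus_id = consensus_id, version = as.integer(version),
             old_name = old_name, new_name = new_name,
             curator = as.character(curator),
             reviewer = as.character(reviewer),
             status = status, comment = comment, timestamp = timestamp,
             prev_hash = prev_hash, hash = .fnv1a(payload))
}

#' Append an entry to a ledger, extending the hash chain
#'
#' @param ledger existing ledger data frame (or `NULL` to start one).
#' @param ... fields passed to [ledger_entry()] (`prev_hash` is taken from
#'   the chain automatically).
#' @return the extended ledger.
#' @export
ledger_append <- function(ledger, ...) {
  prev <- if (is.null(ledger) || nrow(ledger) == 0L) "0"
          else ledger$hash[nrow(ledger)]
  entry <- ledger_entry(..., prev_hash = prev)
  rbind(ledger, entry)
}

#' Verify a ledger's hash chain
#'
#' Recomputes every entry's hash from its fields and its predecessor's
#' hash; any edited, removed or reordered entry breaks the chain.
#'
#' @param ledger ledger data frame.
#' @return `TRUE` when intact, otherwise the index of the first bad entry
#'   (as an error).
#' @export
ledger_verify <- function(ledger) {
  prev <- "0"
  for (i in seq_len(nrow(ledger))) {
    e <- ledger[i, ]
    payload <- paste(e$consensus_id, e$version, e$old_name, e$new_name,
                     e$curator, e$reviewer, e$status, e$comment,
                     e$timestamp, prev, sep = "\x1f")
    if (!identical(e$prev_hash, prev) ||
        !identical(.fnv1a(payload), e$hash))
      stop("ledger hash chain broken at entry ", i)
    prev <- e$hash
  }
  TRUE
}

#' Apply a peer-review transition
#'
#' Legal transitions: raw --curate--> curated --submit--> in_review
#' --accept|return--> accepted | returned; returned --recurate--> curated.
#' `accepted` is terminal. Acceptance requires a reviewer distinct from the
#' original curator.
#'
#' @param state a `review_state` from [review_state()].
#' @param event one of `curate`, `submit`, `accept`, `return`, `recurate`.
#' @param actor name of the person performing the event.
#' @param comment optional note.
#' @return the updated `review_state` (new `state`, history extended).
#' @export
transition <- function(state, event, actor, comment = "") {
  stopifnot(is(state, "review_state"))
  allowed <- .TRANSITIONS[[state$state]]
  if (!event %in% names(allowed))
    stop("illegal transition '", event, "' from state '", state$state,
         "'; allowed: ",
         if (length(allowed)) paste(names(allowed), collapse = ", ")
         else "(none, terminal state)")
  if (event == "accept" && !is.na(state$curator) &&
      identical(actor, state$curator))
    stop("self-review: reviewer must differ from curator '",
         state$curator, "'")
  new_state <- allowed[[event]]
  if (event %in% c("curate", "recurate")) state$curator <- actor
  reviewer <- if (event %in% c("accept", "return")) actor
              else NA_character_
  state$history <- ledger_append(
    state$history, consensus_id = state$consensus_id,
    version = state$version, curator = state$curator,
    reviewer = reviewer, status = new_state, comment = comment)
  state$state <- new_state
  state
}

#' Create a review state for a consensus
#'
#' @param consensus_id record id.
#' @param version record version.
#' @param state initial state (default `raw`).
#' @param curator original curator, if any.
#' @return object of class `review_state`.
#' @export
review_state <- function(consensus_id, version = 1L, state = "raw",
                         curator = NA_character_) {
  state <- match.arg(state, names(.TRANSITIONS))
  structure(list(consensus_id = consensus_id,
                 version = as.integer(version), state = state,
                 curator = curator, history = NULL),
            class = "review_state")
}

#' @export
print.review_state <- function(x, ...) {
  cat(sprintf("<review_state> %s v%d: %s (%d history entr%s)\n",
              x$consensus_id, x$version, x$state,
              NROW(x$history), if (NROW(x$history) == 1) "y" else "ies"))
  invisible(x)
}

#' Audit a ledger for reviewer-distinct acceptance
#'
#' Every accepted consensus must have at least one accepting entry whose
#' reviewer differs from the curator.
#'
#' @param ledger ledger data frame.
#' @return data frame of offending `consensus_id`s (zero rows when clean).
#' @export
ledger_audit <- function(ledger) {
  acc <- ledger[ledger$status == "accepted", , drop = FALSE]
  bad <- acc[is.na(acc$reviewer) | acc$reviewer == acc$curator, ,
             drop = FALSE]
  unique(bad[, "consensus_id", drop = FALSE])
}

#' Append a consensus version to its curation alignment
#'
#' Keeps every version of a consensus in the same alignment file: the new
#' version is added as a row labelled `id.vN` next to the original.
#' When `gapped` is not given, the record is projected onto the MSA
#' coordinate system by aligning it to the anchor row; insertions relative
#' to the anchor that do not fit existing anchor-gap columns are an error.
#'
#' @param record the [consensus_record()] to snapshot.
#' @param msa the family's `te_msa`.
#' @param gapped optional precomputed gapped row (length = MSA columns).
#' @return the extended `te_msa`.
#' @export
snapshot_version <- function(record, msa, gapped = NULL) {
  label <- paste0(record$id, ".v", record$version)
  if (label %in% msa$labels)
    stop("version already present in alignment: ", label)
  if (is.null(gapped)) gapped <- .project_to_msa(record$sequence, msa)
  if (nchar(gapped) != msa_ncol(msa))
    stop("gapped row length does not match alignment")
  new_te_msa(c(msa$labels, label), c(msa$seqs, gapped),
             anchor = msa$anchor)
}

# project an ungapped sequence onto msa columns via the anchor row
.project_to_msa <- function(seq, msa) {
  anchor_gapped <- msa$seqs[msa$anchor]
  anchor_cols <- which(strsplit(anchor_gapped, "")[[1]] != "-")
  anchor_seq <- gsub("-", "", anchor_gapped)
  pa <- .align(seq, anchor_seq, type = "overlap")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  if (IRanges::start(pa@pattern@range) > 1L ||
      IRanges::end(pa@pattern@range) < nchar(seq) ||
      any(as_ == "-"))
    stop("record not projectable onto the alignment coordinate system")
  out <- rep("-", msa_ncol(msa))
  cur <- IRanges::start(pa@subject@range) - 1L
  for (k in seq_along(ap)) {
    cur <- cur + 1L
    out[anchor_cols[cur]] <- ap[k]
  }
  paste(out, collapse = "")
}

#' Parse a versioned alignment row label
#'
#' @param label label(s) of the form `id.vN`.
#' @return data frame with `id` and `version`.
#' @export
parse_version_label <- function(label) {
  m <- regmatches(label, regexec("^(.*)\\.v([0-9]+)$", label))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("not a versioned label: ", label[bad][1])
  data.frame(id = vapply(m, `[`, "", 2L),
             version = as.integer(vapply(m, `[`, "", 3L)))
}
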