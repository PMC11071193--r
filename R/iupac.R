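## IUPAC nucleotide ambiguity handling shared across modules.

# code -> sorted base set
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_CODE <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(.IUPAC_SETS), keys)
})

#' IUPAC code for a set of bases
#'
#' @param bases character vector drawn from A, C, G, T.
#' @return single IUPAC character (`N` for the full set, the base itself for
#'   singletons).
#' @examples
#' iupac_code(c("A", "G"))  # "R"
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0L) return("N")
  code <- .IUPAC_CODE[[paste(bases, collapse = "")]]
  if (is.null(code)) stop("not a base set: ", paste(bases, collapse = ","))
  code
}

#' Bases denoted by an IUPAC code
#'
#' @param code single IUPAC character.
#' @return character vector of bases.
#' @export
iupac_bases <- function(code) {
  s <- .IUPAC_SETS[[toupper(code)]]
  if (is.null(s)) stop("not an IUPAC code: ", code)
  s
}

#' Test IUPAC compatibility of two characters
#'
#' Two IUPAC characters are compatible when their base sets intersect
#' (used when scoring a consensus that may carry ambiguity codes against an
#' unambiguous truth sequence).
#'
#' @param a,b equal-length character vectors of IUPAC characters.
#' @return logical vector.
#' @export
iupac_compatible <- function(a, b) {
  mapply(function(x, y) {
    length(intersect(.IUPAC_SETS[[x]], .IUPAC_SETS[[y]])) > 0L
  }, toupper(a), toupper(b), USE.NAMES = FALSE)
}

.is_iupac_seq <- function(x) {
  grepl("^[ACGTRYSWKMBDHVN]+$", x)
}

#' Column-wise IUPAC consensus of equal-length strings
#'
#' Applies [column_consensus()] to every position of a set of equal-length
#' unambiguous strings (used for TSD motifs and target-site models).
#'
#' @param strings character vector, equal nchar.
#' @param ... passed to [column_consensus()].
#' @return single consensus string.
#' @export
iupac_motif <- function(strings, ...) {
  if (length(strings) == 0L) return("")
  w <- unique(nchar(strings))
  if (length(w) != 1L) stop("strings must have equal length")
  if (w == 0L) return("")
  m <- do.call(rbind, strsplit(toupper(strings), ""))
  paste(vapply(seq_len(w), function(j) {
    column_consensus(table(m[, j]), min_depth = 1, ...)
  }, ""), collapse = "")
}
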