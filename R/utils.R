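# Shared sequence helpers. The scanner works on plain uppercase character
# strings; Biostrings is used at the FASTA boundary only.

.BASES <- c("A", "C", "G", "T")

# Integer codes 1..4 for A,C,G,T (alphabetical); NA for anything else.
.CODE_LOOKUP <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A") + 1L] <- 1L
  v[utf8ToInt("C") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- 3L
  v[utf8ToInt("T") + 1L] <- 4L
  v
})

encode_codes <- function(sequence) {
  .CODE_LOOKUP[as.integer(charToRaw(sequence)) + 1L]
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings. Characters
#' outside `A/C/G/T` (e.g. `N`) are complemented to themselves.
#'
#' @param x Character vector of DNA sequences (case preserved per base:
#'   `acgt` maps to `tgca`).
#' @return Character vector of the same length.
#' @examples
#' revcomp("GAAGTTCCTATTC")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Canonical representative of a sequence and its reverse complement
#'
#' Returns, elementwise, the lexicographic minimum of `x` and `revcomp(x)`.
#' Used to pool exact duplicates irrespective of strand.
#'
#' @inheritParams revcomp
#' @return Character vector of canonical sequences.
#' @export
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Window anatomy: 13-bp left element, 8-bp spacer, 13-bp right element.
.WINDOW_LEN <- 34L
.ELEMENT_POS <- c(-13:-1, 1:13)
.POS_LABELS <- as.character(.ELEMENT_POS)
# Character column (1..34) holding each element position.
.POS_COL <- ifelse(.ELEMENT_POS < 0L, .ELEMENT_POS + 14L, .ELEMENT_POS + 21L)
.SPACER_COLS <- 14:21
# Indices (within 1..26) of the proximal-8 positions -4..-1, 1..4.
.P8_IDX <- match(c(-4:-1, 1:4), .ELEMENT_POS)
.LEFT_IDX <- 1:13
.RIGHT_IDX <- 14:26

window_spacer <- function(x) substr(x, 14L, 21L)
window_left4 <- function(x) substr(x, 10L, 13L)
window_right4 <- function(x) substr(x, 22L, 25L)

abort_if_not_acgt <- function(x, what) {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    rlang::abort(sprintf("%s must contain only A/C/G/T (offending value: '%s')",
                         what, x[which(bad)[1]]))
  }
  invisible(x)
}
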