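# Class/subclass machinery: numeric encoding of the proximal-8 region,
# reverse-complement canonicalization, grouping, and the theoretical
# subclass catalogue.

#' Encode a proximal-8 region as an 8-digit numeric code
#'
#' Maps the eight proximal bases, read in order -4,-3,-2,-1,1,2,3,4, to
#' digits under A=1, T=2, G=3, C=4 and concatenates them into a single
#' integer. This code is the subclass identity (after reverse-complement
#' canonicalization, see [canonical_key()]).
#'
#' @param left4 Character vector of 4-mers at positions -4..-1.
#' @param right4 Character vector of 4-mers at positions 1..4.
#' @return Integer vector of 8-digit codes.
#' @examples
#' encode_proximal8("ATAC", "AATA") # 12141121
#' encode_proximal8("TATT", "GTAT") # 21223212
#' @export
encode_proximal8 <- function(left4, right4) {
  left4 <- toupper(left4)
  right4 <- toupper(right4)
  if (any(nchar(left4) != 4L) || any(nchar(right4) != 4L)) {
    rlang::abort("left4 and right4 must each be 4 nt")
  }
  s <- paste0(left4, right4)
  abort_if_not_acgt(s, "proximal-8 region")
  as.integer(chartr("ATGC", "1234", s))
}

# Forward code, flipped (reverse-complement reading) code, canonical code
# and canonical spacer for accepted windows. The flipped reading of a site
# has left4' = revcomp(right4) and right4' = revcomp(left4).
subclass_annotations <- function(sequence) {
  left4 <- window_left4(sequence)
  right4 <- window_right4(sequence)
  forward <- encode_proximal8(left4, right4)
  flipped <- encode_proximal8(revcomp(right4), revcomp(left4))
  code <- pmin(forward, flipped)
  spacer <- window_spacer(sequence)
  canonical_spacer_site <- ifelse(flipped < forward, revcomp(spacer), spacer)
  list(forward_code = forward, flipped_code = flipped,
       subclass_code = code, canonical_spacer = canonical_spacer_site)
}

#' Canonical subclass key of a 34-nt site
#'
#' Computes the proximal-8 numeric code of the site as read and of its
#' reverse complement; the canonical key is the smaller of the two, so a
#' site and its reverse complement always land in the same subclass.
#'
#' @param sequence Character vector of 34-nt windows.
#' @return A tibble with columns `sequence`, `forward_code`,
#'   `flipped_code`, `code` (the canonical key) and `is_canonical`
#'   (whether the forward reading already is the canonical one).
#' @examples
#' canonical_key(frt_wildtype())
#' @export
canonical_key <- function(sequence) {
  sequence <- check_window_input(sequence)
  ann <- subclass_annotations(sequence)
  tibble::tibble(sequence = sequence,
                 forward_code = ann$forward_code,
                 flipped_code = ann$flipped_code,
                 code = ann$subclass_code,
                 is_canonical = ann$forward_code <= ann$flipped_code)
}

#' Assign sites to classes and canonical subclasses
#'
#' Groups a hit table by class (proximal-8 match count, 8 down to 5) and
#' canonical subclass code, recomputing both from the sequence, and
#' returns the table in deterministic order: descending class, ascending
#' subclass code, genome order within a subclass.
#'
#' @param hits A tibble of accepted sites as produced by [scan_genome()]
#'   or [scan_contig()] (must carry a `sequence` column; `chromosome` and
#'   `chrom_linear_pos` are used for within-subclass ordering when
#'   present).
#' @param model An `frt_consensus` model used to recompute the class.
#' @return The input tibble with (re)computed `class` and `subclass_code`
#'   columns, sorted as above.
#' @export
assign_subclasses <- function(hits, model = default_consensus()) {
  if (nrow(hits) == 0L) {
    return(dplyr::mutate(hits,
                         class = integer(0), subclass_code = integer(0)))
  }
  res <- eval_window_matrix(windows_to_matrix(toupper(hits$sequence)), model)
  cls <- res$proximal8_matches
  if (any(cls < 5L | cls > 8L | !res$accepted)) {
    rlang::abort("assign_subclasses: input contains windows that are not accepted sites")
  }
  ann <- subclass_annotations(toupper(hits$sequence))
  hits$class <- cls
  hits$subclass_code <- ann$subclass_code
  ord <- c("chromosome", "chrom_linear_pos")
  ord <- ord[ord %in% names(hits)]
  dplyr::arrange(hits, dplyr::desc(.data$class), .data$subclass_code,
                 !!!rlang::syms(ord))
}

# Allowed base sets over the proximal-8 positions, in order -4..-1, 1..4.
p8_allowed <- function(model) {
  model$element_allowed[as.character(c(-4:-1, 1:4))]
}

#' Enumerate the theoretical proximal-8 subclass catalogue
#'
#' Enumerates all 4^8 = 65,536 proximal-8 sequences, keeps those with
#' exactly `k` matches to the consensus that satisfy every
#' proximal-8-local acceptance rule (no two adjacent mismatches within a
#' 4-bp segment, not both -1 and 1 mismatched, no forbidden base at -1 or
#' 1), and collapses each sequence with its reverse complement into one
#' canonical subclass. Element-level and spacer rules do not constrain
#' the proximal-8 pattern and are not applied.
#'
#' Under the default consensus there are exactly 10 perfect-match
#' (class-8) subclasses, from the 2x2x2x2 degeneracy at positions
#' -1/1 and -2/2 collapsed over reverse complements.
#'
#' @param k Integer class, 5-8 (number of proximal-8 matches).
#' @inheritParams evaluate_window
#' @return A tibble with one row per canonical subclass: `class`, `code`,
#'   `left4`, `right4`, `pattern` (`left4-right4`) and `n_orientations`
#'   (1 for a palindromic proximal-8 region, else 2).
#' @examples
#' nrow(enumerate_subclasses(8)) # 10
#' @export
enumerate_subclasses <- function(k, model = default_consensus()) {
  if (!is.numeric(k) || length(k) != 1L || !k %in% 5:8) {
    rlang::abort("k must be a single integer between 5 and 8")
  }
  pats <- enumerate_p8_patterns(model)
  pats <- pats[pats$n_matches == k, , drop = FALSE]
  agg <- pats |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(
      left4 = .data$left4[.data$forward_code == .data$code][1],
      right4 = .data$right4[.data$forward_code == .data$code][1],
      n_orientations = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$code)
  tibble::tibble(class = as.integer(k),
                 code = agg$code,
                 left4 = agg$left4,
                 right4 = agg$right4,
                 pattern = paste0(agg$left4, "-", agg$right4),
                 n_orientations = agg$n_orientations)
}

# All concrete proximal-8 sequences passing the proximal-8-local rules,
# with match counts and forward/canonical codes. Memoised per model.
enumerate_p8_patterns <- function(model = default_consensus()) {
  grid <- expand.grid(rep(list(.BASES), 8L), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  B <- as.matrix(grid) # 65536 x 8, columns: -4,-3,-2,-1,1,2,3,4
  allowed <- p8_allowed(model)
  M <- matrix(FALSE, nrow(B), 8L)
  for (j in 1:8) M[, j] <- B[, j] %in% allowed[[j]]
  n_matches <- rowSums(M)
  adj_bad <- (!M[, 1] & !M[, 2]) | (!M[, 2] & !M[, 3]) | (!M[, 3] & !M[, 4]) |
    (!M[, 5] & !M[, 6]) | (!M[, 6] & !M[, 7]) | (!M[, 7] & !M[, 8])
  both_pm1 <- !M[, 4] & !M[, 5]
  forb <- B[, 4] == model$forbidden_base_minus1 |
    B[, 5] == model$forbidden_base_plus1
  ok <- !adj_bad & !both_pm1 & !forb &
    n_matches >= model$min_proximal8_matches
  B <- B[ok, , drop = FALSE]
  left4 <- apply(B[, 1:4, drop = FALSE], 1, paste, collapse = "")
  right4 <- apply(B[, 5:8, drop = FALSE], 1, paste, collapse = "")
  forward <- encode_proximal8(left4, right4)
  flipped <- encode_proximal8(revcomp(right4), revcomp(left4))
  tibble::tibble(left4 = left4, right4 = right4,
                 n_matches = as.integer(n_matches[ok]),
                 forward_code = forward,
                 code = pmin(forward, flipped))
}

#' Theoretical subclass counts per class
#'
#' Convenience summary of [enumerate_subclasses()] over all four classes.
#'
#' @inheritParams evaluate_window
#' @return A tibble with columns `class` (8 down to 5) and `n_subclasses`.
#' @export
subclass_catalogue <- function(model = default_consensus()) {
  purrr::map_dfr(8:5, function(k) {
    tibble::tibble(class = k, n_subclasses = nrow(enumerate_subclasses(k, model)))
  })
}
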