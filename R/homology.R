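# Homology search: find discovered sites most similar to a query site —
# candidate counter-selection targets for Flp-variant evolution. Homology
# is strictly positionwise identity on the fixed-length 34-mer (no gaps).

.ELEMENT_CHAR_COLS <- c(1:13, 22:34)

#' Positionwise identity between 34-nt sites
#'
#' Counts identical bases between `a` and each element of `b`, taking the
#' maximum over `b` as-is and reverse-complemented (so identity is
#' orientation-invariant). Mode `"elements_only"` restricts the count to
#' the 26 binding-element positions, excluding the spacer.
#'
#' @param a A single 34-nt sequence.
#' @param b Character vector of 34-nt sequences.
#' @param mode `"full"` (all 34 positions) or `"elements_only"`.
#' @param both_orientations Compare against both orientations of `b`
#'   (default) or only as stored.
#' @return Integer vector of identity counts, one per element of `b`.
#' @examples
#' identity_count(frt_wildtype(), revcomp(frt_wildtype())) # 34
#' @export
identity_count <- function(a, b, mode = c("full", "elements_only"),
                           both_orientations = TRUE) {
  mode <- match.arg(mode)
  a <- toupper(a)
  b <- toupper(b)
  if (length(a) != 1L || nchar(a) != .WINDOW_LEN || any(nchar(b) != .WINDOW_LEN)) {
    rlang::abort("identity_count compares 34-nt sequences only")
  }
  cols <- if (mode == "full") seq_len(.WINDOW_LEN) else .ELEMENT_CHAR_COLS
  ra <- charToRaw(a)[cols]
  count_one <- function(s) sum(charToRaw(s)[cols] == ra)
  fwd <- vapply(b, count_one, integer(1), USE.NAMES = FALSE)
  if (!both_orientations) return(fwd)
  rev <- vapply(revcomp(b), count_one, integer(1), USE.NAMES = FALSE)
  pmax(fwd, rev)
}

#' Find sites homologous to a query site
#'
#' Scans a pool of discovered sites (typically the unique and duplicated
#' pools together) for sites whose positionwise identity with the query
#' is at least `threshold`, ranked by identity descending then genome
#' order. Self-matches are excluded by genomic coordinate, never by
#' sequence, so exact duplicates of the query elsewhere in the genome are
#' reported — they are precisely the off-target risk a counter-selection
#' target is meant to cover.
#'
#' @param sites Hit tibble (needs `sequence`; `chromosome` and
#'   `chrom_linear_pos` are used for ordering and self-exclusion when
#'   present).
#' @param query A single 34-nt sequence.
#' @param threshold Minimum identity count to report. A threshold above
#'   34 yields an empty result with a warning.
#' @param exclude_position Optional `c(chromosome, position)` (0-based
#'   linear position) identifying the query's own genomic copy to drop.
#' @inheritParams identity_count
#' @return `sites` filtered and ranked, with added columns `identity`,
#'   `rank` and `mode`.
#' @export
find_homologs <- function(sites, query, threshold = 25L,
                          mode = c("full", "elements_only"),
                          both_orientations = TRUE,
                          exclude_position = NULL) {
  mode <- match.arg(mode)
  if (threshold > .WINDOW_LEN) {
    rlang::warn(sprintf("threshold %d exceeds the maximum identity of 34; no site can match",
                        threshold))
    return(dplyr::mutate(sites[0, ], identity = integer(0),
                         rank = integer(0), mode = character(0)))
  }
  out <- sites
  out$identity <- identity_count(query, out$sequence, mode, both_orientations)
  if (!is.null(exclude_position) &&
      all(c("chromosome", "chrom_linear_pos") %in% names(out))) {
    keep <- !(out$chromosome == exclude_position[1] &
                out$chrom_linear_pos == as.integer(exclude_position[2]))
    out <- out[keep, , drop = FALSE]
  }
  out <- out[out$identity >= threshold, , drop = FALSE]
  ord <- c("chromosome", "chrom_linear_pos")
  ord <- ord[ord %in% names(out)]
  out <- dplyr::arrange(out, dplyr::desc(.data$identity), !!!rlang::syms(ord))
  out$rank <- seq_len(nrow(out))
  out$mode <- mode
  dplyr::relocate(out, "rank", "identity", "mode")
}

#' Report the query's whole subclass with identity counts
#'
#' Every member of the subclass to which the query site belongs is
#' reported with its identity count, regardless of threshold: subclass
#' members share the query's functionally critical proximal-8 region and
#' are the first candidates for a counter-selection target even when
#' overall homology is modest. The query must itself be an accepted
#' FRT-like site (it needs a class and subclass); otherwise an error
#' names the rule it failed.
#'
#' @inheritParams find_homologs
#' @param model Consensus model used to classify the query.
#' @return Subclass members with `identity`, `rank` and `mode` columns,
#'   ranked by identity descending then genome order.
#' @export
subclass_report <- function(sites, query, mode = c("full", "elements_only"),
                            model = default_consensus(),
                            exclude_position = NULL) {
  mode <- match.arg(mode)
  v <- evaluate_window(query, model)
  if (!v$accepted) {
    rlang::abort(sprintf("query is not an FRT-like site (failed rule: %s)",
                         v$failure_reason))
  }
  members <- sites[sites$subclass_code == v$subclass_code, , drop = FALSE]
  find_homologs(members, query, threshold = 0L, mode = mode,
                exclude_position = exclude_position)
}
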