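# Spacer grouping: within a subclass, sites whose spacers are identical in
# either orientation can in principle recombine with each other via one Flp
# variant, since strand exchange requires identical spacers.

#' Canonical spacer
#'
#' Of a spacer and its reverse complement, the lexicographically smaller
#' one; two sites share a canonical spacer iff their spacers are identical
#' in either orientation.
#'
#' @param spacer Character vector of 8-nt spacers (A/C/G/T only).
#' @return Character vector of canonical spacers.
#' @examples
#' canonical_spacer("TCTAGAAA") # revcomp is TTTCTAGA; TCTAGAAA sorts first
#' @export
canonical_spacer <- function(spacer) {
  spacer <- toupper(spacer)
  if (any(nchar(spacer) != 8L)) {
    rlang::abort("spacers must be exactly 8 nt")
  }
  abort_if_not_acgt(spacer, "spacer")
  canonical_seq(spacer)
}

#' Group subclass members by shared spacer
#'
#' Buckets the sites of one subclass by canonical spacer, the spacer being
#' read in the site's canonical orientation (column `canonical_spacer`
#' when present, recomputed otherwise) so that orientation cannot split a
#' recombination-compatible pair. Buckets of two or more sites become
#' groups, ordered by size descending then spacer; single-site buckets are
#' singletons and follow the groups.
#'
#' @param sites Hit tibble of one subclass (all rows should share one
#'   `subclass_code`; this is not enforced so the function can also be
#'   mapped over a grouped table).
#' @param raw_orientation If `TRUE`, bucket on the spacer as stored in
#'   contig orientation instead of the canonical site reading.
#' @return The input tibble reordered (groups first, then singletons) with
#'   added columns `spacer_key` (the canonical spacer used for
#'   bucketing), `group_id` (1, 2, ... for groups, `NA` for singletons)
#'   and `group_size`.
#' @export
group_spacers <- function(sites, raw_orientation = FALSE) {
  if (nrow(sites) == 0L) {
    return(dplyr::mutate(sites, spacer_key = character(0),
                         group_id = integer(0), group_size = integer(0)))
  }
  sp <- if (!raw_orientation && "canonical_spacer" %in% names(sites)) {
    sites$canonical_spacer
  } else {
    sites$spacer
  }
  sites$spacer_key <- canonical_spacer(sp)
  sizes <- table(sites$spacer_key)
  sites$group_size <- as.integer(sizes[sites$spacer_key])
  grouped_keys <- names(sizes)[sizes >= 2L]
  # deterministic group ids: size descending, then spacer
  grouped_keys <- grouped_keys[order(-as.integer(sizes[grouped_keys]),
                                     grouped_keys)]
  id_of <- stats::setNames(seq_along(grouped_keys), grouped_keys)
  sites$group_id <- unname(id_of[sites$spacer_key])
  dplyr::arrange(sites, is.na(.data$group_id), .data$group_id, .data$spacer_key)
}
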