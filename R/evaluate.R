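# Window evaluation: decide whether each 34-mer is an FRT-like sequence.
#
# The engine operates on an integer matrix with one row per window and one
# column per character (A=1, C=2, G=3, T=4, NA otherwise), so all rules are
# plain matrix arithmetic and a contig chunk is evaluated in one pass.

.FAILURE_ORDER <- c("non_acgt", "spacer_ends", "spacer_gc", "homopolymer",
                    "proximal8_count", "consecutive_mismatch_in_segment",
                    "both_proximal_mismatch", "forbidden_base_pm1",
                    "position7", "element_matches", "consecutive_run")

allowed_matrix <- function(model) {
  m <- matrix(FALSE, 26L, 4L, dimnames = list(.POS_LABELS, .BASES))
  for (k in seq_len(26L)) {
    m[k, model$element_allowed[[k]]] <- TRUE
  }
  m
}

base_code <- function(base) match(base, .BASES)

# Core rule engine. W: integer window matrix (n x 34). Returns per-window
# vectors; failure_reason is NA for accepted windows and otherwise names the
# first failing rule in the fixed evaluation order (spacer, homopolymer,
# proximal-8 rules, element rules).
eval_window_matrix <- function(W, model) {
  n <- nrow(W)
  allowed <- allowed_matrix(model)

  mask <- matrix(FALSE, n, 26L)
  for (k in seq_len(26L)) {
    mk <- allowed[k, W[, .POS_COL[k]]]
    mk[is.na(mk)] <- FALSE
    mask[, k] <- mk
  }

  non_acgt <- rowSums(is.na(W)) > 0L

  s1 <- W[, 14L]
  s8 <- W[, 21L]
  spacer_ends_bad <- is.na(s1) | is.na(s8) |
    s1 != base_code(model$spacer_first_base) |
    s8 != base_code(model$spacer_last_base)
  S <- W[, .SPACER_COLS, drop = FALSE]
  gcm <- S == 2L | S == 3L
  gcm[is.na(gcm)] <- FALSE
  spacer_gc <- rowSums(gcm)
  spacer_gc_bad <- spacer_gc > model$spacer_max_gc_bases

  eq <- W[, -34L, drop = FALSE] == W[, -1L, drop = FALSE]
  eq[is.na(eq)] <- FALSE
  maxrun <- as.integer(model$max_homopolymer_run)
  hp_bad <- rep(FALSE, n)
  if (maxrun < 33L) {
    for (j in seq_len(33L - maxrun)) {
      cur <- eq[, j]
      for (t in seq_len(maxrun - 1L)) cur <- cur & eq[, j + t]
      hp_bad <- hp_bad | cur
    }
  }

  p8 <- as.integer(rowSums(mask[, .P8_IDX, drop = FALSE]))
  m <- mask
  adj_bad <- (!m[, 10L] & !m[, 11L]) | (!m[, 11L] & !m[, 12L]) |
    (!m[, 12L] & !m[, 13L]) |
    (!m[, 14L] & !m[, 15L]) | (!m[, 15L] & !m[, 16L]) |
    (!m[, 16L] & !m[, 17L])
  both_pm1 <- !m[, 13L] & !m[, 14L]
  bm1 <- W[, 13L]
  bp1 <- W[, 22L]
  forb <- (!is.na(bm1) & bm1 == base_code(model$forbidden_base_minus1)) |
    (!is.na(bp1) & bp1 == base_code(model$forbidden_base_plus1))

  pos7_ok <- if (isTRUE(model$position7_rule)) m[, 7L] | m[, 20L] else rep(TRUE, n)
  left_matches <- rowSums(m[, .LEFT_IDX, drop = FALSE])
  right_matches <- rowSums(m[, .RIGHT_IDX, drop = FALSE])
  elem_ok <- left_matches >= model$min_element_matches_one_side |
    right_matches >= model$min_element_matches_one_side

  run_el <- function(idx) {
    r <- integer(n)
    best <- integer(n)
    for (j in idx) {
      r <- (r + 1L) * m[, j]
      best <- pmax(best, r)
    }
    best
  }
  best_l <- run_el(.LEFT_IDX)
  best_r <- run_el(.RIGHT_IDX)
  consecutive <- pmax(best_l, best_r)
  run_ok <- if (isTRUE(model$run_in_each_element)) {
    best_l >= model$min_consecutive_matches & best_r >= model$min_consecutive_matches
  } else {
    consecutive >= model$min_consecutive_matches
  }

  reason <- rep(NA_character_, n)
  put <- function(flag, label) {
    i <- is.na(reason) & flag
    reason[i] <<- label
  }
  put(non_acgt, "non_acgt")
  put(spacer_ends_bad, "spacer_ends")
  put(spacer_gc_bad, "spacer_gc")
  put(hp_bad, "homopolymer")
  put(p8 < model$min_proximal8_matches, "proximal8_count")
  put(adj_bad, "consecutive_mismatch_in_segment")
  put(both_pm1, "both_proximal_mismatch")
  put(forb, "forbidden_base_pm1")
  put(!pos7_ok, "position7")
  put(!elem_ok, "element_matches")
  put(!run_ok, "consecutive_run")

  list(
    accepted = is.na(reason),
    failure_reason = reason,
    match_mask = mask,
    proximal8_matches = p8,
    overall_score = as.integer(rowSums(mask)),
    weighted_score = as.numeric(mask %*% model$weights),
    consecutive_score = consecutive,
    left_run = best_l,
    right_run = best_r,
    left_matches = as.integer(left_matches),
    right_matches = as.integer(right_matches),
    spacer_gc = as.integer(spacer_gc)
  )
}

windows_to_matrix <- function(sequences) {
  n <- length(sequences)
  codes <- encode_codes(paste(sequences, collapse = ""))
  matrix(codes, nrow = n, ncol = .WINDOW_LEN, byrow = TRUE)
}

check_window_input <- function(sequence) {
  sequence <- toupper(sequence)
  if (length(sequence) == 0L) {
    rlang::abort("no sequences supplied")
  }
  bad <- nchar(sequence) != .WINDOW_LEN
  if (any(bad)) {
    rlang::abort(sprintf("windows must be exactly %d nt; element %d has %d",
                         .WINDOW_LEN, which(bad)[1], nchar(sequence[which(bad)[1]])))
  }
  sequence
}

#' Evaluate 34-nt windows against the FRT-like rule set
#'
#' Applies every identification rule to each window and reports the verdict
#' together with its annotations. A window is accepted iff it contains only
#' A/C/G/T, has a functional spacer (T at s1, A at s8, <= 50% GC), contains
#' no homopolymer run longer than the model's limit, satisfies the
#' proximal-8 rules (match count, no adjacent same-segment mismatches, not
#' both -1/1 mismatched, no G at -1 or C at 1) and the element-level rules
#' (a match at position -7 or 7, enough matches in one element, a long
#' enough run of consecutive matches). Rules are applied in that fixed
#' order, so `failure_reason` names the first rule a rejected window broke.
#'
#' Input is case-folded; windows containing `N` or other non-ACGT
#' characters after folding are rejected (reason `non_acgt`), not errored,
#' so soft-masked genome sequence remains scannable.
#'
#' @param sequence Character vector of 34-character windows.
#' @param model An `frt_consensus` model; see [default_consensus()].
#' @return A tibble with one row per window: `sequence`, `accepted`,
#'   `failure_reason` (NA when accepted), `class` (proximal-8 match count,
#'   5-8, NA when rejected), `proximal8_matches`, `overall_score`,
#'   `weighted_score`, `consecutive_score`, `spacer`, `subclass_code`
#'   (canonical 8-digit code, NA when rejected) and `canonical_spacer`
#'   (spacer read in the canonical site orientation).
#' @examples
#' evaluate_window(frt_wildtype())
#' @export
evaluate_window <- function(sequence, model = default_consensus()) {
  sequence <- check_window_input(sequence)
  res <- eval_window_matrix(windows_to_matrix(sequence), model)
  out <- tibble::tibble(
    sequence = sequence,
    accepted = res$accepted,
    failure_reason = res$failure_reason,
    proximal8_matches = res$proximal8_matches,
    class = ifelse(res$accepted, res$proximal8_matches, NA_integer_),
    overall_score = res$overall_score,
    weighted_score = res$weighted_score,
    consecutive_score = res$consecutive_score,
    spacer = window_spacer(sequence)
  )
  key <- rep(NA_integer_, nrow(out))
  can_sp <- rep(NA_character_, nrow(out))
  acc <- which(out$accepted)
  if (length(acc)) {
    ann <- subclass_annotations(out$sequence[acc])
    key[acc] <- ann$subclass_code
    can_sp[acc] <- ann$canonical_spacer
  }
  out$subclass_code <- key
  out$canonical_spacer <- can_sp
  out
}

#' Spacer functionality check
#'
#' A spacer is functional when it starts with the model's s1 base
#' (default T), ends with the s8 base (default A) and has at most
#' `spacer_max_gc_bases` G/C bases. Non-ACGT characters fail the check.
#'
#' @param spacer Character vector of 8-character spacers.
#' @inheritParams evaluate_window
#' @return Logical vector.
#' @export
check_spacer <- function(spacer, model = default_consensus()) {
  spacer <- toupper(spacer)
  if (any(nchar(spacer) != 8L)) {
    rlang::abort("spacers must be exactly 8 nt")
  }
  vapply(spacer, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    all(ch %in% .BASES) &&
      ch[1] == model$spacer_first_base &&
      ch[8] == model$spacer_last_base &&
      sum(ch %in% c("G", "C")) <= model$spacer_max_gc_bases
  }, logical(1), USE.NAMES = FALSE)
}

#' Homopolymer filter
#'
#' TRUE when the sequence contains no single-base run longer than the
#' model's `max_homopolymer_run` (default 4; a run of exactly 4 passes).
#'
#' @param sequence Character vector of DNA sequences.
#' @inheritParams evaluate_window
#' @return Logical vector.
#' @export
homopolymer_ok <- function(sequence, model = default_consensus()) {
  sequence <- toupper(sequence)
  vapply(sequence, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths) <= model$max_homopolymer_run
  }, logical(1), USE.NAMES = FALSE)
}

#' Per-position match mask of a window
#'
#' For each of the 26 element positions (-13..-1, 1..13), whether the
#' observed base belongs to the model's allowed set at that position.
#'
#' @inheritParams evaluate_window
#' @return A logical matrix with one row per window and 26 columns named
#'   by element position.
#' @export
match_mask <- function(sequence, model = default_consensus()) {
  sequence <- check_window_input(sequence)
  res <- eval_window_matrix(windows_to_matrix(sequence), model)
  colnames(res$match_mask) <- .POS_LABELS
  rownames(res$match_mask) <- NULL
  res$match_mask
}

#' Proximal-8 rule check
#'
#' Counts matches over positions -4..-1 and 1..4 and applies the
#' proximal-8 acceptance rules: at least `min_proximal8_matches` matches,
#' no two adjacent mismatches within the same 4-bp segment, not both -1
#' and 1 mismatched, and no forbidden base at -1 (G) or 1 (C).
#'
#' @inheritParams evaluate_window
#' @return A tibble with columns `count`, `ok` and `reason` (NA when ok).
#' @export
proximal8_checks <- function(sequence, model = default_consensus()) {
  sequence <- check_window_input(sequence)
  res <- eval_window_matrix(windows_to_matrix(sequence), model)
  reason <- res$failure_reason
  p8_reasons <- c("proximal8_count", "consecutive_mismatch_in_segment",
                  "both_proximal_mismatch", "forbidden_base_pm1")
  reason[!reason %in% p8_reasons] <- NA_character_
  tibble::tibble(count = res$proximal8_matches,
                 ok = is.na(reason),
                 reason = reason)
}

#' Element-level rule check
#'
#' Applies the binding-element rules: a match at position -7 or 7, at
#' least `min_element_matches_one_side` matches within one element, and a
#' long enough run of consecutive matched positions within an element.
#'
#' @inheritParams evaluate_window
#' @return A tibble with columns `ok`, `longest_run` (max over the two
#'   elements) and `reason` (NA when ok).
#' @export
element_checks <- function(sequence, model = default_consensus()) {
  sequence <- check_window_input(sequence)
  res <- eval_window_matrix(windows_to_matrix(sequence), model)
  reason <- res$failure_reason
  el_reasons <- c("position7", "element_matches", "consecutive_run")
  reason[!reason %in% el_reasons] <- NA_character_
  tibble::tibble(ok = is.na(reason),
                 longest_run = res$consecutive_score,
                 reason = reason)
}

#' Window scores
#'
#' The three annotation scores carried by every hit: overall (matched
#' element positions, 0-26), weighted (sum of model weights over matched
#' positions) and consecutive (longest run of consecutive matches within
#' an element). Scores never gate acceptance.
#'
#' @inheritParams evaluate_window
#' @return A tibble with columns `overall`, `weighted`, `consecutive`.
#' @export
window_scores <- function(sequence, model = default_consensus()) {
  sequence <- check_window_input(sequence)
  res <- eval_window_matrix(windows_to_matrix(sequence), model)
  tibble::tibble(overall = res$overall_score,
                 weighted = res$weighted_score,
                 consecutive = res$consecutive_score)
}
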