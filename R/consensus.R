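# The consensus/rule model describing which 34-mers count as FRT-like.

# Wild-type FRT, top strand: left element, spacer, right element.
.FRT_WT <- "GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC"

#' Default FRT consensus model
#'
#' Builds the rule model used to decide whether a 34-nt window is an
#' FRT-like sequence. The site anatomy is two 13-bp inverted Flp-binding
#' elements (positions -13..-1 and 1..13) flanking an 8-bp spacer
#' (s1..s8). The default allowed bases are the wild-type FRT bases at
#' every element position except the degeneracy tolerated by evolvable Flp
#' variants: position 1 may be A or G (hence -1 is C or T) and positions
#' -2/2 may be A or T. The model is reverse-complement symmetric, so a
#' single-strand scan still finds sites in either orientation.
#'
#' Rule thresholds (all overridable via [load_consensus()]):
#' * spacer must start with T (s1), end with A (s8), and have at most
#'   `spacer_max_gc_bases = 4` G/C bases (<= 50% GC);
#' * at least `min_proximal8_matches = 5` matches over the proximal-8
#'   region (-4..-1, 1..4), no two adjacent mismatches within the same
#'   4-bp segment, not both -1 and 1 mismatched, no G at -1 and no C at 1;
#' * a match at position -7 or 7 (`position7_rule`);
#' * at least `min_element_matches_one_side = 5` matches within one
#'   element and a run of `min_consecutive_matches = 6` consecutive
#'   matches within an element (by default the max over the two elements
#'   is compared; set `run_in_each_element = TRUE` for the strict reading);
#' * no homopolymer run longer than `max_homopolymer_run = 4` anywhere in
#'   the 34-mer.
#'
#' Per-position score weights default to 1 so the weighted score equals
#' the overall match count unless overridden; scores annotate hits and
#' never gate acceptance.
#'
#' @return An object of class `frt_consensus`.
#' @examples
#' model <- default_consensus()
#' model$element_allowed[["1"]] # A or G at position 1
#' @export
default_consensus <- function() {
  left <- c("G", "A", "A", "G", "T", "T", "C", "C", "T", "A", "T", "W", "Y")
  right <- c("R", "W", "A", "T", "A", "G", "G", "A", "A", "C", "T", "T", "C")
  allowed <- c(lapply(left, expand_iupac), lapply(right, expand_iupac))
  names(allowed) <- .POS_LABELS
  model <- structure(list(
    element_allowed = allowed,
    spacer_first_base = "T",
    spacer_last_base = "A",
    spacer_max_gc_bases = 4L,
    min_proximal8_matches = 5L,
    forbidden_base_minus1 = "G",
    forbidden_base_plus1 = "C",
    min_element_matches_one_side = 5L,
    min_consecutive_matches = 6L,
    max_homopolymer_run = 4L,
    position7_rule = TRUE,
    run_in_each_element = FALSE,
    weights = stats::setNames(rep(1, 26L), .POS_LABELS)
  ), class = "frt_consensus")
  validate_consensus(model)
}

expand_iupac <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) {
    rlang::abort(sprintf("'%s' is not a valid IUPAC nucleotide code", code))
  }
  strsplit(map[[code]], "", fixed = TRUE)[[1]]
}

validate_consensus <- function(model) {
  allowed <- model$element_allowed
  if (!identical(names(allowed), .POS_LABELS)) {
    rlang::abort("element_allowed must cover exactly positions -13..-1, 1..13")
  }
  sizes <- lengths(allowed)
  if (any(sizes == 0L)) {
    rlang::abort(sprintf("element_allowed: empty allowed set at position %s",
                         .POS_LABELS[which(sizes == 0L)[1]]))
  }
  ok_bases <- vapply(allowed, function(s) all(s %in% .BASES), logical(1))
  if (!all(ok_bases)) {
    rlang::abort(sprintf("element_allowed: non-ACGT base at position %s",
                         .POS_LABELS[which(!ok_bases)[1]]))
  }
  for (fld in c("spacer_first_base", "spacer_last_base",
                "forbidden_base_minus1", "forbidden_base_plus1")) {
    if (!model[[fld]] %in% .BASES) {
      rlang::abort(sprintf("%s must be one of A/C/G/T", fld))
    }
  }
  for (fld in c("spacer_max_gc_bases", "min_proximal8_matches",
                "min_element_matches_one_side", "min_consecutive_matches",
                "max_homopolymer_run")) {
    v <- model[[fld]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      rlang::abort(sprintf("%s must be a single non-negative number", fld))
    }
  }
  if (!identical(names(model$weights), .POS_LABELS) ||
      any(model$weights < 0)) {
    rlang::abort("weights must be a non-negative vector over positions -13..-1, 1..13")
  }
  model
}

#' Load a consensus model from a YAML configuration
#'
#' Reads a structured configuration and returns a validated
#' [default_consensus()]-style model. The two binding elements are given
#' as 13-character IUPAC strings (top strand, 5'->3' across the site);
#' any omitted field falls back to the default model's value.
#'
#' ```yaml
#' elements:
#'   left:  GAAGTTCCTATWY
#'   right: RWATAGGAACTTC
#' spacer:
#'   first_base: T
#'   last_base: A
#'   max_gc_bases: 4
#' rules:
#'   min_proximal8_matches: 5
#'   min_element_matches_one_side: 5
#'   min_consecutive_matches: 6
#'   max_homopolymer_run: 4
#'   position7_rule: true
#'   run_in_each_element: false
#'   forbidden_base_minus1: G
#'   forbidden_base_plus1: C
#' weights: 1        # scalar, or a map like {"-7": 2.0, "7": 2.0}
#' ```
#'
#' @param path Path to a YAML file, or `NULL` when `text` is given.
#' @param text YAML text (overrides `path`).
#' @return A validated `frt_consensus` model.
#' @export
load_consensus <- function(path = NULL, text = NULL) {
  cfg <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  model <- default_consensus()
  if (!is.null(cfg$elements)) {
    for (side in c("left", "right")) {
      el <- cfg$elements[[side]]
      if (is.null(el)) next
      chars <- strsplit(toupper(el), "", fixed = TRUE)[[1]]
      if (length(chars) != 13L) {
        rlang::abort(sprintf("elements$%s must be 13 characters, got %d",
                             side, length(chars)))
      }
      pos <- if (side == "left") as.character(-13:-1) else as.character(1:13)
      model$element_allowed[pos] <- lapply(chars, expand_iupac)
    }
  }
  sp <- cfg$spacer
  if (!is.null(sp$first_base)) model$spacer_first_base <- toupper(sp$first_base)
  if (!is.null(sp$last_base)) model$spacer_last_base <- toupper(sp$last_base)
  if (!is.null(sp$max_gc_bases)) model$spacer_max_gc_bases <- as.integer(sp$max_gc_bases)
  rl <- cfg$rules
  int_fields <- c("min_proximal8_matches", "min_element_matches_one_side",
                  "min_consecutive_matches", "max_homopolymer_run")
  for (fld in int_fields) {
    if (!is.null(rl[[fld]])) model[[fld]] <- as.integer(rl[[fld]])
  }
  for (fld in c("position7_rule", "run_in_each_element")) {
    if (!is.null(rl[[fld]])) model[[fld]] <- isTRUE(rl[[fld]])
  }
  for (fld in c("forbidden_base_minus1", "forbidden_base_plus1")) {
    if (!is.null(rl[[fld]])) model[[fld]] <- toupper(rl[[fld]])
  }
  if (!is.null(cfg$weights)) {
    if (is.numeric(cfg$weights) && length(cfg$weights) == 1L) {
      model$weights[] <- cfg$weights
    } else if (is.list(cfg$weights)) {
      for (nm in names(cfg$weights)) {
        if (!nm %in% .POS_LABELS) {
          rlang::abort(sprintf("weights: unknown element position '%s'", nm))
        }
        model$weights[[nm]] <- as.numeric(cfg$weights[[nm]])
      }
    } else {
      rlang::abort("weights must be a scalar or a map from position to weight")
    }
  }
  validate_consensus(model)
}

#' @export
print.frt_consensus <- function(x, ...) {
  pat <- function(pos) {
    vapply(x$element_allowed[as.character(pos)], function(s) {
      if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
    }, character(1))
  }
  cat("<frt_consensus>\n")
  cat("  left element  (-13..-1): ", paste(pat(-13:-1), collapse = ""), "\n", sep = "")
  cat("  right element (1..13):   ", paste(pat(1:13), collapse = ""), "\n", sep = "")
  cat(sprintf("  spacer: %s...%s, max %d G/C of 8\n",
              x$spacer_first_base, x$spacer_last_base, x$spacer_max_gc_bases))
  cat(sprintf(
    "  rules: proximal-8 >= %d; one element >= %d matches; run >= %d (%s); homopolymer <= %d; position-7 %s\n",
    x$min_proximal8_matches, x$min_element_matches_one_side,
    x$min_consecutive_matches,
    if (x$run_in_each_element) "each element" else "best element",
    x$max_homopolymer_run,
    if (x$position7_rule) "required" else "off"))
  invisible(x)
}

#' Wild-type FRT site
#'
#' The 34-bp minimal wild-type Flp recombination target, for reference and
#' as a convenient fixture.
#'
#' @return A single 34-character string.
#' @export
frt_wildtype <- function() .FRT_WT
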