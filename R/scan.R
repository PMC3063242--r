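# Genome scanning: stream contigs, evaluate every 34-nt window, assign
# chromosome-linear coordinates, and partition hits into unique and
# duplicated pools.

#' Scan one contig for FRT-like sequences
#'
#' Slides a 34-nt window over the contig in 1-nt steps and keeps every
#' accepted window. Scanning is single-strand (forward): because the
#' default rule set is reverse-complement symmetric, sites lying in the
#' reverse orientation are still found. The contig is processed in
#' bounded chunks (default 10,000 bp with a 33-bp carry-over between
#' chunks), which yields output identical to scanning the whole string at
#' once.
#'
#' @param sequence Contig DNA as a single string (case-folded; windows
#'   containing non-ACGT characters are skipped).
#' @param contig_id Identifier recorded with each hit.
#' @param model An `frt_consensus` model.
#' @param chunk_size Chunk length in bp for streaming evaluation.
#' @return A tibble with one row per hit: `contig_id`, `contig_offset`
#'   (0-based window start), `sequence`, `spacer`, `class`,
#'   `subclass_code`, `canonical_seq`, `canonical_spacer`,
#'   `overall_score`, `weighted_score`, `consecutive_score`.
#' @examples
#' flank <- strrep("C", 50)
#' scan_contig(paste0(flank, frt_wildtype(), flank), "demo")
#' @export
scan_contig <- function(sequence, contig_id = "contig",
                        model = default_consensus(),
                        chunk_size = 10000L) {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (chunk_size < .WINDOW_LEN) {
    rlang::abort("chunk_size must be at least the window length (34)")
  }
  offsets <- integer(0)
  seqs <- character(0)
  ann <- list()
  if (L >= .WINDOW_LEN) {
    start <- 1L
    while (start <= L - .WINDOW_LEN + 1L) {
      end <- min(L, start + chunk_size - 1L)
      codes <- encode_codes(substr(sequence, start, end))
      n <- length(codes) - .WINDOW_LEN + 1L
      if (n >= 1L) {
        idx <- outer(seq_len(n), 0:(.WINDOW_LEN - 1L), "+")
        W <- codes[idx]
        dim(W) <- dim(idx)
        res <- eval_window_matrix(W, model)
        hit <- which(res$accepted)
        if (length(hit)) {
          gstart <- start + hit - 1L
          offsets <- c(offsets, gstart - 1L)
          seqs <- c(seqs, substring(sequence, gstart, gstart + .WINDOW_LEN - 1L))
          ann[[length(ann) + 1L]] <- tibble::tibble(
            class = res$proximal8_matches[hit],
            overall_score = res$overall_score[hit],
            weighted_score = res$weighted_score[hit],
            consecutive_score = res$consecutive_score[hit]
          )
        }
      }
      # carry over window-1 bases so windows straddling the boundary are seen
      start <- end - .WINDOW_LEN + 2L
      if (end == L) break
    }
  }
  if (!length(offsets)) {
    return(tibble::tibble(
      contig_id = character(0), contig_offset = integer(0),
      sequence = character(0), spacer = character(0),
      class = integer(0), subclass_code = integer(0),
      canonical_seq = character(0), canonical_spacer = character(0),
      overall_score = integer(0), weighted_score = double(0),
      consecutive_score = integer(0)))
  }
  anns <- dplyr::bind_rows(ann)
  sub <- subclass_annotations(seqs)
  tibble::tibble(
    contig_id = contig_id,
    contig_offset = offsets,
    sequence = seqs,
    spacer = window_spacer(seqs),
    class = anns$class,
    subclass_code = sub$subclass_code,
    canonical_seq = canonical_seq(seqs),
    canonical_spacer = sub$canonical_spacer,
    overall_score = anns$overall_score,
    weighted_score = anns$weighted_score,
    consecutive_score = anns$consecutive_score)
}

#' Build a genome layout from a contig manifest
#'
#' The manifest declares, per chromosome, the order of contigs and their
#' lengths; cumulative 0-based offsets place every contig within the
#' concatenated linear chromosome sequence.
#'
#' @param manifest A tibble (or path to a TSV, see [read_manifest()]) with
#'   columns `chromosome`, `order`, `contig_id`, `length`.
#' @return The manifest sorted by (chromosome, order) with an added
#'   0-based `offset` column.
#' @export
genome_layout <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  need <- c("chromosome", "order", "contig_id", "length")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    rlang::abort(paste0("manifest is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(manifest$contig_id)) {
    rlang::abort("manifest contig_id values must be unique")
  }
  manifest |>
    dplyr::arrange(.data$chromosome, .data$order) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$length, default = 0L))) |>
    dplyr::ungroup()
}

#' Scan a directory of contig FASTA files for FRT-like sequences
#'
#' Reads every contig named in the manifest (in manifest order), scans it
#' with [scan_contig()], assigns chromosome-linear coordinates
#' (`chrom_linear_pos = contig offset within chromosome + window offset
#' within contig`, 0-based), and partitions the hits into a unique pool
#' and exact-duplicate groups via [partition_duplicates()]. Contigs found
#' in the directory but absent from the manifest are appended at the end
#' of chromosome `"unplaced"` with a warning.
#'
#' @param fasta_dir Directory containing FASTA files (`.fa`, `.fasta`,
#'   `.fna`; multi-record files supported).
#' @param manifest Manifest tibble or TSV path; see [genome_layout()].
#' @inheritParams scan_contig
#' @return An object of class `frt_scan`: a list with elements `hits`
#'   (all sites, genome order), `unique_pool`, `duplicate_groups` (one
#'   row per canonical duplicated 34-mer, with `copy_number` and a nested
#'   `members` list-column), `stats` (per-chromosome counts and scanned
#'   bases), `layout` and `model`.
#' @export
scan_genome <- function(fasta_dir, manifest, model = default_consensus(),
                        chunk_size = 10000L) {
  layout <- genome_layout(manifest)
  contigs <- read_genome_dir(fasta_dir, layout)
  hits <- purrr::pmap_dfr(
    list(contigs$contig_id, contigs$sequence,
         contigs$chromosome, contigs$offset),
    function(cid, seq, chrom, off) {
      h <- scan_contig(seq, cid, model, chunk_size)
      if (nrow(h)) {
        h$chromosome <- chrom
        h$chrom_linear_pos <- off + h$contig_offset
      } else {
        h$chromosome <- character(0)
        h$chrom_linear_pos <- integer(0)
      }
      h
    })
  hits <- dplyr::arrange(hits, .data$chromosome, .data$chrom_linear_pos) |>
    dplyr::relocate("chromosome", "chrom_linear_pos")
  pools <- partition_duplicates(hits)
  n_dup_members <- sum(pools$duplicate_groups$copy_number)
  stopifnot(nrow(hits) == nrow(pools$unique_pool) + n_dup_members)
  stats <- contigs |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(n_contigs = dplyr::n(),
                     bases = sum(.data$length), .groups = "drop") |>
    dplyr::left_join(
      hits |> dplyr::count(.data$chromosome, name = "n_hits"),
      by = "chromosome") |>
    dplyr::mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L))
  structure(list(hits = hits,
                 unique_pool = pools$unique_pool,
                 duplicate_groups = pools$duplicate_groups,
                 stats = stats,
                 layout = layout,
                 model = model),
            class = "frt_scan")
}

#' Partition hits into unique and exactly-duplicated pools
#'
#' Two hits are exact duplicates when their 34-mers are identical in
#' either orientation, i.e. share one canonical sequence
#' (lexicographic min of the window and its reverse complement). Groups
#' with at least two members form the duplicated pool; singletons form
#' the unique pool.
#'
#' @param hits A hit tibble with at least a `sequence` column
#'   (`canonical_seq` is recomputed if absent).
#' @return A list with `unique_pool` (hit tibble) and `duplicate_groups`
#'   (tibble with `canonical_seq`, `copy_number`, `class`,
#'   `subclass_code` and a nested `members` list-column of hit rows).
#' @export
partition_duplicates <- function(hits) {
  if (!"canonical_seq" %in% names(hits)) {
    hits$canonical_seq <- canonical_seq(toupper(hits$sequence))
  }
  counts <- table(hits$canonical_seq)
  dup_keys <- names(counts)[counts >= 2L]
  is_dup <- hits$canonical_seq %in% dup_keys
  unique_pool <- hits[!is_dup, , drop = FALSE]
  dup <- hits[is_dup, , drop = FALSE]
  if (nrow(dup)) {
    groups <- dup |>
      tidyr::nest(members = -"canonical_seq") |>
      dplyr::mutate(
        copy_number = purrr::map_int(.data$members, nrow),
        class = purrr::map_int(.data$members, ~ .x$class[1]),
        subclass_code = purrr::map_int(.data$members, ~ .x$subclass_code[1])
      ) |>
      dplyr::arrange(dplyr::desc(.data$copy_number), .data$canonical_seq) |>
      dplyr::relocate("canonical_seq", "copy_number", "class", "subclass_code")
  } else {
    groups <- tibble::tibble(canonical_seq = character(0),
                             copy_number = integer(0),
                             class = integer(0),
                             subclass_code = integer(0),
                             members = list())
  }
  list(unique_pool = unique_pool, duplicate_groups = groups)
}

#' @export
print.frt_scan <- function(x, ...) {
  g <- glance(x)
  cat("<frt_scan>\n")
  cat(sprintf("  %s bases scanned across %d chromosome(s), %d contig(s)\n",
              format(g$bases_scanned, big.mark = ","), g$n_chromosomes,
              sum(x$stats$n_contigs)))
  cat(sprintf("  %d FRT-like sites: %d unique, %d in %d exact-duplicate group(s)\n",
              g$n_hits, g$n_unique, g$n_duplicated_sites, g$n_duplicate_groups))
  invisible(x)
}

#' Tidy a genome scan
#'
#' @param x An `frt_scan` object.
#' @param ... Unused.
#' @return `tidy()` returns the full hit tibble in genome order, with a
#'   logical `duplicated` column; `glance()` returns a one-row summary.
#' @method tidy frt_scan
#' @export
tidy.frt_scan <- function(x, ...) {
  dup_keys <- x$duplicate_groups$canonical_seq
  dplyr::mutate(x$hits, duplicated = .data$canonical_seq %in% dup_keys)
}

#' @rdname tidy.frt_scan
#' @method glance frt_scan
#' @export
glance.frt_scan <- function(x, ...) {
  tibble::tibble(
    n_hits = nrow(x$hits),
    n_unique = nrow(x$unique_pool),
    n_duplicate_groups = nrow(x$duplicate_groups),
    n_duplicated_sites = sum(x$duplicate_groups$copy_number),
    n_chromosomes = nrow(x$stats),
    bases_scanned = sum(x$stats$bases)
  )
}

#' Plot per-chromosome site counts of a genome scan
#'
#' @param object An `frt_scan` object.
#' @param ... Unused.
#' @return A ggplot: FRT-like sites per chromosome, stacked by class.
#' @method autoplot frt_scan
#' @export
autoplot.frt_scan <- function(object, ...) {
  d <- dplyr::count(object$hits, .data$chromosome, .data$class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chromosome, y = .data$n,
                                  fill = factor(.data$class))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chromosome", y = "FRT-like sites",
                  fill = "class") +
    ggplot2::theme_minimal()
}
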