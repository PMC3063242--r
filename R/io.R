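# Readers/writers: FASTA in (via Biostrings), TSV and BED6 out.
# Internally all coordinates are 0-based half-open; TSV reports are
# 1-based inclusive and BED keeps the 0-based convention. All writers are
# deterministic (stable orders, no timestamps).

#' Read a contig manifest
#'
#' @param path TSV with columns `chromosome`, `order`, `contig_id`,
#'   `length`.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chromosome = readr::col_character(),
                    order = readr::col_integer(),
                    contig_id = readr::col_character(),
                    length = readr::col_integer()))
}

#' @rdname read_manifest
#' @param manifest Manifest tibble to write.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest[, c("chromosome", "order", "contig_id", "length")],
                   path)
  invisible(path)
}

#' Read all contigs of a genome directory in manifest order
#'
#' Loads every FASTA file under `path` (extensions `.fa`, `.fasta`,
#' `.fna`), case-folds sequences to uppercase (other characters such as
#' `N` are preserved), and returns the records ordered as the layout
#' declares. A manifest contig with no FASTA record is an error; a FASTA
#' record absent from the manifest is appended at the end of chromosome
#' `"unplaced"` with a warning.
#'
#' @param path Directory of FASTA files.
#' @param layout Output of [genome_layout()] (or a manifest accepted by
#'   it).
#' @return A tibble with columns `chromosome`, `order`, `contig_id`,
#'   `length`, `offset`, `sequence`.
#' @export
read_genome_dir <- function(path, layout) {
  layout <- genome_layout(layout)
  files <- list.files(path, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (!length(files)) {
    rlang::abort(sprintf("no FASTA inputs found in '%s'", path))
  }
  recs <- purrr::map_dfr(files, function(f) {
    set <- tryCatch(Biostrings::readDNAStringSet(f),
                    error = function(e) {
                      rlang::abort(sprintf("failed to parse FASTA file '%s': %s",
                                           f, conditionMessage(e)))
                    })
    tibble::tibble(
      contig_id = sub("\\s.*$", "", names(set)),
      sequence = unname(toupper(as.character(set))))
  })
  if (anyDuplicated(recs$contig_id)) {
    rlang::abort("duplicate contig ids across FASTA files")
  }
  missing <- setdiff(layout$contig_id, recs$contig_id)
  if (length(missing)) {
    rlang::abort(sprintf("manifest contig '%s' has no FASTA record in '%s'",
                         missing[1], path))
  }
  extra <- setdiff(recs$contig_id, layout$contig_id)
  if (length(extra)) {
    rlang::warn(sprintf(
      "%d contig(s) in '%s' are absent from the manifest and were appended to chromosome 'unplaced': %s",
      length(extra), path, paste(extra, collapse = ", ")))
    add <- tibble::tibble(
      chromosome = "unplaced",
      order = seq_along(extra),
      contig_id = extra,
      length = nchar(recs$sequence[match(extra, recs$contig_id)]))
    layout <- genome_layout(dplyr::bind_rows(
      layout[, c("chromosome", "order", "contig_id", "length")], add))
  }
  out <- dplyr::left_join(layout, recs, by = "contig_id")
  got <- nchar(out$sequence)
  if (any(got != out$length)) {
    i <- which(got != out$length)[1]
    rlang::warn(sprintf("contig '%s': FASTA length %d differs from manifest length %d; using FASTA",
                        out$contig_id[i], got[i], out$length[i]))
    out$length <- got
    out <- genome_layout(out[, c("chromosome", "order", "contig_id", "length")]) |>
      dplyr::left_join(recs, by = "contig_id")
  }
  out
}

hits_report <- function(hits) {
  n <- nrow(hits)
  col <- function(nm, proto) {
    if (nm %in% names(hits)) hits[[nm]] else rep(proto, n)
  }
  tibble::tibble(
    chromosome = col("chromosome", NA_character_),
    chrom_linear_pos_1based = col("chrom_linear_pos", NA_integer_) + 1L,
    contig_id = col("contig_id", NA_character_),
    contig_offset_1based = col("contig_offset", NA_integer_) + 1L,
    sequence = col("sequence", NA_character_),
    spacer = col("spacer", NA_character_),
    class = col("class", NA_integer_),
    subclass_code = col("subclass_code", NA_integer_),
    overall_score = col("overall_score", NA_integer_),
    weighted_score = col("weighted_score", NA_real_),
    consecutive_score = col("consecutive_score", NA_integer_))
}

#' Write a hit table as a 1-based TSV report
#'
#' @param hits Hit tibble ([scan_genome()] schema).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits_report(hits), path)
  invisible(path)
}

#' Read back a hits TSV into the internal (0-based) schema
#'
#' @param path File written by [write_hits()].
#' @return A hit tibble with 0-based `chrom_linear_pos`/`contig_offset`
#'   and recomputed `canonical_seq`/`canonical_spacer`.
#' @export
read_hits <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  ann <- subclass_annotations(d$sequence)
  tibble::tibble(
    chromosome = as.character(d$chromosome),
    chrom_linear_pos = as.integer(d$chrom_linear_pos_1based - 1L),
    contig_id = as.character(d$contig_id),
    contig_offset = as.integer(d$contig_offset_1based - 1L),
    sequence = d$sequence,
    spacer = d$spacer,
    class = as.integer(d$class),
    subclass_code = as.integer(d$subclass_code),
    canonical_seq = canonical_seq(d$sequence),
    canonical_spacer = ann$canonical_spacer,
    overall_score = as.integer(d$overall_score),
    weighted_score = as.numeric(d$weighted_score),
    consecutive_score = as.integer(d$consecutive_score))
}

#' Write the unique and duplicated pools of a scan
#'
#' Emits `unique.tsv` (hit schema) and `duplicated.tsv` (hit schema plus
#' `canonical_seq` and `copy_number`) under `dir`.
#'
#' @param scan An `frt_scan` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pools <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hits(scan$unique_pool, file.path(dir, "unique.tsv"))
  dup <- tidyr::unnest(
    scan$duplicate_groups[, c("canonical_seq", "copy_number", "members")],
    "members")
  rep_tbl <- hits_report(dup)
  rep_tbl$canonical_seq <- dup$canonical_seq
  rep_tbl$copy_number <- dup$copy_number
  readr::write_tsv(rep_tbl, file.path(dir, "duplicated.tsv"))
  invisible(dir)
}

#' Write one TSV per subclass under class directories
#'
#' Produces `class_<k>/subclass_<code>.tsv` for every populated subclass,
#' files in the hit-report schema, rows in genome order.
#'
#' @param hits Hit tibble.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_subclass_dirs <- function(hits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- split(hits, list(hits$class, hits$subclass_code), drop = TRUE)
  for (p in parts) {
    cdir <- file.path(dir, sprintf("class_%d", p$class[1]))
    dir.create(cdir, showWarnings = FALSE)
    write_hits(p, file.path(cdir, sprintf("subclass_%08d.tsv", p$subclass_code[1])))
  }
  invisible(dir)
}

#' Write spacer groups of one subclass
#'
#' Emits the machine-readable TSV (`<path>`: hit report plus
#' `spacer_key`, `group_id`, `group_size`) and, when `text_path` is
#' given, the human-readable layout: shared-spacer groups first, each
#' delineated by a blank line, followed by the sites with unique spacers.
#'
#' @param grouped Output of [group_spacers()].
#' @param path Output TSV.
#' @param text_path Optional human-readable file.
#' @return `path`, invisibly.
#' @export
write_spacer_groups <- function(grouped, path, text_path = NULL) {
  rep_tbl <- hits_report(grouped)
  rep_tbl$spacer_key <- grouped$spacer_key
  rep_tbl$group_id <- grouped$group_id
  rep_tbl$group_size <- grouped$group_size
  readr::write_tsv(rep_tbl, path)
  if (!is.null(text_path)) {
    line_of <- function(d) {
      sprintf("%s\t%s\t%d\t%s", d$sequence, d$chromosome,
              d$chrom_linear_pos + 1L, d$spacer)
    }
    lines <- character(0)
    gids <- unique(grouped$group_id[!is.na(grouped$group_id)])
    for (g in gids) {
      lines <- c(lines, line_of(grouped[!is.na(grouped$group_id) &
                                          grouped$group_id == g, ]), "")
    }
    singles <- grouped[is.na(grouped$group_id), ]
    if (nrow(singles)) lines <- c(lines, line_of(singles))
    writeLines(lines, text_path)
  }
  invisible(path)
}

#' Export hits as BED6
#'
#' 0-based half-open intervals; name is the zero-padded canonical
#' subclass code, score is the overall score rescaled to 0-1000, strand
#' is `'+'` (scanning is single-strand; orientation is folded into the
#' canonical subclass).
#'
#' @param hits Hit tibble.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  bed <- tibble::tibble(
    chrom = hits$chromosome,
    start = hits$chrom_linear_pos,
    end = hits$chrom_linear_pos + .WINDOW_LEN,
    name = sprintf("%08d", hits$subclass_code),
    score = as.integer(round(hits$overall_score / 26 * 1000)),
    strand = "+")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
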