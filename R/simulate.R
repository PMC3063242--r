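# Seeded synthetic genomes with known ground truth: random background of
# configurable GC, planted FRT-like sites of chosen class, and repeat
# families (a unit carrying a site, copied with optional point mutations).
# Because random background at mammalian-like GC legitimately contains
# FRT-like sites, the emitted truth table is defined by a full scan of the
# assembled sequence, not by the planted coordinates alone.

#' Draw a random FRT-like site of a given class
#'
#' Constructs 34-mers accepted by [evaluate_window()] with exactly `k`
#' proximal-8 matches: the proximal-8 pattern is drawn uniformly from the
#' concrete patterns valid for class `k`, the spacer satisfies the spacer
#' rules, distal element positions start at consensus and receive up to
#' three random mismatches, and the whole site is rejection-sampled
#' against the full rule set (homopolymer runs included). Each returned
#' site is flipped to its reverse complement with probability 1/2 so no
#' orientation is privileged. Randomness comes from R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param k Class, 5-8 (exact number of proximal-8 matches).
#' @param n Number of sites to draw.
#' @inheritParams evaluate_window
#' @param max_tries Retry cap per site; exhausting it signals an
#'   inconsistent model.
#' @return Character vector of `n` accepted 34-mers.
#' @export
random_site <- function(k, n = 1L, model = default_consensus(),
                        max_tries = 200L) {
  pats <- enumerate_p8_patterns(model)
  pats <- pats[pats$n_matches == k, , drop = FALSE]
  if (!nrow(pats)) {
    rlang::abort(sprintf("model admits no proximal-8 pattern with %d matches", k))
  }
  distal_pos <- as.character(c(-13:-5, 5:13))
  consensus_distal <- vapply(model$element_allowed[distal_pos],
                             function(s) s[1], character(1))
  vapply(seq_len(n), function(i) {
    for (try in seq_len(max_tries)) {
      row <- pats[sample.int(nrow(pats), 1L), ]
      distal <- consensus_distal
      n_mut <- sample(0:3, 1L)
      if (n_mut > 0L) {
        at <- sample(seq_along(distal), n_mut)
        for (j in at) {
          distal[j] <- sample(setdiff(.BASES, model$element_allowed[[distal_pos[j]]]), 1L)
        }
      }
      mid <- paste(sample(.BASES, 6L, replace = TRUE,
                          prob = c(.35, .15, .15, .35)), collapse = "")
      spacer <- paste0(model$spacer_first_base, mid, model$spacer_last_base)
      left <- paste0(paste(distal[1:9], collapse = ""), row$left4)
      right <- paste0(row$right4, paste(distal[10:18], collapse = ""))
      site <- paste0(left, spacer, right)
      if (stats::runif(1) < 0.5) site <- revcomp(site)
      v <- evaluate_window(site, model)
      if (v$accepted && v$proximal8_matches == k) return(site)
    }
    rlang::abort(sprintf(
      "random_site: could not draw an accepted class-%d site in %d tries; model rules may be inconsistent",
      k, max_tries))
  }, character(1))
}

random_background <- function(length, gc) {
  paste(sample(.BASES, length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

splice_at <- function(chars, insert, pos0) {
  ins <- strsplit(insert, "", fixed = TRUE)[[1]]
  chars[(pos0 + 1L):(pos0 + length(ins))] <- ins
  chars
}

mutate_copy <- function(unit, rate) {
  if (rate <= 0) return(unit)
  ch <- strsplit(unit, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic genome with known ground truth
#'
#' Assembles per-chromosome sequences of i.i.d. background at the
#' requested GC content, splices in planted sites and repeat-family
#' copies at recorded (or randomly chosen, non-overlapping) positions,
#' writes one FASTA file per contig plus the scanner manifest and a truth
#' table, and returns everything in memory as well. The truth table is
#' produced by scanning every final contig, so background hits and any
#' site accidentally created at a splice junction are part of the truth,
#' with `origin` recording how each hit arose; spliced features are kept
#' clear of contig split points so every planted site is scannable.
#'
#' @param chromosomes Tibble with columns `name`, `length` (bp), `gc`
#'   (fraction 0-1) and optionally `n_contigs` (default 1; the
#'   chromosome is split into that many contig FASTA files).
#' @param planted_sites Optional tibble with columns `chromosome`,
#'   `position` (0-based), `class`, and optionally `sequence` (an
#'   explicit 34-mer; drawn via [random_site()] when `NA`) and
#'   `orientation` (`"+"` or `"-"`). Planted windows must not overlap.
#' @param repeat_families Optional tibble with columns `chromosome`,
#'   `copies`, `mutation_rate` and optionally `unit` (a sequence
#'   containing at least one valid site; generated when `NA`),
#'   `unit_length` (default 300) and `class` (of the embedded site,
#'   default 8). Copies are placed at random non-overlapping positions.
#' @param seed Integer seed; all randomness flows from it.
#' @param dir Output directory (created).
#' @param model Consensus model used for drawing and for the truth scan.
#' @return Invisibly, a list with `dir`, `fasta_files`, `manifest`
#'   (tibble, also written to `manifest.tsv`), `truth` (tibble, also
#'   `truth.tsv`: `chromosome`, `pos_0based`, `sequence`, `class`,
#'   `subclass_code`, `group_id`, `origin`) and `sequences` (named
#'   per-chromosome strings).
#' @export
simulate_genome <- function(chromosomes, planted_sites = NULL,
                            repeat_families = NULL, seed = 1L,
                            dir = tempfile("synthgenome"),
                            model = default_consensus()) {
  set.seed(seed)
  if (!"n_contigs" %in% names(chromosomes)) chromosomes$n_contigs <- 1L
  seqs <- lapply(seq_len(nrow(chromosomes)), function(i) {
    strsplit(random_background(chromosomes$length[i], chromosomes$gc[i]),
             "", fixed = TRUE)[[1]]
  })
  names(seqs) <- chromosomes$name
  # contig split points per chromosome; spliced features must not cross one
  bounds_of <- stats::setNames(lapply(seq_len(nrow(chromosomes)), function(i) {
    floor(seq(0L, chromosomes$length[i],
              length.out = chromosomes$n_contigs[i] + 1L))
  }), chromosomes$name)
  within_one_contig <- function(chrom, start0, len) {
    b <- bounds_of[[chrom]]
    any(start0 >= b[-length(b)] & start0 + len <= b[-1])
  }
  occupied <- stats::setNames(vector("list", nrow(chromosomes)),
                              chromosomes$name)
  note_interval <- function(chrom, start0, len) {
    iv <- occupied[[chrom]]
    if (!is.null(iv) && length(iv)) {
      for (p in iv) {
        if (start0 < p[1] + p[2] && p[1] < start0 + len) {
          rlang::abort(sprintf(
            "planted regions overlap on %s near position %d", chrom, start0))
        }
      }
    }
    occupied[[chrom]] <<- c(occupied[[chrom]], list(c(start0, len)))
  }
  planted_log <- list()

  if (!is.null(planted_sites) && nrow(planted_sites)) {
    if (!"sequence" %in% names(planted_sites)) planted_sites$sequence <- NA_character_
    if (!"orientation" %in% names(planted_sites)) planted_sites$orientation <- "+"
    for (i in seq_len(nrow(planted_sites))) {
      p <- planted_sites[i, ]
      site <- if (is.na(p$sequence)) random_site(p$class, model = model) else toupper(p$sequence)
      v <- evaluate_window(site, model)
      if (!v$accepted) {
        rlang::abort(sprintf("planted site %d is not accepted (rule: %s)",
                             i, v$failure_reason))
      }
      if (p$orientation == "-") site <- revcomp(site)
      L <- length(seqs[[p$chromosome]])
      if (p$position < 0 || p$position + .WINDOW_LEN > L) {
        rlang::abort(sprintf("planted site %d out of bounds on %s", i, p$chromosome))
      }
      if (!within_one_contig(p$chromosome, p$position, .WINDOW_LEN)) {
        rlang::abort(sprintf(
          "planted site %d on %s would straddle a contig split and be unscannable",
          i, p$chromosome))
      }
      note_interval(p$chromosome, p$position, .WINDOW_LEN)
      seqs[[p$chromosome]] <- splice_at(seqs[[p$chromosome]], site, p$position)
      planted_log[[length(planted_log) + 1L]] <- tibble::tibble(
        chromosome = p$chromosome, start0 = as.integer(p$position),
        len = .WINDOW_LEN, origin = "planted")
    }
  }

  if (!is.null(repeat_families) && nrow(repeat_families)) {
    if (!"unit" %in% names(repeat_families)) repeat_families$unit <- NA_character_
    if (!"unit_length" %in% names(repeat_families)) repeat_families$unit_length <- 300L
    if (!"class" %in% names(repeat_families)) repeat_families$class <- 8L
    for (i in seq_len(nrow(repeat_families))) {
      f <- repeat_families[i, ]
      unit <- if (is.na(f$unit)) {
        u <- strsplit(random_background(f$unit_length, 0.45), "", fixed = TRUE)[[1]]
        at <- sample.int(f$unit_length - .WINDOW_LEN + 1L, 1L) - 1L
        paste(splice_at(u, random_site(f$class, model = model), at),
              collapse = "")
      } else toupper(f$unit)
      ulen <- nchar(unit)
      L <- length(seqs[[f$chromosome]])
      for (cp in seq_len(f$copies)) {
        copy <- mutate_copy(unit, f$mutation_rate)
        for (try in 1:1000) {
          pos0 <- sample.int(L - ulen + 1L, 1L) - 1L
          ok <- within_one_contig(f$chromosome, pos0, ulen) &&
            tryCatch({
              note_interval(f$chromosome, pos0, ulen)
              TRUE
            }, error = function(e) FALSE)
          if (ok) break
          if (try == 1000) rlang::abort("could not place repeat copy without overlap")
        }
        seqs[[f$chromosome]] <- splice_at(seqs[[f$chromosome]], copy, pos0)
        planted_log[[length(planted_log) + 1L]] <- tibble::tibble(
          chromosome = f$chromosome, start0 = as.integer(pos0),
          len = as.integer(ulen), origin = "repeat")
      }
    }
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chrom_strings <- vapply(seqs, paste, character(1), collapse = "")

  manifest <- purrr::map_dfr(seq_len(nrow(chromosomes)), function(i) {
    nm <- chromosomes$name[i]
    L <- chromosomes$length[i]
    k <- chromosomes$n_contigs[i]
    bounds <- floor(seq(0L, L, length.out = k + 1L))
    tibble::tibble(chromosome = nm, order = seq_len(k),
                   contig_id = sprintf("%s_ctg%02d", nm, seq_len(k)),
                   start0 = bounds[-(k + 1L)],
                   length = as.integer(diff(bounds)))
  })
  fasta_files <- character(0)
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    sub <- substr(chrom_strings[[m$chromosome]], m$start0 + 1L,
                  m$start0 + m$length)
    f <- file.path(dir, paste0(m$contig_id, ".fa"))
    writeLines(c(paste0(">", m$contig_id),
                 substring(sub, seq(1L, nchar(sub), 70L),
                           pmin(nchar(sub), seq(1L, nchar(sub), 70L) + 69L))),
               f)
    fasta_files <- c(fasta_files, f)
  }
  manifest <- manifest[, c("chromosome", "order", "contig_id", "length")]
  write_manifest(manifest, file.path(dir, "manifest.tsv"))

  # Truth: full scan of every contig exactly as a scanner will see it
  # (windows straddling a contig split are not scannable and are not truth)
  planted_tbl <- dplyr::bind_rows(planted_log)
  truth <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    start0 <- sum(manifest$length[manifest$chromosome == m$chromosome &
                                    manifest$order < m$order])
    sub <- substr(chrom_strings[[m$chromosome]], start0 + 1L,
                  start0 + m$length)
    h <- scan_contig(sub, m$contig_id, model)
    if (!nrow(h)) return(tibble::tibble())
    tibble::tibble(chromosome = m$chromosome,
                   pos_0based = start0 + h$contig_offset,
                   sequence = h$sequence, class = h$class,
                   subclass_code = h$subclass_code,
                   canonical_seq = h$canonical_seq)
  })
  if (nrow(truth)) {
    counts <- table(truth$canonical_seq)
    dup_keys <- names(counts)[counts >= 2L]
    truth$group_id <- match(truth$canonical_seq, dup_keys)
    # a hit is "planted"/"repeat" when its window lies inside a spliced
    # interval of that origin; everything else is background (which may
    # include sites straddling a splice junction)
    origin <- rep("background", nrow(truth))
    for (i in seq_len(nrow(planted_tbl))) {
      iv <- planted_tbl[i, ]
      inside <- truth$chromosome == iv$chromosome &
        truth$pos_0based >= iv$start0 &
        truth$pos_0based + .WINDOW_LEN <= iv$start0 + iv$len
      origin[inside] <- iv$origin
    }
    truth$origin <- origin
    truth$canonical_seq <- NULL
  }
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))

  invisible(list(dir = dir, fasta_files = fasta_files, manifest = manifest,
                 truth = truth, planted = planted_tbl,
                 sequences = chrom_strings))
}
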