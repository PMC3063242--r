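test_that("a planted wild-type site in clean flanks yields exactly one hit at its offset", {
  contig <- plant_in_flanks(FRT_WT, flank_len = 50, seed = 42)
  hits <- scan_contig(contig, "c1")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$contig_offset, 50L)
  expect_identical(hits$sequence, FRT_WT)
  expect_identical(hits$class, 8L)
})

test_that("contigs shorter than the window yield no hits", {
  expect_identical(nrow(scan_contig(strrep("A", 33), "short")), 0L)
  expect_identical(nrow(scan_contig("", "empty")), 0L)
})

test_that("chunked scanning equals whole-string scanning", {
  withr::local_seed(7001)
  contig <- random_dna(100000, 0.41)
  whole <- scan_contig(contig, "c", chunk_size = 200000L)
  expect_gt(nrow(whole), 0)
  for (cs in c(10000L, 137L, 34L)) {
    expect_identical(scan_contig(contig, "c", chunk_size = cs), whole,
                     label = sprintf("chunk_size %d", cs))
  }
})

test_that("chromosome-linear positions add the contig offset from the layout", {
  withr::local_seed(11)
  dirp <- withr::local_tempdir()
  c1 <- random_dna(1000, 0.6)
  c2chars <- strsplit(random_dna(2000, 0.6), "", fixed = TRUE)[[1]]
  c2chars[11:44] <- strsplit(FRT_WT, "", fixed = TRUE)[[1]]
  c2 <- paste(c2chars, collapse = "")
  writeLines(c(">ctgA", c1), file.path(dirp, "ctgA.fa"))
  writeLines(c(">ctgB", c2), file.path(dirp, "ctgB.fa"))
  manifest <- tibble::tibble(chromosome = "chr1", order = 1:2,
                             contig_id = c("ctgA", "ctgB"),
                             length = c(1000L, 2000L))
  scan <- scan_genome(dirp, manifest)
  wt_hit <- scan$hits[scan$hits$sequence == FRT_WT, ]
  expect_identical(wt_hit$contig_id, "ctgB")
  expect_identical(wt_hit$contig_offset, 10L)
  expect_identical(wt_hit$chrom_linear_pos, 1010L)
})

test_that("duplicate partitioning keys on the canonical 34-mer across orientations", {
  s <- FRT_WT
  hits <- tibble::tibble(
    chromosome = "chr1", chrom_linear_pos = c(0L, 100L, 200L),
    contig_id = "c", contig_offset = c(0L, 100L, 200L),
    sequence = c(s, s, revcomp(s)))
  hits <- dplyr::bind_cols(hits, evaluate_window(hits$sequence)[
    c("class", "subclass_code")])
  p <- partition_duplicates(hits)
  expect_identical(nrow(p$unique_pool), 0L)
  expect_identical(nrow(p$duplicate_groups), 1L)
  expect_identical(p$duplicate_groups$copy_number, 3L)
  expect_identical(p$duplicate_groups$canonical_seq, canonical_seq(s))

  distinct <- hits[1, ]
  p2 <- partition_duplicates(distinct)
  expect_identical(nrow(p2$duplicate_groups), 0L)
  expect_identical(nrow(p2$unique_pool), 1L)
})

test_that("a verbatim repeat family groups together; a mutated copy stays unique", {
  withr::local_seed(501)
  site <- random_site(8)
  # a point mutation at a distal position that keeps the site valid
  ch <- strsplit(site, "", fixed = TRUE)[[1]]
  repeat {
    cand <- ch
    cand[2] <- sample(setdiff(c("A", "C", "G", "T"), ch[2]), 1)
    cand <- paste(cand, collapse = "")
    if (evaluate_window(cand)$accepted) break
  }
  unit <- strsplit(random_dna(300, 0.45), "", fixed = TRUE)[[1]]
  unit[101:134] <- strsplit(site, "", fixed = TRUE)[[1]]
  unit <- paste(unit, collapse = "")
  sim <- simulate_genome(
    tibble::tibble(name = "chr1", length = 30000L, gc = 0.55),
    planted_sites = tibble::tibble(chromosome = "chr1", position = 500L,
                                   class = 8L, sequence = cand),
    repeat_families = tibble::tibble(chromosome = "chr1", copies = 6L,
                                     mutation_rate = 0, unit = unit),
    seed = 502, dir = withr::local_tempdir())
  scan <- scan_genome(sim$dir, sim$manifest)
  grp <- scan$duplicate_groups[
    scan$duplicate_groups$canonical_seq == canonical_seq(site), ]
  expect_identical(grp$copy_number, 6L)
  expect_true(cand %in% scan$unique_pool$sequence |
                revcomp(cand) %in% scan$unique_pool$sequence)
})

test_that("hits are conserved across the unique/duplicated partition and sorted", {
  sim <- simulate_genome(
    tibble::tibble(name = c("chr1", "chr2"), length = 20000L, gc = 0.41),
    seed = 77, dir = withr::local_tempdir())
  scan <- scan_genome(sim$dir, sim$manifest)
  g <- glance(scan)
  expect_identical(g$n_hits, g$n_unique + g$n_duplicated_sites)
  expect_identical(
    order(scan$hits$chromosome, scan$hits$chrom_linear_pos),
    seq_len(nrow(scan$hits)))
})

test_that("scanning the reverse-complemented genome finds the same canonical sites", {
  sim <- simulate_genome(
    tibble::tibble(name = "chr1", length = 40000L, gc = 0.38),
    planted_sites = tibble::tibble(chromosome = "chr1",
                                   position = c(1000L, 2000L, 3000L),
                                   class = c(8L, 7L, 6L)),
    seed = 88, dir = withr::local_tempdir())
  fwd <- scan_genome(sim$dir, sim$manifest)
  rcdir <- withr::local_tempdir()
  for (f in sim$fasta_files) {
    set <- Biostrings::readDNAStringSet(f)
    writeLines(c(paste0(">", sub("\\s.*$", "", names(set))),
                 as.character(Biostrings::reverseComplement(set))),
               file.path(rcdir, basename(f)))
  }
  rev <- scan_genome(rcdir, sim$manifest)
  expect_identical(sort(fwd$hits$canonical_seq), sort(rev$hits$canonical_seq))
  expect_identical(sort(fwd$hits$subclass_code), sort(rev$hits$subclass_code))
  expect_identical(table(fwd$hits$class), table(rev$hits$class))
})

test_that("layout and manifest errors are informative", {
  dirp <- withr::local_tempdir()
  manifest <- tibble::tibble(chromosome = "chr1", order = 1L,
                             contig_id = "ctgA", length = 100L)
  expect_error(scan_genome(dirp, manifest), "no FASTA inputs")
  writeLines(c(">ctgB", strrep("A", 50)), file.path(dirp, "ctgB.fa"))
  expect_error(scan_genome(dirp, manifest), "ctgA")
  writeLines(c(">ctgA", strrep("A", 100)), file.path(dirp, "ctgA.fa"))
  expect_warning(scan_genome(dirp, manifest), "unplaced")
  expect_error(genome_layout(tibble::tibble(chromosome = "c")), "missing column")
})

test_that("genome_layout accumulates strictly increasing offsets", {
  lay <- genome_layout(tibble::tibble(
    chromosome = c("chr2", "chr1", "chr1"), order = c(1L, 2L, 1L),
    contig_id = c("b1", "a2", "a1"), length = c(500L, 300L, 200L)))
  expect_identical(lay$contig_id, c("a1", "a2", "b1"))
  expect_identical(lay$offset, c(0L, 200L, 0L))
})

test_that("scan objects print, tidy and plot", {
  sim <- simulate_genome(
    tibble::tibble(name = "chr1", length = 15000L, gc = 0.40),
    seed = 91, dir = withr::local_tempdir())
  scan <- scan_genome(sim$dir, sim$manifest)
  expect_output(print(scan), "FRT-like sites")
  expect_s3_class(tidy(scan), "tbl_df")
  expect_true("duplicated" %in% names(tidy(scan)))
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
  expect_output(print(default_consensus()), "proximal-8 >= 5")
})
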