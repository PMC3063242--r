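# Small fixture builders shared across test files.

FRT_WT <- frtscan::frt_wildtype()

# Mutate wild-type FRT at given 1-based character columns.
mutate_wt <- function(...) {
  muts <- list(...)
  ch <- strsplit(FRT_WT, "", fixed = TRUE)[[1]]
  for (m in muts) ch[m[[1]]] <- m[[2]]
  paste(ch, collapse = "")
}

# Character column holding an element position (for readable tests).
col_of_pos <- function(pos) ifelse(pos < 0, pos + 14L, pos + 21L)

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Flanking sequence guaranteed (by oracle check) to add no accepted
# windows around a planted site.
plant_in_flanks <- function(site, flank_len = 50, seed = 42) {
  withr::with_seed(seed, {
    repeat {
      s <- paste0(random_dna(flank_len, 0.6), site, random_dna(flank_len, 0.6))
      if (identical(oracle_scan(s), as.integer(flank_len))) return(s)
    }
  })
}

run_py_oracle <- function(fasta_files) {
  script <- testthat::test_path("oracle_scan.py")
  out <- system2("python", c(script, fasta_files), stdout = TRUE)
  if (!length(out)) {
    return(tibble::tibble(contig_id = character(0), offset0 = integer(0)))
  }
  parts <- strsplit(out, "\t", fixed = TRUE)
  tibble::tibble(contig_id = vapply(parts, `[`, "", 1),
                 offset0 = as.integer(vapply(parts, `[`, "", 2)))
}
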