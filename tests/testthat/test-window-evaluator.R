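test_that("wild-type FRT is a perfect class-8 site", {
  v <- evaluate_window(FRT_WT)
  expect_true(v$accepted)
  expect_identical(v$class, 8L)
  expect_identical(v$overall_score, 26L)
  expect_identical(v$weighted_score, 26)
  expect_identical(v$consecutive_score, 13L)
  expect_true(all(match_mask(FRT_WT)[1, ]))
  expect_identical(v$spacer, "TCTAGAAA")
})

test_that("spacer rules: T at s1, A at s8, at most four G/C bases", {
  expect_true(check_spacer("TCTAGAAA"))   # wild-type spacer, 2/8 GC
  expect_false(check_spacer("GCTAGAAA"))  # s1 != T
  expect_false(check_spacer("TCTAGAAG"))  # s8 != A
  expect_false(check_spacer("TCCGGCGA"))  # 5/8 GC
  expect_true(check_spacer("TCCGGAAA"))   # exactly 4/8 GC is allowed
  expect_false(check_spacer("TCTNGAAA"))  # non-ACGT rejects, no error
})

test_that("homopolymer rule: runs longer than four are rejected, four passes", {
  expect_true(homopolymer_ok(FRT_WT))
  expect_false(homopolymer_ok(paste0("AAAAA", substr(FRT_WT, 6, 34))))
  # a window carrying an exact 4-run and nothing longer is permitted
  w4 <- paste0("CAAAAC", strrep("GT", 14))
  expect_identical(nchar(w4), 34L)
  expect_true(homopolymer_ok(w4))
  expect_false(homopolymer_ok(paste0("CAAAAAC", strrep("GT", 13), "G")))
})

test_that("match mask maps window characters to element positions correctly", {
  mut <- mutate_wt(list(col_of_pos(1), "C")) # right-element position 1 G->C
  mk <- match_mask(mut)[1, ]
  expect_false(mk[["1"]])
  expect_true(all(mk[setdiff(names(mk), "1")]))
})

test_that("match mask agrees with an independent base-in-set check on random windows", {
  withr::local_seed(314)
  wins <- random_windows(1000)
  wins <- wins[!grepl("N", wins)]
  mk <- match_mask(wins)
  for (i in sample(length(wins), 200)) {
    ch <- strsplit(wins[i], "", fixed = TRUE)[[1]]
    for (k in 1:26) {
      col <- if (k <= 13) k else k + 8
      expect_identical(unname(mk[i, k]), ch[col] %in% ORACLE_ALLOWED[[k]])
    }
  }
})

test_that("proximal-8 rules: count, adjacency, simultaneous -1/1, forbidden bases", {
  expect_identical(proximal8_checks(FRT_WT),
                   tibble::tibble(count = 8L, ok = TRUE, reason = NA_character_))
  # mismatches at -3 and -2 only: adjacent within the left segment
  adj <- mutate_wt(list(col_of_pos(-3), "G"), list(col_of_pos(-2), "G"))
  p <- proximal8_checks(adj)
  expect_identical(p$count, 6L)
  expect_false(p$ok)
  expect_identical(p$reason, "consecutive_mismatch_in_segment")
  # G at -1 is forbidden outright
  forb <- mutate_wt(list(col_of_pos(-1), "G"))
  p <- proximal8_checks(forb)
  expect_identical(p$count, 7L)
  expect_false(p$ok)
  expect_identical(p$reason, "forbidden_base_pm1")
  # mismatches at both -1 and 1 simultaneously
  both <- mutate_wt(list(col_of_pos(-1), "A"), list(col_of_pos(1), "T"))
  expect_identical(proximal8_checks(both)$reason, "both_proximal_mismatch")
})

test_that("element rules: position 7, one-side matches, consecutive run", {
  e <- element_checks(FRT_WT)
  expect_true(e$ok)
  expect_identical(e$longest_run, 13L)
  # no match at -7 or 7
  p7 <- mutate_wt(list(col_of_pos(-7), "A"), list(col_of_pos(7), "A"))
  e <- element_checks(p7)
  expect_false(e$ok)
  expect_identical(e$reason, "position7")
  # breaking runs in both elements (mismatches at -8, -4, 4, 8) caps runs at 5
  runs <- mutate_wt(list(col_of_pos(-8), "G"), list(col_of_pos(-4), "C"),
                    list(col_of_pos(4), "C"), list(col_of_pos(8), "C"))
  e <- element_checks(runs)
  expect_false(e$ok)
  expect_identical(e$longest_run, 5L)
  expect_identical(e$reason, "consecutive_run")
})

test_that("evaluate_window applies rules in fixed order and reports the first failure", {
  expect_identical(
    evaluate_window(sub("TCTAGAAA", "GCTAGAAA", FRT_WT))$failure_reason,
    "spacer_ends")
  expect_identical(
    evaluate_window(mutate_wt(list(col_of_pos(-1), "A"),
                              list(col_of_pos(1), "T")))$failure_reason,
    "both_proximal_mismatch")
  n_win <- mutate_wt(list(3, "N"))
  v <- evaluate_window(n_win)
  expect_false(v$accepted)
  expect_identical(v$failure_reason, "non_acgt")
  expect_error(evaluate_window("ACGT"), "34")
})

test_that("lowercase soft-masked sequence is case-folded, not rejected", {
  expect_true(evaluate_window(tolower(FRT_WT))$accepted)
})

test_that("evaluator agrees with the brute-force oracle on random windows", {
  withr::local_seed(2718)
  wins <- random_windows(4000)
  got <- evaluate_window(wins)$accepted
  want <- vapply(wins, oracle_accept, logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("acceptance is reverse-complement closed under the default model", {
  withr::local_seed(1618)
  wins <- random_windows(4000)
  fwd <- evaluate_window(wins)
  rev <- evaluate_window(revcomp(wins))
  expect_identical(fwd$accepted, rev$accepted)
  # and the annotations of accepted windows are orientation-invariant
  acc <- fwd$accepted
  expect_identical(fwd$class[acc], rev$class[acc])
  expect_identical(fwd$subclass_code[acc], rev$subclass_code[acc])
  expect_identical(fwd$overall_score[acc], rev$overall_score[acc])
})

test_that("every accepted window satisfies the class and spacer invariants", {
  withr::local_seed(99)
  wins <- random_windows(4000)
  v <- evaluate_window(wins)
  acc <- v[v$accepted, ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$class %in% 5:8))
  gc <- vapply(strsplit(acc$spacer, "", fixed = TRUE),
               function(ch) sum(ch %in% c("G", "C")), integer(1))
  expect_true(all(gc <= 4))
  expect_true(all(acc$overall_score >= acc$proximal8_matches))
})

test_that("scores annotate but never gate: zero-weight model still accepts", {
  m <- load_consensus(text = "weights: 0\n")
  v <- evaluate_window(FRT_WT, m)
  expect_true(v$accepted)
  expect_identical(v$weighted_score, 0)
  expect_identical(v$overall_score, 26L)
})

test_that("strict per-element run flag tightens acceptance", {
  strict <- load_consensus(text = "rules:\n  run_in_each_element: true\n")
  # break the run in the left element only; lenient reading accepts
  w <- mutate_wt(list(col_of_pos(-8), "G"), list(col_of_pos(-4), "C"))
  expect_true(evaluate_window(w)$accepted)
  v <- evaluate_window(w, strict)
  expect_false(v$accepted)
  expect_identical(v$failure_reason, "consecutive_run")
})
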