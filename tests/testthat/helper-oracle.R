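# Independent brute-force rule checker, written directly from the textual
# identification rules with naive per-window string operations. It shares
# no code with the package's matrix engine and is deliberately slow and
# literal; it is the reference the scanner is tested against.

ORACLE_ALLOWED <- local({
  left <- list("G", "A", "A", "G", "T", "T", "C", "C", "T", "A", "T",
               c("A", "T"), c("C", "T"))
  right <- list(c("A", "G"), c("A", "T"), "A", "T", "A", "G", "G", "A",
                "A", "C", "T", "T", "C")
  c(left, right) # order: positions -13..-1 then 1..13
})

oracle_longest_true_run <- function(v) {
  r <- rle(v)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

# Accept/reject one 34-mer under the default rules.
oracle_accept <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  if (length(ch) != 34L) stop("oracle needs a 34-mer")
  if (any(!ch %in% c("A", "C", "G", "T"))) return(FALSE)
  sp <- ch[14:21]
  if (sp[1] != "T" || sp[8] != "A") return(FALSE)
  if (sum(sp %in% c("G", "C")) > 4L) return(FALSE)
  if (max(rle(ch)$lengths) > 4L) return(FALSE)
  m <- logical(26L)
  for (k in 1:26) {
    col <- if (k <= 13L) k else k + 8L
    m[k] <- ch[col] %in% ORACLE_ALLOWED[[k]]
  }
  p8 <- m[10:17] # -4,-3,-2,-1,1,2,3,4
  if (sum(p8) < 5L) return(FALSE)
  mm_left <- !p8[1:4]
  mm_right <- !p8[5:8]
  if (any(mm_left[1:3] & mm_left[2:4])) return(FALSE)
  if (any(mm_right[1:3] & mm_right[2:4])) return(FALSE)
  if (!p8[4] && !p8[5]) return(FALSE)
  if (ch[13] == "G" || ch[22] == "C") return(FALSE)
  if (!(m[7] || m[20])) return(FALSE)
  if (sum(m[1:13]) < 5L && sum(m[14:26]) < 5L) return(FALSE)
  if (max(oracle_longest_true_run(m[1:13]),
          oracle_longest_true_run(m[14:26])) < 6L) return(FALSE)
  TRUE
}

oracle_class <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  p8cols <- c(10:13, 22:25)
  p8pos <- c(10:13, 14:17)
  sum(vapply(seq_along(p8cols),
             function(i) ch[p8cols[i]] %in% ORACLE_ALLOWED[[p8pos[i]]],
             logical(1)))
}

# Naive full scan of a sequence string: 0-based offsets of accepted windows.
oracle_scan <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence) - 33L
  if (n < 1L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (oracle_accept(substr(sequence, i, i + 33L))) {
      hits <- c(hits, i - 1L)
    }
  }
  hits
}

# Random test windows biased to exercise the deeper rules: plain uniform
# windows almost always fail the spacer check, so mix in mutated wild-type
# sites and windows with a forced functional spacer.
random_windows <- function(n) {
  wt <- strsplit(frt_wildtype(), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    kind <- i %% 4L
    if (kind == 0L) {
      paste(sample(c(bases, "N"), 34L, replace = TRUE,
                   prob = c(rep(0.245, 4), 0.02)), collapse = "")
    } else if (kind == 1L) {
      paste(sample(bases, 34L, replace = TRUE), collapse = "")
    } else {
      ch <- wt
      nmut <- sample(0:12, 1L)
      at <- sample(34L, nmut)
      for (j in at) ch[j] <- sample(bases, 1L)
      if (kind == 3L) { # force a plausible spacer so later rules are reached
        ch[14] <- "T"
        ch[21] <- "A"
      }
      paste(ch, collapse = "")
    }
  }, character(1))
}
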