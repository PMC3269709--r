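# Independent brute-force oracles used by the tests. These deliberately do
# not share code with the package implementation.

# Enumerate every global alignment of a and b; return the optimal score and
# the set of percent identities (matches / columns * 100, 1 dp) achieved by
# optimal-score alignments. Feasible for lengths <= 6.
oracle_global_alignments <- function(a, b, match = 1, mismatch = 0,
                                     gap = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  results <- new.env()
  results$best <- -Inf
  results$idents <- numeric(0)
  rec <- function(i, j, score, matches, cols) {
    if (i > length(a) && j > length(b)) {
      if (score > results$best + 1e-9) {
        results$best <- score
        results$idents <- round(100 * matches / cols, 1)
      } else if (abs(score - results$best) < 1e-9) {
        results$idents <- unique(c(results$idents,
                                   round(100 * matches / cols, 1)))
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      hit <- a[i] == b[j]
      rec(i + 1, j + 1, score + if (hit) match else mismatch,
          matches + hit, cols + 1)
    }
    if (i <= length(a)) rec(i + 1, j, score + gap, matches, cols + 1)
    if (j <= length(b)) rec(i, j + 1, score + gap, matches, cols + 1)
  }
  rec(1L, 1L, 0, 0L, 0L)
  list(score = results$best, identities = results$idents)
}

# Recompute the alignment score the package's reported identity implies is
# optimal, by rescoring its aligned strings.
rescore_alignment <- function(p, s, match = 1, mismatch = 0, gap = -1) {
  p <- strsplit(p, "")[[1]]; s <- strsplit(s, "")[[1]]
  sum(ifelse(p == "-" | s == "-", gap, ifelse(p == s, match, mismatch)))
}

# Exhaustive maximum over all valid secondary structures (pairs GC/AU/GU,
# min_loop unpaired bases inside every pair). Plain recursion over the
# "first base unpaired or paired with k" decomposition: every structure is
# visited exactly once. No memoization, no traceback.
oracle_fold_score <- function(seq, min_loop = 3,
                              weights = c(GC = 3, AU = 2, GU = 1)) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  pw <- function(x, y) {
    key <- paste0(x, y)
    if (key %in% c("GC", "CG")) weights[["GC"]]
    else if (key %in% c("AU", "UA")) weights[["AU"]]
    else if (key %in% c("GU", "UG")) weights[["GU"]]
    else NA_real_
  }
  rec <- function(i, j) {
    if (j - i < 1) return(0)
    best <- rec(i + 1, j)
    ks <- if (i + min_loop + 1 <= j) seq.int(i + min_loop + 1, j)
          else integer(0)
    for (k in ks) {
      w <- pw(s[i], s[k])
      if (is.na(w)) next
      best <- max(best, w + rec(i + 1, k - 1) + rec(k + 1, j))
    }
    best
  }
  if (length(s) < 2) 0 else rec(1L, length(s))
}

# Quadratic all-pairs anchor-collision oracle.
oracle_anchor_groups <- function(seqs, anchor_len = 6) {
  seqs <- chartr("T", "U", toupper(seqs))
  anch <- substr(seqs, nchar(seqs) - anchor_len + 1, nchar(seqs))
  groups <- list()
  for (i in seq_along(seqs)) {
    members <- names(seqs)[i]
    for (j in seq_along(seqs)[-i]) {
      if (anch[i] == anch[j]) members <- c(members, names(seqs)[j])
    }
    if (length(members) >= 2)
      groups[[anch[i]]] <- sort(unique(c(groups[[anch[i]]], members)))
  }
  groups
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Check that a dot-bracket string is balanced and honors min_loop.
structure_is_valid <- function(structure, min_loop = 3) {
  ch <- strsplit(structure, "")[[1]]
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) return(FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i - j - 1 < min_loop) return(FALSE)
    }
  }
  length(stack) == 0
}
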