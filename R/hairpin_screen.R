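#' Fold an RNA by weighted base-pair maximization
#'
#' Nussinov-style dynamic program maximizing the summed weight of allowed
#' pairs (GC, AU and GU wobble) subject to a minimum hairpin-loop length.
#' This is a hairpin plausibility score, deliberately simpler than a
#' thermodynamic free-energy model: scores are weighted pair counts and are
#' not comparable to mfold/ViennaRNA free energies. The traceback is
#' deterministic (a base pairs whenever pairing achieves the optimum, with
#' the smallest admissible partner on ties), so results are reproducible.
#'
#' @param seq RNA [nuc_seq] or string (DNA input is converted).
#' @param min_loop Minimum unpaired bases enclosed by any pair (default 3).
#' @param weights Named vector with positive entries `GC`, `AU`, `GU`;
#'   defaults 3/2/1, ordered `GU <= AU <= GC`.
#' @return List with `structure` (dot-bracket string, same length as the
#'   sequence) and `pair_score` (the DP optimum).
#' @examples
#' fold_maxpair("GGGAAACCC")  # "(((...)))", score 9
#' @export
fold_maxpair <- function(seq, min_loop = 3L,
                         weights = c(GC = 3, AU = 2, GU = 1)) {
  s <- dna_to_rna(as_nuc_seq(seq, id = "rna"))$seq
  stopifnot(all(c("GC", "AU", "GU") %in% names(weights)))
  w <- weights[c("GC", "AU", "GU")]
  if (any(w <= 0) || !(w["GU"] <= w["AU"] && w["AU"] <= w["GC"]))
    stop("weights must be positive with GU <= AU <= GC", call. = FALSE)
  min_loop <- as.integer(min_loop)
  if (nchar(s) < min_loop + 2L)
    return(list(structure = strrep(".", nchar(s)), pair_score = 0))
  .fold_maxpair_cpp(s, min_loop, w[["GC"]], w[["AU"]], w[["GU"]])
}

# Pair table from a dot-bracket string: for each position, the index of
# its partner (NA when unpaired). Errors on unbalanced brackets.
dotbracket_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i; partner[i] <- j
    } else if (ch[i] != ".") stop("invalid structure character", call. = FALSE)
  }
  if (length(stack)) stop("unbalanced brackets", call. = FALSE)
  partner
}

#' Structural statistics of a folded hairpin candidate
#'
#' Computed from the dot-bracket string: fraction of bases paired, terminal
#' hairpin-loop length (the unpaired run enclosed by the most deeply nested
#' pair whose interior holds no further pairs), and, when the mature
#' position is supplied, the fraction of mature bases paired and the arm
#' (5p/3p by mature midpoint vs structure midpoint).
#'
#' @param structure Dot-bracket string, or a list with elements `structure`
#'   (and optionally `mature_start`) such as a [scan_precursors()] row.
#' @param mature_start 1-based start of the mature within the folded
#'   window (optional).
#' @param mature_length Mature length in nt (optional).
#' @return List `paired_fraction`, `loop_len`, `mature_paired_fraction`,
#'   `arm`.
#' @export
hairpin_stats <- function(structure, mature_start = NULL,
                          mature_length = NULL) {
  if (is.list(structure)) {
    if (is.null(mature_start) && !is.null(structure$mature_start))
      mature_start <- structure$mature_start
    structure <- structure$structure
  }
  stopifnot(is.character(structure), length(structure) == 1L)
  partner <- dotbracket_pairs(structure)
  n <- length(partner)
  paired_fraction <- sum(!is.na(partner)) / n

  loop_len <- NA_integer_
  opens <- which(!is.na(partner) & seq_len(n) < partner)
  if (length(opens)) {
    depth <- cumsum((strsplit(structure, "")[[1]] == "(")) -
      cumsum(c(0, utils::head(strsplit(structure, "")[[1]] == ")", -1)))
    hairpins <- opens[vapply(opens, function(i) {
      j <- partner[i]
      j > i + 1L && all(is.na(partner[(i + 1L):(j - 1L)]))
    }, logical(1))]
    # a pair with an empty interior closes a hairpin loop of length 0
    hairpins <- c(hairpins, opens[partner[opens] == opens + 1L])
    if (length(hairpins)) {
      best <- hairpins[which.max(depth[hairpins])]
      loop_len <- as.integer(partner[best] - best - 1L)
    }
  }

  mature_paired_fraction <- NA_real_
  arm <- "unknown"
  if (!is.null(mature_start) && !is.na(mature_start) &&
      !is.null(mature_length)) {
    span <- mature_start:(mature_start + mature_length - 1L)
    span <- span[span >= 1L & span <= n]
    if (length(span)) {
      mature_paired_fraction <- sum(!is.na(partner[span])) / length(span)
      mid <- mean(range(span))
      arm <- if (mid <= n / 2) "5p" else "3p"
    }
  }
  list(paired_fraction = paired_fraction, loop_len = loop_len,
       mature_paired_fraction = mature_paired_fraction, arm = arm)
}

#' Scan a source sequence for hairpin precursor candidates
#'
#' For every exact occurrence of the mature miRNA in the (RNA-normalised)
#' source, windows of each size in `window_range` that fully contain the
#' occurrence are folded with [fold_maxpair()] and ranked by pair score,
#' then paired fraction, with ties broken by smaller window and leftmost
#' start. The default window sizes (70-90 nt) cover the typical pre-miRNA
#' length range.
#'
#' @param source Genomic/EST sequence ([nuc_seq] or string).
#' @param mature Mature miRNA ([nuc_seq] or string).
#' @param window_range Integer vector of window sizes (default `70:90`).
#' @param step Window start step (default 1).
#' @param top_n Candidates returned (default 5).
#' @inheritParams fold_maxpair
#' @return Data frame of class `hairpin_candidates`, one row per candidate:
#'   `source_id`, `window_start`, `window_end`, `seq`, `structure`,
#'   `pair_score`, `paired_fraction`, `loop_len`, `mature_start` (position
#'   of the mature within the window), `mature_paired_fraction`, `arm`.
#'   Empty (zero rows) when the mature does not occur in the source.
#' @export
scan_precursors <- function(source, mature, window_range = 70:90,
                            step = 1L, top_n = 5L, min_loop = 3L,
                            weights = c(GC = 3, AU = 2, GU = 1)) {
  source <- as_nuc_seq(source, id = "source")
  mature <- as_nuc_seq(mature, id = "mature")
  src <- dna_to_rna(source)$seq
  mat <- dna_to_rna(mature)$seq
  n <- nchar(src); m <- nchar(mat)
  window_range <- sort(unique(as.integer(window_range)))
  step <- as.integer(step)

  occ <- gregexpr(mat, src, fixed = TRUE)[[1]]
  occ <- occ[occ > 0]
  empty <- data.frame(
    source_id = character(), window_start = integer(),
    window_end = integer(), seq = character(), structure = character(),
    pair_score = numeric(), paired_fraction = numeric(),
    loop_len = integer(), mature_start = integer(),
    mature_paired_fraction = numeric(), arm = character(),
    stringsAsFactors = FALSE)
  if (!length(occ)) return(structure(empty, class = c("hairpin_candidates",
                                                      "data.frame")))

  rows <- list()
  seen <- character(0)
  for (m_start in occ) {
    m_end <- m_start + m - 1L
    for (w in window_range) {
      if (w < m || w > n) next
      lo <- max(1L, m_end - w + 1L)
      hi <- min(m_start, n - w + 1L)
      if (hi < lo) next
      for (s0 in seq.int(lo, hi, by = step)) {
        key <- paste(s0, w)
        if (key %in% seen) next
        seen <- c(seen, key)
        win <- substr(src, s0, s0 + w - 1L)
        f <- fold_maxpair(win, min_loop = min_loop, weights = weights)
        st <- hairpin_stats(f$structure, mature_start = m_start - s0 + 1L,
                            mature_length = m)
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = source$id, window_start = s0,
          window_end = s0 + w - 1L, seq = win, structure = f$structure,
          pair_score = f$pair_score, paired_fraction = st$paired_fraction,
          loop_len = st$loop_len, mature_start = m_start - s0 + 1L,
          mature_paired_fraction = st$mature_paired_fraction, arm = st$arm,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$pair_score, -out$paired_fraction,
               out$window_end - out$window_start, out$window_start)
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  structure(out, class = c("hairpin_candidates", "data.frame"))
}

#' Write sequence + structure in Vienna dot-bracket format
#'
#' @param seq RNA string.
#' @param structure Dot-bracket string of the same length.
#' @param id Record id for the header line.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dotbracket <- function(seq, structure, id, path) {
  stopifnot(nchar(seq) == nchar(structure))
  writeLines(c(paste0(">", id), seq, structure), path)
  invisible(path)
}
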