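#' Simulate the reverse-transcription step
#'
#' The stem-loop RT primer anneals to the mature miRNA's 3' anchor and is
#' extended along the rest of the miRNA, giving
#' `cDNA = rt_primer + revcomp(DNA(mature[1 .. n - anchor_len]))`. If the
#' mature's 3' anchor does not match the primer set's anchor the RT priming
#' fails and an error is raised.
#'
#' @param mature Mature miRNA ([nuc_seq] or string).
#' @param ps A `primer_set` (see [design_assay()]).
#' @param b The [stemloop_backbone] the set was designed on.
#' @return cDNA DNA string of length
#'   `nchar(b$seq) + anchor_len + (n - anchor_len)`.
#' @export
simulate_cdna <- function(mature, ps, b) {
  mature <- as_nuc_seq(mature, id = "mature")
  stopifnot(inherits(ps, "primer_set"), inherits(b, "stemloop_backbone"))
  mdna <- rna_to_dna(mature)$seq
  n <- nchar(mdna)
  anchor <- substr(mdna, n - ps$anchor_len + 1L, n)
  rt_anchor <- substr(ps$rt_primer, nchar(ps$rt_primer) - ps$anchor_len + 1L,
                      nchar(ps$rt_primer))
  if (rt_anchor != revcomp(anchor))
    stop(sprintf(
      "RT priming failed: mature 3' anchor %s does not match RT primer (expects %s)",
      anchor, revcomp(rt_anchor)), call. = FALSE)
  paste0(ps$rt_primer, revcomp(substr(mdna, 1L, n - ps$anchor_len)))
}

#' Predict the PCR amplicon for a stem-loop assay
#'
#' The amplicon is bounded by the 5' ends of the forward and reverse
#' primers (standard PCR convention). Its top strand, in forward-primer
#' sense, is `forward + DNA(mature[cover_len+1 .. n]) +
#' revcomp(backbone[rev_primer_start .. end])`, annotated segment-wise as
#' prefix / covered mature / gap / anchor / backbone span. The full mature
#' sequence, gap bases included, is contained in the amplicon.
#'
#' @inheritParams simulate_cdna
#' @return An object of class `amplicon_model`: `mirna_id`, `seq`, `length`
#'   and a `segments` data frame (`label`, `start`, `end`, 1-based
#'   inclusive) tiling `1..length`.
#' @examples
#' ps <- example_assays("group2")[["dme-miR-14"]]
#' predict_amplicon(ps$mature, ps, backbone_preset("group2"))$length  # 76
#' @export
predict_amplicon <- function(mature, ps, b) {
  mature <- as_nuc_seq(mature, id = if (is_nuc_seq(mature)) mature$id
                                    else ps$mirna_id)
  stopifnot(inherits(ps, "primer_set"), inherits(b, "stemloop_backbone"))
  invisible(simulate_cdna(mature, ps, b))  # enforces the priming contract
  mdna <- rna_to_dna(mature)$seq
  n <- nchar(mdna)
  if (ps$cover_len + ps$gap_len + ps$anchor_len != n)
    stop("primer set partition does not match this mature's length",
         call. = FALSE)
  fwd_suffix <- substr(ps$forward, nchar(ps$prefix) + 1L, nchar(ps$forward))
  if (fwd_suffix != substr(mdna, 1L, ps$cover_len))
    stop("forward primer does not match the mature 5' end", call. = FALSE)
  bb_span <- revcomp(substr(b$seq, b$rev_primer_start, nchar(b$seq)))
  seq <- paste0(ps$forward, substr(mdna, ps$cover_len + 1L, n), bb_span)
  p <- nchar(ps$prefix)
  bounds <- cumsum(c(p, ps$cover_len, ps$gap_len, ps$anchor_len,
                     nchar(bb_span)))
  segments <- data.frame(
    label = c("prefix", "covered_mature", "gap", "anchor", "backbone_span"),
    start = c(1L, head_int(bounds, -1) + 1L),
    end = as.integer(bounds), stringsAsFactors = FALSE)
  segments <- segments[segments$end >= segments$start, ]
  rownames(segments) <- NULL
  structure(list(mirna_id = ps$mirna_id, seq = seq,
                 length = nchar(seq), segments = segments),
            class = "amplicon_model")
}

head_int <- function(x, n) as.integer(utils::head(x, n))

#' @export
print.amplicon_model <- function(x, ...) {
  cat(sprintf("<amplicon_model> %s, %d bp\n  %s\n", x$mirna_id, x$length,
              x$seq))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

# Oriented read + forward-primer position, or NULL. Ambiguous (hits on
# both strands or multiple hits) returns the string "ambiguous".
orient_read <- function(read_seq, forward) {
  hit_f <- gregexpr(forward, read_seq, fixed = TRUE)[[1]]
  hit_f <- hit_f[hit_f > 0]
  rc <- revcomp(read_seq)
  hit_r <- gregexpr(forward, rc, fixed = TRUE)[[1]]
  hit_r <- hit_r[hit_r > 0]
  if (length(hit_f) + length(hit_r) > 1L) return("ambiguous")
  if (length(hit_f) == 1L) list(seq = read_seq, pos = hit_f, strand = "+")
  else if (length(hit_r) == 1L) list(seq = rc, pos = hit_r, strand = "-")
  else NULL
}

#' Classify a sequenced clone read against a stem-loop assay
#'
#' Reads are auto-oriented by locating the forward primer on either strand
#' (ambiguous double hits are labelled `other`). A read is `specific` when,
#' from the forward-primer hit, it reproduces the predicted amplicon layout:
#' correct total span, exact anchor and backbone-span segments (up to
#' `max_mismatch` mismatches in those diagnostic regions) — the gap bases
#' are free, since they are read from the clone, not dictated by the
#' primers. A read containing both primers without the mature context is
#' `primer_only` (the primer-dimer artifact seen in blank controls);
#' anything else is `other`.
#'
#' @param read Clone read ([nuc_seq] or DNA string), either strand.
#' @param ps A `primer_set`.
#' @param b The assay's [stemloop_backbone].
#' @param max_mismatch Mismatches tolerated in the anchor + backbone span
#'   (default 0).
#' @return An object of class `clone_call`: `read_id`, `label`,
#'   `inferred_mature` (RNA string, `specific` reads only), `mismatches`.
#' @export
classify_clone <- function(read, ps, b, max_mismatch = 0L) {
  read <- as_nuc_seq(read, id = "read", alphabet = "DNA")
  stopifnot(inherits(ps, "primer_set"), inherits(b, "stemloop_backbone"))
  call <- function(label, mature = NA_character_, mm = NA_integer_)
    structure(list(read_id = read$id, label = label,
                   inferred_mature = mature, mismatches = mm),
              class = "clone_call")

  o <- orient_read(read$seq, ps$forward)
  if (identical(o, "ambiguous") || is.null(o)) return(call("other"))

  bb_span <- revcomp(substr(b$seq, b$rev_primer_start, nchar(b$seq)))
  amp_len <- nchar(ps$forward) + ps$gap_len + ps$anchor_len + nchar(bb_span)
  rt_anchor <- substr(ps$rt_primer, nchar(ps$rt_primer) - ps$anchor_len + 1L,
                      nchar(ps$rt_primer))
  anchor_dna <- revcomp(rt_anchor)

  if (o$pos + amp_len - 1L <= nchar(o$seq)) {
    cand <- substr(o$seq, o$pos, o$pos + amp_len - 1L)
    gap_lo <- nchar(ps$forward) + 1L
    anc_lo <- gap_lo + ps$gap_len
    bb_lo <- anc_lo + ps$anchor_len
    obs_anchor <- substr(cand, anc_lo, bb_lo - 1L)
    obs_bb <- substr(cand, bb_lo, amp_len)
    mm <- hamming(obs_anchor, anchor_dna) + hamming(obs_bb, bb_span)
    if (mm <= max_mismatch) {
      covered <- substr(ps$forward, nchar(ps$prefix) + 1L, nchar(ps$forward))
      gap <- substr(cand, gap_lo, anc_lo - 1L)
      mature <- dna_to_rna(paste0(covered, gap, anchor_dna))
      return(call("specific", mature = mature, mm = mm))
    }
  }
  # primer-dimer artifact: both primers present, no mature context
  has_rev <- grepl(ps$reverse, o$seq, fixed = TRUE) ||
    grepl(revcomp(ps$reverse), o$seq, fixed = TRUE)
  if (has_rev) call("primer_only") else call("other")
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' @export
print.clone_call <- function(x, ...) {
  cat(sprintf("<clone_call> %s: %s%s\n", x$read_id, x$label,
              if (!is.na(x$inferred_mature))
                sprintf(" (mature %s, %d diagnostic mismatches)",
                        x$inferred_mature, x$mismatches) else ""))
  invisible(x)
}

#' Classify many reads into a calls table
#'
#' @param reads List of [nuc_seq] reads (e.g. from [read_fasta()]).
#' @inheritParams classify_clone
#' @return Data frame `read_id`, `label`, `inferred_mature`, `mismatches`.
#' @export
classify_reads <- function(reads, ps, b, max_mismatch = 0L) {
  if (is_nuc_seq(reads)) reads <- list(reads)
  calls <- lapply(reads, classify_clone, ps = ps, b = b,
                  max_mismatch = max_mismatch)
  data.frame(
    read_id = vapply(calls, `[[`, character(1), "read_id"),
    label = vapply(calls, `[[`, character(1), "label"),
    inferred_mature = vapply(calls, `[[`, character(1), "inferred_mature"),
    mismatches = vapply(calls, `[[`, integer(1), "mismatches"),
    stringsAsFactors = FALSE)
}

#' Reconstruct the cloned mature miRNA from a specific read
#'
#' The mature is rebuilt as forward-covered bases (from the primer design)
#' + gap bases read from the clone + anchor bases implied by the RT primer,
#' and returned as an RNA string of length
#' `cover_len + gap_len + anchor_len`.
#'
#' @inheritParams classify_clone
#' @return RNA string.
#' @export
infer_mature <- function(read, ps, b, max_mismatch = 0L) {
  cc <- classify_clone(read, ps, b, max_mismatch = max_mismatch)
  if (cc$label != "specific")
    stop(sprintf("read '%s' is not a specific amplicon (label: %s)",
                 cc$read_id, cc$label), call. = FALSE)
  cc$inferred_mature
}

#' Locate a mature miRNA within a candidate precursor
#'
#' Exact substring search after RNA normalisation of both sequences. The
#' precursor arm is called `5p` when the match midpoint falls in the first
#' half of the precursor and `3p` otherwise.
#'
#' @param precursor,mature [nuc_seq] records or strings; the precursor must
#'   be longer than the mature.
#' @return List `found` (logical), `start` (1-based, NA when absent),
#'   `arm` (`"5p"`, `"3p"` or `"unknown"`).
#' @export
contains_mature <- function(precursor, mature) {
  precursor <- as_nuc_seq(precursor, id = "precursor")
  mature <- as_nuc_seq(mature, id = "mature")
  p <- dna_to_rna(precursor)$seq
  m <- dna_to_rna(mature)$seq
  if (nchar(p) <= nchar(m))
    stop("precursor must be longer than the mature", call. = FALSE)
  pos <- regexpr(m, p, fixed = TRUE)[1]
  if (pos < 0) return(list(found = FALSE, start = NA_integer_,
                           arm = "unknown"))
  mid <- pos + (nchar(m) - 1) / 2
  arm <- if (mid <= nchar(p) / 2) "5p" else "3p"
  list(found = TRUE, start = as.integer(pos), arm = arm)
}
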