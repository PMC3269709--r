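#' Configuration for the synthetic-data generators
#'
#' One object carries every knob the seeded generators use. Defaults mirror
#' the study conditions the package's worked example emulates: eight
#' developmental stages (egg through adult) with three qPCR replicates,
#' the miR-14 fold-change profile as the default expression pattern, a
#' 0.2-cycle Ct noise standard deviation, and mature miRNA lengths of
#' 18-26 nt.
#'
#' @param seed RNG seed; all generators are deterministic given the config.
#' @param n_mirnas Number of mature miRNAs (pairs in variant modes).
#' @param length_range Mature length range, inclusive.
#' @param variant_mode `"none"`, or emit pairs differing only in the 5'
#'   covered region (`"5prime"`, the variants the assay cannot resolve),
#'   only in the 3' anchor (`"3prime"`), or only in the gap (`"gap_only"`).
#' @param clone_props Named proportions (`specific`, `primer_only`,
#'   `other`) for clone-read mixtures; must sum to 1.
#' @param n_reads Clone reads to generate.
#' @param error_rate Per-base substitution rate applied to clone reads.
#' @param ct_noise_sd Gaussian noise sd (cycles) on Ct values.
#' @param fold_changes Named per-stage true fold changes relative to the
#'   first (calibrator) stage.
#' @param n_replicates qPCR replicates per stage.
#' @param baseline_dct Calibrator-stage dCt (target minus reference Ct).
#' @param ref_ct Mean reference-gene Ct.
#' @param base_probs Base-composition probabilities (A, C, G, U).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_mirnas = 10L,
                           length_range = c(18L, 26L),
                           variant_mode = c("none", "3prime", "5prime",
                                            "gap_only"),
                           clone_props = c(specific = 0.6,
                                           primer_only = 0.3, other = 0.1),
                           n_reads = 30L, error_rate = 0,
                           ct_noise_sd = 0.2,
                           fold_changes = c(egg = 1, L1 = 1.47, L3 = 4.22,
                                            L4 = 3.78, L6 = 2.26,
                                            prepupa = 1.87, pupa = 0.37,
                                            adult = 9.07),
                           n_replicates = 3L, baseline_dct = 8,
                           ref_ct = 15,
                           base_probs = c(A = 0.25, C = 0.25, G = 0.25,
                                          U = 0.25)) {
  variant_mode <- match.arg(variant_mode)
  stopifnot(abs(sum(clone_props) - 1) < 1e-8,
            all(clone_props >= 0), error_rate >= 0, error_rate <= 1,
            length_range[1] <= length_range[2],
            all(fold_changes > 0), abs(sum(base_probs) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
                 length_range = as.integer(length_range),
                 variant_mode = variant_mode, clone_props = clone_props,
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 ct_noise_sd = ct_noise_sd, fold_changes = fold_changes,
                 n_replicates = as.integer(n_replicates),
                 baseline_dct = baseline_dct, ref_ct = ref_ct,
                 base_probs = base_probs),
            class = "fixture_config")
}

rand_bases <- function(n, probs = c(A = .25, C = .25, G = .25, U = .25),
                       alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  bases <- if (alphabet == "RNA") c("A", "C", "G", "U")
           else c("A", "C", "G", "T")
  paste(sample(bases, n, replace = TRUE, prob = unname(probs)),
        collapse = "")
}

mutate_at <- function(seq, pos, alphabet = "RNA") {
  bases <- if (alphabet == "RNA") c("A", "C", "G", "U")
           else c("A", "C", "G", "T")
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(bases, cur), 1L)
  }
  seq
}

#' Generate random mature miRNA sequences
#'
#' Seeded random RNA sequences within the configured length range. In the
#' family-variant modes each miRNA is emitted as a pair (`-a`/`-b` id
#' suffixes) differing at exactly one position in the named region: a 5'
#' covered position (positions 1-3), a 3' anchor position, or a gap
#' position (the gap taken as 2 nt ahead of a 6-nt anchor, matching the
#' cross-reactivity default).
#'
#' @param cfg A [fixture_config].
#' @return Named list of RNA [nuc_seq] records.
#' @export
gen_matures <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed, {
    out <- list()
    for (i in seq_len(cfg$n_mirnas)) {
      len <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
      s <- rand_bases(len, cfg$base_probs)
      if (cfg$variant_mode == "none") {
        id <- sprintf("mir-%03d", i)
        out[[id]] <- nuc_seq(s, id = id)
      } else {
        anchor_lo <- len - 5L          # 6-nt anchor
        gap_lo <- len - 7L             # 2-nt gap ahead of the anchor
        pos <- switch(cfg$variant_mode,
          "5prime" = sample(1:3, 1L),
          "3prime" = sample(anchor_lo:len, 1L),
          "gap_only" = sample(gap_lo:(anchor_lo - 1L), 1L))
        v <- mutate_at(s, pos)
        ida <- sprintf("mir-%03da", i); idb <- sprintf("mir-%03db", i)
        out[[ida]] <- nuc_seq(s, id = ida)
        out[[idb]] <- nuc_seq(v, id = idb)
      }
    }
    out
  })
}

#' Generate a synthetic clone-read pool with truth labels
#'
#' Emulates the sequenced clone pools of a stem-loop RT-PCR experiment: a
#' seeded mixture of specific amplicons (random strand), forward +
#' reverse-primer concatemers (the blank-control artifact, with 0-5 random
#' intervening bases), and random sequences, in the configured proportions,
#' with optional per-base substitution error.
#'
#' @param matures Named list of mature [nuc_seq] records.
#' @param assays Named list of `primer_set` objects matching `matures`.
#' @param b The [stemloop_backbone] the assays were designed on.
#' @param cfg A [fixture_config].
#' @return List with `reads` (list of DNA [nuc_seq]) and `truth` (data
#'   frame `read_id`, `label`, `mirna_id`, `strand`).
#' @export
gen_clone_reads <- function(matures, assays, b, cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"),
            all(names(assays) %in% names(matures)))
  dna_probs <- setNames(unname(cfg$base_probs), c("A", "C", "G", "T"))
  with_seed(cfg$seed, {
    labels <- sample(names(cfg$clone_props), cfg$n_reads, replace = TRUE,
                     prob = cfg$clone_props)
    reads <- list(); truth <- list()
    amp_cache <- lapply(names(assays), function(id)
      predict_amplicon(matures[[id]], assays[[id]], b)$seq)
    names(amp_cache) <- names(assays)
    mean_len <- round(mean(nchar(unlist(amp_cache))))
    for (r in seq_along(labels)) {
      lab <- labels[r]
      mid <- NA_character_
      if (lab == "specific") {
        mid <- sample(names(assays), 1L)
        s <- amp_cache[[mid]]
      } else if (lab == "primer_only") {
        mid <- sample(names(assays), 1L)
        ps <- assays[[mid]]
        filler <- sample(0:5, 1L)
        s <- paste0(ps$forward,
                    if (filler > 0) rand_bases(filler, dna_probs, "DNA")
                    else "",
                    revcomp(ps$reverse))
      } else {
        s <- rand_bases(mean_len, dna_probs, "DNA")
      }
      if (cfg$error_rate > 0) {
        hits <- which(stats::runif(nchar(s)) < cfg$error_rate)
        if (length(hits)) s <- mutate_at(s, hits, alphabet = "DNA")
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") s <- revcomp(s)
      id <- sprintf("clone_%03d", r)
      reads[[id]] <- nuc_seq(s, id = id, alphabet = "DNA")
      truth[[id]] <- data.frame(read_id = id, label = lab, mirna_id = mid,
                                strand = strand, stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = do.call(rbind, c(truth,
                                                 make.row.names = FALSE)))
  })
}

#' Plant a hairpin precursor containing a mature miRNA in random sequence
#'
#' Builds a synthetic genomic fragment: one stem arm containing the mature
#' sequence, a loop, the opposite arm as the reverse complement of the
#' first (with a configurable number of mismatches), padded with random
#' flanks to the requested total length. Defaults mirror an 82-nt
#' precursor inside a 322-nt cloned fragment. Truth coordinates are
#' returned for planted-signal recovery tests.
#'
#' @param mature Mature miRNA ([nuc_seq] or string).
#' @param cfg A [fixture_config] (supplies seed and base composition).
#' @param total_length Fragment length (default 322).
#' @param hairpin_length Planted precursor length (default 82).
#' @param loop_length Terminal loop length (default 8; adjusted by 1 when
#'   needed to keep the arms equal).
#' @param arm_mismatches Substitutions introduced into the far arm.
#' @param mature_arm Arm carrying the mature sequence (`"5p"` or `"3p"`).
#' @param embed Set `FALSE` to generate a fragment without the mature
#'   (negative control).
#' @return List: `source` (RNA [nuc_seq]), `hairpin_start`, `hairpin_end`,
#'   `mature_start` (all 1-based on the source; NA when `embed = FALSE`).
#' @export
gen_precursor_context <- function(mature, cfg = fixture_config(),
                                  total_length = 322L,
                                  hairpin_length = 82L, loop_length = 8L,
                                  arm_mismatches = 0L,
                                  mature_arm = c("5p", "3p"),
                                  embed = TRUE) {
  mature_arm <- match.arg(mature_arm)
  mature <- as_nuc_seq(mature, id = "mature")
  m <- dna_to_rna(mature)$seq
  mlen <- nchar(m)
  arm_len <- (hairpin_length - loop_length) %/% 2L
  loop_length <- hairpin_length - 2L * arm_len
  if (arm_len < mlen)
    stop("hairpin arms shorter than the mature sequence", call. = FALSE)

  with_seed(cfg$seed, {
    if (!embed) {
      src <- rand_bases(total_length, cfg$base_probs)
      # make sure the mature is genuinely absent
      while (grepl(m, src, fixed = TRUE))
        src <- rand_bases(total_length, cfg$base_probs)
      return(list(source = nuc_seq(src, id = "synthetic_fragment"),
                  hairpin_start = NA_integer_, hairpin_end = NA_integer_,
                  mature_start = NA_integer_))
    }
    offset <- sample.int(arm_len - mlen + 1L, 1L)
    near_arm <- paste0(
      if (offset > 1L) rand_bases(offset - 1L, cfg$base_probs) else "",
      m,
      if (arm_len - mlen - offset + 1L > 0L)
        rand_bases(arm_len - mlen - offset + 1L, cfg$base_probs) else "")
    far_arm <- revcomp(near_arm)
    if (arm_mismatches > 0L)
      far_arm <- mutate_at(far_arm,
                           sample.int(arm_len, min(arm_mismatches, arm_len)))
    loop <- rand_bases(loop_length, cfg$base_probs)
    hairpin <- if (mature_arm == "5p") paste0(near_arm, loop, far_arm)
               else paste0(far_arm, loop, near_arm)
    flank_total <- total_length - hairpin_length
    left <- sample.int(flank_total + 1L, 1L) - 1L
    src <- paste0(
      if (left > 0L) rand_bases(left, cfg$base_probs) else "",
      hairpin,
      if (flank_total - left > 0L)
        rand_bases(flank_total - left, cfg$base_probs) else "")
    mature_in_hairpin <- if (mature_arm == "5p") offset
                         else arm_len + loop_length + offset
    list(source = nuc_seq(src, id = "synthetic_fragment"),
         hairpin_start = left + 1L,
         hairpin_end = left + hairpin_length,
         mature_start = left + mature_in_hairpin)
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference-gene Ct is a constant plus Gaussian noise; the target Ct is
#' the (noisy) reference Ct plus the calibrator baseline dCt minus
#' log2(fold change), plus noise. At zero noise [delta_delta_ct()] returns
#' the configured fold-change vector exactly (the generator and analyser
#' are inverse).
#'
#' @param cfg A [fixture_config]; `fold_changes` names the stages and the
#'   first entry is the calibrator.
#' @return Data frame `stage`, `replicate`, `ct_target`, `ct_reference`.
#' @export
gen_ct_table <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  stages <- names(cfg$fold_changes)
  if (is.null(stages))
    stop("fold_changes must be a named vector (names = stage labels)",
         call. = FALSE)
  with_seed(cfg$seed, {
    rows <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        stage = stages, stringsAsFactors = FALSE)
    rows <- rows[order(match(rows$stage, stages), rows$replicate), ]
    ref <- cfg$ref_ct + rnorm(nrow(rows), 0, cfg$ct_noise_sd)
    tgt <- ref + cfg$baseline_dct -
      log2(cfg$fold_changes[rows$stage]) +
      rnorm(nrow(rows), 0, cfg$ct_noise_sd)
    data.frame(stage = rows$stage, replicate = rows$replicate,
               ct_target = unname(tgt), ct_reference = unname(ref),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
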