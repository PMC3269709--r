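# The published primer tables used throughout: six RT primers, six forward
# primers, two universal reverse primers.
paper_rt <- list(
  group1 = c(
    "dme-miR-14" = "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACTAGGAG",
    "dme-miR-2a" = "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACGCTCAT",
    "dme-bantam" = "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACAATCAG"),
  group2 = c(
    "dme-miR-14" = "GCACTTCAGTGTCGTGGTCAGTGACGGCAATTTGAAGTGCTAGGAG",
    "dme-miR-2a" = "GCACTTCAGTGTCGTGGTCAGTGACGGCAATTTGAAGTGCGCTCAT",
    "dme-bantam" = "GCACTTCAGTGTCGTGGTCAGTGACGGCAATTTGAAGTGCAATCAG"))
paper_fwd <- list(
  group1 = c("dme-miR-14" = "CGGGGCTCAGTCTTTTTCT",
             "dme-miR-2a" = "GCCAGTATCACAGCCAGCT",
             "dme-bantam" = "GCCCCGTGAGATCATTTTG"),
  group2 = c("dme-miR-14" = "CGCACGACGCATCAGTCAGTCTTTTTCT",
             "dme-miR-2a" = "CGACACACACCATCAGTATCACAGCCAGCT",
             "dme-bantam" = "CGCATCGTAGCATCGCTGAGATCATTTTG"))

test_that("backbone terminal self-complementarity is computed directly", {
  v2 <- validate_backbone(backbone_preset("group2"))
  expect_equal(v2$k_terminal_complement, 8)   # GCACTTCA / TGAAGTGC
  expect_true(v2$ok)
  expect_equal(v2$reverse_primer, "GCACTTCAGTGTCGTGGTCAGTGACGGCAATT")

  v1 <- validate_backbone(backbone_preset("group1"))
  # the 14-mer prefix GTCGTATCCAGTGC is the revcomp of the 14-mer suffix
  # GCACTGGATACGAC; the terminal stem is 14 bp, not shorter
  expect_equal(v1$k_terminal_complement, 14)
  expect_true(v1$ok)
  expect_equal(v1$reverse_primer, "GTGCAGGGTCCGAGGT")

  noisy <- stemloop_backbone("AAAAAAAAAA", "flat", 1, 4)
  expect_equal(validate_backbone(noisy)$k_terminal_complement, 0)
  expect_false(validate_backbone(noisy)$ok)
  expect_error(stemloop_backbone("ACGTACGT", "oob", 5, 10), "out of")
})

test_that("RT primers reproduce every printed primer from the mature 3' end", {
  matures <- read_fasta(system.file("extdata", "dme_matures.fa",
                                    package = "stemloopr"))
  for (grp in c("group1", "group2")) {
    b <- backbone_preset(grp)
    for (id in names(paper_rt[[grp]])) {
      rt <- design_rt_primer(matures[[id]], b)
      expect_equal(rt, unname(paper_rt[[grp]][id]), info = paste(grp, id))
      expect_equal(nchar(rt), nchar(b$seq) + 6)
    }
  }
  expect_error(design_rt_primer("ACGUAC", backbone_preset("group2")),
               "too short")
})

test_that("forward primers with printed prefixes reproduce the tables", {
  matures <- read_fasta(system.file("extdata", "dme_matures.fa",
                                    package = "stemloopr"))
  pars <- list(
    group1 = list("dme-miR-14" = c("CGGGGC", 13),
                  "dme-miR-2a" = c("GCCAG", 14),
                  "dme-bantam" = c("GCCCCG", 13)),
    group2 = list("dme-miR-14" = c("CGCACGACGCATCAG", 13),
                  "dme-miR-2a" = c("CGACACACACCATCAG", 14),
                  "dme-bantam" = c("CGCATCGTAGCATCGC", 13)))
  for (grp in names(pars)) {
    for (id in names(pars[[grp]])) {
      p <- pars[[grp]][[id]]
      f <- design_forward_primer(
        matures[[id]],
        design_config(cover_len = as.integer(p[2]), prefix = p[1]))
      expect_equal(f$forward, unname(paper_fwd[[grp]][id]),
                   info = paste(grp, id))
    }
  }
})

test_that("zero-gap designs are rejected and auto cover honors the minimum gap", {
  m <- nuc_seq("UCAGUCUUUUUCUCUCUCCUA", id = "m")     # 21 nt
  expect_error(design_forward_primer(
    m, design_config(cover_len = 15, prefix = "CGGGGC")), "gap")
  f <- design_forward_primer(m, design_config(prefix = "CGGGGC"))
  expect_equal(f$cover_len, 21 - 6 - 1)                # largest, gap = 1
})

test_that("auto-prefix search is seeded, in-window and reproducible", {
  m <- nuc_seq("UCAGUCUUUUUCUCUCUCCUA", id = "m")
  b <- backbone_preset("group2")
  cfg <- design_config(seed = 99)
  f1 <- design_forward_primer(m, cfg, b = b)
  f2 <- design_forward_primer(m, cfg, b = b)
  expect_identical(f1, f2)
  expect_gte(nchar(f1$prefix), 4); expect_lte(nchar(f1$prefix), 16)
  tm <- melting_temp(f1$forward)
  expect_gte(tm, cfg$tm_range[1]); expect_lte(tm, cfg$tm_range[2])
  f3 <- design_forward_primer(m, design_config(seed = 100), b = b)
  expect_false(identical(f1$prefix, f3$prefix))
  expect_error(design_forward_primer(
    m, design_config(tm_range = c(20, 22), max_tries = 50), b = b),
    "no prefix")
})

test_that("assembled primer sets satisfy the cover/gap/anchor partition", {
  matures <- read_fasta(system.file("extdata", "dme_matures.fa",
                                    package = "stemloopr"))
  sets <- example_assays("group2")
  expect_equal(vapply(sets, `[[`, numeric(1), "gap_len"),
               c("dme-miR-14" = 2, "dme-miR-2a" = 3, "dme-bantam" = 4))
  # structural invariants over random seeded designs
  rnd <- gen_matures(fixture_config(seed = 21, n_mirnas = 15))
  b <- backbone_preset("group2")
  for (m in rnd) {
    ps <- design_assay(m, b, design_config(prefix = "CGGACGCATCAG"))
    n <- nchar(m$seq)
    expect_equal(ps$cover_len + ps$gap_len + ps$anchor_len, n)
    anchor_dna <- rna_to_dna(substr(m$seq, n - 5, n))
    expect_equal(substr(ps$rt_primer, nchar(ps$rt_primer) - 5,
                        nchar(ps$rt_primer)), revcomp(anchor_dna))
    expect_equal(substr(ps$forward, nchar(ps$prefix) + 1, nchar(ps$forward)),
                 substr(rna_to_dna(m)$seq, 1, ps$cover_len))
  }
  expect_warning(design_assay(nuc_seq("ACGUACGUACGUACG"), b,
                              design_config(prefix = "CGGACG")),
                 "18-26")
})

test_that("cross-reactivity separates anchor sharing from 5'/gap variants", {
  a <- "UGAUUGUCCAAACGCAAUUCUU"
  five <- paste0("A", substr(a, 2, nchar(a)))   # position 1 changed (U->A)
  rep_ <- hexamer_cross_reactivity(list(nuc_seq(a, id = "wt"),
                                        nuc_seq(five, id = "var5")))
  expect_equal(rep_$pairs$relationship, "five_prime_variant")

  dup <- hexamer_cross_reactivity(list(nuc_seq(a, id = "x"),
                                       nuc_seq(a, id = "y")))
  expect_equal(lengths(dup$anchor_groups), setNames(2L, substr(a, 17, 22)))
  expect_equal(dup$pairs$relationship, "identical")

  gapv <- paste0(substr(a, 1, 14), "G", substr(a, 16, nchar(a)))  # gap base
  stopifnot(gapv != a)
  gp <- hexamer_cross_reactivity(list(nuc_seq(a, id = "wt"),
                                      nuc_seq(gapv, id = "vg")))
  expect_equal(gp$pairs$relationship, "gap_variant")

  threev <- paste0(substr(a, 1, 19), "GGG")
  tp <- hexamer_cross_reactivity(list(nuc_seq(a, id = "wt"),
                                      nuc_seq(threev, id = "v3")))
  expect_equal(nrow(tp$pairs), 0)               # different anchors
})

test_that("cross-reactivity groups equal the brute-force all-pairs oracle", {
  set.seed(314)
  seqs <- setNames(replicate(50, random_rna(22)), sprintf("m%02d", 1:50))
  # plant collisions so the report is non-trivial
  seqs[5] <- paste0("AAAA", substr(seqs[1], 5, 22))
  seqs[9] <- seqs[2]
  recs <- lapply(names(seqs), function(id) nuc_seq(seqs[[id]], id = id))
  got <- hexamer_cross_reactivity(recs)$anchor_groups
  ora <- oracle_anchor_groups(seqs)
  expect_equal(lapply(got[order(names(got))], sort),
               ora[order(names(ora))])
})

test_that("melting temperature behaves physically", {
  expect_lt(melting_temp("AAAAAAAAAAAA"), melting_temp("GGGGGGGGGGGG"))
  p <- "CGGGGCTCAGTCTTTTTCT"
  expect_gt(melting_temp(p), 50); expect_lt(melting_temp(p), 65)
  expect_gt(melting_temp(p, primer_conc = 5e-7),
            melting_temp(p, primer_conc = 2.5e-7))
  expect_error(melting_temp("ACGT"), "shorter")
})

test_that("primer-set tables survive a TSV round trip", {
  sets <- example_assays("group2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_primer_sets(sets, path)
  back <- read_primer_sets(path)
  expect_equal(length(back), 3)
  expect_equal(back[[1]]$rt_primer, sets[[1]]$rt_primer)
  expect_equal(back[[2]]$cover_len, sets[[2]]$cover_len)
  b <- backbone_preset("group2")
  expect_equal(predict_amplicon(sets[[3]]$mature, back[[3]], b)$length, 79)
})
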