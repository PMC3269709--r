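# stemloopr

Stem-loop RT-qPCR assay design and analysis for highly conserved
microRNAs — aimed at people cloning and quantifying known miRNAs in
non-model organisms (insect pests and other species without sequenced
genomes), where the practical route is to design assays from the conserved
*D. melanogaster* / *B. mori* mature sequences and verify the products by
cloning, sequencing and precursor screening.

Mature miRNAs (~22 nt) are too short to prime directly. A stem-loop RT
primer solves this: its 3'-terminal **anchor** (6 nt) is complementary to
the miRNA 3' end, while its universal **backbone** folds back on itself
and carries the PCR **reverse-primer** site. The **forward primer** is the
miRNA 5' end plus a non-templated prefix, and the mature sequence is
partitioned as

```
cover_len (forward primer) + gap_len + anchor_len (RT primer) = mature length
```

The uncovered **gap** bases are the diagnostic region: only a genuine
miRNA template supplies them, so sequencing separates real amplicons from
primer dimers. Expression is quantified by the 2^−ΔΔCt method
(ΔCt = Ct_target − Ct_reference; ΔΔCt against a calibrator stage;
RQ = 2^−ΔΔCt), with dilution-series efficiency `E = 10^(−1/slope)` and
Duncan multiple-range letters across developmental stages.

The package covers the full in-silico workflow:

| module | functions |
|---|---|
| sequence primitives | `nuc_seq`, `revcomp`, `rna_to_dna`, `read_fasta`, `global_identity` |
| assay design | `backbone_preset`, `validate_backbone`, `design_assay`, `hexamer_cross_reactivity`, `melting_temp` |
| amplicon simulation | `simulate_cdna`, `predict_amplicon`, `classify_clone`, `infer_mature`, `contains_mature` |
| precursor screening | `fold_maxpair`, `scan_precursors`, `hairpin_stats` |
| qPCR analytics | `fit_standard_curve`, `efficiency`, `delta_delta_ct`, `duncan_grouping` |
| synthetic fixtures | `fixture_config`, `gen_matures`, `gen_clone_reads`, `gen_precursor_context`, `gen_ct_table` |

A thin command-line front end (`exec/stemloop`) wraps the same functions
(`design`, `amplicon`, `classify`, `scan`, `qpcr-rq`, `qpcr-curve`,
`fixtures` subcommands).

## Worked example

```r
library(stemloopr)

matures <- read_fasta(system.file("extdata", "dme_matures.fa",
                                  package = "stemloopr"))
b <- backbone_preset("group2")
ps <- design_assay(matures[["dme-miR-14"]], b,
                   design_config(cover_len = 13, prefix = "CGCACGACGCATCAG"))
ps
#> <primer_set> dme-miR-14 (backbone group2)
#>   RT primer : GCACTTCAGTGTCGTGGTCAGTGACGGCAATTTGAAGTGCTAGGAG
#>   forward   : CGCACGACGCATCAGTCAGTCTTTTTCT (prefix CGCACGACGCATCAG + 13 covered nt, Tm 63.3 C)
#>   reverse   : GCACTTCAGTGTCGTGGTCAGTGACGGCAATT
#>   partition : cover 13 + gap 2 + anchor 6

amp <- predict_amplicon(ps$mature, ps, b)
amp$length
#> [1] 76
```

The 46-nt RT primer is the 40-nt universal backbone plus `TAGGAG`, the
reverse complement of the mature's 3' hexamer `CUCCUA`; the 76-bp
amplicon is forward primer (28) + gap (2) + anchor (6) + backbone
complement (40). The sister assays for dme-miR-2a and dme-bantam predict
79 bp each. Classifying a sequenced clone and recovering the cloned
mature:

```r
call <- classify_clone(nuc_seq(amp$seq, id = "clone_001"), ps, b)
call
#> <clone_call> clone_001: specific (mature UCAGUCUUUUUCUCUCUCCUA, 0 diagnostic mismatches)

efficiency(-3.3125)
#> [1] 2.00395
```

The vignette (`vignettes/stemloop-rt-qpcr.Rmd`) walks through precursor
screening and the ΔΔCt / Duncan analysis on generated data.

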