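---
title: "Designing and analysing stem-loop RT-qPCR assays for conserved miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing stem-loop RT-qPCR assays for conserved miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemloopr)
```

## The assay

Mature miRNAs are ~18–26 nt — too short to prime a conventional RT-PCR.
The stem-loop strategy extends them: a reverse-transcription primer whose
universal portion (the *backbone*) is self-complementary at its termini
folds into a stem-loop, and whose 3'-terminal *anchor* (6 nt by default) is
complementary to the miRNA's 3' end. Reverse transcription yields a cDNA
long enough for PCR with a *forward primer* built from the miRNA 5' end
plus a non-templated prefix, and a universal *reverse primer* that is a
substring of the backbone. The mature sequence is therefore partitioned as

```
cover_len (in forward primer) + gap_len + anchor_len (in RT primer) = mature length
```

The *gap* — bases covered by neither primer — is the assay's diagnostic
region: a primer-dimer artifact can reconstitute both primer sequences,
but only a genuine miRNA template supplies the gap and anchor bases in
between, so sequencing an amplicon distinguishes the two. Because the
forward primer overwrites the template's 5' end during amplification, the
assay reliably reports 3'-end variation (a different 3' hexamer fails to
prime the RT step) but *cannot* detect variants that differ only in the 5'
covered region: `hexamer_cross_reactivity()` flags such pairs as
unresolvable, which is the method's documented limitation for miRNA
families that diverge at their 5' ends (e.g. bantam homologues).

```{r design}
matures <- read_fasta(system.file("extdata", "dme_matures.fa",
                                  package = "stemloopr"))
b <- backbone_preset("group2")
validate_backbone(b)
ps <- design_assay(matures[["dme-miR-14"]], b,
                   design_config(cover_len = 13, prefix = "CGCACGACGCATCAG"))
ps
```

Two published backbones ship as presets. Their terminal self-complement
lengths are computed, not assumed: the 40-nt `group2` backbone pairs over
its terminal 8-mers, and the 44-nt `group1` backbone over its terminal
14-mers. `group2` additionally uses its 32-nt 5' prefix as the reverse
primer, so its amplicons span the entire backbone and the product length
is simply `mature + prefix + backbone` — 76, 79 and 79 bp for the three
example assays:

```{r amplicon}
sets <- example_assays("group2")
vapply(sets, function(ps) predict_amplicon(ps$mature, ps, b)$length,
       numeric(1))
```

### Design parameters

* `anchor_len` (default 6 nt): the published anchor length. Shorter
  anchors prime more promiscuously; longer ones reduce the method's
  tolerance for 3' variation. Parameterised but rarely worth changing.
* `min_gap` (default 1 nt): a zero gap would make a specific amplicon
  indistinguishable from a primer dimer by sequence, so it is rejected.
  The published assays used gaps of 2–4 nt.
* `cover_len` (`"auto"`): the largest cover honouring `min_gap`, i.e. the
  hottest forward primer the partition allows.
* `prefix` (`"auto"`): the published tables never state how prefixes were
  chosen, so the package treats them as free design parameters: a seeded
  random search over 4–16-nt prefixes accepts the first whose full-primer
  nearest-neighbor Tm falls inside `tm_range` (default 55–65 °C,
  bracketing typical annealing temperatures) and whose 3'-terminal 8-mer
  is not complementary to the reverse-primer region. Fixed seed ⇒
  reproducible designs; the printed prefixes can be supplied verbatim to
  reproduce the published primers exactly.
* Melting temperatures use the unified nearest-neighbor parameter set
  with the entropic salt correction, at 250 nM primer and 50 mM
  monovalent salt. These constants matter only for prefix selection, not
  for any reported quantity.

## Clone classification

`predict_amplicon()` returns the product with a segment table (prefix /
covered mature / gap / anchor / backbone span, 1-based inclusive).
`classify_clone()` auto-orients a read by locating the forward primer on
either strand, then requires the anchor and backbone-span segments to
match the design exactly (mismatch tolerance configurable for sequencing
error; gap bases are free by construction). `infer_mature()` reconstructs
the cloned mature miRNA as covered + gap + anchor bases. The round trip
`infer_mature(predict_amplicon(m))` is the identity for every valid
design, which the test suite sweeps over a thousand random assays.

## Hairpin precursor screening

To support a claimed miRNA with a plausible precursor, `scan_precursors()`
slides 70–90-nt windows (the canonical pre-miRNA size range) over every
occurrence of the mature in a genomic or EST fragment and folds each
window. The folding engine is a weighted base-pair maximization dynamic
program (`fold_maxpair()`): GC/AU/GU pairs score 3/2/1 with a minimum
hairpin loop of 3 nt. This is a deliberate design choice over a
thermodynamic free-energy model — the score is exhaustively testable
against structure enumeration, deterministic across platforms, and
sufficient for triaging stem-loops, but it is *not* comparable to mfold or
ViennaRNA free energies, and no free-energy threshold is claimed.
Candidates are ranked by pair score, then paired fraction, with ties
broken toward smaller windows and leftmost starts for reproducibility.
Tie-breaking inside the fold prefers pairing over leaving a base unpaired
and the nearest admissible partner, giving one canonical structure per
sequence.

```{r scan}
cfg <- fixture_config(seed = 7)
m <- gen_matures(fixture_config(seed = 7, n_mirnas = 1))[[1]]
ctx <- gen_precursor_context(m, cfg)
hits <- scan_precursors(ctx$source, m, top_n = 3)
hits[, c("window_start", "window_end", "pair_score", "paired_fraction",
         "mature_paired_fraction", "arm")]
c(planted_start = ctx$hairpin_start, planted_end = ctx$hairpin_end)
```

## qPCR analytics

`fit_standard_curve()` regresses Ct on log10 template concentration over a
dilution series and reports the amplification efficiency
`E = 10^(-1/slope)` (ideal doubling: E = 2 at slope −3.32). Relative
quantification uses the 2^−ΔΔCt method: per-replicate
ΔCt = Ct(target) − Ct(reference gene), per-stage mean ΔCt, ΔΔCt against
the calibrator stage, RQ = 2^−ΔΔCt. Computing RQ from stage-mean ΔCt makes
the calibrator's RQ exactly 1, matching the "fold change relative to eggs"
framing; replicate-level RQs are kept for the standard error. Efficiency
is reported but not folded into RQ by default (the uncorrected method is
standard once E ≈ 2 has been verified); pass `base = E` for an
efficiency-corrected analysis.

Stage letters come from Duncan's multiple range test: one-way ANOVA pooled
error, least significant ranges from studentized-range quantiles at
Duncan's protection levels `(1-α)^(p-1)`, harmonic-mean group size for
unequal replication, and the usual containment rule (ranges inside a
non-significant stretch are not tested). The test runs on replicate-level
ΔCt rather than RQ because variances are far more homogeneous on the log
scale; `duncan_on = "rq"` switches this. With all-zero within-group
variance the procedure degenerates and each distinct mean receives its own
letter.

```{r qpcr}
tab <- gen_ct_table(fixture_config(seed = 42))
delta_delta_ct(tab, calibrator = "egg")
```

## What the synthetic generators emulate — and what they do not

`fixture_config()` fixes the emulated study: eight developmental stages
(egg, L1, L3, L4, L6, prepupa, pupa, adult) with three qPCR replicates and
0.2-cycle Gaussian Ct noise; mature miRNAs of 18–26 nt with uniform base
composition; clone pools mixing specific amplicons (random strand),
forward+reverse primer concatemers and random reads at 60/30/10%; and
precursor fragments of 322 nt carrying an 82-nt planted hairpin. The
default fold-change vector (1, 1.47, 4.22, 3.78, 2.26, 1.87, 0.37, 9.07
relative to eggs) reproduces the expression profile of the package's
worked example. Ct noise enters the generator once per replicate ΔCt (the
target Ct is built on the noisy reference Ct), which is the construction
under which the analyser is the generator's exact inverse at zero noise.

These generators validate the *software*, not the assay chemistry: real
clone reads carry vector sequence, indels and quality-dependent errors;
real precursors have bulged, imperfect stems; real Ct noise is neither
Gaussian nor homoscedastic across stages. Passing the planted-signal and
round-trip suites therefore demonstrates correctness of the
implementation under its stated model, not wet-lab performance.

## Numerical choices and limitations

* Global identity uses Needleman–Wunsch with match +1 / mismatch 0 /
  gap −1 and reports matches over all alignment columns (gap columns
  included), to 0.1%. Published "homology" percentages rarely state their
  denominator; ours is explicit and configurable.
* Fold scores are monotone under sequence extension; window ranking is
  therefore biased toward larger windows unless flank pairing is absent.
  This is intentional: the planted-precursor recovery criterion measures
  overlap with the true hairpin, which larger enclosing windows satisfy.
* The amplicon model is primer-bounded (5' end of forward primer to 5'
  end of reverse primer). Under this convention the Group 2 product sizes
  reproduce the published 76/79/79 bp exactly; the published Group 1
  sizes (86/89/89) are not consistent with any primer-bounded computation
  from the printed Group 1 primers (which give 61/62/63 bp) and are
  likely to include cloning-vector context, so they are not used for
  validation anywhere in the package.
* Duncan's letters depend on `qtukey()`; its quantiles reproduce classic
  5% significant-range tables (2.95 / 3.10 / 3.25 for p = 2, 3, 5 at 20
  df) to two decimals.
* Degenerate (IUPAC) primers, multiple sequence alignment, BLAST-style
  search, thermodynamic folding and melting-curve analysis are out of
  scope.

## Problem sizes used by the test suite

The shipped suite exercises: exhaustive-alignment oracles at lengths ≤ 6;
exhaustive fold enumeration for 200 random sequences of 8–22 nt; a
1000-design amplicon round trip; 120-read clone pools; 100 seeded
planted-hairpin recoveries (322-nt fragments, 70–90-nt windows); and 500
seeded ΔΔCt recovery simulations at 0.2-cycle noise with 3 replicates —
sizes chosen so the full suite runs in minutes on a single core while
leaving every property statistically meaningful.
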