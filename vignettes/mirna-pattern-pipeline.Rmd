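---
title: "Discovering and classifying stress-responsive miRNAs from unreplicated small RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and classifying stress-responsive miRNAs from unreplicated small RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpattern)
```

## The analysis problem

A classic design for probing the small RNA response to an abiotic stress
contrasts two genotypes of one crop species — here a drought-tolerant and a
drought-susceptible wheat cultivar — each sequenced once under well-watered
control and once under dehydration stress (PEG-induced osmotic stress).
That yields four unreplicated small RNA libraries: C1/T1 (genotype 1
control/stress) and C2/T2 (genotype 2). The questions are (i) which known
(conserved) miRNAs respond to the stress in each genotype, (ii) which
genomic loci harbour previously unannotated (novel) miRNAs, (iii) how the
responses compare *between* genotypes, and (iv) which transcripts the
responsive miRNAs are likely to target.

`mirpattern` implements this pipeline end to end on tidy data structures,
plus a synthetic-data generator that emulates the study design with a known
ground truth, so that every stage can be validated quantitatively.

## Pipeline stages and their models

### Preprocessing

Reads are 3'-adapter-trimmed (leftmost full adapter occurrence, or a
terminal adapter prefix of at least 6 bases; adapter-free reads already
within the insert range are kept, since an insert may fill the whole read),
then filtered: any N, more than 20% of bases below Q20, or a length outside
16–30 nt drops the read. "Low quality" is not defined precisely in most
study reports; the N/Q20 rule here is the convention of the FASTX era of
small RNA preprocessing. Surviving reads are collapsed to **unique tags**
with per-library counts — the unit of all downstream work. Conservation
(raw = retained + dropped-by-cause) is enforced by construction and tested.

### Cascade annotation

Tags are annotated by first-match-wins cascade against ordered reference
sets: rRNA > tRNA > snoRNA > snRNA > (optional repeat set) > mature miRNA,
mirroring the usual Rfam-then-miRBase triage. The default match policy is
exact substring containment of the tag (either strand) in a reference
record; a ≤1-mismatch mode exists for small inputs. Exact matching is
deterministic and reproducible, which BLAST-style heuristics are not; for
the synthetic fixtures it is also sufficient, since contaminant reads are
generated as verbatim reference fragments. Anything unannotated is "other"
and feeds novel-miRNA calling.

### Novel miRNA calling

Unannotated 20–24 nt tags are mapped to the genome requiring perfect
matches on either strand. Around each locus (up to 20 per tag, bounding
work on repetitive inputs) two candidate windows are excised — 20 nt
upstream/200 nt downstream and the mirror — so the mature can sit on
either hairpin arm. Candidates are folded with an internal Nussinov-style
**weighted maximum-pairing** dynamic programme (GC = 3, AU = 2, GU = 1,
minimum loop 3, deterministic traceback). A thermodynamic model is not
used: maximum pairing is deterministic, dependency-free, and exactly
checkable against exhaustive enumeration, which the test suite does; the
plant-annotation criteria below are structural, not energetic, so the
substitution is benign at fixture scale.

A call requires, following the community criteria for plant miRNA
annotation: the mature entirely within one stem arm; at most 4 unpaired
mature bases in the miRNA/miRNA* duplex; no asymmetric bulge larger than
2 nt inside the duplex; at least 60% of the hairpin region paired; mature
length 20–24 nt. The star sequence is excised from the partner positions
with the canonical 2-nt 3' overhang. The best passing candidate per
distinct mature (highest paired fraction, ties by window order) is
reported, with loci exportable as GFF3 and structures as dot-bracket text.

### Differential expression

Expression is normalised to **TPM** (tags per million): feature reads
divided by the library's clean-read total, ×10⁶. A library with zero reads
for a feature gets TPM 0.01 by convention (the pseudocount), so log ratios
stay defined; substituted entries are flagged. With one library per
condition there are no biological replicates, so inference rests on the
count model. The default test is the exact Poisson (Audic–Claverie) test:
conditional on the count `x` in a library of total `N1`, the count `y` in
a library of total `N2` follows

$$p(y \mid x) = \frac{(N_2/N_1)^y \, (x+y)!}{x!\, y!\, (1 + N_2/N_1)^{x+y+1}},$$

whose tails are summed term by term in log space; the two-sided p-value
doubles the smaller tail and caps at 1. A generalized chi-square test on
the 2×2 table (feature vs rest of library) is available as an alternative
route (`test = "chisq"`). P-values are adjusted per contrast with
Benjamini–Hochberg, and a miRNA is **screened in** when p < 0.01, FDR
q < 0.01, and the TPM fold change (larger of ratio and inverse) is ≥ 2.

### Cross-genotype pattern classification

For miRNAs screened in at least one genotype, the pair of log2
stress/control ratios (L1, L2) — computed after pseudocount substitution —
is classified with threshold 1: up in both (L1 > 1 and L2 > 1), down in
both, opposite (both magnitudes above 1, opposite signs), or differential
in exactly one genotype. The threshold is strict (|L| = 1 does not
qualify). `summarize_classes()` tabulates the categories; applied to the
46 published conserved log2 pairs of the reference study the rule
reproduces their 14 / 6 / 13 / 13 split, which the test suite asserts.

### Target prediction

Targets are scored with a miRU-style penalty scheme over the first 20
miRNA positions after an optimal gapped antiparallel alignment: mismatch
1, G:U wobble 0.5, gap 2, penalties doubled at miRNA positions 2–13 (the
seed), at most one gap, cutoff E ≤ 3. The named tools additionally use a
partition-function accessibility energy (UPE); that term requires a
thermodynamic ensemble model and is deliberately out of scope — the
parameter is parsed with a warning and ignored. Fully paired central
positions 9–11 flag a site as cleavage-competent rather than
translational.

### qPCR arithmetic

Validation-style relative expression uses 2^−ΔΔCT with technical
replicates averaged before differencing and CTs double-normalised to a
reference gene (18S rRNA by default) and the control condition.
`mirna_target_concordance()` reports the sign of the Pearson correlation
between log2 miRNA and target levels across conditions, flagging
zero-variance inputs.

## The synthetic study and what it does (not) show

`sim_config()` defines the reference fixture: four libraries of 200,000
reads, read length 40 nt with the TruSeq small RNA 3' adapter; insert
lengths 16–30 nt with the mode at 24 nt (the hallmark of plant small RNA
libraries, dominated by 24-nt heterochromatic siRNAs); contaminant shares
rRNA 30% / tRNA 25% / snoRNA 8% / snRNA 3% / unassigned 30%, echoing
published annotation tables; 2% low-quality reads; per-base error rate
0.001. Forty conserved and eight novel miRNAs are planted as genuine
hairpin precursors (stems 60–90 nt, loops 4–8 nt, ≤2 stem mismatches,
mature ≥2 nt from the loop, either strand) in a 100 kb genome; conserved
matures are also placed in the mature reference. Baseline expression is
log-uniform over 40–300 reads per library; non-null miRNAs receive fold
changes of 3, 4 or 6 in the direction(s) their category dictates (the
"opposite" category is down in genotype 1 and up in genotype 2, matching
the tolerant/susceptible asymmetry of the motivating design). Counts are
negative binomial with dispersion 0.002 — essentially Poisson, which is
the sampling model the exact test assumes; larger dispersions are
available to study the test's (lack of) robustness to overdispersion, and
exploring them shows the expected null inflation. All randomness derives
from one root seed through named substreams, so any stage can be
regenerated independently and full runs are byte-identical.

What passing the end-to-end tests shows: the plumbing is lossless (read
conservation, collapse/expand round trips), the annotation cascade and
the caller recover planted structure, and the inference stack recovers
planted fold-change patterns at the study's thresholds with controlled
false discoveries *under the generator's assumptions*. What it does not
show: robustness to real-data features the generator omits — sequencing
error profiles beyond uniform substitution, 5' adapters, isomiR length
heterogeneity, repeat-derived multimapping at genome scale, or biological
overdispersion between true replicates. Conclusions about real libraries
still require the usual caution for unreplicated designs.

## Numerical and design choices

- Problem sizes: unit tests run a 4 × 20,000-read fixture; the end-to-end
  validation runs the full 4 × 200,000-read default once. The exact-test
  oracle grid covers all counts ≤ 50 at two library-size ratios; folding
  and alignment oracles each check 500 random cases.
- Ties in the folder's traceback pair the 5'-most pairable base with its
  3'-most partner; ties in the aligner prefer fewer gaps. Both are
  arbitrary but fixed, making structures and alignments reproducible.
- The hairpin "region" for the 60%-paired criterion is the span of the
  outermost pair enclosing the mature (the candidate window includes
  unrelated flanking sequence that should not dilute the stem statistic).
- Degenerate inputs: empty libraries flow through to a valid empty report
  (library percentages become `NA` rather than raising the
  division-by-zero error the standalone `library_stats()` gives);
  zero-margin 2×2 tables return p = 1 with a degeneracy flag; constant
  qPCR series are flagged rather than correlated.
- TPM and log2 values are computed unrounded and printed at two decimals
  by the table emitters, the convention of the published tables this
  layout mirrors. Published rows whose printed log2 disagrees with their
  printed TPMs by more than one final digit (two rows, evidently
  transcription artefacts in the source tables) are excluded from exact
  recomputation checks but retained, with their printed log2 values, for
  classification.
- The four-way rule needs no expression floor for the
  single-genotype category: exactly one |log2| > 1 suffices, which
  reproduces all published single-genotype rows.

## A worked example

```{r example, eval = FALSE}
library(mirpattern)

# simulate the reference study and run everything
cfg <- pipeline_config(simulation = sim_config(seed = 20140101))
bundle <- run_pipeline(cfg)
bundle
#> small RNA pipeline report
#>   clean reads: 196010/196014/196014/196004
#>   unique tags: 358342
#>   novel miRNA calls: 8
#>   screened DE calls: 50
#>   pattern counts: up_both=8, down_both=5, opposite=8,
#>     genotype1_only=5, genotype2_only=5, unclassified=0

# published conserved-miRNA table: classify and tabulate
tab <- conserved_mirna_table()
summarize_classes(classify_pattern(tab$log2_t1_c1, tab$log2_t2_c2))
#>   up_both 14 | down_both 6 | opposite 13 | one genotype 8 + 5

plot_size_distribution(bundle)
autoplot(bundle$de)
```

(The clean-read and call counts above are from one run of the default
seed; they are regenerated, not stored.)

## Limitations

The maximum-pairing folder over-pairs relative to thermodynamic models,
so hairpin calls on real genomes would need energy-based confirmation;
the exact Poisson test is anti-conservative under biological
overdispersion (by design — it models technical sampling only); exact
substring annotation under-annotates diverged family members that BLAST
would catch; and absolute published totals that depend on the original
sequencing depth, genome snapshot and transcript set (total DE counts,
novel-miRNA and target totals) are not reproducible at this scale and are
not claimed.
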