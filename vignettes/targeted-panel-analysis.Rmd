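---
title: "Somatic variant and copy-number analysis of targeted deep-sequencing panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic variant and copy-number analysis of targeted deep-sequencing panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcall)
```

## Scope and model

`panelcall` analyses very deep targeted-capture sequencing of a gene
panel — the setting of molecular AML diagnostics, where ~5000x depth
over a few dozen genes makes it possible to (i) call somatic point
mutations and small indels in the dominant leukaemic clone against a
control sample, (ii) see subclonal mutations down to a few percent of
reads, (iii) count residual mutant reads in remission marrow, and
(iv) read copy number straight off normalised exon depths.

The caller is a rule-based tumour/control comparison on pileup
evidence, not a probabilistic genotyper. At these depths the binomial
uncertainty on an allele fraction is negligible compared to alignment
artefacts, so the design puts its weight on hard evidence thresholds
and artefact filters rather than on a likelihood model. All rules
operate on *quality-filtered* read counts: a read contributes only if
its base quality exceeds 25 and its mapping quality exceeds 15, both
strictly. Strictness matters at the boundary and is tested there.

### Substitution rules

At a site covered by at least 10 filtered reads in both samples, the
best non-reference allele is a candidate when

* at least 20 tumour reads report it,
* strictly fewer than 5% of control reads report the same allele, and
* the second-best non-reference allele carries **less than** one third
  of the best allele's evidence — a site where a third allele reaches
  one third of the evidence is discarded as a likely alignment trap
  (the one-third rule is inclusive: second-best = best/3 discards).

### Indel rules

Indel identity is exact — kind, inserted/deleted sequence, and
anchoring position must match. A candidate indel needs at least 10
tumour reads, strictly fewer than 5 control reads, and at least 10
times more tumour than control reads (a clean control passes
vacuously). A site whose second most supported indel exceeds 40% of
the best indel's evidence is discarded.

### Clonality, regions, residual disease

Calls above 20% variant allele fraction (strictly) are labelled
`dominant`; everything else `subclonal`. At 5000x the absolute read
floors put the practical subclone detection limit near 0.4% of reads,
i.e. mutations present in roughly 1% of cells. Region labels come
from the panel BED: positions inside exonic target intervals are
`exonic`, positions in captured intronic stretches `intronic`.

Residual-disease mining does not re-call variants: it counts filtered
reads supporting *known* diagnostic variants in a remission sample.
A variant is `detected` at the default settings when at least 5
mutant reads are seen and they make up at least 0.1% of filtered
reads. The 0.1% sensitivity bound is therefore exact at 5000x: 5
reads of 5000. The 5-read floor is this package's
choice — a fraction bound alone would let a single chance read at low
depth count as detection; both knobs are in `caller_config()`.

### A note on self-comparisons

Running the caller with identical tumour and control input returns no
calls *except* in one corner that follows directly from the rules: a
sample carrying at least 20 variant reads at under 5% of reads (a
remission sample with residual disease is the canonical case) passes
both the tumour evidence rule and the control tolerance against
itself. This is exactly why the control tolerances are exposed in
`caller_config()`: when a remission sample must serve as the control,
`max_control_alt_fraction` should be lowered (or the remission sample
pre-screened with `mine_known_variants()`).

## Copy number from read depth

The unit of analysis is the *amalgamated exon*: per gene, all
overlapping annotated exons merged into non-redundant intervals
(`amalgamate_exons()`, 0-based half-open, abutting intervals merge).
The normalised count for sample *s* and exon *e* is

    value(s, e) = mean per-base depth over e / total mapped reads of s x 1e6,

which removes library size and leaves a quantity proportional to DNA
copy number. The pipeline is:

1. **Sample QC** (`qc_samples()`): per gene, each sample's mean
   normalised count is screened across samples with Tukey fences in
   both directions; a sample outlying in more than 3 genes is
   excluded. Degraded DNA distorts capture genome-wide, and a real
   CNV touches one or two genes, so the gene-count criterion
   separates the two cleanly. The "more than 3" threshold is
   configurable.
2. **Per-exon coefficient of variability** (`exon_cv()`): sample
   standard deviation (n-1 denominator) over mean, across retained
   samples. A zero-mean exon gets CV 0 with a warning rather than
   NaN.
3. **Tukey screen** (`tukey_outlier_exons()`): an exon is flagged
   when its CV strictly exceeds Q3 + 1.5 x IQR. Only the upper fence
   is used — unusually *uniform* exons are not a copy-number signal.
   Quartiles use linear interpolation between order statistics
   (`quantile()` type 7); the test oracle implements the same formula
   independently, since quartile conventions differ enough to move
   flags at small n.
4. **Gene flags** (`flag_cnv_genes()`): a gene is reported when at
   least two of its exons are flagged *and* at least one sample's
   fold change against the across-sample median reaches the gain
   ratio (default 1.4) or loss ratio (default 0.7). The defaults sit
   inside the heterozygous expectations (1.5x for a single-copy
   gain, 0.5x for a loss) with a noise margin; they are deliberately
   insensitive to sub-0.3-copy events. Genes flagged on fewer than 3
   exons raise a warning: without flanking coverage such calls are
   weak, a known limitation of exon-only capture designs.
5. **Duplication segments** (`detect_duplication_segment()`): within
   a gene, the maximal run of at least 2 consecutive exons elevated
   at or above the gain ratio — the depth signature of a partial
   tandem duplication such as MLL exons 2–9. Single-exon events are
   below this detector's design resolution.

X-linked genes are handled separately. In a mixed-sex cohort their
exon CVs are always elevated (two copies in females, one in males),
which is dosage, not a somatic event; they are passed to
`flag_cnv_genes(exclude = ...)` and assessed instead with
`sex_linked_ratio()`, whose expectation is 2.0 for X-linked genes and
1.0 for autosomes. That the observed ratios land there is itself the
positive control that normalised depth tracks copy number.

Suspected losses can be verified orthogonally with
`allelic_imbalance()` on allele-specific read counts at SNPs inside
the locus. A SNP is *informative* when the comparator minor-allele
fraction lies in [0.3, 0.7]; an informative SNP is *imbalanced* when
the tumour allele fraction shifts by at least 0.15 and a two-sided
Fisher exact test on the 2x2 allele-count table rejects at 0.05. The
locus verdict is `deletion-consistent` with at least two imbalanced
informative SNPs, `suggestive` with one. Because panel SNPs are
unphased, "consistent direction" across SNPs cannot mean a shared
haplotype: each SNP is required to show preferential reduction of one
of its own alleles, and the per-SNP direction is reported for manual
review. The statistic (fraction shift + exact test) is this package's
choice; the qualitative criterion it operationalises is preferential
reduction of one allele relative to the comparator.

## The synthetic cohort

`build_default_spec()` defines a deterministic study cohort on a
fictitious genome (one contig per gene, 150 bp exons every 500 bp):
34 genes, ten samples (seven diagnostic AMLs P1–P7, two remission
samples, one relapse), sequenced to 5000x. It plants:

* the dominant-clone catalogue — 20 exonic events (11 substitutions,
  9 indels, per-sample counts 3,3,4,2,3,3,2) plus one intronic NF1
  event — at 45% VAF, a typical heterozygous mutation at high blast
  fraction;
* subclonal substitutions at 4.4% and 4.1% of reads in P5 and 3.0%
  in P4, and an 8% frameshift in the relapse sample;
* residual disease in P2CR: P2's three exonic mutations at 1.5%,
  2.0% and 2.4% of reads; P1CR is clean and serves as the cohort
  control;
* copy events in the count matrix: CYP2D6 loss in P3 (a germline-type
  CNV — the detector does not distinguish germline from somatic),
  PTEN loss in P2 and P6, MLL exons 2–9 gained 1.5x in P6;
* one QC-fail sample (P5's matrix rows) whose per-gene means are
  distorted by lognormal factors with sd 0.6 on the log2 scale,
  emulating degraded input DNA.

`generate_pileups()` writes extended pileup text (deterministic mode:
exactly `round(vaf x depth)` mutant reads; sampled mode: Poisson
depth, binomial mutant reads under a seed). Planted reads carry base
quality 35 and mapping quality 60 so the quality filters are never
the variable under test unless a fixture degrades them on purpose.
Indel plants put the observation on the anchoring position only.

`generate_count_matrix()` simulates normalised counts directly: a
shared lognormal per-exon capture factor (sdlog 0.2) around 5000x,
Poisson counting noise, per-sample library factors (uniform
0.8–1.2x, cancelling in expectation after normalisation), and a
bounded per-sample-per-gene capture-efficiency factor, uniform within
±5%. The bounded factor is the dominant between-sample noise: in
well-behaved capture data, sample-to-sample differences in capture
efficiency per region far exceed counting noise but stay within a few
percent, and a bounded distribution reproduces the observed cohort
behaviour that sound samples are gene-level Tukey outliers in at most
a handful of genes. Under pure Poisson noise the QC screen's fences
shrink to a fraction of a percent and chance flags accumulate —
unrealistic for capture data and at odds with how such cohorts behave.

What the generator does **not** emulate: sequencing-error noise
bases, strand bias, GC-dependent capture bias, mapping artefacts,
duplicate reads, and FLT3-ITD-style complex events (internal tandem
duplications surface in real data as a mess of indel and substitution
evidence; here indels are planted as clean single events). Passing
tests therefore demonstrate that the *rules* are implemented exactly
and behave as designed under the stated noise — not that the caller's
error rates on real libraries are reproduced.

## Numerical choices and problem sizes

* All inequalities are implemented with the stated strictness
  (">" vs ">=") and each has an on/off boundary test pair.
* Quartiles: type 7. Ties in Tukey screening need no tie-break
  because the fence comparison is strict.
* Degenerate inputs: empty BED, empty overlap between pileups, under
  4 samples for QC, under 3 retained samples for CV, and under 3
  exons for duplication detection are errors; zero-mean exons warn.
* Indels are written to VCF left-anchored on the preceding reference
  base; no further normalisation is attempted.
* The test suite runs the full deterministic cohort (7 tumours x ~80
  sites at 5000x), 25 seeded count-matrix replicates for the sex
  ratio, 1000 random CV vectors against the quantile oracle, and 100
  random sites against a per-read recount oracle; the whole suite
  completes in under a minute on one core.
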