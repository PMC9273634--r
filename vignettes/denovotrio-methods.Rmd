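---
title: "Trio de novo mutation discovery: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio de novo mutation discovery: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovotrio)
```

## The problem

Most nonsyndromic cleft lip with or without cleft palate (nsCL/P) cases are
sporadic, which makes de novo mutations (DNMs) — variants present in an
affected child but absent from both unaffected parents — a natural place to
look for high-impact risk alleles. `denovotrio` implements the analysis
stack for a case-parent trio whole-genome design: cohort quality control,
a staged variant filtration funnel ending in a table of high-confidence
protein-altering DNMs, pathogenicity binning, a folding-stability
classification for candidate missense variants, gene-set enrichment, and
craniofacial expression summaries. Because real trio genomes of this kind
sit under controlled access, the package also ships a synthetic-cohort
generator with a planted-truth ledger, so that every stage is exercised
end-to-end by code anyone can run.

## Quality control

Each trio member is evaluated per sample, and a trio is retained only when
all three members pass every rule (one failing parent discards the whole
trio). All thresholds are strict inequalities and are user-visible in
`qc_thresholds()`:

* **Missingness** — fraction of missing genotypes; excluded when > 0.10.
* **Sex check** — the X-chromosome inbreeding coefficient
  $F = (O_{hom} - E_{hom}) / (N - E_{hom})$ with
  $E_{hom} = \sum_s (1 - 2p_s(1-p_s))$. Hemizygous males (emitted as
  homozygous diploid X calls, the common VCF dialect) push $F \to 1$;
  diploid females $F \to 0$. We infer male above 0.8, female below 0.2, and
  treat the ambiguous middle as a mismatch. X allele frequencies are
  estimated from the pedigree mothers.
* **Hardy–Weinberg** — the exact conditional test (summing the
  probabilities of all heterozygote counts no more probable than the
  observed one, given the allele counts) computed on founders. Sites with
  p < 1e-6 are removed cohort-wide from all downstream analyses. Whether
  the original screen removed sites or samples is ambiguous; we chose
  sites, because HWE is a property of a site, and exposed the
  interpretation as the `hwe_on` knob.
* **Mendelian errors** — per-trio counts of transmission-impossible
  genotype configurations (over sites where all three members are called
  with GQ ≥ 20), excluded when outside 3 SD of the cohort mean.
* **Het/hom ratio** — heterozygous over non-reference-homozygous calls per
  sample, excluded beyond 4 SD of the cohort mean.
* **Relatedness** — a KING-style within-pair method-of-moments kinship
  $\varphi = (N_{Aa,Aa} - 2N_{AA,aa})/(N_{Aa}^{(i)} + N_{Aa}^{(j)})$,
  with each parent–child pair required to fall in the parent-offspring
  window [0.15, 0.35]. The source protocol does not name its statistic or
  window, so this concrete contract is our choice.

The SD-based rules use mean/SD computed once on the full pre-exclusion
cohort (a single screening round); `apply_qc()` accepts previously computed
cohort statistics so that re-screening retained trios is idempotent.

## The filtration funnel

`discover_dnms()` applies, in order: **quality** (GQ ≥ 20 and DP ≥ 10 in
all three members — both bounds inclusive), **de novo configuration**
(parents 0/0, child heterozygous; a hemizygous-alternate male child on
chrX also qualifies; autosomal child 1/1 with hom-ref parents is rejected
as an implausible double hit but counted in a diagnostics channel),
**protein-altering consequence** (protein-truncating or missense), and
**rare** (maximum allele frequency across all loaded panels ≤ 0.01;
inclusive, with a strict-`<` flag, since the study states the threshold
both ways; a variant absent from every panel counts as frequency 0).
Per-stage retained counts form a monotone funnel.

Consequence calling is against explicit transcript models on a reference
genome: codon-level comparison for SNVs (stop gained, start lost — any
change to the unique ATG initiator codon, missense, synonymous), canonical
±1/2 intronic positions for splice donor/acceptor, and indel length mod 3
for frameshifts. Deeper splice-region variants deliberately classify as
intronic: only canonical sites are treated as protein-truncating. A variant
hitting several transcripts takes the single most severe consequence
(severity order stop_gained > frameshift > canonical splice > start_lost >
missense > synonymous > intron > other; ties broken by lowest transcript
id) so that one DNM yields one deterministic table row. Indel alleles are
normalized (shared suffix then prefix trimmed) before frequency and score
lookups; the generator and all packaged fixtures emit left-aligned alleles,
so no reference-based realignment is performed.

## Prioritization, stability, enrichment

CADD bins come from the phred definition itself
($C = -10\log_{10}(\text{rank fraction})$, so ≥ 30/20/10 mean top
0.1%/1%/10%) rather than a shipped genome-wide score file. SIFT < 0.05 is
deleterious; PolyPhen-2 uses the HumDiv cutoffs 0.446/0.85 (the tool's
model variant is unstated in the source; both cutoffs are knobs). Scores
are undefined for protein-truncating variants and propagate as NA.
A DNM is *prioritized* iff its gene carries any craniofacial evidence
(mouse-knockout phenotype — cleft, other craniofacial, or embryonic
lethal —, a CNV report, or an SNV report) in the evidence table, which
replaces live database mining with a curated file.

The stability layer is deliberately thin: per-replicate
$\Delta\Delta G = \Delta G_{folded} - \Delta G_{unfolded}$ (kcal/mol),
summarized as mean ± sample SD; destabilizing iff mean > 0 and
disease-likely iff mean strictly > 1 kcal/mol. The structure prediction
and free-energy simulation that produce the replicate values are upstream
and out of scope. The packaged replicate table
(`shh_ddg_replicates_synthetic.tsv`) is a synthetic stand-in whose three
replicates reproduce the published mean ± SD exactly, since per-replicate
outputs are not published.

Enrichment is a one-sided hypergeometric upper tail, with the optional
EASE variant (tail evaluated at k − 1, the conservative modified Fisher
statistic popularized by DAVID — always ≥ the Fisher p). Nominal p < 0.05
with no multiplicity correction is the default, mirroring the source
analysis; Benjamini–Hochberg is available behind a flag. The background
size defaults to the number of genes carrying any annotation in the loaded
sets, and is an explicit parameter because web-service backgrounds are not
reproducible offline. Expression contrasts use an ε = 1 intensity
pseudo-count ((A+1)/(B+1)) against zero fluorescence floors, with strict
ratio > 1 as "elevated"; heat values are row-wise min-max scaled with
constant rows mapped to 0.5.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` builds 150 case-parent trios: 3000 shared autosomal
background sites in Hardy–Weinberg equilibrium (allele frequencies ~
U(0.05, 0.5)) with child genotypes formed by biparental transmission, 800
common chrX sites encoding sex through hemizygosity, two planted
HWE-violating sites, Poisson(1.2) planted protein-altering DNMs per clean
case in a 94% missense / 6% protein-truncating mix, decoy variants that
each violate exactly one funnel filter (low GQ, low DP, inherited, common
MAF, noncoding, missing parent genotype), and 20 trios violating exactly
one QC rule each (8 missingness, 4 sex mismatch, 4 relatedness, 4
Mendelian excess). The mini-genome is 23 contigs of 100 kb carrying 24
all-coding transcript models on both strands (one with 45 exons and 4800
codons, so deep-exon truncating variants exist). Everything is
reproducible from (spec, seed), and every planted object is recorded in a
truth ledger that the tests compare against.

Two generator defaults deserve justification because the QC thresholds are
fixed by the study and the null must be "well behaved" under them:

* **800 X sites at frequency U(0.2, 0.5)** keep the sampling SD of the
  X-inbreeding F around 0.04, far from the 0.2/0.8 sex cutoffs. With
  sparser or rarer markers, clean females drift past F = 0.2 and trios are
  lost to the sex check for no biological reason.
* **3000 autosomal sites** keep the het/hom ratio's counting noise close
  to normal. The ratio's denominator is the non-reference homozygote count
  (~280 at 3000 sites), whose finite-sample skew inflates the 4 SD rule's
  false-positive rate (measured per-cohort false-exclusion probability:
  ~23% at 1200 sites, ~13% at 3000, ~5% at 6000, against the ~3% floor
  that max|z| over 450 samples has even under a perfect normal null). At
  desk scale the residual risk cannot be driven to zero — in real WGS the
  statistic is averaged over millions of sites and its spread is dominated
  by genuine between-sample heterogeneity. Consequently, at an arbitrary
  simulation seed the screen may exclude one extra clean trio with roughly
  10% probability; the packaged default cohort (seed 1) retains exactly
  130 of 150 with exactly the 20 planted reason codes.

The relatedness failure is planted as a **duplicate-sample anomaly** (the
father's autosomal genotypes replaced by a copy of the child's, X left
untouched): father-child kinship ≈ 0.5 falls outside the parent-offspring
window, and — unlike an unrelated-father swap, which scatters
opposite-homozygote Mendelian errors — a duplicated child provably
introduces no new Mendelian inconsistencies, so the trio fails only the
targeted rule.

The generator does **not** emulate read-level data (no FASTQ/BAM, so no
allele-balance filters), linkage disequilibrium, population stratification
(the source study's PCA ancestry check is out of scope), recurrent
mutation, or genotyping-error processes beyond the planted classes. A
green planted-truth recovery test therefore establishes that the filter
logic is faithful to its contracts — not that the pipeline's operating
characteristics on real sequencing artifacts are known.

## Numerical and degenerate-input choices

* The HWE exact test compares probabilities with a 1 + 1e-12 relative
  guard so ties in floating point match the enumeration definition.
* A sample with heterozygous calls but zero non-reference homozygotes gets
  ratio `Inf`: it is flagged extreme by the SD rule, never a crash.
* Monomorphic sites return HWE p = 1 (a single attainable configuration).
* Multi-allelic VCF rows decompose into one record per alternate allele,
  with other-alt alleles recoded to reference (the `bcftools norm -m-`
  convention), conserving the total ALT count.
* chrY and mitochondrial records are skipped with a counter; chr1–chr22
  and chrX are processed.
* Genotypes are treated as unordered; phase is ignored throughout.
* ΔΔG exactly 1.0 kcal/mol is *not* disease-likely, and mean exactly 0 is
  *not* destabilizing (strict inequalities as published).
* Funnel counts are validated to be monotone non-increasing at
  construction time.

## Known limitations

* The funnel's intermediate counts are validated against planted truth,
  not against the study's own intermediate numbers, which are not legible
  in the source figure.
* X-chromosome DNM calling assumes the hemizygous-male-as-diploid VCF
  dialect; other encodings (explicit haploid GT) are normalized at read
  time but not otherwise modeled.
* In-frame indels fall outside the consequence vocabulary and classify as
  `other`; the generator does not plant them.
* The enrichment background at default is the annotated-gene count of the
  loaded collection, which is smaller and cleaner than any web-service
  background; absolute p-values are therefore not comparable to DAVID's,
  only the machinery is.
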