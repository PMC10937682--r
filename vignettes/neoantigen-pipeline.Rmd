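---
title: "From somatic variants to a neoantigen catalog: methods and design notes"
author: "neoforge developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From somatic variants to a neoantigen catalog: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoforge)
```

## Scope and model

`neoforge` implements the computational cascade used to catalogue MHC
class I neoantigens in a pair of tumour cell lines — a parental line and
a hypermutated derivative — and the cohort statistics used to relate
dendritic-cell and effector T-cell gene signatures to tumour mutational
burden and overall survival. Upstream read alignment and raw mutational
calling are out of scope: the pipeline starts from variant call sets
(VCF with per-sample allelic depths), transcript models (GTF CDS
features plus reference FASTA), RNA-seq variant calls and gene-level
expression (TPM).

The cascade is, in order:

1. **Germline subtraction.** A tumour variant is removed if the matched
   normal contains an *allele-exact* `(chrom, pos, ref, alt)` match.
   Position-only matching was rejected because it would delete genuine
   somatic alleles at polymorphic sites.
2. **WES support.** Keep variants with `alt_reads >= 5` (inclusive —
   "5 or more"). The altered-read count is taken from the `AD` FORMAT
   field, the standard carrier of per-allele depths; a VCF without `AD`
   is an error rather than a guess.
3. **Peptide enumeration.** Each variant is mapped into CDS coordinates
   (minus-strand alleles reverse-complemented), the coding sequence is
   edited, and the mutant protein translated. All windows of length
   8–11 that contain at least one mutated residue and do not occur in
   the transcript's wild-type protein are candidate neoepitopes.
4. **Strong binders.** Candidates are scored per allele; a peptide
   passes if *any* allele gives `%rank <= 0.5` (inclusive), and the
   best (minimum-rank) allele is reported.
5. **RNA validation.** A WES-passed variant survives only if the same
   allele appears in the RNA-seq calls with `alt_reads >= 3`
   (inclusive). The join is anchored on the WES set; RNA-only variants
   are never emitted.
6. **TPM attachment and classification.** Gene-level TPM is attached
   (genes absent from the table get 0 with a warning), and the two
   per-line catalogs are compared: shared = intersection, unique = set
   differences, *keyed on peptide sequence* — identical peptides from
   different genomic events are immunologically one entity. Whether the
   original counts were keyed on peptides or variants is not
   determinable; peptide keying is this package's documented choice.

## Variant application semantics

* **SNV**: codon-aware substitution. Synonymous changes yield an empty
  mutated span (no peptides). A stop-gain truncates the protein and
  also yields no peptides — there are no novel residues.
* **In-frame indel** (length difference divisible by 3): the mutated
  span covers the altered residue run under a longest common
  prefix/suffix alignment. A clean deletion that changes no residue is
  assigned the two junction residues, since novel junction-spanning
  peptides can still arise. If the indel introduces a premature stop,
  suffix alignment is disabled (the wild-type C-terminus is lost) and
  the span runs from the first changed residue to the new C-terminus.
* **Frameshift**: translation continues past the original coding frame
  directly into the stored downstream UTR sequence until the first stop
  codon; if none occurs, translation runs to the end of the sequence
  with a warning. The span runs from the codon containing the first
  changed nucleotide to the C-terminus.
* The transcript model stores the CDS (ATG start, no in-frame stop,
  stop codon excluded) and the downstream sequence as directly
  adjacent strings; frameshift read-through concatenates them. A
  consequence of this contract is that the stop codon itself is not
  addressable, so stop-loss SNVs cannot be expressed in this model;
  they would require annotating the stop codon explicitly.
* Variants spanning a CDS boundary, and ref alleles that disagree with
  the transcript sequence, are hard errors. Variants outside every CDS
  are skipped with a log message. Ambiguity codes (N) inside a consumed
  codon are errors, never guessed residues.
* Wild-type subtraction defaults to the same transcript's protein; the
  `wt_extra` argument widens it to any additional protein set (e.g. a
  whole proteome). The default matches the per-gene neoantigen
  definition and keeps results deterministic and fast.
* Duplicate peptide sequences from one variant are deduplicated keeping
  the smallest window start; the same sequence arising from different
  variants is collapsed at catalog level (one record per peptide per
  line, first provenance kept after a deterministic sort, others
  logged).

## Binding predictions

Real predictions come from NetMHC-style whitespace tables
(`parse_netmhc_table()`, accepting both the NetMHC 4.0 and netMHCpan
4.0 header spellings — published methods sections cite both, and the
two cannot be distinguished after the fact). Allele spellings are
normalized (`H-2-Kb`, `h2kb` → `H2-Kb`).

The built-in toy predictor is a *deliberately non-biological* pure
function used so the pipeline is fully testable without external
software: H2-K<sup>b</sup> "anchors" are F/Y at position 5 and L/M/I/V
at the C-terminus; H2-D<sup>b</sup> requires N at position 5 and
M/I/L/V at the C-terminus; 2, 1 or 0 matched anchors map to ranks 0.1,
1.0, 50 and IC50 50, 500, 5000 nM. With the default 0.5 cutoff, only
two-anchor peptides pass.

## The synthetic world

The generator module emulates the statistical structure of the study's
inputs so no download is required. Its defaults are fixed once and are
not tuned to test outcomes:

* **Transcriptome**: one transcript per gene on its own contig, CDS
  lengths 150–300 nt, 60 nt random 3' UTR terminated by stop codons in
  all three frames (so frameshift read-through always ends inside the
  transcript), alternating strands, and every other transcript split
  into two CDS exons to exercise splicing.
* **Variants**: planted per consequence class (missense, synonymous,
  frameshift indels of 1–2 nt, in-frame 3 nt indels, germline SNVs).
  Line B carries all of line A's somatic variants plus extra, mirroring
  a derivative clone. WES altered reads are Poisson(mean 20); because
  recovery criteria require planted designs to pass the >= 5 filter
  *deterministically*, counts are floored at 5 unless a configurable
  fraction is explicitly forced to 0–4 to exercise the boundary
  (Poisson(20) falls below 5 with probability ~1e-5, which would make
  exact-recovery tests flaky at no informational gain). The same logic
  applies to RNA support (Binomial(depth 100, VAF 0.5), floored at 3,
  with a forceable 1–2-read subset). VAF is fixed at 0.5 (clonal
  heterozygous); only the thresholds, not read-level error models, are
  the object of study.
* **Guaranteed strong binders**: for Venn-recovery designs the
  transcriptome is restricted to residues that match no toy-predictor
  anchor, and each design variant inserts 27 nt encoding a distinct
  9-mer with F at position 5 and L at the C-terminus. In that world,
  a window can only place an anchor residue at position 5 *and* at its
  C-terminus if it is exactly the inserted 9-mer (the two anchors sit
  4 residues apart, forcing window length 9 and a unique alignment), so
  each design variant contributes exactly one strong binder — the Venn
  counts equal the planted counts by construction, not by calibration.
* **Ground truth**: expected peptides are computed at generation time
  by a deliberately naive, self-contained oracle (plain string edit,
  hard-coded codon table, exhaustive substring enumeration, wild-type
  subtraction) kept in its own file and never calling pipeline code.
  The central acceptance property is set-equality between pipeline and
  oracle over 100+ seeded datasets.
* **Cohort**: a latent factor `f ~ N(0,1)` per sample; each signature
  gene is `beta * f + N(0,1)`, re-standardized per gene to cohort
  z-scores; TMB is log-normal and independent of `f`; survival is
  exponential with the baseline hazard (median 50 months) multiplied by
  `hr` for the `f < 0` group, under independent uniform censoring on
  [0, 120] months. With `beta = 1`, `hr = 2`, `n = 500` the planted
  coupling and survival split are comfortably detectable; with
  `beta = 0`, `hr = 1` the analysis pipeline must hold its nominal 5%
  false-positive rate.

What the generator does **not** emulate: read-level sequencing error,
mutational signatures of mismatch-repair deficiency, subclonal
structure, isoform-level expression, linkage between TMB and the latent
factor, or non-exponential hazards. A green test therefore establishes
the correctness of the cascade's logic and statistics on data obeying
the stated model — not concordance with any particular sequencing
experiment.

## Numerical conventions

* **Median split**: `high` means strictly above the median; ties go to
  `low`. **Quartiles**: linear-interpolation quantiles (R type 7);
  bottom/top membership is inclusive at the boundary. Both conventions
  are stated because the original group sizes are not reproducible
  without knowing the exact convention used upstream.
* **Pearson p-value**: exact t transform with n − 2 df, two-tailed —
  not a normal approximation.
* **Log-rank**: the one-degree-of-freedom Mantel–Cox statistic with the
  standard hypergeometric variance at tied event times; a zero variance
  (e.g. identical groups) returns chi2 = 0, p = 1 rather than NaN.
* **Kaplan–Meier**: product-limit with right censoring; censored
  subjects at an event time remain at risk for that time (`time >= t`).
* No multiple-testing correction is applied anywhere, matching the
  analyses this mirrors.
* All writers format numbers deterministically (15 significant digits,
  no scientific notation) and sort rows on explicit keys, so identical
  inputs give byte-identical outputs; every generator is a pure
  function of its seed.

## Open design points and limitations

* Multi-allelic VCF records are rejected with instructions to decompose
  rather than silently split — germline matching must stay
  allele-exact. Indels must be left-aligned and anchored on a shared
  first base (standard VCF); no re-normalization is attempted.
* GTF only (`key "value";` attributes); GFF3 is not supported.
* Whether the RNA threshold should be applied per replicate or pooled
  is not determinable from the methods this follows; it is applied per
  provided VCF.
* The toy predictor's ranks are three discrete values; thresholds
  strictly between 0.1 and 1.0 therefore all behave like 0.5. Tests of
  rank-threshold monotonicity use 0.1 and 2.0 as the informative
  settings.
* The cohort-statistics functions operate on whatever value matrix they
  are given; applying `signature_score()` to single-cell normalized
  expression reproduces the per-cell mean-expression signature scores
  used for violin plots.
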