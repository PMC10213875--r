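---
title: "Methods: sperm/serum sncRNA annotation and transgenerational differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sperm/serum sncRNA annotation and transgenerational differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sncTrans reimplements, as a tested pipeline over synthetic data with
known truth, a small-non-coding-RNA (sncRNA) analysis of the kind used
to study transgenerational epigenetic inheritance through the male
germline: sperm sncRNA profiles of exposed mouse lineages followed
over three generations, compared against a human serum cohort. This
vignette describes the models and procedures, the parameters that
matter, the synthetic-data generator, and the design decisions taken
where the method left room.

## Read QC

Single-end small-RNA reads carry the insert followed by the 3'
sequencing adaptor (default `AGATCGGAAGAGCACACGTCTGAACTCCAGTCA`).
`trim_adaptor()` removes, per read, the leftmost occurrence of an
adaptor *prefix*: at a candidate position the first
`min(adaptor length, bases remaining)` adaptor bases are compared, and
the occurrence is accepted when the overlap is at least `min_overlap`
(default 3 nt) with at most `floor(error_rate * overlap)` mismatches
(default `error_rate = 0.1`). These are the trimming semantics of the
standard adaptor trimmers; since only the tool and the adaptor are
fixed by the protocol we pin the dialect here and expose both knobs in
`qc_config()`. A read whose adaptor starts at position one keeps an
empty insert and is discarded as too short.

`filter_reads()` retains a read iff (i) an adaptor occurrence was
found — absence of the adaptor means the insert ran past the read and
its true 3' end is unknown; (ii) the insert is 15–45 nt (inclusive);
and (iii) at least 80% of insert bases have Phred quality strictly
above Q20 (a base at exactly Q20 does not count). Quality encoding is
Phred+33 by default with a `phred_offset = 64` escape hatch for legacy
data.

## Reference preprocessing and the annotation index

References are normalized to the uppercase DNA alphabet at load time
(U→T), because public small-RNA databases mix RNA and DNA alphabets;
matching then happens in a single alphabet. tRNA genes are turned into
the mature sequences that tRNA-derived fragments actually come from:
predicted introns are spliced out, the post-transcriptionally added
3' `CCA` is appended, and histidine tRNAs receive the extra 5' `G`.
Sequences containing `N` never match anything (conservative). Biotype
databases are indexed sense-strand only — they store mature sense
sequences — while the genome presence check used during rescue
searches both strands, mirroring strand-agnostic genome mapping.

## Hierarchical annotation

Distinct retained sequences (annotation operates on distinct
sequences, not reads) are matched end-to-end as Hamming-distance
substrings of the references: no indels, because at an edit budget of
one an indel alignment would blur the positional tsRNA subtype
boundaries that the classification depends on.

The cascade queries the biotype databases sequentially — miRNA, rRNA,
tRNA, piRNA, other ncRNA — at **zero** mismatches; the first biotype
with a hit wins and later databases are never consulted. A zero
mismatch budget at this stage trades a known information leak (RNA
base modifications read out as mismatches) for mapping accuracy. Hits
on rRNA become **rsRNA**, hits on tRNA become **tsRNA**.

*rsRNA parent assignment.* rRNA databases are internally redundant:
18S, 5.8S and 28S are contained verbatim in the 45S precursor. To
avoid double counting, a fragment hitting several rRNA species is
credited to the smallest Svedberg class under the fixed order
4.5S < 5S < 5.8S < 12S < 16S < 18S < 28S < 45S; within a class the
lexicographically smallest reference id is the primary parent.

*tsRNA subtypes.* On the processed (CCA-tailed) tRNA, a fragment
starting at base 1 is `tsRNA_5p`; ending at the final base,
`tsRNA_3p_CCA`; ending exactly three bases before the final base
(abutting but excluding the CCA), `tsRNA_3p`; anything else,
`tsRNA_internal`. When one hit satisfies several definitions (short
parents) or multiple parents disagree, the precedence
5p > 3p_CCA > 3p > internal applies. The subtype boundary tolerance is
zero bases; this is exposed in code should a sensitivity analysis want
to relax it.

*Rescue.* Sequences left as piRNA or no-annotation whose sequence is
absent from the genome at zero mismatches (either strand) are exactly
the candidates whose cascade failure is plausibly a base-modification
artifact. They are re-matched at up to one mismatch against rRNA and
then tRNA; a hit rewrites the biotype to rsRNA/tsRNA with
`rescued = TRUE`. Two points the procedure leaves open, decided here:
the rRNA-before-tRNA priority for rescue ties simply reuses the
cascade order (flagged in the documentation, not claimed to be the
original authors' intent), and genome presence is tested at zero
mismatches. If no genome is supplied, every piRNA/no-annotation
sequence is treated as a candidate, which preserves the intent of the
step at the cost of specificity.

## Quantification

Retained reads collapse into identical-sequence clusters — exact
duplicate collapse, deliberately not a 97%-radius OTU clustering: the
upstream method applies its clustering tool to *identical* sequences,
and sequence identity is what makes features comparable across
samples, generations and species. The cluster identifier is therefore
the sequence itself. miRNA clusters are additionally aggregated by
mature miRNA ID, so isomiR variants (e.g. 3'-trimmed copies) of one
mature miRNA form a single feature; every other biotype keeps the
sequence as feature identity. Counts are normalized to reads per
million, `RPM = count * 1e6 / library size`, where the library size is
the sample's total *retained* read count — "library depth" most
naturally means retained depth, and the choice is configurable.

## Differential expression

Features with `log2(mean RPM) < 1` across the comparison's samples
(mean RPM < 2; the boundary is kept) are filtered as noise. The test
follows the classic count-based exact-test workflow:

1. Counts are scaled to a common (geometric-mean) library size and
   rounded — pseudo-counts make the conditional test below
   well-defined.
2. A single **common dispersion** φ (NB variance μ + φμ²) is
   estimated by maximizing, over all retained features, the
   conditional likelihood of the within-group counts given the group
   totals, on the delta = φ/(1+φ) scale, clamped to [0, 10]. Common
   dispersion only — no tagwise shrinkage — keeps the estimator
   transparent and testable; this is a documented divergence from the
   full edgeR machinery, which our tests nevertheless use as an
   independent cross-check (agreement to ~1e-4 at this design).
3. Per feature, the split of the grand total between the groups is
   tested exactly: conditional on the total, the two group sums are
   negative binomial with sizes n·(1/φ), and the two-sided p-value is
   the sum of the probabilities of all splits at most as probable as
   the observed one. At φ = 0 this is the conditional binomial
   (Poisson limit); our tests verify agreement with the closed form to
   1e-8 and with edgeR's small-p exact test to 1e-10.
4. log2 fold change is computed from group mean RPM with a prior
   count of 0.5 per group mean, which keeps zero-count features
   finite.
5. A feature is DE iff `|log2FC| > 1` and raw `p < 0.05`, both strict;
   BH-adjusted FDR is reported but deliberately not used for calling,
   matching the workflow being reimplemented.

Replicates are required (≥ 2 per group); there is no replicate-free
mode.

## Transgenerational overlap

For each exposed lineage (androgenized and obese vs the unexposed
control; the combined lineage vs the obese one — each generation
against its parallel-bred control), a feature is **transgenerational**
iff it is DE with the *same direction* in F1, F2 and F3; F1∩F2 gives
the intergenerational sets. Direction consistency is required because
the fold-change heatmaps this feeds show sign-consistent rows; the
code can relax the intersection to presence-only for sensitivity
analyses. A feature filtered out by the expression filter in any
generation cannot be transgenerational — that is implied by the DE
definition and documented rather than patched around.

## Cross-species homology

Argonaute-loaded small RNAs recognize targets through the seed
beginning at the second 5' base, so homology between a serum DE
feature and a mouse transgenerational feature ignores base 1 entirely:
let m be the longest identical block anchored at base 2 of both
sequences; the pair is accepted iff m covers strictly more than 90% of
*each* sequence's length. "Coverage of their total lengths" is
ambiguous between both-sequence and shorter-sequence coverage; the
both-sequence reading is adopted (and configurable) as the only
reading that makes the acceptance threshold symmetric. Pairing is
restricted to equal biotypes, is many-to-many, and is implemented as
direct string comparison — at 15–45 nt there is nothing for a
heuristic aligner to add.

## The synthetic-data generator

The generator emulates the structure of the study the pipeline
targets, with one pseudo-random stream per run (`seed` in
`sim_config()`; identical configs give byte-identical FASTQ):

* **Design**: 4 lineages (control, androgenized, obese, combined) ×
  F1–F3 × 4 sperm samples, plus a 9-vs-9 serum comparison.
* **References**: ≥ 5 mature miRNAs (22 nt), 8 tRNA genes including a
  histidine tRNA and two intron-carrying genes, the full rRNA class
  set with 18S/5.8S/28S embedded verbatim in a 45S precursor (so
  Svedberg precedence is genuinely exercised), ≥ 10 piRNAs, other
  ncRNAs, and a single-contig mini-genome concatenating all gene loci.
* **Rescue decoys**: one-mismatch mutants of rRNA/tRNA windows,
  excluded from the genome; half sit in the piRNA database (first-pass
  piRNA, rescued to rsRNA/tsRNA), half in no database (first-pass
  no-annotation, rescued).
* **Counts**: per-feature baseline abundances are drawn on the RPM
  scale and normalized to one million total, planted features at
  150–1000 RPM so they clear the expression filter decisively; counts
  are NB with common dispersion φ (default 0.1, a typical bulk
  small-RNA value). Planted effects are 8-fold, direction-consistent
  across F1–F3 for the transgenerational features, F1+F2 for
  intergenerational and F1-only otherwise; the combined lineage
  multiplies its own effects onto the obese lineage's means, since it
  is compared against the obese control. Library sizes are jittered
  ±20% to exercise RPM and pseudo-count scaling. Planted features are
  kept at low relative abundance so their fold changes do not distort
  the library composition of the null features — an early draft let
  them dominate and produced purely compositional false positives.
* **Reads**: per-biotype fragment lengths follow the sizes typical of
  sperm sncRNA (miRNA 22–24, piRNA 20–34, rsRNA 15–44, tsRNA 27–36
  nt), tsRNA/rsRNA fragments are drawn from their parents with the
  intended subtype, a configurable fraction of miRNA reads is emitted
  as the 3'-trimmed isomiR, adaptors are appended to a configurable
  fraction of reads (default 0.95), substitution errors at the
  configured rate (default 0.001), and a small fraction (0.02) of
  reads receives low base qualities.
* **Serum features**: homologs of mouse transgenerational features are
  copies with base 1 and fewer than 10%-of-length 3' bases mutated
  (guaranteed acceptance); reject-decoys are internally mutated copies
  planted DE in serum (guaranteed rejection, so the matcher is
  exercised on live candidates); plus serum-specific DE and null
  features.

What the generator does **not** emulate: ligation and GC bias, RNA
modifications themselves (only their mismatch shadow via the decoys),
real database sequences and their homology structure, multi-mapping
across paralogous loci, and adapter dimers. Passing the end-to-end
tests therefore demonstrates the pipeline's logic and statistics on
data satisfying its own model assumptions, not performance on real
libraries.

## Problem sizes and numerical choices

The package's own verification runs use 48 sperm samples at 50,000
reads each (≈ 2.4 million reads end-to-end), 2,000 features for the
type-I-error and dispersion-recovery checks, and the generator's
default design otherwise; the generator's default depth is 200,000
reads per sample. Exact-test p-value ties are resolved with a 1e-7
relative tolerance when summing probabilities "at most as probable as
observed", the convention of the standard exact tests. The dispersion
optimizer treats estimates below 2e-6 (or a boundary-dominated
likelihood) as zero. All reported coordinates are 1-based inclusive.

## Known limitations

* Common dispersion only; strongly feature-specific overdispersion
  will be mis-calibrated (the type-I test covers the common-φ case
  only).
* The rescue pass allows exactly one mismatch; doubly modified
  fragments stay unannotated, as in the reimplemented procedure.
* Multi-parent ambiguity is resolved by deterministic precedence
  rules, not by probabilistic assignment.
* RPM normalization does not correct library composition; very large
  planted effect mass can masquerade as opposite-direction DE in null
  features (see the generator note above).
* The homology criterion has no statistical significance model — it
  is a deterministic acceptance rule, as in the original analysis.
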