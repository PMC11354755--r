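---
title: "Measuring terminator readthrough from nascent-RNA coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring terminator readthrough from nascent-RNA coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtindex)
```

## The measurement problem

Run-on sequencing assays (GRO-seq and relatives) report, strand
specifically, where transcriptionally engaged RNA polymerase sits on
the genome: each read marks the 3′ end of a nascent transcript, so
per-nucleotide 3′-end counts are a snapshot of polymerase density.
When termination at the poly(A) signal works, that density drops
sharply past the cleavage site; when termination is defective,
polymerase continues into the downstream region and the density
persists. `rtindex` turns this qualitative picture into a per-gene
statistic and a genotype comparison.

## The readthrough index

For a gene with poly(A) site `pA`, working in strandward offsets
(negative = upstream in the direction of transcription), the
readthrough index of one replicate is

$$\mathrm{RTI} = \frac{\sum_{d \in [+50, +500)} c(d)}{\sum_{d \in [-500, -50)} c(d)}$$

with `c(d)` the strand-matched 3′-end count at offset `d`. Both
windows are 450 nt wide; the 50 nt directly flanking the cleavage site
are excluded because cleavage/processing intermediates and the
termination transition itself concentrate there, and including them
would blur the body/downstream contrast. The geometry is exposed as
`exclusion_nt` (default 50) and `window_nt` (default 450). RTI is a
ratio of counts from the same library, so it is invariant to
sequencing depth; no between-library normalization is applied
anywhere in the pipeline, and none is needed because every downstream
statistic is either a ratio or CDS-normalized.

RTI is undefined when the upstream sum is zero; such replicates are
dropped rather than imputed (the expression filter makes them rare,
and imputation would invent signal). Windows that run off a chromosome
end flag the record as incomplete; incomplete records are excluded
instead of zero-padded, because padding would deflate the affected
window asymmetrically.

## Coordinate conventions

All internal coordinates are 0-based half-open, as in BED; GFF3 input
(1-based closed) is converted on read. The poly(A) site is the 0-based
coordinate of the last transcribed nucleotide (`end − 1` on `+`,
`start` on `−`), overridable per gene from a sidecar table when a
dedicated 3′-end annotation (e.g. condition-specific cleavage sites)
is available — gene ends and measured cleavage sites routinely differ.
A single convention everywhere removes the usual ±1 drift in window
arithmetic; the test suite checks the strand-mirror and
reflection-invariance properties explicitly.

## Gene filters

Three inclusion criteria define the analyzed set, all inclusive
(`≥`):

- **Neighbor distance ≥ 500 nt** between the 3′ end and the nearest
  nucleotide of the next same-strand gene *downstream* (the direction
  readthrough travels). In a compact genome the terminator of one gene
  often sits inside the promoter or terminator of the next; the
  downstream window must not read a neighbor's transcription.
  "Nearest-edge" and "3′-to-5′" interpretations coincide for
  non-overlapping downstream genes; nearest-edge is implemented, and a
  gene with no downstream neighbor passes any threshold (distance
  `Inf`). Overlap yields distance 0, never negative.
- **Length ≥ 500 nt**, so the upstream window fits inside the gene
  body.
- **Expression ≥ 1 read/nt over the CDS in ≥ 3 replicates**, pooled
  across both genotypes. Pooling is a design choice the configuration
  exposes (`min_replicates_passing`): the criterion's natural reading
  names replicates, not genotypes, and a gene silent in one genotype
  but active in the other should be testable rather than discarded.

The funnel counts are reported in the fixed order distance → length →
expression; the surviving *set* is order-independent (an intersection
of three predicates), which the suite verifies, so the order only
affects bookkeeping.

## Differential readthrough

Per gene, replicate RTIs of the mutant are compared against wild type
with a one-sided unequal-variance (Welch) t-test, alternative mutant >
WT — readthrough is a directional hypothesis. A gene is called
significant when

- one-sided `p < 0.05` (`alpha`),
- `log2(mean RTI mutant / mean RTI WT) > 1`, i.e. at least 2-fold
  (`log2_fc_threshold`), and
- at least 5 defined replicate values in total with at least 2 per
  genotype (`min_total`, `min_per_group`).

The 2-fold default is the threshold consistent with the boxed
selection region of a volcano display (log2 ratio > 1, p < 0.05); a
stricter 4-fold criterion is one configuration flag away. Raw RTIs
(not log-RTIs) enter the t-test; at 3 replicates per group the choice
is essentially a convention, and raw values keep the degenerate-case
rules simple. No multiple-testing correction gates the significance
flag — the per-gene criterion is an explicit raw-p rule — but a
Benjamini–Hochberg `q_value` column is always emitted so users can
apply FDR control.

**Degenerate inputs.** With zero variance in both groups the Welch
statistic is undefined; the implementation reports the limiting
p-value (0 if the mutant mean is larger, 1 if smaller, 0.5 on a tie)
and flags the gene `degenerate`. This keeps noiseless fixtures and
pathological real genes well-defined without special-casing callers.

**Genome-wide summaries.** Per-gene RTIs are first averaged over
replicates within genotype, then summarized over genes with an
unweighted mean and median (the median being the outlier-robust
display). The averaging order (genes of replicate-means, rather than
pooling all replicates) weights every gene equally regardless of
replicate dropout; the alternative is one flag away in
`summarize_rti()`'s inputs since the function consumes the replicate
table directly. The mean comparison uses a two-sided *paired* t-test
across genes (each gene is its own control); the median display uses
a two-sided Welch test.

## Metagene profiles and heat maps

Each gene's signal over offsets −200..+199 around the poly(A) site is
divided by its average CDS read density, putting the body plateau of
every gene near 1 irrespective of expression; the profile is then the
per-offset mean over the pooled (gene × replicate) values, with
standard error computed over the same pool. Pooling is the default
because one band per genotype is drawn from all replicates; computing
SE across genes only (treating replicates as fixed) is a
`metagene_rows()`-level variant left to the user. By construction the
mean normalized density over a gene's own CDS is exactly 1, which the
suite asserts per gene.

Heat-map rows are ordered by ascending per-gene mean *mutant* RTI —
"increasing readthrough phenotype" needs a concrete key, and the
mutant RTI is the phenotype being ranked — with ties broken
lexicographically by gene id so the order is total and reproducible.
The same row order is used for every sample of both genotypes; genes
without a defined mutant RTI sort last and are flagged.

## BNSAF proteomics

Spectral counts are length-biased (longer proteins yield more
peptides), so a protein's abundance in an affinity-purified sample is
summarized as SAF = counts / length in amino acids. Dividing by the
bait's SAF in the same purification gives the bait-normalized SAF
(BNSAF), which cancels purification yield and instrument loading: the
bait is exactly 1 everywhere, and BNSAF is invariant to scaling all
counts of a sample, a property the suite tests. Amino-acid length is
the documented normalization; when lengths are unavailable a
counts-only mode (`bnsaf = counts/counts_bait`) is provided and
labeled distinctly in the output. Chromatin and soluble fractions are
analyzed separately and never merged — the biology of interest is
fraction-specific.

Genotype comparison is a two-sided *paired* t-test per protein
(replicates are paired purifications), with percent change
`100·(mean_mut − mean_wt)/mean_wt`. All-zero paired differences are
degenerate and reported as p = 1 with a flag. Complex-level summaries
average member percent changes (CF1: Rna14, Rna15, Pcf11, Clp1, Hrp1;
Rat1: Rat1, Rai1; CPF core subunits; general transcription factors as
a comparison group) and always lie between the member extremes.

## ChIP and TRO normalization

Factor occupancy is `(ChIP/input) / (PolII ChIP/PolII input)` at the
same amplicon: the first ratio removes chromatin amount and primer
efficiency, the second expresses recruitment per transcribing
polymerase so that a transcription change alone does not masquerade as
a recruitment change. The operation is agnostic to whether the PolII
signals come from the same or a parallel chromatin preparation. TRO
signal is the nascent RT-PCR signal over the 18S control of the same
reaction. Genotype declines use group means of replicate-level
normalized values with a two-tailed Welch test by default (sidedness
is configurable; the targeted assays are confirmatory, so two-tailed
is the conservative default).

## The synthetic-data generator

The generator emulates exactly the features the statistics consume:

- per-nucleotide gene-body counts are Poisson with mean `body_rate`
  (default 10 reads/nt, a well-expressed yeast gene at typical
  run-on depth);
- past the poly(A) site, counts are Poisson with mean
  `body_rate · r · g(d)` over `readthrough_extent_nt` (default 500 nt),
  where `r` is the genotype's true readthrough fraction and `g` is
  either constant (default) or an exponential decay with configurable
  half-life;
- genes (default 200) are placed sequentially with spacing drawn from
  700–1200 nt so every analysis window is clean, strands assigned at
  random; CDS equals the gene span;
- replicates (default 3 per genotype) are independent with derived
  sub-seeds; everything is byte-reproducible under the configured
  seed.

The default readthrough fractions are 0.05 (wild type) and 0.15
(mutant) — a 3-fold shift of the same order as a real termination-
defective mutant. The reference problem sizes used throughout the
suite are 200 genes for recovery checks and 500 genes for the
null-calibration test; these are large enough that estimator standard
errors are far below the planted effects.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: overdispersion beyond Poisson
(an extension point; real biological replicates vary more), mappability
gaps and multi-mapping artifacts, antisense and intragenic
transcription, isoform-specific or heterogeneous cleavage sites,
convergent-gene interference, and any upstream read-processing effects
(the contract starts at 3′-end coverage). Spectral counts are likewise
Poisson around `abundance · length · scale` with no peptide-level
structure, and ChIP/TRO tables use log-normal technical noise around
the planted truth.

Under the null (equal `r` in both genotypes) the differential stage's
false-positive rate at `alpha = 0.05` is checked to stay below 8% over
500 genes: a one-sided Welch test at n = 3 + 3 is only approximately
calibrated, so the bound is deliberately loose rather than a claim of
exactness.

## Pipeline and reproducibility

`run_pipeline()` executes filter → RTI → differential → metagene →
heat map in dependency order; a stage requested without its upstream
artifact fails with an error naming what to run first, and stages can
resume from a previous run's TSVs. Every output table begins with
`# key=value` comment lines recording the exact thresholds and window
parameters of the run, so any number in any table can be traced to its
configuration. Reruns on fixed inputs are byte-identical. The
command-line wrapper in `inst/cli/` adds nothing beyond flag parsing.

## Known limitations

- One 3′ end per gene: no isoform handling, no UTR inference, no
  alternative poly(A)-site selection.
- RTI is the only readthrough statistic; no change-point detection of
  the termination zone position.
- The expression filter uses raw reads/nt with no between-replicate
  normalization — intentional (the criterion is a raw-depth floor),
  but it means very shallow libraries under-count passing replicates.
- Welch tests at 2–3 replicates per group have limited power and
  approximate calibration; the replicate minimums exist precisely to
  keep the worst cases out.
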