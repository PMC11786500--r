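---
title: "Measuring XCI skewing and escape from phased single-cell reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring XCI skewing and escape from phased single-cell reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciskew)
```

## The measurement problem

In female cells one X chromosome is epigenetically silenced. Across a
tissue the silenced copy varies cell to cell, so at any expressed
heterozygous chrX variant a *population* of cells emits a mixture of the
two alleles. Two departures from the null picture matter:

* **Skewing** — the mixture is far from 50:50, because the cell
  population preferentially inactivated one X.
* **Escape** — a single cell emits *both* alleles, i.e. the locus is
  transcribed from the inactive X as well.

Bulk RNA-seq confounds these: a 70:30 bulk ratio could be skewing, escape,
or a mixture. Droplet scRNA-seq disentangles them because every read
carries a cell barcode and a UMI. `xciskew` operates strictly downstream
of phasing: its input is a table of per-read observations
(position, base, haplotype H1/H2, cell barcode, UMI), the text export of
read-backed phasing on a chrX-only BAM.

## From reads to per-position quantities

Three nested counting layers are kept deliberately distinct:

| quantity | layer | meaning |
|---|---|---|
| `barcoding_frequency` | reads | raw coverage at the position |
| `x1`, `x2` | UMIs | molecules supporting each haplotype |
| `n_barcodes` | cells | breadth of expression |

Reads are grouped by (position, barcode, UMI). A group whose reads agree
on the haplotype becomes one molecule; a conflicting group (PCR/sequencing
artefact or UMI collision) is discarded from `x1`/`x2` but *retained* in
`barcoding_frequency`, because coverage is a property of the data, while
allele support must be unambiguous. This reads > UMIs > cells hierarchy is
the only self-consistent reading of the published per-sample summary
tables, where mean coverage exceeds mean `x1 + x2`, which exceeds the mean
barcode count; whether the published X1/X2 are UMI counts or deduplicated
read counts is not stated anywhere we could verify, so the choice is
recorded here as an interpretation.

### The filter funnel

A position enters the skewing analysis only if (defaults, all bounds
inclusive):

| parameter | default | unit | rationale |
|---|---|---|---|
| `freq_min`–`freq_max` | 10–1000 | reads | excludes noise floor and collapsed repeats/PCR pileups |
| `barcode_min`–`barcode_max` | 3–30 | cells | population skew needs ≥ 3 cells; > 30 suggests ambient contamination at this depth |
| `allele_min` | 3 | UMIs per allele | both alleles must be seen ≥ 3 times |

Inclusive bounds are not cosmetic: the published per-sample minima sit
*exactly* on 3 (X1, X2, barcodes) and 10 (coverage), which is only
possible if positions on the boundary are retained. The source documents
alternate between "more than three" and "greater than or equal to 3"; the
table minima decide the question in favour of ≥.

## The skewing statistic and its categories

For retained positions, `skew = 100·max(x1, x2)/(x1 + x2)`, a number in
[50, 100] that is symmetric in the alleles and invariant under scaling
both counts. Categories:

* R (relatively random) — [50, 70)
* S (skewing) — [70, 80)
* SS (severe skewing) — [80, 90)
* E (extreme severe skewing) — [90, 100]

The published ranges "50–70 / 70–80 / 80–90 / 90–100" touch at the
boundaries; we resolve them as half-open intervals with the final bin
closed, making the four bins a true partition of [50, 100]. The test
suite checks by exhaustive enumeration over all count pairs 3 ≤ x1, x2 ≤ 30
that every pair lands in exactly one bin.

Haplotype labels from read-backed phasing are sample-local: H1 in one
individual has no relationship to H1 in another, and neither is anchored
to parental origin. Skew direction is therefore never interpreted across
samples; only its magnitude is.

### Reporting conventions

Category percentages are rounded *half up* to one decimal
(`round_half_up`), not banker's-rounded: this is what spreadsheet-based
reporting does, and it is the convention under which the published
per-category counts reproduce the published percentages exactly (verified
in the acceptance tests, including the "skewing or higher" and "severe or
higher" aggregates). Descriptive tables default to the sample standard
deviation (n−1); population SD is available via `sd_type = "population"`
because the convention behind the published tables cannot be verified
without the deposited per-position data.

## The escape criterion

`call_escape()` retains positions with exactly one barcode, ≥ 3 molecules
for *each* haplotype, and coverage in [10, 1000]. This is an operational,
per-position definition — biallelic expression inside one cell — not a
claim that the *gene* escapes XCI tissue-wide. Because the one cell is
the whole position, per-cell and per-position counts coincide, and the
escape set is disjoint from the skewing set (1 barcode vs ≥ 3) by
construction.

Gene annotation is a point-in-interval query against a user-supplied BED
file: a 1-based call position `pos` maps to a gene whose 0-based
half-open interval contains `pos − 1`. So an interval `[0, 100)` covers
1-based positions 1–100. No transcript-model awareness is attempted; the
analysis reports gene symbols only.

## Comparing two samples

At each position passing the funnel in *both* samples a 2×2 table is
formed. Because haplotype labels are not comparable across individuals,
the default orientation is per-sample **(major, minor)** counts: the test
asks whether the *degree* of allelic imbalance differs, not whether the
same haplotype is favoured. (`orientation = "haplotype_labels"` is
available for within-individual designs where labels do align.)

Choices fixed here, exposed as options:

* **Z test** — pooled-variance two-proportion form; the variant is not
  otherwise determined, and pooling gives the identity χ² = Z², which the
  suite verifies on 1000 random tables to 1e-9.
* **χ²** — Pearson, *no* Yates correction by default (preserving the
  identity); `yates = TRUE` available.
* **Degenerate tables** — if the pooled proportion is 0 or 1 there is no
  variation to test: Z = 0, p = 1, and the comparison loop applies the
  same convention to χ² so the identity survives.
* **Corrections** — Bonferroni, Hochberg, Hommel, and "false discovery"
  read as Benjamini–Hochberg step-up (the standard reading;
  Benjamini–Yekutieli available as `"by"`). All four are applied once
  over the full family of shared positions, never per subset.
* **Effect size** — Woolf's log-OR interval under Haldane's +½-cell
  correction, finite and positive for any non-negative table; swapping
  rows inverts the estimate exactly.
* **Ties** — at x1 = x2 the (major, minor) order falls back to (x1, x2);
  the OR direction is meaningless at perfect balance and should not be
  interpreted there.

## What the simulator emulates — and what it does not

`simulate_phased_reads()` generates the *post-phasing* data layer under a
known truth, one record per read:

* Each cell inactivates H2 with probability `mosaic_fraction` (π), so π
  is the expected population skew toward H1. Default 0.7 — the scale of
  mean skew reported for CD4+ T cells in the motivating study.
* A cell expresses a given position with probability `expr_rate`
  (default 0.02; with the default 500 cells this yields roughly 8–10
  expressing cells per position, the scale of the published barcode
  counts). Expressing cells emit zero-truncated-Poisson UMI counts
  (mean parameter `umis_per_cell_position`, default 3) and each UMI
  carries a zero-truncated-Poisson read count (`reads_per_umi`,
  default 1.8), reproducing the reads > UMIs > cells hierarchy.
  `expr_rate` is a generator parameter beyond the minimal field list
  because zero-truncated molecule counts require an explicit
  expressing-cell mechanism.
* `leak_rate` (default 0.01) flips a molecule's haplotype in monoallelic
  cells — a catch-all for phasing errors, barcode swapping and ambient
  RNA.
* Escape positions (`escape_rate`, default 0.05) are expressed in
  exactly one cell with 3 + Poisson(`umis_per_cell_position`) molecules
  *per haplotype*, topped up to ≥ 10 reads, so every planted site meets
  the operational criterion — the generator plants the *definition*, not
  a biological model of escape across cells.
* Homozygous decoys emit only H1 everywhere; they must never be called.

Barcodes are 16-mers and UMIs 10-mers over {A,C,G,T}, mirroring 10x v2
conventions; both are kept collision-free by construction. A fixed seed
reproduces records and truth byte-identically, and the generator restores
the caller's RNG state.

Deliberately **not** modelled: alignment and base-calling error, intronic
reads, doublets, ambient-RNA profiles, cell-type structure, XIST
expression, gene-level expression correlation, and phasing switch errors
beyond the symmetric leak. Passing the recovery tests therefore shows the
*pipeline arithmetic* is correct under the stated model — it does not
validate behaviour against those real-data artefacts.

## Validation design and problem sizes

The suite favours independent oracles over re-asserted constants:
brute-force grouping/tally oracles for aggregation; exhaustive bin
enumeration for classification; textbook Σ(O−E)²/E, closed-form Haldane
OR and step-up/closed-testing (Simes-enumeration) recursions for the
statistics; and a CIGAR hand-walk for alignment ingestion (soft clips,
deletions, missing tags, unmapped reads).

Simulation-based checks run at desk scale, chosen to keep the full suite
around half a minute while leaving the statistical assertions
well-powered: ~100–110 positions × 500 cells with ~25 expressing cells
per position for parameter recovery (mean recovered skew within 3
standard errors of 100π = 80), sensitivity/specificity of escape/decoy
recovery at leak 0 (both exactly 1.0), and 200 replicates of a 7-position
family for planted-difference power under BH-FDR.

## Known limitations

* Skewing direction is unanchored (no trio/parental phasing); all
  cross-sample statements are about magnitude.
* `barcoding_frequency` is a read count, `x1`/`x2` UMI counts: positions
  with extreme PCR duplication can pass the coverage gate on few
  molecules (the `allele_min` gate is the guard).
* The escape criterion is per-position and single-cell; recurrence across
  cells or positions in the same gene is left to downstream judgement.
* With very deep data the 3–30 barcode window starts discarding genuinely
  informative positions; the thresholds object exists precisely so the
  funnel can be re-tuned per dataset.
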