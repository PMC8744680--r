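---
title: "Calling and classifying transcription start sites from ReCappable-seq libraries"
author: "recaptss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying transcription start sites from ReCappable-seq libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recaptss)
```

## The measurement and the model

ReCappable-seq tags the 5′ ends of *primary* transcripts — those still
carrying either an m7G cap (RNA polymerase II products, after enzymatic
decapping to a diphosphate) or a 5′ triphosphate (Pol I, Pol III and
mitochondrial polymerase products) — with a biotinylated cap analog, and
enriches them on streptavidin. Sequencing the enriched library pinpoints
transcription start sites (TSSs) at single-nucleotide resolution for all
RNA polymerases at once; processed and degraded 5′ ends (monophosphate,
e.g. mature rRNA) are left untagged and drop out.

Three matched libraries drive the downstream analysis this package
implements:

* **ALL** — the enriched library; its per-position 5′-tag signal defines
  candidate TSSs.
* **CT** — an unenriched control (streptavidin step omitted); positions
  that are *not* enriched relative to this background are artifacts of
  abundant processed RNA.
* **CIP** — enriched after pretreatment with calf intestinal alkaline
  phosphatase, which destroys 5′ triphosphates but not caps; depletion in
  this library marks a triphosphorylated (non–Pol II) start.

Per library, a read's 5′ *tag* is its 5′-most aligned base: the leftmost
aligned position for `+` reads, the rightmost for `-` reads. Soft-clipped
5′ prefixes occupy no reference position, so they never shift the tag;
the clipped bases are retained because runs of nontemplated adenosines at
a start are a real biological signature (transcription-initiation
stuttering at mitochondrial promoters). Counts are normalized to tags per
million primary mappable reads, $\mathrm{TPM} = 10^6 \, c / N$.

The decision cascade, with every threshold inclusive exactly as written:

1. **Candidate**: $\mathrm{TPM}_{\mathrm{ALL}} \ge 1$.
2. **High confidence (HC)**: enrichment ratio
   $\mathrm{TPM}_{\mathrm{ALL}} / \mathrm{TPM}_{\mathrm{CT}} \ge 1$;
   otherwise the candidate is a false positive.
3. **Polymerase class**: among HC positions, CIP ratio
   $\mathrm{TPM}_{\mathrm{ALL}} / \mathrm{TPM}_{\mathrm{CIP}} \ge 4$
   means CIP-sensitive, hence **non–Pol II**; below 4 means
   CIP-resistant, hence **Pol II**.

The two ratios define four quadrants (II = HC non–Pol II, IV = HC
Pol II, I/III = false positives split by the CIP ratio), which is what
`plot()` on a `recaptss_calls` object draws.

A known, deliberate property of this classification: 5′ ends bearing a
gamma-methylated triphosphate (the RN7SK-type end) resist CIP and are
therefore classified with Pol II even though the transcript is a Pol III
product. The simulator's truth table encodes this same expectation rather
than idealizing it away.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_tpm` | 1 | TPM | candidate threshold; at 63 M reads one TPM is 63 tags |
| `hc_ratio` | 1 | ratio | enrichment over the unenriched control |
| `cip_threshold` | 4 | ratio | CIP-sensitivity cutoff separating the classes |
| `pseudocount` | 0 | TPM | 0 keeps absent-in-control positions maximally enriched (+Inf) |
| `max_upstream` | 200 | bp | TSS-to-exon assignment range |
| `max_gap` | 20 | bp | single-linkage gap for unannotated loci |
| `mapq_threshold` | 3 | MAPQ | uniqueness cutoff (STAR convention; use 39 for Bowtie 2) |
| `min_ratio` | 0.8 | fraction | unique-mapping ratio for mitochondrial positions |

Zero denominators are treated as limits, not errors: a candidate absent
from the control is maximally enriched (ratio $+\infty$, HC), a candidate
absent from the CIP library is maximally CIP-sensitive ($+\infty$,
non–Pol II). A `pseudocount` option regularizes both ratios for users who
prefer shrinkage; it is off by default so the thresholds act exactly on
the measured ratios. Matching across the three libraries is by exact
(chromosome, position, strand) key — the method is single-nucleotide by
construction, and no cross-position aggregation is done (CAGE-style tag
clustering is deliberately out of scope).

Coordinates are 0-based half-open everywhere inside the package
(BED/bedGraph convention); `pos0_to_pos1()` / `pos1_to_pos0()` are the
only conversion points. In the bedGraph writer the sign of the value
carries the class — positive for Pol II, negative for non–Pol II — which
matches the browser-track convention for these data; BED6 output is the
lossless companion (strand, class, full-precision TPM).

## Gene assignment and annotation-side choices

`assign_tss_to_genes()` reproduces closest-*downstream*-exon semantics:
candidate exons either overlap the TSS (distance 0) or begin downstream
of it in the gene's orientation; exons the TSS has already passed are
never candidates, because a genuine TSS sits upstream of or within its
gene, not beyond it. The nearest candidate wins, ties break by
annotation input order, and the assignment stands iff the distance is at
most 200 bp (inclusive — the boundary case is not specified anywhere, so
the package fixes it inclusively, consistent with every other threshold).
Assignment is computed against *all* exons, not first exons only.

Unassigned TSSs are clustered per (chromosome, strand) by single-linkage
chaining with a 20 bp gap. Strand separation is a package choice: a
sense and an antisense start 5 bp apart are different biology and should
not merge into one locus; it is configurable.

## The simulator: what it emulates and what it does not

`simulate_recappable()` builds a uniform-random genome, places
non-overlapping transcription units of four 5′-end chemistries, and
samples aligned reads per library with capture probabilities that encode
the enrichment chemistry (`default_capture_matrix()`): ALL captures
capped, triphosphorylated and gamma-methyl ends and rejects processed
ends; CIP additionally rejects plain triphosphates; CT captures
everything. Rejected chemistries leak through at `epsilon` so that the
ratio thresholds — not mere presence/absence — are what the end-to-end
tests exercise.

Default study conditions, chosen once: one 100 kb contig; 50 units
(20 capped, 15 ppp, 5 gamma-methyl, 10 processed) of 350–600 bp;
abundances uniform in [0.5, 2] (keeps every unit's expected tag count in
the hundreds at 10^5 reads, so recovery failures indicate logic errors,
not starvation); `epsilon = 0.01`; `degraded_fraction = 0.3` (the
unenriched control in real data is dominated by processed 5′ ends —
roughly 70% rRNA — and 30% degraded reads gives the control the same
qualitative role at desk scale); `positional_jitter = 0.05` for ±1 bp
start imprecision (real promoters show minor satellite starts); 50 nt
reads (the read length at which these libraries are analysed); 10^5
reads per library. Everything is a pure function of the configuration
seed; libraries use decorrelated sub-seeds.

The simulator emits already-aligned SAM, not FASTQ: the package's scope
begins downstream of alignment, and this keeps the whole test suite
aligner-free. It does not model sequencing error, PCR duplication,
multimapping ambiguity, biased capture efficiencies per position, or
genomic repeat structure. Consequently, passing end-to-end tests
demonstrates the correctness of the counting/thresholding/classification
logic under the stated sampling model — not robustness to the mapping
artifacts, promoter microheterogeneity or chemistry-efficiency variation
of real libraries.

Problem sizes used by the validation suite: the noise-free end-to-end
run uses 10^5 reads per library, the noisy stress run 2 × 10^5; the
counting oracle uses 10^4 random reads; metric oracles use
hundreds-of-position fixtures. These sizes put every per-gene count far
above the thresholds being tested while keeping each run in seconds.

## Numerical and degenerate-input conventions

* TPM with a zero library size is an error (`recaptss_zero_library`),
  never a silent 0/0; undefined precision/sensitivity (zero
  denominators) propagate as `NA`.
* Unmapped reads abort tag extraction with a typed condition
  (`recaptss_unmapped_read`).
* Transcript body coverage bins 0-based position rank $r$ of a
  length-$L$ transcript into bin $\lfloor 100 r / L \rfloor + 1$, ties to
  the lower bin; the exact convention is covered by a conservation
  invariant (row sums equal kept tag counts), which holds for any
  monotone binning.
* The qPCR recovery formula
  $100 \times 2^{-(\overline{Cq}_\mathrm{input} - \overline{Cq}_\mathrm{enriched})}$
  is evaluated on mean Cq values; applied to two-decimal published Cq
  pairs it reproduces published percentages to a few tenths of a
  percentage point (instrument-precision Cqs would be needed for the
  last digit), e.g.

```{r qpcr}
qpcr_recovery(c(25.9, 25.7), c(24.2, 24.1))
```

* Mitochondrial positions with zero tags are dropped from the
  unique-mapping filter with a warning rather than treated as ratio 0.

## A small worked run

```{r pipeline}
cfg <- sim_config(n_reads = 20000L, seed = 5L)
sim <- end_to_end_check(cfg)
sim$confusion
sim$recovery_pct
summary(sim$calls)
```

All 50 true starts are recovered with their expected class (including
the gamma-methyl units deliberately landing in Pol II), no processed
unit reaches high confidence, and the degraded-background candidates are
overwhelmingly removed by the control filter.

## Known limitations

* Per-position analysis only: closely spaced alternative starts are
  reported separately, never aggregated into promoters.
* The classification inherits the method's chemistry blind spots:
  CIP-resistant noncanonical ends (gamma-methyl triphosphates, possibly
  NAD caps) land in the Pol II class.
* Precision/sensitivity depend on externally supplied references (CAGE,
  annotation, peak sets, FPKM tables); the package evaluates, it does
  not derive them.
* The simulator validates logic, not aligner behaviour; MAPQ values in
  simulated reads are constants, so the mitochondrial uniqueness filter
  is exercised on constructed tallies rather than simulated multimappers.
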