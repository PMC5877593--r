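---
title: "somaticflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somaticflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticflow)
library(dplyr)
```

somaticflow implements the downstream half of a matched tumor/normal
whole-exome analysis: everything after the callers. This vignette explains
the decision rules, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical conventions —
including the choices we had to make where the procedure is genuinely
underdetermined.

## The variant selection cascade

Raw caller output for low-burden tumors is dominated by germline
polymorphisms, low-support noise and functionally silent events. The
cascade applies three per-record predicates in order:

1. **Depth/VAF** — keep records with total depth strictly greater than 10
   and Ratio (alternate reads over total reads) strictly greater
   than 0.2. All comparators in the package are strict: the thresholds are
   quoted as strict inequalities and boundary records (depth exactly 10,
   Ratio exactly 0.2) are excluded. A record with zero total depth has no
   defined Ratio and is removed.
2. **Functional scope** — keep coding non-silent effects and variants at
   ±3 of splice sites; remove silent and non-coding records. Records with
   a missing effect annotation are rejected with a warning and counted
   separately rather than silently dropped.
3. **Rarity** — keep records that are novel (no population-frequency
   entry) or strictly rarer than 0.01 in *every* database that reports a
   frequency. Requiring rarity in all databases, not just one, is the
   stricter reading of filtering "on databases of human variability": a
   variant common anywhere is a polymorphism.

Because each stage is a pure per-record predicate, the stages are
idempotent, the functional and rarity stages commute, and the whole
cascade equals a single conjunction — properties the test suite checks
against a brute-force re-evaluation. Multi-allelic records are split into
per-alternate rows before filtering, since depth and Ratio are per-allele
quantities.

## Somatic classification from the matched normal

The classifier looks only at the normal pileup at the variant locus:

| normal total depth | alternate reads | status |
|---|---|---|
| < 5 | any | undetermined |
| = 5 | any | undetermined (see below) |
| > 5 | 0 | somatic |
| ≥ 15 | 1 | somatic |
| ≥ 30 | 2 | somatic |
| > 5, otherwise | ≥ 1 | germline |

The tolerance for one or two alternate reads at high depth absorbs
sequencing error and trace tumor-in-normal contamination without
sacrificing somatic calls.

Two conventions deserve a note:

* **Depth exactly 5.** The rule as stated covers "> 5" (somatic-eligible)
  and "< 5" (undetermined) and is silent about 5 itself. We assign
  undetermined: at five reads the absence of the alternate allele is weak
  evidence either way, and the conservative reading avoids both false
  somatic and false germline calls at the boundary.
* **Alternate-allele counting.** Only reads supporting the *exact*
  alternate allele of the tumor record count against somatic status (the
  indel tally for length-changing alleles). A different non-reference
  base in the normal is independent evidence and does not disqualify the
  call.

Loci missing from the pileup are undetermined and flagged; a duplicated
pileup row for one locus is an input error, not a silent first-match.

Undetermined variants are excluded from every downstream count (burden,
recurrence, clonal partition) and reported separately: they are absence
of evidence, not evidence.

## Mutational burden

Burden is the somatic count over the merged capture size:
`n_somatic / target_Mb`. The numerator is restricted to the same
functional scope as the cascade (coding non-silent plus splice ±3) so the
two statistics describe the same variant universe; the denominator is the
union of the capture intervals — merging prevents double-counting
overlapping probes — rather than the genome, because only captured
territory can yield calls.

## CNV consensus

Two read-depth callers rarely agree on exact boundaries but should agree
on events. A same-state pair (one segment per caller, same chromosome)
reaches consensus when the intersection covers at least 80% of **each**
segment; the emitted region is the intersection. The 80% overlap could be
read as one-sided (80% of one caller's segment); we adopt the reciprocal
reading because it is symmetric in the callers and strictly more
demanding. The uncertainty score carried by one caller is applied
strictly (< 80) and only where present — the second caller reports none,
and the rule is written so that swapping the callers (moving the
uncertainty column with them) cannot change the result.

One segment may pair with several segments of the other caller; each
qualifying pair contributes its intersection and overlapping same-state
intersections are merged. The per-base meaning is simple — a base is
consensus if and only if it lies in some qualifying pair's intersection —
and the tests verify exactly that against brute-force per-base
computation on toy chromosomes.

Coordinates are 1-based inclusive in every file and user-facing tibble
(the convention of the segment files themselves); interval arithmetic is
0-based half-open internally and the conversion round-trips exactly.

Consensus segments whose length is at least half covered by the union of
catalogued polymorphic regions are removed as likely copy-number
polymorphisms. Focality for the gene-deletion query is a declared 3 Mb
length ceiling — "focal" has no standard definition, and 3 Mb cleanly
separates gene-scale deletions from arm-level losses; it is a parameter,
not a constant.

## Fusion consensus and structural triage

Cross-caller matching is by sample and **ordered** 5′→3′ gene pair.
Ordered, because read-through interpretation depends on orientation; a
swapped pair is a different event. Gene-level rather than
breakpoint-level, because the four predictors report different breakpoint
conventions for the same fusion. Duplicate calls within one caller
collapse before voting, and at least two *distinct* callers are required.
The representative breakpoints come from the best-supported call, ties
broken deterministically by caller name.

Triage: a consensus fusion between same-chromosome, same-strand partners
is read-through/conjoined when the 3′ partner is the next same-strand
gene downstream of the 5′ partner, or begins within 100 kb of its end in
transcriptional orientation. The 100 kb gap and next-gene rule are our
operational definition of a narrative category; both are parameters.
Remaining same-chromosome events are intra-chromosomal, the rest
inter-chromosomal.

## Clonal partition

For a patient with *n* ≥ 2 lesions, each somatic variant — identified
across lesions by its exact (chrom, pos, ref, alt) key, as all lesions
are called against one reference — is truncal (present in all *n*),
private (exactly 1) or partial (otherwise). The three sets are disjoint
and exhaustive by construction. Only variants classified somatic and in
the burden scope enter the partition; whether silent somatic variants
should count is not determined by the source procedure, and we keep one
variant universe throughout. The lesion × gene matrix orders genes
truncal-first, then by decreasing lesion count, which reproduces the
familiar "trunk on the left" layout in `autoplot()`.

## The synthetic cohort generator

The generator emulates *caller output*, not sequencing: no reads, no
base-level error model, no FFPE artifacts. It exists so that every stage
above can be scored against known truth.

What it draws, and why:

* **Cohort structure** — 14 patients, 19 tumor samples (one patient with
  five metastatic lesions, one with two), one matched normal per
  patient. A 30 Mb capture target of equal-sized genes on 24 named
  chromosomes; a handful of well-known symbols (PDGFRA, DMD, TP53, IDH1,
  FBXW7, SDHB) are pinned to their canonical chromosomes so narrative
  queries have stable coordinates.
* **Depths** — negative-binomial around the configured means (60× tumor
  and normal), dispersion 10: capture data is over-dispersed, and a
  Poisson model would almost never produce the shallow normals that
  exercise the undetermined branch.
* **VAFs** — Beta-distributed: clonal somatic variants around 0.4
  (purity below 1), germline around 0.5. The source cohort reports no
  purity estimates; these centers are stated assumptions.
* **Somatic rates** — Poisson with per-lesion expectation
  0.5/Mb × 30 Mb, split into truncal (30%), partial (10%, patients with
  ≥ 3 lesions) and private budgets so that each lesion's expected count
  equals the configured rate regardless of how many lesions the patient
  has. The driver occupies one truncal slot in every patient.
* **Detectability conditioning** — emitted somatic records are drawn
  conditional on caller-style detectability (depth ≥ 12, VAF ≥ 0.22).
  A real caller's VCF contains only events it called; emitting records a
  caller would never have written would simulate the wrong object. This
  also keeps shared variants observable in every lesion carrying them,
  which is what makes exact clonal recovery a fair expectation.
* **Matched normal** — one pileup per patient covering every emitted
  locus; germline loci at Beta(0.5) allele fraction, somatic loci clean
  (an optional contamination knob injects 1–2 alternate reads at a
  configurable fraction of somatic loci to exercise the 1/15 and 2/30
  branches). Two percent of loci get a shallow normal (mean depth 3) to
  populate the undetermined class; the driver locus is exempt, being a
  molecularly confirmed locus whose normal coverage would be verified.
* **Filter fodder** — rare germline (3/Mb), common polymorphisms (2/Mb),
  silent/non-coding records (1/Mb) and unlabeled caller false positives
  (1/Mb) that fail the depth/VAF stage by construction, so every filter
  has real work to do.
* **CNVs** — six true segments per sample (0.2–1.2 Mb), plus a focal
  DMD deletion in 42% of samples and two polymorphic segments drawn from
  a shared five-region catalog. Each pseudo-caller re-reports every
  segment with ±5 kb boundary jitter; the first carries an uncertainty
  score below 80 for genuine segments and up to 95 for its private false
  positives. False segments live on caller-specific chromosome
  territories, emulating each algorithm's characteristic artifact
  profile and keeping them caller-private. Somatic truth avoids the
  polymorphic catalog: a somatic segment coinciding with a known
  polymorphic locus is exactly what the downstream filter is designed to
  discard, so it cannot be recoverable truth.
* **Fusions** — three true events per sample (two read-through between
  adjacent same-strand genes, one genuine rearrangement), each reported
  by 2–4 randomly chosen callers with ±500 bp breakpoint disagreement;
  caller-private false pairs at one expected call per caller per sample.
* **Expression** — each gene expressed in a sample with probability 1/3,
  matching the observed fraction of mutated genes with detectable
  expression.

Identical configurations (including the seed) produce bit-identical
cohorts and output files.

What passing tests on this generator do **not** show: robustness to
alignment artifacts, FFPE damage, shared artifact loci between callers,
subclonal VAF structure, or annotation errors — none of which the
generator models. The recovery results say the *rules are implemented
correctly and are mutually consistent*, not that the thresholds are
optimal for any particular real dataset.

## Problem sizes and runtime

The shipped tests and the acceptance script run the full pipeline on the
default 19-sample, 30 Mb cohort (~4,000 caller records, ~120 CNV
segments, ~200 fusion calls), the classifier oracle over all normal
count pairs up to depth 40, the filter oracle on 1,000 random records,
the CNV per-base oracle on 100 random toy-chromosome configurations and
the fusion oracle on 500 random calls. These sizes were chosen to
exercise every branch while keeping a full run in seconds on one core.

```{r quick-run}
report <- run_pipeline(run_config(
  sim = list(n_patients = 3,
             lesions_per_patient = c(P01 = 1L, P02 = 2L, P03 = 1L),
             target_size_mb = 5),
  seed = 7L, out_dir = file.path(tempdir(), "vignette_run")))
report
```

## Known limitations

* The somatic rule is count-based; it does not model strand bias,
  mapping quality or positional error profiles.
* Consensus is defined for exactly two CNV callers; generalising to *k*
  callers would require choosing a voting rule the source procedure does
  not define.
* The clonal partition is presence/absence sharing only — no cancer cell
  fractions, no phylogeny; lesions with diverging purity can demote a
  truncal variant to partial if the caller misses it in one lesion.
* The shipped actionable-gene list is a small illustrative table;
  real analyses should supply a licensed clinical database.
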