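# somaticflow

Downstream integration of matched tumor/normal whole-exome and
transcriptome caller output, for cancer-genomics analysts who receive
annotated variant calls, copy-number segments and fusion predictions from
upstream callers and need the post-calling half of the analysis: somatic
filtering and classification, mutational burden, cross-caller consensus,
and multi-lesion clonal interpretation.

The package grew out of the analysis pattern used for rare, driver-defined
tumor cohorts (the motivating case is PDGFRA D842V-mutant gastrointestinal
stromal tumors sequenced with their matched normals): a handful of
patients, some contributing several metastatic lesions, one truncal driver
mutation shared by every tumor, and a low mutational burden in which every
additional somatic event deserves scrutiny.

## What it computes

**Variant selection cascade.** Raw caller records are reduced to
high-confidence, rare, functionally relevant candidates by three strict
filters applied in order:

* depth/allele-fraction: total depth > 10 and Ratio > 0.2, where
  Ratio = alt reads / total reads (the VAF);
* functional consequence: coding non-silent effects plus variants at
  ±3 of splice sites;
* population rarity: frequency < 0.01 in *every* reporting database
  (novel variants pass).

**Somatic / germline / undetermined classification.** Each surviving
variant is tested against the matched-normal pileup: it is *somatic* when
the normal has total depth > 5 and essentially no alternate support
(0 alternate reads; 1 tolerated at depth ≥ 15; 2 at depth ≥ 30),
*undetermined* when the normal is uninformative (depth < 5; the boundary
depth of exactly 5 is treated conservatively as uninformative), otherwise
*germline*.

**Mutational burden.** Somatic, coding/splice-scope variants per megabase
of the merged capture target:

    burden = n_somatic / target_Mb

**CNV consensus.** Segments from two read-depth callers agree when a
same-state pair overlaps reciprocally by ≥ 80% and the reported
uncertainty (where present) is < 80; the consensus region is the
intersection. Consensus segments mostly covered by catalogued
copy-number-polymorphic regions are removed; per-chromosome gain/loss
fractions and focal gene-deletion queries (default focality ceiling 3 Mb)
summarise the rest.

**Fusion consensus and triage.** A fusion is retained when at least 2 of
the 4 predictors report the same ordered 5′→3′ gene pair in the same
sample (breakpoint coordinates are deliberately not matched). Retained
fusions are triaged into read-through/conjoined transcripts (adjacent
same-strand genes), intra-chromosomal and inter-chromosomal events.

**Clonal partition.** For patients with several sequenced lesions, somatic
variants are partitioned by lesion sharing into truncal (all lesions),
partial, and private sets, with a lesion × gene presence matrix and tile
plot.

**Synthetic cohorts with truth.** `simulate_cohort()` generates the whole
input bundle — per-sample VCFs, matched-normal pileups, two CNV tables,
four fusion tables, gene model, capture target, expression matrix — with
known somatic/germline labels, clonal assignments, true CNVs and true
fusions, so every stage can be scored against ground truth. Defaults: 14
patients / 19 tumor samples (one patient with 5 lesions, one with 2), a
30 Mb target at 60× mean depth, 0.5 somatic mutations per Mb, and a
PDGFRA driver locus truncal in every tumor.

## Worked example

```r
library(somaticflow)

report <- run_pipeline(run_config(sim = list(), seed = 7L,
                                  out_dir = "demo_run"))
print(report)
#> <somaticflow_report>
#>   variants: input=4282 -> depth_vaf=3737 -> functional=3169 -> rarity=1998
#>   status: germline=1715, somatic=262, undetermined=21
#>   mean burden: 0.460 /Mb; consensus CNVs: 122; consensus fusions: 57
#>   clonal partitions: P04, P06
```

Of 4,282 raw caller records, 1,998 survive the depth/VAF, functional and
rarity filters; classification against the matched normals calls 262 of
them somatic (21 sit on uninformative normals). The mean burden of
0.46 somatic mutations per Mb recovers the simulated rate of 0.5/Mb. The
two multi-lesion patients get clonal partitions:

```r
glance(report$clonal[["P06"]])
#> # A tibble: 1 × 6
#>   patient_id n_lesions n_variants n_truncal n_partial n_private
#> 1 P06                5         47         4         2        41
autoplot(report$clonal[["P06"]])   # lesion-by-gene tile plot
```

Per-sample burden and the CNV chromosome summary are plain tibbles
(`report$burden`, `report$cnv_summary`) with companion plots
(`plot_burden()`, `plot_cnv_summary()`).

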