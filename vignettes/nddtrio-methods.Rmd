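---
title: "Methods: family-based variant prioritization with nddtrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based variant prioritization with nddtrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nddtrio)
```

## What the package computes

nddtrio implements a family-based (trio/quad) prioritization pipeline for
whole-genome variant calls in neurodevelopmental disorder (NDD) cohorts.
Its input is the post-calling layer of a WGS study: multi-sample
short-variant VCFs per family, per-caller structural-variant (SV) call
sets, read-depth CNV segment tables, a pedigree, a curated gene table and
a variant annotation table. Its outputs are inheritance-labelled filtered
variants, consensus/merged/prioritized SVs, cross-class compound
heterozygotes, candidate/suggestive calls with a diagnostic-yield table
and group statistics, kinship QC, ACMG secondary findings, and
delta-log-likelihood scores for variants under a sequence model.

Alignment, variant calling and annotation generation are out of scope:
gnomAD frequencies, CADD, GERP, ClinVar/InterVar labels, ACMG classes and
AlphaMissense calls are consumed as annotation columns, exactly as a
pipeline downstream of Annovar/AnnotSV would consume them.

## The short-variant cascade

Retained short variants must satisfy, jointly:

1. **Site QC** — FILTER `PASS`, a single ALT allele, and a called proband
   genotype supported by at least `dp_min = 10` reads. Multiallelic
   records are excluded by default (a config switch decomposes them into
   per-ALT records instead).
2. **Frequency** — population allele frequency below
   `gnomad_af_max = 0.005` (a missing frequency passes, i.e. novel
   variants are treated as rare), **and** fewer than 5 heterozygous and
   fewer than 3 homozygous carriers in the internal cohort (all sequenced
   individuals). Both internal bounds are strict.
3. **Consequence** — functional region exonic or splicing; not
   synonymous; not labelled Benign/Likely benign by ClinVar *or*
   InterVar ("Conflicting" labels are not benign; unrecognized labels are
   conservatively kept); CADD_phred strictly above 20, with unassigned
   CADD passing.
4. **Gene list** — the gene symbol must be on the curated
   neurodevelopmental gene list. Records with no gene symbol cannot lie
   within a listed gene and are dropped.

The four annotation filters are pure conjunctions, so their order is
irrelevant; the test suite verifies the cascade against an independent
single-pass predicate oracle on randomized records.

### Inheritance labels

Each retained (variant, proband) pair gets exactly one label:

* `inherited_maternal` / `inherited_paternal` — one parent carries the
  allele and the other is confidently reference;
* `de_novo` — both parents sequenced, genotyped homozygous-reference at
  `dp_min` or more reads. Low-depth or missing parental calls demote to
  `unknown` rather than risking a false de novo from allele dropout;
* `putative_de_novo` — only one parental genome available and that parent
  is reference; the variant cannot be confirmed de novo;
* `homozygous_recessive` — homozygous proband, both parents heterozygous;
* `x_linked` — hemizygous male proband on the X contig (outside
  configured pseudoautosomal intervals), heterozygous mother, father not
  a carrier;
* `unknown` — anything ambiguous, e.g. both parents carriers.

A gene-level pass then relabels variants `composite_recessive` in any
proband that inherited at least one filtered variant from each parent in
the same gene; this is only attempted when both parents are sequenced,
since parental origin is otherwise unresolvable. Sibling genotypes are
reported but never veto a label.

## Structural variants

Two routes converge on family-level SVs:

* **Read-depth CNV segments** are kept when the log2 copy ratio exceeds
  +0.35 (gain) or falls below −0.4 (loss), with p-value < 1e-5 and
  weight > 20; surviving same-type segments closer than 50 kb are merged
  (min-start/max-end). Copy state is the sign of the log2 ratio.
* **Multi-caller consensus**: deletions and duplications smaller than
  500 kb are clustered per sample and type across callers by ≥ 50%
  reciprocal overlap (single linkage); clusters with at least two
  distinct callers survive. Insertions pass through from the manta-like
  caller and mobile-element insertions from the melt-like caller.
  Consensus breakpoints take the manta-like caller's coordinates when
  present (split-read precision) and the per-breakpoint median otherwise.
  The size cap is applied at the consensus stage.

Per-member calls are merged to family level when both breakpoints lie
within 1000 bp, producing one record with a carrier map from which
segregation is derived with the same carrier logic as for short variants.
Family-level SVs are then filtered: deletions/duplications need at least
1 bp of exon overlap in a listed gene; insertions/MEIs need a breakpoint
closer than 20 bp to such an exon; population frequency must be below
0.01 (a missing frequency counts as rare, matching how unannotated SVs
are treated in curated tables); and loci recurring in more than 10% of
enrolled families are removed (an absolute count rule is available via
`family_count_rule` — with 100 families the two coincide). Finally,
de novo or hemizygous SVs over a gene meeting the matching
dosage-sensitivity threshold (pHaplo ≥ 0.55 for deletions,
pTriplo ≥ 0.68 for duplications, pLI > 0.9 for insertions/MEIs) are
tier "high"; every other surviving SV stays tier "review", because
lower-sensitivity calls still warrant manual evaluation. Reported SV rows
are proband-centric: an SV carried only by a parent is retained in the
family merge output but not in the proband-level filtered set.

## Integration and yield

A variant is a **candidate** when its gene is an established NDD disease
gene, its ACMG class is not B/LB, and the observed inheritance is
compatible with the gene's inheritance mode (AD: de novo/putative/
inherited; AR: homozygous or composite recessive; XL: X-linked or de
novo). It is **suggestive** when the gene is on the broader
neurodevelopmental list but not established. The "phenotype match" and
"hot/warm VUS" judgments of a clinical workflow are not computable from
sequence, so they enter as inputs: the ACMG class vocabulary includes
`VUS_hot`/`VUS_warm`, and mode compatibility is the machine-checkable
part of the phenotype rule. Only candidates classified P, LP, or
hot/warm VUS count toward the diagnostic yield; a proband is positive
iff it carries at least one such variant.

Cross-class compound heterozygotes are probands with a filtered SV and a
filtered short variant in the same gene from opposite parents — the
configuration only WGS can expose in one analysis when one allele is
structural.

Secondary findings are screened on the *unfiltered* cohort genotypes
(parents included) and before any gene-list restriction, because the
ACMG reporting panel lies outside NDD gene lists: variants labelled
pathogenic/likely pathogenic by ClinVar, InterVar or both are reported
per carrier when heterozygous in a dominant panel gene or
homozygous/hemizygous in a recessive one.

## Kinship QC

Pairwise kinship uses the KING-robust between-family estimator on
autosomal, biallelic, PASS genotypes with depth ≥ 10 in both samples:

$$\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}}$$

with the heterozygote-concordance count in the numerator penalized by
opposite homozygotes, normalized by the two samples' heterozygote counts.
Self/MZ pairs give 0.5 exactly; parent-offspring and full-sibling pairs
concentrate near 0.25; unrelated pairs near 0. Declared relationships
are binned with the conventional cutpoints (first degree
[0.177, 0.354); unrelated < 0.0442), both configurable, since the source
tools' thresholds are conventions rather than published constants. All
declared parent-child and sibling pairs plus each family's mother-father
pair are evaluated; pairs without genotypes are skipped with a warning.

## Delta-likelihood scoring

For each short variant, an 8000-bp reference window is extracted with the
variant anchor at 0-based offset 4000 (1-based window
`[pos−4000, pos+3999]`); windows overhanging a contig edge shift inward,
never pad, and the shift is recorded. The variant window substitutes the
ALT base at the anchor (SNV), removes the deleted bases after the anchor
and extends downstream to restore the length (deletion; a symmetric
extension is available by config), or inserts bases after the anchor and
trims the window end (insertion). Both windows and their reverse
complements are scored; strands are averaged as the arithmetic mean of
total log-likelihoods; delta = ll(variant) − ll(reference). Degenerate
ref==alt input gives delta 0 for any deterministic scorer, and the
strand average makes delta invariant to pre-reverse-complemented input.

The scorer is a contract — any deterministic function from an
A/C/G/T/N string to a total log-likelihood. The package ships an order-5
Markov chain with add-one smoothing fitted on the reference as its
default scorer; positions whose context runs off the start, or whose
6-mer contains N, score as uniform log(1/4). A trained genomic language
model plugs into the same contract; its weights are deliberately not
part of this package, so any comparison against scores published for a
specific large model is out of reach here and statements in this
vignette are confined to what the shipped scorer computes.

ClinVar contextualization harmonizes raw clinical-significance labels
into P_LP / B_LB / VUS (conflicting interpretations are uncertain);
unknown labels are rejected loudly rather than silently binned. Genes
with more than 450 records have their B_LB and VUS records subsampled
(seeded) down to a total of 450, always keeping every P_LP record. A
variant's delta is then placed as an empirical percentile within each
category's distribution for its gene, and flagged pathogenic-like iff it
is at or below the gene's median P_LP delta. That median rule is this
package's numeric operationalization of "comparable to known P/LP
scores" — the underlying judgment is visual in clinical practice — and
the flag is reported as undefined when a gene has no scored P/LP record.

## Group statistics

Diagnostic yields are pure arithmetic on positive/negative counts per
clinical group (ASD, ID, ASD-ID), displayed at one decimal with the
unrounded value retained. Homogeneity across the R×2 table uses the
Pearson chi-squared statistic without continuity correction (df = R−1);
pairwise comparisons use a two-sided Fisher exact test implemented by
full hypergeometric enumeration with the minimum-likelihood convention
(sum all tables with fixed margins whose probability does not exceed the
observed one, with the customary 1+1e-7 floating-point tolerance). The
test suite checks this implementation against R's reference
implementation over an exhaustive small-table sweep. No multiple-testing
correction is applied to the pairwise tests.

## The synthetic cohort generator

Because patient genomes in family studies are not redistributable, the
package ships a generator whose defaults reproduce the cohort structure
of the study design it targets: 100 families with 10 multiplex quads
(110 probands), 10 trio probands with a single sequenced parent and one
no-parent quad (two probands without parental genomes; 298 sequenced
individuals), 71% male probands, and clinical groups in 40/27/43
proportion. Planted event counts follow the published filtered-variant
segregation where stated — 37 de novo, 33 X-linked, 5 homozygous
recessive — plus 6 cross-class compound (SV + short variant) probands, 6
composite-recessive and 20 inherited-candidate events, and 30
benign-noise variants; the last three counts are desk-scale choices, not
published figures.

What it emulates:

* founders in Hardy-Weinberg equilibrium at uniform MAFs with Mendelian
  transmission (background Mendelian-error rate is exactly 0 by
  construction; a genotype-error knob exists and defaults to 0 because
  the recovery targets assume clean genotypes);
* hemizygous X genotypes in males outside a configurable pseudoautosomal
  interval;
* per-caller SV call sets with per-caller sensitivity and Gaussian
  breakpoint jitter (defaults 1.0 and 20 bp — the clean-call condition
  that the 100%-recovery checks presuppose; dropout is a knob);
* read-depth segments at single-copy log2 targets of −1.0 (deletion) and
  +0.585 (duplication) with sd 0.05, sitting clearly beyond the segment
  filters at default noise;
* annotation columns constructed so each planted pathogenic event passes
  every cascade clause, while each benign-noise event fails exactly one
  named clause (non-PASS, low depth, common in gnomAD, too many internal
  heterozygotes/homozygotes, intronic, synonymous, benign label, low
  CADD, unlisted gene) — which makes per-filter attribution testable.

What it does **not** emulate: linkage disequilibrium, read-level error
profiles, caller-specific breakpoint biases, population structure,
mosaicism, and realistic genome/gene scale. Contigs are 3 × 300 kb
autosome-like sequences plus a 200-kb X-like contig carrying ~180 genes,
and the background marker set is 300 SNPs — sizes chosen so the full
pipeline and its tests run in seconds while every code path is
exercised. Passing recovery tests therefore demonstrates the logic of
the pipeline, not its behaviour under real-data noise.

Reference sequences are drawn from an order-2 Markov chain with two
favored bases per dinucleotide context (probability 0.49 each). This
gives the genome a biased k-mer spectrum, so a k-mer scorer fitted on it
assigns materially lower likelihoods to substitutions that create rare
k-mers ("disruptive") than to substitutions into the alternative favored
base ("neutral") — the desk-scale analogue of the separation between
pathogenic and neutral variants under a genomic language model. The
planting of these two classes uses the *generating* transition matrix,
keeping it independent of the fitted scorer it is later evaluated with.

## Numerical and design choices

* Intervals are half-open 0-based internally; VCF positions are 1-based;
  report output is 1-based inclusive. Converting twice is the identity.
* The "supported by at least 10 reads" wording is applied to the proband
  (the member the filter names explicitly); requiring depth in the
  proband plus confident parental genotypes for de novo labels covers
  the stricter readings' intent.
* Depth threshold is DP ≥ 10 ("at least"), following the procedural
  methods text over a figure caption that says "more than".
* Half-called genotypes default to missing (configurable), since no
  published treatment exists for them.
* Consensus reciprocal overlap (0.5) and family-merge breakpoint
  tolerance (1000 bp) are the common defaults of multi-caller merging
  tools; both are configurable because the source protocol does not
  state them.
* Kinship is computed for all declared pairs plus mother-father pairs;
  whether the source ran per family or jointly is unstated, and the
  estimator is pairwise either way.
* Simulation sizes used by the tests and the calibration script: 100
  trios × 20,000 SNPs for kinship calibration; the default synthetic
  cohort for recovery checks; ≥ 500 planted variants for the delta-score
  separation analysis.

## Known limitations

* The ACMG class, including hot/warm VUS status, is an input; the
  package does not re-derive ACMG evidence codes.
* The SV caller behaviour is simulated at the call level; no BAM-level
  evidence or breakpoint refinement exists.
* The shipped Markov scorer is a testing instrument. Its absolute delta
  values are not comparable to those of a trained genomic language
  model; only the protocol around the scorer (windows, strand averaging,
  delta, contextualization) is model-independent.
* Phasing is pedigree-based only: compound configurations are detected
  through parental origin, never from read-backed phasing.
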