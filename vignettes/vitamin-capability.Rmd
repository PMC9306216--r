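---
title: "Methods: vitamin biosynthesis capability and abundance profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vitamin biosynthesis capability and abundance profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitacap)
```

## The model

`vitacap` answers two questions about gut microbial communities. First, at
the genome level: can this organism synthesize a given B vitamin (or
menaquinone, K2) de novo? Second, at the community level: how much
biosynthetic gene content does each sample carry per vitamin, attributed
to which taxa, and how does it differ between groups of samples (gut
regions, diets)?

### Pathway knowledge base

The unit of pathway description is the **functional role**: the set of
KEGG orthologies (KOs) that perform the same reaction step. Roles exist
because the same step is often realized by non-orthologous genes (e.g.
the thiazole synthases thiG/thiH, or the four interchangeable pimeloyl-ACP
methyl ester esterases bioH/bioZ/bioG/bioK); collapsing KOs into roles is
what makes a completeness rule meaningful. A **pathway variant** is one
alternative route to a vitamin — an ordered list of roles with a subset
marked *indispensable*. The curated default covers the branch structure
that matters in anaerobic gut communities: thiamine's thiH vs thiO
thiazole branches, niacin's NaMNAT vs NMNAT adenylylation branches,
pyridoxine's DXP-dependent and R5P routes, biotin's pimelate (bioW) vs
malonyl-ACP (bioC + esterase) routes, menaquinone's classical (men) vs
futalosine (mqn) pathways, and folate, riboflavin and pantothenate as
single routes.

Cobalamin needs more structure. Its corrin-ring synthesis proceeds by an
anaerobic route (early cobalt insertion via the cbiK/cbiX chelatases) or
an aerobic route (late insertion via the cobN/cobS/cobT complex); both
converge on cob(II)yrinate a,c-diamide, after which a shared
**post-cobyrinate tail** (MMAB/cobO, cobQ, cbiB, cobP/cobU, cobS/cobV)
completes adenosylcobalamin. We encode this as two *full-route* variants
(anaerobic + tail, aerobic + tail, tagged `anaerobic`/`aerobic`) plus the
tail alone as a variant tagged `post_cobyrinate`. The tail-only variant is
deliberately excluded from producer determination — possessing only the
late steps does not make a de novo producer — which reconciles "producer
iff some variant is satisfied" with the biological requirement that a
complete producer satisfies (anaerobic or aerobic) *and* the tail.
Cobalamin also carries two utilization lists that mark consumers rather
than producers: transporters (btuB, btuF, btuC, btuD, cbrT, cbrV) and
cobalamin-dependent enzymes (metH, pduCDE, dhaB, mal, eutBC, kamDE, ordSE,
glmES, MCM, nrdJ, mcr, mtaA, mtaB, mtmB, mttB).

KO identity constraints: a KO may back at most one role *within* a vitamin
(so role and pathway aggregation never double-count), but may be shared
*across* vitamins (early tetrapyrrole steps legitimately serve several
pathways). Where KEGG merges anaerobic/aerobic orthologs into one KO
(cbiL/cobI, cbiH/cobJ, cbiF/cobM, cbiJ/cobK), the default curation keeps a
single role referenced by both routes. The shipped file is an explicitly
versioned best-effort curation; analyses that require fidelity to a
specific KEGG release should load their own JSON (the schema ships in
`inst/extdata/`). All of the package's correctness tests run on synthetic
knowledge bases, so nothing downstream depends on the curation's
biological accuracy.

### Capability calls

A genome satisfies a variant when **every indispensable role has at least
one of its KOs** in the genome's annotation; it is a producer of a vitamin
when it satisfies at least one de novo route. The call is monotone (adding
annotations can only add verdicts) and reports, per unsatisfied variant,
exactly which indispensable roles are missing — the unit of interpretation
for missing-gene archetypes such as Prevotella-like genomes lacking
cysG/cbiL/cbiJ/cbiT/cbiE in the anaerobic route, or Methanobrevibacter-like
genomes stalled before adenosylcobalamin by the loss of MMAB and cobP.

Quality gates precede capability calls: completeness strictly above 90%
and contamination strictly below 5%, the conventional "high-quality MAG"
gate. Strict inequalities mean boundary genomes (completeness exactly 90)
are rejected. Filtering happens *before* prediction, not after, so
reported producer counts refer to the high-quality set. Genome sizes can
be corrected for incompleteness and contamination as
`assembly_size × (100/completeness) × (1 − contamination/100)`; the exact
rescaling formula is this package's choice of the standard correction.

Cobalamin typology: `complete` (a full route satisfied), `partial` (at
least one biosynthesis role present but no complete route), `absent`.
Transporter and dependent-enzyme presence are independent facets; a single
transporter gene suffices (we do not require a complete btuFCD ABC
system — an intact ECF/ABC requirement can be layered on by the caller).
Core-function comparisons between producer and non-producer sets use a
strict prevalence rule ("more than 90%" means > 0.9, so 9/10 is not core),
and "core KOs only present in producers" defaults to the strictest
existence reading — absent from every non-producer genome — with a
documented `core_difference` relaxation.

### Abundance profiling

Gene profiles use transcripts-per-million over the **whole** gene catalog:
`tpm = (c/L) / Σ(c/L) × 10⁶`. The denominator scope matters: profiling the
entire catalog and then subsetting to vitamin genes yields different (and
smaller) absolute values than renormalising within vitamin genes, and is
what keeps contrasts interpretable when only a few pathways change.
Columns with any signal sum to exactly 10⁶; all-zero samples stay zero
rather than erroring, since partial runs are common. Counts are consumed
as given (reads or fragments — the caller's mapping pipeline decides the
unit).

Aggregation is summation: KO = its genes, role = its KOs, pathway = the
vitamin's KO set with each KO counted once even when several variants
reference it, taxon = the vitamin's genes grouped by phylum or genus with
an explicit `unassigned` bucket so taxon totals always reconstruct the
pathway abundance. A gene annotated to two KOs (one row per KO in the
input dialect) contributes its full TPM to each.

### Group statistics

Richness counts entities with positive abundance (no rarefaction);
Shannon uses the natural logarithm (vegan's convention), with all-zero
rows defined as 0. Bray–Curtis distances come from `vegan::vegdist`, with
the pair-of-empty-samples case defined as distance 0. PCoA is classical
scaling (`stats::cmdscale`); negative eigenvalues are dropped without
Lingoes/Cailliez correction and their total magnitude reported.

AMOVA follows the Excoffier squared-distance decomposition as implemented
in mothur: `SS_total = Σ_{i<j} d²/N`, within-group sums divided by group
size, and `Fs = (SS_among/(k−1)) / (SS_within/(N−k))`. Significance uses
random label permutations with the add-one estimator
`p = (1 + #{Fs* ≥ Fs})/(1 + B)` (B = 1000 by default), so p is never 0 and
has resolution 1/(B+1); the stream is seeded and invariant to group
renaming. Exceedance uses a 1e−12 tolerance so floating-point ties count
as exceedances.

Wilcoxon rank-sum tests are exact (distribution enumeration) when the
pooled size is ≤ 12 with no ties, otherwise normal approximation with
midranks, tie correction and continuity correction — the two regimes of
`stats::wilcox.test`, pinned down so the exact branch is testable against
full enumeration. Tests are two-sided throughout; the conventional raw
P < 0.05 screen is the default, with Benjamini–Hochberg available.
Differential enrichment assigns direction by the larger group median
(ties → none) and flags entities at raw p < alpha.

The LDA effect size follows the LEfSe convention, which the literature
usually cites by its threshold ("significant at |LDA score| > 3") without
internals, so the internals are fixed here explicitly: samples are scaled
to a 10⁶ total (the [1, 10⁶] axis); each feature is screened by rank-sum
test; a one-dimensional linear discriminant (`MASS::lda`, unit-norm
direction, with a standardized mean-difference fallback for degenerate
fits) is fitted on 30 bootstrap rounds of two-thirds subsamples per group;
the per-feature effect is the bootstrap mean of
`(w_j · Δ_projection + Δ_raw_means)/2`, and the reported score is
`sign × log10(1 + |effect|)`. Defaults: threshold 3, screen alpha 0.05.
Constant features score 0 and are never significant.

## Synthetic data: what it emulates and what it does not

The generator plants machine-readable truth at three levels.

**Knowledge bases** (`make_kb`): configurable role/variant/KO counts;
cobalamin always tri-segmented with utilization lists; all roles
indispensable (keeps retention arithmetic exact); synthetic KO ids are
globally unique, so vitamins never share KOs.

**Genomes** (`simulate_genomes`): planted producers receive every KO of a
randomly chosen route; non-producers receive a random KO subset with one
indispensable role per route fully removed, so no route can be satisfied
and the truth is unambiguous rather than merely probable. Annotation
dropout then removes each KO independently with probability d; a planted
producer therefore still validates with probability
`Π_r (1 − d^{k_r})` over the route's roles (k_r = KOs per role), which is
the yardstick the dropout tests use. Quality numbers are drawn in the
high-quality range (completeness 92–99.9, contamination 0–4.9) and
taxonomy from a fixed 5-phylum/12-genus ontology of dominant rumen taxa.

**Communities** (`simulate_community`): one gene per genome × KO plus
unannotated background genes at one per 2 kb of assembly — prokaryotic
gene density — so vitamin genes are a small, realistic fraction of the
catalog (about 2%) and the TPM denominator is background-dominated, as in
a real whole-metagenome catalog. This matters: without background, TPM's
compositionality would turn "seven pathways up, one unchanged" into
"one pathway spuriously down". Gene lengths are uniform on 300–3000 bp;
genomes get lognormal baseline abundances (sdlog 1) and per-sample
lognormal jitter (sdlog 0.3, a between-animal variance scale typical of
rumen profiles); group fold changes multiply the vitamin genes' expected
read weights so pathway fold changes hold in expectation; counts are
multinomial at fixed depth (10⁶ by default), keeping per-sample depth
exact and TPM denominators stable (a Poisson scheme would jitter depth to
no analytical benefit).

Two presets encode the package's study designs. `diet`: CON vs HG, 12
samples each, cobalamin ×0.5 (inhibited), pyridoxine ×1.0 (null), the
other seven vitamins ×1.3 (enhanced). `region`: RUM/ILE/CEC, 8 samples
each, thiamine/niacin/pyridoxine ×1.5 in the large-intestine group.

What the generator does **not** emulate: phylogenetic correlation of gene
content (capabilities are drawn independently per genome), strain-level
gene sharing, read-level artefacts (no FASTQ simulation — mapping and
annotation noise are summarized as KO dropout), compositional interactions
beyond the closed multinomial, and realistic covariance between taxa.
Passing the planted-truth tests therefore demonstrates that the
*computations* are correct under the stated generative model, not that
the model captures every property of real rumen data.

## Numerical choices and degenerate inputs

* TPM: all-zero sample columns → all-zero output, no division by zero.
* Bray–Curtis between two all-zero samples → 0; NaNs from vegan are
  patched under this documented convention.
* PCoA with no positive eigenvalues (all points coincident) → all-zero
  coordinates with a warning; fewer positive axes than requested → fewer
  axes with a warning.
* Shannon of an all-zero row → 0; richness 0.
* Rank test on empty samples → error; constant LDA features → score 0.
* AMOVA requires ≥ 2 groups of ≥ 2; permutation exceedance tolerance
  1e−12.
* Unknown KOs in genome annotations are ignored by design — whole-genome
  annotations far exceed the knowledge base's universe.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  identical calls are byte-identical; the pipeline writes md5 manifests
  to make this auditable.

## Problem sizes used in the checks

The verification suite (and `scripts/acceptance.R`) uses: 1000 random
knowledge-base/genome pairs against a brute-force checker; 200 genomes ×
9 vitamins for zero-dropout recovery; 100 random matrices for TPM
normalisation; all 874 rank configurations with 2 ≤ n, m ≤ 5 for the
exact Wilcoxon branch; 1000 replicates × 1000 permutations for AMOVA
type-I error; 40 simulated diet studies at depth 10⁶ for contrast power;
50 planar points for PCoA recovery; and 50 seeds × fold changes
{2, 10, 100, 1000} for LDA monotonicity. These sizes give the acceptance
checks binomial standard errors comfortably below the bands they assert.

## Known limitations

* The default knowledge base is a curation, not a KEGG release export;
  KO assignments for a handful of accessory genes (bioZ/bioG/bioK
  esterases, cbrT/cbrV transporters, several cobalamin-dependent enzymes)
  are best-effort.
* Capability is presence-based: it ignores gene expression, enzyme
  integrity and regulatory context, and annotation dropout biases calls
  toward non-producer (quantified by the retention bound above).
* LDA effect sizes are defined for exactly two groups; multi-group
  designs need one-vs-rest framing by the caller.
* TPM is compositional; cross-sample comparisons of absolute biosynthetic
  capacity require external calibration that is out of scope here.
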