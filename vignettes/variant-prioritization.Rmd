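---
title: "Family-based exome variant prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based exome variant prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famprior)
```

## The problem

When a rare disease such as pulmonary arterial hypertension (PAH) clusters
in a family and a targeted panel of established risk genes comes back
negative, the next step is whole-exome sequencing of the affected members
and as many relatives as possible, followed by a prioritization cascade
that reduces tens of thousands of coding variants to a handful of
candidates. `famprior` implements that cascade as a tested, reusable
pipeline: every filter is an explicit, configurable predicate, every
decision is recorded in a per-variant trace, and a seeded synthetic-data
generator lets the whole chain be verified offline, with no access to
patient data.

The cascade, in the order `run_prioritization()` executes it:

1. **Per-genotype quality control.** Each genotype call must satisfy
   minimum read depth, minimum genotype quality (GQ) and an allele-balance
   window. A failing genotype is demoted to *missing* rather than
   discarding the variant for the whole family — one badly sequenced
   sample should not delete a true causal variant; the segregation step
   decides what missingness implies.
2. **Known-gene panel pre-screen.** Variants in a configured panel of
   established disease genes are set aside and reported separately: a
   pathogenic panel hit would end a diagnostic search, and only
   panel-negative families proceed to discovery.
3. **Segregation analysis** under explicit inheritance models, per family
   (see below).
4. **Population frequency and novelty.** Variants whose allele frequency
   in any configured control database (gnomAD exomes/genomes, Kaviar,
   Beacon, Bravo, ESP, 1000G phase III in the default schema) is strictly
   above the cutoff (default 1%) are removed; a variant reported absent or
   at exactly zero everywhere is additionally flagged *novel*.
5. **Pathogenicity assessment, tiering and ranking** from the in-silico
   annotations carried in the VCF: a dbNSFP-style per-tool call vector and
   a phred-scaled CADD score. These scores are consumed as annotations,
   never recomputed.

## Inheritance models

`segregate()` evaluates a declarative predicate per family:

* `dominant_complete` — every affected member carries the alternate allele
  (het or hom-alt) and every unaffected member is hom-ref.
* `dominant_incomplete` — every affected member is a carrier; unaffected
  members are unconstrained. This is the model required by a dominant
  family in which an obligate carrier remains healthy — the classic
  incomplete-penetrance pattern, and the reason a hard
  "unaffected must be hom-ref" rule would destroy true positives in
  late-onset or multi-hit diseases.
* `de_novo` — the designated proband is a carrier and **both** parents are
  *confidently* hom-ref: hom-ref genotype with depth and GQ at or above
  the QC thresholds. Requiring confident absence rather than mere absence
  guards against allele dropout in an undersequenced parent. The proband
  defaults to the first affected member with both parents in the
  pedigree; a config override is available. Requesting `de_novo` in a
  family with no such member is an `incomplete trio` error.
* `recessive_hom` — every affected member is hom-alt, every genotyped
  parent of an affected member is het, and no unaffected member is
  hom-alt. Compound heterozygosity is deliberately out of scope: it
  requires phasing this pipeline does not perform.

Hom-alt counts as a carrier in the dominant models (dominance concerns
allele presence). Members of unknown phenotype are excluded from
segregation constraints but still transmit genotypes. Sex chromosomes are
treated autosomally; X-linked models are a non-goal. When a genotype the
model needs is missing (including QC-demoted ones), the result is
*uninformative* and never compatible — missingness can veto but never
create a candidate.

Every model also exists as `brute_force_segregation()`, an independently
written predicate on raw genotype vectors, capped at 8 members. The test
suite enumerates all $3^n$ genotype assignments for a trio (27), a quartet
(81) and a six-member family (729) under all four models and demands exact
agreement with the engine — the oracle shares no helper code with it.

## Pathogenicity aggregation, tiers and ranking

Predictor calls are normalized to a three-value code
(damaging / tolerated / unknown) through a configurable per-tool
translation table; unknown calls are excluded from the denominator, so a
nonsense variant sparsely covered by missense predictors naturally reports
a smaller denominator (5/9) than a missense variant (12/19). With no
informative call at all the damaging fraction is undefined — not zero —
and the CADD gate alone decides.

Tiers:

* **Tier 1** — protein-truncating consequences (stop-gain; frameshift and
  splice classes are honoured when annotated).
* **Tier 2** — missense with damaging fraction ≥ 0.5 *and* CADD ≥ 20.
* **Tier 3** — everything else that survived the hard filters.

No published numeric priority function exists for this step, so the
ranking is deliberately lexicographic rather than a weighted score: tier
ascending, then CADD descending (missing last), then damaging fraction
descending, then genomic coordinate. This reproduces the qualitative
ordering practitioners expect (a truncating variant outranks a damaging
missense) without inventing weights, and makes reports reproducible
byte-for-byte. By default the candidate report keeps tiers 1–2
(`max_report_tier = 2`): tier 3 exists so that nothing silently
disappears — tier-3 survivors are visible through the verbose trace — but
a default report that ends with "and 400 bland leftovers" would bury the
signal the cascade exists to find.

`codon_of()` (`ceiling(cdna_pos / 3)`) and `parse_hgvs_p()` cross-check
cDNA and protein coordinates; `spike_spec()` refuses inconsistent pairs.
Of note for the two shipped example variants: the TNIP2 spike encodes
c.697A>G — the substitution actually consistent with Ser233Gly at a
codon-first position, where descriptions elsewhere vary between A>C and
A>G — and the TRAF2 spike encodes c.417C>A (cytosine to adenine),
producing Cys139Ter.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_depth` | 10 | reads | below ~10x a diploid genotype is unreliable |
| `min_gq` | 20 | phred | 1% genotype error ceiling |
| `het_ab_range` | 0.25–0.75 | alt fraction | balanced support for a true het |
| `min_hom_alt_fraction` | 0.85 | alt fraction | residual ref reads tolerated |
| `max_pop_af` | 0.01 | frequency | "above 1%" removal, strict `>` |
| `min_damaging_fraction` | 0.5 | fraction | majority of informative tools |
| `min_cadd` | 20 | phred | top 1% genome-wide deleteriousness |
| `penetrance` (simulator) | 0.75 | probability | leaves unaffected carriers plausible |
| `depth_mean`, `depth_dispersion` | 60, 10 | reads | typical exome coverage, negative binomial |

All are config-overridable; the quality thresholds are field-standard
values, stated here as this package's defaults. Two boundary decisions are
worth naming explicitly. First, the frequency rule removes *strictly
above* the cutoff, so an AF of exactly 0.01 is retained (and not novel).
Second, the cutoff is applied to the **maximum** AF across configured
databases rather than per-database; this is the stricter reading and the
report's trace records the maximum used. A called genotype whose DP or GQ
field is absent from the VCF is not failed on that rule — the rule cannot
be evaluated — rather than failing every record from a caller that omits
those fields.

## What the simulator emulates — and what it does not

`simulate_family()` draws the causal genotype by Mendelian transmission
from founder carriers (dominant), from het×het parents (recessive), or by
construction (de novo: proband het, parents hom-ref), then assigns
affection status: carriers are affected with probability `penetrance`,
non-carriers are never affected (no phenocopies). At least one affected
member is guaranteed by deterministic resampling on an incremented seed
stream. `generate_vcf()` adds:

* the spiked causal variants, fully annotated from their `spike_spec()`s;
* one **decoy per requested class**, each violating *exactly one* filter
  while otherwise looking causal: `qc_fail` (carriers at depth 4),
  `common_af` (gnomAD-exomes AF 0.05, zero elsewhere), `non_segregating`
  (carried by an unaffected member only), `benign_prediction` (1/19
  damaging, CADD 2), `panel_gene` (an otherwise-causal BMPR2 variant);
* a background of non-causal variants, alternately common (AF 2–40%) or
  rare-but-benign.

Depth is negative-binomial (mean 60, dispersion 10), GQ and allelic depths
are sampled per call, and all randomness flows from the master seed
through per-variant derived streams, so adding background variants never
perturbs spiked genotypes and identical seeds give byte-identical files.

Three deliberate simplifications define what passing tests do and do not
show. Causal spike-in calls are drawn inside the quality envelope (depth
clamped ≥ 15, allele balance 0.40–0.60): complete recovery at zero
genotype error is a *structural* contract of the generator, and quality
degradation is modelled explicitly through `genotype_error_rate` and the
`qc_fail` decoy instead of leaking randomly into every replicate. Decoys
themselves receive no genotype errors, because a random flip would break
the "violates exactly one filter" property they exist to test. And the
coordinate space is a toy two-contig genome: no real build, no linkage
structure, no annotation noise, no multi-gene transcripts. Recovery and
rejection rates on these data therefore validate the *logic* of the
cascade, not its performance on real exomes, where caller artifacts,
segmental duplications and annotation disagreements dominate.

One trace-attribution subtlety: a `qc_fail` decoy is only *visible* as a
segregation failure (its carrier genotypes are demoted to missing). The
pipeline therefore re-evaluates segregation on the raw genotypes whenever
the masked ones fail; if the raw pattern was compatible, the failure is
attributed to the `genotype_qc` stage and the segregation stage records
that the pattern was compatible before quality masking. Every rejected
variant thus names exactly one failing stage.

## Network proximity

The interaction-graph step is supporting evidence, never a filter: each
candidate gene is annotated with its breadth-first distance to the nearest
member of a seed set of established disease genes on a user-supplied,
unweighted edge list (an offline surrogate for a STRING export used
qualitatively). On the illustrative bundled edge list, TRAF2 sits at
distance 1 from the seed set through its direct CAV1 interaction, while
TNIP2 reaches it only through NF-κB components (distance 4). Confidence
scores are not modelled. The bundled list encodes only a handful of
well-known relations and is labelled illustrative; real analyses should
supply their own export.

## Worked example

```{r example, eval = FALSE}
fx <- make_paper_fixture()
res <- run_prioritization(fx$vcf, fx$ped, fx$config)
res
#> famprior result: 2 candidate(s); 1 panel-gene hit(s)
#>   rank tier  gene                  hgvs_p consequence cadd
#> 1    1    1 TRAF2 NP_066961.2:p.Cys139Ter   stop_gain 35.0
#> 2    2    2 TNIP2 NP_077285.3:p.Ser233Gly    missense 25.8
#>             segregation_model
#> 1 dominant_incomplete+de_novo
#> 2         dominant_incomplete
```

The fixture is the package's canonical study design: Family 1, six
sequenced members, two affected het carriers of the TNIP2 missense
variant plus one unaffected het sibling (hence `dominant_incomplete`;
`dominant_complete` rejects the pattern), and Family 2, a trio in which
the TRAF2 nonsense variant is de novo in the proband. The fixture's
carrier and affection pattern is hard-coded rather than sampled — the true
penetrance of such variants is unknown, and the fixture asserts none. Its
six-member topology places the index and her spouse as founders, three
children, and the index's unaffected sibling as a founder carrier (the
siblings' unsequenced parents are omitted rather than carried as no-call
rows).

## Problem sizes and numerical choices

The shipped tests run the exhaustive oracle comparison (27 + 81 + 729
assignments × 4 models), 100 seeded end-to-end recovery replicates
(50 dominant, 50 de novo), and a 45-replicate error-rate monotonicity
sweep; the acceptance script repeats the cascade, the enumeration and 50
replicates from a caller-supplied seed. These sizes were chosen as the
smallest that exercise every code path exhaustively where enumeration is
feasible and estimate rates stably where it is not. Ties in ranking break
on genomic coordinates; character sorting of stage names and decoy plans
is fixed at generation time; all derived seeds stay below $2^{31}$.

## Limitations

* Single-allele logic after decomposition: no phasing, no compound-het
  recessive model, no structural or copy-number variants, no gVCF.
* Annotations are trusted inputs; the pipeline never recomputes CADD or
  any constituent predictor, and disagreements between annotation engines
  are invisible to it beyond the codon-consistency check.
* Kinship is taken from the PED file at face value — no relatedness
  verification, no Mendelian-error rate estimation, no mosaicism model.
* The synthetic generator validates pipeline logic, not real-exome
  performance (see above).
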