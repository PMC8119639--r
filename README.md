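# famprior

Family-based whole-exome variant prioritization for rare-disease studies.

When a disease such as pulmonary arterial hypertension clusters in a
family and a targeted panel of known risk genes is negative, the standard
next step is whole-exome sequencing of affected members and relatives
followed by a prioritization cascade. `famprior` implements that cascade
as a tested R package:

1. **per-genotype QC** — depth ≥ 10, GQ ≥ 20, het allele balance in
   [0.25, 0.75], hom-alt fraction ≥ 0.85; failing genotypes are demoted to
   missing, not discarded globally;
2. **known-gene panel pre-screen** — panel hits are reported separately
   from discovery candidates;
3. **segregation analysis** per family under explicit inheritance models:
   autosomal dominant with complete or incomplete penetrance
   (every affected is a carrier; unaffected carriers tolerated), de novo
   (proband carrier, both parents *confidently* hom-ref), and homozygous
   recessive — each model also implemented as an independent brute-force
   oracle used in exhaustive 3^n testing;
4. **population frequency / novelty** — removal strictly above 1% maximum
   AF across the configured control databases (gnomAD, Kaviar, Beacon,
   Bravo, ESP, 1000G in the default schema); novel = absent or zero
   everywhere;
5. **pathogenicity** — dbNSFP-style predictor aggregation ("m of n tools
   damaging", unknown calls excluded from the denominator) plus a CADD
   gate: tier 1 = truncating, tier 2 = missense with damaging fraction
   ≥ 0.5 and CADD ≥ 20, ranked tier → CADD → damaging fraction →
   coordinate;
6. **network proximity** — breadth-first distance of each candidate gene
   to a seed set of established disease genes on a user-supplied edge
   list (annotation only, never a filter).

A seeded synthetic-data generator produces pedigrees and annotated
multi-sample VCFs with the inheritance structure the cascade assumes —
including decoy variants that each violate exactly one filter — so the
whole pipeline is verifiable offline.

## Worked example

```r
library(famprior)
fx  <- make_paper_fixture()                       # two-family demo dataset
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

The fixture encodes the package's canonical study design. Family 1: six
sequenced members, two affected heterozygous carriers of a novel TNIP2
missense variant (c.697A>G, p.Ser233Gly, 12/19 predictors damaging, CADD
25.8) plus one unaffected carrier sibling — compatible with dominant
inheritance only under incomplete penetrance. Family 2: a trio whose
proband carries a de novo TRAF2 nonsense variant (c.417C>A, p.Cys139Ter,
5/9, CADD 35). The truncating variant ranks first (tier 1); every decoy
(QC-failing, common, non-segregating, benign, panel-gene) is rejected with
a filter trace naming exactly the violated filter. `write_candidate_report()`
writes the ranked table as TSV with the full trace per row.

A thin command-line interface wraps the same functions:

```sh
exec/famprior simulate --scenario paper --seed 104729 --out demo/
exec/famprior run --vcf demo/cohort.vcf --ped demo/cohort.ped \
    --config demo/famprior.yaml --out demo/report.tsv --verbose-trace
```

See the methods vignette (`vignettes/variant-prioritization.Rmd`) for the
models, parameter rationale and the simulator's scope.

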