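Package: famprior
Title: Family-Based Whole-Exome Variant Prioritization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for prioritizing candidate disease
    variants from family-based whole-exome sequencing. Reads annotated
    multi-sample VCFs and 6-column PED pedigrees; applies per-genotype
    quality filters (depth, genotype quality, allele balance), a known-gene
    panel pre-screen, pedigree segregation analysis under explicit
    inheritance models (autosomal dominant with complete or incomplete
    penetrance, de novo, homozygous recessive), population allele-frequency
    and novelty filters, and in-silico pathogenicity aggregation
    (dbNSFP-style predictor tallies plus a CADD gate) to produce a ranked,
    tiered candidate report with a complete per-variant filter trace. Also
    provides graph-proximity triage of candidate genes against a seed set of
    known disease genes on a user-supplied interaction edge list, and a
    seeded synthetic-data generator that emulates dominant families with
    incomplete penetrance and de novo trios, including decoy variants that
    each violate exactly one filter, so the whole cascade is verifiable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
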