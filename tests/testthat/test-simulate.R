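# independent trio-consistency predicate: the child's alt-allele count must
# be expressible as one transmitted allele from each genotyped parent
mendelian_consistent <- function(ped, gt) {
  alt_of <- c(hom_ref = 0, het = 1, hom_alt = 2)
  gives <- function(g) switch(g, hom_ref = 0, het = c(0, 1), hom_alt = 1)
  for (i in seq_len(nrow(ped))) {
    fa <- ped$father_id[i]; mo <- ped$mother_id[i]
    if (is.na(fa) || is.na(mo) || !fa %in% ped$id || !mo %in% ped$id) next
    kid_alt <- alt_of[gt[ped$id[i]]]
    ok <- any(outer(gives(gt[fa]), gives(gt[mo]), `+`) == kid_alt)
    if (!ok) return(FALSE)
  }
  TRUE
}

test_that("de novo trios are built by construction", {
  cfg <- synthetic_family_config(template = "trio", model = "de_novo",
                                 penetrance = 1, seed = 42)
  fam <- simulate_family(cfg)
  ped <- fam$pedigree
  proband <- ped$id[!is.na(ped$father_id)]
  expect_equal(fam$genotypes[[proband]], "het")
  parents <- setdiff(ped$id, proband)
  expect_true(all(fam$genotypes[parents] == "hom_ref"))
  expect_equal(ped$affected[ped$id == proband], "affected")
  expect_true(all(ped$affected[ped$id %in% parents] == "unaffected"))
})

test_that("full penetrance leaves no unaffected carriers", {
  for (seed in 1:20) {
    cfg <- synthetic_family_config(template = "six_member_two_affected",
                                   model = "dominant_complete",
                                   penetrance = 1, seed = seed)
    fam <- simulate_family(cfg)
    carriers <- names(fam$genotypes)[fam$genotypes != "hom_ref"]
    status <- fam$pedigree$affected[match(carriers, fam$pedigree$id)]
    expect_true(all(status == "affected"))
  }
})

test_that("incomplete penetrance can leave an unaffected carrier", {
  seen_unaffected_carrier <- FALSE
  for (seed in 1:40) {
    cfg <- synthetic_family_config(template = "six_member_two_affected",
                                   model = "dominant_incomplete",
                                   penetrance = 0.6, seed = seed)
    fam <- simulate_family(cfg)
    expect_gte(sum(fam$pedigree$affected == "affected"), 1)
    carriers <- names(fam$genotypes)[fam$genotypes != "hom_ref"]
    status <- fam$pedigree$affected[match(carriers, fam$pedigree$id)]
    if (any(status == "unaffected")) seen_unaffected_carrier <- TRUE
  }
  expect_true(seen_unaffected_carrier)
})

test_that("simulated genotypes obey Mendelian transmission at zero error", {
  for (seed in 1:25) {
    for (model in c("dominant_incomplete", "de_novo", "recessive_hom")) {
      template <- if (model == "de_novo") "trio" else "quartet"
      cfg <- synthetic_family_config(template = template, model = model,
                                     penetrance = 0.9, seed = seed)
      fam <- simulate_family(cfg)
      if (model == "de_novo") next   # de novo violates transmission by design
      expect_true(mendelian_consistent(fam$pedigree, fam$genotypes))
    }
  }
})

test_that("a missing seed or bad decoy type is rejected", {
  expect_error(synthetic_family_config(), "seed is mandatory")
  expect_error(synthetic_family_config(seed = 1, decoy_plan = "nonsense_decoy"),
               "unknown decoy")
  expect_error(
    simulate_family(synthetic_family_config(template = "six_member_two_affected",
                                            model = "de_novo", seed = 1)),
    NA)  # six-member template has a child with both parents: de novo allowed
})

test_that("identical seeds produce byte-identical VCF and PED files", {
  out1 <- simulate_scenario("dominant", seed = 77, dir = tempfile("sim1"))
  out2 <- simulate_scenario("dominant", seed = 77, dir = tempfile("sim2"))
  expect_identical(readLines(out1$vcf), readLines(out2$vcf))
  expect_identical(readLines(out1$ped), readLines(out2$ped))
  out3 <- simulate_scenario("dominant", seed = 78, dir = tempfile("sim3"))
  expect_false(identical(readLines(out1$vcf), readLines(out3$vcf)))
})

test_that("the common-AF decoy is the one variant above the frequency cutoff at zero AF elsewhere", {
  out <- simulate_scenario("dominant", seed = 5, dir = tempfile("simaf"))
  ped <- read_ped(out$ped)
  recs <- read_annotated_vcf(out$vcf, pedigree = ped)
  decoy <- Filter(function(r) identical(r$annotation$gene, "DECOY_AF"), recs)
  expect_length(decoy, 1)
  afs <- decoy[[1]]$annotation$pop_afs
  expect_equal(unname(afs["gnomad_exomes"]), 0.05)
  expect_true(all(afs[names(afs) != "gnomad_exomes"] == 0))
})

test_that("the TRAF2 spike is annotated 5/9 damaging, CADD 35, stop-gain", {
  out <- simulate_scenario("denovo", seed = 9, dir = tempfile("simtr"))
  recs <- read_annotated_vcf(out$vcf, pedigree = read_ped(out$ped))
  traf2 <- Filter(function(r) identical(r$annotation$gene, "TRAF2"), recs)
  expect_length(traf2, 1)
  ann <- traf2[[1]]$annotation
  agg <- aggregate_predictors(ann$predictor_calls)
  expect_equal(agg$n_damaging, 5)
  expect_equal(agg$n_informative, 9)
  expect_equal(ann$cadd, 35)
  expect_equal(ann$consequence, "stop_gain")
  expect_true(all(ann$pop_afs == 0))
})

test_that("the worked-example fixture encodes the two-family study design", {
  fx <- make_paper_fixture(tempfile("fxsim"))
  ped <- read_ped(fx$ped)
  fams <- split_families(ped)
  expect_named(fams, c("F1", "F2"))
  expect_equal(nrow(fams$F1), 6)
  expect_equal(sum(fams$F1$affected == "affected"), 2)
  expect_equal(nrow(fams$F2), 3)

  recs <- read_annotated_vcf(fx$vcf, pedigree = ped)
  tnip2 <- Filter(function(r) identical(r$annotation$gene, "TNIP2"), recs)[[1]]
  seg <- segregate(tnip2, fams$F1, "dominant_incomplete")
  expect_true(seg$compatible)
  expect_equal(seg$affected_carriers, 2)
  expect_equal(seg$unaffected_carriers, 1)

  traf2 <- Filter(function(r) identical(r$annotation$gene, "TRAF2"), recs)[[1]]
  expect_true(segregate(traf2, fams$F2, "de_novo")$compatible)
})
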