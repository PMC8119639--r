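test_that("the dominant family with an unaffected carrier needs incomplete penetrance", {
  v <- family1_variant()
  ped <- six_ped()
  inc <- segregate(v, ped, "dominant_incomplete")
  expect_true(inc$compatible)
  expect_true(inc$informative)
  expect_equal(inc$affected_carriers, 2)
  expect_equal(inc$unaffected_carriers, 1)
  expect_equal(inc$affected_noncarriers, 0)
  # complete penetrance rejects the unaffected carrier
  expect_false(segregate(v, ped, "dominant_complete")$compatible)
})

test_that("de novo requires a carrier proband and confident hom-ref parents", {
  ped <- trio_ped()
  v <- make_variant(c("I.1" = "hom_ref", "I.2" = "hom_ref", "II.1" = "het"),
                    depth = 40)
  res <- segregate(v, ped, "de_novo")
  expect_true(res$compatible)
  expect_equal(res$proband, "II.1")

  # shallow parental coverage is not confident absence
  v_shallow <- variant_record("1", 1000, "A", "G", {
    calls <- make_calls(c("I.1" = "hom_ref", "I.2" = "hom_ref", "II.1" = "het"))
    calls$depth[calls$sample_id == "I.1"] <- 5
    calls
  }, annotation_bundle())
  shallow <- segregate(v_shallow, ped, "de_novo")
  expect_false(shallow$compatible)
  expect_true(shallow$informative)

  # a missing parental genotype makes the call uninformative, never compatible
  v_missing <- make_variant(c("I.1" = "missing", "I.2" = "hom_ref",
                              "II.1" = "het"))
  missing <- segregate(v_missing, ped, "de_novo")
  expect_false(missing$compatible)
  expect_false(missing$informative)

  # carrier parent: informative incompatibility
  v_inherited <- make_variant(c("I.1" = "het", "I.2" = "hom_ref",
                                "II.1" = "het"))
  expect_false(segregate(v_inherited, ped, "de_novo")$compatible)
})

test_that("de novo without both parents in the pedigree is an error", {
  ped <- validate_pedigree(data.frame(
    family_id = "S", id = c("A", "B"), father_id = NA_character_,
    mother_id = NA_character_, sex = "unknown",
    affected = c("affected", "unaffected"), stringsAsFactors = FALSE))
  v <- make_variant(c(A = "het", B = "hom_ref"))
  expect_error(segregate(v, ped, "de_novo"), "incomplete trio")
})

test_that("recessive model constrains affecteds, parents and unaffecteds", {
  ped <- quartet_ped()
  v_good <- make_variant(c("I.1" = "het", "I.2" = "het",
                           "II.1" = "hom_alt", "II.2" = "het"))
  expect_true(segregate(v_good, ped, "recessive_hom")$compatible)
  v_hom_parent <- make_variant(c("I.1" = "hom_alt", "I.2" = "het",
                                 "II.1" = "hom_alt", "II.2" = "het"))
  expect_false(segregate(v_hom_parent, ped, "recessive_hom")$compatible)
  v_unaff_hom <- make_variant(c("I.1" = "het", "I.2" = "het",
                                "II.1" = "hom_alt", "II.2" = "hom_alt"))
  expect_false(segregate(v_unaff_hom, ped, "recessive_hom")$compatible)
})

test_that("missing required genotypes never yield informative compatibility", {
  ped <- six_ped()
  for (model in inheritance_models()) {
    gt <- setNames(rep("het", 6), ped$id)
    gt["F1-III.1"] <- "missing"   # an affected member (and de novo proband)
    res <- segregate(make_variant(gt), ped, model)
    expect_false(res$compatible && res$informative)
    expect_false(res$informative)
  }
})

test_that("unknown-phenotype members are free of segregation constraints", {
  ped <- trio_ped(affected = c("I.1" = "unknown", "I.2" = "unaffected",
                               "II.1" = "affected"))
  # carrier father of unknown phenotype does not break complete dominance
  v <- make_variant(c("I.1" = "het", "I.2" = "hom_ref", "II.1" = "het"))
  expect_true(segregate(v, ped, "dominant_complete")$compatible)
})

test_that("brute-force oracle evaluates model predicates directly", {
  ped <- trio_ped()
  all_ref <- setNames(rep("hom_ref", 3), ped$id)
  expect_false(brute_force_segregation(all_ref, ped, "dominant_complete"))
  all_het <- setNames(rep("het", 3), ped$id)
  expect_true(brute_force_segregation(all_het, ped, "dominant_incomplete"))
  big <- validate_pedigree(data.frame(
    family_id = "B", id = as.character(1:9), father_id = NA_character_,
    mother_id = NA_character_, sex = "unknown", affected = "unaffected",
    stringsAsFactors = FALSE))
  expect_error(
    brute_force_segregation(setNames(rep("het", 9), big$id), big, "dominant_complete"),
    "refuses")
})

test_that("engine and oracle agree on every trio genotype assignment", {
  ped <- trio_ped()
  grid <- all_genotype_assignments(3)
  for (model in inheritance_models()) {
    for (i in seq_len(nrow(grid))) {
      gt <- setNames(grid[i, ], ped$id)
      engine <- segregate(make_variant(gt), ped, model)$compatible
      oracle <- brute_force_segregation(gt, ped, model)
      expect_identical(engine, oracle)
    }
  }
})

test_that("complete dominance is nested within incomplete dominance", {
  ped <- six_ped()
  grid <- all_genotype_assignments(6)
  complete <- logical(nrow(grid)); incomplete <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gt <- setNames(grid[i, ], ped$id)
    complete[i] <- brute_force_segregation(gt, ped, "dominant_complete")
    incomplete[i] <- brute_force_segregation(gt, ped, "dominant_incomplete")
  }
  expect_gt(sum(complete), 0)
  expect_true(all(!complete | incomplete))
  expect_gt(sum(incomplete), sum(complete))
})

test_that("lowering the depth threshold never shrinks the de novo set", {
  ped <- trio_ped()
  set.seed(5)
  strict <- logical(0); lax <- logical(0)
  for (depth in c(5, 15, 25, 40)) {
    grid <- all_genotype_assignments(3)
    for (i in seq_len(nrow(grid))) {
      v <- make_variant(setNames(grid[i, ], ped$id), depth = depth)
      strict <- c(strict, segregate(v, ped, "de_novo",
                                    filter_config(min_depth = 20))$compatible)
      lax <- c(lax, segregate(v, ped, "de_novo",
                              filter_config(min_depth = 10))$compatible)
    }
  }
  expect_gt(sum(strict), 0)
  expect_true(all(!strict | lax))
  expect_gt(sum(lax), sum(strict))  # depth 15 passes only the lax threshold
})
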