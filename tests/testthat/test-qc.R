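call_of <- function(gt, depth = 50, gq = 99, af = 0.48) {
  list(gt = gt, depth = depth, gq = gq, alt_fraction = af)
}

test_that("genotype QC fails on the first violated rule, by name", {
  cfg <- filter_config()
  expect_equal(genotype_passes_qc(call_of("het"), cfg),
               list(pass = TRUE, reason = "ok"))
  expect_equal(genotype_passes_qc(call_of("het", depth = 5), cfg)$reason,
               "depth")
  expect_equal(genotype_passes_qc(call_of("het", gq = 10), cfg)$reason, "gq")
  expect_equal(genotype_passes_qc(call_of("het", af = 0.05), cfg)$reason,
               "allele_balance")
  expect_equal(genotype_passes_qc(call_of("hom_alt", af = 0.6), cfg)$reason,
               "allele_balance")
  expect_equal(genotype_passes_qc(call_of("missing", depth = NA, gq = NA,
                                          af = NA), cfg)$reason, "missing")
  # unevaluable depth/gq on a called genotype is not a failure
  expect_true(genotype_passes_qc(call_of("het", depth = NA, gq = NA), cfg)$pass)
})

ann_with_af <- function(...) {
  afs <- c(...)
  annotation_bundle(pop_afs = afs)
}

test_that("frequency filter removes strictly above the cutoff and flags novelty", {
  cfg <- filter_config()
  all_zero <- ann_with_af(gnomad_exomes = 0, kaviar = 0, bravo = 0)
  expect_equal(frequency_filter(all_zero, cfg)[c("retained", "novel")],
               list(retained = TRUE, novel = TRUE))
  expect_false(frequency_filter(ann_with_af(gnomad_exomes = 0.05), cfg)$retained)
  # boundary: exactly 1% is retained ("above 1%" removal) but not novel
  at_cutoff <- frequency_filter(ann_with_af(gnomad_exomes = 0.01), cfg)
  expect_true(at_cutoff$retained)
  expect_false(at_cutoff$novel)
  # nothing reported anywhere: retained and novel
  none <- frequency_filter(annotation_bundle(), cfg)
  expect_true(none$retained && none$novel)
})

test_that("novelty implies retention for any non-negative cutoff", {
  set.seed(11)
  for (i in 1:50) {
    afs <- sample(c(0, NA_real_, runif(1, 0, 0.2)), 4, replace = TRUE)
    names(afs) <- paste0("db", 1:4)
    cutoff <- runif(1, 0, 0.05)
    res <- frequency_filter(annotation_bundle(pop_afs = afs),
                            filter_config(max_pop_af = cutoff))
    if (res$novel) expect_true(res$retained)
  }
})

test_that("filters are monotone in their thresholds", {
  set.seed(7)
  anns <- lapply(1:40, function(i) {
    afs <- sample(c(0, NA_real_, runif(1, 0, 0.2)), 3, replace = TRUE)
    names(afs) <- paste0("db", 1:3)
    annotation_bundle(pop_afs = afs)
  })
  retained_at <- function(cut) {
    vapply(anns, function(a) {
      frequency_filter(a, filter_config(max_pop_af = cut))$retained
    }, logical(1))
  }
  # lowering max_pop_af never adds a retained variant
  expect_true(all(retained_at(0.001) <= retained_at(0.01)))
  expect_true(all(retained_at(0.01) <= retained_at(0.1)))

  calls <- lapply(1:40, function(i) {
    call_of("het", depth = sample(1:60, 1), gq = sample(1:99, 1),
            af = runif(1, 0.3, 0.7))
  })
  pass_at <- function(md) {
    vapply(calls, function(cl) {
      genotype_passes_qc(cl, filter_config(min_depth = md))$pass
    }, logical(1))
  }
  # raising min_depth never adds a passing genotype
  expect_true(all(pass_at(30) <= pass_at(10)))
})

test_that("QC and frequency commute on the surviving set", {
  set.seed(21)
  cfg <- filter_config()
  items <- lapply(1:30, function(i) {
    afs <- c(db1 = sample(c(0, 0.005, 0.05), 1))
    list(call = call_of("het", depth = sample(c(5, 50), 1)),
         ann = annotation_bundle(pop_afs = afs))
  })
  qc_then_freq <- vapply(items, function(x) {
    genotype_passes_qc(x$call, cfg)$pass && frequency_filter(x$ann, cfg)$retained
  }, logical(1))
  freq_then_qc <- vapply(items, function(x) {
    frequency_filter(x$ann, cfg)$retained && genotype_passes_qc(x$call, cfg)$pass
  }, logical(1))
  expect_equal(qc_then_freq, freq_then_qc)
})

test_that("panel pre-screen partitions by gene membership", {
  cfg <- filter_config(panel_genes = c("BMPR2", "CAV1", "TBX4", "SOX17", "KDR"))
  in_bmpr2 <- make_variant(c(A = "het"),
                           annotation_bundle(gene = "BMPR2"))
  in_tnip2 <- make_variant(c(A = "het"),
                           annotation_bundle(gene = "TNIP2"))
  parts <- panel_prescreen(list(in_bmpr2, in_tnip2), cfg)
  expect_length(parts$in_panel, 1)
  expect_equal(parts$in_panel[[1]]$annotation$gene, "BMPR2")
  expect_length(parts$outside_panel, 1)
  expect_equal(parts$outside_panel[[1]]$annotation$gene, "TNIP2")

  empty <- panel_prescreen(list(), cfg)
  expect_length(empty$in_panel, 0)
  expect_length(empty$outside_panel, 0)

  expect_error(panel_prescreen(list(), filter_config()), "non-empty")
})

test_that("the bundled panel list reads with comments stripped", {
  panel <- read_panel(system.file("extdata", "pah_panel.txt", package = "famprior"))
  expect_true(all(c("BMPR2", "CAV1", "TBX4", "SOX17", "KDR") %in% panel))
  expect_false(any(grepl("#", panel)))
})
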