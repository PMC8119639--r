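trio_ped_file <- function() {
  write_test_ped(c("T1\tI.1\t0\t0\t1\t1",
                   "T1\tI.2\t0\t0\t2\t1",
                   "T1\tII.1\tI.1\tI.2\t2\t2"))
}

test_that("alt fraction comes from AD over DP", {
  vcf <- write_test_vcf(
    paste("1", "100", ".", "A", "G", "50", "PASS", "GENE=X",
          "GT:DP:GQ:AD", "0/1:23:99:12,11", "0/0:30:99:30,0",
          "0/0:30:99:30,0", sep = "\t"),
    samples = c("II.1", "I.1", "I.2"))
  recs <- read_annotated_vcf(vcf, pedigree = read_ped(trio_ped_file()))
  expect_length(recs, 1)
  call <- recs[[1]]$calls
  expect_equal(call$alt_fraction[call$sample_id == "II.1"], 11 / 23,
               tolerance = 1e-12)
  expect_equal(call$gt[call$sample_id == "II.1"], "het")
})

test_that("multiallelic sites decompose into biallelic records", {
  vcf <- write_test_vcf(
    paste("1", "100", ".", "C", "A,G", "50", "PASS", "GENE=X",
          "GT:DP:GQ:AD", "1/2:40:99:0,20,20", "0/1:40:99:20,20,0",
          "0/0:40:99:40,0,0", sep = "\t"),
    samples = c("II.1", "I.1", "I.2"))
  recs <- read_annotated_vcf(vcf, pedigree = read_ped(trio_ped_file()))
  expect_length(recs, 2)
  expect_equal(vapply(recs, `[[`, character(1), "alt"), c("A", "G"))
  expect_equal(vapply(recs, `[[`, numeric(1), "pos"), c(100, 100))
  # sample II.1 is 1/2: het for each decomposed allele
  gts <- vapply(recs, function(r) r$calls$gt[r$calls$sample_id == "II.1"],
                character(1))
  expect_equal(gts, c("het", "het"))
  # I.1 is 0/1: het for allele 1, hom_ref for allele 2
  gts <- vapply(recs, function(r) r$calls$gt[r$calls$sample_id == "I.1"],
                character(1))
  expect_equal(gts, c("het", "hom_ref"))
})

test_that("decomposition conserves the total ALT allele count", {
  body <- c(
    paste("1", "100", ".", "C", "A,G", "50", "PASS", ".", "GT", "0/1", "0/0", "0/0", sep = "\t"),
    paste("1", "200", ".", "T", "A", "50", "PASS", ".", "GT", "0/1", "0/0", "0/0", sep = "\t"),
    paste("2", "300", ".", "G", "A,C,T", "50", "PASS", ".", "GT", "0/1", "0/0", "0/0", sep = "\t"))
  vcf <- write_test_vcf(body, samples = c("II.1", "I.1", "I.2"))
  recs <- read_annotated_vcf(vcf, pedigree = read_ped(trio_ped_file()))
  expect_length(recs, 2 + 1 + 3)
})

test_that("predictor strings parse under the schema translation table", {
  schema <- default_schema()
  schema$predictor_tools <- c("sift", "polyphen", "mutaster")
  vcf <- write_test_vcf(
    paste("1", "100", ".", "A", "G", "50", "PASS", "DBNSFP=D,D,T",
          "GT", "0/1", "0/0", "0/0", sep = "\t"),
    samples = c("II.1", "I.1", "I.2"))
  recs <- read_annotated_vcf(vcf, schema, read_ped(trio_ped_file()))
  calls <- recs[[1]]$annotation$predictor_calls
  expect_named(calls, c("sift", "polyphen", "mutaster"))
  expect_equal(sum(calls == "damaging"), 2)
  expect_equal(sum(calls == "tolerated"), 1)
})

test_that("a VCF lacking every schema key still parses with missing annotation", {
  vcf <- write_test_vcf(
    paste("1", "100", ".", "A", "G", "50", "PASS", ".",
          "GT", "0/1", "0/0", "0/0", sep = "\t"),
    samples = c("II.1", "I.1", "I.2"))
  recs <- read_annotated_vcf(vcf, pedigree = read_ped(trio_ped_file()))
  ann <- recs[[1]]$annotation
  expect_true(is.na(ann$gene))
  expect_true(is.na(ann$cadd))
  expect_true(all(is.na(ann$pop_afs)))
  expect_length(ann$predictor_calls, 0)
  expect_equal(ann$consequence, "unknown")
})

test_that("pedigree samples missing from the VCF are an error naming them", {
  vcf <- write_test_vcf(
    paste("1", "100", ".", "A", "G", "50", "PASS", ".", "GT", "0/1",
          "0/0", sep = "\t"),
    samples = c("II.1", "I.1"))
  expect_error(read_annotated_vcf(vcf, pedigree = read_ped(trio_ped_file())),
               "I\\.2")
})

test_that("VCF samples outside the pedigree are ignored with a warning", {
  vcf <- write_test_vcf(
    paste("1", "100", ".", "A", "G", "50", "PASS", ".", "GT", "0/1",
          "0/0", "0/0", "1/1", sep = "\t"),
    samples = c("II.1", "I.1", "I.2", "STRANGER"))
  expect_warning(
    recs <- read_annotated_vcf(vcf, pedigree = read_ped(trio_ped_file())),
    "STRANGER")
  expect_false("STRANGER" %in% recs[[1]]$calls$sample_id)
})

test_that("candidate reports round-trip through their own reader", {
  fx <- make_paper_fixture(tempfile("fxio"))
  res <- run_prioritization(fx$vcf, fx$ped, fx$config)
  path <- tempfile(fileext = ".tsv")
  write_candidate_report(res$candidates, path)
  lines <- readLines(path)
  expect_length(lines, nrow(res$candidates) + 1)  # header + one per candidate
  back <- read_candidate_report(path)
  expect_equal(as.data.frame(back), as.data.frame(res$candidates))
})

test_that("an empty report writes a header-only file", {
  path <- tempfile(fileext = ".tsv")
  write_candidate_report(rank_candidates(list()), path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines[1], "^rank\ttier\tgene")
  expect_equal(nrow(read_candidate_report(path)), 0)
})
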