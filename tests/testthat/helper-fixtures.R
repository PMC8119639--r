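# Shared builders for hand-crafted pedigrees, calls and VCF text.

make_calls <- function(gt, depth = 60, gq = 99, alt_fraction = NULL) {
  ids <- names(gt)
  if (is.null(alt_fraction)) {
    alt_fraction <- c(hom_ref = 0, het = 0.5, hom_alt = 1,
                      missing = NA_real_)[gt]
  }
  data.frame(sample_id = ids, gt = unname(gt),
             depth = rep_len(depth, length(ids)),
             gq = rep_len(gq, length(ids)),
             alt_fraction = unname(alt_fraction),
             stringsAsFactors = FALSE)
}

make_variant <- function(gt, annotation = annotation_bundle(), ...) {
  variant_record("1", 1000, "A", "G", make_calls(gt, ...), annotation)
}

trio_ped <- function(affected = c("I.1" = "unaffected", "I.2" = "unaffected",
                                  "II.1" = "affected")) {
  ped <- data.frame(
    family_id = "T1",
    id = c("I.1", "I.2", "II.1"),
    father_id = c(NA, NA, "I.1"),
    mother_id = c(NA, NA, "I.2"),
    sex = c("male", "female", "female"),
    affected = unname(affected[c("I.1", "I.2", "II.1")]),
    stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

quartet_ped <- function() {
  ped <- data.frame(
    family_id = "Q1",
    id = c("I.1", "I.2", "II.1", "II.2"),
    father_id = c(NA, NA, "I.1", "I.1"),
    mother_id = c(NA, NA, "I.2", "I.2"),
    sex = c("male", "female", "female", "male"),
    affected = c("unaffected", "unaffected", "affected", "unaffected"),
    stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

six_ped <- function() {
  ped <- pedigree_template("six_member_two_affected", "F1")
  ped$affected <- ifelse(ped$id %in% c("F1-II.1", "F1-III.1"),
                         "affected", "unaffected")
  validate_pedigree(ped)
}

family1_variant <- function(annotation = annotation_bundle()) {
  gt <- c("F1-II.1" = "het", "F1-II.2" = "hom_ref", "F1-II.3" = "het",
          "F1-III.1" = "het", "F1-III.2" = "hom_ref", "F1-III.3" = "hom_ref")
  make_variant(gt, annotation)
}

# minimal annotated VCF text for IO tests
write_test_vcf <- function(body_lines, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="c">',
    '##INFO=<ID=AF_GNOMAD_EX,Number=1,Type=Float,Description="af">',
    '##INFO=<ID=DBNSFP,Number=.,Type=String,Description="p">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="gq">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="ad">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

write_test_ped <- function(lines, path = tempfile(fileext = ".ped")) {
  writeLines(lines, path)
  path
}

all_genotype_assignments <- function(n) {
  codes <- c("hom_ref", "het", "hom_alt")
  as.matrix(expand.grid(rep(list(codes), n), stringsAsFactors = FALSE))
}
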