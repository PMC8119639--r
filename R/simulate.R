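#' Synthetic family/VCF generator configuration
#'
#' Parameters of the simulator that emulates the study design the pipeline
#' assumes: a pedigree template, an inheritance model, penetrance (the
#' probability that an obligate carrier is affected), a background of
#' non-causal variants, a decoy plan (each decoy violates exactly one named
#' filter), an exome-like read-depth distribution, a genotype error rate,
#' and a mandatory master seed (no implicit randomness).
#'
#' @param template One of `trio`, `quartet`, `six_member_two_affected`, or
#'   an explicit single-family `fam_pedigree`.
#' @param model One of [inheritance_models()].
#' @param penetrance Probability in (0, 1] that a carrier is affected.
#' @param n_background_variants Number of random non-causal variants.
#' @param decoy_plan Subset of `c("qc_fail", "common_af",
#'   "non_segregating", "benign_prediction", "panel_gene")`.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth
#'   parameters (mean 60, dispersion 10: typical exome coverage).
#' @param genotype_error_rate Per-call probability of replacing a genotype
#'   with a random different one.
#' @param seed Master integer seed; required.
#' @param family_id Family identifier and sample-id prefix.
#' @return A list of class `synthetic_family_config`.
#' @export
synthetic_family_config <- function(template = "six_member_two_affected",
                                    model = "dominant_incomplete",
                                    penetrance = 0.75,
                                    n_background_variants = 20,
                                    decoy_plan = character(0),
                                    depth_mean = 60, depth_dispersion = 10,
                                    genotype_error_rate = 0,
                                    seed, family_id = "F1") {
  if (missing(seed)) stop("seed is mandatory: the generator has no implicit randomness")
  stopifnot(penetrance > 0, penetrance <= 1,
            genotype_error_rate >= 0, genotype_error_rate < 1,
            n_background_variants >= 0, depth_mean > 0, depth_dispersion > 0)
  model <- match.arg(model, inheritance_models())
  known_decoys <- c("qc_fail", "common_af", "non_segregating",
                    "benign_prediction", "panel_gene")
  bad <- setdiff(decoy_plan, known_decoys)
  if (length(bad)) stop("unknown decoy type(s): ", paste(bad, collapse = ", "))
  structure(
    list(template = template, model = model, penetrance = penetrance,
         n_background_variants = n_background_variants,
         decoy_plan = decoy_plan, depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         genotype_error_rate = genotype_error_rate,
         seed = as.integer(seed), family_id = family_id),
    class = "synthetic_family_config"
  )
}

# deterministic sub-stream seed from the master seed and a string tag;
# kept below 2^31 (R integers are 32-bit)
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

#' Pedigree templates
#'
#' Builds the family structures the simulator supports. Individual ids are
#' prefixed with the family id so several families can share one VCF.
#' `six_member_two_affected` mirrors a dominant family with incomplete
#' penetrance: an index case and her unaffected spouse (founders), three
#' children, and the index's sibling entered as a founder (the siblings'
#' parents are not part of the sequenced set).
#'
#' @param template Template name.
#' @param family_id Family identifier.
#' @return A single-family `fam_pedigree` with `affected` set to
#'   `unknown` (the simulator assigns affection status).
#' @export
pedigree_template <- function(template, family_id = "F1") {
  p <- function(local) paste0(family_id, "-", local)
  rows <- switch(template,
    trio = data.frame(
      id = p(c("I.1", "I.2", "II.1")),
      father_id = c(NA, NA, p("I.1")),
      mother_id = c(NA, NA, p("I.2")),
      sex = c("male", "female", "female"),
      stringsAsFactors = FALSE),
    quartet = data.frame(
      id = p(c("I.1", "I.2", "II.1", "II.2")),
      father_id = c(NA, NA, p("I.1"), p("I.1")),
      mother_id = c(NA, NA, p("I.2"), p("I.2")),
      sex = c("male", "female", "female", "male"),
      stringsAsFactors = FALSE),
    six_member_two_affected = data.frame(
      id = p(c("II.1", "II.2", "II.3", "III.1", "III.2", "III.3")),
      father_id = c(NA, NA, NA, p("II.2"), p("II.2"), p("II.2")),
      mother_id = c(NA, NA, NA, p("II.1"), p("II.1"), p("II.1")),
      sex = c("female", "male", "female", "female", "male", "female"),
      stringsAsFactors = FALSE),
    stop("unknown pedigree template: ", template)
  )
  ped <- data.frame(family_id = family_id, rows, affected = "unknown",
                    stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

#' Simulate one family: genotypes by Mendelian transmission, affection by
#' penetrance
#'
#' Draws the spiked variant's genotypes by transmission from founder
#' carriers (dominant/recessive) or by construction (de novo: proband het,
#' parents hom-ref), then assigns affection status: carriers are affected
#' with probability `penetrance`, non-carriers are unaffected. At least one
#' affected member is guaranteed by deterministic resampling with an
#' incremented seed stream.
#'
#' @param config A [synthetic_family_config()].
#' @return List with `pedigree` (affection filled in), `genotypes` (named
#'   hom_ref/het/hom_alt vector for the spiked variant) and `model`.
#' @export
simulate_family <- function(config) {
  ped <- if (inherits(config$template, "fam_pedigree")) config$template
         else pedigree_template(config$template, config$family_id)
  model <- config$model

  has_trio_child <- any(!is.na(ped$father_id) & !is.na(ped$mother_id) &
                        ped$father_id %in% ped$id & ped$mother_id %in% ped$id)
  if (model == "de_novo" && !has_trio_child) {
    stop("impossible configuration: de_novo requires a child with both parents in the pedigree")
  }
  if (model == "recessive_hom" && !has_trio_child) {
    stop("impossible configuration: recessive_hom requires a child with both genotyped parents")
  }

  for (attempt in 1:200) {
    set.seed(derive_seed(config$seed, paste0("family-", config$family_id,
                                             "-attempt-", attempt)))
    gt <- draw_genotypes(ped, model)
    carrier <- switch(model,
      recessive_hom = gt == "hom_alt",
      gt != "hom_ref")
    if (model == "de_novo") {
      # only the de novo event is penetrant; transmitted copies do not exist
      affected <- ifelse(carrier, "affected", "unaffected")
    } else {
      affected <- ifelse(carrier & stats::runif(nrow(ped)) <= config$penetrance,
                         "affected", "unaffected")
    }
    if (any(affected == "affected")) {
      ped$affected <- affected
      return(list(pedigree = validate_pedigree(ped), genotypes = gt,
                  model = model))
    }
  }
  stop("impossible configuration: no affected member obtainable under model ",
       model, " with penetrance ", config$penetrance)
}

# genotype transmission for the spiked variant (expects parents to precede
# children in the template row order)
draw_genotypes <- function(ped, model) {
  n <- nrow(ped)
  gt <- setNames(rep("hom_ref", n), ped$id)
  founders <- ped$id[is.na(ped$father_id) & is.na(ped$mother_id)]
  children <- ped$id[!ped$id %in% founders]

  if (model == "de_novo") {
    kids <- ped$id[!is.na(ped$father_id) & !is.na(ped$mother_id) &
                   ped$father_id %in% ped$id & ped$mother_id %in% ped$id]
    gt[kids[1]] <- "het"
    return(gt)
  }
  if (model == "recessive_hom") {
    # both parents of the first child-with-parents are het carriers
    kid_rows <- which(!is.na(ped$father_id) & !is.na(ped$mother_id) &
                      ped$father_id %in% ped$id & ped$mother_id %in% ped$id)
    fa <- ped$father_id[kid_rows[1]]; mo <- ped$mother_id[kid_rows[1]]
    gt[fa] <- "het"; gt[mo] <- "het"
  } else {
    # dominant: one random founder carries one alt allele
    gt[sample(founders, 1)] <- "het"
  }
  n_alt <- function(g) c(hom_ref = 0, het = 1, hom_alt = 2)[g]
  for (id in children) {
    row <- ped[ped$id == id, ]
    alleles <- 0L
    for (par in c(row$father_id, row$mother_id)) {
      p_alt <- if (is.na(par) || !par %in% ped$id) 0 else n_alt(gt[par]) / 2
      alleles <- alleles + stats::rbinom(1, 1, p_alt)
    }
    gt[id] <- c("hom_ref", "het", "hom_alt")[alleles + 1]
  }
  gt
}

#' Built-in causal variant specifications
#'
#' The two published-style causal variants shipped with the package: a
#' heterozygous missense change in TNIP2 (NM_024309.3:c.697A>G,
#' p.Ser233Gly; 12 of 19 informative predictors damaging; CADD 25.8) and a
#' heterozygous nonsense change in TRAF2 (NM_021138.3:c.417C>A,
#' p.Cys139Ter; 5 of 9; CADD 35). Both are absent (AF 0) from every
#' configured control database.
#'
#' @return Named list of `spike_spec` objects (`TNIP2`, `TRAF2`).
#' @export
builtin_spikes <- function() {
  list(
    TNIP2 = spike_spec(
      gene = "TNIP2", chrom = "4", pos = 2743805, ref = "A", alt = "G",
      transcript = "NM_024309.3",
      hgvs_c = "NM_024309.3:c.697A>G", hgvs_p = "NP_077285.3:p.Ser233Gly",
      consequence = "missense", n_damaging = 12, n_informative = 19,
      cadd = 25.8),
    TRAF2 = spike_spec(
      gene = "TRAF2", chrom = "9", pos = 139788312, ref = "C", alt = "A",
      transcript = "NM_021138.3",
      hgvs_c = "NM_021138.3:c.417C>A", hgvs_p = "NP_066961.2:p.Cys139Ter",
      consequence = "stop_gain", n_damaging = 5, n_informative = 9,
      cadd = 35)
  )
}

#' Construct a causal-variant spike specification
#'
#' A spike carries everything needed to place a fully annotated causal
#' variant into a simulated VCF. Codon arithmetic is validated: the codon
#' implied by the cDNA position in `hgvs_c` must match the protein position
#' in `hgvs_p`.
#'
#' @param gene,chrom,pos,ref,alt Site fields.
#' @param transcript,hgvs_c,hgvs_p Annotation strings.
#' @param consequence Consequence class.
#' @param n_damaging,n_informative Predictor tally (m of n damaging).
#' @param n_tools Total predictor slots (the remainder beyond
#'   `n_informative` are unknown calls).
#' @param cadd Phred-scaled CADD score.
#' @param pop_afs Named numeric; defaults to 0 in every default-schema
#'   database (a novel variant).
#' @return A list of class `spike_spec`.
#' @export
spike_spec <- function(gene, chrom, pos, ref, alt, transcript = NA_character_,
                       hgvs_c = NA_character_, hgvs_p = NA_character_,
                       consequence = "missense", n_damaging = 0,
                       n_informative = 0, n_tools = 19, cadd = NA_real_,
                       pop_afs = NULL) {
  stopifnot(n_damaging <= n_informative, n_informative <= n_tools)
  if (is.null(pop_afs)) {
    dbs <- names(default_schema()$pop_af)
    pop_afs <- setNames(rep(0, length(dbs)), dbs)
  }
  cdna <- NA_integer_
  if (!is.na(hgvs_c)) {
    m <- regmatches(hgvs_c, regexpr("c\\.([0-9]+)", hgvs_c))
    if (length(m)) cdna <- as.integer(sub("c\\.", "", m))
  }
  if (!hgvs_consistent(cdna, hgvs_p)) {
    stop("spike_spec inconsistency: codon of cDNA position ", cdna,
         " does not match the protein position in ", hgvs_p)
  }
  structure(
    list(gene = gene, chrom = as.character(chrom), pos = as.integer(pos),
         ref = ref, alt = alt, transcript = transcript, hgvs_c = hgvs_c,
         hgvs_p = hgvs_p, consequence = consequence,
         n_damaging = n_damaging, n_informative = n_informative,
         n_tools = n_tools, cadd = cadd, pop_afs = pop_afs),
    class = "spike_spec"
  )
}

predictor_code_string <- function(n_damaging, n_informative, n_tools) {
  paste(c(rep("D", n_damaging), rep("T", n_informative - n_damaging),
          rep(".", n_tools - n_informative)), collapse = ",")
}

#' Write a simulated multi-sample VCF and matching PED
#'
#' Assembles the spiked causal variants, one decoy per requested decoy
#' class (each violating exactly its named filter while otherwise looking
#' causal), and a background of non-causal variants (common, or rare but
#' predictor-benign), then writes a VCF 4.2 text file plus the combined
#' PED. Per-genotype DP/GQ/AD are sampled from the configured depth
#' distribution; genotype errors are injected into spiked and background
#' calls at `genotype_error_rate` (decoys stay error-free so each keeps
#' its single engineered violation). Output is byte-identical for
#' identical seeds. Coordinates live on a toy 2-contig space; no genome
#' build is referenced.
#'
#' @param families Named list (family id -> [simulate_family()] result or
#'   a hand-built list with `pedigree` and `genotypes`).
#' @param spikes Named list (family id -> [spike_spec()]); each family's
#'   spike gets that family's simulated genotypes, hom-ref elsewhere.
#' @param config A [synthetic_family_config()] (depth distribution,
#'   background size, decoy plan, error rate, seed).
#' @param vcf_path,ped_path Output paths.
#' @return Invisibly, list of the two paths.
#' @export
generate_vcf <- function(families, spikes, config, vcf_path, ped_path) {
  ped_all <- do.call(rbind, lapply(families, function(f) as.data.frame(f$pedigree)))
  rownames(ped_all) <- NULL
  class(ped_all) <- c("fam_pedigree", "data.frame")
  samples <- ped_all$id

  full_gt <- function(fam_id) {
    gt <- setNames(rep("hom_ref", length(samples)), samples)
    fam_gt <- families[[fam_id]]$genotypes
    gt[names(fam_gt)] <- fam_gt
    gt
  }

  rows <- list()
  for (fam_id in names(spikes)) {
    sp <- spikes[[fam_id]]
    gt <- inject_genotype_errors(full_gt(fam_id), config,
                                 tag = paste0("err-spike-", fam_id))
    rows[[length(rows) + 1L]] <- vcf_row(sp, gt, config,
                                         tag = paste0("spike-", fam_id))
  }

  base_fam <- names(spikes)[1]
  for (decoy in sort(config$decoy_plan)) {
    d <- make_decoy(decoy, families[[base_fam]], samples)
    rows[[length(rows) + 1L]] <- vcf_row(d$spec, d$genotypes, config,
                                         tag = paste0("decoy-", decoy),
                                         depth_override = d$depth_override)
  }

  used_pos <- vapply(rows, function(r) paste(r$chrom, r$pos), character(1))
  for (i in seq_len(config$n_background_variants)) {
    set.seed(derive_seed(config$seed, paste0("bg-site-", i)))
    repeat {
      chrom <- sample(c("4", "9"), 1)
      pos <- sample(10000:50000000, 1)
      if (!paste(chrom, pos) %in% used_pos) break
    }
    used_pos <- c(used_pos, paste(chrom, pos))
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    common <- i %% 2 == 1
    if (common) {
      af <- stats::runif(1, 0.02, 0.4)
      dbs <- names(default_schema()$pop_af)
      pop_afs <- setNames(pmin(1, af * stats::runif(length(dbs), 0.8, 1.2)), dbs)
      n_dam <- sample(0:12, 1); n_inf <- 19
      cadd <- stats::runif(1, 0, 30)
    } else {
      pop_afs <- NULL  # spike_spec default: absent everywhere
      af <- 0.15       # within-dataset genotype draw only
      n_dam <- sample(0:2, 1); n_inf <- 19
      cadd <- stats::runif(1, 0, 8)
    }
    sp <- spike_spec(gene = sprintf("BGGENE%02d", i), chrom = chrom,
                     pos = pos, ref = ref, alt = alt,
                     consequence = sample(c("missense", "synonymous", "other"), 1),
                     n_damaging = n_dam, n_informative = n_inf,
                     cadd = round(cadd, 1), pop_afs = pop_afs)
    p <- if (common) mean(pop_afs) else af
    gt_codes <- sample(c("hom_ref", "het", "hom_alt"), length(samples),
                       replace = TRUE,
                       prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    gt <- inject_genotype_errors(setNames(gt_codes, samples), config,
                                 tag = paste0("err-bg-", i))
    rows[[length(rows) + 1L]] <- vcf_row(sp, gt, config,
                                         tag = paste0("bg-", i))
  }

  ord <- order(vapply(rows, `[[`, character(1), "chrom"),
               vapply(rows, `[[`, numeric(1), "pos"))
  write_vcf_text(rows[ord], samples, vcf_path)
  write_ped(ped_all, ped_path)
  invisible(list(vcf = vcf_path, ped = ped_path))
}

inject_genotype_errors <- function(gt, config, tag) {
  if (config$genotype_error_rate <= 0) return(gt)
  set.seed(derive_seed(config$seed, tag))
  flip <- stats::runif(length(gt)) < config$genotype_error_rate
  codes <- c("hom_ref", "het", "hom_alt")
  for (j in which(flip)) {
    gt[j] <- sample(setdiff(codes, gt[j]), 1)
  }
  gt
}

# One decoy per class: identical to a causal variant except for the single
# violated filter.
make_decoy <- function(type, base_family, samples) {
  causal_gt <- setNames(rep("hom_ref", length(samples)), samples)
  causal_gt[names(base_family$genotypes)] <- base_family$genotypes

  base <- function(gene, chrom, pos, ...) {
    spike_spec(gene = gene, chrom = chrom, pos = pos, ref = "G", alt = "T",
               consequence = "missense", n_damaging = 15, n_informative = 19,
               cadd = 28, ...)
  }
  if (type == "qc_fail") {
    list(spec = base("DECOY_QC", "4", 9100100), genotypes = causal_gt,
         depth_override = 4)   # carriers sequenced too shallow to trust
  } else if (type == "common_af") {
    afs <- setNames(rep(0, length(default_schema()$pop_af)),
                    names(default_schema()$pop_af))
    afs["gnomad_exomes"] <- 0.05
    list(spec = base("DECOY_AF", "4", 9100200, pop_afs = afs),
         genotypes = causal_gt, depth_override = NULL)
  } else if (type == "non_segregating") {
    ped <- base_family$pedigree
    gt <- setNames(rep("hom_ref", length(samples)), samples)
    unaff <- ped$id[ped$affected == "unaffected"]
    if (length(unaff)) gt[unaff[1]] <- "het"   # carrier is the wrong person
    list(spec = base("DECOY_SEG", "9", 9100300), genotypes = gt,
         depth_override = NULL)
  } else if (type == "benign_prediction") {
    list(spec = spike_spec(gene = "DECOY_BENIGN", chrom = "9", pos = 9100400,
                           ref = "G", alt = "T", consequence = "missense",
                           n_damaging = 1, n_informative = 19, cadd = 2),
         genotypes = causal_gt, depth_override = NULL)
  } else if (type == "panel_gene") {
    list(spec = base("BMPR2", "4", 9100500), genotypes = causal_gt,
         depth_override = NULL)
  } else {
    stop("unknown decoy type: ", type)
  }
}

# sample per-call FORMAT fields; causal-pattern calls are drawn inside the
# quality envelope so that, at zero genotype error, recovery is structural
vcf_row <- function(spec, genotypes, config, tag, depth_override = NULL) {
  set.seed(derive_seed(config$seed, paste0("fmt-", tag)))
  n <- length(genotypes)
  depth <- stats::rnbinom(n, mu = config$depth_mean,
                          size = config$depth_dispersion)
  clean <- is.null(depth_override) && !startsWith(tag, "bg-")
  if (clean) depth <- pmax(depth, 15)
  if (!is.null(depth_override)) {
    depth[genotypes != "hom_ref"] <- depth_override
    depth[genotypes == "hom_ref"] <- pmax(depth[genotypes == "hom_ref"], 15)
  }
  depth <- pmax(depth, 1)
  gq <- if (clean || !is.null(depth_override)) sample(60:99, n, replace = TRUE)
        else sample(15:99, n, replace = TRUE)

  fmt <- character(n)
  for (j in seq_len(n)) {
    g <- genotypes[j]
    if (g == "missing") { fmt[j] <- "./.:.:.:."; next }
    alt_reads <- switch(g,
      hom_ref = 0,
      hom_alt = depth[j] - min(depth[j], stats::rbinom(1, 2, 0.3)),
      het = if (clean || !is.null(depth_override)) {
        round(depth[j] * stats::runif(1, 0.40, 0.60))
      } else {
        stats::rbinom(1, depth[j], 0.5)
      })
    gt_str <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[g]
    fmt[j] <- sprintf("%s:%d:%d:%d,%d", gt_str, depth[j], gq[j],
                      depth[j] - alt_reads, alt_reads)
  }
  list(chrom = spec$chrom, pos = as.numeric(spec$pos), spec = spec,
       fmt = fmt)
}

fmt_num <- function(x) {
  ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE, digits = 7))
}

write_vcf_text <- function(rows, samples, path) {
  schema <- default_schema()
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famprior-simulator",
    "##contig=<ID=4,length=190214555>",
    "##contig=<ID=9,length=141213431>",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description="Transcript accession">',
    '##INFO=<ID=HGVSC,Number=1,Type=String,Description="HGVS cDNA change">',
    '##INFO=<ID=HGVSP,Number=1,Type=String,Description="HGVS protein change">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="Phred-scaled CADD score">',
    vapply(unname(schema$pop_af), function(key) {
      sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Control population allele frequency">', key)
    }, character(1)),
    '##INFO=<ID=DBNSFP,Number=.,Type=String,Description="Comma-joined per-tool pathogenicity calls (D damaging, T tolerated, . unknown)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(rows, function(r) {
    sp <- r$spec
    info <- c(
      if (!is.na(sp$gene)) paste0("GENE=", sp$gene),
      if (!is.na(sp$transcript)) paste0("TRANSCRIPT=", sp$transcript),
      if (!is.na(sp$hgvs_c)) paste0("HGVSC=", sp$hgvs_c),
      if (!is.na(sp$hgvs_p)) paste0("HGVSP=", sp$hgvs_p),
      paste0("CSQ=", sp$consequence),
      if (!is.na(sp$cadd)) paste0("CADD=", fmt_num(sp$cadd)),
      vapply(names(sp$pop_afs), function(db) {
        paste0(schema$pop_af[[db]], "=", fmt_num(sp$pop_afs[[db]]))
      }, character(1)),
      paste0("DBNSFP=", predictor_code_string(sp$n_damaging,
                                              sp$n_informative, sp$n_tools))
    )
    paste(c(sp$chrom, sp$pos, ".", sp$ref, sp$alt, "100", "PASS",
            paste(info, collapse = ";"), "GT:DP:GQ:AD", r$fmt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
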