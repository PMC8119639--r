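#' Read an annotated multi-sample VCF into variant records
#'
#' Loads a VCF (plain or bgzipped, v4.2), decomposes multiallelic sites into
#' biallelic records, extracts per-sample genotype calls (GT, DP, GQ, AD) and
#' maps INFO annotations into the internal model via a schema
#' ([default_schema()]). Samples present in the VCF but absent from the
#' pedigree are dropped with a warning; a pedigree member absent from the
#' VCF is an error. INFO keys missing from a record (or from the whole file)
#' yield missing annotation fields, never a failure.
#'
#' @param path Path to the VCF.
#' @param schema Annotation schema list; see [default_schema()].
#' @param pedigree A `fam_pedigree` from [read_ped()].
#' @return A list of `variant_record` objects, each with fields `chrom`,
#'   `pos`, `ref`, `alt`, `calls` (data frame: `sample_id`, `gt`, `depth`,
#'   `gq`, `alt_fraction`) and `annotation` (see [annotation_bundle()]).
#' @export
read_annotated_vcf <- function(path, schema = default_schema(), pedigree) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error   = function(e) stop("malformed VCF: ", conditionMessage(e)),
    warning = function(w) stop("malformed VCF: ", conditionMessage(w))
  )
  samples <- colnames(vcf@gt)[-1]
  absent <- setdiff(pedigree$id, samples)
  if (length(absent)) {
    stop("pedigree sample(s) absent from VCF: ", paste(absent, collapse = ", "))
  }
  extra <- setdiff(samples, pedigree$id)
  if (length(extra)) {
    warning("ignoring VCF sample(s) not in pedigree: ",
            paste(extra, collapse = ", "))
  }
  keep <- pedigree$id
  n <- nrow(vcf@fix)
  if (n == 0L) return(list())

  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  dp_mat <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq_mat <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  ad_mat <- vcfR::extract.gt(vcf, element = "AD")

  records <- list()
  for (i in seq_len(n)) {
    chrom <- vcf@fix[i, "CHROM"]
    pos   <- as.integer(vcf@fix[i, "POS"])
    ref   <- vcf@fix[i, "REF"]
    alts  <- strsplit(vcf@fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info  <- parse_info_field(vcf@fix[i, "INFO"])
    for (k in seq_along(alts)) {
      calls <- build_calls(keep, k,
                           gt_mat[i, , drop = TRUE], dp_mat[i, , drop = TRUE],
                           gq_mat[i, , drop = TRUE], ad_mat[i, , drop = TRUE])
      ann <- annotation_from_info(info, schema,
                                  allele_index = k, n_alleles = length(alts))
      records[[length(records) + 1L]] <-
        variant_record(chrom, pos, ref, alts[k], calls, ann)
    }
  }
  records
}

parse_info_field <- function(info) {
  if (is.na(info) || info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq > 0) {
      out[[substr(p, 1, eq - 1)]] <- substr(p, eq + 1, nchar(p))
    } else {
      out[[p]] <- TRUE   # flag
    }
  }
  out
}

# Number=A fields carry one value per ALT allele; take the k-th when the
# lengths line up, otherwise the single site-level value.
info_allele_value <- function(info, key, allele_index, n_alleles) {
  if (is.null(key) || is.null(info[[key]])) return(NA_character_)
  vals <- strsplit(as.character(info[[key]]), ",", fixed = TRUE)[[1]]
  if (length(vals) == n_alleles && n_alleles > 1L) {
    vals[allele_index]
  } else {
    vals[1L]
  }
}

annotation_from_info <- function(info, schema, allele_index = 1L, n_alleles = 1L) {
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  chr_or_na <- function(x) if (is.na(x) || x == ".") NA_character_ else x

  gene       <- chr_or_na(info_allele_value(info, schema$gene, allele_index, n_alleles))
  transcript <- chr_or_na(info_allele_value(info, schema$transcript, allele_index, n_alleles))
  hgvs_c     <- chr_or_na(info_allele_value(info, schema$hgvs_c, allele_index, n_alleles))
  hgvs_p     <- chr_or_na(info_allele_value(info, schema$hgvs_p, allele_index, n_alleles))
  csq        <- chr_or_na(info_allele_value(info, schema$consequence, allele_index, n_alleles))
  cadd       <- num_or_na(info_allele_value(info, schema$cadd, allele_index, n_alleles))

  pop_afs <- vapply(schema$pop_af, function(key) {
    num_or_na(info_allele_value(info, key, allele_index, n_alleles))
  }, numeric(1))
  names(pop_afs) <- names(schema$pop_af)

  predictor_calls <- character(0)
  raw <- if (!is.null(schema$predictors)) info[[schema$predictors]] else NULL
  if (!is.null(raw)) {
    codes <- strsplit(as.character(raw), ",", fixed = TRUE)[[1]]
    predictor_calls <- unname(schema$predictor_map[codes])
    predictor_calls[is.na(predictor_calls)] <- "unknown"
    tools <- schema$predictor_tools
    if (is.null(tools) || length(tools) != length(predictor_calls)) {
      tools <- paste0("tool", seq_along(predictor_calls))
    }
    names(predictor_calls) <- tools
  }

  annotation_bundle(gene = gene, transcript = transcript,
                    hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                    consequence = normalize_consequence(csq),
                    pop_afs = pop_afs, predictor_calls = predictor_calls,
                    cadd = cadd)
}

normalize_consequence <- function(x) {
  if (is.na(x)) return("unknown")
  x <- tolower(x)
  if (x %in% c("missense", "missense_variant")) return("missense")
  if (x %in% c("stop_gain", "stop_gained", "nonsense", "non-sense")) return("stop_gain")
  if (x %in% c("synonymous", "synonymous_variant")) return("synonymous")
  if (x %in% c("frameshift", "frameshift_variant")) return("frameshift")
  if (x %in% c("splice", "splice_donor_variant", "splice_acceptor_variant")) return("splice")
  "other"
}

#' Construct an annotation bundle
#'
#' Internal container for the per-variant annotations the filters consume:
#' gene/transcript/HGVS fields, a map of control-database allele
#' frequencies, a named vector of normalized predictor calls
#' (damaging/tolerated/unknown) and a CADD score. The 1-based coding
#' position `cdna_pos` is parsed from the HGVS c. string when present.
#'
#' @param gene,transcript,hgvs_c,hgvs_p Character scalars or NA.
#' @param consequence One of missense, stop_gain, synonymous, frameshift,
#'   splice, other, unknown.
#' @param pop_afs Named numeric vector of allele frequencies in `[0,1]`
#'   (NA = not reported by that database).
#' @param predictor_calls Named character vector over tools with values
#'   damaging/tolerated/unknown; may be empty.
#' @param cadd Non-negative phred-scaled score or NA.
#' @return A list of class `annotation_bundle`.
#' @export
annotation_bundle <- function(gene = NA_character_, transcript = NA_character_,
                              hgvs_c = NA_character_, hgvs_p = NA_character_,
                              consequence = "unknown",
                              pop_afs = numeric(0),
                              predictor_calls = character(0),
                              cadd = NA_real_) {
  observed <- pop_afs[!is.na(pop_afs)]
  if (length(observed) && (any(observed < 0) || any(observed > 1))) {
    stop("population allele frequencies must lie in [0, 1]")
  }
  cdna_pos <- NA_integer_
  if (!is.na(hgvs_c)) {
    m <- regmatches(hgvs_c, regexpr("c\\.([0-9]+)", hgvs_c))
    if (length(m)) cdna_pos <- as.integer(sub("c\\.", "", m))
  }
  structure(
    list(gene = gene, transcript = transcript, cdna_pos = cdna_pos,
         hgvs_c = hgvs_c, hgvs_p = hgvs_p, consequence = consequence,
         pop_afs = pop_afs, predictor_calls = predictor_calls, cadd = cadd),
    class = "annotation_bundle"
  )
}

#' Construct a variant record
#'
#' One normalized biallelic site with per-sample genotype calls and an
#' annotation bundle. Coordinates are 1-based (VCF convention).
#'
#' @param chrom,pos,ref,alt Site fields; `alt` is a single allele.
#' @param calls Data frame with columns `sample_id`, `gt`
#'   (hom_ref/het/hom_alt/missing), `depth`, `gq`, `alt_fraction`.
#' @param annotation An [annotation_bundle()].
#' @return A list of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alt, calls, annotation) {
  stopifnot(nchar(ref) > 0, nchar(alt) > 0, pos >= 1)
  if (!all(c("sample_id", "gt", "depth", "gq", "alt_fraction") %in% names(calls))) {
    stop("calls must have columns sample_id, gt, depth, gq, alt_fraction")
  }
  bad <- !calls$gt %in% c("hom_ref", "het", "hom_alt", "missing")
  if (any(bad)) stop("invalid genotype code(s): ", paste(unique(calls$gt[bad]), collapse = ", "))
  af <- calls$alt_fraction
  if (any(!is.na(af) & (af < 0 | af > 1))) stop("alt_fraction must lie in [0, 1]")
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = ref, alt = alt, calls = calls, annotation = annotation),
    class = "variant_record"
  )
}

# Map VCF GT/DP/GQ/AD strings for one site into call rows for allele k.
# Other ALT alleles are treated as reference for this biallelic record;
# any no-call allele makes the genotype missing.
build_calls <- function(sample_ids, k, gt_row, dp_row, gq_row, ad_row) {
  n <- length(sample_ids)
  gt  <- character(n); depth <- rep(NA_real_, n)
  gq  <- rep(NA_real_, n); af <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    s <- sample_ids[j]
    g <- gt_row[[s]]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) {
      gt[j] <- "missing"
    } else {
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) {
        gt[j] <- "missing"
      } else {
        hits <- sum(alleles == as.character(k))
        gt[j] <- if (hits >= 2) "hom_alt" else if (hits == 1) "het" else "hom_ref"
      }
    }
    depth[j] <- if (is.null(dp_row[[s]])) NA_real_ else dp_row[[s]]
    gq[j]    <- if (is.null(gq_row[[s]])) NA_real_ else gq_row[[s]]
    ad <- ad_row[[s]]
    if (!is.na(ad) && ad != ".") {
      counts <- suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]]))
      if (length(counts) > k && !anyNA(counts)) {
        total <- if (!is.na(depth[j]) && depth[j] > 0) depth[j] else sum(counts)
        if (!is.na(total) && total > 0) {
          af[j] <- min(1, counts[k + 1] / total)
        }
      }
    }
  }
  data.frame(sample_id = sample_ids, gt = gt, depth = depth, gq = gq,
             alt_fraction = af, stringsAsFactors = FALSE)
}
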