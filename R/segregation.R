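#' Inheritance models
#'
#' The models the segregation engine understands:
#' \describe{
#'   \item{dominant_complete}{Every affected member carries the variant
#'     (het or hom-alt) and every unaffected member is hom-ref.}
#'   \item{dominant_incomplete}{Every affected member carries the variant;
#'     unaffected members are unconstrained (obligate carriers may remain
#'     healthy).}
#'   \item{de_novo}{The designated proband carries the variant and both
#'     parents are *confidently* hom-ref (hom-ref with depth and GQ at or
#'     above the QC thresholds, guarding against allele dropout).}
#'   \item{recessive_hom}{Every affected member is hom-alt, every genotyped
#'     parent of an affected member is het, and no unaffected member is
#'     hom-alt.}
#' }
#' Members with unknown phenotype are excluded from segregation constraints.
#' Sex chromosomes are treated autosomally.
#'
#' @return Character vector of the model names.
#' @export
inheritance_models <- function() {
  c("dominant_complete", "dominant_incomplete", "de_novo", "recessive_hom")
}

#' Test a variant's compatibility with an inheritance model in one family
#'
#' Evaluates the declarative model predicate (see [inheritance_models()])
#' on the genotype calls of one family's members, and tallies carriers
#' among affected and unaffected members. When a genotype required by the
#' model rule is missing, the result is uninformative (`informative =
#' FALSE`) and never compatible.
#'
#' @param variant A `variant_record`. Genotype QC (demoting low-quality
#'   calls to missing) should have been applied first; see
#'   [apply_genotype_qc()].
#' @param pedigree A single-family `fam_pedigree`.
#' @param model One of [inheritance_models()].
#' @param config A [filter_config()]; supplies the parental-confidence
#'   thresholds for `de_novo`.
#' @param proband Individual id to use as the de novo proband; by default
#'   the first affected member with both parents in the pedigree.
#' @return A `segregation_result` list: `compatible`, `model`,
#'   `affected_carriers`, `unaffected_carriers`, `affected_noncarriers`,
#'   `informative`, and (for de_novo) `proband`.
#' @export
segregate <- function(variant, pedigree, model, config = filter_config(),
                      proband = NULL) {
  model <- match.arg(model, inheritance_models())
  calls <- variant$calls
  idx <- match(pedigree$id, calls$sample_id)
  gt <- ifelse(is.na(idx), "missing", calls$gt[idx])
  names(gt) <- pedigree$id
  depth <- calls$depth[idx]; names(depth) <- pedigree$id
  gq <- calls$gq[idx];       names(gq) <- pedigree$id

  affected   <- pedigree$id[pedigree$affected == "affected"]
  unaffected <- pedigree$id[pedigree$affected == "unaffected"]
  carrier <- gt %in% c("het", "hom_alt")
  names(carrier) <- pedigree$id
  known <- gt != "missing"

  res <- list(
    compatible = FALSE, model = model,
    affected_carriers    = sum(carrier[affected] & known[affected]),
    unaffected_carriers  = sum(carrier[unaffected] & known[unaffected]),
    affected_noncarriers = sum(gt[affected] == "hom_ref"),
    informative = TRUE, proband = NA_character_
  )

  if (model == "dominant_complete") {
    required <- c(affected, unaffected)
    if (any(!known[required])) {
      res$informative <- FALSE
    } else {
      res$compatible <- all(carrier[affected]) && all(gt[unaffected] == "hom_ref")
    }
  } else if (model == "dominant_incomplete") {
    if (any(!known[affected])) {
      res$informative <- FALSE
    } else {
      res$compatible <- all(carrier[affected])
    }
  } else if (model == "de_novo") {
    pb <- proband
    if (is.null(pb)) pb <- find_denovo_proband(pedigree)
    if (is.na(pb)) stop("incomplete trio: no affected individual with both parents in the pedigree")
    row <- pedigree[pedigree$id == pb, ]
    if (is.na(row$father_id) || is.na(row$mother_id) ||
        !all(c(row$father_id, row$mother_id) %in% pedigree$id)) {
      stop("incomplete trio: proband ", pb, " lacks both parents in the pedigree")
    }
    res$proband <- pb
    parents <- c(row$father_id, row$mother_id)
    if (!known[pb] || any(!known[parents])) {
      res$informative <- FALSE
    } else {
      confident_ref <- vapply(parents, function(p) {
        gt[p] == "hom_ref" &&
          !is.na(depth[p]) && depth[p] >= config$min_depth &&
          !is.na(gq[p]) && gq[p] >= config$min_gq
      }, logical(1))
      res$compatible <- carrier[pb] && all(confident_ref)
    }
  } else { # recessive_hom
    parents_of_affected <- unique(stats::na.omit(unlist(
      pedigree[pedigree$id %in% affected, c("father_id", "mother_id")]
    )))
    parents_of_affected <- intersect(parents_of_affected, pedigree$id)
    required <- c(affected, unaffected)
    if (any(!known[required])) {
      res$informative <- FALSE
    } else {
      genotyped_parents <- parents_of_affected[known[parents_of_affected]]
      res$compatible <- all(gt[affected] == "hom_alt") &&
        all(gt[genotyped_parents] == "het") &&
        !any(gt[unaffected] == "hom_alt")
    }
  }
  if (!res$informative) res$compatible <- FALSE
  structure(res, class = "segregation_result")
}

#' Default de novo proband: first affected member with both parents present
#'
#' @param pedigree A single-family `fam_pedigree`.
#' @return Individual id, or NA when no member qualifies.
#' @export
find_denovo_proband <- function(pedigree) {
  for (i in seq_len(nrow(pedigree))) {
    row <- pedigree[i, ]
    if (row$affected == "affected" &&
        !is.na(row$father_id) && !is.na(row$mother_id) &&
        all(c(row$father_id, row$mother_id) %in% pedigree$id)) {
      return(row$id)
    }
  }
  NA_character_
}

#' Demote QC-failing genotypes to missing
#'
#' A variant with a QC-failing genotype in one member is not discarded
#' globally: only that genotype is set to missing, and segregation decides
#' downstream. Returns the variant with masked calls plus the list of
#' demotions.
#'
#' @param variant A `variant_record`.
#' @param config A [filter_config()].
#' @return List with `variant` (masked copy) and `demoted` (data frame of
#'   `sample_id`, `reason` for each demoted call; zero rows when all pass).
#' @export
apply_genotype_qc <- function(variant, config = filter_config()) {
  calls <- variant$calls
  demoted_id <- character(0); demoted_reason <- character(0)
  for (j in seq_len(nrow(calls))) {
    if (calls$gt[j] == "missing") next
    verdict <- genotype_passes_qc(calls[j, ], config)
    if (!verdict$pass) {
      demoted_id <- c(demoted_id, calls$sample_id[j])
      demoted_reason <- c(demoted_reason, verdict$reason)
      calls$gt[j] <- "missing"
    }
  }
  variant$calls <- calls
  list(variant = variant,
       demoted = data.frame(sample_id = demoted_id, reason = demoted_reason,
                            stringsAsFactors = FALSE))
}
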