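#' Brute-force segregation oracle
#'
#' Evaluates an inheritance-model predicate directly on a vector of genotype
#' codes, written independently of [segregate()] (no shared helper code), so
#' the two can be checked against each other over all `3^n` genotype
#' assignments of a small pedigree. Genotypes here are always observed
#' (hom_ref/het/hom_alt); missingness semantics belong to the engine.
#'
#' @param genotypes Named character vector (names = individual ids) with
#'   values `hom_ref`, `het` or `hom_alt`, covering every pedigree member.
#' @param pedigree A single-family `fam_pedigree` with at most 8 members.
#' @param model One of [inheritance_models()].
#' @return Logical: is the assignment compatible with the model?
#' @export
brute_force_segregation <- function(genotypes, pedigree, model) {
  if (nrow(pedigree) > 8) {
    stop("brute-force oracle refuses pedigrees larger than 8 members")
  }
  stopifnot(all(pedigree$id %in% names(genotypes)))
  if (!all(genotypes %in% c("hom_ref", "het", "hom_alt"))) {
    stop("oracle genotypes must be hom_ref, het or hom_alt")
  }
  model <- match.arg(model, inheritance_models())

  ids <- pedigree$id
  g <- genotypes[ids]
  is_aff <- pedigree$affected == "affected"
  is_un  <- pedigree$affected == "unaffected"
  has_alt <- g == "het" | g == "hom_alt"

  if (model == "dominant_complete") {
    return(all(has_alt[is_aff]) && all(g[is_un] == "hom_ref"))
  }
  if (model == "dominant_incomplete") {
    return(all(has_alt[is_aff]))
  }
  if (model == "de_novo") {
    pb_idx <- which(is_aff &
                    !is.na(pedigree$father_id) & !is.na(pedigree$mother_id) &
                    pedigree$father_id %in% ids & pedigree$mother_id %in% ids)
    if (!length(pb_idx)) {
      stop("incomplete trio: no affected individual with both parents in the pedigree")
    }
    pb <- pb_idx[1]
    fa <- pedigree$father_id[pb]; mo <- pedigree$mother_id[pb]
    return(has_alt[pb] && g[fa] == "hom_ref" && g[mo] == "hom_ref")
  }
  # recessive_hom
  if (!all(g[is_aff] == "hom_alt")) return(FALSE)
  if (any(g[is_un] == "hom_alt")) return(FALSE)
  for (i in which(is_aff)) {
    for (par in c(pedigree$father_id[i], pedigree$mother_id[i])) {
      if (!is.na(par) && par %in% ids && g[par] != "het") return(FALSE)
    }
  }
  TRUE
}
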