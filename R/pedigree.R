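#' Read a 6-column PED pedigree file
#'
#' Parses the standard whitespace-delimited PED format (family, individual,
#' father, mother, sex, phenotype) into a validated pedigree table. A single
#' file may contain several families; downstream segregation analysis treats
#' each `family_id` independently.
#'
#' Codes follow the PLINK convention: parent `"0"` means unknown/absent;
#' sex `1` = male, `2` = female, anything else unknown; phenotype `2` =
#' affected, `1` = unaffected, anything else unknown. Individuals with an
#' unknown phenotype are excluded from segregation constraints but retained
#' for genotype transmission checks.
#'
#' @param path Path to a PED file. Lines starting with `#` are ignored.
#' @return A `fam_pedigree` data frame with columns `family_id`, `id`,
#'   `father_id`, `mother_id` (NA when unknown), `sex`
#'   (`male`/`female`/`unknown`) and `affected`
#'   (`affected`/`unaffected`/`unknown`).
#' @examples
#' ped <- read_ped(system.file("extdata", "example_trio.ped", package = "famprior"))
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("PED format error: ", conditionMessage(e))
  )
  if (ncol(raw) < 6) {
    stop("PED format error: expected 6 whitespace-delimited columns, found ",
         ncol(raw))
  }
  raw <- raw[, 1:6]
  names(raw) <- c("family_id", "id", "father_id", "mother_id", "sex", "pheno")
  ped <- data.frame(
    family_id = raw$family_id,
    id        = raw$id,
    father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
    mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
    sex       = decode_sex(raw$sex),
    affected  = decode_phenotype(raw$pheno),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

decode_sex <- function(x) {
  out <- rep("unknown", length(x))
  out[x == "1"] <- "male"
  out[x == "2"] <- "female"
  out
}

decode_phenotype <- function(x) {
  out <- rep("unknown", length(x))
  out[x == "2"] <- "affected"
  out[x == "1"] <- "unaffected"
  out
}

#' Validate a pedigree table
#'
#' Checks the structural invariants every pedigree must satisfy: unique
#' individual ids, parental references that resolve within the same family
#' (or are missing), and no individual being its own ancestor.
#'
#' @param ped A data frame with the columns produced by [read_ped()].
#' @return The validated pedigree, classed `fam_pedigree`.
#' @export
validate_pedigree <- function(ped) {
  required <- c("family_id", "id", "father_id", "mother_id", "sex", "affected")
  missing_cols <- setdiff(required, names(ped))
  if (length(missing_cols)) {
    stop("pedigree is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(ped) == 0L) stop("pedigree is empty")
  if (anyDuplicated(ped$id)) {
    dup <- unique(ped$id[duplicated(ped$id)])
    stop("PED format error: duplicate individual id(s): ",
         paste(dup, collapse = ", "))
  }
  for (fam in unique(ped$family_id)) {
    members <- ped[ped$family_id == fam, ]
    for (col in c("father_id", "mother_id")) {
      refs <- members[[col]]
      dangling <- setdiff(refs[!is.na(refs)], members$id)
      if (length(dangling)) {
        stop("PED format error: parent id(s) not found in family ", fam, ": ",
             paste(dangling, collapse = ", "))
      }
    }
    check_acyclic(members, fam)
  }
  class(ped) <- c("fam_pedigree", "data.frame")
  ped
}

# walk ancestors of each individual; any revisit of the starting id is a cycle
check_acyclic <- function(members, fam) {
  parent_of <- function(id) {
    row <- members[members$id == id, ]
    c(row$father_id, row$mother_id)
  }
  for (id in members$id) {
    frontier <- parent_of(id)
    seen <- character()
    while (length(frontier)) {
      frontier <- frontier[!is.na(frontier)]
      if (id %in% frontier) {
        stop("PED format error: individual ", id,
             " is its own ancestor (cycle in family ", fam, ")")
      }
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unlist(lapply(frontier, parent_of))
    }
  }
  invisible(NULL)
}

#' Write a pedigree back to 6-column PED format
#'
#' Inverse of [read_ped()]; writing then reading returns an identical
#' pedigree.
#'
#' @param ped A `fam_pedigree` data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  phe_code <- c(affected = "2", unaffected = "1", unknown = "0")[ped$affected]
  lines <- paste(ped$family_id, ped$id,
                 ifelse(is.na(ped$father_id), "0", ped$father_id),
                 ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                 sex_code, phe_code, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Split a multi-family pedigree into per-family pedigrees
#'
#' @param ped A `fam_pedigree` data frame.
#' @return Named list of single-family `fam_pedigree` objects.
#' @export
split_families <- function(ped) {
  fams <- unique(ped$family_id)
  out <- lapply(fams, function(f) {
    sub <- ped[ped$family_id == f, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("fam_pedigree", "data.frame")
    sub
  })
  names(out) <- fams
  out
}
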