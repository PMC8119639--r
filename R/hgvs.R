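#' Codon number of a coding-sequence position
#'
#' Maps a 1-based cDNA coding position to the 1-based codon (amino-acid)
#' number: `ceiling(pos / 3)`. Positions 1-3 are codon 1, 4-6 codon 2, etc.
#'
#' @param cdna_pos Positive integer position within the coding sequence.
#' @return Integer codon number.
#' @examples
#' codon_of(697)  # 233
#' codon_of(417)  # 139
#' @export
codon_of <- function(cdna_pos) {
  if (!is.numeric(cdna_pos) || any(is.na(cdna_pos)) || any(cdna_pos < 1) ||
      any(cdna_pos != floor(cdna_pos))) {
    stop("cdna_pos must be a positive integer (1-based coding position)")
  }
  as.integer(ceiling(cdna_pos / 3))
}

#' Parse an HGVS protein-change string
#'
#' Accepts `p.` notation with or without the parentheses that mark a
#' predicted consequence, e.g. `p.Cys139Ter` or `p.(Ser233Gly)`. The
#' consequence class follows from the amino acids: `Ter` (or `*`) is a
#' stop-gain, identical reference and alternate residues are synonymous,
#' anything else is missense. An unparseable string yields a warning and
#' consequence `"unknown"`.
#'
#' @param hgvs_p HGVS protein string (a leading transcript accession and
#'   colon is tolerated).
#' @return List with `ref_aa`, `codon`, `alt_aa` and `consequence`.
#' @examples
#' parse_hgvs_p("p.Cys139Ter")    # stop_gain at codon 139
#' parse_hgvs_p("p.(Ser233Gly)")  # missense at codon 233
#' @export
parse_hgvs_p <- function(hgvs_p) {
  failed <- list(ref_aa = NA_character_, codon = NA_integer_,
                 alt_aa = NA_character_, consequence = "unknown")
  if (is.na(hgvs_p) || !nzchar(hgvs_p)) {
    warning("empty HGVS p. string")
    return(failed)
  }
  s <- sub("^.*:", "", hgvs_p)           # drop protein accession
  s <- sub("^p\\.", "", s)
  s <- gsub("[()]", "", s)
  m <- regexec("^([A-Z][a-z]{2})([0-9]+)(Ter|\\*|[A-Z][a-z]{2})$", s)
  parts <- regmatches(s, m)[[1]]
  if (length(parts) != 4) {
    warning("unparseable HGVS p. string: ", hgvs_p)
    return(failed)
  }
  ref_aa <- parts[2]; codon <- as.integer(parts[3]); alt_aa <- parts[4]
  if (alt_aa == "*") alt_aa <- "Ter"
  consequence <- if (alt_aa == "Ter") "stop_gain"
                 else if (alt_aa == ref_aa) "synonymous"
                 else "missense"
  list(ref_aa = ref_aa, codon = codon, alt_aa = alt_aa,
       consequence = consequence)
}

#' Check cDNA-position / protein-position consistency
#'
#' The codon implied by the cDNA coding position must equal the codon in the
#' protein HGVS string when both are present. Returns TRUE when consistent
#' or when either side is missing; FALSE flags an annotation inconsistency.
#'
#' @param cdna_pos 1-based coding position or NA.
#' @param hgvs_p HGVS protein string or NA.
#' @return Logical.
#' @export
hgvs_consistent <- function(cdna_pos, hgvs_p) {
  if (is.na(cdna_pos) || is.na(hgvs_p)) return(TRUE)
  parsed <- suppressWarnings(parse_hgvs_p(hgvs_p))
  if (is.na(parsed$codon)) return(TRUE)
  codon_of(cdna_pos) == parsed$codon
}
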