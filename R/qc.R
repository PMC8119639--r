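#' Hard-filter configuration
#'
#' Thresholds for the pre-filters: per-genotype quality (depth, genotype
#' quality, allele balance), the population-frequency cutoff, and the
#' known-gene panel used for pre-screening. Defaults are field-standard
#' exome values: depth >= 10 reads, GQ >= 20, heterozygous allele balance
#' in \[0.25, 0.75\], homozygous-alt allele fraction >= 0.85, and removal of
#' variants with any control-database frequency strictly above 1%.
#'
#' @param min_depth Minimum read depth for a confident genotype.
#' @param min_gq Minimum phred-scaled genotype quality.
#' @param het_ab_range Length-2 numeric: allowed alt-allele fraction for
#'   heterozygous calls.
#' @param min_hom_alt_fraction Minimum alt-allele fraction for hom-alt calls.
#' @param max_pop_af Maximum tolerated population allele frequency;
#'   variants strictly above it are removed.
#' @param panel_genes Character vector of known-disease-gene symbols for the
#'   panel pre-screen (may be empty).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10, min_gq = 20,
                          het_ab_range = c(0.25, 0.75),
                          min_hom_alt_fraction = 0.85,
                          max_pop_af = 0.01,
                          panel_genes = character(0)) {
  stopifnot(max_pop_af >= 0, max_pop_af <= 1,
            length(het_ab_range) == 2, het_ab_range[1] <= het_ab_range[2],
            het_ab_range[1] >= 0, het_ab_range[2] <= 1,
            min_depth >= 0, min_gq >= 0)
  structure(
    list(min_depth = min_depth, min_gq = min_gq,
         het_ab_range = het_ab_range,
         min_hom_alt_fraction = min_hom_alt_fraction,
         max_pop_af = max_pop_af,
         panel_genes = toupper(panel_genes)),
    class = "filter_config"
  )
}

#' Per-genotype quality control
#'
#' Tests one genotype call against the depth, genotype-quality and allele
#' balance rules, reporting the first violated rule by name. Missing
#' genotypes always fail with reason `"missing"`. A present genotype whose
#' depth or GQ field is absent is not failed on that rule (it cannot be
#' evaluated).
#'
#' @param call One row of a `variant_record` calls data frame (or a list
#'   with the same fields).
#' @param config A [filter_config()].
#' @return List with `pass` (logical) and `reason` (`"ok"`, `"missing"`,
#'   `"depth"`, `"gq"` or `"allele_balance"`).
#' @export
genotype_passes_qc <- function(call, config = filter_config()) {
  if (call$gt == "missing") return(list(pass = FALSE, reason = "missing"))
  if (!is.na(call$depth) && call$depth < config$min_depth) {
    return(list(pass = FALSE, reason = "depth"))
  }
  if (!is.na(call$gq) && call$gq < config$min_gq) {
    return(list(pass = FALSE, reason = "gq"))
  }
  ab <- call$alt_fraction
  if (!is.na(ab)) {
    if (call$gt == "het" &&
        (ab < config$het_ab_range[1] || ab > config$het_ab_range[2])) {
      return(list(pass = FALSE, reason = "allele_balance"))
    }
    if (call$gt == "hom_alt" && ab < config$min_hom_alt_fraction) {
      return(list(pass = FALSE, reason = "allele_balance"))
    }
  }
  list(pass = TRUE, reason = "ok")
}

#' Population-frequency and novelty filter
#'
#' A variant is retained when its maximum observed control-database allele
#' frequency does not exceed `max_pop_af` (strictly-above removal: an AF of
#' exactly the cutoff is retained). It is novel when every configured
#' database reports it absent or at frequency exactly zero. Novelty implies
#' retention for any non-negative cutoff.
#'
#' @param annotation An [annotation_bundle()].
#' @param config A [filter_config()].
#' @return List with logicals `retained` and `novel`, plus `max_af` (the
#'   maximum observed frequency, 0 when none is reported).
#' @export
frequency_filter <- function(annotation, config = filter_config()) {
  afs <- annotation$pop_afs
  observed <- afs[!is.na(afs)]
  max_af <- if (length(observed)) max(observed) else 0
  list(
    retained = max_af <= config$max_pop_af,
    novel    = length(observed) == 0 || all(observed == 0),
    max_af   = max_af
  )
}

#' Known-gene panel pre-screen
#'
#' Partitions variant records by membership of their gene in the configured
#' panel. Panel-gene hits would end a diagnostic search if pathogenic and
#' are reported separately; the remainder proceed to discovery
#' prioritization. Matching is case-insensitive on gene symbols.
#'
#' @param records List of `variant_record` objects.
#' @param config A [filter_config()] with non-empty `panel_genes`.
#' @return List with elements `in_panel` and `outside_panel`, each a list of
#'   records.
#' @export
panel_prescreen <- function(records, config) {
  if (!length(config$panel_genes)) stop("panel_genes must be non-empty")
  in_panel <- vapply(records, function(r) {
    g <- r$annotation$gene
    !is.na(g) && toupper(g) %in% config$panel_genes
  }, logical(1))
  list(in_panel = records[in_panel], outside_panel = records[!in_panel])
}

#' Read a gene-panel list
#'
#' One gene symbol per line; `#` comments and blank lines are ignored.
#'
#' @param path Path to the panel file.
#' @return Character vector of uppercased gene symbols.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  toupper(lines[nzchar(lines)])
}
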