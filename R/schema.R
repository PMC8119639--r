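#' Default annotation schema
#'
#' The pipeline consumes population frequencies, per-tool pathogenicity
#' calls, a phred-scaled CADD score and gene/HGVS fields from VCF INFO keys.
#' Different annotation engines use different key names, so the mapping from
#' INFO keys to internal fields is configuration, not code. This default
#' matches the VCFs written by [generate_vcf()].
#'
#' `pop_af` maps a control-database name to the INFO key holding its allele
#' frequency. `predictors` names a key holding a comma-joined vector of
#' per-tool calls (one element per tool in `predictor_tools`), and
#' `predictor_map` translates raw call codes to the 3-value code
#' damaging/tolerated/unknown; codes absent from the map (including `"."`)
#' are unknown and are excluded from predictor denominators.
#'
#' @return A list with elements `gene`, `transcript`, `hgvs_c`, `hgvs_p`,
#'   `consequence`, `cadd`, `pop_af`, `predictors`, `predictor_tools`,
#'   `predictor_map`.
#' @export
default_schema <- function() {
  list(
    gene        = "GENE",
    transcript  = "TRANSCRIPT",
    hgvs_c      = "HGVSC",
    hgvs_p      = "HGVSP",
    consequence = "CSQ",
    cadd        = "CADD",
    pop_af = c(
      gnomad_exomes    = "AF_GNOMAD_EX",
      gnomad_genomes   = "AF_GNOMAD_GE",
      kaviar           = "AF_KAVIAR",
      beacon           = "AF_BEACON",
      bravo            = "AF_BRAVO",
      esp              = "AF_ESP",
      thousand_genomes = "AF_1000G3"
    ),
    predictors      = "DBNSFP",
    predictor_tools = NULL,
    predictor_map   = c(D = "damaging", T = "tolerated")
  )
}

#' Read an annotation schema from a YAML file
#'
#' Keys absent from the file keep their [default_schema()] values, so a
#' config only needs to name the fields that differ.
#'
#' @param path Path to a YAML file whose top-level keys match the names in
#'   [default_schema()].
#' @return A schema list.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  user <- yaml::read_yaml(path)
  schema <- default_schema()
  for (key in names(user)) {
    val <- user[[key]]
    if (key %in% c("pop_af", "predictor_map")) val <- unlist(val)
    if (key == "predictor_tools") val <- as.character(unlist(val))
    schema[[key]] <- val
  }
  schema
}
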