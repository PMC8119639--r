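#' Aggregate per-tool pathogenicity calls
#'
#' Summarizes a vector of normalized predictor calls into the familiar
#' "m of n tools damaging" tally. Unknown calls are excluded from the
#' denominator, so denominators differ per variant (e.g. 12/19 for a
#' missense change widely covered by missense predictors vs 5/9 for a
#' nonsense change). The damaging fraction is undefined (NA), not zero,
#' when no tool gives an informative call.
#'
#' @param calls Named character vector with values
#'   damaging/tolerated/unknown; may be empty.
#' @return List with `n_damaging`, `n_informative` and `damaging_fraction`.
#' @examples
#' aggregate_predictors(c(a = "damaging", b = "damaging", c = "tolerated"))
#' @export
aggregate_predictors <- function(calls) {
  if (length(calls) && !all(calls %in% c("damaging", "tolerated", "unknown"))) {
    stop("predictor calls must be damaging, tolerated or unknown")
  }
  n_damaging <- sum(calls == "damaging")
  n_informative <- sum(calls %in% c("damaging", "tolerated"))
  list(
    n_damaging = n_damaging,
    n_informative = n_informative,
    damaging_fraction = if (n_informative > 0) n_damaging / n_informative else NA_real_
  )
}

#' Prioritization configuration
#'
#' Gates and tier rules for predicted pathogenicity. Defaults: at least
#' half of the informative predictors calling damaging, and CADD >= 20
#' (phred scale; the top 1% most deleterious substitutions genome-wide).
#' `max_report_tier` bounds which tiers enter the default candidate report;
#' lower-priority survivors remain visible via the verbose filter trace.
#'
#' @param min_damaging_fraction Minimum damaging fraction for tier 2.
#' @param min_cadd Minimum phred-scaled CADD score for tier 2.
#' @param max_report_tier Highest (numerically largest) tier included in
#'   the candidate report.
#' @return A list of class `prioritization_config`.
#' @export
prioritization_config <- function(min_damaging_fraction = 0.5,
                                  min_cadd = 20,
                                  max_report_tier = 2) {
  stopifnot(min_damaging_fraction >= 0, min_cadd >= 0, max_report_tier >= 1)
  structure(
    list(min_damaging_fraction = min_damaging_fraction,
         min_cadd = min_cadd, max_report_tier = max_report_tier),
    class = "prioritization_config"
  )
}

#' Build a pathogenicity assessment for one variant
#'
#' Combines the predictor tally, CADD score, consequence class and codon.
#' When the annotated consequence is unknown, it is derived from the HGVS
#' protein string.
#'
#' @param annotation An [annotation_bundle()].
#' @return A list of class `pathogenicity_assessment`.
#' @export
assess_pathogenicity <- function(annotation) {
  agg <- aggregate_predictors(annotation$predictor_calls)
  consequence <- annotation$consequence
  codon <- NA_integer_
  if (!is.na(annotation$hgvs_p)) {
    parsed <- suppressWarnings(parse_hgvs_p(annotation$hgvs_p))
    codon <- parsed$codon
    if (consequence %in% c("unknown", "other") &&
        parsed$consequence != "unknown") {
      consequence <- parsed$consequence
    }
  }
  if (is.na(codon) && !is.na(annotation$cdna_pos)) {
    codon <- codon_of(annotation$cdna_pos)
  }
  structure(
    c(agg, list(cadd = annotation$cadd, consequence = consequence,
                codon = codon)),
    class = "pathogenicity_assessment"
  )
}

#' Assign a pathogenicity tier
#'
#' Tier 1: protein-truncating consequences (stop-gain, frameshift, splice).
#' Tier 2: missense with damaging fraction at or above the gate *and* CADD
#' at or above the gate; a missense variant with no informative predictor
#' calls is gated on CADD alone (truncating-adjacent changes are sparsely
#' covered by missense predictors). Tier 3: everything else that survived
#' the hard filters.
#'
#' @param assessment A [assess_pathogenicity()] result.
#' @param config A [prioritization_config()].
#' @return Integer tier (1, 2 or 3).
#' @export
assign_tier <- function(assessment, config = prioritization_config()) {
  if (assessment$consequence %in% c("stop_gain", "frameshift", "splice")) {
    return(1L)
  }
  if (assessment$consequence == "missense") {
    cadd_ok <- !is.na(assessment$cadd) && assessment$cadd >= config$min_cadd
    frac <- assessment$damaging_fraction
    frac_ok <- is.na(frac) || frac >= config$min_damaging_fraction
    if (cadd_ok && frac_ok) return(2L)
  }
  3L
}

#' Rank assessed candidates into a report table
#'
#' Sort key: tier ascending, then CADD descending (missing CADD last), then
#' damaging fraction descending (undefined last), then genomic coordinate
#' (chrom, pos) ascending. Ranks are contiguous from 1. A tier-1 variant
#' therefore always outranks any tier-2 variant, and re-running on the same
#' input yields an identical ordering (no hidden randomness).
#'
#' @param assessed List of candidate entries, each a list with elements
#'   `variant` (a `variant_record`), `assessment`, `tier`, `segregation`
#'   (a `segregation_result` or compatible summary), `max_af`, `trace`
#'   (data frame of stage/passed/reason) and optionally `network_distance`
#'   and `nearest_seed`.
#' @return A `candidate_report` data frame, one row per candidate.
#' @export
rank_candidates <- function(assessed) {
  if (!length(assessed)) return(empty_candidate_report())
  tier <- vapply(assessed, function(x) as.numeric(x$tier), numeric(1))
  cadd <- vapply(assessed, function(x) {
    v <- x$assessment$cadd
    if (is.na(v)) -Inf else v
  }, numeric(1))
  frac <- vapply(assessed, function(x) {
    v <- x$assessment$damaging_fraction
    if (is.na(v)) -Inf else v
  }, numeric(1))
  chrom <- vapply(assessed, function(x) x$variant$chrom, character(1))
  pos <- vapply(assessed, function(x) as.numeric(x$variant$pos), numeric(1))
  ord <- order(tier, -cadd, -frac, chrom, pos)
  rows <- lapply(seq_along(ord), function(r) {
    x <- assessed[[ord[r]]]
    candidate_row(x, rank = r)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("candidate_report", "data.frame")
  report
}

candidate_row <- function(x, rank) {
  v <- x$variant; a <- x$annotation_override %||% v$annotation
  seg <- x$segregation
  nd <- x$network_distance %||% NA_real_
  data.frame(
    rank = as.integer(rank),
    tier = as.integer(x$tier),
    gene = a$gene %||% NA_character_,
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    hgvs_c = a$hgvs_c, hgvs_p = a$hgvs_p,
    consequence = x$assessment$consequence,
    max_pop_af = x$max_af,
    n_damaging = x$assessment$n_damaging,
    n_predictors = x$assessment$n_informative,
    cadd = x$assessment$cadd,
    segregation_model = seg$model,
    affected_carriers = seg$affected_carriers,
    unaffected_carriers = seg$unaffected_carriers,
    network_distance = nd,
    filter_trace = format_trace(x$trace),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_trace <- function(trace) {
  if (is.null(trace) || !nrow(trace)) return("")
  paste(sprintf("%s:%s(%s)", trace$stage,
                ifelse(trace$passed, "pass", "fail"),
                trace$reason),
        collapse = ";")
}

empty_candidate_report <- function() {
  report <- data.frame(
    rank = integer(0), tier = integer(0), gene = character(0),
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), hgvs_c = character(0), hgvs_p = character(0),
    consequence = character(0), max_pop_af = numeric(0),
    n_damaging = integer(0), n_predictors = integer(0), cadd = numeric(0),
    segregation_model = character(0), affected_carriers = integer(0),
    unaffected_carriers = integer(0), network_distance = numeric(0),
    filter_trace = character(0), stringsAsFactors = FALSE
  )
  class(report) <- c("candidate_report", "data.frame")
  report
}
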