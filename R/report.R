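#' Write a candidate report to a tab-separated file
#'
#' One row per candidate; `network_distance` of `Inf` (gene unreachable
#' from every seed) is written as the token `unreachable`. The file
#' round-trips through [read_candidate_report()].
#'
#' @param report A `candidate_report` data frame (see [rank_candidates()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_candidate_report <- function(report, path) {
  out <- as.data.frame(report)
  nd <- out$network_distance
  out$network_distance <- ifelse(is.na(nd), "NA",
                          ifelse(is.infinite(nd), "unreachable",
                                 format(nd, trim = TRUE, scientific = FALSE)))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write candidate report to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a candidate report written by [write_candidate_report()]
#'
#' @param path Path to the TSV.
#' @return A `candidate_report` data frame.
#' @export
read_candidate_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  report <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "",
                              colClasses = "character")
  for (col in c("rank", "tier", "pos", "n_damaging", "n_predictors",
                "affected_carriers", "unaffected_carriers")) {
    report[[col]] <- as.integer(report[[col]])
  }
  for (col in c("max_pop_af", "cadd")) {
    report[[col]] <- as.numeric(report[[col]])
  }
  nd <- report$network_distance
  report$network_distance <- suppressWarnings(
    ifelse(nd == "unreachable", Inf, as.numeric(nd))
  )
  class(report) <- c("candidate_report", "data.frame")
  report
}
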