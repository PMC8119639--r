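#' Pipeline run configuration
#'
#' Bundles everything [run_prioritization()] needs beyond the input files:
#' hard-filter thresholds, prioritization gates, the annotation schema,
#' per-family inheritance models, an optional proband override, and an
#' optional interaction graph + seed genes for network annotation.
#'
#' `family_models` maps family id to the inheritance models evaluated for
#' that family; a variant is retained when compatible with at least one
#' requested model in at least one family. Families absent from the map
#' get `default_models`. A `de_novo` request for a family with no
#' affected member having both parents in the pedigree is skipped with a
#' warning rather than aborting the run.
#'
#' @param filter A [filter_config()].
#' @param prior A [prioritization_config()].
#' @param schema Annotation schema; see [default_schema()].
#' @param family_models Named list: family id -> character vector of
#'   models from [inheritance_models()].
#' @param default_models Models for families not named in `family_models`.
#' @param proband Named character vector: family id -> proband individual
#'   id for `de_novo` (overrides the first-affected-with-parents default).
#' @param network `NULL`, or a list with `graph` (from [load_edge_list()])
#'   and `seeds` (character vector).
#' @return A list of class `famprior_config`.
#' @export
run_config <- function(filter = filter_config(),
                       prior = prioritization_config(),
                       schema = default_schema(),
                       family_models = list(),
                       default_models = c("dominant_incomplete", "de_novo"),
                       proband = character(0),
                       network = NULL) {
  stopifnot(inherits(filter, "filter_config"),
            inherits(prior, "prioritization_config"))
  for (m in c(unlist(family_models), default_models)) {
    match.arg(m, inheritance_models())
  }
  structure(
    list(filter = filter, prior = prior, schema = schema,
         family_models = family_models, default_models = default_models,
         proband = proband, network = network),
    class = "famprior_config"
  )
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized top-level keys: `filter` (named thresholds for
#' [filter_config()]), `prior` (for [prioritization_config()]), `schema`
#' (inline annotation schema), `panel` (path to a gene-panel file),
#' `family_models`, `default_models`, `proband`, `network` (with `edges`
#' and `seeds` file paths). Relative paths are resolved against the config
#' file's directory.
#'
#' @param path Path to the YAML config.
#' @return A `famprior_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }

  fargs <- y$filter %||% list()
  if (!is.null(fargs$het_ab_range)) fargs$het_ab_range <- as.numeric(unlist(fargs$het_ab_range))
  if (!is.null(y$panel)) fargs$panel_genes <- read_panel(resolve(y$panel))
  if (!is.null(fargs$panel_genes)) fargs$panel_genes <- as.character(unlist(fargs$panel_genes))
  filter <- do.call(filter_config, fargs)

  prior <- do.call(prioritization_config, y$prior %||% list())

  schema <- default_schema()
  if (!is.null(y$schema)) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(y$schema, tmp)
    schema <- read_schema(tmp)
    unlink(tmp)
  }

  network <- NULL
  if (!is.null(y$network)) {
    network <- list(graph = load_edge_list(resolve(y$network$edges)),
                    seeds = read_seed_genes(resolve(y$network$seeds)))
  }

  run_config(filter = filter, prior = prior, schema = schema,
             family_models = lapply(y$family_models %||% list(), unlist),
             default_models = as.character(
               unlist(y$default_models %||% c("dominant_incomplete", "de_novo"))),
             proband = unlist(y$proband %||% character(0)),
             network = network)
}

#' Run the full variant-prioritization cascade
#'
#' Executes, in order: read inputs, per-genotype QC, known-gene panel
#' pre-screen, per-family segregation under the configured inheritance
#' models, population-frequency/novelty filtering, pathogenicity
#' assessment, tiering and ranking. Every variant carries a full filter
#' trace recording each stage's verdict and reason; rejected variants'
#' traces are returned when `verbose_trace = TRUE`.
#'
#' @param vcf_path Annotated multi-sample VCF.
#' @param ped_path 6-column PED file (may contain several families).
#' @param config A [run_config()] (or path handled by [read_run_config()]
#'   upstream).
#' @param verbose_trace Keep traces of rejected variants in the result.
#' @return A list of class `famprior_result` with elements `candidates`
#'   (a `candidate_report`), `in_panel` (report-like rows for panel-gene
#'   hits that survived QC-aware segregation and frequency screens, for
#'   diagnostic follow-up) and, when requested, `rejected` (data frame of
#'   per-variant traces).
#' @export
run_prioritization <- function(vcf_path, ped_path, config = run_config(),
                               verbose_trace = FALSE) {
  pedigree <- read_ped(ped_path)
  if (nrow(pedigree) == 0L) stop("empty pedigree")
  families <- split_families(pedigree)
  records <- read_annotated_vcf(vcf_path, config$schema, pedigree)

  models_by_family <- resolve_family_models(families, config)

  assessed <- list()
  in_panel_rows <- list()
  rejected <- list()

  for (v in records) {
    res <- evaluate_variant(v, families, models_by_family, config)
    if (res$is_candidate) {
      assessed[[length(assessed) + 1L]] <- res$entry
    } else if (identical(res$fail_stage, "panel")) {
      in_panel_rows[[length(in_panel_rows) + 1L]] <- res$entry
    } else if (verbose_trace) {
      rejected[[length(rejected) + 1L]] <- res$entry
    }
  }

  report <- rank_candidates(assessed)
  out <- list(candidates = report,
              in_panel = summarize_rejected(in_panel_rows),
              rejected = if (verbose_trace) summarize_rejected(rejected) else NULL)
  class(out) <- "famprior_result"
  out
}

resolve_family_models <- function(families, config) {
  out <- list()
  for (fam in names(families)) {
    models <- config$family_models[[fam]] %||% config$default_models
    if ("de_novo" %in% models) {
      pb <- config$proband[fam]
      if (is.na(pb) || is.null(pb)) pb <- find_denovo_proband(families[[fam]])
      if (is.na(pb)) {
        warning("family ", fam, ": de_novo model skipped (incomplete trio)")
        models <- setdiff(models, "de_novo")
      }
    }
    out[[fam]] <- models
  }
  out
}

# Evaluate every stage for one variant (all stages always run, so a trace
# is complete even for rejected variants) and decide candidacy.
evaluate_variant <- function(variant, families, models_by_family, config) {
  trace <- data.frame(stage = character(0), passed = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  add <- function(stage, passed, reason) {
    rbind(trace, data.frame(stage = stage, passed = passed, reason = reason,
                            stringsAsFactors = FALSE))
  }

  # -- per-genotype QC (demote, never discard the variant) --
  qc <- apply_genotype_qc(variant, config$filter)
  masked <- qc$variant
  qc_note <- if (nrow(qc$demoted)) {
    paste(sprintf("%s:%s", qc$demoted$sample_id, qc$demoted$reason),
          collapse = ",")
  } else "all genotypes pass"

  # -- panel pre-screen --
  gene <- variant$annotation$gene
  in_panel <- !is.na(gene) && length(config$filter$panel_genes) &&
    toupper(gene) %in% config$filter$panel_genes
  panel_reason <- if (in_panel) paste0("known-gene panel hit: ", toupper(gene))
                  else "outside panel"

  # -- segregation on QC-masked genotypes, per family and model --
  seg_best <- NULL
  compatible_models <- character(0)
  for (fam in names(families)) {
    ped <- families[[fam]]
    for (model in models_by_family[[fam]]) {
      pb <- config$proband[fam]
      if (is.null(pb) || is.na(pb)) pb <- NULL
      s <- segregate(masked, ped, model, config$filter, proband = pb)
      if (s$compatible) {
        compatible_models <- c(compatible_models,
                               paste0(fam, ":", model))
        if (is.null(seg_best)) seg_best <- s
      }
    }
  }
  seg_pass <- length(compatible_models) > 0

  # Attribute QC-caused segregation failures to the QC stage: if the raw
  # (pre-masking) genotypes segregate but the masked ones do not, the
  # quality filter -- not the inheritance pattern -- removed the variant.
  qc_fail <- FALSE
  raw_models <- character(0)
  if (!seg_pass && nrow(qc$demoted)) {
    for (fam in names(families)) {
      for (model in models_by_family[[fam]]) {
        s <- segregate(variant, families[[fam]], model, config$filter)
        if (s$compatible) raw_models <- c(raw_models, paste0(fam, ":", model))
      }
    }
    qc_fail <- length(raw_models) > 0
  }

  trace <- add("genotype_qc", !qc_fail,
               if (qc_fail) paste0("carrier genotype(s) failed QC: ", qc_note)
               else qc_note)
  trace <- add("panel", !in_panel, panel_reason)
  trace <- add("segregation", seg_pass || qc_fail,
               if (seg_pass) paste0("compatible: ",
                                    paste(compatible_models, collapse = "+"))
               else if (qc_fail) paste0("pattern compatible before quality masking: ",
                                        paste(raw_models, collapse = "+"))
               else "incompatible with all configured models")

  # -- population frequency / novelty --
  freq <- frequency_filter(variant$annotation, config$filter)
  trace <- add("frequency", freq$retained,
               sprintf("max pop AF %s (cutoff %s)%s",
                       format(freq$max_af), format(config$filter$max_pop_af),
                       if (freq$novel) ", novel" else ""))

  # -- pathogenicity --
  assessment <- assess_pathogenicity(variant$annotation)
  tier <- assign_tier(assessment, config$prior)
  path_pass <- tier <= config$prior$max_report_tier
  trace <- add("pathogenicity", path_pass,
               sprintf("tier %d (consequence %s, %d/%d damaging, CADD %s)",
                       tier, assessment$consequence, assessment$n_damaging,
                       assessment$n_informative,
                       ifelse(is.na(assessment$cadd), "NA",
                              format(assessment$cadd))))

  seg_summary <- if (!is.null(seg_best)) {
    seg_best$model <- paste(sub("^.*:", "", compatible_models), collapse = "+")
    seg_best
  } else {
    list(model = "none", affected_carriers = NA_integer_,
         unaffected_carriers = NA_integer_)
  }

  entry <- list(variant = variant, assessment = assessment, tier = tier,
                segregation = seg_summary, max_af = freq$max_af,
                novel = freq$novel, trace = trace)

  if (!is.null(config$network) && !is.na(gene)) {
    prox <- proximity(gene, config$network$seeds, config$network$graph)
    entry$network_distance <- prox$distance
    entry$nearest_seed <- prox$nearest_seed
  }

  fails <- trace$stage[!trace$passed]
  list(is_candidate = length(fails) == 0,
       fail_stage = if (length(fails)) fails[1] else NA_character_,
       entry = entry)
}

summarize_rejected <- function(entries) {
  if (!length(entries)) {
    return(data.frame(gene = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), fail_stages = character(0),
                      filter_trace = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(entries, function(x) {
    data.frame(
      gene = x$variant$annotation$gene %||% NA_character_,
      chrom = x$variant$chrom, pos = x$variant$pos,
      ref = x$variant$ref, alt = x$variant$alt,
      fail_stages = paste(x$trace$stage[!x$trace$passed], collapse = ","),
      filter_trace = format_trace(x$trace),
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.famprior_result <- function(x, ...) {
  cat("famprior result:", nrow(x$candidates), "candidate(s)")
  if (nrow(x$in_panel)) cat(";", nrow(x$in_panel), "panel-gene hit(s)")
  cat("\n")
  if (nrow(x$candidates)) {
    print(as.data.frame(
      x$candidates[, c("rank", "tier", "gene", "hgvs_p", "consequence",
                       "cadd", "segregation_model")]
    ))
  }
  invisible(x)
}
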