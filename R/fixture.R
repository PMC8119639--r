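#' Deterministic two-family worked-example fixture
#'
#' Writes a complete, fully deterministic test dataset: Family 1 is a
#' six-member dominant family with incomplete penetrance carrying the
#' built-in TNIP2 missense spike in two affected members and one unaffected
#' sibling; Family 2 is a trio carrying the TRAF2 nonsense spike de novo in
#' the proband. One decoy per filter class and a background of non-causal
#' variants are included. Running [run_prioritization()] on the fixture
#' returns exactly the two spiked variants, the truncating TRAF2 variant
#' ranked first.
#'
#' The carrier/affection pattern is hard-coded rather than sampled (no
#' penetrance value is asserted as fact); the seed only drives read-depth
#' and quality sampling.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed for the FORMAT-field sampling.
#' @return List with `vcf`, `ped`, `config` (a ready `famprior_config`)
#'   and `config_path` (YAML consumed by the command-line interface).
#' @export
make_paper_fixture <- function(dir = tempfile("famprior_fixture"), seed = 104729) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ped1 <- pedigree_template("six_member_two_affected", "F1")
  ped1$affected <- ifelse(ped1$id %in% c("F1-II.1", "F1-III.1"),
                          "affected", "unaffected")
  ped1 <- validate_pedigree(ped1)
  gt1 <- setNames(rep("hom_ref", 6), ped1$id)
  gt1[c("F1-II.1", "F1-III.1", "F1-II.3")] <- "het"

  ped2 <- pedigree_template("trio", "F2")
  ped2$affected <- ifelse(ped2$id == "F2-II.1", "affected", "unaffected")
  ped2 <- validate_pedigree(ped2)
  gt2 <- setNames(c("hom_ref", "hom_ref", "het"), ped2$id)

  config <- synthetic_family_config(
    seed = seed, n_background_variants = 25,
    decoy_plan = c("qc_fail", "common_af", "non_segregating",
                   "benign_prediction", "panel_gene"))

  vcf_path <- file.path(dir, "cohort.vcf")
  ped_path <- file.path(dir, "cohort.ped")
  generate_vcf(
    families = list(F1 = list(pedigree = ped1, genotypes = gt1),
                    F2 = list(pedigree = ped2, genotypes = gt2)),
    spikes = list(F1 = builtin_spikes()$TNIP2,
                  F2 = builtin_spikes()$TRAF2),
    config = config, vcf_path = vcf_path, ped_path = ped_path)

  cfg <- write_scenario_config(dir)
  list(vcf = vcf_path, ped = ped_path, config = cfg$config,
       config_path = cfg$config_path)
}

# copy the bundled panel / edge list / seed genes next to the dataset and
# write a YAML run config referencing them by relative name
write_scenario_config <- function(dir) {
  for (f in c("pah_panel.txt", "pah_edges.tsv", "pah_seed_genes.txt")) {
    file.copy(system.file("extdata", f, package = "famprior"),
              file.path(dir, f), overwrite = TRUE)
  }
  config_path <- file.path(dir, "famprior.yaml")
  yaml::write_yaml(list(
    panel = "pah_panel.txt",
    default_models = c("dominant_incomplete", "de_novo"),
    network = list(edges = "pah_edges.tsv", seeds = "pah_seed_genes.txt")
  ), config_path)
  list(config = read_run_config(config_path), config_path = config_path)
}

#' Simulate a named scenario to disk
#'
#' Convenience wrapper used by the command-line interface and the test
#' suite. `"paper"` writes the deterministic two-family worked example
#' ([make_paper_fixture()]); `"dominant"` simulates a six-member dominant
#' family with incomplete penetrance (penetrance 0.75) carrying the TNIP2
#' spike; `"denovo"` simulates a trio carrying the TRAF2 spike de novo.
#' The stochastic scenarios include the full decoy plan and 20 background
#' variants.
#'
#' @param scenario One of `paper`, `dominant`, `denovo`.
#' @param seed Master seed.
#' @param dir Output directory.
#' @param genotype_error_rate Per-call genotype error probability
#'   (stochastic scenarios only).
#' @return List with `vcf`, `ped`, `config`, `config_path`.
#' @export
simulate_scenario <- function(scenario = c("paper", "dominant", "denovo"),
                              seed, dir = tempfile("famprior_sim"),
                              genotype_error_rate = 0) {
  scenario <- match.arg(scenario)
  if (scenario == "paper") {
    if (missing(seed)) seed <- 104729
    return(make_paper_fixture(dir, seed))
  }
  if (missing(seed)) stop("seed is mandatory for stochastic scenarios")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  decoys <- c("qc_fail", "common_af", "non_segregating",
              "benign_prediction", "panel_gene")
  if (scenario == "dominant") {
    config <- synthetic_family_config(
      template = "six_member_two_affected", model = "dominant_incomplete",
      penetrance = 0.75, n_background_variants = 20, decoy_plan = decoys,
      genotype_error_rate = genotype_error_rate, seed = seed,
      family_id = "F1")
    spike <- builtin_spikes()$TNIP2
  } else {
    config <- synthetic_family_config(
      template = "trio", model = "de_novo", penetrance = 1,
      n_background_variants = 20, decoy_plan = decoys,
      genotype_error_rate = genotype_error_rate, seed = seed,
      family_id = "F1")
    spike <- builtin_spikes()$TRAF2
  }
  fam <- simulate_family(config)
  vcf_path <- file.path(dir, "cohort.vcf")
  ped_path <- file.path(dir, "cohort.ped")
  generate_vcf(families = setNames(list(fam), config$family_id),
               spikes = setNames(list(spike), config$family_id),
               config = config, vcf_path = vcf_path, ped_path = ped_path)
  cfg <- write_scenario_config(dir)
  list(vcf = vcf_path, ped = ped_path, config = cfg$config,
       config_path = cfg$config_path)
}
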