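# End-to-end pipelines wiring the stages together. Each run_* function is
# a thin orchestration over the module functions and writes a
# machine-readable run report (tool version, config echo, input digests,
# seed) next to its outputs.

write_run_report <- function(out_dir, step, config, inputs = character(),
                             extra = list()) {
  digests <- if (length(inputs) > 0)
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  report <- c(list(
    tool = "picspec",
    version = as.character(utils::packageVersion("picspec")),
    step = step,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_digests = digests), extra)
  path <- file.path(out_dir, sprintf("%s_run_report.json", step))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

config_echo <- function(config) {
  lapply(config, function(x) {
    if (inherits(x, "enzyme_spec"))
      list(name = x$name, p1 = paste(x$p1_residues, collapse = ""),
           blocked = paste(x$blocked_p1prime_residues, collapse = ""))
    else if (is.atomic(x)) x
    else NULL
  })
}

#' Simulate a PICS experiment and write its inputs to disk
#'
#' Writes the proteome FASTA, the control/treated PSM tables and the
#' ground-truth JSON for a simulated peptide-library experiment.
#'
#' @param proteome Named list of [protein_record()] objects.
#' @param model A [specificity_model()].
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return List of written paths plus the in-memory simulation result.
#' @export
run_simulate <- function(proteome, model, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(proteome, model, config)
  paths <- list(
    proteome = file.path(out_dir, "proteome.fasta"),
    control = file.path(out_dir, "psm_control.csv"),
    treated = file.path(out_dir, "psm_treated.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json"))
  write_fasta(proteome, paths$proteome)
  write_psm_table(sim$psm$control, paths$control)
  write_psm_table(sim$psm$treated, paths$treated)
  write_ground_truth(sim$ground_truth, paths$ground_truth)
  write_run_report(out_dir, "simulate",
                   config_echo(unclass(config)),
                   extra = list(seed = config$seed,
                                n_proteins = length(proteome),
                                n_library_peptides = nrow(sim$library),
                                n_ground_truth_sites = nrow(sim$ground_truth)))
  c(paths, list(simulation = sim))
}

#' Run the full PICS profiling pipeline
#'
#' parse -> classify -> map -> reconstruct -> statistics -> export: turns a
#' pair of channel-labeled PSM tables and the source proteome into unique
#' P6-P6' cleavage sites and a specificity profile, and writes the census.
#'
#' @param psm_paths Character vector of PSM CSV paths (control + treated).
#' @param proteome_path Proteome FASTA path.
#' @param design An [experiment_design()].
#' @param out_dir Output directory.
#' @param alpha Significance level for the percent-difference profile.
#' @param experiment Experiment tag.
#' @return List with `sites`, `census`, `profile` and written paths.
#' @export
run_pics_profile <- function(psm_paths, proteome_path, design,
                             out_dir, alpha = 0.05, experiment = "pics") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proteome <- read_fasta(proteome_path)
  records <- do.call(rbind, lapply(psm_paths, parse_psm_table,
                                   confidence_threshold =
                                     design$confidence_threshold))
  index <- proteome_index(proteome, collapse_il = design$collapse_il)
  classified <- classify_peptides(records, design, index)
  recon <- reconstruct_sites(classified, index, design,
                             experiment = experiment)
  background <- background_frequencies(proteome,
                                       proteome_id = basename(proteome_path))
  profile <- NULL
  site_path <- file.path(out_dir, "sites.tsv")
  write_sites(recon$sites, site_path)
  if (nrow(recon$sites) > 0) {
    profile <- specificity_profile(recon$sites, background, alpha = alpha)
    export_profile(profile, out_dir, prefix = experiment)
  }
  census_path <- file.path(out_dir, "census.json")
  jsonlite::write_json(recon$census, census_path, auto_unbox = TRUE,
                       digits = NA)
  write_run_report(out_dir, "pics_profile",
                   list(psm_paths = psm_paths, proteome = proteome_path,
                        confidence_threshold = design$confidence_threshold,
                        library_enzyme = design$library_enzyme$name,
                        require_treated_only = design$require_treated_only,
                        alpha = alpha),
                   inputs = c(psm_paths, proteome_path),
                   extra = list(census = recon$census))
  list(sites = recon$sites, census = recon$census, profile = profile,
       paths = list(sites = site_path, census = census_path))
}

#' Run the protein-substrate profiling pipeline
#'
#' Infers unique cleavage sites from one or more substrate digests (single
#' and/or sequential mode), computes per-substrate coverage, performs the
#' unique-site set algebra across experiments and exports a combined
#' specificity profile.
#'
#' @param peptide_sets Named list: per experiment tag, a character vector
#'   of identified peptide sequences.
#' @param experiments Named list of [substrate_experiment()] objects with
#'   matching names.
#' @param background A [background_frequencies()] vector for the profile.
#' @param out_dir Output directory.
#' @param alpha Significance level.
#' @return List with per-experiment `sites`, `coverage`, the `summary` set
#'   algebra, and the combined `profile`.
#' @export
run_substrate_profile <- function(peptide_sets, experiments, background,
                                  out_dir, alpha = 0.05) {
  stopifnot(identical(sort(names(peptide_sets)), sort(names(experiments))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (tag in names(peptide_sets)) {
    res <- infer_substrate_sites(peptide_sets[[tag]], experiments[[tag]])
    write_sites(res$sites, file.path(out_dir, sprintf("sites_%s.tsv", tag)))
    results[[tag]] <- res
  }
  site_sets <- lapply(results, function(r) r$sites)
  summary <- site_set_algebra(site_sets)
  write_set_summary(summary, file.path(out_dir, "set_summary.json"))
  all_windows <- unique(unlist(lapply(site_sets, function(s) s$window)))
  profile <- NULL
  if (length(all_windows) > 0) {
    profile <- specificity_profile(all_windows, background, alpha = alpha)
    export_profile(profile, out_dir, prefix = "substrate")
  }
  coverage <- list()
  for (tag in names(peptide_sets)) {
    for (sub_id in names(experiments[[tag]]$substrates)) {
      cov <- compute_coverage(peptide_sets[[tag]],
                              experiments[[tag]]$substrates[[sub_id]])
      coverage[[paste(tag, sub_id, sep = ":")]] <- cov
      format_coverage_map(cov, file.path(out_dir,
        sprintf("coverage_%s_%s.txt", tag, sub_id)))
    }
  }
  write_run_report(out_dir, "substrate_profile",
                   list(experiments = names(experiments), alpha = alpha),
                   extra = list(set_sizes = as.list(summary$sizes),
                                grand_union = summary$grand_union))
  list(results = results, summary = summary, profile = profile,
       coverage = coverage)
}
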