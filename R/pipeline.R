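#' Default pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list
#' that round-trips losslessly through YAML. Defaults are the standard
#' analysis constants: depth filter 100, FDR 0.5%, consistency tiers
#' 100/90/80%, coverage filter 15 crosses / 3 maize / 5 teosinte inbreds,
#' D/A thresholds 0.25 and 0.75-1.25, Dixon alpha 0.05.
#'
#' @param min_depth Minimum depth in both hybrid and parent comparison.
#' @param fdr_threshold q-value significance threshold.
#' @param tier_thresholds Named vector `c(A=, B=, C=)` of consistency cuts.
#' @param min_crosses,min_maize,min_teosinte Coverage filter thresholds.
#' @param da_additive,da_dominant_low,da_dominant_high D/A class bounds.
#' @param dixon_alpha Dixon filter significance level.
#' @param n_boot Bootstrap replicates for the cis-share bins.
#' @param seed Master seed for simulation and bootstraps.
#' @param n_genes Number of genes when the pipeline simulates its input.
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_depth = 100, fdr_threshold = 0.005,
                       tier_thresholds = c(A = 1.0, B = 0.9, C = 0.8),
                       min_crosses = 15, min_maize = 3, min_teosinte = 5,
                       da_additive = 0.25, da_dominant_low = 0.75,
                       da_dominant_high = 1.25, dixon_alpha = 0.05,
                       n_boot = 200, seed = 1L, n_genes = 500L) {
  cfg <- list(min_depth = min_depth, fdr_threshold = fdr_threshold,
              tier_thresholds = tier_thresholds, min_crosses = min_crosses,
              min_maize = min_maize, min_teosinte = min_teosinte,
              da_additive = da_additive, da_dominant_low = da_dominant_low,
              da_dominant_high = da_dominant_high,
              dixon_alpha = dixon_alpha, n_boot = n_boot,
              seed = as.integer(seed), n_genes = as.integer(n_genes))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A configuration list.
#' @export
validate_config <- function(cfg) {
  stopifnot(cfg$min_depth >= 0,
            cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
            all(cfg$tier_thresholds <= 1), all(cfg$tier_thresholds >= 0),
            !is.unsorted(rev(unname(cfg$tier_thresholds))),
            cfg$min_crosses >= 1, cfg$min_maize >= 1, cfg$min_teosinte >= 1,
            cfg$da_additive > 0, cfg$da_dominant_low > cfg$da_additive,
            cfg$da_dominant_high > cfg$da_dominant_low,
            cfg$dixon_alpha > 0, cfg$dixon_alpha < 1,
            cfg$n_boot >= 0, cfg$n_genes >= 1)
  invisible(TRUE)
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A [run_config()] object.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   validated `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.null(names(x))) x else as.list(x)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$tier_thresholds <- unlist(obj$tier_thresholds)
  do.call(run_config, obj)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order and writes one TSV per stage
#' output plus a YAML run manifest (package version, seed, configuration and
#' its hash) into `out_dir`. When `counts` / `design` are `NULL` the
#' pipeline simulates its own input with [simulate_design()] /
#' [simulate_counts()] under `cfg$seed`, writing the planted truth alongside.
#' All outputs have headers and deterministic row order, so a re-run with
#' the same inputs and seed is byte-identical.
#'
#' @param cfg A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param counts Optional replicate-level count data.frame; simulated when
#'   `NULL`.
#' @param design Optional `cross_design`; simulated when `NULL`.
#' @return Invisibly, a list with the main in-memory results
#'   (`ratios`, `overall`, `calls`, `membership`, `dominance`, `varpart`).
#' @export
run_all <- function(cfg = run_config(), out_dir, counts = NULL,
                    design = NULL) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  simulated <- is.null(counts)
  if (is.null(design)) design <- simulate_design(seed = cfg$seed)
  validate_design(design)
  truth <- NULL
  if (simulated) {
    params <- sim_params(n_genes = cfg$n_genes, seed = cfg$seed)
    truth <- simulate_truth(design, params)
    counts <- simulate_counts(design, truth, params)
    write_tsv(truth$truth, file.path(out_dir, "truth.tsv"))
  } else {
    validate_counts(counts)
  }
  write_design(design, file.path(out_dir, "design.yaml"))

  pooled <- pool_replicates(counts)
  ratios <- cross_ratios(pooled, design, min_depth = cfg$min_depth)
  write_tsv(ratios, file.path(out_dir, "cross_ratios.tsv"))

  overall <- overall_ratios(ratios)
  write_tsv(overall, file.path(out_dir, "overall_ratios.tsv"))

  cls <- classify_all(overall, fdr = cfg$fdr_threshold)
  write_tsv(cls$calls, file.path(out_dir, "regulatory_calls.tsv"))
  write_tsv(cls$summary, file.path(out_dir, "category_summary.tsv"))

  cons <- consistency_tier(ratios)
  membership <- build_lists(cls$calls, cons,
                            min_crosses = cfg$min_crosses,
                            min_maize = cfg$min_maize,
                            min_teosinte = cfg$min_teosinte)
  write_tsv(membership, file.path(out_dir, "candidate_lists.tsv"))

  bins <- cis_share_by_bin(overall, n_boot = cfg$n_boot, seed = cfg$seed)
  write_tsv(bins, file.path(out_dir, "cis_share_bins.tsv"))
  loo <- loo_influence(ratios)
  if (nrow(loo$per_gene))
    write_tsv(loo$per_gene, file.path(out_dir, "loo_influence.tsv"))

  vp <- variance_partition(balance_design(ratios))
  write_tsv(vp, file.path(out_dir, "variance_partition.tsv"))
  sig <- count_significant_parents(vp)
  write_tsv(sig, file.path(out_dir, "variance_significance.tsv"))

  dom <- dominance_table(ratios, alpha = cfg$dixon_alpha)
  write_tsv(dom, file.path(out_dir, "dominance.tsv"))

  manifest <- list(
    package = "cistrans",
    version = as.character(utils::packageVersion("cistrans")),
    seed = cfg$seed,
    simulated_input = simulated,
    config = lapply(unclass(cfg), function(x)
      if (is.null(names(x))) x else as.list(x)),
    config_hash = rlang::hash(unclass(cfg)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(design = design, truth = truth, ratios = ratios,
                 overall = overall, calls = cls$calls,
                 summary = cls$summary, membership = membership,
                 bins = bins, varpart = vp, dominance = dom))
}
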