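#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with its default: DEGs at fold-change > 1.5 and
#' FDR < 0.05; DAPs at t-test p < 0.05; a 40 kb window centred on the TSS for
#' peak-gene linkage; soft-threshold powers 10 (RNA) and 14 (protein);
#' eigengene merge dissimilarity 0.25; module-overlap admission at FDR < 0.05
#' with >= 10 shared members; connector admission at FDR < 0.01 with >= 5
#' (PPI) or >= 4 (regulatory network) connections; expression restriction at
#' mean RPKM > 0.5 in at least one condition; community detection with clique
#' size 6 and complex size 2.
#'
#' @param window_bp TSS window width in bp (even, > 0).
#' @param rrho_step RRHO rank step; `NULL` means `max(1, floor(N/100))`.
#' @param soft_power_rna,soft_power_prot soft-threshold powers per layer.
#' @param merge_dissimilarity eigengene dissimilarity below which modules merge.
#' @param min_module_size,cut_height module detection parameters
#'   (`cut_height` applies to the RNA layer network).
#' @param cut_height_prot static cut height for the protein-layer network;
#'   higher than `cut_height` because the larger soft power compresses
#'   topological overlap toward zero.
#' @param n_resamples resamples for module quality Z (100 for desk scale;
#'   1000 reproduces the full-scale analysis).
#' @param deg_fc,deg_fdr DEG selection: fold-change and FDR thresholds.
#' @param dap_p DAP selection p-value threshold.
#' @param overlap_fdr,overlap_min module-overlap admission rule.
#' @param connector_fdr,connector_min_ppi,connector_min_grn connector
#'   admission rule per network kind.
#' @param expressed_rpkm expression threshold for network restriction.
#' @param clique_size,complex_size community detection thresholds.
#' @param seed integer seed recorded in all outputs.
#' @param paths named list of input paths (see [run_pipeline()]).
#' @param stages character vector of stages to run.
#' @param synthetic logical; generate inputs with the synthetic module.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window_bp = 40000L,
                       rrho_step = NULL,
                       soft_power_rna = 10L,
                       soft_power_prot = 14L,
                       merge_dissimilarity = 0.25,
                       min_module_size = 20L,
                       cut_height = 0.99,
                       cut_height_prot = 0.999,
                       n_resamples = 100L,
                       deg_fc = 1.5,
                       deg_fdr = 0.05,
                       dap_p = 0.05,
                       overlap_fdr = 0.05,
                       overlap_min = 10L,
                       connector_fdr = 0.01,
                       connector_min_ppi = 5L,
                       connector_min_grn = 4L,
                       expressed_rpkm = 0.5,
                       clique_size = 6L,
                       complex_size = 2L,
                       seed = NULL,
                       paths = list(),
                       stages = c("rrho", "link-ocr", "modules", "preserve",
                                  "overlap", "network"),
                       synthetic = FALSE) {
  cfg <- list(window_bp = as.integer(window_bp), rrho_step = rrho_step,
              soft_power_rna = as.integer(soft_power_rna),
              soft_power_prot = as.integer(soft_power_prot),
              merge_dissimilarity = merge_dissimilarity,
              min_module_size = as.integer(min_module_size),
              cut_height = cut_height,
              cut_height_prot = cut_height_prot,
              n_resamples = as.integer(n_resamples),
              deg_fc = deg_fc, deg_fdr = deg_fdr, dap_p = dap_p,
              overlap_fdr = overlap_fdr, overlap_min = as.integer(overlap_min),
              connector_fdr = connector_fdr,
              connector_min_ppi = as.integer(connector_min_ppi),
              connector_min_grn = as.integer(connector_min_grn),
              expressed_rpkm = expressed_rpkm,
              clique_size = as.integer(clique_size),
              complex_size = as.integer(complex_size),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              paths = paths, stages = stages, synthetic = isTRUE(synthetic))
  thresholds <- c("window_bp", "soft_power_rna", "soft_power_prot",
                  "merge_dissimilarity", "min_module_size", "cut_height", "cut_height_prot",
                  "n_resamples", "deg_fc", "deg_fdr", "dap_p", "overlap_fdr",
                  "overlap_min", "connector_fdr", "connector_min_ppi",
                  "connector_min_grn", "expressed_rpkm", "clique_size",
                  "complex_size")
  for (nm in thresholds)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be a positive scalar")
  if (cfg$window_bp %% 2L != 0L) stop("window_bp must be even")
  if (!is.null(cfg$rrho_step) &&
      (!is.numeric(cfg$rrho_step) || cfg$rrho_step < 1))
    stop("rrho_step must be >= 1 or NULL")
  cfg$synthetic <- isTRUE(synthetic)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}
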