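#' Evenly spaced synthetic gene annotation
#'
#' TSSs placed every `spacing` bp on one chromosome so that default TSS
#' windows do not overlap between neighbouring genes.
#'
#' @param gene_ids gene identifiers.
#' @param spacing distance between consecutive TSSs (default 100000).
#' @param chrom chromosome name.
#' @return A [gene_annotation()].
#' @export
synthetic_annotation <- function(gene_ids, spacing = 100000L, chrom = "chr1") {
  n <- length(gene_ids)
  gene_annotation(gene_ids, rep(chrom, n),
                  tss = 50000L + spacing * (seq_len(n) - 1L),
                  strand = rep(c("+", "-"), length.out = n))
}

#' Run the integration pipeline
#'
#' Executes the requested stages and writes every result as delimited text
#' plus a single JSON manifest recording the package version, seed,
#' thresholds, and per-stage record counts. Given an identical configuration
#' and seed the run is idempotent: manifests are byte-identical.
#'
#' In synthetic mode the generator module produces all inputs (written under
#' `out_dir/inputs` together with `truth.json`). Otherwise `config$paths`
#' must name the input files each enabled stage needs: `mrna_values`,
#' `mrna_meta`, `prot_values`, `prot_meta` (modules/preserve/overlap),
#' `mrna_table`, `prot_table` (rrho/link-ocr/overlap), `peaks`, `annotation`
#' (link-ocr), `network` (network).
#'
#' @param config a [run_config()]; `config$seed` is required in synthetic
#'   mode.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  if (config$synthetic && is.null(config$seed))
    stop("config error: synthetic mode requires a seed")
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(package = "interomics",
                   version = as.character(utils::packageVersion("interomics")),
                   seed = config$seed,
                   synthetic = config$synthetic,
                   stages = stages,
                   thresholds = config[c("window_bp", "soft_power_rna",
                                         "soft_power_prot",
                                         "merge_dissimilarity",
                                         "min_module_size", "cut_height",
                                         "cut_height_prot",
                                         "n_resamples", "deg_fc", "deg_fdr",
                                         "dap_p", "overlap_fdr", "overlap_min",
                                         "connector_fdr", "connector_min_ppi",
                                         "connector_min_grn", "expressed_rpkm",
                                         "clique_size", "complex_size")],
                   counts = list())
  inputs <- list()
  if (config$synthetic) {
    inputs <- run_stage("simulate", .synthetic_inputs(config, out_dir))
  } else {
    inputs <- run_stage("load-inputs", .load_inputs(config, stages))
  }
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    df <- as.data.frame(df)
    df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  if ("rrho" %in% stages) {
    run_stage("rrho", {
      ra <- rank_by_fold_change(inputs$mrna_table)
      rb <- rank_by_fold_change(inputs$prot_table)
      map <- rrho_map(ra, rb, step = config$rrho_step)
      utils::write.table(map$k_matrix, file.path(out_dir, "rrho_k.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(round(map$neglog_p, 6),
                         file.path(out_dir, "rrho_neglog_p.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(round(map$neglog_p_adj, 6),
                         file.path(out_dir, "rrho_neglog_p_adj.tsv"),
                         sep = "\t", quote = FALSE)
      sig <- shared_top_signature(ra, rb, n_top = 150L)
      tsv(data.frame(gene_id = sig), "rrho_shared_signature.tsv")
      manifest$counts$rrho <- list(universe = map$universe_n, step = map$step,
                                    max_neglog_p_adj = round(max(map$neglog_p_adj), 4),
                                    signature_size = length(sig))
    })
  }
  if ("link-ocr" %in% stages) {
    run_stage("link-ocr", {
      if (is.null(inputs$annotation))
        stop("config error: annotation required for link-ocr")
      links <- link_peaks_to_genes(inputs$peaks, inputs$annotation,
                                   window_bp = config$window_bp)
      tsv(links, "ocr_links.tsv")
      freq <- status_frequency_by_links(links, inputs$mrna_table)
      tsv(freq, "ocr_status_frequency.tsv")
      up <- inputs$mrna_table$feature_id[inputs$mrna_table$status %in% "up"]
      enr <- tryCatch(gained_enrichment_chi2(links, up,
                                             inputs$annotation$gene_id),
                      error = function(e) NULL)
      manifest$counts$link_ocr <- list(
        n_peaks = nrow(inputs$peaks),
        n_linked_genes = sum(links$n_gained + links$n_stable + links$n_lost > 0),
        chi2_up_vs_gained = if (is.null(enr)) NA else round(enr$chi2, 4),
        chi2_one_sided_p = if (is.null(enr)) NA else signif(enr$p_one_sided, 6))
    })
  }
  modules <- list()
  if (any(c("modules", "preserve", "overlap") %in% stages)) {
    run_stage("modules", {
      for (layer in c("mrna", "protein")) {
        mat <- inputs[[if (layer == "mrna") "mrna_matrix" else "prot_matrix"]]
        power <- if (layer == "mrna") config$soft_power_rna else config$soft_power_prot
        cut <- if (layer == "mrna") config$cut_height else config$cut_height_prot
        if (layer == "protein") mat <- suppressWarnings(normalize_within_group(mat))
        net <- build_network(mat, soft_power = power)
        ms <- suppressWarnings(
          detect_modules(net, min_module_size = config$min_module_size,
                         cut_height = cut))
        ms <- merge_modules(ms, mat,
                            dissimilarity_threshold = config$merge_dissimilarity)
        modules[[layer]] <- list(matrix = mat, network = net, modules = ms,
                                  power = power)
        tsv(data.frame(feature_id = names(ms$assignment),
                       module = unname(ms$assignment)),
            sprintf("modules_%s.tsv", layer))
        if (length(ms$eigengenes)) {
          E <- do.call(cbind, ms$eigengenes)
          colnames(E) <- paste0("module_", names(ms$eigengenes))
          tsv(data.frame(sample = rownames(mat$sample_meta), E),
              sprintf("eigengenes_%s.tsv", layer))
        }
        manifest$counts[[paste0("modules_", layer)]] <-
          list(n_modules = length(unique(ms$assignment[ms$assignment > 0])),
               n_assigned = sum(ms$assignment > 0))
      }
    })
  }
  if ("preserve" %in% stages) {
    run_stage("preserve", {
      for (layer in names(modules)) {
        if (!any(modules[[layer]]$modules$assignment > 0)) {
          manifest$counts[[paste0("preserve_", layer)]] <-
            list(n_high_quality = 0L, min_z_summary = NA)
          next
        }
        q <- module_quality(modules[[layer]]$matrix, modules[[layer]]$modules,
                            n_resamples = config$n_resamples,
                            seed = if (is.null(config$seed)) 1L else config$seed,
                            soft_power = modules[[layer]]$power)
        tsv(data.frame(q), sprintf("module_quality_%s.tsv", layer))
        manifest$counts[[paste0("preserve_", layer)]] <-
          list(n_high_quality = sum(q$z_summary > 10),
               min_z_summary = round(min(q$z_summary), 4))
      }
    })
  }
  overlap_res <- NULL
  if ("overlap" %in% stages) {
    run_stage("overlap", {
      deg <- select_deg(inputs$mrna_table, fc = config$deg_fc,
                        fdr = config$deg_fdr)
      dap <- select_dap(inputs$prot_table, p = config$dap_p)
      mm <- module_members(modules$mrna$modules, restrict_to = deg)
      pm <- module_members(modules$protein$modules, restrict_to = dap)
      universe <- unique(c(unlist(mm), unlist(pm)))
      if (length(mm) && length(pm) && length(universe)) {
        overlap_res <- module_overlap(mm, pm, universe,
                                      overlap_fdr = config$overlap_fdr,
                                      overlap_min = config$overlap_min)
        tsv(overlap_res, "module_overlap.tsv")
      }
      manifest$counts$overlap <- list(
        n_deg = length(deg), n_dap = length(dap),
        n_pairs_tested = if (is.null(overlap_res)) 0L else nrow(overlap_res),
        n_significant = if (is.null(overlap_res)) 0L
                        else sum(overlap_res$significant))
    })
  }
  if ("network" %in% stages) {
    run_stage("network", {
      # one module network per significant overlapping pair, as in the
      # per-module PPI analysis; fall back to an explicitly given module
      module_list <- list()
      if (!is.null(overlap_res) && any(overlap_res$significant)) {
        sig <- overlap_res[overlap_res$significant, ]
        module_list <- stats::setNames(sig$shared_ids,
                                       sprintf("pair_%s_%s", sig$mrna_module,
                                               sig$prot_module))
      }
      if (!is.null(inputs$network_module))
        module_list$given <- inputs$network_module
      if (!length(module_list))
        stop("no module available for network analysis")
      n_admitted <- 0L; n_nodes_total <- 0L; n_comms <- 0L
      for (nm in names(module_list)) {
        conn <- suppressMessages(
          connector_enrichment(inputs$network, module_list[[nm]],
                               min_connections = config$connector_min_ppi,
                               fdr_threshold = config$connector_fdr))
        tsv(conn, sprintf("connectors_%s.tsv", nm))
        sub <- build_module_network(inputs$network, module_list[[nm]], conn,
                                    table = inputs$prot_table)
        write_edge_list(sub$edges,
                        file.path(out_dir, sprintf("module_network_edges_%s.tsv", nm)))
        tsv(sub$nodes, sprintf("module_network_nodes_%s.tsv", nm))
        comm <- tryCatch(detect_communities(sub$edges,
                                            clique_size = config$clique_size,
                                            complex_size = config$complex_size),
                         warning = function(w) NULL)
        n_admitted <- n_admitted + sum(conn$admitted)
        n_nodes_total <- n_nodes_total + nrow(sub$nodes)
        n_comms <- n_comms + if (is.null(comm)) 0L else length(comm$communities)
      }
      manifest$counts$network <- list(
        n_module_networks = length(module_list),
        n_admitted_connectors = n_admitted,
        n_subgraph_nodes = n_nodes_total,
        n_communities = n_comms)
    })
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}

# Generate every synthetic input, write it under out_dir/inputs, and return
# the in-memory objects keyed as the stages expect.
.synthetic_inputs <- function(config, out_dir) {
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  sim <- simulate_multiomics(seed = seed)
  annotation <- synthetic_annotation(rownames(sim$mrna$values))
  up <- sim$tables$mrna_24h$feature_id[sim$tables$mrna_24h$status == "up"]
  pk <- simulate_peaks(annotation, up, window_bp = config$window_bp,
                       seed = seed + 1L)
  genes <- rownames(sim$mrna$values)
  module_nodes <- names(sim$truth$assignment_mrna)[sim$truth$assignment_mrna == 1][1:20]
  net <- simulate_background_network(n_nodes = length(genes), module = module_nodes,
                                     seed = seed + 2L, nodes = genes)
  write_expression_matrix(sim$mrna, file.path(in_dir, "mrna_values.tsv"),
                          file.path(in_dir, "mrna_meta.tsv"))
  write_expression_matrix(sim$protein, file.path(in_dir, "prot_values.tsv"),
                          file.path(in_dir, "prot_meta.tsv"))
  write_differential_table(sim$tables$mrna_24h,
                           file.path(in_dir, "mrna_table.tsv"))
  write_differential_table(sim$tables$protein_24h,
                           file.path(in_dir, "prot_table.tsv"))
  write_bed_peaks(pk$peaks, file.path(in_dir, "peaks.bed"))
  write_gene_annotation(annotation, file.path(in_dir, "annotation.bed"))
  write_edge_list(net$edges, file.path(in_dir, "network.tsv"))
  jsonlite::write_json(list(seed = seed,
                            multiomics = list(assignment = as.list(sim$truth$assignment_mrna),
                                              effects = sim$truth$effects),
                            peaks = pk$truth,
                            network = net$truth),
                       file.path(in_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(mrna_matrix = sim$mrna, prot_matrix = sim$protein,
       mrna_table = sim$tables$mrna_24h, prot_table = sim$tables$protein_24h,
       peaks = pk$peaks, annotation = annotation, network = net$edges,
       network_module = module_nodes)
}

.load_inputs <- function(config, stages) {
  p <- config$paths
  need <- function(keys, stage) {
    miss <- keys[!vapply(keys, function(k) !is.null(p[[k]]), TRUE)]
    if (length(miss))
      stop("config error: stage '", stage, "' needs path(s): ",
           paste(miss, collapse = ", "))
  }
  inputs <- list()
  if (any(c("rrho", "link-ocr", "overlap", "network") %in% stages)) {
    need(c("mrna_table", "prot_table"), "rrho")
    inputs$mrna_table <- read_differential_table(p$mrna_table)
    inputs$prot_table <- read_differential_table(p$prot_table)
  }
  if ("link-ocr" %in% stages) {
    need(c("peaks", "annotation"), "link-ocr")
    inputs$peaks <- read_bed_peaks(p$peaks)
    inputs$annotation <- read_gene_annotation(p$annotation)
  }
  if (any(c("modules", "preserve", "overlap") %in% stages)) {
    need(c("mrna_values", "mrna_meta", "prot_values", "prot_meta"), "modules")
    inputs$mrna_matrix <- read_expression_matrix(p$mrna_values, p$mrna_meta)
    inputs$prot_matrix <- read_expression_matrix(p$prot_values, p$prot_meta)
  }
  if ("network" %in% stages) {
    need("network", "network")
    inputs$network <- read_edge_list(p$network)
    if (!is.null(p$network_module))
      inputs$network_module <- utils::read.delim(p$network_module,
                                                 header = FALSE)[[1]]
  }
  inputs
}
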