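#' Simulate a paired mRNA/protein multi-omics experiment
#'
#' Generates log-scale expression for two conditions (control, treated) at
#' two time points (8 h and 24 h) with planted co-expression modules and
#' planted treatment effects, plus a protein layer that mirrors the mRNA
#' layer with attenuated effects.
#'
#' Module members load on a shared per-sample latent factor:
#' `x = sqrt(intra_cor) * f + sqrt(1 - intra_cor) * e`, so the expected
#' pairwise correlation of members is `intra_cor`. Treated samples add a
#' per-module, per-time mean shift drawn from `N(0, effect_sd)`. The protein
#' layer shares the latent factors (so co-expression modules coincide with
#' the mRNA modules), receives `protein_attenuation` times the mRNA effect,
#' and adds independent noise; features in downregulated modules receive
#' doubled decoupling noise, emulating the weaker concordance of repressed
#' genes with their proteins. Differential tables are computed from the
#' simulated groups by two-sample Welch t-tests with Benjamini-Hochberg FDR
#' (generator-internal scaffolding, not an analysis method).
#'
#' @param n_genes total number of features.
#' @param n_modules number of planted modules.
#' @param module_size members per module (`n_modules * module_size <=
#'   n_genes`; remaining features are unstructured background).
#' @param n_samples_per_group replicates per condition-time group.
#' @param intra_cor target within-module correlation, in (0, 1).
#' @param effect_sd standard deviation of planted per-module log2 effects.
#' @param noise_sd standard deviation of additive feature noise.
#' @param protein_attenuation slope of protein effects relative to mRNA
#'   effects, in (0, 1].
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A list with `mrna`, `protein` ([expression_matrix()]s),
#'   `tables` (per layer and time point, [differential_table()]s with
#'   derived status), and `truth` (planted module assignment per layer,
#'   module-overlap mapping, and true effects).
#' @export
simulate_multiomics <- function(n_genes = 300L, n_modules = 3L,
                                module_size = 40L, n_samples_per_group = 10L,
                                intra_cor = 0.8, effect_sd = 2.0,
                                noise_sd = 0.3, protein_attenuation = 0.8,
                                seed = 1L) {
  if (n_modules * module_size > n_genes)
    stop("n_modules * module_size must not exceed n_genes")
  if (intra_cor <= 0 || intra_cor >= 1) stop("intra_cor must be in (0, 1)")
  if (protein_attenuation <= 0 || protein_attenuation > 1)
    stop("protein_attenuation must be in (0, 1]")
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  genes <- sprintf("g%04d", seq_len(n_genes))
  assignment <- integer(n_genes)
  assignment[seq_len(n_modules * module_size)] <-
    rep(seq_len(n_modules), each = module_size)
  names(assignment) <- genes
  times <- c(8, 24)
  conditions <- c("control", "treated")
  meta <- expand.grid(replicate = seq_len(n_samples_per_group),
                      time_h = times, condition = conditions,
                      stringsAsFactors = FALSE)[, c("condition", "time_h", "replicate")]
  n_samples <- nrow(meta)
  sample_ids <- sprintf("%s_%gh_r%d", substr(meta$condition, 1, 4),
                        meta$time_h, meta$replicate)
  # per-module, per-time planted treatment effects (log2 units)
  effects <- matrix(stats::rnorm(n_modules * length(times), 0, effect_sd),
                    n_modules, length(times),
                    dimnames = list(NULL, paste0("t", times)))
  factors <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
  a <- sqrt(intra_cor); b <- sqrt(1 - intra_cor)
  base_signal <- function() {
    x <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    for (m in seq_len(n_modules)) {
      rows <- which(assignment == m)
      x[rows, ] <- a * matrix(factors[m, ], length(rows), n_samples,
                              byrow = TRUE) + b * x[rows, ]
    }
    x
  }
  treated <- meta$condition == "treated"
  t_idx <- match(meta$time_h, times)
  shift <- matrix(0, n_genes, n_samples)
  for (m in seq_len(n_modules)) {
    rows <- which(assignment == m)
    for (ti in seq_along(times)) {
      cols <- which(treated & t_idx == ti)
      shift[rows, cols] <- effects[m, ti]
    }
  }
  mrna_vals <- base_signal() + shift +
    matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples)
  # protein layer: shared factors, attenuated effects, extra decoupling
  # noise on members of downregulated modules
  down_modules <- which(rowMeans(effects) < 0)
  decouple_sd <- ifelse(assignment %in% down_modules, 2 * noise_sd, noise_sd)
  prot_vals <- base_signal() + protein_attenuation * shift +
    matrix(stats::rnorm(n_genes * n_samples, 0, 1), n_genes, n_samples) *
      decouple_sd
  dimnames(mrna_vals) <- dimnames(prot_vals) <- list(genes, sample_ids)
  mrna <- expression_matrix(mrna_vals, meta)
  protein <- expression_matrix(prot_vals, meta)
  tables <- list()
  for (layer in c("mrna", "protein")) {
    vals <- if (layer == "mrna") mrna_vals else prot_vals
    for (ti in seq_along(times)) {
      ctrl <- which(!treated & t_idx == ti)
      trt <- which(treated & t_idx == ti)
      tables[[sprintf("%s_%dh", layer, times[ti])]] <-
        .de_table(vals, ctrl, trt)
    }
  }
  true_effect <- matrix(0, n_genes, length(times),
                        dimnames = list(genes, paste0("t", times)))
  for (m in seq_len(n_modules))
    true_effect[assignment == m, ] <- matrix(effects[m, ],
                                             sum(assignment == m),
                                             length(times), byrow = TRUE)
  truth <- list(assignment_mrna = assignment, assignment_protein = assignment,
                module_pairs = data.frame(mrna_module = seq_len(n_modules),
                                          prot_module = seq_len(n_modules),
                                          k_common = module_size),
                effects = effects, true_effect = true_effect, seed = seed)
  list(mrna = mrna, protein = protein, tables = tables, truth = truth)
}

# Welch two-sample t per feature with BH FDR and a derived status label.
.de_table <- function(vals, ctrl_cols, trt_cols, fc_label = 1.5,
                      fdr_label = 0.05) {
  x <- vals[, ctrl_cols, drop = FALSE]
  y <- vals[, trt_cols, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  se2 <- vx / nx + vy / ny
  tstat <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  log2fc <- my - mx
  status <- ifelse(abs(log2fc) > log2(fc_label) & fdr < fdr_label,
                   ifelse(log2fc > 0, "up", "down"), "stable")
  differential_table(rownames(vals), log2fc, p, fdr, status)
}

#' Simulate labelled peaks around gene TSSs
#'
#' Half of the peaks are placed uniformly inside the TSS window
#' (`window_bp` wide, centred) of a uniformly chosen gene; the other half
#' fall in background regions away from all windows. Peaks in the window of
#' an upregulated gene are labelled `gained` with probability
#' `p_gain_near_up`; all other peaks with probability `p_gain_background`;
#' non-gained peaks are `stable`.
#'
#' @param annotation a [gene_annotation()] (non-empty).
#' @param up_genes ids of upregulated genes.
#' @param p_gain_near_up,p_gain_background gain probabilities
#'   (`p_gain_near_up > p_gain_background`).
#' @param n_peaks total number of peaks.
#' @param window_bp TSS window width (default 40000).
#' @param peak_width peak width in bp (default 400).
#' @param seed integer seed.
#' @return A list with `peaks` (a [peak_set()]) and `truth` (`data.frame`
#'   with each peak's target gene or `NA`).
#' @export
simulate_peaks <- function(annotation, up_genes, p_gain_near_up = 0.9,
                           p_gain_background = 0.1, n_peaks = 500L,
                           window_bp = 40000L, peak_width = 400L, seed = 1L) {
  if (!nrow(annotation)) stop("empty annotation")
  if (p_gain_near_up <= p_gain_background)
    stop("p_gain_near_up must exceed p_gain_background")
  if (n_peaks == 0)
    return(list(peaks = peak_set(character(0), integer(0), integer(0),
                                 character(0)),
                truth = data.frame(peak_id = character(0),
                                   target_gene = character(0))))
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  half <- window_bp %/% 2L
  n_near <- n_peaks %/% 2L
  n_bg <- n_peaks - n_near
  gi <- sample.int(nrow(annotation), n_near, replace = TRUE)
  tss <- annotation$tss[gi]
  lo <- pmax(tss - half, 0L)
  hi <- tss + half - peak_width
  start_near <- lo + floor(stats::runif(n_near) * pmax(hi - lo, 1L))
  chrom_near <- annotation$chrom[gi]
  # background peaks: on a dedicated contig, away from every annotated window
  bg_span <- 1e7
  start_bg <- floor(stats::runif(n_bg) * bg_span)
  chrom_bg <- rep("chrBG", n_bg)
  chrom <- c(chrom_near, chrom_bg)
  start <- as.integer(c(start_near, start_bg))
  end <- start + as.integer(peak_width)
  target <- c(annotation$gene_id[gi], rep(NA_character_, n_bg))
  near_up <- !is.na(target) & target %in% up_genes
  p_gain <- ifelse(near_up, p_gain_near_up, p_gain_background)
  label <- ifelse(stats::runif(n_peaks) < p_gain, "gained", "stable")
  peaks <- peak_set(chrom, start, end, label)
  list(peaks = peaks,
       truth = data.frame(peak_id = peaks$peak_id, target_gene = target,
                          stringsAsFactors = FALSE))
}

#' Simulate a pair of ranked lists with a planted shared top
#'
#' Produces two permutations of the same `n` ids in which exactly
#' `n_shared_top` ids occur in both `top_size` prefixes; the rest of each
#' list is uniformly random. Requires `n >= 2 * top_size - n_shared_top` so
#' the prefix fillers of the two lists can be disjoint.
#'
#' @param n universe size.
#' @param n_shared_top number of ids planted in both prefixes.
#' @param top_size prefix length.
#' @param seed integer seed.
#' @return A list with `a`, `b` (`ranked_gene_list`s with synthetic
#'   decreasing scores) and `truth` (the planted shared ids).
#' @export
simulate_ranked_pair <- function(n, n_shared_top, top_size, seed = 1L) {
  if (n_shared_top > top_size || top_size > n)
    stop("require n_shared_top <= top_size <= n")
  if (n < 2 * top_size - n_shared_top)
    stop("universe too small for exactly n_shared_top co-occurring ids ",
         "(need n >= 2 * top_size - n_shared_top)")
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  ids <- sprintf("g%05d", seq_len(n))
  shuffled <- sample(ids)
  shared <- shuffled[seq_len(n_shared_top)]
  n_fill <- top_size - n_shared_top
  fill_a <- shuffled[n_shared_top + seq_len(n_fill)]
  fill_b <- shuffled[n_shared_top + n_fill + seq_len(n_fill)]
  rest <- shuffled[-seq_len(n_shared_top + 2 * n_fill)]
  top_a <- sample(c(shared, fill_a))
  top_b <- sample(c(shared, fill_b))
  tail_a <- sample(c(fill_b, rest))
  tail_b <- sample(c(fill_a, rest))
  scores <- seq(5, -5, length.out = n)
  mk <- function(order_ids) structure(list(ids = order_ids, log2fc = scores),
                                      class = "ranked_gene_list")
  list(a = mk(c(top_a, tail_a)), b = mk(c(top_b, tail_b)),
       truth = list(shared_top = shared, top_size = top_size, seed = seed))
}

#' Simulate a background network with planted connector nodes
#'
#' An Erdos-Renyi background graph on `n_nodes` nodes plus `connectors`
#' extra nodes, each wired to `k_connector` distinct members of the given
#' module.
#'
#' @param n_nodes background graph size.
#' @param p_edge background edge probability.
#' @param module node ids (subset of the background nodes) forming the
#'   module of interest.
#' @param connectors number of planted connector nodes.
#' @param k_connector connections from each connector into the module
#'   (`<= |module|`).
#' @param seed integer seed.
#' @param nodes optional character vector of `n_nodes` background node ids
#'   (default `n0001`, `n0002`, ...).
#' @return A list with `edges` (an [edge_list()]), `nodes` (all node ids)
#'   and `truth` (the planted connector ids).
#' @export
simulate_background_network <- function(n_nodes = 500L, p_edge = 0.01,
                                        module, connectors = 3L,
                                        k_connector = 8L, seed = 1L,
                                        nodes = NULL) {
  module <- unique(as.character(module))
  if (k_connector > length(module))
    stop("k_connector must not exceed the module size")
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  if (is.null(nodes)) nodes <- sprintf("n%04d", seq_len(n_nodes))
  if (length(nodes) != n_nodes) stop("nodes must have length n_nodes")
  if (!all(module %in% nodes))
    stop("module must be a subset of the background node ids")
  g <- igraph::sample_gnp(n_nodes, p_edge, directed = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)
  from <- nodes[ends[, 1]]
  to <- nodes[ends[, 2]]
  conn_ids <- if (connectors > 0) sprintf("conn%02d", seq_len(connectors))
              else character(0)
  for (cid in conn_ids) {
    targets <- sample(module, k_connector)
    from <- c(from, rep(cid, k_connector))
    to <- c(to, targets)
  }
  edges <- edge_list(from, to, directed = FALSE)
  list(edges = edges, nodes = c(nodes, conn_ids),
       truth = list(connectors = conn_ids, module = module, seed = seed))
}
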