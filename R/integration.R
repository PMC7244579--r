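#' Select differentially expressed features
#'
#' A feature is differentially expressed when its absolute fold-change
#' exceeds `fc` (strictly; i.e. `|log2fc| > log2(fc)`) and its FDR is below
#' `fdr` (strictly). Both tails are selected.
#'
#' @param table a [differential_table()].
#' @param fc fold-change threshold on the linear scale (default 1.5).
#' @param fdr FDR threshold (default 0.05).
#' @return Character vector of selected feature ids.
#' @export
select_deg <- function(table, fc = 1.5, fdr = 0.05) {
  table$feature_id[abs(table$log2fc) > log2(fc) & table$fdr < fdr]
}

#' Select differentially abundant features by raw p-value
#'
#' Selection rule for proteomics layers where differential abundance is
#' called at a raw t-test p-value below `p` (strictly).
#'
#' @param table a [differential_table()].
#' @param p p-value threshold (default 0.05).
#' @return Character vector of selected feature ids.
#' @export
select_dap <- function(table, p = 0.05) {
  table$feature_id[table$p_value < p]
}

#' Cross-layer module overlap test
#'
#' For every (mRNA module, protein module) pair the shared member count is
#' tested against the hypergeometric null on the given universe:
#' `p = P(X >= k)` with `X ~ Hypergeom(|universe|, |A|, |B|)`.
#' Benjamini-Hochberg FDR is applied across all pairs; a pair is significant
#' when `fdr < overlap_fdr` and at least `overlap_min` members are shared.
#'
#' @param mrna_modules,prot_modules named lists of member id vectors (e.g.
#'   module label -> DEG/DAP-restricted members), or `module_set` objects
#'   (converted with [module_members()]).
#' @param universe feature ids forming the hypergeometric universe; must
#'   cover all module members.
#' @param overlap_fdr,overlap_min admission rule (defaults 0.05 and 10).
#' @return A `data.frame` of class `module_overlap_result`: one row per
#'   pair with `mrna_module`, `prot_module`, `n_mrna`, `n_prot`, `k_common`,
#'   `p`, `fdr`, `significant`, and list-column `shared_ids`.
#' @export
module_overlap <- function(mrna_modules, prot_modules, universe,
                           overlap_fdr = 0.05, overlap_min = 10L) {
  mrna_modules <- module_members(mrna_modules)
  prot_modules <- module_members(prot_modules)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty overlap universe")
  all_members <- unique(c(unlist(mrna_modules), unlist(prot_modules)))
  if (!all(all_members %in% universe))
    stop("universe must cover every module member")
  N <- length(universe)
  grid <- expand.grid(mrna_module = names(mrna_modules),
                      prot_module = names(prot_modules),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    A <- unique(mrna_modules[[grid$mrna_module[i]]])
    B <- unique(prot_modules[[grid$prot_module[i]]])
    shared <- intersect(A, B)
    k <- length(shared)
    p <- hypergeom_tail(k, N, length(A), length(B))
    data.frame(mrna_module = grid$mrna_module[i],
               prot_module = grid$prot_module[i],
               n_mrna = length(A), n_prot = length(B), k_common = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- .bh_adjust(res$p)
  res$significant <- res$fdr < overlap_fdr & res$k_common >= overlap_min
  res$shared_ids <- lapply(seq_len(nrow(grid)), function(i) {
    intersect(mrna_modules[[grid$mrna_module[i]]],
              prot_modules[[grid$prot_module[i]]])
  })
  class(res) <- c("module_overlap_result", "data.frame")
  res
}

#' Module membership as a named list
#'
#' @param modules a `module_set` or an already-named list of id vectors.
#' @param restrict_to optional id set to intersect each module with (e.g.
#'   the DEG or DAP selection).
#' @return Named list: module label -> member ids.
#' @export
module_members <- function(modules, restrict_to = NULL) {
  if (inherits(modules, "module_set")) {
    labs <- sort(unique(modules$assignment[modules$assignment > 0]))
    modules <- stats::setNames(lapply(labs, function(m)
      names(modules$assignment)[modules$assignment == m]), as.character(labs))
  }
  if (!is.list(modules) || is.null(names(modules)))
    stop("modules must be a module_set or a named list of member vectors")
  if (!is.null(restrict_to))
    modules <- lapply(modules, intersect, y = restrict_to)
  modules
}

#' Stratify protein effects by retained-intron splicing change
#'
#' Splits proteins into three groups by the delta-percent-spliced-in (dPSI)
#' of retained-intron events in their genes: `removal` (dPSI < -dpsi_cut at
#' FDR < fdr_cut), `retention` (dPSI > dpsi_cut at FDR < fdr_cut) and
#' `unchanged` (everything else), then summarises protein log2FC per group
#' and tests for any group difference with a seeded permutation one-way
#' ANOVA on the F statistic.
#'
#' @param events `data.frame` with columns `event_id`, `gene_id`, `dpsi`
#'   (in `[-1, 1]`), `fdr`, `event_type`; only `retained_intron` rows are
#'   used.
#' @param proteins a [differential_table()] keyed by gene id.
#' @param dpsi_cut,fdr_cut classification thresholds (defaults 0.2, 0.05).
#' @param n_perm permutations for the ANOVA null (default 10000).
#' @param seed integer seed.
#' @return A list with `summary` (per group `n`, `mean`, `sem`), `f_statistic`
#'   and `p_value` (`NA` with a warning when a group is empty).
#' @export
stratify_protein_by_dpsi <- function(events, proteins, dpsi_cut = 0.2,
                                     fdr_cut = 0.05, n_perm = 10000L,
                                     seed = 1L) {
  if (any(abs(events$dpsi) > 1)) stop("dpsi must lie in [-1, 1]")
  ri <- events[events$event_type == "retained_intron", , drop = FALSE]
  idx <- match(ri$gene_id, proteins$feature_id)
  keep <- !is.na(idx)
  ri <- ri[keep, , drop = FALSE]
  effect <- proteins$log2fc[idx[keep]]
  group <- ifelse(ri$dpsi < -dpsi_cut & ri$fdr < fdr_cut, "removal",
                  ifelse(ri$dpsi > dpsi_cut & ri$fdr < fdr_cut, "retention",
                         "unchanged"))
  lv <- c("removal", "retention", "unchanged")
  summ <- do.call(rbind, lapply(lv, function(g) {
    x <- effect[group == g]
    data.frame(group = g, n = length(x),
               mean = if (length(x)) mean(x) else NaN,
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NaN,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  if (any(summ$n == 0)) {
    warning("empty dPSI group; permutation test skipped")
    return(list(summary = summ, f_statistic = NA_real_, p_value = NA_real_))
  }
  f_stat <- function(g, x) {
    mu <- mean(x)
    means <- tapply(x, g, mean)
    ns <- tapply(x, g, length)
    ssb <- sum(ns * (means - mu)^2)
    ssw <- sum((x - means[g])^2)
    dfb <- length(means) - 1
    dfw <- length(x) - length(means)
    (ssb / dfb) / (ssw / dfw)
  }
  obs <- f_stat(group, effect)
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  perm <- vapply(seq_len(n_perm), function(i) f_stat(sample(group), effect), 0)
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(summary = summ, f_statistic = obs, p_value = p)
}
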