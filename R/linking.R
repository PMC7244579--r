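#' Link peaks to genes by TSS windows
#'
#' A peak (0-based half-open interval) is linked to a gene when it overlaps
#' by at least 1 bp the window `[tss - window_bp/2, tss + window_bp/2)`
#' centred on the gene's TSS. A peak may link to several genes; each linked
#' gene counts the peak once. Overlap is computed with an interval index
#' ([IRanges::findOverlaps()]), so cost is near-linear in peaks plus genes.
#'
#' @param peaks a [peak_set()].
#' @param annotation a [gene_annotation()].
#' @param window_bp window width in bp, even and > 0 (default 40000, i.e.
#'   peaks within 20 kb of the TSS).
#' @return A `data.frame` of class `ocr_link_table`: one row per gene with
#'   `gene_id`, `n_gained`, `n_stable`, `n_lost`, and a list-column
#'   `peak_ids` of linked peak identifiers.
#' @export
link_peaks_to_genes <- function(peaks, annotation, window_bp = 40000L) {
  window_bp <- as.integer(window_bp)
  if (window_bp <= 0L || window_bp %% 2L != 0L)
    stop("window_bp must be even and > 0")
  half <- window_bp %/% 2L
  missing_chr <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
  if (length(missing_chr))
    warning("peak chromosome(s) absent from annotation (peaks left unlinked): ",
            paste(missing_chr, collapse = ", "))
  n_genes <- nrow(annotation)
  empty <- data.frame(gene_id = annotation$gene_id,
                      n_gained = 0L, n_stable = 0L, n_lost = 0L,
                      stringsAsFactors = FALSE)
  empty$peak_ids <- replicate(n_genes, character(0), simplify = FALSE)
  if (!nrow(peaks)) {
    class(empty) <- c("ocr_link_table", "data.frame")
    return(empty)
  }
  # convert 0-based half-open to 1-based closed for IRanges
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  win_start0 <- pmax(annotation$tss - half, 0L)
  win_end0 <- annotation$tss + half
  win_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = win_start0 + 1L, end = win_end0))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(peak_gr, win_gr, minoverlap = 1L))
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- empty
  if (length(pi)) {
    lab <- peaks$label[pi]
    tab <- function(which_label) {
      cnt <- tabulate(gi[lab == which_label], nbins = n_genes)
      as.integer(cnt)
    }
    out$n_gained <- tab("gained")
    out$n_stable <- tab("stable")
    out$n_lost <- tab("lost")
    out$peak_ids <- unname(split(peaks$peak_id[pi],
                                 factor(gi, levels = seq_len(n_genes))))
  }
  class(out) <- c("ocr_link_table", "data.frame")
  out
}

#' Status frequencies by linkage stratum
#'
#' Cross-tabulates differential status (up / down / stable / not_expressed)
#' against how strongly each gene is linked to gained open chromatin.
#' Strata are either the count of linked gained peaks (`0`, `1`, `2`, `>=3`)
#' or, with `by = "any_gained"`, genes with at least one gained linked peak
#' versus genes whose linked peaks are all non-gained. Genes absent from the
#' differential table are counted as `not_expressed`.
#'
#' @param links an `ocr_link_table` from [link_peaks_to_genes()].
#' @param table a [differential_table()] with `status` set.
#' @param by `"count_of_gained"` (default) or `"any_gained"`.
#' @return A `data.frame` with one row per stratum: `stratum`, `n`, and one
#'   proportion column per status (rows sum to 1; `NaN` for empty strata).
#' @export
status_frequency_by_links <- function(links, table,
                                      by = c("count_of_gained", "any_gained")) {
  by <- match.arg(by)
  status <- table$status[match(links$gene_id, table$feature_id)]
  status[is.na(status)] <- "not_expressed"
  if (by == "count_of_gained") {
    stratum <- ifelse(links$n_gained >= 3L, ">=3", as.character(links$n_gained))
    levels <- c("0", "1", "2", ">=3")
  } else {
    any_peak <- (links$n_gained + links$n_stable + links$n_lost) > 0L
    stratum <- ifelse(links$n_gained > 0L, "gained",
                      ifelse(any_peak, "stable_only", "no_ocr"))
    levels <- c("no_ocr", "stable_only", "gained")
  }
  st_levels <- c("up", "down", "stable", "not_expressed")
  out <- do.call(rbind, lapply(levels, function(lv) {
    in_lv <- stratum == lv
    n <- sum(in_lv)
    if (n == 0) {
      warning("empty linkage stratum: ", lv)
      props <- stats::setNames(rep(NaN, length(st_levels)), st_levels)
    } else {
      props <- vapply(st_levels, function(s) mean(status[in_lv] == s), 0)
    }
    data.frame(stratum = lv, n = n, t(props), stringsAsFactors = FALSE)
  }))
  names(out)[-(1:2)] <- st_levels
  rownames(out) <- NULL
  out
}

#' Effect size by count of linked gained peaks, with a permutation trend test
#'
#' Summarises the log2 fold-change distribution per stratum of linked gained
#' peak counts (`0 .. max_count-1`, `>= max_count`) and tests for a monotone
#' increasing trend with a Jonckheere-Terpstra-style statistic (sum of
#' between-stratum Mann-Whitney counts), with a one-sided permutation null.
#'
#' @param links an `ocr_link_table`.
#' @param table a [differential_table()]; restrict it to upregulated
#'   features beforehand to reproduce the induced-protein analysis.
#' @param max_count top stratum is `>= max_count` (default 3).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutation null.
#' @return A list with `summary` (per-stratum `n`, `mean`, `median`),
#'   `statistic` (observed trend statistic), and `p_value` (one-sided,
#'   increasing trend).
#' @export
effect_by_gained_count <- function(links, table, max_count = 3L,
                                   n_perm = 10000L, seed = 1L) {
  idx <- match(links$gene_id, table$feature_id)
  keep <- !is.na(idx)
  counts <- pmin(links$n_gained[keep], max_count)
  effect <- table$log2fc[idx[keep]]
  levels_present <- sort(unique(counts))
  if (length(levels_present) < 2)
    stop("need at least 2 non-empty strata for a trend test")
  lab <- function(k) if (k >= max_count) paste0(">=", max_count) else as.character(k)
  summ <- do.call(rbind, lapply(levels_present, function(k) {
    x <- effect[counts == k]
    data.frame(stratum = lab(k), n = length(x), mean = mean(x),
               median = stats::median(x), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  jt_stat <- function(g, x) {
    s <- 0
    for (i in seq_along(levels_present)[-length(levels_present)]) {
      for (j in seq((i + 1), length(levels_present))) {
        xi <- x[g == levels_present[i]]
        xj <- x[g == levels_present[j]]
        r <- rank(c(xi, xj))
        # Mann-Whitney count of (xi < xj) pairs, ties counted half
        s <- s + sum(r[seq_along(xj) + length(xi)]) -
          length(xj) * (length(xj) + 1) / 2
      }
    }
    s
  }
  obs <- jt_stat(counts, effect)
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  perm <- vapply(seq_len(n_perm), function(i) jt_stat(sample(counts), effect), 0)
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(summary = summ, statistic = obs, p_value = p)
}

#' Chi-squared enrichment of gained open chromatin in a module
#'
#' Builds the 2x2 table (in/out module) x (has / has no linked gained peak)
#' and reports the one-sided chi-squared p-value for enrichment: half the
#' two-sided p when the module's gained fraction exceeds the background, and
#' one minus half the two-sided p otherwise. No continuity correction.
#'
#' @param links an `ocr_link_table`.
#' @param module_genes gene ids forming the module (subset of `universe`).
#' @param universe gene ids over which to test.
#' @return A list with `chi2`, `p_one_sided`, and `table2x2`.
#' @export
gained_enrichment_chi2 <- function(links, module_genes, universe) {
  module_genes <- unique(as.character(module_genes))
  universe <- unique(as.character(universe))
  if (!all(module_genes %in% universe))
    stop("module_genes must be a subset of universe")
  has_gained <- links$gene_id[links$n_gained > 0L]
  in_mod <- universe %in% module_genes
  gained <- universe %in% has_gained
  tab <- matrix(c(sum(in_mod & gained), sum(in_mod & !gained),
                  sum(!in_mod & gained), sum(!in_mod & !gained)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_module", "out_module"),
                                c("gained", "no_gained")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the 2x2 table is zero; consider Fisher's exact test")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  p_in <- tab[1, 1] / sum(tab[1, ])
  p_out <- tab[2, 1] / sum(tab[2, ])
  p_one <- if (p_in > p_out) ct$p.value / 2
           else if (p_in < p_out) 1 - ct$p.value / 2
           else 0.5
  list(chi2 = unname(ct$statistic), p_one_sided = p_one, table2x2 = tab)
}

#' mRNA-protein fold-change concordance
#'
#' Categorises matched features per layer (up / down / equal, strict
#' fold-change inequalities with an FDR gate: by default mRNA
#' `|log2FC| > 0.58` at FDR < 0.05, protein `|log2FC| > 0.58` at FDR < 0.15)
#' and reports the Pearson r-squared of protein versus mRNA log2FC within
#' the mRNA-up and mRNA-down categories, plus the 3x3 category counts.
#'
#' @param mrna,protein [differential_table()]s matched by feature id.
#' @param mrna_fc,prot_fc absolute log2FC thresholds (strict).
#' @param mrna_fdr,prot_fdr FDR gates per layer.
#' @return A list with `r2` (named: `up`, `down`), `counts` (3x3 matrix,
#'   mRNA category x protein category), and `data` (the matched table with
#'   category columns). `r2` is `NaN` for categories with < 3 pairs.
#' @export
mrna_protein_concordance <- function(mrna, protein, mrna_fc = 0.58,
                                     mrna_fdr = 0.05, prot_fc = 0.58,
                                     prot_fdr = 0.15) {
  shared <- intersect(mrna$feature_id, protein$feature_id)
  mi <- match(shared, mrna$feature_id)
  pi <- match(shared, protein$feature_id)
  cat_of <- function(fc, fdr, fc_cut, fdr_cut) {
    ifelse(fc > fc_cut & fdr < fdr_cut, "up",
           ifelse(fc < -fc_cut & fdr < fdr_cut, "down", "equal"))
  }
  mcat <- cat_of(mrna$log2fc[mi], mrna$fdr[mi], mrna_fc, mrna_fdr)
  pcat <- cat_of(protein$log2fc[pi], protein$fdr[pi], prot_fc, prot_fdr)
  df <- data.frame(feature_id = shared,
                   mrna_log2fc = mrna$log2fc[mi],
                   protein_log2fc = protein$log2fc[pi],
                   mrna_category = mcat, protein_category = pcat,
                   stringsAsFactors = FALSE)
  lv <- c("up", "down", "equal")
  counts <- table(factor(mcat, lv), factor(pcat, lv))
  counts <- matrix(as.integer(counts), 3, 3, dimnames = list(mRNA = lv, protein = lv))
  r2_in <- function(category) {
    sub <- df[df$mrna_category == category, ]
    if (nrow(sub) < 3) return(NaN)
    stats::cor(sub$mrna_log2fc, sub$protein_log2fc)^2
  }
  list(r2 = c(up = r2_in("up"), down = r2_in("down")),
       counts = counts, data = df)
}
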