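#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more white balls when drawing `n` balls
#' without replacement from an urn of `N` balls of which `K` are white:
#' `P(X >= k)`. This is the enrichment p-value used throughout the pipeline
#' (rank-rank overlap, module overlap, connector enrichment). Evaluated in
#' log space via [stats::phyper()] so extreme tails do not underflow.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param N universe size.
#' @param K number of "successes" in the universe.
#' @param n number drawn.
#' @return `P(X >= k)` in `(0, 1]`. Vectorized over `k`, `K`, `n`.
#' @export
hypergeom_tail <- function(k, N, K, n) {
  if (length(N) != 1) stop("N must be scalar")
  m <- max(length(k), length(K), length(n))
  k <- rep_len(as.numeric(k), m)
  K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m)
  if (anyNA(c(k, N, K, n))) stop("missing values in hypergeometric parameters")
  if (N < 0 || any(K < 0) || any(n < 0) || any(K > N) || any(n > N))
    stop("require 0 <= K, n <= N")
  if (any(k < 0) || any(k > pmin(K, n)))
    stop("require 0 <= k <= min(K, n)")
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Minus-log10 upper-tail hypergeometric probability
#'
#' Log-space companion of [hypergeom_tail()] for plotting and map building;
#' capped at 320 for numeric hygiene.
#'
#' @inheritParams hypergeom_tail
#' @param cap ceiling on the returned value.
#' @return `-log10 P(X >= k)`, capped.
#' @export
neglog10_hypergeom_tail <- function(k, N, K, n, cap = 320) {
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  pmin(-lp / log(10), cap)
}

#' Rank features by log2 fold-change
#'
#' Produces the ordered gene list consumed by the rank-rank overlap map:
#' descending signed log2FC by default (most upregulated first). Ties are
#' broken lexicographically by feature id so the order is deterministic.
#'
#' @param table a [differential_table()].
#' @param direction `"descending"` (default) or `"ascending"`.
#' @return A list of class `ranked_gene_list` with `ids` and `log2fc`.
#' @export
rank_by_fold_change <- function(table, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (anyNA(table$log2fc) || any(!is.finite(table$log2fc)))
    stop("log2fc must be finite for ranking")
  ord <- order(if (direction == "descending") -table$log2fc else table$log2fc,
               table$feature_id, method = "radix")
  structure(list(ids = table$feature_id[ord], log2fc = table$log2fc[ord]),
            class = "ranked_gene_list")
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' Step-up FDR control valid under arbitrary dependence: sorted `p_(i)` maps
#' to `min_{j >= i} p_(j) * m * c(m) / j` with `c(m) = sum_{h=1..m} 1/h`,
#' capped at 1. Delegates to [stats::p.adjust()] after range validation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
by_adjust <- function(p) {
  if (anyNA(p)) stop("p must not contain missing values")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Rank-rank hypergeometric overlap map
#'
#' For two rankings of the same gene universe the map evaluates, at every
#' pair of rank thresholds `(i, j)` on a regular step grid, the hypergeometric
#' enrichment of the overlap between the top-`i` prefix of list `a` and the
#' top-`j` prefix of list `b`. Significance is adjusted across all cells
#' jointly with the Benjamini-Yekutieli procedure. Prefix overlap counts are
#' accumulated by 2-d binning of each gene's rank pair, so the cost is linear
#' in the universe plus the number of cells.
#'
#' @param a,b `ranked_gene_list` objects over a common universe.
#' @param step rank step between thresholds; `NULL` gives
#'   `max(1, floor(N/100))` (a grid of about 100 x 100 cells).
#' @param cap ceiling for the `-log10` matrices.
#' @return A list of class `rrho_map`: `step`, `thresholds_a`,
#'   `thresholds_b`, `k_matrix`, `neglog_p`, `neglog_p_adj`, `universe_n`.
#' @export
rrho_map <- function(a, b, step = NULL, cap = 320) {
  common <- intersect(a$ids, b$ids)
  N <- length(common)
  if (N == 0) stop("the two ranked lists share no genes")
  ra <- a$ids[a$ids %in% common]
  rb <- b$ids[b$ids %in% common]
  if (is.null(step)) step <- max(1L, N %/% 100L)
  step <- as.integer(step)
  if (step < 1) stop("step must be >= 1")
  pos_a <- match(ra, ra)                       # 1..N by construction
  pos_b <- match(ra, rb)                       # rank in b of gene at rank i in a
  thresholds <- seq.int(step, N, by = step)
  nt <- length(thresholds)
  # bin each gene's (rank_a, rank_b) pair, then 2-d cumulative sum
  bin_a <- ceiling(seq_len(N) / step)
  bin_b <- ceiling(pos_b / step)
  nb <- ceiling(N / step)
  counts <- matrix(0L, nb, nb)
  for (g in seq_len(N)) counts[bin_a[g], bin_b[g]] <- counts[bin_a[g], bin_b[g]] + 1L
  cum <- apply(apply(counts, 2, cumsum), 1, cumsum)  # cum[j, i] after transpose
  cum <- t(cum)
  k_matrix <- cum[seq_len(nt), seq_len(nt), drop = FALSE]
  storage.mode(k_matrix) <- "integer"
  K <- matrix(thresholds, nt, nt, byrow = FALSE)   # rows: threshold in a
  n <- matrix(thresholds, nt, nt, byrow = TRUE)    # cols: threshold in b
  logp <- stats::phyper(as.numeric(k_matrix) - 1, as.numeric(K),
                        N - as.numeric(K), as.numeric(n),
                        lower.tail = FALSE, log.p = TRUE)
  p <- exp(logp)
  p_adj <- by_adjust(p)
  neglog_p <- matrix(pmin(-logp / log(10), cap), nt, nt)
  neglog_p_adj <- matrix(pmin(-log10(pmax(p_adj, 10^(-cap))), cap), nt, nt)
  dimnames(k_matrix) <- dimnames(neglog_p) <- dimnames(neglog_p_adj) <-
    list(thresholds, thresholds)
  structure(list(step = step, thresholds_a = thresholds,
                 thresholds_b = thresholds, k_matrix = k_matrix,
                 neglog_p = neglog_p, neglog_p_adj = neglog_p_adj,
                 universe_n = N),
            class = "rrho_map")
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf("rrho_map: universe %d, step %d, grid %d x %d\n",
              x$universe_n, x$step, length(x$thresholds_a),
              length(x$thresholds_b)))
  cat(sprintf("max -log10 adjusted p: %.2f\n", max(x$neglog_p_adj)))
  invisible(x)
}

#' Heatmap of an RRHO map
#'
#' @param x an `rrho_map`.
#' @param adjusted plot the BY-adjusted surface (default) or the raw one.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot_rrho_map <- function(x, adjusted = TRUE, ...) {
  z <- if (adjusted) x$neglog_p_adj else x$neglog_p
  graphics::image(x = x$thresholds_a, y = x$thresholds_b, z = z,
                  xlab = "rank threshold, list A",
                  ylab = "rank threshold, list B",
                  main = if (adjusted) "-log10 adjusted p" else "-log10 p",
                  ...)
  invisible(x)
}

#' Shared top-of-list signature
#'
#' Extracts the `n_top` genes that appear earliest in both rankings: the two
#' prefixes are grown in lock-step and genes are collected as soon as they
#' have been seen in both lists, stopping once `n_top` shared genes are
#' found. The returned order is by mean of the two ranks. If fewer than
#' `n_top` genes are shared in total, all shared genes are returned with a
#' warning.
#'
#' @param a,b `ranked_gene_list` objects over a common universe.
#' @param n_top signature size (e.g. 150 for a top-150 shared signature).
#' @return Character vector of gene ids, ordered by mean rank.
#' @export
shared_top_signature <- function(a, b, n_top) {
  common <- intersect(a$ids, b$ids)
  if (!length(common)) {
    warning("no shared genes between the two lists")
    return(character(0))
  }
  ra <- a$ids[a$ids %in% common]
  rb <- b$ids[b$ids %in% common]
  N <- length(common)
  rank_a <- match(common, ra)
  rank_b <- match(common, rb)
  depth_needed <- pmax(rank_a, rank_b)  # prefix length at which gene is in both
  ord <- order(depth_needed, rank_a + rank_b, common, method = "radix")
  take <- min(n_top, N)
  if (N < n_top)
    warning(sprintf("only %d shared genes available (requested %d)", N, n_top))
  sel <- ord[seq_len(take)]
  sel <- sel[order(rank_a[sel] + rank_b[sel], common[sel], method = "radix")]
  common[sel]
}
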