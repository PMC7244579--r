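# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately avoid the code paths they check.

# P(X >= k) by exhaustive enumeration of all n-subsets of a universe of N
# elements whose first K are "successes". Feasible for N <= 12.
enum_hyper_tail <- function(k, N, K, n) {
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Topological overlap by literal triple sum over shared neighbours.
brute_force_tom <- function(adj) {
  p <- nrow(adj)
  k <- sapply(seq_len(p), function(i) sum(adj[i, -i]))
  tom <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(p)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
      tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
    }
  }
  tom
}

# All-pairs peak-gene linkage on 0-based half-open coordinates.
brute_force_links <- function(peaks, annotation, window_bp) {
  half <- window_bp %/% 2
  out <- lapply(seq_len(nrow(annotation)), function(g) {
    ws <- max(annotation$tss[g] - half, 0)
    we <- annotation$tss[g] + half
    hits <- which(peaks$chrom == annotation$chrom[g] &
                    peaks$start < we & peaks$end > ws)
    c(n_gained = sum(peaks$label[hits] == "gained"),
      n_stable = sum(peaks$label[hits] == "stable"),
      n_lost = sum(peaks$label[hits] == "lost"))
  })
  cbind(data.frame(gene_id = annotation$gene_id, stringsAsFactors = FALSE),
        do.call(rbind, out))
}

# Extended modularity for overlapping communities, literal double loop.
brute_force_eq <- function(edges, communities) {
  g <- as_igraph(edges)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nodes <- rownames(A)
  k <- rowSums(A)
  two_m <- sum(k)
  O <- stats::setNames(numeric(length(nodes)), nodes)
  for (C in communities) O[C] <- O[C] + 1
  total <- 0
  for (C in communities)
    for (i in C) for (j in C)
      total <- total + (A[i, j] - k[i] * k[j] / two_m) / (O[i] * O[j])
  unname(total / two_m)
}

# Small deterministic differential table for interface tests.
toy_diff_table <- function(n = 10, seed = 1) {
  set.seed(seed)
  differential_table(sprintf("g%02d", seq_len(n)),
                     log2fc = stats::rnorm(n),
                     p_value = stats::runif(n),
                     fdr = stats::runif(n))
}

# Adjusted Rand index (Hubert & Arabie), self-contained so recovery tests
# do not depend on a suggested package.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}
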