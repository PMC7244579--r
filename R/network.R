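#' Restrict a background network to expressed nodes
#'
#' Keeps only nodes whose mean abundance exceeds `threshold` (strictly) in
#' at least one condition; edges incident to removed nodes are dropped.
#' Nodes absent from the expression summary are treated as not expressed.
#'
#' @param network an [edge_list()].
#' @param expression `data.frame` with a `feature_id` column and one numeric
#'   column of mean abundance per condition.
#' @param threshold expression threshold (default 0.5, e.g. mean RPKM).
#' @return The restricted [edge_list()]; attribute `nodes` holds the kept
#'   node ids (including any left isolated) and attribute `n_dropped`
#'   counts the removed nodes.
#' @export
restrict_to_expressed <- function(network, expression, threshold = 0.5) {
  if (!"feature_id" %in% names(expression))
    stop("expression summary needs a 'feature_id' column")
  vals <- as.matrix(expression[, setdiff(names(expression), "feature_id"),
                               drop = FALSE])
  expressed <- expression$feature_id[apply(vals > threshold, 1, any)]
  nodes <- edge_list_nodes(network)
  keep <- nodes %in% expressed
  dropped <- sum(!keep)
  kept_nodes <- nodes[keep]
  sel <- network$from %in% kept_nodes & network$to %in% kept_nodes
  out <- edge_list(network$from[sel], network$to[sel],
                   directed = isTRUE(attr(network, "directed")))
  if (!nrow(out)) warning("no edges remain after expression restriction")
  attr(out, "nodes") <- kept_nodes
  attr(out, "n_dropped") <- dropped
  out
}

#' Hypergeometric connector enrichment
#'
#' Identifies background-network nodes with significantly more connections
#' into a module than expected by chance. For candidate node `v` with degree
#' `d_v` (out-degree on directed networks) and `k` neighbours inside the
#' module, the p-value is `P(X >= k)` for
#' `X ~ Hypergeom(N - 1, |module \\ {v}|, d_v)` where `N` is the number of
#' network nodes. Benjamini-Hochberg FDR is applied across all tested nodes;
#' a node is admitted when `fdr < fdr_threshold` and `k >= min_connections`
#' (5 for protein-protein interaction networks, 4 for regulatory networks).
#'
#' @param network an [edge_list()].
#' @param module node ids forming the module; members absent from the
#'   network are ignored (with a message).
#' @param min_connections minimum in-module connections for admission.
#' @param fdr_threshold FDR threshold for admission (default 0.01).
#' @param include_module also test module members themselves (default
#'   `FALSE`: only outside nodes are candidates).
#' @return A `data.frame` of class `connector_result`: `node`, `degree`,
#'   `k_to_module`, `p`, `fdr`, `admitted`.
#' @export
connector_enrichment <- function(network, module, min_connections = 5L,
                                 fdr_threshold = 0.01,
                                 include_module = FALSE) {
  g <- as_igraph(network)
  nodes <- igraph::V(g)$name
  N <- length(nodes)
  module <- unique(as.character(module))
  if (length(module) > N) stop("module is larger than the network")
  absent <- setdiff(module, nodes)
  if (length(absent))
    message(length(absent), " module member(s) absent from the network ignored")
  module_in <- intersect(module, nodes)
  directed <- igraph::is_directed(g)
  mode <- if (directed) "out" else "all"
  deg <- igraph::degree(g, mode = mode)
  in_module <- nodes %in% module_in
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj_to_module <- as.integer(A %*% as.numeric(in_module))
  candidates <- if (include_module) seq_len(N) else which(!in_module)
  if (!length(candidates))
    return(structure(data.frame(node = character(0), degree = integer(0),
                                k_to_module = integer(0), p = numeric(0),
                                fdr = numeric(0), admitted = logical(0)),
                     class = c("connector_result", "data.frame")))
  k <- adj_to_module[candidates]
  d <- deg[candidates]
  m_prime <- length(module_in) - ifelse(in_module[candidates], 1L, 0L)
  p <- hypergeom_tail(k, N - 1, m_prime, pmin(d, N - 1))
  fdr <- .bh_adjust(p)
  out <- data.frame(node = nodes[candidates], degree = as.integer(d),
                    k_to_module = as.integer(k), p = p, fdr = fdr,
                    admitted = fdr < fdr_threshold & k >= min_connections,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$node), ]
  rownames(out) <- NULL
  class(out) <- c("connector_result", "data.frame")
  out
}

#' Assemble a module network with its admitted connectors
#'
#' Induced subgraph on the module members plus every admitted connector,
#' with optional up/down/equal node annotation from a differential table
#' (strict `|log2FC| > fc_cut` with an FDR gate, matching the concordance
#' categories).
#'
#' @param network an [edge_list()].
#' @param module node ids of the module.
#' @param connectors a `connector_result` from [connector_enrichment()].
#' @param table optional [differential_table()] for node annotation.
#' @param fc_cut,fdr_cut annotation thresholds (defaults 0.58, 0.15).
#' @return A list with `edges` (the induced [edge_list()]) and `nodes`
#'   (`data.frame` with `node`, `role` = `member`/`connector`, `regulation`).
#' @export
build_module_network <- function(network, module, connectors, table = NULL,
                                 fc_cut = 0.58, fdr_cut = 0.15) {
  module <- unique(as.character(module))
  admitted <- connectors$node[connectors$admitted]
  keep <- union(intersect(module, edge_list_nodes(network)), admitted)
  sel <- network$from %in% keep & network$to %in% keep
  edges <- edge_list(network$from[sel], network$to[sel],
                     directed = isTRUE(attr(network, "directed")))
  regulation <- rep("equal", length(keep))
  if (!is.null(table)) {
    idx <- match(keep, table$feature_id)
    fc <- table$log2fc[idx]
    fdr <- table$fdr[idx]
    regulation <- ifelse(!is.na(idx) & fc > fc_cut & fdr < fdr_cut, "up",
                         ifelse(!is.na(idx) & fc < -fc_cut & fdr < fdr_cut,
                                "down", "equal"))
  }
  nodes <- data.frame(node = keep,
                      role = ifelse(keep %in% admitted & !(keep %in% module),
                                    "connector", "member"),
                      regulation = regulation, stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

#' Overlapping community detection by clique agglomeration
#'
#' An agglomerative procedure in the style of maximal-clique community
#' algorithms: (1) maximal cliques of size >= `clique_size` seed the initial
#' communities; nodes belonging only to smaller cliques are "subordinate";
#' (2) the pair of communities with the largest similarity
#' `s(C1, C2) = |C1 and C2| / min(|C1|, |C2|)` is merged repeatedly, building
#' a dendrogram; (3) the dendrogram is cut at the level maximising the
#' extended modularity
#' `EQ = (1/2m) sum_C sum_{i,j in C} (A_ij - k_i k_j / 2m) / (O_i O_j)`
#' where `O_i` counts the communities containing node `i`; (4) subordinate
#' nodes are attached to the community they share most edges with (ties:
#' all tied communities), and communities smaller than `complex_size` are
#' discarded. Communities may overlap.
#'
#' @param network an undirected [edge_list()] (at most 2000 nodes; maximal
#'   clique enumeration is exponential in the worst case).
#' @param clique_size minimum clique size seeding communities (default 6).
#' @param complex_size minimum size of a reported community (default 2).
#' @return A list of class `community_set`: `communities` (list of node-id
#'   vectors), `eq` (extended modularity of the chosen cut), `clique_size`,
#'   `complex_size`.
#' @export
detect_communities <- function(network, clique_size = 6L, complex_size = 2L) {
  if (isTRUE(attr(network, "directed")))
    stop("community detection requires an undirected network")
  g <- as_igraph(network)
  if (igraph::vcount(g) > 2000)
    stop("network too large for exact maximal-clique enumeration (> 2000 nodes)")
  cliques <- igraph::max_cliques(g, min = clique_size)
  empty <- structure(list(communities = list(), eq = NA_real_,
                          clique_size = as.integer(clique_size),
                          complex_size = as.integer(complex_size)),
                     class = "community_set")
  if (!length(cliques)) {
    warning("no maximal clique of size >= ", clique_size,
            "; no communities detected")
    return(empty)
  }
  comms <- lapply(cliques, function(cl) sort(cl$name))
  comms <- comms[order(vapply(comms, paste, "", collapse = ","))]
  covered <- unique(unlist(comms))
  subordinate <- setdiff(igraph::V(g)$name, covered)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(A)
  two_m <- sum(k)
  eq_of <- function(communities) {
    O <- stats::setNames(numeric(nrow(A)), rownames(A))
    for (C in communities) O[C] <- O[C] + 1
    total <- 0
    for (C in communities) {
      ki <- k[C]
      Oi <- O[C]
      total <- total + sum((A[C, C, drop = FALSE] - outer(ki, ki) / two_m) /
                             outer(Oi, Oi))
    }
    total / two_m
  }
  # agglomerate, keeping the cut with maximal extended modularity
  best <- list(eq = eq_of(comms), comms = comms)
  while (length(comms) > 1) {
    n <- length(comms)
    best_s <- -1; bi <- 1L; bj <- 2L
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        s <- length(intersect(comms[[i]], comms[[j]])) /
          min(length(comms[[i]]), length(comms[[j]]))
        if (s > best_s) { best_s <- s; bi <- i; bj <- j }
      }
    }
    merged <- sort(union(comms[[bi]], comms[[bj]]))
    comms <- c(comms[-c(bi, bj)], list(merged))
    eq <- eq_of(comms)
    if (eq > best$eq) best <- list(eq = eq, comms = comms)
  }
  final <- best$comms
  # attach subordinate nodes to the community they share most edges with
  for (v in subordinate) {
    shared <- vapply(final, function(C) sum(A[v, C]), 0)
    mx <- max(shared)
    if (mx > 0)
      for (ci in which(shared == mx))
        final[[ci]] <- sort(c(final[[ci]], v))
  }
  final <- final[vapply(final, length, 0L) >= complex_size]
  structure(list(communities = final, eq = best$eq,
                 clique_size = as.integer(clique_size),
                 complex_size = as.integer(complex_size)),
            class = "community_set")
}
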