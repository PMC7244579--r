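#' Standardise expression within sample groups
#'
#' Centres and scales each feature within each sample group (for example
#' each condition-time combination): subtract the group mean and divide by
#' the group sample standard deviation (denominator `n - 1`). Used to bring
#' protein abundances onto a comparable scale per temporal group before
#' network construction. Zero-variance features within a group become zeros
#' with a warning.
#'
#' @param matrix an [expression_matrix()].
#' @param group_by metadata column name(s) defining groups (default
#'   `c("condition", "time_h")`).
#' @return A standardised [expression_matrix()].
#' @export
normalize_within_group <- function(matrix, group_by = c("condition", "time_h")) {
  meta <- matrix$sample_meta
  miss <- setdiff(group_by, names(meta))
  if (length(miss)) stop("unknown metadata column(s): ", paste(miss, collapse = ", "))
  key <- interaction(meta[group_by], drop = TRUE)
  vals <- matrix$values
  any_constant <- FALSE
  for (g in levels(key)) {
    idx <- which(key == g)
    if (length(idx) < 2)
      stop("group '", g, "' has fewer than 2 samples")
    sub <- vals[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    zero <- sdv == 0
    if (any(zero)) { any_constant <- TRUE; sdv[zero] <- 1 }
    sub <- (sub - mu) / sdv
    sub[zero, ] <- 0
    vals[, idx] <- sub
  }
  if (any_constant)
    warning("constant feature(s) within a group set to zero")
  expression_matrix(vals, meta)
}

#' Build a weighted co-expression network
#'
#' Unsigned weighted adjacency `a_ij = |cor(x_i, x_j)|^beta` (Pearson) with
#' soft-threshold power `beta`, and the topological overlap matrix
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{u != i} a_iu` and `TOM_ii = 1`.
#'
#' @param matrix an [expression_matrix()] (>= 4 samples).
#' @param soft_power integer soft-threshold power, >= 1 (10 is typical for
#'   RNA-seq, 14 for group-standardised proteomics).
#' @return A list of class `coexpression_network` with `feature_ids`,
#'   `adjacency`, `tom`, `soft_power`.
#' @export
build_network <- function(matrix, soft_power) {
  soft_power <- as.integer(soft_power)
  if (soft_power < 1) stop("soft_power must be >= 1")
  x <- matrix$values
  if (ncol(x) < 4) stop("need at least 4 samples to estimate correlations")
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0))
    stop("constant feature(s): correlation undefined for ",
         paste(utils::head(rownames(x)[sdv == 0], 3), collapse = ", "))
  adj <- abs(stats::cor(t(x)))^soft_power
  diag(adj) <- 1
  tom <- .tom_from_adjacency(adj)
  structure(list(feature_ids = rownames(x), adjacency = adj, tom = tom,
                 soft_power = soft_power),
            class = "coexpression_network")
}

# TOM via matrix products: L_ij = (A %*% A)_ij - 2 a_ij (diag(A) = 1) equals
# the shared-neighbour sum over u != i, j.
.tom_from_adjacency <- function(adj) {
  k <- colSums(adj) - 1
  L <- adj %*% adj - 2 * adj          # off-diagonal: sum_{u != i,j} a_iu a_uj
  kmin <- outer(k, k, pmin)
  tom <- (L + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' `1 - TOM`, cut statically at `cut_height`. Clusters smaller than
#' `min_module_size` are left unassigned (label 0). Surviving modules are
#' relabelled 1, 2, ... by decreasing size.
#'
#' @param network a `coexpression_network`.
#' @param min_module_size minimum members per module (default 20).
#' @param cut_height static cut height on the dissimilarity dendrogram
#'   (default 0.99).
#' @return A list of class `module_set` with `assignment` (named integer
#'   vector, 0 = unassigned), `eigengenes` (`NULL` until computed), and
#'   `merge_history`.
#' @export
detect_modules <- function(network, min_module_size = 20L, cut_height = 0.99) {
  d <- stats::as.dist(1 - network$tom)
  fit <- stats::hclust(d, method = "average")
  raw <- stats::cutree(fit, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  assignment <- integer(length(raw))
  names(assignment) <- network$feature_ids
  if (!length(keep)) {
    warning("no cluster reaches min_module_size; all features unassigned")
  } else {
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep))
      assignment[raw == as.integer(keep[i])] <- i
  }
  structure(list(assignment = assignment, eigengenes = NULL,
                 merge_history = list()),
            class = "module_set")
}

#' Module eigengene
#'
#' First principal component of the feature-standardised module submatrix,
#' scaled to unit variance across samples and sign-oriented so that its
#' correlation with the mean member profile is non-negative. The orientation
#' follows the data: negating every member negates the eigengene, leaving
#' all correlation-based downstream quantities unchanged.
#'
#' @param matrix an [expression_matrix()].
#' @param members feature ids of the module (>= 2).
#' @return Numeric vector, one value per sample.
#' @export
module_eigengene <- function(matrix, members) {
  members <- intersect(members, rownames(matrix$values))
  if (length(members) < 2) stop("need at least 2 module members")
  x <- matrix$values[members, , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples")
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- (x - rowMeans(x)) / sdv
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  s <- stats::sd(e)
  if (s > 0) e <- e / s
  mean_profile <- colMeans(xs)
  if (stats::sd(mean_profile) > 0 && stats::cor(e, mean_profile) < 0) e <- -e
  names(e) <- colnames(matrix$values)
  e
}

#' Eigengenes for every module in a module set
#' @param matrix an [expression_matrix()].
#' @param modules a `module_set`.
#' @return The `module_set` with `eigengenes` filled (list by module label).
#' @export
compute_eigengenes <- function(matrix, modules) {
  labs <- sort(unique(modules$assignment[modules$assignment > 0]))
  modules$eigengenes <- stats::setNames(lapply(labs, function(m) {
    module_eigengene(matrix, names(modules$assignment)[modules$assignment == m])
  }), as.character(labs))
  modules
}

#' Merge similar modules by eigengene correlation
#'
#' Iteratively merges the pair of modules whose eigengene dissimilarity
#' `d = 1 - cor(E_a, E_b)` is smallest, as long as `d` is below the
#' threshold; eigengenes are recomputed after every merge. On return no
#' surviving pair has eigengene dissimilarity below the threshold.
#'
#' @param modules a `module_set`.
#' @param matrix the [expression_matrix()] the modules were detected on.
#' @param dissimilarity_threshold merge threshold (default 0.25).
#' @return The merged `module_set` (labels renumbered by decreasing size);
#'   `merge_history` records each merge as `c(kept, absorbed, d)`.
#' @export
merge_modules <- function(modules, matrix, dissimilarity_threshold = 0.25) {
  modules <- compute_eigengenes(matrix, modules)
  assignment <- modules$assignment
  history <- modules$merge_history
  repeat {
    labs <- sort(unique(assignment[assignment > 0]))
    if (length(labs) < 2) break
    E <- vapply(as.character(labs), function(m) modules$eigengenes[[m]],
                numeric(ncol(matrix$values)))
    d <- 1 - stats::cor(E)
    diag(d) <- Inf
    min_d <- min(d)
    if (min_d >= dissimilarity_threshold) break
    idx <- which(d == min_d, arr.ind = TRUE)[1, ]
    a <- labs[min(idx)]; b <- labs[max(idx)]
    assignment[assignment == b] <- a
    history[[length(history) + 1]] <- c(kept = a, absorbed = b, d = min_d)
    modules$assignment <- assignment
    modules <- compute_eigengenes(matrix, modules)
  }
  # renumber by decreasing size
  labs <- sort(unique(assignment[assignment > 0]))
  sizes <- vapply(labs, function(m) sum(assignment == m), 0L)
  new_lab <- integer(max(labs, 0L))
  new_lab[labs[order(-sizes)]] <- seq_along(labs)
  relabelled <- assignment
  relabelled[assignment > 0] <- new_lab[assignment[assignment > 0]]
  modules$assignment <- relabelled
  modules$merge_history <- history
  compute_eigengenes(matrix, modules)
}

#' Module quality Z statistics by resampling
#'
#' For each module the observed density (mean intra-module adjacency, off
#' diagonal) and separability (density minus the mean adjacency from module
#' members to non-members) are compared with a resampling null: in each
#' resample the samples (columns) are bootstrapped, the adjacency rebuilt,
#' and a size-matched random module scored. `Z = (observed - null mean) /
#' null sd` per statistic, and `z_summary = median(z_density,
#' z_separability)`. `z_summary > 2` indicates moderate and `> 10` high
#' module quality.
#'
#' @param matrix an [expression_matrix()].
#' @param modules a `module_set`.
#' @param n_resamples number of resamples (>= 20; default 100, 1000 for
#'   full-scale analyses).
#' @param seed integer seed.
#' @param soft_power soft-threshold power used to rebuild adjacencies.
#' @return A `data.frame` of class `preservation_stats`: one row per module
#'   with `module`, `size`, `density`, `separability`, `z_density`,
#'   `z_separability`, `z_summary`, `n_resamples`.
#' @export
module_quality <- function(matrix, modules, n_resamples = 100L, seed = 1L,
                           soft_power = 10L) {
  n_resamples <- as.integer(n_resamples)
  if (n_resamples < 20) stop("n_resamples must be >= 20")
  x <- matrix$values
  n_feat <- nrow(x)
  n_samp <- ncol(x)
  labs <- sort(unique(modules$assignment[modules$assignment > 0]))
  if (!length(labs)) stop("module set has no assigned modules")
  obs_adj <- abs(stats::cor(t(x)))^soft_power
  diag(obs_adj) <- 1
  stat_pair <- function(adj, members_idx) {
    inside <- adj[members_idx, members_idx, drop = FALSE]
    m <- length(members_idx)
    density <- (sum(inside) - m) / (m * (m - 1))
    outside <- adj[members_idx, -members_idx, drop = FALSE]
    separability <- density - mean(outside)
    c(density = density, separability = separability)
  }
  member_idx <- lapply(labs, function(m) which(modules$assignment == m))
  obs <- vapply(member_idx, function(ix) stat_pair(obs_adj, ix), numeric(2))
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  null_stats <- array(NA_real_, c(2, length(labs), n_resamples))
  for (r in seq_len(n_resamples)) {
    cols <- sample.int(n_samp, n_samp, replace = TRUE)
    xr <- x[, cols, drop = FALSE]
    sdv <- apply(xr, 1, stats::sd)
    ok <- sdv > 0
    adj_r <- matrix(0, n_feat, n_feat)
    adj_r[ok, ok] <- abs(stats::cor(t(xr[ok, , drop = FALSE])))^soft_power
    diag(adj_r) <- 1
    for (mi in seq_along(labs)) {
      size <- length(member_idx[[mi]])
      rand <- sample.int(n_feat, size)
      null_stats[, mi, r] <- stat_pair(adj_r, rand)
    }
  }
  out <- do.call(rbind, lapply(seq_along(labs), function(mi) {
    mu <- rowMeans(null_stats[, mi, ])
    sdv <- apply(null_stats[, mi, ], 1, stats::sd)
    z <- (obs[, mi] - mu) / sdv
    if (any(sdv == 0)) {
      warning("null sd = 0 for module ", labs[mi], "; Z reported as Inf")
      z[sdv == 0] <- sign(obs[sdv == 0, mi] - mu[sdv == 0]) * Inf
    }
    data.frame(module = labs[mi], size = length(member_idx[[mi]]),
               density = obs["density", mi],
               separability = obs["separability", mi],
               z_density = z["density"], z_separability = z["separability"],
               z_summary = stats::median(z), n_resamples = n_resamples)
  }))
  rownames(out) <- NULL
  class(out) <- c("preservation_stats", "data.frame")
  out
}
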