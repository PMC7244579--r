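make_em <- function(values, n_per_group = NULL) {
  n <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  meta <- data.frame(condition = rep(c("control", "treated"),
                                     length.out = n),
                     time_h = 8, replicate = seq_len(n))
  expression_matrix(values, meta)
}

test_that("within-group standardisation centres and scales per group", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), 1, byrow = TRUE)
  rownames(x) <- "f1"
  em <- expression_matrix(x, data.frame(
    condition = rep(c("control", "treated"), each = 3),
    time_h = 8, replicate = rep(1:3, 2)))
  out <- normalize_within_group(em, "condition")
  expect_equal(unname(out$values[1, 1:3]), c(-1, 0, 1))
  expect_equal(unname(out$values[1, 4:6]), c(-1, 0, 1))

  # constant feature becomes zero with a warning
  x2 <- rbind(f1 = c(1, 2, 3, 4), f2 = rep(5, 4))
  em2 <- expression_matrix(x2, data.frame(condition = rep("control", 4),
                                          time_h = 8, replicate = 1:4))
  expect_warning(out2 <- normalize_within_group(em2, "condition"),
                 "constant")
  expect_equal(unname(out2$values["f2", ]), rep(0, 4))

  em3 <- expression_matrix(x2[, 1:3],
                           data.frame(condition = c("control", "control",
                                                    "treated"),
                                      time_h = 8, replicate = 1:3))
  expect_error(normalize_within_group(em3, "condition"), "fewer than 2")
})

test_that("soft-threshold adjacency and TOM follow their definitions", {
  # adjacency: |cor|^power
  set.seed(1)
  base <- rnorm(20)
  x <- rbind(f1 = base, f2 = base * 2 + 1, f3 = rnorm(20))
  em <- make_em(x)
  net <- build_network(em, soft_power = 10)
  expect_equal(net$adjacency["f1", "f2"], 1)  # perfectly correlated pair
  r13 <- abs(cor(x["f1", ], x["f3", ]))
  expect_equal(net$adjacency["f1", "f3"], r13^10, tolerance = 1e-12)
  expect_true(isSymmetric(net$tom))
  expect_true(all(net$tom >= 0 & net$tom <= 1 + 1e-12))

  # hand example for the TOM formula
  adj <- matrix(c(1, .8, .2, .8, 1, .4, .2, .4, 1), 3, 3)
  tom <- interomics:::.tom_from_adjacency(adj)
  expect_equal(tom[1, 2], (0.2 * 0.4 + 0.8) / (min(1.0, 1.2) + 1 - 0.8),
               tolerance = 1e-12)

  # two perfectly correlated nodes alone: TOM = 1
  em2 <- make_em(rbind(f1 = base, f2 = base * 3))
  net2 <- build_network(em2, soft_power = 6)
  expect_equal(net2$tom[1, 2], 1, tolerance = 1e-12)

  # brute-force triple-sum equivalence on random adjacencies
  set.seed(2)
  for (i in 1:10) {
    r <- matrix(runif(100), 10, 10)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    expect_equal(interomics:::.tom_from_adjacency(a), brute_force_tom(a),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  const <- make_em(rbind(f1 = rep(1, 10), f2 = rnorm(10)))
  expect_error(build_network(const, 10), "constant")
})

test_that("module detection recovers planted blocks and ignores noise", {
  for (seed in 1:3) {
    # blocks defined purely by correlation: no differential shift
    sim <- simulate_multiomics(n_genes = 140, n_modules = 2, module_size = 40,
                               effect_sd = 1e-12, seed = seed)
    net <- build_network(sim$mrna, 10)
    ms <- detect_modules(net, min_module_size = 20, cut_height = 0.99)
    planted <- sim$truth$assignment_mrna[1:80]
    expect_gte(adjusted_rand_index(ms$assignment[1:80], planted), 0.9)
  }
  # pure noise: almost everything unassigned
  set.seed(9)
  noise <- make_em(matrix(rnorm(150 * 40), 150, 40))
  msn <- suppressWarnings(detect_modules(build_network(noise, 10), 20, 0.99))
  expect_gte(mean(msn$assignment == 0), 0.9)
  # impossible minimum size
  small <- make_em(matrix(rnorm(10 * 8), 10, 8))
  expect_warning(ms0 <- detect_modules(build_network(small, 2), 50, 0.99),
                 "unassigned")
  expect_true(all(ms0$assignment == 0))
})

test_that("module eigengene is the oriented unit-variance first PC", {
  v <- c(-2, -1, 0, 1, 2, 3)
  x <- rbind(f1 = v, f2 = 2 * v + 5, f3 = 0.5 * v - 1)
  em <- make_em(x)
  e <- module_eigengene(em, c("f1", "f2", "f3"))
  expect_equal(sd(e), 1, tolerance = 1e-12)
  expect_equal(abs(cor(e, v)), 1, tolerance = 1e-9)
  expect_gte(cor(e, v), 0)  # oriented with the mean member profile
  # negating the data negates the eigengene (orientation follows the
  # mean member profile); correlations downstream are unaffected
  em_neg <- make_em(-x)
  expect_equal(module_eigengene(em_neg, c("f1", "f2", "f3")), -e,
               tolerance = 1e-9)
  expect_error(module_eigengene(em, "f1"), "at least 2")
})

test_that("eigengene merging reaches a fixed point below the threshold", {
  set.seed(4)
  f1 <- rnorm(30); f2 <- f1 * 0.95 + rnorm(30, 0, 0.3); f3 <- rnorm(30)
  mk_block <- function(f, n) t(sapply(seq_len(n), function(i)
    f + rnorm(length(f), 0, 0.2)))
  x <- rbind(mk_block(f1, 20), mk_block(f2, 20), mk_block(f3, 20))
  rownames(x) <- sprintf("f%03d", 1:60)
  em <- make_em(x)
  ms <- structure(list(assignment = setNames(rep(1:3, each = 20),
                                             rownames(x)),
                       eigengenes = NULL, merge_history = list()),
                  class = "module_set")
  merged <- merge_modules(ms, em, dissimilarity_threshold = 0.25)
  labs <- unique(merged$assignment[merged$assignment > 0])
  # blocks 1 and 2 are highly correlated and must merge; block 3 survives
  expect_equal(length(labs), 2L)
  E <- sapply(as.character(sort(labs)), function(m) merged$eigengenes[[m]])
  d <- 1 - cor(E)
  expect_true(all(d[upper.tri(d)] >= 0.25))
  expect_gte(length(merged$merge_history), 1L)
})

test_that("module quality Z separates planted modules from random sets", {
  sim <- simulate_multiomics(n_genes = 160, n_modules = 2, module_size = 40,
                             seed = 12)
  ms <- structure(list(assignment = sim$truth$assignment_mrna,
                       eigengenes = NULL, merge_history = list()),
                  class = "module_set")
  q <- module_quality(sim$mrna, ms, n_resamples = 40, seed = 3,
                      soft_power = 10)
  expect_true(all(q$z_summary > 10))
  expect_equal(q$z_summary, apply(cbind(q$z_density, q$z_separability), 1,
                                  median))
  # a random feature set looks like the null
  rand <- sim$truth$assignment_mrna
  rand[] <- 0L
  set.seed(21)
  rand[sample(160, 40)] <- 1L
  msr <- structure(list(assignment = rand, eigengenes = NULL,
                        merge_history = list()), class = "module_set")
  qr <- module_quality(sim$mrna, msr, n_resamples = 40, seed = 3,
                       soft_power = 10)
  expect_lt(abs(qr$z_summary), 2)
  # determinism
  q2 <- module_quality(sim$mrna, ms, n_resamples = 40, seed = 3,
                       soft_power = 10)
  expect_identical(q$z_summary, q2$z_summary)
  expect_error(module_quality(sim$mrna, ms, n_resamples = 5), ">= 20")
})
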