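test_that("TSS window linkage honours half-open boundaries", {
  ann <- gene_annotation("g1", "chr1", 50000L, "+")
  link1 <- link_peaks_to_genes(peak_set("chr1", 30000, 30100, "gained"), ann)
  expect_equal(link1$n_gained, 1L)          # overlaps [30000, 70000)
  link2 <- link_peaks_to_genes(peak_set("chr1", 29900, 30000, "gained"), ann)
  expect_equal(link2$n_gained, 0L)          # ends exactly at window start
  link3 <- link_peaks_to_genes(peak_set("chr1", 69990, 70050, "stable"), ann)
  expect_equal(link3$n_stable, 1L)          # partial overlap at the far edge
  link4 <- link_peaks_to_genes(peak_set("chr1", 70000, 70100, "stable"), ann)
  expect_equal(link4$n_stable, 0L)          # starts exactly at window end
  expect_warning(link_peaks_to_genes(peak_set("chrX", 10, 20, "lost"), ann),
                 "absent from annotation")
})

test_that("window linkage equals all-pairs brute force on random instances", {
  set.seed(11)
  for (i in 1:30) {
    n_genes <- sample(5:50, 1)
    n_peaks <- sample(0:200, 1)
    ann <- gene_annotation(sprintf("g%03d", seq_len(n_genes)),
                           sample(c("chr1", "chr2"), n_genes, replace = TRUE),
                           sample.int(200000, n_genes),
                           sample(c("+", "-"), n_genes, replace = TRUE))
    start <- sample.int(220000, n_peaks)
    pk <- peak_set(sample(c("chr1", "chr2", "chr3"), n_peaks, replace = TRUE),
                   start, start + sample.int(500, n_peaks),
                   sample(c("gained", "stable", "lost"), n_peaks,
                          replace = TRUE))
    w <- sample(c(2000L, 40000L), 1)
    got <- suppressWarnings(link_peaks_to_genes(pk, ann, w))
    want <- brute_force_links(pk, ann, w)
    expect_equal(got$n_gained, want$n_gained)
    expect_equal(got$n_stable, want$n_stable)
    expect_equal(got$n_lost, want$n_lost)
  }
})

test_that("status frequencies stratify genes and normalise to one", {
  ann <- synthetic_annotation(sprintf("g%03d", 1:60))
  up <- sprintf("g%03d", 1:20)
  sim <- simulate_peaks(ann, up, n_peaks = 300, seed = 2)
  links <- suppressWarnings(link_peaks_to_genes(sim$peaks, ann))
  tab <- differential_table(ann$gene_id,
                            c(rep(2, 20), rep(0, 40)),
                            rep(.01, 60), rep(.01, 60),
                            c(rep("up", 20), rep("stable", 40)))
  freq <- suppressWarnings(status_frequency_by_links(links, tab))
  sums <- rowSums(freq[, c("up", "down", "stable", "not_expressed")])
  expect_true(all(abs(sums[freq$n > 0] - 1) < 1e-12))
  expect_true(all(is.nan(sums[freq$n == 0])))

  # all-stable table: up fraction zero in every stratum
  stab <- differential_table(ann$gene_id, rep(0, 60), rep(.5, 60),
                             rep(.5, 60), rep("stable", 60))
  f2 <- suppressWarnings(status_frequency_by_links(links, stab))
  expect_true(all(f2$up[f2$n > 0] == 0))

  # genes absent from the table are counted as not expressed
  short <- differential_table("g001", 2, .01, .01, "up")
  f3 <- suppressWarnings(status_frequency_by_links(links, short,
                                                   by = "any_gained"))
  expect_true(all(f3$not_expressed[f3$n > 0] > 0.9))
})

test_that("gained-count effect summary detects a planted monotone trend", {
  mk <- function(means, n, sd, seed) {
    set.seed(seed)
    counts <- rep(seq_along(means) - 1L, each = n)
    effect <- rnorm(length(counts), rep(means, each = n), sd)
    genes <- sprintf("g%04d", seq_along(counts))
    links <- data.frame(gene_id = genes, n_gained = counts,
                        n_stable = 0L, n_lost = 0L)
    class(links) <- c("ocr_link_table", "data.frame")
    tab <- differential_table(genes, effect, rep(.5, length(genes)),
                              rep(.5, length(genes)))
    list(links = links, tab = tab)
  }
  hits <- sapply(1:10, function(seed) {
    d <- mk(c(0, 0.5, 1.0, 1.5), n = 50, sd = 0.5, seed = seed)
    effect_by_gained_count(d$links, d$tab, n_perm = 500, seed = seed)$p_value
  })
  expect_gte(mean(hits < 0.01), 0.9)

  # null: uniform p, reject rate near nominal
  null_p <- sapply(1:40, function(seed) {
    d <- mk(c(0, 0, 0, 0), n = 25, sd = 0.5, seed = seed + 100)
    effect_by_gained_count(d$links, d$tab, n_perm = 199, seed = seed)$p_value
  })
  expect_lte(mean(null_p < 0.05), 0.15)
  expect_gte(mean(null_p < 0.5), 0.3)

  d <- mk(c(1), n = 10, sd = 0.5, seed = 1)
  expect_error(effect_by_gained_count(d$links, d$tab), "2 non-empty strata")
})

test_that("gained-OCR chi-squared enrichment is one-sided and directional", {
  mk_links <- function(gained_genes, all_genes) {
    links <- data.frame(gene_id = all_genes,
                        n_gained = as.integer(all_genes %in% gained_genes),
                        n_stable = 1L, n_lost = 0L)
    class(links) <- c("ocr_link_table", "data.frame")
    links
  }
  universe <- sprintf("g%03d", 1:300)
  module <- universe[1:100]
  # 2x2 table [[30,70],[10,190]]: chi2 = 300*5000^2/(100*200*40*260)
  gained <- c(module[1:30], universe[101:110])
  enr <- gained_enrichment_chi2(mk_links(gained, universe), module, universe)
  expect_equal(unname(enr$table2x2),
               matrix(c(30, 70, 10, 190), 2, byrow = TRUE))
  expect_equal(enr$chi2, 300 * 5000^2 / (100 * 200 * 40 * 260),
               tolerance = 1e-9)
  expect_lt(enr$p_one_sided, 1e-8)

  # identical proportions: no signal, p = 0.5
  gained_flat <- c(module[1:10], universe[101:120])
  flat <- gained_enrichment_chi2(mk_links(gained_flat, universe), module,
                                 universe)
  expect_equal(flat$chi2, 0, tolerance = 1e-9)
  expect_equal(flat$p_one_sided, 0.5)

  # depleted module flips past 0.5
  gained_dep <- universe[101:140]
  dep <- gained_enrichment_chi2(mk_links(gained_dep, universe), module,
                                universe)
  expect_gt(dep$p_one_sided, 0.5)

  expect_error(gained_enrichment_chi2(mk_links(character(0), universe),
                                      module, universe), "margin")
})

test_that("mRNA-protein concordance categorises and reports r-squared", {
  ids <- sprintf("g%03d", 1:200)
  set.seed(5)
  m_fc <- c(rnorm(60, 2, 0.5), rnorm(60, -2, 0.5), rnorm(80, 0, 0.1))
  mrna <- differential_table(ids, m_fc, rep(.001, 200), rep(.001, 200))
  ident <- differential_table(ids, m_fc, rep(.001, 200), rep(.001, 200))
  res <- mrna_protein_concordance(mrna, ident)
  expect_equal(unname(res$r2["up"]), 1, tolerance = 1e-9)
  expect_equal(unname(res$r2["down"]), 1, tolerance = 1e-9)

  # exact threshold is excluded (strict inequality)
  edge <- differential_table(c("a", "b"), c(0.58, 0.59), c(.01, .01),
                             c(.01, .01))
  res2 <- mrna_protein_concordance(edge, edge)
  cats <- res2$data$mrna_category
  expect_equal(cats[res2$data$feature_id == "a"], "equal")
  expect_equal(cats[res2$data$feature_id == "b"], "up")

  # attenuated protein layer: empirical r2 near the signal/noise prediction
  atten <- 0.8; noise_sd <- 0.4
  prot_fc <- atten * m_fc + rnorm(200, 0, noise_sd)
  prot <- differential_table(ids, prot_fc, rep(.001, 200), rep(.001, 200))
  res3 <- mrna_protein_concordance(mrna, prot)
  sig_var <- atten^2 * var(m_fc[1:60])
  expected_r2 <- sig_var / (sig_var + noise_sd^2)
  expect_equal(unname(res3$r2["up"]), expected_r2, tolerance = 0.15)
})
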