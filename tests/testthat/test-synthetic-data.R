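test_that("configuration validation is strict", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(length_range_bp = c(1000, 500)),
               "length_range_bp")
  expect_error(simulation_config(dispersion = -1), "dispersion")
  expect_error(simulation_config(de_fraction = 1.5), "de_fraction")
  d <- two_group_design(3)
  d$decay_scale_bp[1] <- -5
  expect_error(simulation_config(design = d), "decay_scale_bp")
  # DE needs >= 2 samples per contrasted group
  expect_error(
    simulation_config(design = two_group_design(1), de_fraction = 0.1),
    ">= 2 samples")
})

test_that("simulated gene models respect the configured structure", {
  cfg <- simulation_config(n_genes = 200, length_range_bp = c(500, 10000),
                           n_transcripts_per_gene_range = c(1, 3),
                           design = two_group_design(2), de_fraction = 0.1,
                           reads_per_sample = 1e4, seed = 11)
  sim <- simulate_gene_models(cfg)
  tx <- sim$models$transcripts
  # direct scan: spliced lengths within the configured range, spanning it
  expect_true(all(tx$spliced_length >= 500 & tx$spliced_length <= 10000))
  dom_len <- spliced_lengths(sim$models)
  expect_lt(min(dom_len), 1500)
  expect_gt(max(dom_len), 8000)
  # one strict abundance maximum per gene = the flagged dominant
  for (g in unique(tx$gene_id)[1:25]) {
    sub <- tx[tx$gene_id == g, ]
    expect_equal(sub$transcript_id[which.max(sub$abundance)],
                 sub$transcript_id[sub$dominant])
    if (nrow(sub) > 1) {
      ab <- sort(sub$abundance, decreasing = TRUE)
      expect_gt(ab[1], ab[2])
    }
  }
  # exon counts in 1..4 and no overlapping genes on the chromosome
  n_ex <- table(sim$models$exons$transcript_id)
  expect_true(all(n_ex >= 1 & n_ex <= 4))
  # DE bookkeeping
  expect_equal(sum(sim$truth$is_de), round(0.1 * 200))
  expect_equal(sum(sim$truth$true_log2fc != 0), sum(sim$truth$is_de))
})

test_that("single-isoform config makes every transcript its own dominant", {
  cfg <- simulation_config(n_genes = 30,
                           n_transcripts_per_gene_range = c(1, 1),
                           design = two_group_design(2), de_fraction = 0,
                           reads_per_sample = 1e4, seed = 2)
  sim <- simulate_gene_models(cfg)
  expect_equal(nrow(sim$models$transcripts), 30L)
  expect_true(all(sim$models$transcripts$dominant))
})

test_that("a fixed seed reproduces byte-identical GTF output", {
  cfg <- simulation_config(n_genes = 50, design = two_group_design(2),
                           de_fraction = 0, reads_per_sample = 1e4,
                           seed = 7)
  p1 <- withr::local_tempfile(fileext = ".gtf")
  p2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(simulate_gene_models(cfg)$models, p1)
  write_gtf(simulate_gene_models(cfg)$models, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("3'-distances follow the truncated exponential decay", {
  # single 1500 bp single-exon gene, large sample of reads
  ex <- data.frame(gene_id = "g", transcript_id = "g.t1", chrom = "c",
                   start = 0, end = 1500, strand = "+")
  m <- select_dominant_transcripts(gene_models(ex, c(g.t1 = 1)))
  mk_cfg <- function(lam) {
    d <- two_group_design(2, lam, lam)
    simulation_config(n_genes = 1, length_range_bp = c(1500, 1501),
                      design = d, de_fraction = 0,
                      reads_per_sample = 4e4, seed = 21)
  }
  truth <- function(lam, cfg) {
    structure(list(
      mu = matrix(1, 1, 4, dimnames = list("g", cfg$design$sample_id)),
      baseline = c(g = 1), is_de = c(g = FALSE), true_log2fc = c(g = 0),
      dominant = c(g = "g.t1"), dominant_length = c(g = 1500),
      decay_scale = setNames(cfg$design$decay_scale_bp,
                             cfg$design$sample_id),
      design = cfg$design), class = "ground_truth")
  }
  # uniform mode: fraction of reads with d < 500 on 1500 bp is ~1/3
  cfg_u <- mk_cfg(Inf)
  r_u <- simulate_read_positions(m, truth(Inf, cfg_u), cfg_u)
  expect_equal(mean(r_u$three_prime_distance < 500), 1 / 3,
               tolerance = 0.03)
  expect_true(all(r_u$three_prime_distance < 1500))

  # lambda = 500: expected fraction below 500 is (1-e^-1)/(1-e^-3),
  # cross-checked against numerical integration of the density
  cfg_5 <- mk_cfg(500)
  r_5 <- simulate_read_positions(m, truth(500, cfg_5), cfg_5)
  dens <- function(d) exp(-d / 500)
  frac_int <- integrate(dens, 0, 500)$value / integrate(dens, 0, 1500)$value
  expect_equal(frac_int, (1 - exp(-1)) / (1 - exp(-3)), tolerance = 1e-8)
  expect_equal(mean(r_5$three_prime_distance < 500), frac_int,
               tolerance = 0.02)
})

test_that("reads on transcripts shorter than the window all fall inside it", {
  ex <- data.frame(gene_id = "g", transcript_id = "g.t1", chrom = "c",
                   start = 0, end = 400, strand = "-")
  m <- select_dominant_transcripts(gene_models(ex, c(g.t1 = 1)))
  cfg <- simulation_config(n_genes = 1, length_range_bp = c(400, 401),
                           design = two_group_design(2, 800, 800),
                           de_fraction = 0, reads_per_sample = 5e3,
                           seed = 3)
  tr <- structure(list(
    mu = matrix(1, 1, 4, dimnames = list("g", cfg$design$sample_id)),
    baseline = c(g = 1), is_de = c(g = FALSE), true_log2fc = c(g = 0),
    dominant = c(g = "g.t1"), dominant_length = c(g = 400),
    decay_scale = setNames(cfg$design$decay_scale_bp,
                           cfg$design$sample_id),
    design = cfg$design), class = "ground_truth")
  r <- simulate_read_positions(m, tr, cfg)
  expect_true(all(r$three_prime_distance < 500))
})

test_that("library sizes land within 20% of the target and counts sum close", {
  cfg <- simulation_config(n_genes = 500, design = two_group_design(3),
                           de_fraction = 0, reads_per_sample = 5e4,
                           seed = 13)
  sim <- simulate_gene_models(cfg)
  y <- simulate_counts(sim$models, sim$truth, cfg, mode = "full_length")
  # multinomial-style allocation: per-sample totals near the target
  expect_true(all(abs(colSums(y$counts) / 5e4 - 1) < 0.25))
  reads <- simulate_read_positions(sim$models, sim$truth, cfg)
  per_sample <- table(reads$sample_id)
  expect_true(all(per_sample >= 0.8 * 5e4 & per_sample <= 1.2 * 5e4))
})

test_that("dispersion 0 gives Poisson counts", {
  cfg <- simulation_config(n_genes = 2000, design = two_group_design(2),
                           de_fraction = 0, dispersion = 0,
                           reads_per_sample = 2e5, seed = 17)
  sim <- simulate_gene_models(cfg)
  y <- simulate_counts(sim$models, sim$truth, cfg)$counts
  # rescale to a common depth so library-size draws do not inflate the
  # variance, then check variance/mean ~ 1 across replicates
  y <- sweep(y, 2, mean(colSums(y)) / colSums(y), "*")
  m <- rowMeans(y)
  v <- apply(y, 1, var)
  ratio <- mean(v[m > 20] / m[m > 20])
  expect_equal(ratio, 1, tolerance = 0.15)
})

test_that("null equal-decay samples give symmetric fold changes", {
  cfg <- simulation_config(n_genes = 800, design = two_group_design(3),
                           de_fraction = 0, dispersion = 0.05,
                           reads_per_sample = 1e5, seed = 19)
  sim <- simulate_gene_models(cfg)
  y <- simulate_counts(sim$models, sim$truth, cfg)$counts
  # common-depth scaling removes the deliberate +/-20% library jitter
  y <- sweep(y, 2, mean(colSums(y)) / colSums(y), "*")
  l2 <- log2((rowMeans(y[, 4:6]) + 0.5) / (rowMeans(y[, 1:3]) + 0.5))
  expect_lt(abs(mean(l2)), 0.05)
  # |log2FC| shrinks with baseline mean
  m <- rowMeans(y)
  lo <- abs(l2[m < quantile(m, 0.25)])
  hi <- abs(l2[m > quantile(m, 0.75)])
  expect_gt(mean(lo), mean(hi))
})

test_that("unequal decay induces the closed-form length-dependent bias", {
  lamA <- 4000
  lamB <- 800
  cfg <- simulation_config(n_genes = 1500,
                           design = two_group_design(3, lamA, lamB),
                           de_fraction = 0, dispersion = 0,
                           reads_per_sample = 3e5, seed = 23)
  sim <- simulate_gene_models(cfg)
  y <- simulate_counts(sim$models, sim$truth, cfg, mode = "full_length")
  yc <- y$counts
  L <- sim$truth$dominant_length
  obs <- log2((rowMeans(yc[, 4:6]) + 0.5) / (rowMeans(yc[, 1:3]) + 0.5))
  pred <- log2((1 - exp(-L / lamB)) / (1 - exp(-L / lamA)))
  # gene-by-gene agreement with the closed form up to one global constant
  keep <- rowMeans(yc) > 50
  resid <- (obs - pred)[keep]
  expect_lt(sd(resid), 0.2)
  expect_gt(cor(obs[keep], pred[keep]), 0.85)
})

test_that("window-truncated expectations are length-independent on nulls", {
  # all transcripts >= 500 bp and decay slower than any length: expected
  # truncated counts depend only on expression, not on length
  cfg <- simulation_config(n_genes = 2000, length_range_bp = c(500, 10000),
                           design = two_group_design(1, 1e7, 1e7),
                           de_fraction = 0, dispersion = 0,
                           baseline_mean_range = c(100, 100.01),
                           reads_per_sample = 5e5, seed = 29)
  sim <- simulate_gene_models(cfg)
  y <- simulate_counts(sim$models, sim$truth, cfg, mode = "truncated_500")
  rho <- cor(y$counts[, 1], sim$truth$dominant_length, method = "spearman")
  expect_lt(abs(rho), 0.05)
})

test_that("read-level and closed-form count paths agree in expectation", {
  cfg <- simulation_config(n_genes = 300,
                           design = two_group_design(3, 2000, 800),
                           de_fraction = 0, dispersion = 0,
                           reads_per_sample = 1e5, seed = 31)
  sim <- simulate_gene_models(cfg)
  reads <- simulate_read_positions(sim$models, sim$truth, cfg)
  y_read <- count_reads_in_window(reads, sim$models, 500)$counts
  y_fast <- simulate_counts(sim$models, sim$truth, cfg,
                            mode = "truncated_500")$counts
  s1 <- rowSums(y_read) / sum(y_read)
  s2 <- rowSums(y_fast) / sum(y_fast)
  expect_gt(cor(s1, s2), 0.99)
  expect_lt(mean(abs(s1 - s2)) / mean(s1), 0.15)
})
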