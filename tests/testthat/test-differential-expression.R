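test_that("common-dispersion CML recovers the simulated dispersion", {
  sim <- sim_two_group(n_genes = 800, n_per_group = 3, phi = 0.2, seed = 71)
  est <- estimate_common_dispersion(sim$y, sim$group)
  expect_gt(est$dispersion, 0.2 * 0.8)
  expect_lt(est$dispersion, 0.2 * 1.2)
  # Poisson data pushes the estimate to the lower boundary
  simp <- sim_two_group(n_genes = 800, n_per_group = 3, phi = 0, seed = 72)
  estp <- estimate_common_dispersion(simp$y, simp$group)
  expect_lte(estp$dispersion, 0.01)
  expect_error(estimate_common_dispersion(matrix(0, 2, 4)[0, ],
                                          factor(rep(1, 4))), "empty")
})

test_that("equal counts across samples carry no overdispersion evidence", {
  y <- matrix(7L, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  grp <- factor(rep(c("a", "b"), each = 3))
  # conditional likelihood is monotone decreasing in phi here
  lik <- function(phi) {
    r <- 1 / phi
    sum(sapply(split(1:6, grp), function(idx) {
      n <- length(idx)
      z <- sum(y[, idx])
      sum(lgamma(y[, idx] + r)) + lgamma(n * r) - lgamma(z + n * r) -
        n * lgamma(r)
    }))
  }
  phis <- c(1e-4, 1e-3, 1e-2, 0.1, 1, 5)
  expect_true(all(diff(sapply(phis, lik)) < 0))
  est <- estimate_common_dispersion(y, grp)
  expect_lt(est$dispersion, 2e-4)
})

test_that("exact test at phi = 0 equals the binomial conditional test", {
  for (grp_sizes in list(c(3, 3), c(2, 5))) {
    n1 <- grp_sizes[1]
    n2 <- grp_sizes[2]
    for (s in c(1, 2, 7, 25, 60)) {
      oracle <- oracle_binom_pvals(s, n1, n2)
      y <- matrix(0L, s + 1, n1 + n2)
      y[, 1] <- 0:s
      y[, n1 + 1] <- s - (0:s)
      colnames(y) <- paste0("s", seq_len(n1 + n2))
      rownames(y) <- paste0("g", 0:s)
      grp <- factor(rep(c("a", "b"), c(n1, n2)))
      p <- nb_exact_test(y, grp, dispersion = 0)
      expect_equal(p, oracle, tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("exact test symmetries and monotonicity in dispersion hold", {
  sim <- sim_two_group(n_genes = 100, n_per_group = 3, phi = 0.1, seed = 73)
  p1 <- nb_exact_test(sim$y, sim$group, 0.1)
  # swapping group labels leaves p unchanged
  p2 <- nb_exact_test(sim$y[, c(4:6, 1:3)],
                      factor(rep(c("b", "a"), each = 3),
                             levels = c("b", "a")), 0.1)
  expect_equal(p1, p2)
  # identical group sums in a symmetric design are modal: p = 1
  y_eq <- matrix(c(5L, 5L, 5L, 5L, 5L, 5L), 1,
                 dimnames = list("g", paste0("s", 1:6)))
  expect_equal(nb_exact_test(y_eq, sim$group, 0.1), 1,
               ignore_attr = TRUE)
  # all-zero gene: p = 1 by convention
  y0 <- matrix(0L, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  expect_equal(nb_exact_test(y0, sim$group, 0.1), 1, ignore_attr = TRUE)
  # increasing phi never decreases p
  grid_y <- matrix(c(30L, 10L, 20L, 2L, 3L, 4L), 1,
                   dimnames = list("g", paste0("s", 1:6)))
  ps <- sapply(c(0, 0.05, 0.1, 0.2, 0.5, 1), function(phi) {
    nb_exact_test(grid_y, sim$group, phi)
  })
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("large totals use the truncated enumeration consistently", {
  # straddle the enumeration switchover: p must be continuous across it
  grp <- factor(rep(c("a", "b"), each = 3))
  for (s_target in c(4990, 5010, 20000)) {
    a <- round(s_target * 0.55)
    b <- s_target - a
    y <- matrix(c(a, 0L, 0L, b, 0L, 0L), 1,
                dimnames = list("g", paste0("s", 1:6)))
    p <- nb_exact_test(y, grp, 0.05)
    expect_true(p > 0 && p <= 1)
  }
  # direct check at the boundary: full enumeration vs truncated ranges
  a <- 2760L
  b <- 2245L  # s = 5005 > 5000 -> truncated path
  y <- matrix(c(a, 0L, 0L, b, 0L, 0L), 1,
              dimnames = list("g", paste0("s", 1:6)))
  p_trunc <- nb_exact_test(y, grp, 0.1)
  # brute force over the full support
  s <- a + b
  mu <- s / 6
  lw <- dnbinom(0:s, size = 3 / 0.1, mu = 3 * mu, log = TRUE) +
    dnbinom(s - (0:s), size = 3 / 0.1, mu = 3 * mu, log = TRUE)
  w <- exp(lw - max(lw))
  p_full <- sum(w[w <= w[a + 1] * (1 + 1e-12)]) / sum(w)
  expect_equal(p_trunc, p_full, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("null exact-test p-values are calibrated", {
  sim <- sim_two_group(n_genes = 1000, n_per_group = 3, phi = 0.1,
                       seed = 74)
  p_known <- nb_exact_test(sim$y, sim$group, 0.1)
  expect_gt(mean(p_known < 0.05), 0.03)
  expect_lt(mean(p_known < 0.05), 0.07)
  est <- estimate_common_dispersion(sim$y, sim$group)
  p_est <- nb_exact_test(sim$y, sim$group, est$dispersion)
  expect_gt(mean(p_est < 0.05), 0.02)
  expect_lt(mean(p_est < 0.05), 0.08)
})

test_that("BH adjustment matches the hand example and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(75, {
    for (i in 1:5) {
      p <- runif(50)
      expect_equal(bh_adjust(p), oracle_bh(p))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
  # FDR >= p and non-decreasing along sorted p
  withr::with_seed(76, p <- runif(100))
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("run_contrast wires normalization into the exact test", {
  cfg <- simulation_config(n_genes = 600, design = two_group_design(3),
                           de_fraction = 0.1, de_log2fc = 2,
                           dispersion = 0.05, reads_per_sample = 2e5,
                           seed = 77)
  sim <- simulate_gene_models(cfg)
  y <- simulate_counts(sim$models, sim$truth, cfg, mode = "truncated_500")
  norm <- binned_normalize(filter_by_cpm(y), "transcript_length", 10)
  ct <- define_contrast("tg", paste0("NTg_r", 1:3), paste0("Tg_r", 1:3))
  res <- run_contrast(norm, ct)
  expect_s3_class(res, "de_result")
  expect_true(all(res$PValue > 0 & res$PValue <= 1))
  expect_true(all(res$FDR >= res$PValue))
  # spiked genes with decent expression recover their true log2FC
  truth_lfc <- sim$truth$true_log2fc[res$gene_id]
  strong <- truth_lfc == 2 &
    rowMeans(norm$pseudo[res$gene_id, ]) >= 50
  expect_equal(mean(res$logFC[strong]), 2, tolerance = 0.15)
  # determinism
  res2 <- run_contrast(norm, ct)
  expect_identical(res, res2)
  # missing samples fail fast
  expect_error(run_contrast(norm, define_contrast("x", c("a", "b"),
                                                  c("c", "d"))),
               "not in the normalized matrix")
})

test_that("permuted null labels give approximately uniform p-values", {
  # null NB counts at informative depth, unconfounded random lengths,
  # pushed through the full normalize + round + estimate + test path
  withr::with_seed(85, {
    mu <- exp(runif(2000, log(50), log(2000)))
    y <- sapply(1:6, function(i) rnbinom(2000, mu = mu, size = 1 / 0.1))
    dimnames(y) <- list(paste0("g", 1:2000), paste0("s", 1:6))
    genes <- data.frame(gene_id = rownames(y),
                        length = runif(2000, 500, 9000))
  })
  norm <- binned_normalize(filter_by_cpm(count_matrix(y, genes = genes)),
                           "transcript_length", 10)
  ids <- colnames(norm$pseudo)
  for (perm in list(c(1, 4, 5), c(1, 3, 5))) {
    ct <- define_contrast("perm", ids[perm], ids[setdiff(1:6, perm)])
    res <- run_contrast(norm, ct)
    ks <- suppressWarnings(stats::ks.test(res$PValue, "punif"))$statistic
    expect_lt(unname(ks), 0.05)
  }
})

test_that("threshold filters and Venn intersections behave", {
  res <- structure(data.frame(
    gene_id = c("g1", "g2", "g3"),
    logFC = c(2.1, 1.0, -2.5),
    logCPM = c(5, 5, 5),
    PValue = c(0.01, 0.01, 0.2),
    FDR = c(0.03, 0.03, 0.2)
  ), class = c("de_result", "data.frame"))
  hit <- threshold_de(res, min_abs_log2fc = 2, max_p = 0.05)
  expect_equal(hit$gene_id, "g1")
  expect_equal(hit$direction, "up")
  expect_equal(nrow(threshold_de(res, 0, 1.0)), 3L)
  empty <- res[0, ]
  expect_equal(nrow(threshold_de(empty, 1, 0.05)), 0L)

  # constructed 4-set intersection with exactly 19 genes shared by all
  core <- paste0("core", 1:19)
  sets <- list(
    A = c(core, paste0("a", 1:5)),
    B = c(core, paste0("b", 1:3)),
    C = c(core, paste0("c", 1:7)),
    D = c(core, paste0("d", 1:2))
  )
  venn <- intersect_de_sets(sets)
  allway <- venn$regions$count[venn$regions$region == "A&B&C&D"]
  expect_equal(allway, 19L)
  # disjoint sets: no multi-set region is occupied
  dis <- intersect_de_sets(list(X = c("x1", "x2"), Y = c("y1")))
  multi <- grepl("&", dis$regions$region)
  expect_true(all(dis$regions$count[multi] == 0L))
  # identical sets: everything in the all-way region
  ident <- intersect_de_sets(list(P = core, Q = core))
  expect_equal(ident$regions$count[ident$regions$region == "P&Q"], 19L)
  expect_error(intersect_de_sets(list(core)), "named")
})
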