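# Independent, deliberately unvectorized reference implementations used to
# cross-check the package's fast paths.

# TMM factors computed step by step, gene by gene
oracle_tmm <- function(y, N, trim_m = 0.3, trim_a = 0.05) {
  ng <- nrow(y)
  ns <- ncol(y)
  f75 <- numeric(ns)
  for (s in seq_len(ns)) {
    v <- numeric(ng)
    for (g in seq_len(ng)) v[g] <- y[g, s] / N[s] * 1e6
    f75[s] <- quantile(v, 0.75, names = FALSE)
  }
  m75 <- mean(f75)
  ref <- 1
  bestd <- Inf
  for (s in seq_len(ns)) {
    if (abs(f75[s] - m75) < bestd) {
      bestd <- abs(f75[s] - m75)
      ref <- s
    }
  }
  logf <- numeric(ns)
  for (k in seq_len(ns)) {
    if (k == ref) next
    M <- c()
    A <- c()
    w <- c()
    for (g in seq_len(ng)) {
      if (y[g, k] > 0 && y[g, ref] > 0) {
        M <- c(M, log2((y[g, k] / N[k]) / (y[g, ref] / N[ref])))
        A <- c(A, 0.5 * log2((y[g, k] / N[k]) * (y[g, ref] / N[ref])))
        w <- c(w, 1 / ((N[k] - y[g, k]) / (N[k] * y[g, k]) +
                         (N[ref] - y[g, ref]) / (N[ref] * y[g, ref])))
      }
    }
    n <- length(M)
    rM <- rank(M)
    rA <- rank(A)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    num <- 0
    den <- 0
    for (g in seq_len(n)) {
      if (rM[g] >= loM && rM[g] <= hiM && rA[g] >= loA && rA[g] <= hiA) {
        num <- num + w[g] * M[g]
        den <- den + w[g]
      }
    }
    logf[k] <- num / den
  }
  f <- 2^logf
  f / exp(mean(log(f)))
}

# two-sided exact binomial conditional p-values for every split a of total
# s between n1 and n2 samples (the phi = 0 limit of the NB exact test)
oracle_binom_pvals <- function(s, n1, n2) {
  pr <- n1 / (n1 + n2)
  w <- dbinom(0:s, s, pr)
  p <- numeric(s + 1)
  for (a in 0:s) {
    p[a + 1] <- sum(w[w <= w[a + 1] * (1 + 1e-12)])
  }
  pmin(p, 1)
}

# hypergeometric upper tail P(X >= k) as an explicit sum of choose terms
oracle_hyper_tail <- function(N, K, n, k) {
  tot <- 0
  for (i in k:min(n, K)) {
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  }
  tot / choose(N, n)
}

# BH step-up computed by the textbook recursion
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(1, p[o[i]] * m / i)
    prev <- min(prev, val)
    q[o[i]] <- prev
  }
  q
}

# spreadsheet-style 2^-ddCt: explicit per-sample arithmetic
oracle_ddct <- function(cts, target, refs, control_group = "control") {
  avg <- aggregate(ct ~ sample_id + group + gene_id, cts, mean)
  samples <- unique(avg$sample_id)
  dct <- setNames(numeric(length(samples)), samples)
  grp <- setNames(character(length(samples)), samples)
  for (sid in samples) {
    sub <- avg[avg$sample_id == sid, ]
    ref_ct <- 0
    for (r in refs) ref_ct <- ref_ct + sub$ct[sub$gene_id == r]
    dct[sid] <- sub$ct[sub$gene_id == target] - ref_ct / length(refs)
    grp[sid] <- sub$group[1]
  }
  ddct <- dct - mean(dct[grp == control_group])
  2^(-ddct)
}

# tiny two-group simulation used by several DE tests
sim_two_group <- function(n_genes = 400, n_per_group = 3, mu = 100,
                          phi = 0.1, lfc = 0, frac_de = 0, seed = 1) {
  withr::with_seed(seed, {
    mu_g <- rexp(n_genes, 1 / mu) + 10
    lfc_g <- numeric(n_genes)
    if (frac_de > 0) {
      idx <- seq_len(round(frac_de * n_genes))
      lfc_g[idx] <- lfc
    }
    draw <- function(m) {
      if (phi == 0) rpois(length(m), m) else
        rnbinom(length(m), size = 1 / phi, mu = m)
    }
    y <- cbind(
      sapply(seq_len(n_per_group), function(i) draw(mu_g)),
      sapply(seq_len(n_per_group), function(i) draw(mu_g * 2^lfc_g))
    )
    dimnames(y) <- list(paste0("g", seq_len(n_genes)),
                        paste0("s", seq_len(2 * n_per_group)))
    list(y = y, true_lfc = lfc_g,
         group = factor(rep(c("g1", "g2"), each = n_per_group)))
  })
}

# hand-written two-transcript fixture on both strands (internal 0-based
# half-open coordinates), used by truncation tests
fixture_models <- function() {
  ex <- data.frame(
    gene_id = c("gp", "gp", "gm", "gm", "gs"),
    transcript_id = c("gp.t1", "gp.t1", "gm.t1", "gm.t1", "gs.t1"),
    chrom = "chrT",
    start = c(100, 600, 100, 600, 2000),
    end = c(400, 900, 400, 900, 2400),
    strand = c("+", "+", "-", "-", "+"),
    stringsAsFactors = FALSE
  )
  gene_models(ex, abundance = c(gp.t1 = 5, gm.t1 = 5, gs.t1 = 5))
}
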