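#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Estimates a single dispersion phi shared by all genes from counts with
#' equalized library sizes (the pseudo-counts produced by normalization,
#' rounded to integers). For each gene and each group with n replicate
#' counts y_j summing to z, the conditional log-likelihood given the group
#' total is
#' `sum_j lgamma(y_j + r) + lgamma(n r) - lgamma(z + n r) - n lgamma(r)`
#' with `r = 1/phi`; the estimate maximizes the sum over genes and groups
#' by golden-section search on log phi over `[1e-4, 5]`. All-zero genes
#' contribute nothing and are skipped.
#'
#' @param counts integer matrix (genes x samples) of rounded
#'   pseudo-counts.
#' @param group factor of group labels, one per column.
#' @param interval search interval for phi.
#' @param tol convergence tolerance on log phi.
#' @return List of class `dispersion_estimate`: `dispersion`, `loglik`,
#'   `interval`.
#' @export
estimate_common_dispersion <- function(counts, group,
                                       interval = c(1e-4, 5),
                                       tol = 1e-6) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("empty count matrix")
  group <- as.factor(group)
  if (length(group) != ncol(counts)) {
    stop("group length must match the number of samples")
  }
  keep <- rowSums(counts) > 0
  y <- counts[keep, , drop = FALSE]
  if (nrow(y) == 0L) stop("all genes have zero counts")
  idx_by_grp <- split(seq_along(group), group)
  idx_by_grp <- idx_by_grp[vapply(idx_by_grp, length, 1L) > 0L]

  cml <- function(log_phi) {
    r <- exp(-log_phi)   # 1/phi
    tot <- 0
    for (idx in idx_by_grp) {
      n <- length(idx)
      yg <- y[, idx, drop = FALSE]
      z <- rowSums(yg)
      tot <- tot + sum(rowSums(lgamma(yg + r)) + lgamma(n * r) -
                         lgamma(z + n * r) - n * lgamma(r))
    }
    tot
  }

  # golden-section maximization on log phi
  gold <- (sqrt(5) - 1) / 2
  a <- log(interval[1])
  b <- log(interval[2])
  c1 <- b - gold * (b - a)
  d1 <- a + gold * (b - a)
  fc <- cml(c1)
  fd <- cml(d1)
  while (b - a > tol) {
    if (fc > fd) {
      b <- d1
      d1 <- c1
      fd <- fc
      c1 <- b - gold * (b - a)
      fc <- cml(c1)
    } else {
      a <- c1
      c1 <- d1
      fc <- fd
      d1 <- a + gold * (b - a)
      fd <- cml(d1)
    }
  }
  log_phi <- (a + b) / 2
  structure(list(dispersion = exp(log_phi), loglik = cml(log_phi),
                 interval = interval),
            class = "dispersion_estimate")
}

# Exact conditional NB p-value for one gene: group sums a, b from n1 and
# n2 replicates, total s, common dispersion phi. Group sums are NB with
# means n_i * s/(n1+n2) and sizes n_i/phi (Poisson when phi ~ 0); the
# two-sided p-value sums, over all splits of s no more probable than the
# observed one, the conditional probability given the total.
.nb_exact_pvalue <- function(a, b, n1, n2, phi) {
  s <- a + b
  if (s == 0) return(1)
  mu <- s / (n1 + n2)
  poisson <- phi < 1e-10
  lw_fun <- function(x) {
    if (poisson) {
      dpois(x, n1 * mu, log = TRUE) + dpois(s - x, n2 * mu, log = TRUE)
    } else {
      dnbinom(x, size = n1 / phi, mu = n1 * mu, log = TRUE) +
        dnbinom(s - x, size = n2 / phi, mu = n2 * mu, log = TRUE)
    }
  }
  if (s <= 5000) {
    x <- 0:s
  } else {
    # enumerate only the region carrying non-negligible conditional mass;
    # the discarded tails hold < 4e-18 of it
    if (poisson) {
      q1 <- qpois(c(1e-18, 1 - 1e-18), n1 * mu)
      q2 <- qpois(c(1e-18, 1 - 1e-18), n2 * mu)
    } else {
      q1 <- qnbinom(c(1e-18, 1 - 1e-18), size = n1 / phi, mu = n1 * mu)
      q2 <- qnbinom(c(1e-18, 1 - 1e-18), size = n2 / phi, mu = n2 * mu)
    }
    lo <- max(0, min(q1[1], s - q2[2], a))
    hi <- min(s, max(q1[2], s - q2[1], a))
    x <- lo:hi
  }
  lw <- lw_fun(x)
  w <- exp(lw - max(lw))
  w_obs <- w[match(a, x)]
  p <- sum(w[w <= w_obs * (1 + 1e-12)]) / sum(w)
  min(max(p, 0), 1)
}

#' Negative-binomial exact test
#'
#' Conditional two-group exact test on equal-library pseudo-counts: per
#' gene, the two group sums given their total are compared under
#' negative-binomial sums with a common dispersion, and the p-value
#' aggregates all splits of the total at most as probable as the observed
#' one. With `dispersion = 0` the conditional law is binomial and the test
#' reduces to the two-sided exact binomial test.
#'
#' @param counts integer matrix of rounded pseudo-counts (equalized
#'   library sizes).
#' @param group factor with exactly two levels, one per column; the test
#'   contrasts level 2 against level 1.
#' @param dispersion common NB dispersion phi (>= 0).
#' @return Numeric vector of per-gene p-values in (0, 1].
#' @export
nb_exact_test <- function(counts, group, dispersion) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (dispersion < 0) stop("dispersion must be >= 0")
  i1 <- which(group == levels(group)[1L])
  i2 <- which(group == levels(group)[2L])
  a <- rowSums(counts[, i1, drop = FALSE])
  b <- rowSums(counts[, i2, drop = FALSE])
  vapply(seq_along(a), function(g) {
    .nb_exact_pvalue(a[g], b[g], length(i1), length(i2), dispersion)
  }, numeric(1L))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of FDR-adjusted values (same order as `p`).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Define a two-group contrast
#'
#' @param name contrast label.
#' @param group1,group2 character vectors of sample ids (reference group
#'   first; fold changes are group2 vs group1). Groups must be disjoint
#'   with at least 2 samples each.
#' @return List of class `de_contrast`.
#' @export
define_contrast <- function(name, group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each contrast group needs >= 2 samples")
  }
  if (length(intersect(group1, group2)) > 0L) {
    stop("contrast groups must be disjoint")
  }
  structure(list(name = name, group1 = group1, group2 = group2),
            class = "de_contrast")
}

#' Select sample ids from a design table
#'
#' @param design design data.frame with a `sample_id` column.
#' @param ... named filters, e.g. `genotype = "Tg", sex = "F"`; a sample
#'   is selected when every named column matches.
#' @return Character vector of sample ids.
#' @export
select_samples <- function(design, ...) {
  filt <- list(...)
  keep <- rep(TRUE, nrow(design))
  for (nm in names(filt)) {
    if (!nm %in% names(design)) stop("no design column '", nm, "'")
    keep <- keep & design[[nm]] %in% filt[[nm]]
  }
  design$sample_id[keep]
}

#' Run a differential-expression contrast
#'
#' The exact-test workflow on normalized pseudo-counts: pseudo-counts for
#' the contrast samples are rounded half-to-even to integers, the common
#' dispersion is estimated by conditional maximum likelihood, the
#' negative-binomial exact test is applied per gene, and BH FDR values are
#' attached. Fold changes are computed on the *unrounded* pseudo-counts
#' with a prior count of 0.5:
#' `log2FC = log2((mean2 + 0.5)/(mean1 + 0.5))`;
#' `logCPM = log2` of the average CPM across the contrast samples (same
#' prior), on the common effective library.
#'
#' @param norm a `norm_result` from [binned_normalize()] (or
#'   [libsize_normalize()]).
#' @param contrast a [define_contrast()] object.
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `logFC`, `logCPM`, `PValue`, `FDR`; attributes `contrast` and
#'   `dispersion`.
#' @export
run_contrast <- function(norm, contrast) {
  stopifnot(inherits(norm, "norm_result"), inherits(contrast, "de_contrast"))
  ids <- c(contrast$group1, contrast$group2)
  missing_ids <- setdiff(ids, colnames(norm$pseudo))
  if (length(missing_ids) > 0L) {
    stop("contrast samples not in the normalized matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  yy <- norm$pseudo[, ids, drop = FALSE]
  n1 <- length(contrast$group1)
  n2 <- length(contrast$group2)
  grp <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))
  yint <- round(yy)
  disp <- estimate_common_dispersion(yint, grp)
  pval <- nb_exact_test(yint, grp, disp$dispersion)
  m1 <- rowMeans(yy[, seq_len(n1), drop = FALSE])
  m2 <- rowMeans(yy[, n1 + seq_len(n2), drop = FALSE])
  res <- data.frame(
    gene_id = rownames(yy),
    logFC = log2((m2 + 0.5) / (m1 + 0.5)),
    logCPM = log2((rowMeans(yy) + 0.5) / norm$effective_lib * 1e6),
    PValue = pval,
    FDR = bh_adjust(pval),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast$name
  attr(res, "dispersion") <- disp$dispersion
  class(res) <- c("de_result", "data.frame")
  res
}

#' Threshold a DE result into a gene set
#'
#' Genes passing both an absolute fold-change cutoff (`|logFC| >=
#' min_abs_log2fc`) and a significance cutoff (`p < max_p`, strict), with
#' their direction. `use_fdr` switches the significance column from raw
#' p-values to BH FDR.
#'
#' @param res a `de_result`.
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1,
#'   i.e. 2-fold).
#' @param max_p significance cutoff (default 0.05).
#' @param use_fdr apply `max_p` to FDR instead of raw p (default FALSE).
#' @return data.frame with `gene_id`, `logFC`, `direction` ("up"/"down").
#' @export
threshold_de <- function(res, min_abs_log2fc = 1, max_p = 0.05,
                         use_fdr = FALSE) {
  pcol <- if (use_fdr) res$FDR else res$PValue
  sel <- abs(res$logFC) >= min_abs_log2fc & pcol < max_p
  out <- res[sel, c("gene_id", "logFC"), drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Intersect named DE gene sets (Venn partition)
#'
#' @param sets named list (>= 2) of character gene-id vectors.
#' @return List with `membership` (logical data.frame over the union) and
#'   `regions` (data.frame with one row per non-empty label combination of
#'   the Venn partition and its gene count, including zero counts).
#' @export
intersect_de_sets <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)) || any(names(sets) == "")) {
    stop("need >= 2 named gene sets")
  }
  all_genes <- sort(unique(unlist(sets)))
  memb <- as.data.frame(
    lapply(sets, function(s) all_genes %in% s),
    row.names = all_genes
  )
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  region <- apply(combos, 1L, function(z) {
    paste(names(sets)[as.logical(z)], collapse = "&")
  })
  count <- apply(combos, 1L, function(z) {
    sum(apply(memb, 1L, function(m) all(m == as.logical(z))))
  })
  list(membership = memb,
       regions = data.frame(region = region, count = as.integer(count),
                            row.names = NULL, stringsAsFactors = FALSE))
}
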