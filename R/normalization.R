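#' Expression pre-filter by CPM
#'
#' Keeps gene g iff its CPM exceeds `cpm_threshold` (strictly) in at least
#' `min_samples` samples. Library sizes are *not* recomputed after
#' filtering: CPM and TMM downstream keep using the frozen pre-filter
#' totals, which makes the result independent of filter order.
#'
#' @param counts a [count_matrix].
#' @param cpm_threshold CPM cutoff (default 2, strict `>`).
#' @param min_samples minimum number of samples above the cutoff
#'   (default 3).
#' @return The filtered [count_matrix] (library sizes unchanged).
#' @export
filter_by_cpm <- function(counts, cpm_threshold = 2, min_samples = 3) {
  stopifnot(inherits(counts, "count_matrix"))
  x <- cpm(counts)
  keep <- rowSums(x > cpm_threshold) >= min_samples
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  if (!is.null(counts$genes)) {
    out$genes <- counts$genes[keep, , drop = FALSE]
    rownames(out$genes) <- NULL
  }
  out
}

#' Quantile bin assignment
#'
#' Splits genes into `n_bins` covariate-ordered groups of near-equal size
#' (sizes differ by at most 1 when covariate values are distinct). Tied
#' covariate values always land in the same bin (the lowest bin touched by
#' the tie run), so bin sizes can deviate under heavy ties; with a
#' constant covariate everything collapses into a single bin.
#'
#' @param values numeric covariate, one per gene.
#' @param n_bins number of bins (default 10).
#' @return Integer vector of bin indices in `1..n_bins`, ordered by
#'   covariate (bin 1 holds the smallest values).
#' @export
assign_bins <- function(values, n_bins = 10) {
  n <- length(values)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds number of genes (",
                       n, ")")
  if (anyNA(values)) stop("covariate has missing values")
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  b <- integer(n)
  b[order(values)] <- rep.int(seq_len(n_bins), sizes)
  # ties share the lowest bin touched by their run
  as.integer(ave(b, values, FUN = min))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values with the canonical defaults: the reference
#' sample is the one whose 75th-percentile CPM is closest to the mean 75th
#' percentile; for sample k against reference r, using genes with positive
#' counts in both, per-gene log-ratios `M = log2((y_k/N_k)/(y_r/N_r))` and
#' average log-abundances `A = 0.5*log2((y_k/N_k)(y_r/N_r))` are doubly
#' trimmed (upper/lower 30% of M, upper/lower 5% of A by rank) and
#' combined by a precision-weighted mean with delta-method weights
#' `w = 1/((N_k-y_k)/(N_k y_k) + (N_r-y_r)/(N_r y_r))`. Factors are
#' rescaled so their geometric mean is 1. If trimming leaves no usable
#' genes the factor falls back to 1 with a warning.
#'
#' @param counts a [count_matrix] or numeric matrix (genes x samples);
#'   real-valued "counts" (pseudo-counts) are accepted.
#' @param lib_sizes library sizes for a plain matrix (defaults to column
#'   sums; a `count_matrix` supplies its own).
#' @param trim_m,trim_a two-sided trim fractions for M and A (defaults
#'   0.30 and 0.05).
#' @return Numeric vector of per-sample factors (geometric mean 1), with
#'   the reference sample index in attribute `ref`.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, trim_m = 0.3,
                        trim_a = 0.05) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(lib_sizes)) lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  ns <- ncol(counts)
  if (ns < 2L) stop("TMM needs at least 2 samples")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  x <- cpm(counts, lib_sizes)
  f75 <- apply(x, 2L, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(f75 - mean(f75)))
  logf <- numeric(ns)
  yr_all <- counts[, ref]
  Nr <- lib_sizes[ref]
  for (k in seq_len(ns)) {
    if (k == ref) next
    use <- counts[, k] > 0 & yr_all > 0
    if (!any(use)) {
      warning("no genes positive in both sample ", k, " and the reference; ",
              "factor set to 1")
      next
    }
    yk <- counts[use, k]
    yr <- yr_all[use]
    Nk <- lib_sizes[k]
    M <- log2((yk / Nk) / (yr / Nr))
    A <- 0.5 * log2((yk / Nk) * (yr / Nr))
    n <- length(M)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) {
      warning("trimming removed all genes for sample ", k,
              "; factor set to 1")
      next
    }
    w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
    logf[k] <- sum(w[keep] * M[keep]) / sum(w[keep])
  }
  f <- 2^logf
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "ref") <- ref
  f
}

#' Binned TMM normalization
#'
#' The degradation-aware normalization: genes are split into
#' covariate-quantile bins (dominant-transcript length by default, average
#' CPM for the abundance pass), TMM factors are computed independently
#' within each bin, and the bins are merged back into a single matrix of
#' adjusted pseudo-counts
#' `yhat_gs = y_gs * Ntilde / (N_s * f_{s,b(g)})`,
#' where `Ntilde` is the geometric mean of the library sizes. All samples
#' thus share the common effective library size `Ntilde`, as the exact
#' test downstream requires. Pseudo-counts are kept real-valued; rounding
#' happens only inside the test.
#'
#' @param counts a pre-filtered [count_matrix].
#' @param covariate `"transcript_length"` (needs a `length` column in
#'   `counts$genes`) or `"average_cpm"`.
#' @param n_bins number of bins (default 10).
#' @param trim_m,trim_a TMM trim fractions, passed to [tmm_factors()].
#' @return List of class `norm_result`: `pseudo` (real-valued adjusted
#'   counts), `factors` (bins x samples), `bins` (per-gene bin index),
#'   `lib_sizes`, `effective_lib` (`Ntilde`), `genes`, `counts`,
#'   `covariate`.
#' @export
binned_normalize <- function(counts,
                             covariate = c("transcript_length",
                                           "average_cpm"),
                             n_bins = 10, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  covariate <- match.arg(covariate)
  y <- counts$counts
  N <- counts$lib_sizes
  cov_val <- switch(covariate,
    transcript_length = {
      if (is.null(counts$genes) || is.null(counts$genes$length)) {
        stop("transcript_length covariate needs counts$genes$length")
      }
      counts$genes$length
    },
    average_cpm = rowMeans(cpm(y, N))
  )
  bins <- assign_bins(cov_val, n_bins)
  fac <- matrix(1, n_bins, ncol(y),
                dimnames = list(NULL, colnames(y)))
  for (b in sort(unique(bins))) {
    idx <- bins == b
    fac[b, ] <- tmm_factors(y[idx, , drop = FALSE], N,
                            trim_m = trim_m, trim_a = trim_a)
  }
  Ntilde <- exp(mean(log(N)))
  denom <- fac[bins, , drop = FALSE] * rep(N, each = nrow(y))
  pseudo <- y * (Ntilde / denom)
  dimnames(pseudo) <- dimnames(y)
  structure(list(
    pseudo = pseudo, factors = fac, bins = bins, lib_sizes = N,
    effective_lib = Ntilde, genes = counts$genes, counts = y,
    covariate = covariate
  ), class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat("norm_result:", nrow(x$pseudo), "genes x", ncol(x$pseudo),
      "samples;", max(x$bins), "bins by", x$covariate,
      "; effective library", format(round(x$effective_lib)), "\n")
  invisible(x)
}

#' Abundance-bin renormalization pass
#'
#' Second binned-TMM pass that removes residual dependence of fold changes
#' on expression level: the pseudo-counts from the length-bin pass are
#' re-binned by average CPM and TMM-normalized again within each bin. The
#' returned object composes both passes (its `pseudo` matrix reflects
#' length-bin then abundance-bin adjustment); the first pass is kept in
#' `$first_pass`.
#'
#' @param result a `norm_result` from [binned_normalize()].
#' @param n_bins number of abundance bins (default 10).
#' @param trim_m,trim_a TMM trim fractions.
#' @return A `norm_result` with covariate `"average_cpm"` and the input
#'   attached as `$first_pass`.
#' @export
abundance_renormalize <- function(result, n_bins = 10, trim_m = 0.3,
                                  trim_a = 0.05) {
  stopifnot(inherits(result, "norm_result"))
  cm <- count_matrix(result$pseudo, lib_sizes = colSums(result$pseudo),
                     genes = result$genes)
  out <- binned_normalize(cm, covariate = "average_cpm", n_bins = n_bins,
                          trim_m = trim_m, trim_a = trim_a)
  out$first_pass <- result
  out
}

#' Library-size-only normalization
#'
#' The naive baseline the binned TMM is compared against: pseudo-counts
#' are the raw counts rescaled to the common effective library size with
#' all normalization factors fixed at 1.
#'
#' @param counts a [count_matrix].
#' @return A `norm_result` with unit factors and a single bin.
#' @export
libsize_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  y <- counts$counts
  N <- counts$lib_sizes
  Ntilde <- exp(mean(log(N)))
  pseudo <- sweep(y, 2L, Ntilde / N, "*")
  structure(list(
    pseudo = pseudo, factors = matrix(1, 1L, ncol(y),
                                      dimnames = list(NULL, colnames(y))),
    bins = rep(1L, nrow(y)), lib_sizes = N, effective_lib = Ntilde,
    genes = counts$genes, counts = y, covariate = "none"
  ), class = "norm_result")
}
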