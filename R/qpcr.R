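#' Relative expression by the 2^-ddCt method
#'
#' Quantifies a target gene relative to reference genes (e.g. act5c and
#' tub84B) from qPCR cycle-threshold values. Technical replicates are
#' averaged per sample and gene; per sample,
#' `dCt = Ct_target - mean(Ct_references)` (the arithmetic mean of
#' reference Cts, equivalent to the geometric mean of reference
#' expression); `ddCt = dCt - mean(dCt over control samples)`; the
#' relative ratio is `2^-ddCt`. Group ratios are geometric means of the
#' per-sample ratios, so the control group's ratio is 1 by construction.
#'
#' @param cts long-format data.frame with columns `sample_id`, `group`,
#'   `gene_id`, `ct` (one row per technical replicate; Ct > 0).
#' @param target target gene id.
#' @param references character vector of reference gene ids; every
#'   reference must be measured in every sample.
#' @param control_group label of the control group in `cts$group`.
#' @return List of class `ddct_result`: `samples` (per-sample `delta_ct`,
#'   `delta_delta_ct`, `ratio`), `group_ratios` (geometric mean ratio per
#'   group), `target`, `references`.
#' @export
delta_delta_ct <- function(cts, target, references,
                           control_group = "control") {
  req <- c("sample_id", "group", "gene_id", "ct")
  miss <- setdiff(req, names(cts))
  if (length(miss) > 0L) stop("Ct table missing columns: ",
                              paste(miss, collapse = ", "))
  if (any(cts$ct <= 0)) stop("Ct values must be > 0")
  if (!control_group %in% cts$group) {
    stop("no samples in control group '", control_group, "'")
  }
  # average technical replicates
  avg <- aggregate(ct ~ sample_id + group + gene_id, data = cts, FUN = mean)
  samples <- unique(avg[, c("sample_id", "group")])
  dct <- numeric(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    sub <- avg[avg$sample_id == sid, , drop = FALSE]
    for (g in c(target, references)) {
      if (!g %in% sub$gene_id) {
        stop("gene '", g, "' not measured in sample '", sid, "'")
      }
    }
    ct_t <- sub$ct[sub$gene_id == target]
    ct_r <- mean(sub$ct[match(references, sub$gene_id)])
    dct[i] <- ct_t - ct_r
  }
  ctrl <- samples$group == control_group
  ddct <- dct - mean(dct[ctrl])
  ratio <- 2^(-ddct)
  per_sample <- data.frame(
    sample_id = samples$sample_id, group = samples$group,
    delta_ct = dct, delta_delta_ct = ddct, ratio = ratio,
    stringsAsFactors = FALSE
  )
  grp_ratio <- tapply(ratio, samples$group, function(r) exp(mean(log(r))))
  structure(list(samples = per_sample,
                 group_ratios = setNames(as.numeric(grp_ratio),
                                         names(grp_ratio)),
                 target = target, references = references),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat("2^-ddCt for", x$target, "vs",
      paste(x$references, collapse = "+"), "\n")
  for (g in names(x$group_ratios)) {
    cat(sprintf("  %s: %.3f\n", g, x$group_ratios[g]))
  }
  invisible(x)
}

#' Nonparametric comparison of expression ratios
#'
#' Mann-Whitney (unpaired) or Wilcoxon signed-rank (paired) test of two
#' groups of relative-expression ratios. Exact enumeration is used for
#' small tie-free samples (both groups <= 12); larger or tied data fall
#' back to the normal approximation with continuity and tie correction.
#'
#' @param treated,control numeric vectors of ratios (>= 3 each for the
#'   unpaired test; equal lengths for the paired test).
#' @param paired paired Wilcoxon signed-rank instead of Mann-Whitney.
#' @return Two-sided p-value.
#' @export
rank_test <- function(treated, control, paired = FALSE) {
  if (paired) {
    if (length(treated) != length(control)) {
      stop("paired test needs equal-length groups")
    }
    if (length(treated) < 3L) stop("need >= 3 pairs")
    diffs <- treated - control
    if (all(diffs == 0)) return(1)
    exact <- length(diffs) <= 12L && !any(diffs == 0) &&
      !any(duplicated(abs(diffs)))
  } else {
    if (length(treated) < 3L || length(control) < 3L) {
      stop("need >= 3 values per group")
    }
    if (identical(sort(treated), sort(control))) return(1)
    exact <- length(treated) <= 12L && length(control) <= 12L &&
      !any(duplicated(c(treated, control)))
  }
  wilcox.test(treated, control, paired = paired, exact = exact,
              correct = TRUE)$p.value
}
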