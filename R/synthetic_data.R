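#' Sample design tables
#'
#' `study_design()` builds the default experimental layout the simulator
#' emulates: 2 genotypes (transgenic `Tg`, non-transgenic `NTg`) x 2 sexes
#' x 3 age groups x `n_replicates` biological replicates. Each sample gets
#' a degradation scale `decay_scale_bp` (the exponential 3'-coverage decay
#' length, the simulator's stand-in for RNA integrity): lower values mean
#' more degraded RNA. By default degradation worsens with age, which is the
#' confounded situation the normalization is designed to withstand.
#'
#' `two_group_design()` is a minimal two-condition layout used throughout
#' the tests and bias diagnostics: `n_per_group` replicates per genotype
#' with a per-group decay scale.
#'
#' @param n_replicates biological replicates per condition (default 3).
#' @param decay_scale_bp named numeric vector of decay scales per age group
#'   (bp), or a single value recycled to all samples.
#' @return data.frame with columns `sample_id`, `genotype`, `sex`, `age`,
#'   `replicate`, `decay_scale_bp`.
#' @export
study_design <- function(n_replicates = 3,
                         decay_scale_bp = c(young = 3000, mature = 1500,
                                            old = 800)) {
  grid <- expand.grid(
    replicate = seq_len(n_replicates),
    age = c("young", "mature", "old"),
    sex = c("M", "F"),
    genotype = c("NTg", "Tg"),
    stringsAsFactors = FALSE
  )
  lam <- if (length(decay_scale_bp) == 1L) {
    rep(decay_scale_bp, nrow(grid))
  } else {
    unname(decay_scale_bp[grid$age])
  }
  data.frame(
    sample_id = paste(grid$genotype, grid$sex, grid$age,
                      paste0("r", grid$replicate), sep = "_"),
    genotype = grid$genotype,
    sex = grid$sex,
    age = grid$age,
    replicate = grid$replicate,
    decay_scale_bp = lam,
    stringsAsFactors = FALSE
  )
}

#' @rdname study_design
#' @param n_per_group replicates per group.
#' @param decay_group1,decay_group2 decay scale (bp) for the `NTg` and `Tg`
#'   group respectively; `Inf` means uniform coverage (no degradation).
#' @export
two_group_design <- function(n_per_group = 3, decay_group1 = 2000,
                             decay_group2 = 2000) {
  g <- rep(c("NTg", "Tg"), each = n_per_group)
  r <- rep(seq_len(n_per_group), 2L)
  data.frame(
    sample_id = paste0(g, "_r", r),
    genotype = g,
    sex = "F",
    age = "young",
    replicate = r,
    decay_scale_bp = rep(c(decay_group1, decay_group2), each = n_per_group),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The defaults mirror the scale of a bulk fly RNA-seq study (thousands of
#' genes, three biological replicates per condition) with library sizes
#' scaled down to desk size.
#'
#' @param n_genes number of genes.
#' @param length_range_bp range of spliced transcript lengths (bp).
#' @param n_transcripts_per_gene_range range of isoform counts per gene.
#' @param design sample design data.frame (see [study_design()]); must
#'   contain `sample_id` and `decay_scale_bp` columns.
#' @param baseline_mean_range range of expected full-length read counts per
#'   gene; baselines are drawn log-uniformly in this range.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param de_fraction fraction of genes that are differentially expressed.
#' @param de_log2fc absolute log2 fold change of DE genes (sign assigned
#'   randomly, half up, half down).
#' @param de_group_column,de_group_level design column and level that
#'   receives the DE effect (default genotype "Tg").
#' @param reads_per_sample target library size; realized sizes are drawn
#'   uniformly within +/-20% to exercise normalization.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              length_range_bp = c(500, 10000),
                              n_transcripts_per_gene_range = c(1, 3),
                              design = study_design(),
                              baseline_mean_range = c(20, 2000),
                              dispersion = 0.1,
                              de_fraction = 0.1,
                              de_log2fc = 2,
                              de_group_column = "genotype",
                              de_group_level = "Tg",
                              reads_per_sample = 5e5,
                              seed = 1L) {
  chk_range <- function(r, name, int_ok = TRUE) {
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      stop("invalid ", name, ": must be a positive, ordered pair")
    }
  }
  if (n_genes < 1) stop("n_genes must be >= 1")
  chk_range(length_range_bp, "length_range_bp")
  chk_range(n_transcripts_per_gene_range, "n_transcripts_per_gene_range")
  chk_range(baseline_mean_range, "baseline_mean_range")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  if (reads_per_sample <= 0) stop("reads_per_sample must be > 0")
  req <- c("sample_id", "decay_scale_bp")
  if (!all(req %in% names(design))) {
    stop("design needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop("duplicated sample ids in design")
  if (any(design$decay_scale_bp <= 0)) {
    stop("decay_scale_bp must be > 0 (use Inf for uniform coverage)")
  }
  if (de_fraction > 0) {
    if (!de_group_column %in% names(design)) {
      stop("de_group_column '", de_group_column, "' not in design")
    }
    in_grp <- design[[de_group_column]] == de_group_level
    if (sum(in_grp) < 2 || sum(!in_grp) < 2) {
      stop("DE simulation needs >= 2 samples in and out of the DE group")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes),
    length_range_bp = length_range_bp,
    n_transcripts_per_gene_range = as.integer(n_transcripts_per_gene_range),
    design = design,
    baseline_mean_range = baseline_mean_range,
    dispersion = dispersion,
    de_fraction = de_fraction,
    de_log2fc = de_log2fc,
    de_group_column = de_group_column,
    de_group_level = de_group_level,
    reads_per_sample = reads_per_sample,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate gene models and ground truth
#'
#' Generates random single-chromosome gene models (1-4 exons per
#' transcript, non-overlapping genes) with one dominant isoform per gene:
#' alternative isoforms share the dominant transcript's 3' end and differ
#' by 5' extent, with strictly smaller abundance. Alongside the models it
#' returns the ground truth driving all later stages: per-gene baseline
#' expression, per-sample expected means, DE flags and true log2 fold
#' changes, dominant transcript ids and per-sample decay scales.
#'
#' @param config a [simulation_config()].
#' @return list with elements `models` ([gene_models]) and `truth` (class
#'   `ground_truth`).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  ng <- config$n_genes
  lr <- config$length_range_bp
  tr <- config$n_transcripts_per_gene_range
  gene_ids <- sprintf("g%04d", seq_len(ng))

  cursor <- 1000
  ex_list <- vector("list", ng)
  ab_list <- vector("list", ng)
  dom_len <- numeric(ng)
  dom_id <- character(ng)
  for (i in seq_len(ng)) {
    L <- round(runif(1, lr[1], lr[2]))
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample.int(4L, 1L)
    if (L < n_ex * 50) n_ex <- max(1L, L %/% 50)
    # random spliced split into n_ex exon pieces of >= 1 bp
    if (n_ex > 1L) {
      cuts <- sort(sample.int(L - 1L, n_ex - 1L))
      pieces <- diff(c(0L, cuts, L))
      introns <- sample(200:2000, n_ex - 1L, replace = TRUE)
    } else {
      pieces <- L
      introns <- integer(0)
    }
    starts <- cursor + cumsum(c(0, pieces[-n_ex] + introns))
    ends <- starts + pieces
    k <- if (tr[1] == tr[2]) tr[1] else sample(seq(tr[1], tr[2]), 1L)
    tx_ids <- paste0(gene_ids[i], ".t", seq_len(k))
    ab <- sort(runif(k, 1, 100), decreasing = TRUE)
    dom_ex <- data.frame(
      gene_id = gene_ids[i], transcript_id = tx_ids[1L],
      chrom = "sim_1", start = starts, end = ends, strand = strand,
      stringsAsFactors = FALSE
    )
    exs <- list(dom_ex)
    if (k > 1L) {
      for (j in 2:k) {
        # alternative isoform: same 3' end, shorter 5' extent
        Lj <- round(runif(1, min(lr[1], L), L))
        alt <- .truncate_exon_rows(dom_ex, max(Lj, 1))
        alt$transcript_id <- tx_ids[j]
        exs[[j]] <- alt
      }
    }
    ex_list[[i]] <- do.call(rbind, exs)
    ab_list[[i]] <- setNames(ab, tx_ids)
    dom_len[i] <- L
    dom_id[i] <- tx_ids[1L]
    cursor <- max(ends) + sample(500:1500, 1L)
  }
  models <- gene_models(do.call(rbind, ex_list),
                        abundance = unlist(ab_list))
  models <- select_dominant_transcripts(models)

  bl <- exp(runif(ng, log(config$baseline_mean_range[1]),
                  log(config$baseline_mean_range[2])))
  n_de <- round(config$de_fraction * ng)
  lfc <- numeric(ng)
  if (n_de > 0) {
    de_idx <- sample.int(ng, n_de)
    sgn <- rep(c(1, -1), length.out = n_de)
    lfc[de_idx] <- config$de_log2fc * sgn[sample.int(n_de)]
  }
  design <- config$design
  in_grp <- if (config$de_fraction > 0) {
    design[[config$de_group_column]] == config$de_group_level
  } else {
    rep(FALSE, nrow(design))
  }
  mu <- matrix(bl, ng, nrow(design))
  mu[, in_grp] <- mu[, in_grp, drop = FALSE] * 2^lfc
  dimnames(mu) <- list(gene_ids, design$sample_id)

  truth <- structure(list(
    mu = mu,
    baseline = setNames(bl, gene_ids),
    is_de = setNames(lfc != 0, gene_ids),
    true_log2fc = setNames(lfc, gene_ids),
    dominant = setNames(dom_id, gene_ids),
    dominant_length = setNames(dom_len, gene_ids),
    decay_scale = setNames(design$decay_scale_bp, design$sample_id),
    design = design
  ), class = "ground_truth")
  list(models = models, truth = truth)
}

# inverse-CDF sampler for 3'-distances: density on [0, L) proportional to
# exp(-d/lambda), truncated; lambda = Inf gives the uniform limit
.sample_3p_distances <- function(n, L, lambda) {
  u <- runif(n)
  if (!is.finite(lambda)) return(u * L)
  -lambda * log(1 - u * (1 - exp(-L / lambda)))
}

# expected fraction of a transcript's reads falling within `win` bp of the
# 3' end, under exponential decay with scale lambda
.window_mass <- function(L, lambda, win = L) {
  w <- pmin(L, win)
  if (!is.finite(lambda)) return(w / L)
  1 - exp(-w / lambda)
}

#' Simulate per-read 3'-distances
#'
#' For every sample, allocates the library (drawn uniformly within +/-20%
#' of the target size) across genes by a multinomial whose weights are the
#' expected per-gene read yields `mu * (1 - exp(-L/lambda))`, then draws
#' each read's 3'-distance from the truncated exponential decay density
#' `exp(-d/lambda)` on `[0, L)`. Degraded samples (small `lambda`) thus
#' lose reads far from the 3' end, and short transcripts lose
#' proportionally fewer reads than long ones.
#'
#' @param models,truth output of [simulate_gene_models()].
#' @param config the same [simulation_config()].
#' @return data.frame of class `read_positions`: `sample_id`, `gene_id`,
#'   `transcript_id`, `three_prime_distance` (bp, `0 <= d < L`).
#' @export
simulate_read_positions <- function(models, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  withr::local_seed(config$seed + 1L)
  L <- truth$dominant_length
  out <- vector("list", nrow(config$design))
  for (s in seq_len(nrow(config$design))) {
    sid <- config$design$sample_id[s]
    lam <- truth$decay_scale[sid]
    if (lam <= 0) stop("decay scale must be > 0 for sample ", sid)
    N <- round(config$reads_per_sample * runif(1, 0.8, 1.2))
    w <- truth$mu[, sid] * .window_mass(L, lam)
    cnt <- as.vector(rmultinom(1, N, w))
    gene_rep <- rep(names(L), cnt)
    d <- unlist(lapply(which(cnt > 0), function(i) {
      .sample_3p_distances(cnt[i], L[i], lam)
    }), use.names = FALSE)
    out[[s]] <- data.frame(
      sample_id = sid,
      gene_id = gene_rep,
      transcript_id = unname(truth$dominant[gene_rep]),
      three_prime_distance = d,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("read_positions", "data.frame")
  res
}

#' Simulate gene-level count matrices directly
#'
#' Fast path that skips per-read simulation: expected counts per gene are
#' the library size times the gene's share of the decay-weighted expression
#' mass, with the counting window either the full transcript
#' (`full_length`) or the 3'-most `window_bp` bases (`truncated_500`); the
#' share's denominator is always the full-length mass, since sequencing
#' depth is spent on whole transcripts regardless of how reads are counted
#' afterwards. Counts are negative-binomial with dispersion `phi`
#' (Poisson when `phi = 0`). This closed-form windowed expectation agrees
#' with counting simulated read positions in the same window.
#'
#' @param models,truth output of [simulate_gene_models()].
#' @param config a [simulation_config()].
#' @param mode counting window: `"full_length"` or `"truncated_500"`.
#' @param window_bp window size for `truncated_500` (default 500).
#' @return A [count_matrix] with per-gene dominant-transcript lengths
#'   attached.
#' @export
simulate_counts <- function(models, truth, config,
                            mode = c("full_length", "truncated_500"),
                            window_bp = 500) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  mode <- match.arg(mode)
  withr::local_seed(config$seed + 2L + (mode == "truncated_500"))
  L <- truth$dominant_length
  win <- if (mode == "full_length") Inf else window_bp
  ns <- nrow(config$design)
  y <- matrix(0L, length(L), ns,
              dimnames = list(names(L), config$design$sample_id))
  for (s in seq_len(ns)) {
    sid <- config$design$sample_id[s]
    lam <- truth$decay_scale[sid]
    N <- round(config$reads_per_sample * runif(1, 0.8, 1.2))
    mass_full <- .window_mass(L, lam)
    mass_win <- .window_mass(L, lam, win)
    mu_full <- truth$mu[, sid] * mass_full
    mu_win <- truth$mu[, sid] * mass_win
    m <- N * mu_win / sum(mu_full)
    y[, s] <- if (config$dispersion == 0) {
      rpois(length(m), m)
    } else {
      rnbinom(length(m), size = 1 / config$dispersion, mu = m)
    }
  }
  count_matrix(y, genes = data.frame(gene_id = names(L), length = unname(L),
                                     stringsAsFactors = FALSE))
}

#' Write simulation outputs as plain text
#'
#' Convenience writer used by the pipeline: truth tables, design and read
#' positions as TSV with documented headers.
#'
#' @param truth a `ground_truth` object.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_truth_tables <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- data.frame(
    gene_id = names(truth$baseline),
    baseline_mean = unname(truth$baseline),
    is_de = unname(truth$is_de),
    true_log2fc = unname(truth$true_log2fc),
    dominant_transcript = unname(truth$dominant),
    dominant_length_bp = unname(truth$dominant_length),
    stringsAsFactors = FALSE
  )
  p1 <- file.path(dir, "truth_genes.tsv")
  write.table(genes, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "sample_design.tsv")
  write.table(truth$design, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genes = p1, design = p2))
}
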