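#' Count matrices
#'
#' Container for a genes x samples table of non-negative integer read
#' counts with per-sample library sizes and optional per-gene covariates
#' (dominant-transcript length, average CPM) used by binned normalization.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @param genes optional data.frame of per-gene covariates with a
#'   `gene_id` column matching the rownames.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lib_sizes = colSums(counts), genes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene-id rownames")
  if (is.null(colnames(counts))) stop("counts must have sample-id colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(lib_sizes) != ncol(counts)) {
    stop("lib_sizes length must match the number of samples")
  }
  lib_sizes <- setNames(as.numeric(lib_sizes), colnames(counts))
  if (!is.null(genes)) {
    if (!"gene_id" %in% names(genes)) stop("genes needs a gene_id column")
    genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(counts = counts, lib_sizes = lib_sizes, genes = genes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; median library size",
      format(median(x$lib_sizes), big.mark = ","), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Counts per million
#'
#' `cpm_gs = counts_gs / lib_size_s * 1e6`. Library sizes default to the
#' ones stored in the `count_matrix` (column sums unless frozen earlier).
#'
#' @param counts a [count_matrix] or a plain numeric matrix.
#' @param lib_sizes per-sample library sizes; required for plain matrices.
#' @return Numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(lib_sizes)) lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  if (is.null(lib_sizes)) stop("lib_sizes required for a plain matrix")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' 3'-coverage profile
#'
#' Histograms each sample's read 3'-distances into fixed-width bins and
#' normalizes to fractions, the minimal statistic behind gene-body
#' coverage diagnostics: degraded samples show an exponential-looking
#' decay of the fraction with distance from the 3' end.
#'
#' @param reads a read-position table (columns `sample_id`,
#'   `three_prime_distance`), e.g. from [simulate_read_positions()].
#' @param max_bp right edge of the last bin; reads at or beyond it are
#'   dropped before normalization (fractions sum to 1 over the kept bins).
#' @param bin_bp bin width in bp (default 50).
#' @return List of class `coverage_profile`: `breaks` (bin edges) and
#'   `fractions` (bins x samples matrix).
#' @export
coverage_profile <- function(reads, max_bp = 2000, bin_bp = 50) {
  if (is.null(reads) || nrow(reads) == 0L) {
    stop("empty read table: no coverage profile to compute")
  }
  breaks <- seq(0, max_bp, by = bin_bp)
  samples <- unique(reads$sample_id)
  frac <- matrix(0, length(breaks) - 1L, length(samples),
                 dimnames = list(NULL, samples))
  for (s in samples) {
    d <- reads$three_prime_distance[reads$sample_id == s]
    d <- d[d < max_bp]
    if (length(d) == 0L) next
    h <- hist(d, breaks = breaks, plot = FALSE, right = FALSE)
    frac[, s] <- h$counts / length(d)
  }
  structure(list(breaks = breaks, fractions = frac),
            class = "coverage_profile")
}

#' Count reads against gene models, optionally in a 3' window
#'
#' Tallies reads per gene and sample. With `window_bp` set, a read is
#' counted iff its 3'-distance is strictly less than `window_bp`
#' (half-open window, so a read at exactly the window edge is excluded);
#' with `window_bp = NULL` every read is counted. Genes present in the
#' models but without reads get zero rows; reads referring to unknown
#' genes are an error.
#'
#' @param reads a read-position table (`sample_id`, `gene_id`,
#'   `three_prime_distance`).
#' @param models a [gene_models] object defining the gene universe (and,
#'   when dominant transcripts are flagged, per-gene lengths).
#' @param window_bp window size in bp, or `NULL` for full-length counting.
#' @return A [count_matrix]; library sizes are the column sums.
#' @export
count_reads_in_window <- function(reads, models, window_bp = NULL) {
  stopifnot(inherits(models, "gene_models"))
  genes <- unique(models$transcripts$gene_id)
  unknown <- setdiff(unique(reads$gene_id), genes)
  if (length(unknown) > 0L) {
    stop("reads refer to genes absent from the models: ",
         paste(head(unknown, 10L), collapse = ", "))
  }
  samples <- unique(reads$sample_id)
  if (!is.null(window_bp)) {
    reads <- reads[reads$three_prime_distance < window_bp, , drop = FALSE]
  }
  tab <- table(factor(reads$gene_id, levels = genes),
               factor(reads$sample_id, levels = samples))
  y <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  gmeta <- NULL
  if (any(models$transcripts$dominant)) {
    len <- spliced_lengths(models)
    gmeta <- data.frame(gene_id = genes, length = unname(len[genes]),
                        stringsAsFactors = FALSE)
  }
  count_matrix(y, genes = gmeta)
}

#' Write/read TSV helpers for counts and profiles
#'
#' @param counts a [count_matrix].
#' @param path output path.
#' @return `path` invisibly (`write_counts`), or a [count_matrix]
#'   (`read_counts`).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param genes optional per-gene covariate data.frame passed through to
#'   [count_matrix()].
#' @export
read_counts <- function(path, genes = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  y <- as.matrix(df[, -1L, drop = FALSE])
  rownames(y) <- df[[1L]]
  storage.mode(y) <- "integer"
  count_matrix(y, genes = genes)
}
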