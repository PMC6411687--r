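#' Read and write gene-set collections (GMT)
#'
#' `read_gmt()` parses a GMT file into a named list of gene-id vectors;
#' `write_gmt()` writes one (tab-separated: set name, description, gene
#' ids).
#'
#' @param path GMT file path.
#' @return Named list of character vectors (`read_gmt`); `path` invisibly
#'   (`write_gmt`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of character gene-id vectors.
#' @param description description field written for every set (default
#'   "na").
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets))) stop("gene sets must be named")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Random gene sets for demonstrations
#'
#' Draws `n_sets` gene sets of random sizes from a gene universe; used by
#' the pipeline when no GMT file is supplied.
#'
#' @param genes character vector of gene ids (the universe).
#' @param n_sets number of sets.
#' @param size_range set-size range.
#' @return Named list of gene-id vectors.
#' @export
random_gene_sets <- function(genes, n_sets = 50, size_range = c(10, 200)) {
  sizes <- sample(seq(size_range[1], min(size_range[2], length(genes))),
                  n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  sets
}

#' Fisher over-representation test
#'
#' One-sided over-representation of a gene set within a hit list drawn
#' from a background universe: the p-value is the hypergeometric upper
#' tail `P(X >= k)` with universe size N, in-universe set size K, list
#' size n and overlap k.
#'
#' @param hits character vector of selected genes; must be a subset of
#'   `universe`.
#' @param set character vector, the gene set (intersected with the
#'   universe before testing).
#' @param universe background gene list (e.g. all genes passing the
#'   expression pre-filter).
#' @return List: `p.value`, `table` (the 2x2 contingency table), and the
#'   margins `k`, `K`, `n`, `N`.
#' @export
fisher_enrichment <- function(hits, set, universe) {
  hits <- unique(hits)
  universe <- unique(universe)
  out_univ <- setdiff(hits, universe)
  if (length(out_univ) > 0L) {
    stop("hits outside the universe: ",
         paste(head(out_univ, 5L), collapse = ", "))
  }
  set_u <- intersect(unique(set), universe)
  k <- length(intersect(hits, set_u))
  K <- length(set_u)
  n <- length(hits)
  N <- length(universe)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2L, 2L,
                dimnames = list(c("in_set", "not_in_set"),
                                c("in_list", "not_in_list")))
  list(p.value = p, table = tab, k = k, K = K, n = n, N = N)
}

#' Top-list Fisher enrichment
#'
#' For each direction (up / down) takes the genes with `p < max_p` and the
#' matching fold-change sign, ordered by ascending p-value (ties broken by
#' larger `|logFC|`, then gene id), forms the top-N lists for each size in
#' `top_sizes` (shorter when fewer genes are available), and Fisher-tests
#' every gene set against each list over the pre-filtered universe.
#'
#' @param res a `de_result` (see [run_contrast()]).
#' @param sets named list of gene sets.
#' @param universe background genes; defaults to all genes in `res` (the
#'   pre-filtered expression universe).
#' @param top_sizes top-list sizes (default 50, 100, 200, 500, 1000).
#' @param max_p significance cutoff for list membership (default 0.05).
#' @return data.frame of class `enrichment_table`: one row per
#'   (set, direction, top_n) with the 2x2 margins and Fisher p-value.
#'   Empty (with a message) when no gene passes `max_p`.
#' @export
toplist_enrichment <- function(res, sets, universe = NULL,
                               top_sizes = c(50, 100, 200, 500, 1000),
                               max_p = 0.05) {
  if (is.null(universe)) universe <- res$gene_id
  if (length(universe) == 0L) stop("empty background universe")
  if (is.null(names(sets))) stop("gene sets must be named")
  rows <- list()
  for (dir in c("up", "down")) {
    sgn <- if (dir == "up") res$logFC > 0 else res$logFC < 0
    cand <- res[res$PValue < max_p & sgn, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ord <- order(cand$PValue, -abs(cand$logFC), cand$gene_id)
    ranked <- cand$gene_id[ord]
    for (n_top in top_sizes) {
      hits <- head(ranked, n_top)
      for (nm in names(sets)) {
        fe <- fisher_enrichment(hits, sets[[nm]], universe)
        rows[[length(rows) + 1L]] <- data.frame(
          set = nm, direction = dir, top_n = n_top,
          list_size = fe$n, overlap = fe$k, set_size = fe$K,
          universe_size = fe$N, p.value = fe$p.value,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    message("no genes passed p < ", max_p, "; enrichment table is empty")
    out <- data.frame(set = character(), direction = character(),
                      top_n = integer(), list_size = integer(),
                      overlap = integer(), set_size = integer(),
                      universe_size = integer(), p.value = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Merge top-list enrichment results
#'
#' Collapses the per-top-size Fisher p-values of each (set, direction)
#' pair to their minimum — the merged statistic reported by the top-list
#' procedure. The minimum is *not* corrected for testing five list sizes;
#' a Bonferroni-across-lists companion column is reported alongside as a
#' conservative reference.
#'
#' @param table an `enrichment_table` from [toplist_enrichment()].
#' @return data.frame: `set`, `direction`, `min_p` (merged minimum),
#'   `n_lists`, `bonferroni_p` (`min(1, min_p * n_lists)`),
#'   `best_top_n` (list size achieving the minimum).
#' @export
merge_toplists <- function(table) {
  if (nrow(table) == 0L) {
    return(data.frame(set = character(), direction = character(),
                      min_p = numeric(), n_lists = integer(),
                      bonferroni_p = numeric(), best_top_n = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(table$set, table$direction, drop = TRUE)
  parts <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    sub <- table[idx, , drop = FALSE]
    i <- which.min(sub$p.value)
    data.frame(set = sub$set[1L], direction = sub$direction[1L],
               min_p = sub$p.value[i], n_lists = nrow(sub),
               bonferroni_p = min(1, sub$p.value[i] * nrow(sub)),
               best_top_n = sub$top_n[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$direction, out$min_p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
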