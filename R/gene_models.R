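#' Gene model collections
#'
#' A `gene_models` object holds a set of genes, each with one or more
#' transcripts described by strand-aware exon lists, plus a per-transcript
#' expression abundance used to pick the dominant isoform. Coordinates are
#' stored 0-based half-open internally; GTF input/output converts to the
#' on-disk 1-based inclusive convention at the boundary.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` ("+" or "-").
#' @param abundance named numeric vector of per-transcript abundances
#'   (names are transcript ids), or `NULL` if exons carry an `abundance`
#'   column or abundances are unknown.
#' @return An object of class `gene_models`: a list with elements `exons`
#'   (the validated, sorted exon table) and `transcripts` (one row per
#'   transcript: `transcript_id`, `gene_id`, `chrom`, `strand`, `abundance`,
#'   `spliced_length`, `dominant`).
#' @export
gene_models <- function(exons, abundance = NULL) {
  req <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(exons))
  if (length(miss) > 0L) {
    stop("exon table is missing columns: ", paste(miss, collapse = ", "))
  }
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  if (any(exons$start >= exons$end)) {
    bad <- which(exons$start >= exons$end)
    stop("exon start must be < end (0-based half-open); offending rows: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (is.null(abundance) && "abundance" %in% names(exons)) {
    ab <- tapply(as.numeric(exons$abundance), exons$transcript_id, `[`, 1L)
    abundance <- setNames(as.numeric(ab), names(ab))
  }
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), req,
                 drop = FALSE]
  rownames(exons) <- NULL
  .check_exon_overlap(exons)

  first <- !duplicated(exons$transcript_id)
  tx <- data.frame(
    transcript_id = exons$transcript_id[first],
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    stringsAsFactors = FALSE
  )
  len <- tapply(exons$end - exons$start, exons$transcript_id, sum)
  tx$spliced_length <- as.numeric(len[tx$transcript_id])
  tx$abundance <- if (is.null(abundance)) NA_real_ else {
    as.numeric(abundance[tx$transcript_id])
  }
  tx$dominant <- FALSE
  rownames(tx) <- NULL
  structure(list(exons = exons, transcripts = tx), class = "gene_models")
}

.check_exon_overlap <- function(exons) {
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      s <- exons$start[idx]
      e <- exons$end[idx]
      if (any(s[-1L] < e[-length(e)])) {
        stop("overlapping exons within transcript ",
             exons$transcript_id[idx[1L]])
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(unique(x$transcripts$gene_id)), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons\n")
  if (any(x$transcripts$dominant)) {
    cat("  dominant transcripts selected\n")
  }
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses exon features from a GTF file (1-based inclusive coordinates on
#' disk) into the internal 0-based half-open representation. The attributes
#' `gene_id` and `transcript_id` are mandatory; a numeric `abundance`
#' attribute, when present, populates the per-transcript abundance used for
#' dominant-isoform selection.
#'
#' @param path path to a GTF file.
#' @return A [gene_models] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF: ", path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id) || is.null(mc$transcript_id)) {
    stop("GTF exons must carry gene_id and transcript_id attributes")
  }
  exons <- data.frame(
    gene_id = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ab <- NULL
  if (!is.null(mc$abundance)) {
    exons$abundance <- as.numeric(as.character(mc$abundance))
  }
  gene_models(exons, abundance = ab)
}

#' Write gene models to a GTF file
#'
#' Emits one exon feature per exon with `gene_id`, `transcript_id` and
#' (when known) `abundance` attributes, converting internal 0-based
#' half-open coordinates back to the GTF 1-based inclusive convention.
#' Comment headers that vary between runs (date stamps) are stripped so
#' that identical models always produce byte-identical files.
#'
#' @param models a [gene_models] object.
#' @param path output path.
#' @param truncated if `TRUE`, write only the dominant transcript of each
#'   gene (the single-isoform truncated gene model); requires dominant
#'   transcripts to be flagged.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, truncated = FALSE) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  tx <- models$transcripts
  if (truncated) {
    if (!any(tx$dominant)) {
      stop("truncated output requires dominant transcripts; ",
           "run select_dominant_transcripts() first")
    }
    keep <- tx$transcript_id[tx$dominant]
    ex <- ex[ex$transcript_id %in% keep, , drop = FALSE]
  }
  ab <- setNames(tx$abundance, tx$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1, end = ex$end),
    strand = ex$strand,
    type = "exon",
    source = "degbias",
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id
  )
  if (!all(is.na(ab))) {
    S4Vectors::mcols(gr)$abundance <- as.numeric(ab[ex$transcript_id])
  }
  rtracklayer::export(gr, path, format = "gtf")
  lines <- readLines(path)
  lines <- lines[!grepl("^##(date|source-version)", lines)]
  writeLines(lines, path)
  invisible(path)
}

#' Select the dominant transcript of each gene
#'
#' Flags, for every gene, the single most abundantly expressed transcript;
#' all other isoforms are treated as discarded in downstream truncated gene
#' models. Ties in abundance are broken by longer spliced length, then by
#' lexicographically smallest transcript id, so the choice is deterministic.
#'
#' @param models a [gene_models] object with abundances set.
#' @return The models with `transcripts$dominant` flagged (exactly one
#'   `TRUE` per gene).
#' @export
select_dominant_transcripts <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  tx <- models$transcripts
  if (nrow(tx) == 0L) stop("no transcripts to select from")
  if (anyNA(tx$abundance)) {
    stop("every transcript needs an abundance for dominant selection")
  }
  tx$dominant <- FALSE
  for (g in unique(tx$gene_id)) {
    idx <- which(tx$gene_id == g)
    o <- order(-tx$abundance[idx], -tx$spliced_length[idx],
               tx$transcript_id[idx])
    tx$dominant[idx[o[1L]]] <- TRUE
  }
  models$transcripts <- tx
  models
}

#' Dominant transcript ids
#'
#' @param models a [gene_models] object after [select_dominant_transcripts()].
#' @return Named character vector: dominant transcript id per gene id.
#' @export
dominant_transcripts <- function(models) {
  tx <- models$transcripts
  if (!any(tx$dominant)) stop("dominant transcripts not selected")
  d <- tx[tx$dominant, , drop = FALSE]
  setNames(d$transcript_id, d$gene_id)
}

# Truncate one transcript's exon rows (sorted by genomic start, 0-based
# half-open) to the window_bp spliced bases nearest the 3' end. For "+"
# the 3' end is the highest coordinate, for "-" the lowest.
.truncate_exon_rows <- function(ex, window_bp) {
  n <- nrow(ex)
  lens <- ex$end - ex$start
  if (sum(lens) <= window_bp) return(ex)
  remaining <- window_bp
  keep <- vector("list", n)
  order_3p <- if (ex$strand[1L] == "+") rev(seq_len(n)) else seq_len(n)
  for (i in order_3p) {
    if (remaining <= 0) break
    if (lens[i] <= remaining) {
      keep[[i]] <- ex[i, , drop = FALSE]
      remaining <- remaining - lens[i]
    } else {
      frag <- ex[i, , drop = FALSE]
      if (ex$strand[1L] == "+") {
        frag$start <- frag$end - remaining
      } else {
        frag$end <- frag$start + remaining
      }
      keep[[i]] <- frag
      remaining <- 0
    }
  }
  out <- do.call(rbind, keep[!vapply(keep, is.null, logical(1L))])
  out[order(out$start), , drop = FALSE]
}

#' Truncate gene models to a 3'-end window
#'
#' Builds the 3'-truncated gene model: each gene is reduced to its dominant
#' transcript, and that transcript's exons are cut down to the `window_bp`
#' spliced bases closest to the 3' end (strand-aware; for "+" transcripts
#' the 3' end is at the highest genomic coordinate, for "-" at the lowest).
#' Transcripts shorter than the window are kept unchanged, so the truncated
#' spliced length is `min(L, window_bp)`. The operation is idempotent.
#'
#' @param models a [gene_models] object; dominant transcripts are selected
#'   on the fly if abundances are available and none are flagged.
#' @param window_bp window size in spliced bases from the 3' end (default
#'   500).
#' @param dominant_only keep only the dominant transcript per gene
#'   (default `TRUE`, the single-isoform counting model).
#' @return A new [gene_models] object with truncated exons.
#' @export
truncate_models <- function(models, window_bp = 500, dominant_only = TRUE) {
  stopifnot(inherits(models, "gene_models"))
  if (window_bp <= 0) stop("window_bp must be > 0")
  tx <- models$transcripts
  if (dominant_only) {
    if (!any(tx$dominant)) models <- select_dominant_transcripts(models)
    tx <- models$transcripts
    keep_tx <- tx$transcript_id[tx$dominant]
  } else {
    keep_tx <- tx$transcript_id
  }
  ex <- models$exons[models$exons$transcript_id %in% keep_tx, , drop = FALSE]
  parts <- lapply(split(ex, ex$transcript_id),
                  .truncate_exon_rows, window_bp = window_bp)
  out_ex <- do.call(rbind, parts)
  rownames(out_ex) <- NULL
  ab <- setNames(tx$abundance, tx$transcript_id)[unique(out_ex$transcript_id)]
  out <- gene_models(out_ex, abundance = ab)
  out$transcripts$dominant <- out$transcripts$transcript_id %in%
    tx$transcript_id[tx$dominant]
  out
}

#' Truncate a single transcript's exons
#'
#' Low-level worker behind [truncate_models()], exposed for fixtures and
#' spot checks: truncates one transcript, given as an exon data.frame in
#' internal coordinates, to the 3'-most `window_bp` spliced bases.
#'
#' @param exons data.frame with `start`, `end` (0-based half-open) and
#'   `strand` columns, one transcript, sorted or not.
#' @param window_bp window size in spliced bases.
#' @return The truncated exon data.frame, sorted by genomic start.
#' @export
truncate_transcript <- function(exons, window_bp = 500) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (length(unique(exons$strand)) != 1L) {
    stop("exons must come from a single transcript (one strand)")
  }
  ex <- exons[order(exons$start), , drop = FALSE]
  out <- .truncate_exon_rows(ex, window_bp)
  rownames(out) <- NULL
  out
}

#' Spliced lengths of (dominant) transcripts
#'
#' @param models a [gene_models] object.
#' @param dominant_only if `TRUE` (default), one length per gene from its
#'   dominant transcript; otherwise one per transcript.
#' @return Named numeric vector of spliced lengths in bp.
#' @export
spliced_lengths <- function(models, dominant_only = TRUE) {
  tx <- models$transcripts
  if (dominant_only) {
    if (!any(tx$dominant)) stop("dominant transcripts not selected")
    tx <- tx[tx$dominant, , drop = FALSE]
    setNames(tx$spliced_length, tx$gene_id)
  } else {
    setNames(tx$spliced_length, tx$transcript_id)
  }
}
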