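#' Concatenate curated loci into a partitioned supermatrix
#'
#' Loci are ordered lexicographically by locus name; a taxon absent from a
#' locus is filled with `'?'` across that partition. Each input alignment
#' must have at most one sequence per taxon.
#'
#' @param alns list of [protein_alignment()], each with one row per taxon.
#' @param taxa ordered taxon names defining the rows; defaults to the
#'   sorted union over loci.
#' @return an object of class `supermatrix`: list with `taxa`, `mat`
#'   (character matrix taxa x columns) and `partitions` (data.frame
#'   `locus`, `start`, `end`, 1-based inclusive).
#' @export
concatenate <- function(alns, taxa = NULL) {
  if (!length(alns)) stop("no alignments to concatenate")
  for (a in alns)
    if (anyDuplicated(a$taxon))
      stop("duplicate taxon '", a$taxon[duplicated(a$taxon)][1L],
           "' in locus '", a$locus, "'")
  alns <- alns[order(vapply(alns, function(a) a$locus, character(1)))]
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(alns, function(a) a$taxon))))
  widths <- vapply(alns, function(a) ncol(a$mat), integer(1))
  total <- sum(widths)
  mat <- matrix("?", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  at <- 1L
  parts <- data.frame(locus = vapply(alns, function(a) a$locus, character(1)),
                      start = integer(length(alns)),
                      end = integer(length(alns)))
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    cols <- at:(at + widths[i] - 1L)
    rows <- match(a$taxon, taxa)
    if (anyNA(rows))
      stop("taxon '", a$taxon[is.na(rows)][1L], "' in locus '", a$locus,
           "' not in the supplied taxon set")
    mat[rows, cols] <- a$mat
    parts$start[i] <- at
    parts$end[i] <- at + widths[i] - 1L
    at <- at + widths[i]
  }
  structure(list(taxa = taxa, mat = mat, partitions = parts),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d columns, %d partitions\n",
              length(x$taxa), ncol(x$mat), nrow(x$partitions)))
  invisible(x)
}

#' Split a supermatrix back into per-locus alignments
#' @param m a [concatenate()] result.
#' @return list of [protein_alignment()] in partition order; rows with only
#'   `'?'` in a partition (taxa absent from that locus) are dropped.
#' @export
split_partitions <- function(m) {
  lapply(seq_len(nrow(m$partitions)), function(i) {
    cols <- m$partitions$start[i]:m$partitions$end[i]
    sub <- m$mat[, cols, drop = FALSE]
    present <- rowSums(sub != "?") > 0L
    protein_alignment(sub[present, , drop = FALSE], m$partitions$locus[i],
                      taxon = m$taxa[present])
  })
}

#' Supermatrix composition statistics
#'
#' Counts gaps (`'-'`) and missing cells (`'?'` or `'X'`) with percentages
#' over all `taxa x columns` cells, and per-taxon locus inclusion (loci
#' where the taxon has at least one non-missing cell). Asserts the
#' conservation identity residues + gaps + missing = taxa x columns.
#'
#' @param m a [concatenate()] result.
#' @return object of class `matrix_stats`; see [stats_from_counts()] for
#'   the fields.
#' @export
matrix_stats <- function(m) {
  n_taxa <- length(m$taxa)
  n_col <- ncol(m$mat)
  n_gap <- sum(m$mat == "-")
  n_missing <- sum(m$mat == "?" | m$mat == "X")
  n_res <- sum(!m$mat %in% c("-", "?", "X"))
  stopifnot(n_res + n_gap + n_missing == n_taxa * n_col)
  incl_count <- stats::setNames(integer(n_taxa), m$taxa)
  for (i in seq_len(nrow(m$partitions))) {
    cols <- m$partitions$start[i]:m$partitions$end[i]
    sub <- m$mat[, cols, drop = FALSE]
    incl_count <- incl_count + (rowSums(!(sub == "?" | sub == "X")) > 0L)
  }
  out <- stats_from_counts(n_loci = nrow(m$partitions), n_columns = n_col,
                           n_taxa = n_taxa, n_gap = n_gap,
                           n_missing = n_missing)
  out$per_taxon_inclusion <- data.frame(
    taxon = m$taxa, count = as.integer(incl_count),
    percent = round(100 * incl_count / nrow(m$partitions), 2))
  out$mean_inclusion_pct <- round(mean(out$per_taxon_inclusion$percent), 2)
  out
}

#' Composition statistics from printed counts
#'
#' Builds a `matrix_stats` object directly from cell counts, so published
#' matrix dimensions can be turned into the derived percentages. The
#' percentage denominator is `n_taxa * n_columns`; values are rounded to
#' two decimals for reporting.
#'
#' @param n_loci,n_columns,n_taxa matrix dimensions.
#' @param n_gap,n_missing gap and missing cell counts.
#' @return object of class `matrix_stats` with fields `n_loci`,
#'   `n_columns`, `n_gap`, `n_missing`, `pct_gap`, `pct_missing`.
#' @export
stats_from_counts <- function(n_loci, n_columns, n_taxa, n_gap, n_missing) {
  cells <- as.numeric(n_taxa) * n_columns
  stopifnot(cells > 0, n_gap + n_missing <= cells)
  structure(list(n_loci = n_loci, n_columns = n_columns, n_taxa = n_taxa,
                 n_gap = n_gap, n_missing = n_missing,
                 pct_gap = round(100 * n_gap / cells, 2),
                 pct_missing = round(100 * n_missing / cells, 2),
                 per_taxon_inclusion = NULL, mean_inclusion_pct = NULL),
            class = "matrix_stats")
}

#' @export
print.matrix_stats <- function(x, ...) {
  cat(sprintf("matrix_stats: %d loci, %d columns, %d taxa\n",
              x$n_loci, x$n_columns, x$n_taxa))
  cat(sprintf("  gaps    %d (%.2f%%)\n", x$n_gap, x$pct_gap))
  cat(sprintf("  missing %d (%.2f%%)\n", x$n_missing, x$pct_missing))
  invisible(x)
}

#' Dataset-optimization reduction report
#'
#' Compares pre- and post-optimization matrix statistics: the retained
#' fraction of aligned columns (percent) and the percentage-point drops in
#' gap and missing-data content.
#'
#' @param pre,post `matrix_stats` computed over the same taxon set.
#' @return list with `pct_size_retained`, `gap_reduction_points`,
#'   `missing_reduction_points`.
#' @export
inclusion_report <- function(pre, post) {
  if (pre$n_columns == 0) stop("pre-optimization matrix has no columns")
  stopifnot(pre$n_taxa == post$n_taxa)
  list(pct_size_retained = round(100 * post$n_columns / pre$n_columns, 2),
       gap_reduction_points = round(pre$pct_gap - post$pct_gap, 2),
       missing_reduction_points = round(pre$pct_missing - post$pct_missing, 2))
}

#' Per-taxon locus-inclusion percentages
#'
#' Turns per-taxon locus counts into inclusion percentages with a common
#' locus-number denominator, plus their mean.
#'
#' @param counts named integer vector (or data.frame with `taxon`/`count`).
#' @param n_loci total number of loci.
#' @return data.frame `taxon`, `count`, `percent`, with attribute
#'   `"mean_pct"`.
#' @export
taxon_inclusion_summary <- function(counts, n_loci) {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$count %||% counts[[2]], counts$taxon %||% counts[[1]])
  stopifnot(n_loci > 0, all(counts <= n_loci))
  out <- data.frame(taxon = names(counts), count = as.integer(counts),
                    percent = round(100 * counts / n_loci, 2))
  rownames(out) <- NULL
  attr(out, "mean_pct") <- round(mean(out$percent), 2)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transcriptome completeness summary against the core eukaryotic genes
#'
#' Converts per-taxon complete/partial CEG hit counts into percentages of
#' the CEG set size and appends column means, mirroring standard CEGMA
#' reporting.
#'
#' @param counts data.frame with columns `taxon`, `complete`, `partial`.
#' @param ceg_total size of the CEG reference set (default 248).
#' @return object of class `coverage_summary`: data.frame with percentage
#'   columns and a `Mean` row; all reported to two decimals.
#' @export
coverage_summary <- function(counts, ceg_total = 248L) {
  stopifnot(all(counts$complete <= ceg_total),
            all(counts$partial <= ceg_total))
  pct <- function(x) round(100 * x / ceg_total, 2)
  out <- data.frame(taxon = counts$taxon,
                    complete = counts$complete,
                    complete_pct = pct(counts$complete),
                    partial = counts$partial,
                    partial_pct = pct(counts$partial))
  means <- data.frame(taxon = "Mean",
                      complete = round(mean(counts$complete), 2),
                      complete_pct = round(mean(pct(counts$complete)), 2),
                      partial = round(mean(counts$partial), 2),
                      partial_pct = round(mean(pct(counts$partial)), 2))
  structure(rbind(out, means), class = c("coverage_summary", "data.frame"))
}

#' Sequencing and assembly summary statistics
#'
#' Per-taxon read retention through quality control plus means of retention
#' percent, assembled contig count and recovered ortholog count -- the
#' headline numbers of a transcriptome sequencing campaign.
#'
#' @param sequencing data.frame with columns `taxon`, `raw_reads`,
#'   `processed_reads`, `contigs`, `orthologs`.
#' @return list with `per_taxon` (data.frame incl. `retention_pct`),
#'   `mean_retention_pct`, `mean_contigs`, `mean_orthologs`.
#' @export
sequencing_summary <- function(sequencing) {
  ret <- 100 * sequencing$processed_reads / sequencing$raw_reads
  per_taxon <- data.frame(sequencing, retention_pct = round(ret, 2))
  list(per_taxon = per_taxon,
       mean_retention_pct = round(mean(ret), 2),
       mean_contigs = round(mean(sequencing$contigs), 2),
       mean_orthologs = round(mean(sequencing$orthologs), 2))
}

#' Write a supermatrix to disk
#'
#' Writes the matrix as FASTA or relaxed (interleaved-free) PHYLIP plus a
#' RAxML-style partition file (`WAG, locus = start-end` lines).
#'
#' @param m a [concatenate()] result.
#' @param path output alignment file.
#' @param format `"fasta"` or `"phylip"`.
#' @param partition_path optional partition file path.
#' @export
write_supermatrix <- function(m, path, format = c("fasta", "phylip"),
                              partition_path = NULL) {
  format <- match.arg(format)
  seqs <- apply(m$mat, 1L, paste, collapse = "")
  if (format == "fasta") {
    writeLines(paste0(">", m$taxa, "\n", seqs), path)
  } else {
    writeLines(c(paste(length(m$taxa), ncol(m$mat)),
                 paste(formatC(m$taxa, width = max(nchar(m$taxa)) + 2,
                               flag = "-"), seqs)), path)
  }
  if (!is.null(partition_path))
    writeLines(sprintf("WAG, %s = %d-%d", m$partitions$locus,
                       m$partitions$start, m$partitions$end),
               partition_path)
  invisible(path)
}
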