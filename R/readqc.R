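#' Read quality-control configuration
#'
#' Defaults follow classic FASTX-style processing of 50 bp paired-end
#' Illumina RNA-seq: truncate at the first base with Phred quality <= 20,
#' discard reads shorter than 30 bases, then strip the first 9 bases to
#' remove primer artifacts, and finally keep only pairs where both mates
#' survive.
#'
#' @param q_threshold Phred score at or below which a position triggers
#'   truncation (default 20).
#' @param min_len minimum read length in bases after truncation (default 30).
#' @param head_trim bases removed from the 5' end after the length filter
#'   (default 9).
#' @param phred_offset ASCII offset of the quality encoding (default 33,
#'   Sanger/Illumina 1.8+).
#' @export
qc_config <- function(q_threshold = 20L, min_len = 30L, head_trim = 9L,
                      phred_offset = 33L) {
  stopifnot(q_threshold >= 0, min_len >= 0, head_trim >= 0)
  structure(list(q_threshold = as.integer(q_threshold),
                 min_len = as.integer(min_len),
                 head_trim = as.integer(head_trim),
                 phred_offset = as.integer(phred_offset)),
            class = "qc_config")
}

#' Read a FASTQ file into a record table
#'
#' Parsing goes through [Biostrings::readDNAStringSet()]; qualities are
#' decoded to integer Phred scores.
#'
#' @param path FASTQ file (optionally gzipped).
#' @param phred_offset quality encoding offset (default 33).
#' @return data.frame with columns `id` (first whitespace token of the
#'   header), `seq` (character) and `qual` (list column of integer vectors).
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  qual <- lapply(as.character(S4Vectors::mcols(ss)$qualities),
                 function(q) as.integer(utf8ToInt(q)) - phred_offset)
  out <- data.frame(id = sub("\\s.*$", "", names(ss)),
                    seq = as.character(ss))
  out$qual <- qual
  rownames(out) <- NULL
  out
}

#' Write a FASTQ record table
#' @param reads record table as returned by [read_fastq()].
#' @param path output file.
#' @param phred_offset quality encoding offset (default 33).
#' @export
write_fastq <- function(reads, path, phred_offset = 33L) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  q <- vapply(reads$qual,
              function(x) intToUtf8(x + phred_offset), character(1))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(q))
  invisible(path)
}

# index of the first position with quality <= threshold, or 0 if none
first_low_quality <- function(qual, threshold) {
  hit <- which(qual <= threshold)
  if (length(hit)) hit[1L] else 0L
}

#' Quality-truncate a single read
#'
#' Removes all positions occurring after the first base whose Phred score
#' is at or below `cfg$q_threshold`; the triggering base itself is kept
#' (reading "all sites occurring after" literally). A read with no low-
#' quality position is returned unchanged; an empty read stays empty.
#'
#' @param read one-row record (list with `seq` and `qual`).
#' @param cfg a [qc_config()].
#' @return the truncated record.
#' @export
quality_truncate <- function(read, cfg = qc_config()) {
  q <- read$qual[[1]]
  cut <- first_low_quality(q, cfg$q_threshold)
  if (cut > 0L && cut < length(q)) {
    read$seq <- substr(read$seq, 1L, cut)
    read$qual <- list(q[seq_len(cut)])
  }
  read
}

# vectorized single-file pass: truncate -> length filter -> head trim
qc_single <- function(reads, cfg) {
  cuts <- vapply(reads$qual, first_low_quality, integer(1),
                 threshold = cfg$q_threshold)
  len <- nchar(reads$seq)
  newlen <- ifelse(cuts > 0L, cuts, len)
  keep <- newlen >= cfg$min_len
  out <- reads[keep, , drop = FALSE]
  newlen <- newlen[keep]
  from <- pmin(cfg$head_trim + 1L, newlen + 1L)
  out$seq <- substr(out$seq, from, newlen)
  out$qual <- Map(function(q, a, b) if (a > b) integer(0) else q[a:b],
                  out$qual, from, newlen)
  rownames(out) <- NULL
  out
}

# mate suffixes like "/1", "/2", or trailing ".1" are ignored when pairing
strip_mate_suffix <- function(id) sub("[/.][12]$", "", id)

#' Process a pair of FASTQ streams
#'
#' Applies, per read and in order: quality truncation
#' ([quality_truncate()]), deletion of reads shorter than `cfg$min_len`,
#' removal of the first `cfg$head_trim` bases, and finally pair
#' resynchronization -- only pairs where both mates survive are kept, in
#' their original order.
#'
#' @param r1,r2 record tables ([read_fastq()]) for the two mate files,
#'   ordered with matching read ids (mate suffix ignored).
#' @param cfg a [qc_config()].
#' @return list with `r1`, `r2` (processed, synchronized record tables) and
#'   `report`: a data.frame with one row per file giving `raw` and
#'   `processed` read counts and the `retention` fraction (NA on empty
#'   input).
#' @export
process_pairs <- function(r1, r2, cfg = qc_config()) {
  raw <- c(nrow(r1), nrow(r2))
  bad <- which(strip_mate_suffix(r1$id)[seq_len(min(raw))] !=
               strip_mate_suffix(r2$id)[seq_len(min(raw))])
  if (length(bad))
    stop("paired files out of sync at read '", r1$id[bad[1L]], "'")
  p1 <- qc_single(r1, cfg)
  p2 <- qc_single(r2, cfg)
  k1 <- strip_mate_suffix(p1$id)
  k2 <- strip_mate_suffix(p2$id)
  common <- intersect(k1, k2)
  o1 <- p1[k1 %in% common, , drop = FALSE]
  o2 <- p2[k2 %in% common, , drop = FALSE]
  if (!identical(strip_mate_suffix(o1$id), strip_mate_suffix(o2$id)))
    stop("mate order mismatch after resynchronization at read '",
         o1$id[which(strip_mate_suffix(o1$id) !=
                     strip_mate_suffix(o2$id))[1L]], "'")
  report <- data.frame(
    file = c("r1", "r2"), raw = raw,
    processed = c(nrow(o1), nrow(o2)),
    retention = ifelse(raw > 0, c(nrow(o1), nrow(o2)) / raw, NA_real_))
  list(r1 = o1, r2 = o2, report = report)
}

#' Run paired-end QC on files
#'
#' File-level wrapper around [process_pairs()]; writes the processed mates
#' and a tab-delimited report of raw and processed read counts.
#'
#' @param in1,in2 input FASTQ paths.
#' @param out1,out2 output FASTQ paths.
#' @param report_path optional path for the tab-delimited QC report.
#' @inheritParams process_pairs
#' @return the QC report data.frame, invisibly.
#' @export
qc_fastq_files <- function(in1, in2, out1, out2, cfg = qc_config(),
                           report_path = NULL) {
  res <- process_pairs(read_fastq(in1, cfg$phred_offset),
                       read_fastq(in2, cfg$phred_offset), cfg)
  write_fastq(res$r1, out1, cfg$phred_offset)
  write_fastq(res$r2, out2, cfg$phred_offset)
  if (!is.null(report_path))
    utils::write.table(res$report, report_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(res$report)
}
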