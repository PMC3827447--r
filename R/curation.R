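#' Per-locus curation configuration
#'
#' Thresholds for the alignment-hygiene cascade applied to each ortholog
#' alignment: leading-ambiguity masking, consensus-divergence paralog
#' removal, minimum sequence and alignment lengths, taxon occupancy, and
#' the per-locus missing-data ceiling used during locus selection.
#'
#' @param lead_window residues inspected for leading ambiguity (default 20).
#' @param divergence_threshold fraction of comparable columns at or above
#'   which a sequence is deleted as putatively paralogous (default 0.75).
#' @param min_seq_len minimum non-gap residues per sequence (default 100).
#' @param min_aln_len minimum alignment columns (default 100).
#' @param min_taxa minimum distinct taxa per retained locus (default 11).
#' @param scafos_missing_max maximum percent of gap-or-missing cells a
#'   retained locus may contain (default 50).
#' @export
curation_config <- function(lead_window = 20L, divergence_threshold = 0.75,
                            min_seq_len = 100L, min_aln_len = 100L,
                            min_taxa = 11L, scafos_missing_max = 50) {
  stopifnot(lead_window >= 0, divergence_threshold > 0,
            divergence_threshold <= 1, min_seq_len > 0, min_aln_len > 0,
            min_taxa > 0, scafos_missing_max >= 0)
  structure(list(lead_window = as.integer(lead_window),
                 divergence_threshold = divergence_threshold,
                 min_seq_len = as.integer(min_seq_len),
                 min_aln_len = as.integer(min_aln_len),
                 min_taxa = as.integer(min_taxa),
                 scafos_missing_max = scafos_missing_max),
            class = "curation_config")
}

#' Mask leading ambiguous residues
#'
#' Within the first `window` alignment positions of each sequence, finds the
#' last `'X'` and replaces everything from position 1 through that `'X'`
#' with gaps. Sequence length is unchanged, so alignment geometry stays
#' valid. Sequences with no in-window `'X'` are untouched.
#'
#' @param aln a [protein_alignment()].
#' @param window number of leading positions inspected (default 20).
#' @return the masked alignment.
#' @export
trim_leading_ambiguity <- function(aln, window = 20L) {
  stopifnot(window >= 0)
  w <- min(window, ncol(aln$mat))
  if (w == 0L) return(aln)
  for (i in seq_len(nrow(aln$mat))) {
    hits <- which(aln$mat[i, seq_len(w)] == "X")
    if (length(hits)) aln$mat[i, seq_len(hits[length(hits)])] <- "-"
  }
  aln
}

#' Plurality consensus sequence of an alignment
#'
#' Per column, the most frequent non-gap residue; ties are broken
#' alphabetically and all-gap columns yield `'-'`. `'X'` and `'?'` count as
#' characters of their own but never beat a residue in a tie (alphabetical
#' order places letters before neither -- all are letters; `'X'` simply
#' competes alphabetically).
#'
#' @param aln a [protein_alignment()].
#' @return character vector of single characters, one per column.
#' @export
consensus <- function(aln) {
  stopifnot(nrow(aln$mat) > 0)
  apply(aln$mat, 2L, function(col) {
    col <- col[col != "-" & col != "?"]
    if (!length(col)) return("-")
    tab <- table(col)
    names(tab)[tab == max(tab)][1L]  # table() names are sorted -> alphabetical
  })
}

# per-sequence divergence from a fixed consensus; comparable columns are
# those where both the sequence and the consensus hold a non-gap residue
divergence_from <- function(aln, cons) {
  vapply(seq_len(nrow(aln$mat)), function(i) {
    s <- aln$mat[i, ]
    comp <- s != "-" & s != "?" & cons != "-"
    if (!any(comp)) return(NA_real_)
    mean(s[comp] != cons[comp])
  }, numeric(1))
}

#' Remove putatively paralogous sequences by consensus divergence
#'
#' Computes the plurality [consensus()] once, then deletes every sequence
#' whose divergence (mismatches over columns where both the sequence and
#' the consensus have a non-gap residue) is at or above `threshold`. The
#' consensus is not recomputed between removals. A sequence with zero
#' comparable columns is removed and reported.
#'
#' @param aln a [protein_alignment()] with at least two members.
#' @param threshold divergence fraction (default 0.75).
#' @return the filtered alignment, with attribute `"removed"` naming the
#'   deleted sequence ids.
#' @export
remove_divergent <- function(aln, threshold = 0.75) {
  stopifnot(nrow(aln$mat) >= 2)
  div <- divergence_from(aln, consensus(aln))
  drop <- is.na(div) | div >= threshold
  out <- aln_subset(aln, rows = !drop)
  attr(out, "removed") <- rownames(aln$mat)[drop]
  attr(out, "divergence") <- div
  out
}

#' Delete all-gap and singleton columns
#'
#' Columns containing zero or one non-gap characters are removed; the order
#' of the surviving columns is preserved. `'?'` counts as a gap here.
#'
#' @param aln a [protein_alignment()].
#' @return the column-filtered alignment.
#' @export
drop_uninformative_columns <- function(aln) {
  nongap <- colSums(aln$mat != "-" & aln$mat != "?")
  aln_subset(aln, cols = nongap >= 2L)
}

#' Reduce each taxon to a single representative sequence
#'
#' Emulates the chimera-building "representative" selection used when a
#' taxon contributed several non-overlapping contigs of one ortholog. If a
#' taxon's sequences occupy pairwise disjoint column sets they are merged
#' into one chimeric sequence (union of residues, gaps elsewhere); if any
#' two overlap, only the sequence with the most non-gap residues is kept
#' (ties broken by alphabetically first sequence id).
#'
#' @param aln a [protein_alignment()].
#' @return an alignment with at most one sequence per taxon.
#' @export
representative_per_taxon <- function(aln) {
  keep_rows <- list()
  for (tx in unique(aln$taxon)) {
    rows <- which(aln$taxon == tx)
    if (length(rows) == 1L) {
      keep_rows[[tx]] <- aln$mat[rows, ]
      next
    }
    occ <- aln$mat[rows, , drop = FALSE] != "-" & aln$mat[rows, , drop = FALSE] != "?"
    disjoint <- all(colSums(occ) <= 1L)
    if (disjoint) {
      merged <- rep("-", ncol(aln$mat))
      for (r in seq_along(rows))
        merged[occ[r, ]] <- aln$mat[rows[r], occ[r, ]]
      keep_rows[[tx]] <- merged
    } else {
      cover <- rowSums(occ)
      ids <- rownames(aln$mat)[rows]
      best <- rows[order(-cover, ids)][1L]
      keep_rows[[tx]] <- aln$mat[best, ]
    }
  }
  m <- do.call(rbind, keep_rows)
  rownames(m) <- names(keep_rows)
  protein_alignment(m, aln$locus, taxon = names(keep_rows))
}

#' Length, occupancy and missing-data filters over a locus collection
#'
#' Per alignment, in order: delete sequences with fewer than
#' `cfg$min_seq_len` non-gap residues; delete alignments narrower than
#' `cfg$min_aln_len` columns; delete alignments with fewer than
#' `cfg$min_taxa` distinct taxa; delete alignments in which more than
#' `cfg$scafos_missing_max` percent of cells are gap or missing.
#'
#' @param alns list of [protein_alignment()].
#' @param cfg a [curation_config()].
#' @return list with `alignments` (the survivors) and `report`: a
#'   data.frame of per-stage removal counts (`stage`, `loci_removed`,
#'   `sequences_removed`).
#' @export
apply_length_and_occupancy <- function(alns, cfg = curation_config()) {
  seq_removed <- 0L
  alns <- lapply(alns, function(a) {
    nongap <- rowSums(a$mat != "-" & a$mat != "?")
    drop <- nongap < cfg$min_seq_len
    seq_removed <<- seq_removed + sum(drop)
    aln_subset(a, rows = !drop)
  })
  n0 <- length(alns)
  alns <- Filter(function(a) ncol(a$mat) >= cfg$min_aln_len, alns)
  short_loci <- n0 - length(alns)
  n1 <- length(alns)
  alns <- Filter(function(a) n_taxa(a) >= cfg$min_taxa, alns)
  sparse_loci <- n1 - length(alns)
  n2 <- length(alns)
  alns <- Filter(function(a) {
    pct <- 100 * mean(a$mat == "-" | a$mat == "?" | a$mat == "X")
    pct <= cfg$scafos_missing_max
  }, alns)
  gappy_loci <- n2 - length(alns)
  report <- data.frame(
    stage = c("short_sequences", "short_alignments", "low_occupancy",
              "excess_missing"),
    loci_removed = c(0L, short_loci, sparse_loci, gappy_loci),
    sequences_removed = c(seq_removed, 0L, 0L, 0L))
  list(alignments = alns, report = report)
}
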