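#' Synthetic ortholog-set configuration
#'
#' Parameters of the synthetic transcriptome-ortholog generator. The
#' defaults emulate the study dataset this package was validated against:
#' 12 taxa, 1005 ortholog alignments averaging ~529 aligned residues, and
#' per-taxon locus recovery probabilities matching the published
#' pre-optimization inclusion levels (from ~0.17 for the sparse EST taxon
#' *Archispirostreptus* up to ~0.92, with the reference taxon *Daphnia*
#' always recovered). Defect rates inject the artifacts the curation
#' cascade exists to remove; each injected defect is labeled in
#' per-sequence metadata so filters can be scored.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_loci number of ortholog alignments.
#' @param mean_locus_len mean alignment length in residues (>= 100).
#' @param recovery_prob per-taxon probability that a locus is recovered;
#'   scalar or vector of length `n_taxa`.
#' @param paralog_rate probability a locus gains a divergent paralogous
#'   copy of one of its taxa.
#' @param lead_ambiguity_rate probability a sequence starts with a run of
#'   ambiguous `'X'` residues inside its first 20 positions.
#' @param gap_region_rate probability a locus contains an indel-rich,
#'   misaligned segment.
#' @param fragment_rate probability a sequence is truncated to a fragment
#'   below 100 residues.
#' @param taxa taxon names (default [STUDY_TAXA] when `n_taxa` is 12).
#' @param seed integer random seed; the same seed reproduces the set
#'   byte-for-byte.
#' @export
sim_config <- function(n_taxa = 12L, n_loci = 1005L, mean_locus_len = 529L,
                       recovery_prob = NULL, paralog_rate = 0.05,
                       lead_ambiguity_rate = 0.10, gap_region_rate = 0.25,
                       fragment_rate = 0.05, taxa = NULL, seed = 1L) {
  chk_prob <- function(x, nm) {
    if (any(x < 0 | x > 1))
      stop("sim_config field '", nm, "' must lie in [0, 1]")
    x
  }
  if (n_taxa < 4) stop("sim_config field 'n_taxa' must be >= 4")
  if (n_loci < 1) stop("sim_config field 'n_loci' must be >= 1")
  if (mean_locus_len < 100)
    stop("sim_config field 'mean_locus_len' must be >= 100")
  if (is.null(taxa))
    taxa <- if (n_taxa == 12L) STUDY_TAXA else paste0("taxon", seq_len(n_taxa))
  stopifnot(length(taxa) == n_taxa)
  if (is.null(recovery_prob)) {
    recovery_prob <- if (identical(taxa, STUDY_TAXA)) {
      counts <- millipede_study_counts()
      p <- stats::setNames(counts$inclusion$pre / counts$matrix_pre$n_loci,
                           counts$inclusion$taxon)
      unname(c(Daphnia = 1, p)[taxa])
    } else rep(0.85, n_taxa)
  }
  if (length(recovery_prob) == 1L) recovery_prob <- rep(recovery_prob, n_taxa)
  stopifnot(length(recovery_prob) == n_taxa)
  chk_prob(recovery_prob, "recovery_prob")
  chk_prob(paralog_rate, "paralog_rate")
  chk_prob(lead_ambiguity_rate, "lead_ambiguity_rate")
  chk_prob(gap_region_rate, "gap_region_rate")
  chk_prob(fragment_rate, "fragment_rate")
  structure(list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
                 mean_locus_len = as.integer(mean_locus_len),
                 recovery_prob = recovery_prob,
                 paralog_rate = paralog_rate,
                 lead_ambiguity_rate = lead_ambiguity_rate,
                 gap_region_rate = gap_region_rate,
                 fragment_rate = fragment_rate,
                 taxa = taxa, seed = as.integer(seed)),
            class = "sim_config")
}

# one synthetic locus; cfg must be a sim_config
simulate_locus <- function(cfg, locus) {
  L <- max(120L, round(stats::rgamma(1, shape = 8,
                                     scale = cfg$mean_locus_len / 8)))
  dominant <- sample(AA_ALPHABET, L, replace = TRUE)
  conservation <- stats::rbeta(L, 5, 1)  # per-column identity to the profile
  present <- stats::runif(cfg$n_taxa) < cfg$recovery_prob
  if (sum(present) < 2L) present[sample(cfg$n_taxa, 2L)] <- TRUE
  taxa <- cfg$taxa[present]

  draw_seq <- function() {
    hit <- stats::runif(L) < conservation
    res <- dominant
    alt <- sample(AA_ALPHABET, L, replace = TRUE)
    res[!hit] <- alt[!hit]
    res
  }
  rows <- lapply(taxa, function(t) draw_seq())
  ids <- taxa
  meta <- rep(list(list(defects = character(0))), length(taxa))
  taxon_of <- taxa

  ## indel-rich misaligned segment (locus-level defect)
  if (stats::runif(1) < cfg$gap_region_rate) {
    wid <- sample(6:20, 1)
    at <- sample(L - wid, 1)
    seg <- at:(at + wid - 1L)
    for (i in seq_along(rows)) {
      if (stats::runif(1) < 0.5) rows[[i]][seg] <- "-"
      else rows[[i]][seg] <- sample(AA_ALPHABET, wid, replace = TRUE)
      meta[[i]]$defects <- c(meta[[i]]$defects, "gap_region")
    }
  }

  ## per-sequence defects
  for (i in seq_along(rows)) {
    if (stats::runif(1) < cfg$lead_ambiguity_rate) {
      k <- sample(1:15, 1)
      rows[[i]][seq_len(k)] <- "X"
      meta[[i]]$defects <- c(meta[[i]]$defects, "lead_ambiguity")
    }
    if (stats::runif(1) < cfg$fragment_rate) {
      keep_len <- sample(30:99, 1)
      start <- sample(L - keep_len, 1)
      gapped <- rep("-", L)
      seg <- start:(start + keep_len - 1L)
      gapped[seg] <- rows[[i]][seg]
      rows[[i]] <- gapped
      meta[[i]]$defects <- c(meta[[i]]$defects, "fragment")
    }
  }

  ## one taxon's recovered sequence replaced by a divergent paralog
  ## (redrawn at 90% of its residue positions)
  if (stats::runif(1) < cfg$paralog_rate) {
    src <- sample.int(length(taxa), 1)
    copy <- rows[[src]]
    nong <- which(copy %in% AA_ALPHABET)
    flip <- nong[sample.int(length(nong), ceiling(0.9 * length(nong)))]
    shift <- sample(19, length(flip), replace = TRUE)
    copy[flip] <- AA_ALPHABET[(match(copy[flip], AA_ALPHABET) - 1L + shift) %% 20L + 1L]
    rows[[src]] <- copy
    meta[[src]]$defects <- c(meta[[src]]$defects, "paralog")
    meta[[src]]$divergence_target <- 0.9
  }

  m <- do.call(rbind, rows)
  rownames(m) <- ids
  protein_alignment(m, locus, taxon = taxon_of, meta = meta)
}

#' Simulate a synthetic ortholog set
#'
#' Generates `cfg$n_loci` per-locus amino-acid alignments with the
#' statistical structure the curation cascade assumes: variable per-taxon
#' recovery, per-column conservation drawn from a Beta(5, 1) profile,
#' and injected labeled defects (divergent paralog copies redrawn at 90%
#' of non-gap positions, leading `'X'` runs, indel-rich segments, and
#' sub-100-residue fragments). Fully reproducible given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return named list of [protein_alignment()] (`locus0001`, ...); each
#'   row's metadata carries a `defects` character vector.
#' @export
simulate_ortholog_set <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    loci <- sprintf("locus%04d", seq_len(cfg$n_loci))
    stats::setNames(lapply(loci, function(l) simulate_locus(cfg, l)), loci)
  })
}

#' List defect labels of an alignment's sequences
#' @param aln a [protein_alignment()].
#' @return data.frame `id`, `taxon`, `defects` (comma-separated).
#' @export
defect_labels <- function(aln) {
  data.frame(id = rownames(aln$mat), taxon = aln$taxon,
             defects = vapply(aln$meta, function(m)
               paste(m$defects %||% character(0), collapse = ","),
               character(1)))
}

#' Write an ortholog set as per-locus FASTA files
#' @param alns list of [protein_alignment()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ortholog_set <- function(alns, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in alns)
    write_locus_fasta(a, file.path(dir, paste0(a$locus, ".fasta")))
  invisible(dir)
}

#' Read a directory of per-locus FASTA alignments
#' @param dir directory of `.fasta` files.
#' @return named list of [protein_alignment()].
#' @export
read_ortholog_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|faa)$",
                           full.names = TRUE))
  alns <- lapply(files, read_locus_fasta)
  stats::setNames(alns, vapply(alns, function(a) a$locus, character(1)))
}
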