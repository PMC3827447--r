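#' Amino-acid alignment container
#'
#' A `protein_alignment` holds one per-locus multiple sequence alignment as a
#' character matrix (one row per sequence, one column per aligned position)
#' over the 20 amino acids plus `'X'` (ambiguous) and `'-'` (gap). Rows are
#' keyed by a sequence id; each row also carries the taxon it belongs to
#' (several rows may share a taxon before representative selection) and
#' free-form metadata labels (used e.g. to tag synthetic defects).
#'
#' @param mat character matrix of single residues; rownames are sequence ids.
#' @param locus locus name.
#' @param taxon character vector, one taxon per row. Defaults to rownames
#'   with any `"|..."` copy suffix stripped.
#' @param meta optional list of per-row metadata (named by sequence id).
#' @return an object of class `protein_alignment`.
#' @export
protein_alignment <- function(mat, locus, taxon = NULL, meta = NULL) {
  stopifnot(is.matrix(mat), is.character(mat))
  if (is.null(rownames(mat)) && nrow(mat) > 0)
    rownames(mat) <- paste0("seq", seq_len(nrow(mat)))
  if (is.null(taxon)) taxon <- sub("\\|.*$", "", rownames(mat))
  stopifnot(length(taxon) == nrow(mat))
  if (is.null(meta)) meta <- rep(list(list()), nrow(mat))
  stopifnot(length(meta) == nrow(mat))
  names(meta) <- rownames(mat)
  bad <- !mat %in% c(AA_ALPHABET, "X", "-", "?")
  if (any(bad)) stop("invalid residue characters: ",
                     paste(unique(mat[bad]), collapse = " "))
  structure(list(locus = as.character(locus), mat = mat,
                 taxon = as.character(taxon), meta = meta),
            class = "protein_alignment")
}

#' The 20 standard amino-acid one-letter codes (PAML/WAG order)
#' @export
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment '%s': %d sequences x %d columns (%d taxa)\n",
              x$locus, nrow(x$mat), ncol(x$mat), length(unique(x$taxon))))
  invisible(x)
}

#' @export
dim.protein_alignment <- function(x) dim(x$mat)

n_taxa <- function(aln) length(unique(aln$taxon))

#' Subset an alignment by row and/or column
#'
#' Keeps metadata and taxon assignments in step with the retained rows.
#' Column subsetting never reorders columns unless explicitly asked to.
#'
#' @param aln a [protein_alignment()].
#' @param rows,cols logical or integer index vectors (default: keep all).
#' @return a `protein_alignment`.
#' @export
aln_subset <- function(aln, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(aln$mat))
  if (is.null(cols)) cols <- seq_len(ncol(aln$mat))
  m <- aln$mat[rows, cols, drop = FALSE]
  protein_alignment(m, aln$locus, taxon = aln$taxon[rows],
                    meta = aln$meta[rows])
}

#' Read a per-locus FASTA alignment
#'
#' Headers are taken as sequence ids; the taxon is the id up to the first
#' `'|'` (copy suffixes like `"Cambala|frag2"` mark multiple sequences of one
#' taxon). Parsing goes through [Biostrings::readAAStringSet()].
#'
#' @param path FASTA file.
#' @param locus locus name; defaults to the file name without extension.
#' @return a [protein_alignment()].
#' @export
read_locus_fasta <- function(path, locus = NULL) {
  if (is.null(locus))
    locus <- sub("\\.(fa|fasta|faa)$", "", basename(path), ignore.case = TRUE)
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  chars <- strsplit(toupper(as.character(ss)), "", fixed = TRUE)
  len <- unique(lengths(chars))
  if (length(len) != 1L)
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  m <- do.call(rbind, chars)
  rownames(m) <- ids
  m[m == "."] <- "-"
  protein_alignment(m, locus)
}

#' Write a per-locus FASTA alignment
#' @param aln a [protein_alignment()].
#' @param path output file.
#' @export
write_locus_fasta <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- rownames(aln$mat)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# internal: alignment as residue index matrix (1..20, NA for gap/X/?)
aln_state_matrix <- function(aln) {
  m <- match(aln$mat, AA_ALPHABET)
  dim(m) <- dim(aln$mat)
  rownames(m) <- rownames(aln$mat)
  m
}
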