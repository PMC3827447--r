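#' Conserved-block selection configuration
#'
#' Parameters of the classic conserved-block algorithm. With `n` sequences
#' the study settings are `is_min = fs_min = floor(n/2) + 1`, a maximum run
#' of 8 contiguous nonconserved positions, a minimum block length of 10,
#' and the "half" gap rule -- which is what the defaults reproduce.
#'
#' @param is_min minimum count of the most frequent residue for a position
#'   to be "conserved" (default `floor(n/2) + 1`, resolved per alignment).
#' @param fs_min flank threshold for "highly conserved" (same default).
#' @param cp_max maximum tolerated run of contiguous nonconserved positions
#'   (default 8).
#' @param bl_min minimum block length in columns (default 10).
#' @param gap_mode `"half"` (gap position when >= 50% of sequences are
#'   gapped; default), `"none"` (any gap) or `"all"` (never).
#' @export
block_config <- function(is_min = NULL, fs_min = NULL, cp_max = 8L,
                         bl_min = 10L, gap_mode = c("half", "none", "all")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(cp_max >= 0, bl_min >= 1)
  structure(list(is_min = is_min, fs_min = fs_min,
                 cp_max = as.integer(cp_max), bl_min = as.integer(bl_min),
                 gap_mode = gap_mode),
            class = "block_config")
}

# resolve the n-dependent defaults against a concrete alignment
resolve_block_config <- function(cfg, n) {
  if (is.null(cfg$is_min)) cfg$is_min <- n %/% 2L + 1L
  if (is.null(cfg$fs_min)) cfg$fs_min <- n %/% 2L + 1L
  stopifnot(cfg$is_min <= cfg$fs_min, cfg$fs_min <= n)
  cfg
}

#' Classify alignment positions for block selection
#'
#' A column is `gap` when the configured gap rule fires (`half`: at least
#' half the sequences gapped; `none`: any gap; `all`: never). Otherwise,
#' with `m` the count of the most frequent residue, the column is
#' `nonconserved` if `m < is_min`, `conserved` if `is_min <= m < fs_min`,
#' and `highly_conserved` if `m >= fs_min`. With the study's equal
#' `is_min`/`fs_min` setting the two conserved classes coincide.
#'
#' @param aln a [protein_alignment()].
#' @param cfg a [block_config()].
#' @return character vector of per-column classes.
#' @export
classify_positions <- function(aln, cfg = block_config()) {
  stopifnot(nrow(aln$mat) > 0)
  n <- nrow(aln$mat)
  cfg <- resolve_block_config(cfg, n)
  isgap <- aln$mat == "-" | aln$mat == "?"
  gapfrac <- colSums(isgap) / n
  gapclass <- switch(cfg$gap_mode,
                     half = gapfrac >= 0.5,
                     none = gapfrac > 0,
                     all  = rep(FALSE, ncol(aln$mat)))
  vapply(seq_len(ncol(aln$mat)), function(j) {
    if (gapclass[j]) return("gap")
    col <- aln$mat[!isgap[, j], j]
    m <- if (length(col)) max(table(col)) else 0L
    if (m < cfg$is_min) "nonconserved"
    else if (m < cfg$fs_min) "conserved"
    else "highly_conserved"
  }, character(1))
}

# runs of TRUE in a logical vector as a data.frame(start, end)
runs_of <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start[r$values], end = end[r$values])
}

#' Select conserved alignment blocks
#'
#' Applies, in order: (1) reject every run of more than `cp_max` contiguous
#' nonconserved positions; (2) trim each remaining block inward until both
#' flanks are highly conserved; (3) reject all gap-class positions together
#' with every contiguous run of nonconserved positions adjacent to one;
#' (4) reject remaining blocks shorter than `bl_min`. Everything not
#' rejected is kept. The result is independent of sequence order.
#'
#' @inheritParams classify_positions
#' @return a [column_mask()].
#' @export
select_blocks <- function(aln, cfg = block_config()) {
  cls <- classify_positions(aln, cfg)
  cfg <- resolve_block_config(cfg, nrow(aln$mat))
  L <- length(cls)
  rejected <- rep(FALSE, L)

  ## (1) long nonconserved runs
  nc <- runs_of(cls == "nonconserved")
  for (i in seq_len(nrow(nc)))
    if (nc$end[i] - nc$start[i] + 1L > cfg$cp_max)
      rejected[nc$start[i]:nc$end[i]] <- TRUE

  ## (2) trim block ends inward to highly conserved flanks
  blocks <- runs_of(!rejected)
  for (i in seq_len(nrow(blocks))) {
    a <- blocks$start[i]; b <- blocks$end[i]
    while (a <= b && cls[a] != "highly_conserved") { rejected[a] <- TRUE; a <- a + 1L }
    while (b >= a && cls[b] != "highly_conserved") { rejected[b] <- TRUE; b <- b - 1L }
  }

  ## (3) gap positions and adjacent nonconserved runs
  gaps <- which(cls == "gap")
  rejected[gaps] <- TRUE
  for (g in gaps) {
    j <- g - 1L
    while (j >= 1L && cls[j] == "nonconserved") { rejected[j] <- TRUE; j <- j - 1L }
    j <- g + 1L
    while (j <= L && cls[j] == "nonconserved") { rejected[j] <- TRUE; j <- j + 1L }
  }

  ## (4) minimum block length
  blocks <- runs_of(!rejected)
  for (i in seq_len(nrow(blocks)))
    if (blocks$end[i] - blocks$start[i] + 1L < cfg$bl_min)
      rejected[blocks$start[i]:blocks$end[i]] <- TRUE

  column_mask(aln$locus, !rejected)
}

#' Column mask
#'
#' Per-locus boolean keep vector over alignment columns, with conversion to
#' 1-based inclusive interval lists for reporting.
#'
#' @param locus locus name.
#' @param keep logical vector, one entry per column.
#' @export
column_mask <- function(locus, keep) {
  stopifnot(is.logical(keep))
  structure(list(locus = locus, keep = keep), class = "column_mask")
}

#' @export
print.column_mask <- function(x, ...) {
  cat(sprintf("column_mask '%s': %d/%d columns kept\n",
              x$locus, sum(x$keep), length(x$keep)))
  invisible(x)
}

#' @rdname column_mask
#' @param mask a `column_mask`.
#' @export
mask_intervals <- function(mask) runs_of(mask$keep)

#' Apply a column mask to its alignment
#' @param aln a [protein_alignment()].
#' @param mask a [column_mask()] of matching length.
#' @return the alignment restricted to kept columns.
#' @export
apply_mask <- function(aln, mask) {
  stopifnot(length(mask$keep) == ncol(aln$mat))
  aln_subset(aln, cols = mask$keep)
}

#' Sliding-window masking configuration
#'
#' Parameters for Monte-Carlo detection of alignment windows whose pairwise
#' identity score is no better than randomly composed sequence.
#'
#' @param window window width in columns (default 6).
#' @param n_randomizations null windows drawn per sequence pair
#'   (default 100).
#' @param score_quantile null-score quantile at or below which a window
#'   votes its columns low-signal (default 0.95).
#' @param seed integer seed for the null draws.
#' @export
mask_config <- function(window = 6L, n_randomizations = 100L,
                        score_quantile = 0.95, seed = 1L) {
  stopifnot(window >= 1, n_randomizations >= 1,
            score_quantile > 0, score_quantile < 1)
  structure(list(window = as.integer(window),
                 n_randomizations = as.integer(n_randomizations),
                 score_quantile = score_quantile, seed = as.integer(seed)),
            class = "mask_config")
}

# identity score per column for one sequence pair: +1 identical non-gap, -1 else
pair_column_scores <- function(a, b) {
  ifelse(a != "-" & a != "?" & a == b, 1L, -1L)
}

#' Monte-Carlo masking of low-signal columns
#'
#' For every sequence pair, every sliding window of `cfg$window` columns is
#' scored (+1 for identical non-gap residues, -1 otherwise, summed over the
#' window) and compared to the `score_quantile` of scores from
#' `n_randomizations` windows built by drawing residues from the pair's
#' pooled non-gap composition. Windows scoring at or below that null
#' quantile vote all their columns "low signal" for that pair; a column is
#' masked when more than half of the pairs vote it low-signal. Downstream,
#' masked columns are deleted ([apply_mask()]).
#'
#' @param aln a [protein_alignment()] with at least two sequences.
#' @param cfg a [mask_config()].
#' @return a [column_mask()] (`keep` is FALSE for masked columns).
#' @export
mask_low_signal <- function(aln, cfg = mask_config()) {
  stopifnot(nrow(aln$mat) >= 2)
  L <- ncol(aln$mat)
  w <- cfg$window
  if (L < w) return(column_mask(aln$locus, rep(TRUE, L)))
  nseq <- nrow(aln$mat)
  pairs <- utils::combn(nseq, 2L)
  votes <- integer(L)
  with_seed(cfg$seed, {
    for (p in seq_len(ncol(pairs))) {
      a <- aln$mat[pairs[1L, p], ]
      b <- aln$mat[pairs[2L, p], ]
      colsc <- pair_column_scores(a, b)
      obs <- as.integer(stats::filter(colsc, rep(1, w), sides = 1))[w:L]
      pool <- c(a, b)
      pool <- pool[pool != "-" & pool != "?"]
      if (length(pool) < 2L) next
      ra <- matrix(sample(pool, cfg$n_randomizations * w, replace = TRUE),
                   ncol = w)
      rb <- matrix(sample(pool, cfg$n_randomizations * w, replace = TRUE),
                   ncol = w)
      null_scores <- rowSums(ifelse(ra == rb, 1L, -1L))
      cut <- stats::quantile(null_scores, cfg$score_quantile, names = FALSE,
                             type = 1)
      low <- rep(FALSE, L)
      for (s in which(obs <= cut)) {
        start <- s  # window s covers columns s..s+w-1
        low[start:(start + w - 1L)] <- TRUE
      }
      votes <- votes + low
    }
  })
  column_mask(aln$locus, votes <= ncol(pairs) / 2)
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
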