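# Test helpers: small alignment builders and independent brute-force
# oracles. The oracles deliberately use a different coding style (explicit
# scans and loops) from the package implementations they check.

# build a protein_alignment from equal-length strings
make_aln <- function(..., locus = "L1", taxa = NULL) {
  seqs <- c(...)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- if (is.null(taxa)) paste0("t", seq_along(seqs)) else taxa
  protein_alignment(m, locus)
}

# random small alignment over a reduced alphabet, with gaps
random_aln <- function(n_seq, n_col, gap_prob = 0.2,
                       alphabet = c("A", "C", "D", "E")) {
  m <- matrix(sample(alphabet, n_seq * n_col, replace = TRUE), n_seq, n_col)
  m[matrix(runif(n_seq * n_col) < gap_prob, n_seq, n_col)] <- "-"
  rownames(m) <- paste0("t", seq_len(n_seq))
  protein_alignment(m, "rnd")
}

# independent scan-based implementation of the four block-selection steps,
# operating on a per-column class vector
oracle_block_keep <- function(cls, cp_max = 8L, bl_min = 10L) {
  L <- length(cls)
  rej <- rep(FALSE, L)
  # step 1: runs of > cp_max contiguous nonconserved columns
  i <- 1L
  while (i <= L) {
    if (cls[i] == "nonconserved") {
      j <- i
      while (j < L && cls[j + 1L] == "nonconserved") j <- j + 1L
      if (j - i + 1L > cp_max) rej[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  # step 2: trim every maximal unrejected segment to highly conserved flanks
  i <- 1L
  while (i <= L) {
    if (!rej[i]) {
      j <- i
      while (j < L && !rej[j + 1L]) j <- j + 1L
      a <- i
      while (a <= j && cls[a] != "highly_conserved") { rej[a] <- TRUE; a <- a + 1L }
      b <- j
      while (b >= a && cls[b] != "highly_conserved") { rej[b] <- TRUE; b <- b - 1L }
      i <- j + 1L
    } else i <- i + 1L
  }
  # step 3: gap columns and nonconserved runs touching them
  for (g in seq_len(L)) {
    if (cls[g] != "gap") next
    rej[g] <- TRUE
    k <- g - 1L
    while (k >= 1L && cls[k] == "nonconserved") { rej[k] <- TRUE; k <- k - 1L }
    k <- g + 1L
    while (k <= L && cls[k] == "nonconserved") { rej[k] <- TRUE; k <- k + 1L }
  }
  # step 4: drop short surviving blocks
  i <- 1L
  while (i <= L) {
    if (!rej[i]) {
      j <- i
      while (j < L && !rej[j + 1L]) j <- j + 1L
      if (j - i + 1L < bl_min) rej[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  !rej
}

# brute-force likelihood of one site by summing over all internal-node
# state assignments, using Matrix::expm for the transition probabilities
oracle_site_loglik <- function(tree, states, model) {
  n <- length(tree$tip.label)
  ntot <- n + tree$Nnode
  internal <- (n + 1L):ntot
  P_of <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(model$Q * tree$edge.length[e])))
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  assign_full <- matrix(0L, nrow(grid), ntot)
  assign_full[, internal] <- grid
  for (v in seq_len(n)) assign_full[, v] <- states[v]
  lik <- model$pi[assign_full[, n + 1L]]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    lik <- lik * P_of[[e]][cbind(assign_full[, p], assign_full[, ch])]
  }
  log(sum(lik))
}

# random rooted binary tree with random tip states for ASR checks
random_asr_instance <- function(n_tips, n_states = 2L) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  st <- sample.int(n_states, n_tips, replace = TRUE) - 1L
  names(st) <- tr$tip.label
  list(tree = tr, chr = character_matrix("c", st))
}
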