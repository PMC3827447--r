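#' Discrete character matrix
#'
#' Taxon-to-state codings for one discrete, unordered character. States are
#' small non-negative integers; `NA` codes a missing observation (written as
#' `"?"` on disk).
#'
#' @param name character name.
#' @param states named integer vector (names = taxa; `NA` = missing).
#' @param labels optional named character vector mapping state to a label;
#'   its names also declare the full state universe.
#' @export
character_matrix <- function(name, states, labels = NULL) {
  stopifnot(!is.null(names(states)))
  nm <- names(states)
  states <- as.integer(states)
  names(states) <- nm
  structure(list(name = name, states = states, labels = labels),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character '%s': %d taxa, states {%s}\n", x$name,
              length(x$states),
              paste(sort(unique(stats::na.omit(x$states))), collapse = ",")))
  invisible(x)
}

#' Read/write tab-delimited character matrices
#'
#' Two columns, `taxon TAB state`, with `"?"` for missing; one file per
#' character.
#' @param path file path.
#' @param name character name (defaults to file name).
#' @rdname character_io
#' @export
read_character_matrix <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("taxon", "state"),
                         colClasses = "character")
  st <- suppressWarnings(as.integer(ifelse(d$state == "?", NA, d$state)))
  names(st) <- d$taxon
  structure(list(name = name, states = st, labels = NULL),
            class = "character_matrix")
}

#' @param chr a [character_matrix()].
#' @rdname character_io
#' @export
write_character_matrix <- function(chr, path) {
  st <- ifelse(is.na(chr$states), "?", as.character(chr$states))
  utils::write.table(data.frame(names(chr$states), st), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# state universe for a character: declared labels if present, else observed
chr_states <- function(chr) {
  if (!is.null(chr$labels)) sort(as.integer(names(chr$labels)))
  else sort(unique(stats::na.omit(chr$states)))
}

# observed states per tree tip; missing tips -> NA (full set), with a note
tip_states <- function(tree, chr) {
  extra <- setdiff(names(chr$states), tree$tip.label)
  if (length(extra))
    stop("character '", chr$name, "' codes taxa absent from the tree: ",
         paste(extra, collapse = ", "))
  obs <- chr$states[match(tree$tip.label, names(chr$states))]
  uncoded <- setdiff(tree$tip.label, names(chr$states))
  if (length(uncoded))
    message("tips without codings treated as fully ambiguous: ",
            paste(uncoded, collapse = ", "))
  names(obs) <- tree$tip.label
  obs
}

#' Fitch parsimony ancestral-state reconstruction
#'
#' Unordered-character parsimony on a rooted tree. The first (down) pass
#' computes classic Fitch state sets, generalized over polytomies by
#' majority-intersection (states present in the maximum number of child
#' sets). Final per-node sets are the exact MPR sets -- the states a node
#' takes in at least one most-parsimonious reconstruction -- computed by
#' unit-cost dynamic programming over subtree and outside costs, which also
#' yields the parsimony score (minimum number of changes). On binary trees
#' the score equals the number of Fitch union events.
#'
#' @param tree rooted [ape::phylo]; polytomies allowed.
#' @param chr a [character_matrix()]; every tip should be coded (missing
#'   tips are treated as fully ambiguous and noted).
#' @return an object of class `asr_result`: list with `score`, `downpass`
#'   and `mpr` (lists of integer state sets indexed by ape node number),
#'   `states` (the state universe) and the input `tree`.
#' @seealso [enumerate_mprs()] for the brute-force oracle,
#'   [asr_states()] to query a clade's MPR set.
#' @export
fitch <- function(tree, chr) {
  stopifnot(inherits(tree, "phylo"))
  sts <- chr_states(chr)
  k <- length(sts)
  obs <- tip_states(tree, chr)
  bad <- stats::na.omit(obs)[!stats::na.omit(obs) %in% sts]
  if (length(bad))
    stop("observed states outside declared universe: ",
         paste(unique(bad), collapse = ","))
  n <- length(tree$tip.label)
  ntot <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  root <- n + 1L

  ## subtree (down) costs: Sankoff DP with unit costs
  cost <- matrix(0, ntot, k)
  for (i in seq_len(n))
    if (!is.na(obs[i])) cost[i, ] <- ifelse(sts == obs[i], 0, Inf)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    cost[p, ] <- cost[p, ] + pmin(cost[ch, ], min(cost[ch, ]) + 1)
  }
  score <- min(cost[root, ])

  ## outside costs g[v,s] = best total score with v fixed to s
  g <- matrix(Inf, ntot, k)
  g[root, ] <- cost[root, ]
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    away <- g[p, ] - pmin(cost[ch, ], min(cost[ch, ]) + 1)
    g[ch, ] <- cost[ch, ] + pmin(away, min(away[is.finite(away)]) + 1)
  }
  mpr <- lapply(seq_len(ntot), function(v) sts[g[v, ] <= score])

  ## generalized Fitch downpass sets
  inset <- matrix(FALSE, ntot, k)
  for (i in seq_len(n))
    inset[i, ] <- if (is.na(obs[i])) rep(TRUE, k) else sts == obs[i]
  for (p in unique(po$edge[, 1L])) {
    kids <- po$edge[po$edge[, 1L] == p, 2L]
    cnt <- colSums(inset[kids, , drop = FALSE])
    inset[p, ] <- cnt == max(cnt)
  }
  downpass <- lapply(seq_len(ntot), function(v) sts[inset[v, ]])

  structure(list(score = score, downpass = downpass, mpr = mpr,
                 states = sts, tree = tree, character = chr$name),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("parsimony reconstruction of '%s': score %d (min changes)\n",
              x$character, x$score))
  invisible(x)
}

#' Query the reconstructed state set of a clade
#'
#' @param res an `asr_result` from [fitch()] or [enumerate_mprs()].
#' @param tips a single tip name, or two or more tip names whose MRCA is
#'   the node of interest.
#' @param pass `"mpr"` (default) or `"downpass"` (only for [fitch()]).
#' @return integer vector of states.
#' @export
asr_states <- function(res, tips, pass = c("mpr", "downpass")) {
  pass <- match.arg(pass)
  node <- if (length(tips) == 1L) match(tips, res$tree$tip.label)
          else ape::getMRCA(res$tree, tips)
  if (is.na(node) || is.null(node)) stop("tips not found on tree")
  res[[pass]][[node]]
}

#' Exhaustive enumeration of most-parsimonious reconstructions
#'
#' Brute-force oracle: enumerates every assignment of states to internal
#' nodes (and to uncoded tips), counts state changes along edges, and
#' returns the minimum score with the per-node union of optimal
#' assignments. Guarded to small problems.
#'
#' @inheritParams fitch
#' @param max_assignments guard on the total enumeration size.
#' @return an `asr_result` (with `downpass = NULL`).
#' @export
enumerate_mprs <- function(tree, chr, max_assignments = 6e6) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  sts <- chr_states(chr)
  k <- length(sts)
  if (n > 12L || k > 4L)
    stop("enumeration guard: at most 12 tips and 4 states")
  obs <- suppressMessages(tip_states(tree, chr))
  ntot <- n + tree$Nnode
  free <- c(which(is.na(obs)), (n + 1L):ntot)
  ncomb <- k^length(free)
  if (ncomb > max_assignments) stop("enumeration too large: ", ncomb)

  idx <- seq_len(ncomb) - 1L
  assign_of <- vector("list", ntot)
  for (j in seq_along(free))
    assign_of[[free[j]]] <- (idx %/% k^(j - 1L)) %% k + 1L
  for (v in seq_len(n))
    if (!is.na(obs[v])) assign_of[[v]] <- rep.int(match(obs[v], sts), ncomb)

  chg <- integer(ncomb)
  for (e in seq_len(nrow(tree$edge)))
    chg <- chg + (assign_of[[tree$edge[e, 1L]]] !=
                  assign_of[[tree$edge[e, 2L]]])
  score <- min(chg)
  best <- chg == score
  mpr <- lapply(seq_len(ntot), function(v)
    sts[sort(unique(assign_of[[v]][best]))])
  structure(list(score = score, downpass = NULL, mpr = mpr, states = sts,
                 tree = tree, character = chr$name),
            class = "asr_result")
}

#' Tabulate an ancestral-state reconstruction
#'
#' One row per node; internal nodes are identified by the alphabetically
#' first and last tips of their clade (MRCA notation).
#'
#' @param res an `asr_result`.
#' @return data.frame with columns `node`, `label`, `states`.
#' @export
asr_table <- function(res) {
  tr <- res$tree
  n <- length(tr$tip.label)
  lab <- vapply(seq_along(res$mpr), function(v) {
    if (v <= n) return(tr$tip.label[v])
    tips <- sort(ape::extract.clade(tr, v)$tip.label)
    paste0("MRCA(", tips[1L], ",", tips[length(tips)], ")")
  }, character(1))
  data.frame(node = seq_along(res$mpr), label = lab,
             states = vapply(res$mpr, paste, character(1), collapse = ","))
}
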