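#' Amino-acid substitution model
#'
#' A time-reversible empirical rate model: symmetric exchangeabilities,
#' equilibrium frequencies, and equiprobable discrete-gamma rate
#' categories (Yang-style category means). The assembled generator is
#' normalized to one expected substitution per unit branch length. `"wag"`
#' uses the published WAG exchangeabilities and frequencies (taken from
#' phangorn's model table); `"poisson"` is the equal-rates, equal-frequency
#' model convenient for analytic checks.
#'
#' @param model `"wag"` or `"poisson"`.
#' @param gamma_shape shape of the gamma rate distribution (default 1).
#' @param n_categories discrete rate categories (default 4; 1 disables
#'   rate heterogeneity).
#' @return object of class `rate_model` with the eigendecomposition of the
#'   generator cached for fast transition probabilities.
#' @export
rate_model <- function(model = c("wag", "poisson"), gamma_shape = 1,
                       n_categories = 4L) {
  model <- match.arg(model)
  stopifnot(gamma_shape > 0, n_categories >= 1)
  if (model == "poisson") {
    S <- matrix(1, 20, 20); diag(S) <- 0
    pi <- rep(1 / 20, 20)
  } else {
    wag <- get(".WAG", envir = asNamespace("phangorn"))
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- wag$Q
    S <- S + t(S)
    pi <- as.numeric(wag$bf)
    pi <- pi / sum(pi)
  }
  dimnames(S) <- list(AA_ALPHABET, AA_ALPHABET)
  names(pi) <- AA_ALPHABET
  Q <- S * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))      # diag(sp) Q diag(1/sp), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(name = model, S = S, pi = pi,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 rates = discrete_gamma_rates(gamma_shape, n_categories),
                 U = e$vectors / sp, Uinv = t(e$vectors) * rep(sp, each = 20),
                 lambda = e$values, Q = Q),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("rate_model '%s': %d gamma categories (shape %.3g)\n",
              x$name, x$n_categories, x$gamma_shape))
  invisible(x)
}

#' Discrete-gamma category rates (mean method)
#'
#' Splits a mean-one gamma distribution into `k` equiprobable categories
#' and returns each category's conditional mean; the means average to 1.
#'
#' @param shape gamma shape parameter.
#' @param k number of categories.
#' @return numeric vector of length `k`.
#' @export
discrete_gamma_rates <- function(shape, k) {
  if (k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape,
                     rate = shape)
  p <- stats::pgamma(b, shape = shape + 1, rate = shape)
  r <- k * diff(p)
  r / mean(r) * 1  # guard tiny numeric drift; means must average to 1
}

#' Transition probability matrix P(t)
#' @param model a [rate_model()].
#' @param t branch length (expected substitutions per site).
#' @param rate rate multiplier (default 1).
#' @return 20 x 20 stochastic matrix.
#' @export
transition_prob <- function(model, t, rate = 1) {
  P <- model$U %*% (exp(model$lambda * t * rate) * model$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

## ---- alignment patterns -------------------------------------------------

# compress an alignment (or supermatrix) to site patterns in the order of
# `taxa`; gaps, '?' and 'X' are fully missing (NA)
compress_patterns <- function(aln, taxa) {
  mat <- if (inherits(aln, "supermatrix")) aln$mat else aln$mat
  rown <- if (inherits(aln, "supermatrix")) aln$taxa
          else aln$taxon
  rows <- match(taxa, rown)
  if (anyNA(rows))
    stop("taxa absent from alignment: ",
         paste(taxa[is.na(rows)], collapse = ", "))
  M <- match(mat[rows, , drop = FALSE], AA_ALPHABET)
  dim(M) <- c(length(taxa), ncol(mat))
  key <- apply(M, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(states = M[, first, drop = FALSE], weights = tabulate(map),
       map = map, n_sites = ncol(mat))
}

## ---- pruning ------------------------------------------------------------

# down (subtree) partial likelihoods for one rate category.
# returns list(partial = list of 20 x npat matrices, logscale = list of
# per-pattern log scaling vectors)
down_partials <- function(tree, pat, model, rate) {
  n <- length(tree$tip.label)
  ntot <- n + tree$Nnode
  npat <- ncol(pat$states)
  partial <- vector("list", ntot)
  logscale <- rep(list(numeric(npat)), ntot)
  for (i in seq_len(n)) {
    Ptip <- matrix(0, 20, npat)
    s <- pat$states[i, ]
    Ptip[cbind(s[!is.na(s)], which(!is.na(s)))] <- 1
    Ptip[, is.na(s)] <- 1
    partial[[i]] <- Ptip
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    t_e <- po$edge.length[e]
    F <- transition_prob(model, t_e, rate) %*% partial[[ch]]
    if (is.null(partial[[p]])) {
      partial[[p]] <- F
      logscale[[p]] <- logscale[[ch]]
    } else {
      partial[[p]] <- partial[[p]] * F
      logscale[[p]] <- logscale[[p]] + logscale[[ch]]
    }
    mx <- apply(partial[[p]], 2L, max)
    mx[mx <= 0] <- 1
    partial[[p]] <- partial[[p]] / rep(mx, each = 20)
    logscale[[p]] <- logscale[[p]] + log(mx)
  }
  list(partial = partial, logscale = logscale, root = n + 1L)
}

# outside partials: for each non-root node v, the likelihood of all data
# outside subtree(v) conditional on the state at parent(v), pi included
outside_partials <- function(tree, dp, model, rate) {
  n <- length(tree$tip.label)
  ntot <- n + tree$Nnode
  npat <- length(dp$logscale[[1]])
  root <- dp$root
  G <- vector("list", ntot)
  lsG <- vector("list", ntot)
  po <- ape::reorder.phylo(tree, "postorder")
  edge_of <- integer(ntot)           # edge index whose child is v
  edge_of[po$edge[, 2L]] <- seq_len(nrow(po$edge))
  kids_of <- split(po$edge[, 2L], po$edge[, 1L])
  # child factor [P(t_s) D_s] reused across siblings
  factor_of <- vector("list", ntot)
  for (v in po$edge[, 2L]) {
    t_e <- po$edge.length[edge_of[v]]
    factor_of[[v]] <- transition_prob(model, t_e, rate) %*% dp$partial[[v]]
  }
  for (e in rev(seq_len(nrow(po$edge)))) {  # preorder traversal
    p <- po$edge[e, 1L]; v <- po$edge[e, 2L]
    sibs <- setdiff(kids_of[[as.character(p)]], v)
    acc <- matrix(1, 20, npat)
    lacc <- numeric(npat)
    for (s in sibs) {
      acc <- acc * factor_of[[s]]
      lacc <- lacc + dp$logscale[[s]]
    }
    if (p == root) {
      acc <- acc * model$pi
    } else {
      t_p <- po$edge.length[edge_of[p]]
      up <- crossprod(transition_prob(model, t_p, rate), G[[p]])
      acc <- acc * up
      lacc <- lacc + lsG[[p]]
    }
    mx <- apply(acc, 2L, max)
    mx[mx <= 0] <- 1
    G[[v]] <- acc / rep(mx, each = 20)
    lsG[[v]] <- lacc + log(mx)
  }
  list(G = G, logscale = lsG)
}

# log(mean(exp(x))) over rows of a K x npat matrix
log_mean_exp <- function(x) {
  if (is.null(dim(x))) return(x)
  mx <- apply(x, 2L, max)
  log(colMeans(exp(x - rep(mx, each = nrow(x))))) + mx
}

#' Per-site log-likelihoods under a fixed tree
#'
#' Felsenstein pruning over the rooted tree, averaging site likelihoods
#' over the equiprobable discrete-gamma categories. Gaps, `'?'` and `'X'`
#' are fully missing data. Duplicate site patterns are compressed; the
#' result carries both the per-pattern values and the per-site expansion.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param aln a [protein_alignment()] or `supermatrix` containing every
#'   tree tip.
#' @param model a [rate_model()].
#' @return object of class `site_loglik`: list with `pattern_loglik`,
#'   `weights`, `map` (site -> pattern), `site_loglik` and `total`.
#' @export
site_logliks <- function(tree, aln, model = rate_model()) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  pat <- compress_patterns(aln, tree$tip.label)
  ll <- pattern_logliks(tree, pat, model)
  if (any(!is.finite(ll)))
    stop("non-finite site log-likelihood at pattern ",
         which(!is.finite(ll))[1L])
  structure(list(pattern_loglik = ll, weights = pat$weights, map = pat$map,
                 site_loglik = ll[pat$map],
                 total = sum(ll * pat$weights)),
            class = "site_loglik")
}

# per-pattern mixture log-likelihood
pattern_logliks <- function(tree, pat, model) {
  percat <- vapply(model$rates, function(r) {
    dp <- down_partials(tree, pat, model, r)
    lik <- colSums(dp$partial[[dp$root]] * model$pi)
    log(lik) + dp$logscale[[dp$root]]
  }, numeric(ncol(pat$states)))
  if (is.null(dim(percat))) percat <- matrix(percat, nrow = 1)
  log_mean_exp(t(percat))
}

#' Total log-likelihood of an alignment on a tree
#' @inheritParams site_logliks
#' @return scalar log-likelihood.
#' @export
tree_loglik <- function(tree, aln, model = rate_model()) {
  site_logliks(tree, aln, model)$total
}

#' Optimize branch lengths by coordinate-wise Brent search
#'
#' Sweeps over branches, optimizing each length by bracketed 1-D search on
#' the likelihood with all other lengths fixed (the per-branch profile is
#' computed from inside and outside partials, so each trial length costs a
#' single transition-matrix product). A new length is accepted only if it
#' improves the total log-likelihood, which is therefore nondecreasing
#' across sweeps; sweeping stops when a full round improves the total by
#' less than `tol` or after `max_rounds` rounds. Optionally alternates
#' with 1-D optimization of the gamma shape.
#'
#' @inheritParams site_logliks
#' @param max_rounds maximum sweeps (default 20).
#' @param tol convergence tolerance on the total log-likelihood
#'   (default 1e-6).
#' @param min_bl,max_bl branch-length search bounds.
#' @param estimate_shape also optimize the gamma shape (default FALSE).
#' @return the tree with optimized `edge.length`; attributes `"loglik"`
#'   and (if estimated) `"gamma_shape"`.
#' @export
optimize_branch_lengths <- function(tree, aln, model = rate_model(),
                                    max_rounds = 20L, tol = 1e-6,
                                    min_bl = 1e-8, max_bl = 10,
                                    estimate_shape = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  pat <- compress_patterns(aln, tree$tip.label)
  total <- function(tr) {
    ll <- sum(pattern_logliks(tr, pat, model) * pat$weights)
    if (!is.finite(ll)) stop("non-finite likelihood during optimization")
    ll
  }
  cur <- total(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  n_edge <- nrow(po$edge)
  for (round in seq_len(max_rounds)) {
    prev <- cur
    for (e in seq_len(n_edge)) {
      v <- po$edge[e, 2L]
      prof <- branch_profile(po, pat, model, v)
      opt <- stats::optimize(prof, c(min_bl, max_bl), maximum = TRUE,
                             tol = min_bl)
      if (opt$objective > cur + 1e-12) {
        po$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (estimate_shape && model$n_categories > 1L) {
      so <- stats::optimize(function(a) {
        m2 <- model
        m2$gamma_shape <- a
        m2$rates <- discrete_gamma_rates(a, model$n_categories)
        sum(pattern_logliks(po, pat, m2) * pat$weights)
      }, c(0.05, 50), maximum = TRUE, tol = 1e-3)
      if (so$objective > cur + 1e-12) {
        model$gamma_shape <- so$maximum
        model$rates <- discrete_gamma_rates(so$maximum, model$n_categories)
        cur <- so$objective
      }
    }
    if (cur - prev < tol) break
  }
  out <- po
  attr(out, "loglik") <- cur
  if (estimate_shape) attr(out, "gamma_shape") <- model$gamma_shape
  out
}

# profile log-likelihood of branch (parent(v), v) as a function of its
# length, all else fixed
branch_profile <- function(tree, pat, model, v) {
  K <- length(model$rates)
  npat <- length(pat$weights)
  Gs <- vector("list", K); Ds <- vector("list", K); ls <- vector("list", K)
  for (k in seq_len(K)) {
    dp <- down_partials(tree, pat, model, model$rates[k])
    op <- outside_partials(tree, dp, model, model$rates[k])
    Gs[[k]] <- op$G[[v]]
    Ds[[k]] <- dp$partial[[v]]
    ls[[k]] <- op$logscale[[v]] + dp$logscale[[v]]
  }
  function(t) {
    percat <- vapply(seq_len(K), function(k) {
      lik <- colSums(Gs[[k]] * (transition_prob(model, t, model$rates[k]) %*%
                                  Ds[[k]]))
      log(lik) + ls[[k]]
    }, numeric(npat))
    if (is.null(dim(percat))) percat <- matrix(percat, nrow = 1)
    sum(log_mean_exp(t(percat)) * pat$weights)
  }
}

#' Simulate sequence evolution along a tree
#'
#' Draws root states from the model's equilibrium frequencies and evolves
#' them down every branch with the model's transition probabilities; each
#' site is assigned one gamma rate category.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param model a [rate_model()].
#' @param n_sites alignment length.
#' @param seed integer seed.
#' @return a [protein_alignment()] over the tree's tips.
#' @export
simulate_on_tree <- function(tree, model, n_sites, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n <- length(tree$tip.label)
  ntot <- n + tree$Nnode
  with_seed(seed, {
    cat_of <- sample.int(length(model$rates), n_sites, replace = TRUE)
    states <- matrix(NA_integer_, ntot, n_sites)
    states[n + 1L, ] <- sample.int(20, n_sites, replace = TRUE,
                                   prob = model$pi)
    po <- ape::reorder.phylo(tree, "postorder")
    for (e in rev(seq_len(nrow(po$edge)))) {  # preorder: parents first
      p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      for (k in unique(cat_of)) {
        P <- transition_prob(model, po$edge.length[e], model$rates[k])
        cp <- t(apply(P, 1L, cumsum))
        idx <- which(cat_of == k)
        u <- stats::runif(length(idx))
        parent_states <- states[p, idx]
        states[ch, idx] <- vapply(seq_along(idx), function(i) {
          sum(cp[parent_states[i], ] < u[i]) + 1L
        }, integer(1))
      }
    }
    m <- matrix(AA_ALPHABET[states[seq_len(n), ]], n, n_sites)
    rownames(m) <- tree$tip.label
    protein_alignment(m, "simulated", taxon = tree$tip.label)
  })
}

#' Site log-likelihood matrix over candidate topologies
#'
#' Evaluates each candidate tree on the same alignment (optionally
#' re-optimizing its branch lengths first) and stacks the per-site
#' log-likelihood rows into the matrix consumed by the topology test
#' battery. Patterns are compressed once and shared.
#'
#' @param trees named list of rooted [ape::phylo].
#' @param aln alignment or supermatrix.
#' @param model a [rate_model()].
#' @param optimize logical: optimize branch lengths per topology
#'   (default TRUE).
#' @param ... passed to [optimize_branch_lengths()].
#' @return object of class `site_loglik_matrix`: list with `loglik`
#'   (topologies x patterns), `weights`, `map`, `n_sites`, `total`.
#' @export
site_loglik_matrix <- function(trees, aln, model = rate_model(),
                               optimize = TRUE, ...) {
  stopifnot(length(trees) >= 1)
  if (is.null(names(trees)))
    names(trees) <- paste0("topology", seq_along(trees))
  rows <- lapply(trees, function(tr) {
    if (optimize) tr <- optimize_branch_lengths(tr, aln, model, ...)
    site_logliks(tr, aln, model)
  })
  first <- rows[[1]]
  ll <- do.call(rbind, lapply(rows, function(r) r$pattern_loglik))
  rownames(ll) <- names(trees)
  structure(list(loglik = ll, weights = first$weights, map = first$map,
                 n_sites = length(first$map),
                 total = vapply(rows, function(r) r$total, numeric(1))),
            class = "site_loglik_matrix")
}

#' Write site log-likelihoods in CONSEL-style plain-text layout
#'
#' One row per topology: topology index, number of sites, then the
#' per-site log-likelihoods (pattern values expanded to sites).
#'
#' @param m a [site_loglik_matrix()].
#' @param path output file.
#' @export
write_sitelik <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m$loglik), m$n_sites), con)
  for (i in seq_len(nrow(m$loglik)))
    writeLines(paste(c(rownames(m$loglik)[i],
                       formatC(m$loglik[i, m$map], digits = 10,
                               format = "g")), collapse = " "), con)
  invisible(path)
}
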