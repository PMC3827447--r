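#' Topology test configuration
#'
#' @param n_boot RELL bootstrap replicates per scale (default 10,000;
#'   at least 1,000 is recommended for reported p-values).
#' @param au_scales relative resample sizes for the multiscale bootstrap
#'   (default 0.5 to 1.4 by 0.1; must include 1).
#' @param seed integer seed for the replicate draws.
#' @param alpha nominal significance level used when printing (default
#'   0.05).
#' @export
test_config <- function(n_boot = 10000L,
                        au_scales = seq(0.5, 1.4, by = 0.1),
                        seed = 1L, alpha = 0.05) {
  stopifnot(n_boot >= 1, all(au_scales > 0),
            any(abs(au_scales - 1) < 1e-9))
  if (n_boot < 1000)
    warning("fewer than 1,000 replicates; p-values will be noisy")
  structure(list(n_boot = as.integer(n_boot), au_scales = au_scales,
                 seed = as.integer(seed), alpha = alpha),
            class = "test_config")
}

#' RELL bootstrap of site log-likelihoods
#'
#' Each replicate draws `ceiling(scale * n_sites)` sites with replacement
#' (pattern counts as weights) and sums the per-topology site
#' log-likelihoods -- resampling estimated log-likelihoods, no re-fitting.
#'
#' @param m a [site_loglik_matrix()].
#' @param scale relative resample size (default 1).
#' @param n number of replicates.
#' @param seed integer seed; the same seed reproduces the table.
#' @return `n` x `n_topologies` matrix of replicate total log-likelihoods.
#' @export
rell_resample <- function(m, scale = 1, n, seed = 1L) {
  stopifnot(nrow(m$loglik) >= 1, n >= 1, scale > 0)
  size <- ceiling(scale * m$n_sites)
  with_seed(seed, {
    counts <- stats::rmultinom(n, size, prob = m$weights / sum(m$weights))
    t(m$loglik %*% counts)
  })
}

#' Pairwise Kishino-Hasegawa RELL p-value
#'
#' One-sided KH test of topology `i` against a fixed comparator `j`:
#' the observed log-likelihood difference is compared to the centered
#' RELL bootstrap distribution of the same difference.
#'
#' @param m a [site_loglik_matrix()].
#' @param i index of the tested topology.
#' @param j index of the comparator topology.
#' @param n_boot replicates.
#' @param seed integer seed.
#' @return p-value in `[0, 1]`.
#' @export
kh_pvalue <- function(m, i, j, n_boot = 10000L, seed = 1L) {
  obs <- as.numeric(m$loglik %*% m$weights)
  reps <- rell_resample(m, 1, n_boot, seed)
  d <- reps[, j] - reps[, i]
  mean(d - mean(d) >= obs[j] - obs[i])
}

#' Run the CONSEL-style topology test battery
#'
#' Computes, per candidate topology: total log-likelihood and difference
#' from the best; the approximately unbiased test (AU) via multiscale RELL
#' bootstrap with a weighted-least-squares probit fit of the two-parameter
#' signed-distance/curvature model; bootstrap proportions BP (strict best
#' count at scale 1) and NP (tie-split, add-half smoothed); Bayesian
#' posterior probabilities PP (normalized exponentiated total
#' log-likelihoods); and the KH, SH, WKH and WSH tests from centered RELL
#' replicates. With a single fixed comparator, studentization cancels in
#' the pairwise test, so WKH numerically tracks KH; WSH differs from SH by
#' studentizing each pairwise difference inside the max-statistic.
#'
#' @param m a [site_loglik_matrix()] with at least two topologies.
#' @param cfg a [test_config()].
#' @return object of class `topo_test_result`: data.frame with one row per
#'   topology and columns `topology`, `lnl`, `delta`, `au`, `np`, `bp`,
#'   `pp`, `kh`, `sh`, `wkh`, `wsh`.
#' @export
run_battery <- function(m, cfg = test_config()) {
  k <- nrow(m$loglik)
  stopifnot(k >= 2)
  obs <- as.numeric(m$loglik %*% m$weights)
  best <- which.max(obs)
  delta <- obs[best] - obs

  reps <- rell_resample(m, 1, cfg$n_boot, cfg$seed)
  C <- sweep(reps, 2L, colMeans(reps))

  ## pairwise difference SDs for the weighted tests
  sdmat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j) sdmat[i, j] <- stats::sd(reps[, j] - reps[, i])
  sdmat[sdmat == 0] <- Inf  # identical rows: zero difference everywhere

  kh <- sh <- wkh <- wsh <- numeric(k)
  for (i in seq_len(k)) {
    d_obs <- obs[best] - obs[i]
    d_rep <- C[, best] - C[, i]
    kh[i] <- mean(d_rep >= d_obs)
    wkh[i] <- mean(d_rep / sdmat[i, best] >= d_obs / sdmat[i, best])
    oth <- setdiff(seq_len(k), i)
    s_obs <- max(obs[oth] - obs[i])
    s_rep <- apply(C[, oth, drop = FALSE] - C[, i], 1L, max)
    sh[i] <- mean(s_rep >= s_obs)
    ws_obs <- max((obs[oth] - obs[i]) / sdmat[i, oth])
    ws_rep <- apply(sweep(C[, oth, drop = FALSE] - C[, i], 2L,
                          sdmat[i, oth], "/"), 1L, max)
    wsh[i] <- mean(ws_rep >= ws_obs)
  }

  ## bootstrap proportions at scale 1
  win <- max.col(reps, ties.method = "first")
  bp <- tabulate(win, k) / cfg$n_boot
  ties <- reps == apply(reps, 1L, max)
  np_counts <- colSums(ties / rowSums(ties))
  np <- (np_counts + 0.5) / (cfg$n_boot + 1)

  ## posterior probabilities on total log-likelihoods
  pp <- exp(obs - max(obs))
  pp <- pp / sum(pp)

  au <- au_pvalues(m, cfg, k)

  structure(data.frame(topology = rownames(m$loglik), lnl = obs,
                       delta = delta, au = au, np = np, bp = bp, pp = pp,
                       kh = kh, sh = sh, wkh = wkh, wsh = wsh),
            class = c("topo_test_result", "data.frame"))
}

# AU p-values from the multiscale bootstrap
au_pvalues <- function(m, cfg, k) {
  scales <- cfg$au_scales
  bp_scale <- matrix(NA_real_, length(scales), k)
  for (s in seq_along(scales)) {
    reps <- rell_resample(m, scales[s], cfg$n_boot,
                          seed = cfg$seed + s)
    win <- max.col(reps, ties.method = "first")
    bp_scale[s, ] <- tabulate(win, k) / cfg$n_boot
  }
  vapply(seq_len(k), function(i) {
    bp <- bp_scale[, i]
    use <- bp > 0 & bp < 1
    if (sum(use) < 2) {
      warning("degenerate AU fit for topology ", i,
              "; p clamped to its bootstrap proportion limit")
      return(if (mean(bp) > 0.5) 1 else 0)
    }
    sq <- sqrt(scales[use])
    y <- -stats::qnorm(bp[use])               # = d*sqrt(s) + c/sqrt(s)
    w <- cfg$n_boot * stats::dnorm(stats::qnorm(bp[use]))^2 /
      (bp[use] * (1 - bp[use]))
    X <- cbind(sq, 1 / sq)
    fit <- stats::lm.wfit(X, y, w)
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    min(1, max(0, stats::pnorm(-d + cc)))
  }, numeric(1))
}

#' @export
print.topo_test_result <- function(x, digits = 4, ...) {
  cat("topology test battery (RELL bootstrap):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write a topology test result as a tab-delimited table
#' @param res a `topo_test_result`.
#' @param path output file.
#' @export
write_topotest <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
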