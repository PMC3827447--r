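test_that("rate models are valid reversible generators", {
  for (nm in c("wag", "poisson")) {
    mdl <- rate_model(nm, n_categories = 1)
    expect_equal(sum(mdl$pi), 1)
    expect_equal(rowSums(mdl$Q), rep(0, 20), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # unit expected rate and detailed balance
    expect_equal(-sum(mdl$pi * diag(mdl$Q)), 1, tolerance = 1e-12)
    expect_equal(mdl$pi * mdl$Q, t(mdl$pi * mdl$Q), tolerance = 1e-12)
    P <- transition_prob(mdl, 0.37)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
})

test_that("discrete gamma category means average to one", {
  for (shape in c(0.3, 1, 5)) {
    r <- discrete_gamma_rates(shape, 4)
    expect_length(r, 4)
    expect_equal(mean(r), 1, tolerance = 1e-10)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(discrete_gamma_rates(1, 1), 1)
})

test_that("degenerate limits give the closed-form likelihood", {
  mdl <- rate_model("wag", n_categories = 4)
  tr <- ape::read.tree(text = "(A:0,B:0);")
  aln <- protein_alignment(matrix("A", 2, 1,
                                  dimnames = list(c("A", "B"), NULL)), "x")
  expect_equal(site_logliks(tr, aln, mdl)$total,
               log(unname(mdl$pi["A"])), tolerance = 1e-9)
})

test_that("two-tip likelihood equals the matrix-exponential closed form", {
  mdl <- rate_model("wag", n_categories = 1)
  tr <- ape::read.tree(text = "(A:0.3,B:0.5);")
  P <- as.matrix(Matrix::expm(mdl$Q * 0.8))
  for (pair in list(c("A", "W"), c("C", "C"), c("R", "V"))) {
    aln <- protein_alignment(matrix(pair, 2, 1,
                                    dimnames = list(c("A", "B"), NULL)), "x")
    want <- log(mdl$pi[pair[1]] * P[match(pair[1], AA_ALPHABET),
                                    match(pair[2], AA_ALPHABET)])
    expect_equal(site_logliks(tr, aln, mdl)$total, unname(want),
                 tolerance = 1e-10)
  }
})

test_that("pruning equals state enumeration on small random trees", {
  set.seed(21)
  for (i in 1:6) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", 1:n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
    mdl <- rate_model(sample(c("wag", "poisson"), 1), n_categories = 1)
    states <- sample.int(20, n, replace = TRUE)
    m <- matrix(AA_ALPHABET[states], n, 1, dimnames = list(tr$tip.label,
                                                           NULL))
    got <- site_logliks(tr, protein_alignment(m, "x"), mdl)$total
    want <- oracle_site_loglik(tr, states, mdl)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under re-rooting", {
  mdl <- rate_model("wag", gamma_shape = 0.8, n_categories = 4)
  tr <- ape::read.tree(
    text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.2);")
  aln <- simulate_on_tree(tr, mdl, 80, seed = 3)
  base <- site_logliks(tr, aln, mdl)$total
  rerooted <- ape::root(ape::unroot(tr), outgroup = "C",
                        resolve.root = TRUE)
  expect_equal(site_logliks(rerooted, aln, mdl)$total, base,
               tolerance = 1e-8)
})

test_that("pattern compression does not change the likelihood", {
  mdl <- rate_model("poisson", n_categories = 2)
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.2);")
  m <- matrix(c("A", "A", "C",
                "A", "A", "C",
                "W", "V", "W"), 3, 3, byrow = FALSE,
              dimnames = list(c("A", "B", "C"), NULL))
  sl <- site_logliks(tr, protein_alignment(m, "x"), mdl)
  # columns 1 and 2 are the same pattern
  expect_length(sl$pattern_loglik, 2)
  expect_equal(sl$weights, c(2L, 1L))
  expect_equal(sum(sl$site_loglik), sl$total)
  expect_equal(sl$site_loglik[1], sl$site_loglik[2])
})

test_that("gaps and ambiguity codes are fully missing data", {
  mdl <- rate_model("wag", n_categories = 1)
  tr <- ape::read.tree(text = "(A:0.2,B:0.4);")
  for (ch in c("-", "?", "X")) {
    m <- matrix(c("A", ch), 2, 1, dimnames = list(c("A", "B"), NULL))
    expect_equal(site_logliks(tr, protein_alignment(m, "x"), mdl)$total,
                 log(unname(mdl$pi["A"])), tolerance = 1e-10)
  }
  expect_error(site_logliks(tr, protein_alignment(
    matrix("A", 1, 1, dimnames = list("A", NULL)), "x"), mdl),
    "absent")
})

test_that("invariant alignments drive branch lengths to the floor", {
  mdl <- rate_model("poisson", n_categories = 1)
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.2);")
  m <- matrix("A", 3, 30, dimnames = list(c("A", "B", "C"), NULL))
  opt <- optimize_branch_lengths(tr, protein_alignment(m, "x"), mdl)
  expect_true(all(opt$edge.length <= 1e-6))
  # deterministic: same start, same result
  opt2 <- optimize_branch_lengths(tr, protein_alignment(m, "x"), mdl)
  expect_identical(opt$edge.length, opt2$edge.length)
})

test_that("branch optimization never decreases the log-likelihood", {
  mdl <- rate_model("wag", n_categories = 1)
  tr <- ape::read.tree(
    text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.2);")
  aln <- simulate_on_tree(tr, mdl, 200, seed = 8)
  start <- tr
  start$edge.length <- rep(0.5, nrow(tr$edge))
  before <- site_logliks(start, aln, mdl)$total
  opt <- optimize_branch_lengths(start, aln, mdl)
  expect_gte(attr(opt, "loglik"), before)
  expect_equal(attr(opt, "loglik"), site_logliks(opt, aln, mdl)$total,
               tolerance = 1e-8)
})

test_that("simulation on a tree is seed-reproducible", {
  mdl <- rate_model("wag", n_categories = 4)
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.2);")
  expect_identical(simulate_on_tree(tr, mdl, 50, seed = 5),
                   simulate_on_tree(tr, mdl, 50, seed = 5))
})

test_that("site log-likelihood matrices stack topologies consistently", {
  mdl <- rate_model("poisson", n_categories = 1)
  trees <- list(one = ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.2);"),
                two = ape::read.tree(text = "((A:0.2,C:0.3):0.1,B:0.2);"))
  aln <- simulate_on_tree(trees$one, mdl, 60, seed = 2)
  slm <- site_loglik_matrix(trees, aln, mdl, optimize = FALSE)
  expect_equal(rownames(slm$loglik), c("one", "two"))
  expect_equal(sum(slm$weights), 60)
  expect_equal(unname(slm$total),
               unname(as.numeric(slm$loglik %*% slm$weights)))
  f <- withr::local_tempfile(fileext = ".txt")
  write_sitelik(slm, f)
  expect_equal(readLines(f)[1], "2 60")
})
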