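test_that("degenerate defect-free config yields complete clean loci", {
  cfg <- sim_config(n_taxa = 6, n_loci = 10, mean_locus_len = 150,
                    recovery_prob = 1, paralog_rate = 0,
                    lead_ambiguity_rate = 0, gap_region_rate = 0,
                    fragment_rate = 0, seed = 7)
  alns <- simulate_ortholog_set(cfg)
  expect_length(alns, 10)
  for (a in alns) {
    expect_equal(nrow(a$mat), 6)
    expect_false(any(a$mat == "X"))
    expect_false(any(a$mat == "-"))
    expect_true(all(vapply(a$meta, function(m) length(m$defects) == 0,
                           logical(1))))
  }
})

test_that("the same seed reproduces the ortholog set exactly", {
  cfg <- sim_config(n_taxa = 8, n_loci = 15, mean_locus_len = 120,
                    recovery_prob = 0.9, seed = 1)
  expect_identical(simulate_ortholog_set(cfg), simulate_ortholog_set(cfg))
  cfg2 <- cfg; cfg2$seed <- 2L
  expect_false(identical(simulate_ortholog_set(cfg),
                         simulate_ortholog_set(cfg2)))
})

test_that("paralog injection rate matches its binomial expectation", {
  cfg <- sim_config(n_taxa = 8, n_loci = 1000, mean_locus_len = 120,
                    recovery_prob = 1, paralog_rate = 0.1,
                    lead_ambiguity_rate = 0, gap_region_rate = 0,
                    fragment_rate = 0, seed = 99)
  alns <- simulate_ortholog_set(cfg)
  has_paralog <- vapply(alns, function(a)
    any(grepl("paralog", defect_labels(a)$defects)), logical(1))
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_lt(abs(mean(has_paralog) - 0.1), 3 * se)
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(sim_config(n_taxa = 3), "n_taxa")
  expect_error(sim_config(mean_locus_len = 50), "mean_locus_len")
  expect_error(sim_config(paralog_rate = 1.5), "paralog_rate")
  expect_error(sim_config(recovery_prob = -0.1), "recovery_prob")
})

test_that("study defaults match the published dataset shape", {
  cfg <- sim_config()
  expect_equal(cfg$n_loci, 1005L)
  expect_equal(cfg$taxa, STUDY_TAXA)
  # recovery of the EST taxon is the sparsest, the reference taxon always 1
  expect_equal(cfg$recovery_prob[match("Daphnia", cfg$taxa)], 1)
  expect_lt(cfg$recovery_prob[match("Archispirostreptus", cfg$taxa)], 0.2)
})

test_that("ortholog sets round-trip through per-locus FASTA", {
  cfg <- sim_config(n_taxa = 5, n_loci = 3, mean_locus_len = 110,
                    recovery_prob = 1, seed = 4)
  alns <- simulate_ortholog_set(cfg)
  dir <- withr::local_tempdir()
  write_ortholog_set(alns, dir)
  back <- read_ortholog_set(dir)
  expect_equal(names(back), names(alns))
  for (nm in names(alns))
    expect_equal(back[[nm]]$mat, alns[[nm]]$mat)
})

test_that("reference topology encodes the recovered clades", {
  tr <- millipede_topology()
  cl <- millipede_clades()
  expect_setequal(tr$tip.label, STUDY_TAXA)
  for (nm in names(cl)) {
    node <- ape::getMRCA(tr, cl[[nm]])
    expect_setequal(ape::extract.clade(tr, node)$tip.label, cl[[nm]])
  }
  # Stemmiulida sister to Juliformia: their MRCA excludes Prostemmiulus
  jf <- ape::extract.clade(tr, ape::getMRCA(tr, c("Cambala",
                                                  "Archispirostreptus")))
  expect_false("Prostemmiulus" %in% jf$tip.label)
  # Coelocheta excludes the polydesmidan exemplar
  cc <- ape::extract.clade(tr, ape::getMRCA(tr, c("Abacion", "Cleidogona")))
  expect_false("Pseudopolydesmus" %in% cc$tip.label)
})

test_that("topology round-trips through Newick", {
  tr <- millipede_topology()
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
})

test_that("character codings match the ordinal morphology", {
  ch <- millipede_characters()
  expect_equal(unname(ch$gonopods$states["Glomeridesmus"]), 0L)
  expect_equal(unname(ch$gonopods$states["Petaserpes"]), 1L)
  expect_equal(unname(ch$gonopods$states["Cambala"]), 2L)
  expect_equal(unname(ch$ozopores$states["Cleidogona"]), 0L)
  expect_equal(unname(ch$ozopores$states["Brachycybe"]), 1L)
  expect_equal(unname(ch$spinnerets$states["Cambala"]), 0L)
  expect_equal(unname(ch$spinnerets$states["Prostemmiulus"]), 1L)
  # outgroups carry none of the millipede character states
  for (c in ch)
    expect_true(all(c$states[c("Ixodes", "Daphnia", "Lithobius")] == 0L))
})
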