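two_locus_set <- function() {
  a <- protein_alignment(matrix("A", 3, 120,
                                dimnames = list(c("t1", "t2", "t3"), NULL)),
                         "locB")
  b <- protein_alignment(matrix("C", 2, 150,
                                dimnames = list(c("t1", "t2"), NULL)),
                         "locA")
  list(a, b)
}

test_that("concatenation tiles partitions and fills absent taxa with ?", {
  sm <- concatenate(two_locus_set())
  expect_equal(ncol(sm$mat), 270)
  # loci ordered lexicographically: locA first
  expect_equal(sm$partitions$locus, c("locA", "locB"))
  expect_equal(sm$partitions$start, c(1, 151))
  expect_equal(sm$partitions$end, c(150, 270))
  # t3 absent from locA: 150 '?' in partition 1
  expect_true(all(sm$mat["t3", 1:150] == "?"))
  expect_true(all(sm$mat["t3", 151:270] == "A"))
  expect_error(concatenate(list()), "no alignments")
  dup <- protein_alignment(matrix("A", 2, 5), "x", taxon = c("t1", "t1"))
  expect_error(concatenate(list(dup)), "duplicate taxon")
})

test_that("concatenate then split recovers the input loci cell-for-cell", {
  alns <- two_locus_set()
  back <- split_partitions(concatenate(alns))
  expect_equal(back[[1]]$locus, "locA")
  expect_equal(unname(back[[2]]$mat), unname(alns[[1]]$mat))
  expect_equal(unname(back[[1]]$mat), unname(alns[[2]]$mat))
})

test_that("matrix statistics count gaps and missing with the conservation
          identity", {
  m <- matrix("A", 3, 10, dimnames = list(c("t1", "t2", "t3"), NULL))
  m[1, 1:2] <- "-"; m[2, 3] <- "X"; m[3, 4:5] <- "?"
  sm <- structure(list(taxa = rownames(m), mat = m,
                       partitions = data.frame(locus = "L", start = 1,
                                               end = 10)),
                  class = "supermatrix")
  st <- matrix_stats(sm)
  expect_equal(st$n_gap, 2)
  expect_equal(st$n_missing, 3)
  expect_equal(st$pct_gap, round(100 * 2 / 30, 2))
  # no gaps and no missing: 0.00 / 0.00
  sm0 <- structure(list(taxa = c("a", "b"),
                        mat = matrix("A", 2, 5),
                        partitions = data.frame(locus = "L", start = 1,
                                                end = 5)),
                   class = "supermatrix")
  st0 <- matrix_stats(sm0)
  expect_identical(c(st0$pct_gap, st0$pct_missing), c(0, 0))
})

test_that("matrix statistics are invariant to taxon and locus order", {
  set.seed(8)
  alns <- lapply(1:4, function(i) {
    n <- sample(3:5, 1)
    m <- matrix(sample(c(AA_ALPHABET, "-"), n * 30, TRUE), n, 30)
    rownames(m) <- sample(paste0("t", 1:5), n)
    protein_alignment(m, paste0("loc", i))
  })
  taxa <- paste0("t", 1:5)
  s1 <- matrix_stats(concatenate(alns, taxa))
  s2 <- matrix_stats(concatenate(rev(alns), rev(taxa)))
  expect_equal(s1$n_gap, s2$n_gap)
  expect_equal(s1$n_missing, s2$n_missing)
  expect_equal(s1$mean_inclusion_pct, s2$mean_inclusion_pct)
})

test_that("published matrix counts reproduce the printed percentages", {
  counts <- millipede_study_counts()
  post <- do.call(stats_from_counts, counts$matrix_post[c(
    "n_loci", "n_columns", "n_taxa", "n_gap", "n_missing")])
  expect_identical(post$pct_gap, 7.20)
  expect_identical(post$pct_missing, 10.16)
  pre <- do.call(stats_from_counts, counts$matrix_pre[c(
    "n_loci", "n_columns", "n_taxa", "n_gap", "n_missing")])
  expect_identical(pre$pct_gap, 28.02)
  expect_identical(pre$pct_missing, 28.73)
  red <- inclusion_report(pre, post)
  expect_identical(red$pct_size_retained, 11.59)
  expect_identical(red$gap_reduction_points, 20.82)
  expect_identical(red$missing_reduction_points, 18.57)
  # identical pre/post: 100% retained, zero-point reductions
  same <- inclusion_report(post, post)
  expect_identical(same$pct_size_retained, 100.00)
  expect_identical(same$gap_reduction_points, 0)
  expect_error(inclusion_report(stats_from_counts(1, 0, 12, 0, 0), post))
})

test_that("inclusion summaries reproduce the printed per-taxon levels", {
  counts <- millipede_study_counts()
  pre <- taxon_inclusion_summary(
    stats::setNames(counts$inclusion$pre, counts$inclusion$taxon), 1005)
  expect_identical(pre$percent[pre$taxon == "Lithobius"], 87.36)
  post <- taxon_inclusion_summary(
    stats::setNames(counts$inclusion$post, counts$inclusion$taxon), 221)
  expect_identical(attr(post, "mean_pct"), 88.15)
  expect_error(taxon_inclusion_summary(c(a = 5), 4))
})

test_that("coverage summaries reproduce the printed CEG percentages", {
  counts <- millipede_study_counts()
  cov <- coverage_summary(counts$ceg$counts, counts$ceg$ceg_total)
  expect_identical(cov$complete_pct[cov$taxon == "Brachycybe"], 81.85)
  expect_identical(cov$complete_pct[cov$taxon == "Mean"], 57.48)
  expect_identical(cov$complete[cov$taxon == "Mean"], 142.56)
  expect_error(coverage_summary(data.frame(taxon = "x", complete = 300,
                                           partial = 0), 248))
})

test_that("sequencing summary reproduces the printed means", {
  sumr <- sequencing_summary(millipede_study_counts()$sequencing)
  expect_identical(sumr$mean_retention_pct, 74.18)
  expect_identical(sumr$mean_contigs, 17833.44)
  expect_identical(sumr$mean_orthologs, 810.11)
})

test_that("supermatrix writers emit FASTA, PHYLIP and partition lines", {
  sm <- concatenate(two_locus_set())
  fa <- withr::local_tempfile(fileext = ".fasta")
  pp <- withr::local_tempfile(fileext = ".txt")
  write_supermatrix(sm, fa, "fasta", partition_path = pp)
  lines <- readLines(pp)
  expect_equal(lines[1], "WAG, locA = 1-150")
  fasta <- readLines(fa)
  expect_equal(fasta[seq(1, length(fasta), by = 2)],
               paste0(">", sm$taxa))
  expect_equal(nchar(fasta[2]), 270)
  ph <- withr::local_tempfile(fileext = ".phy")
  write_supermatrix(sm, ph, "phylip")
  expect_equal(readLines(ph)[1], "3 270")
})
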