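test_that("leading ambiguity is gapped through the last in-window X", {
  aln <- make_aln(paste0("AXAAX", strrep("M", 15)),
                  strrep("M", 20))
  out <- trim_leading_ambiguity(aln, 20)
  expect_equal(paste(out$mat[1, 1:5], collapse = ""), "-----")
  expect_equal(paste(out$mat[1, 6:20], collapse = ""), strrep("M", 15))
  expect_equal(out$mat[2, ], aln$mat[2, ])  # untouched row

  # X beyond the window is ignored
  s <- paste0(strrep("A", 24), "X", strrep("A", 5))
  aln2 <- make_aln(s, strrep("C", 30))
  expect_equal(trim_leading_ambiguity(aln2, 20)$mat, aln2$mat)
  # no X at all: no-op
  aln3 <- make_aln(strrep("W", 30), strrep("C", 30))
  expect_equal(trim_leading_ambiguity(aln3, 20)$mat, aln3$mat)
  # alignment length is never changed
  expect_equal(dim(trim_leading_ambiguity(aln, 20)$mat), dim(aln$mat))
})

test_that("consensus is plurality with alphabetical tie-break", {
  ident <- make_aln("ACD", "ACD", "ACD")
  expect_equal(consensus(ident), c("A", "C", "D"))
  # {A:2, V:1, -:1} -> A ; {A:1, V:1} -> A ; all-gap -> '-'
  aln <- make_aln("AV-", "AA-", "VA-", "-A-")
  expect_equal(consensus(aln), c("A", "A", "-"))
})

test_that("divergence filter removes at 75% and keeps below it", {
  base <- strrep("A", 100)
  div80 <- paste0(strrep("C", 80), strrep("A", 20))
  div74 <- paste0(strrep("C", 74), strrep("A", 26))
  aln <- make_aln(base, base, base, div80)
  out <- remove_divergent(aln, 0.75)
  expect_equal(attr(out, "removed"), "t4")
  expect_equal(nrow(out$mat), 3)

  aln2 <- make_aln(base, base, base, div74)
  out2 <- remove_divergent(aln2, 0.75)
  expect_length(attr(out2, "removed"), 0)

  # identical sequences: nothing removed
  out3 <- remove_divergent(make_aln(base, base), 0.75)
  expect_length(attr(out3, "removed"), 0)

  # zero comparable columns (an all-gap sequence): removed and reported
  aln4 <- make_aln("AAAA", "AAAA", "----")
  out4 <- remove_divergent(aln4, 0.75)
  expect_equal(attr(out4, "removed"), "t3")
})

test_that("constructed paralogs are removed and mild divergence is kept", {
  # sequences at controlled divergence from a uniform consensus
  set.seed(12)
  L <- 200
  cons <- sample(AA_ALPHABET, L, replace = TRUE)
  at_divergence <- function(d) {
    s <- cons
    flip <- sample(L, round(d * L))
    s[flip] <- vapply(s[flip], function(r)
      sample(setdiff(AA_ALPHABET, r), 1), character(1))
    paste(s, collapse = "")
  }
  for (d_hi in c(0.80, 0.90, 1.00)) {
    aln <- make_aln(paste(cons, collapse = ""), paste(cons, collapse = ""),
                    paste(cons, collapse = ""), at_divergence(0.3),
                    at_divergence(0.5), at_divergence(d_hi))
    out <- remove_divergent(aln, 0.75)
    expect_identical(attr(out, "removed"), "t6")  # only the paralog-like row
  }
})

test_that("all-gap and singleton columns are deleted, order preserved", {
  aln <- make_aln("A-A-C", "A---C", "A--AC")
  out <- drop_uninformative_columns(aln)
  # col2 all gaps, col3 singleton A, col4 singleton A -> dropped
  expect_equal(ncol(out$mat), 2)
  expect_equal(out$mat[1, ], c("A", "C"))
  # two residues survive
  aln2 <- make_aln("AA", "A-", "A-")
  expect_equal(ncol(drop_uninformative_columns(aln2)$mat), 1)
})

test_that("representative selection merges disjoint fragments and keeps the
          longest overlapping copy", {
  frag1 <- paste0(strrep("A", 50), strrep("-", 70))
  frag2 <- paste0(strrep("-", 60), strrep("C", 60))
  m <- rbind(strsplit(frag1, "")[[1]], strsplit(frag2, "")[[1]],
             rep("G", 120))
  rownames(m) <- c("tax1|f1", "tax1|f2", "tax2")
  aln <- protein_alignment(m, "L", taxon = c("tax1", "tax1", "tax2"))
  out <- representative_per_taxon(aln)
  expect_equal(nrow(out$mat), 2)
  merged <- out$mat["tax1", ]
  expect_equal(paste(merged[1:50], collapse = ""), strrep("A", 50))
  expect_equal(paste(merged[61:120], collapse = ""), strrep("C", 60))
  expect_true(all(merged[51:60] == "-"))

  # overlapping copies: maximal non-gap coverage wins
  long <- strrep("A", 120)
  short <- paste0(strrep("C", 90), strrep("-", 30))
  m2 <- rbind(strsplit(long, "")[[1]], strsplit(short, "")[[1]])
  rownames(m2) <- c("tax1|a", "tax1|b")
  aln2 <- protein_alignment(m2, "L", taxon = c("tax1", "tax1"))
  expect_equal(unname(representative_per_taxon(aln2)$mat[1, 1]), "A")

  # single sequence per taxon: unchanged content
  aln3 <- make_aln(strrep("A", 10), strrep("C", 10), taxa = c("x", "y"))
  expect_equal(unname(representative_per_taxon(aln3)$mat),
               unname(aln3$mat))
})

test_that("length and occupancy filters apply the study thresholds", {
  cfg <- curation_config()
  wide <- function(tax, res, n) {
    m <- matrix(res, length(tax), n)
    rownames(m) <- tax
    protein_alignment(m, paste0("L", n), taxon = tax)
  }
  # a 99-residue sequence is removed, a 100-residue one kept
  a <- wide(paste0("t", 1:11), "A", 100)
  a$mat[1, 100] <- "-"  # t1 drops to 99 non-gap residues
  res <- apply_length_and_occupancy(list(a), cfg)
  expect_equal(res$report$sequences_removed[1], 1)
  expect_length(res$alignments, 0)  # 10 taxa remain < 11

  # 100 columns, 11 taxa: retained
  b <- wide(paste0("t", 1:11), "A", 100)
  res2 <- apply_length_and_occupancy(list(b), cfg)
  expect_length(res2$alignments, 1)

  # 99 columns: locus deleted
  c99 <- wide(paste0("t", 1:11), "A", 99)
  res3 <- apply_length_and_occupancy(list(c99), cfg)
  expect_length(res3$alignments, 0)
  expect_equal(res3$report$loci_removed[2], 1)
})
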