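test_that("occupancy filter retains exactly the all-taxa alignments", {
  taxa <- paste0("sp", 1:6)
  full <- gene_alignment("og1", setNames(rep("ACGTAC", 6), taxa))
  partial <- gene_alignment("og2", setNames(rep("ACGTAC", 5), taxa[-3]))
  kept <- occupancy_filter(list(full, partial), taxa)
  expect_equal(vapply(kept, `[[`, character(1), "id"), "og1")
  # order preserved
  kept2 <- occupancy_filter(list(partial, full, full), taxa)
  expect_equal(length(kept2), 2L)
  expect_equal(occupancy_filter(list(), taxa), list())
  expect_error(occupancy_filter(list(full), character(0)), "non-empty")
})

test_that("RF distance matches hand-enumerated bipartitions", {
  t1 <- toy_tree("((A,B),(C,D),E);")
  t2 <- toy_tree("((A,C),(B,D),E);")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 4L)
  # pruning consistency: distance on the shared set equals the distance of
  # the manually pruned pair
  t3 <- toy_tree("(((A,B),(C,D)),(E,F));")
  t4 <- toy_tree("(((A,C),(B,D)),E);")        # F missing
  manual <- rf_distance(ape::drop.tip(t3, "F"), t4)
  expect_equal(rf_distance(t3, t4), manual)
  expect_error(rf_distance(toy_tree("((A,B),C);"),
                           toy_tree("((A,B),C);")), "4 shared")
})

test_that("RF distance agrees with the bipartition-enumeration oracle", {
  set.seed(8)
  for (n in c(6L, 9L, 12L)) {
    for (rep in 1:4) {
      t1 <- ape::rtree(n, tip.label = paste0("s", 1:n))
      t2 <- ape::rtree(n, tip.label = paste0("s", 1:n))
      expect_equal(rf_distance(t1, t2), oracle_rf(t1, t2))
    }
  }
})

test_that("RF behaves as a metric on shared-taxon topologies", {
  set.seed(13)
  n <- 8L
  for (rep in 1:4) {
    ts <- replicate(3, ape::rtree(n, tip.label = paste0("s", 1:n)),
                    simplify = FALSE)
    d12 <- rf_distance(ts[[1]], ts[[2]])
    d21 <- rf_distance(ts[[2]], ts[[1]])
    d13 <- rf_distance(ts[[1]], ts[[3]])
    d23 <- rf_distance(ts[[2]], ts[[3]])
    expect_equal(d12, d21)                       # symmetry
    expect_lte(d13, d12 + d23)                   # triangle inequality
  }
})

test_that("the RF threshold rule discards at-or-above-threshold trees", {
  ref <- toy_tree("((A,B),(C,D),(E,F));")
  near <- toy_tree("((A,C),(B,D),(E,F));")       # RF 4
  far <- toy_tree("((A,E),(C,B),(D,F));")        # RF 6
  res <- filter_by_rf(list(og_near = near, og_far = far, og_same = ref),
                      ref, threshold = 6)
  expect_setequal(res$retained, c("og_near", "og_same"))
  expect_equal(res$discarded, "og_far")
  expect_equal(res$report$rf[res$report$id == "og_near"], 4L)
  expect_equal(res$report$rf[res$report$id == "og_far"], 6L)
  # exactly-at-threshold is discarded
  res4 <- filter_by_rf(list(og_near = near), ref, threshold = 4)
  expect_equal(res4$discarded, "og_near")
  # a tree with too few shared taxa is discarded with a reason
  tiny <- toy_tree("((A,B),G,H);")
  res5 <- filter_by_rf(list(bad = tiny), ref)
  expect_equal(res5$discarded, "bad")
  expect_match(res5$report$reason[1], "shared taxa")
})

test_that("third-position stripping removes columns 3, 6, 9, ...", {
  aln <- gene_alignment("og", c(s1 = "ATGGCA", s2 = "ATGGCT"),
                        codon_aligned = TRUE)
  out <- strip_third_positions(aln)
  expect_equal(paste(out$mat["s1", ], collapse = ""), "ATGC")
  expect_equal(ncol(out$mat), 4L)
  expect_false(out$codon_aligned)
  # all-gap third positions equal manual column removal
  aln2 <- gene_alignment("og2", c(s1 = "AT-GC-", s2 = "AT-GC-"),
                        codon_aligned = TRUE)
  expect_equal(paste(strip_third_positions(aln2)$mat["s1", ],
                     collapse = ""), "ATGC")
  expect_error(strip_third_positions(gene_alignment("x", c(a = "ACGT"))),
               "not codon-aligned")
  # composed column-count formula: 9 -> 6 -> 4
  a9 <- gene_alignment("og3", c(s1 = "ACGTACGTA"), codon_aligned = TRUE)
  s1 <- strip_third_positions(a9)
  expect_equal(ncol(s1$mat), 6L)
  s2 <- strip_third_positions(gene_alignment("og3b", s1$mat,
                                             codon_aligned = TRUE))
  expect_equal(ncol(s2$mat), 4L)
})

test_that("concatenation arithmetic, partitions and descriptor are exact", {
  g1 <- gene_alignment("og1", c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC"))
  g2 <- gene_alignment("og2", c(a = "ACGTACGTA", b = "ACGTACGTA"))
  sm <- concatenate_alignments(list(g1, g2))
  expect_equal(sm$n_char, 15L)
  expect_equal(sm$partitions$start, c(1L, 7L))
  expect_equal(sm$partitions$end, c(6L, 15L))
  expect_equal(sm$completeness, 100 * (3 * 6 + 2 * 9) / (3 * 15))
  expect_equal(paste(sm$mat["c", 7:15], collapse = ""), "?????????")
  expect_match(format(sm), "^80% complete DNA alignment of 3 taxa and 15 characters$")
  # single gene is the identity
  sm1 <- concatenate_alignments(list(g1))
  expect_equal(sm1$mat, g1$mat, ignore_attr = TRUE)
  expect_equal(sm1$completeness, 100)
  expect_error(concatenate_alignments(list(g1, g1)), "duplicate")
  # partition file format
  f <- withr::local_tempfile()
  write_partitions(sm, f)
  expect_equal(readLines(f), c("DNA, og1 = 1-6", "DNA, og2 = 7-15"))
})

test_that("FASTA round trip preserves sequences", {
  g <- gene_alignment("og1", c(sp1 = "ACGT-CA?N", sp2 = "ACGTTCAGN"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, f)
  g2 <- read_gene_alignment(f, id = "og1")
  expect_equal(g2$mat, g$mat)
})
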