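test_that("simulated chronograms are ultrametric, sized and reproducible", {
  tr <- simulate_chronogram(29, birth_rate = 0.05, root_age = 120,
                            seed = 1)
  expect_equal(ape::Ntip(tr), 29L)
  expect_equal(tr$Nnode, 28L)
  expect_silent(validate_chronogram(tr))
  expect_equal(tree_height(tr), 120, tolerance = 1e-9)
  tr2 <- simulate_chronogram(29, birth_rate = 0.05, root_age = 120,
                             seed = 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr3 <- simulate_chronogram(29, birth_rate = 0.05, root_age = 120,
                             seed = 2)
  expect_false(identical(ape::write.tree(tr), ape::write.tree(tr3)))
})

test_that("Yule waiting times have the expected exponential means", {
  # with k lineages the unscaled inter-speciation interval is Exp(k b)
  set.seed(99)
  b <- 0.2
  n <- 6L
  reps <- 400L
  ints <- matrix(0, reps, n - 2L)
  for (r in seq_len(reps)) {
    tr <- simulate_chronogram(n, birth_rate = b, root_age = NULL)
    ages <- sort(unique(round(
      tree_height(tr) - ape::node.depth.edgelength(tr)[(n + 1L):(2L * n - 1L)],
      10)), decreasing = TRUE)
    times <- tree_height(tr) - ages       # speciation times from the root
    ints[r, ] <- diff(times)              # interval with k = 2, 3, ... lineages
  }
  for (k in 2:(n - 1L)) {
    m <- mean(ints[, k - 1L])
    se <- stats::sd(ints[, k - 1L]) / sqrt(reps)
    expect_lt(abs(m - 1 / (k * b)), 4 * se)
  }
})

test_that("zero-rate range simulation propagates the root singleton", {
  sp <- toy_space2()
  tr <- simulate_chronogram(12, root_age = 50, seed = 3)
  sim <- simulate_ranges(tr, dec_params(0, 0), sp, seed = 4)
  expect_equal(length(unique(sim$tip_ranges)), 1L)
  expect_true(unique(sim$tip_ranges) %in% c("A", "B"))
  expect_equal(sum(sim$branch_events$gains), 0L)
  expect_equal(sum(sim$branch_events$losses), 0L)
  expect_equal(sim$restarts, 0L)
})

test_that("range simulation is reproducible and records true histories", {
  sp <- build_state_space(area_set(), 2, include_null = FALSE)
  tr <- simulate_chronogram(20, root_age = 100, seed = 5)
  s1 <- simulate_ranges(tr, dec_params(0.02, 0.01), sp, seed = 6)
  s2 <- simulate_ranges(tr, dec_params(0.02, 0.01), sp, seed = 6)
  expect_identical(s1$tip_ranges, s2$tip_ranges)
  expect_identical(s1$node_states, s2$node_states)
  # tip rows of node_states are the emitted data
  expect_equal(unname(s1$node_states[seq_len(20)]),
               unname(s1$tip_ranges[tr$tip.label]))
  expect_true(all(s1$node_states %in% sp$labels))
})

test_that("simulated tip-pattern frequencies match the likelihood engine", {
  # simulator <-> likelihood cross-validation on a fixed 3-tip tree
  sp <- build_state_space(area_set(c("A", "B")), 2, include_null = FALSE)
  tr <- toy_tree("((t1:1,t2:1):1,t3:2);")
  p <- dec_params(0.15, 0.1)
  reps <- 2000L
  set.seed(7)
  pats <- character(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_ranges(tr, p, sp)
    pats[r] <- paste(sim$tip_ranges[c("t1", "t2", "t3")], collapse = "/")
  }
  freq <- table(pats) / reps
  # model probability: root drawn uniformly over singletons
  for (pat in names(freq)) {
    st <- strsplit(pat, "/", fixed = TRUE)[[1]]
    rng <- c(t1 = st[1], t2 = st[2], t3 = st[3])
    prob <- mean(c(
      exp(dec_loglik(tr, rng, p, sp, root = "conditional",
                     root_state = "A")),
      exp(dec_loglik(tr, rng, p, sp, root = "conditional",
                     root_state = "B"))))
    se <- sqrt(prob * (1 - prob) / reps)
    expect_lt(abs(freq[[pat]] - prob), max(4 * se, 0.01))
  }
})

test_that("discordant gene trees obey the NNI/RF relationship", {
  ref <- simulate_chronogram(12, root_age = 1, seed = 8)
  same <- simulate_discordant_genetrees(ref, 5, nni_moves = 0,
                                        missing_fraction = 0, seed = 9)
  for (gt in same) expect_equal(rf_distance(gt, ref), 0L)
  moved <- simulate_discordant_genetrees(ref, 10, nni_moves = 3,
                                         missing_fraction = 0, seed = 10)
  for (gt in moved) expect_lte(rf_distance(gt, ref), 2L * 3L)
  # single NNI moves displace at most one internal edge
  one <- simulate_discordant_genetrees(ref, 10, nni_moves = 1, seed = 11)
  for (gt in one) expect_lte(rf_distance(gt, ref), 2L)
  # missing taxa are dropped but at least 4 tips remain
  mis <- simulate_discordant_genetrees(ref, 5, nni_moves = 0,
                                       missing_fraction = 0.5, seed = 12)
  for (gt in mis) {
    expect_equal(ape::Ntip(gt), 6L)
    expect_true(all(gt$tip.label %in% ref$tip.label))
  }
  expect_error(simulate_discordant_genetrees(ref, 2, missing_fraction = 0.9),
               "missing_fraction")
})

pairwise_identity <- function(mat) {
  n <- nrow(mat)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(mat[i, ] == mat[j, ]); cnt <- cnt + 1
  }
  tot / cnt
}

test_that("codon alignments show elevated third-position divergence", {
  tr <- simulate_chronogram(8, root_age = 120, seed = 13)
  aln <- simulate_codon_alignment(tr, length_codons = 400,
                                  third_position_rate_multiplier = 5,
                                  seed = 14)
  expect_true(aln$codon_aligned)
  expect_equal(ncol(aln$mat), 1200L)
  i3 <- pairwise_identity(aln$mat[, seq(3, 1200, by = 3)])
  i12 <- pairwise_identity(aln$mat[, -seq(3, 1200, by = 3)])
  expect_lt(i3, i12)
  # stripping the saturated positions raises overall identity
  stripped <- strip_third_positions(aln)
  expect_gt(pairwise_identity(stripped$mat), pairwise_identity(aln$mat))
  # determinism
  a2 <- simulate_codon_alignment(tr, length_codons = 400,
                                 third_position_rate_multiplier = 5,
                                 seed = 14)
  expect_identical(aln$mat, a2$mat)
  # equal rates leave the positions statistically interchangeable
  flat <- simulate_codon_alignment(tr, length_codons = 400,
                                   third_position_rate_multiplier = 1,
                                   seed = 15)
  f3 <- pairwise_identity(flat$mat[, seq(3, 1200, by = 3)])
  f12 <- pairwise_identity(flat$mat[, -seq(3, 1200, by = 3)])
  expect_lt(abs(f3 - f12), 0.05)
})
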