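test_that("no events are counted when no events are possible", {
  sp <- toy_space2()
  tr <- toy_tree("((t1:1,t2:1)v:1,t3:2);")
  rng <- c(t1 = "A", t2 = "A", t3 = "A")
  em <- count_events(tr, rng, dec_params(0, 0), sp, node = "v",
                     n_maps = 50, seed = 1,
                     root = "conditional", root_state = "A")
  expect_equal(em$count, c(0L, 0L, 0L))
  expect_equal(em$expected, c(0, 0, 0))
})

test_that("a forced vicariant split counts exactly one vicariance", {
  sp <- toy_space2()
  tr <- toy_tree("(t1:1,t2:1)r;")
  rng <- c(t1 = "A", t2 = "B")
  # with d = e = 0 the only possible history is root AB splitting by
  # vicariance into A and B
  em <- count_events(tr, rng, dec_params(0, 0), sp, node = "r",
                     n_maps = 100, seed = 2)
  expect_equal(em$count[em$event == "vicariance"], 1L)
  expect_equal(em$count[em$event == "dispersal"], 0L)
  expect_equal(em$count[em$event == "extinction"], 0L)
  expect_equal(em$expected[em$event == "vicariance"], 1)
})

test_that("a forced founder event counts as dispersal in every map", {
  sp <- toy_space2()
  tr <- toy_tree("(t1:1,t2:1)r;")
  rng <- c(t1 = "A", t2 = "B")
  pj <- dec_params(0, 0, j = 1, family = "DEC", jump = TRUE)
  # root clamped to {A} and zero anagenetic rates: the (A, B) tip pair is
  # only reachable through a jump at the root's cladogenesis
  em <- count_events(tr, rng, pj, sp, node = "r", n_maps = 100, seed = 3,
                     root = "conditional", root_state = "A")
  expect_equal(em$count[em$event == "dispersal"], 1L)
  expect_equal(em$expected[em$event == "dispersal"], 1)
  expect_equal(em$count[em$event == "vicariance"], 0L)
})

test_that("a branch forced to switch areas yields both a gain and a loss", {
  sp <- toy_space2()
  tr <- toy_tree("((t1:1,t2:1)v:1,t3:2);")
  rng <- c(t1 = "B", t2 = "B", t3 = "A")
  p <- dec_params(0.05, 0.05)
  # root clamped to {A}: the subtending branch of v must gain B on the
  # way to state B or AB, so every sampled history has >= 1 dispersal;
  # the matching loss of A may fall on a daughter branch (outside the
  # focal window) when v is AB, so extinction is only sometimes seen
  em <- count_events(tr, rng, p, sp, node = "v", n_maps = 80, seed = 5,
                     root = "conditional", root_state = "A")
  expect_gte(em$count[em$event == "dispersal"], 1L)
  expect_gte(em$expected[em$event == "dispersal"], 1)
  expect_gt(em$expected[em$event == "extinction"], 0)
})

test_that("clado-only window drops subtending-branch events", {
  set.seed(77)
  sp <- toy_space3(max_range = 2L)
  tr <- simulate_chronogram(8, root_age = 40)
  sim <- simulate_ranges(tr, dec_params(0.03, 0.01), sp)
  node <- 8L + 2L                        # an internal node below the root
  p <- dec_params(0.03, 0.01)
  em_b <- count_events(tr, sim$tip_ranges, p, sp, node = node,
                       n_maps = 60, seed = 4)
  em_c <- count_events(tr, sim$tip_ranges, p, sp, node = node,
                       n_maps = 60, seed = 4, window = "clado")
  expect_true(all(em_c$expected[em_c$event == "extinction"] <=
                    em_b$expected[em_b$event == "extinction"] + 1e-12))
  expect_true(all(em_c$expected[em_c$event == "dispersal"] <=
                    em_b$expected[em_b$event == "dispersal"] + 1e-12))
})

test_that("stochastic branch histories match the analytic expectation", {
  sp <- toy_space3(max_range = 2L)
  Q <- build_rate_matrix(dec_params(0.05, 0.02), sp)
  a <- state_index(sp, "A")
  t <- 4
  set.seed(12)
  n_sim <- 4000
  gains <- numeric(n_sim); losses <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    h <- simulate_branch_history(a, t, Q)
    gains[i] <- h$gains; losses[i] <- h$losses
  }
  ex <- expected_branch_events(a, t, Q, sp)
  se_g <- stats::sd(gains) / sqrt(n_sim)
  se_l <- stats::sd(losses) / sqrt(n_sim)
  expect_lt(abs(mean(gains) - ex$gain), 3 * se_g)
  expect_lt(abs(mean(losses) - ex$loss), 3 * se_l)
})

test_that("event counting validates its inputs", {
  sp <- toy_space2()
  tr <- toy_tree("((t1:1,t2:1)v:1,t3:2);")
  rng <- c(t1 = "A", t2 = "A", t3 = "A")
  p <- dec_params(0.1, 0.05)
  expect_error(count_events(tr, rng, p, sp, node = "t1"), "internal")
  expect_error(count_events(tr, rng, p, sp, node = "v", n_maps = 0),
               "n_maps")
})
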