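test_that("degenerate zero-rate instances have probability one", {
  sp <- toy_space2()
  tr <- toy_tree("(A:1,B:1);")
  p0 <- dec_params(0, 0)
  expect_equal(dec_loglik(tr, c(A = "A", B = "A"), p0, sp,
                          root = "conditional", root_state = "A"), 0)
  # with no change possible, mismatching data are impossible
  expect_equal(dec_loglik(tr, c(A = "A", B = "B"), p0, sp,
                          root = "conditional", root_state = "A"), -Inf)
})

test_that("pruning equals history enumeration on small instances", {
  # the oracle enumerates cladogenetic scenarios and ancestral states with
  # an independent matrix exponential
  trees <- list(toy_tree("((A:1,B:1):1,C:2);"),
                toy_tree("((A:0.5,B:0.5):1.5,(C:1,D:1):1);"),
                toy_tree("(((A:1,B:1):1,C:2):1,D:3);"))
  spaces <- list(toy_space2(), toy_space3(),
                 toy_space3(max_range = 2L),
                 toy_space3(exclusions = "AC"))
  params <- list(dec_params(0.1, 0.05),
                 dec_params(0.3, 0.2, j = 0.7, family = "DEC", jump = TRUE),
                 dec_params(0.15, 0.1, family = "DIVALIKE"),
                 dec_params(0.2, 0.02, j = 1.5, family = "BAYAREALIKE",
                            jump = TRUE))
  set.seed(42)
  for (tr in trees) {
    for (sp in spaces) {
      labs <- sp$labels[nzchar(sp$labels)]
      rng <- sample(labs, ape::Ntip(tr), replace = TRUE)
      names(rng) <- tr$tip.label
      for (p in params) {
        lhs <- dec_loglik(tr, rng, p, sp)
        rhs <- log(oracle_dec_lik(tr, rng, p, sp))
        expect_equal(lhs, rhs, tolerance = 1e-8,
                     label = sprintf("%s+%s on %d tips", p$family,
                                     p$jump, ape::Ntip(tr)))
      }
    }
  }
})

test_that("the +J model with j = 0 reduces exactly to the base model", {
  set.seed(1)
  tr <- simulate_chronogram(8, root_age = 10)
  sp <- toy_space3()
  rng <- sample(sp$labels[nzchar(sp$labels)], 8, replace = TRUE)
  names(rng) <- tr$tip.label
  for (fam in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    base <- dec_params(0.05, 0.02, family = fam)
    pj <- dec_params(0.05, 0.02, j = 0, family = fam, jump = TRUE)
    expect_equal(dec_loglik(tr, rng, pj, sp),
                 dec_loglik(tr, rng, base, sp), tolerance = 1e-12)
  }
})

test_that("likelihood is invariant under relabeling of areas", {
  set.seed(5)
  tr <- simulate_chronogram(10, root_age = 50)
  sp <- toy_space3(max_range = 2L)
  labs <- sp$labels[nzchar(sp$labels)]
  rng <- sample(labs, 10, replace = TRUE)
  names(rng) <- tr$tip.label
  p <- dec_params(0.04, 0.01, j = 0.4, family = "DEC", jump = TRUE)
  l1 <- dec_loglik(tr, rng, p, sp)
  # permute A->B->C->A
  perm <- c(A = "B", B = "C", C = "A")
  rng2 <- vapply(rng, function(s) {
    ch <- perm[strsplit(s, "")[[1]]]
    paste(sort(ch), collapse = "")
  }, character(1))
  l2 <- dec_loglik(tr, rng2, p, sp)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("polytomies and uncoded tips are rejected with clear errors", {
  sp <- toy_space2()
  p <- dec_params(0.1, 0.05)
  poly <- toy_tree("((A:1,B:1,C:1):1,D:2);")
  expect_error(dec_loglik(poly, c(A = "A", B = "A", C = "B", D = "B"), p,
                          sp), "bifurcating")
  tr <- toy_tree("(A:1,B:1);")
  expect_error(dec_loglik(tr, c(A = "A"), p, sp), "without a range")
})

test_that("marginal reconstructions match clamped enumeration", {
  trees <- list(toy_tree("((A:1,B:1):1,C:2);"),
                toy_tree("((A:0.5,B:0.5):1.5,(C:1,D:1):1);"))
  sp <- toy_space3(max_range = 2L)
  labs <- sp$labels[nzchar(sp$labels)]
  set.seed(99)
  params <- list(dec_params(0.2, 0.1),
                 dec_params(0.1, 0.02, j = 1, family = "DEC", jump = TRUE))
  for (tr in trees) {
    nt <- ape::Ntip(tr)
    rng <- sample(labs, nt, replace = TRUE)
    names(rng) <- tr$tip.label
    for (p in params) {
      m <- ancestral_marginals(tr, rng, p, sp)
      for (v in (nt + 1L):(nt + tr$Nnode)) {
        exp_m <- oracle_dec_marginal(tr, rng, p, sp, v)
        expect_equal(unname(m[v, ]), exp_m, tolerance = 1e-8)
      }
      expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-9)
      expect_equal(unname(m[, 1L]), rep(0, nrow(m)))  # null range
    }
  }
})

test_that("symmetric two-tip instance gives a symmetric root marginal", {
  sp <- toy_space2()
  tr <- toy_tree("(A:1,B:1);")
  p <- dec_params(0.1, 0.05)
  m <- ancestral_marginals(tr, c(A = "A", B = "B"), p, sp)
  root <- m[3L, ]
  expect_equal(unname(root["A"]), unname(root["B"]), tolerance = 1e-10)
})
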