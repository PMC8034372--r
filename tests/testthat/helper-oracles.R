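# Independent reference implementations used as oracles.  These avoid the
# package's compiled pruning path: matrix exponentials by scaled Taylor
# series, likelihoods by explicit recursion over cladogenetic scenarios
# and ancestral states, RF distances by bipartition enumeration, and
# binary-character marginals by enumeration of all internal state
# assignments.

oracle_expm <- function(A, order = 24L) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 2L)
  As <- A / 2^s
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(order)) {
    term <- term %*% As / i
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# Total likelihood (and optionally one node's marginal) by explicit
# summation over cladogenetic scenarios and ancestral states.  `clamp`
# restricts the state at one node.
oracle_dec_lik <- function(tree, ranges, params, space,
                           root = "uniform", root_state = NULL,
                           clamp_node = NULL, clamp_state = NULL) {
  Q <- build_rate_matrix(params, space)
  scen <- decrange:::clado_probs(
    decrange:::clado_scenarios(space, params$family, params$jump),
    params$j)
  k <- space$k
  nt <- ape::Ntip(tree)
  edge <- tree$edge
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  Pm <- lapply(seq_len(nrow(edge)), function(e)
    oracle_expm(Q * tree$edge.length[e]))
  tipidx <- state_index(space, unname(unclass(ranges)[tree$tip.label]))
  ip <- state_index(space, scen$parent)
  il <- state_index(space, scen$left)
  ir <- state_index(space, scen$right)
  rec <- function(v, s) {
    if (!is.null(clamp_node) && v == clamp_node && s != clamp_state)
      return(0)
    if (v <= nt) return(as.numeric(tipidx[v] == s))
    ed <- kids[[as.character(v)]]
    tot <- 0
    for (r in which(ip == s)) {
      f <- scen$prob[r]
      starts <- c(il[r], ir[r])
      for (side in 1:2) {
        e <- ed[side]
        child <- edge[e, 2L]
        ssum <- 0
        for (sc in seq_len(k))
          ssum <- ssum + Pm[[e]][starts[side], sc] * rec(child, sc)
        f <- f * ssum
        if (f == 0) break
      }
      tot <- tot + f
    }
    tot
  }
  prior <- numeric(k)
  if (root == "uniform") {
    nn <- which(nzchar(space$labels))
    prior[nn] <- 1 / length(nn)
  } else {
    prior[state_index(space, root_state)] <- 1
  }
  sum(vapply(seq_len(k), function(s)
    if (prior[s] > 0) prior[s] * rec(nt + 1L, s) else 0, numeric(1L)))
}

oracle_dec_marginal <- function(tree, ranges, params, space, node,
                                root = "uniform", root_state = NULL) {
  k <- space$k
  w <- vapply(seq_len(k), function(s)
    oracle_dec_lik(tree, ranges, params, space, root, root_state,
                   clamp_node = node, clamp_state = s), numeric(1L))
  w / sum(w)
}

# Non-trivial bipartitions of an unrooted tree, canonicalized as the
# sorted side containing the alphabetically first tip.
oracle_splits <- function(tree) {
  nt <- ape::Ntip(tree)
  labels <- sort(tree$tip.label)
  anchor <- labels[1L]
  edge <- tree$edge
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  repeat {
    done <- TRUE
    # accumulate bottom-up until all internal nodes resolved
    for (v in unique(edge[, 1L])) {
      if (!is.null(below[[v]])) next
      ch <- edge[edge[, 1L] == v, 2L]
      if (all(!vapply(below[ch], is.null, logical(1L)))) {
        below[[v]] <- unlist(below[ch])
      } else {
        done <- FALSE
      }
    }
    if (done) break
  }
  splits <- character(0)
  for (e in seq_len(nrow(edge))) {
    c_ <- edge[e, 2L]
    if (c_ <= nt) next
    side <- sort(below[[c_]])
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (anchor %in% side) side else other
    splits <- c(splits, paste(canon, collapse = "|"))
  }
  unique(splits)
}

oracle_rf <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  p1 <- ape::unroot(ape::keep.tip(t1, shared))
  p2 <- ape::unroot(ape::keep.tip(t2, shared))
  s1 <- oracle_splits(p1)
  s2 <- oracle_splits(p2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Exact presence marginals of the two-state symmetric model by
# enumeration of all internal-node state assignments.
oracle_binary_marginals <- function(tree, presence, rate) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  edge <- tree$edge
  x <- as.integer(presence[tree$tip.label])
  psame <- 0.5 + 0.5 * exp(-2 * rate * tree$edge.length)
  total <- 0
  marg <- numeric(nn)
  for (code in 0:(2^nn - 1L)) {
    st <- c(x, as.integer(intToBits(code))[seq_len(nn)])
    pr <- 0.5
    for (e in seq_len(nrow(edge))) {
      same <- st[edge[e, 1L]] == st[edge[e, 2L]]
      pr <- pr * if (same) psame[e] else 1 - psame[e]
    }
    total <- total + pr
    marg <- marg + pr * st[(nt + 1L):(nt + nn)]
  }
  c(x, marg / total)
}

# Deterministic fixture trees used across test files.
toy_tree <- function(newick) ape::read.tree(text = newick)

toy_space2 <- function() build_state_space(area_set(c("A", "B")),
                                           max_range_size = 2L)

toy_space3 <- function(max_range = 3L, exclusions = character())
  build_state_space(area_set(c("A", "B", "C")), max_range_size = max_range,
                    exclusions = exclusions)
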