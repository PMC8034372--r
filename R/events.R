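# Endpoint-conditioned CTMC path sampling by uniformization, plus the
# per-node event-matrix assembly (dispersal / vicariance / extinction).

# Sample the number of uniformized jumps and the state sequence of a CTMC
# bridge from state a to state b over time t.  Returns the sequence of
# visited states (including a and b; virtual self-jumps removed).
sample_ctmc_bridge <- function(a, b, t, Q, max_n = 200L) {
  k <- nrow(Q)
  lam <- max(-diag(Q))
  if (lam <= 0) {
    if (a != b) stop("impossible endpoint pair under a zero-rate process")
    return(a)
  }
  R <- diag(k) + Q / lam
  # R^n powers, built lazily
  Rpow <- list(diag(k), R)
  getR <- function(n) {
    while (length(Rpow) < n + 1L)
      Rpow[[length(Rpow) + 1L]] <<- Rpow[[length(Rpow)]] %*% R
    Rpow[[n + 1L]]
  }
  # P(N = n | a, b, t) ~ dpois(n, lam t) R^n[a,b]
  u <- stats::runif(1L)
  norm <- 0
  probs <- numeric(0)
  for (m in 0:max_n) {
    pm <- stats::dpois(m, lam * t) * getR(m)[a, b]
    probs <- c(probs, pm)
    norm <- norm + pm
    if (m >= 5L && stats::ppois(m, lam * t) > 1 - 1e-12) break
  }
  if (norm <= 0) stop("endpoint pair has zero probability")
  probs <- probs / norm
  n <- which(u <= cumsum(probs))[1L] - 1L
  if (is.na(n)) n <- length(probs) - 1L
  if (n == 0L) return(a)
  states <- integer(n + 1L)
  states[1L] <- a
  states[n + 1L] <- b
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      w <- R[states[i], ] * getR(n - i)[, b]
      states[i + 1L] <- sample.int(nrow(Q), 1L, prob = w)
    }
  }
  states[c(TRUE, diff(states) != 0L)]     # drop virtual self-jumps
}

# Classify the real transitions of a path as gains (dispersal) or losses
# (extinction) using state cardinalities.
count_path_events <- function(path, size) {
  if (length(path) < 2L) return(c(gain = 0L, loss = 0L))
  d <- diff(size[path])
  c(gain = sum(d > 0), loss = sum(d < 0))
}

#' Count biogeographic events at a focal node
#'
#' Stochastic mapping of the events that shape a focal node, conditioned on
#' all tip data under a fitted DEC-family model.  Each map samples (i) the
#' state of the focal node's parent, (ii) the cladogenetic scenario at the
#' parent (fixing the focal branch's starting range), (iii) an
#' endpoint-conditioned anagenetic history along the focal node's
#' subtending branch (by uniformization), and (iv) the cladogenetic
#' scenario at the focal node itself.  Anagenetic range gains count as
#' dispersal and range losses as extinction; a vicariant scenario at the
#' focal node counts one vicariance and a founder-event (jump) scenario
#' counts one dispersal.  By default the counting window is the focal
#' node's cladogenesis plus its subtending branch; `window = "clado"`
#' restricts it to the cladogenesis alone.
#'
#' @inheritParams dec_loglik
#' @param params Fitted model parameters ([dec_params()]).
#' @param node Focal node: ape index or internal node label.
#' @param n_maps Number of stochastic maps (default 200).
#' @param seed Optional integer seed.
#' @param window `"branch+clado"` (default) or `"clado"`.
#' @return An `event_matrix` data frame with one row per event type
#'   (`dispersal`, `vicariance`, `extinction`), the modal count over maps
#'   (`count`) and the mean (`expected`).
#' @export
count_events <- function(tree, ranges, params, space, node,
                         n_maps = 200L, seed = NULL,
                         window = c("branch+clado", "clado"),
                         root = c("uniform", "conditional"),
                         root_state = NULL) {
  window <- match.arg(window)
  root <- match.arg(root)
  if (n_maps < 1L) stop("'n_maps' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  v <- resolve_node(tree, node)
  nt <- ape::Ntip(tree)
  if (v <= nt) stop("focal node must be internal")
  eng <- dec_engine(tree, ranges, params, space, root, root_state,
                    return_arrays = TRUE)
  po <- eng$po
  res <- eng$res
  scen <- eng$scen
  k <- space$k
  ip <- state_index(space, scen$parent)
  il <- state_index(space, scen$left)
  ir <- state_index(space, scen$right)
  size <- space$size
  kv <- match(v, po$nodes)                 # focal node's traversal slot
  # outside pass down to the focal node's parent (reuse marginals machinery)
  marg <- ancestral_marginals(tree, ranges, params, space, root = root,
                              root_state = root_state)
  # parent bookkeeping
  pe <- which(tree$edge[, 2L] == v)
  has_parent <- length(pe) == 1L && window == "branch+clado"
  if (has_parent) {
    p <- tree$edge[pe, 1L]
    kp <- match(p, po$nodes)
    focal_is_c1 <- po$child1[kp] == v
    t_v <- if (focal_is_c1) po$blen1[kp] else po$blen2[kp]
    P_v <- if (focal_is_c1) res$P1[, , kp] else res$P2[, , kp]
    B_sib <- if (focal_is_c1) res$B2[kp, ] else res$B1[kp, ]
    marg_p <- marg[p, ]
  }
  disp <- integer(n_maps); vic <- integer(n_maps); ext <- integer(n_maps)
  clv_v <- res$clv[v, ]
  Bv1 <- res$B1[kv, ]; Bv2 <- res$B2[kv, ]
  for (m in seq_len(n_maps)) {
    nd <- 0L; nv <- 0L; nx <- 0L
    if (has_parent) {
      sp <- sample.int(k, 1L, prob = marg_p)
      rows <- which(ip == sp)
      # scenario at the parent, conditioned on both daughter subtrees
      wts <- scen$prob[rows] *
        (if (focal_is_c1)
          (P_v %*% clv_v)[il[rows]] * B_sib[ir[rows]]
         else
          B_sib[il[rows]] * (P_v %*% clv_v)[ir[rows]])
      r <- rows[sample.int(length(rows), 1L, prob = wts)]
      a <- if (focal_is_c1) il[r] else ir[r]
      # focal-node state given branch start and subtree data
      wb <- P_v[a, ] * clv_v
      b <- sample.int(k, 1L, prob = wb)
      path <- sample_ctmc_bridge(a, b, t_v, eng$Q)
      ev <- count_path_events(path, size)
      nd <- nd + ev[["gain"]]
      nx <- nx + ev[["loss"]]
    } else {
      b <- sample.int(k, 1L, prob = marg[v, ])
    }
    # cladogenetic scenario at the focal node
    rows <- which(ip == b)
    wts <- scen$prob[rows] * Bv1[il[rows]] * Bv2[ir[rows]]
    r <- rows[sample.int(length(rows), 1L, prob = wts)]
    cat_ <- scen$category[r]
    if (cat_ == "vicariance") nv <- nv + 1L
    if (cat_ == "jump") nd <- nd + 1L
    disp[m] <- nd; vic[m] <- nv; ext[m] <- nx
  }
  modal <- function(x) as.integer(names(which.max(table(x))))
  out <- data.frame(
    event = c("dispersal", "vicariance", "extinction"),
    count = c(modal(disp), modal(vic), modal(ext)),
    expected = c(mean(disp), mean(vic), mean(ext)),
    stringsAsFactors = FALSE)
  attr(out, "node") <- v
  attr(out, "n_maps") <- n_maps
  attr(out, "window") <- window
  class(out) <- c("event_matrix", "data.frame")
  out
}

#' Expected anagenetic gain rate along a branch (analytic)
#'
#' The expected number of range-gain (dispersal) events on a branch of
#' length `t` started in state `a`, unconditioned on the endpoint:
#' the integral over the branch of the instantaneous gain rate weighted by
#' the state distribution, evaluated on a fine time grid.
#'
#' @param a Starting state index.
#' @param t Branch length (Ma).
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param space The matching state space.
#' @param n_grid Number of grid intervals for the time integral.
#' @return List with `gain` and `loss` expected counts.
#' @export
expected_branch_events <- function(a, t, Q, space, n_grid = 400L) {
  size <- space$size
  k <- nrow(Q)
  gain_rate <- numeric(k); loss_rate <- numeric(k)
  for (i in seq_len(k)) {
    up <- which(size > size[i])
    dn <- which(size < size[i])
    gain_rate[i] <- sum(Q[i, up])
    loss_rate[i] <- sum(Q[i, dn])
  }
  dt <- t / n_grid
  step <- expm_series(Q * dt)
  g <- 0; l <- 0
  pvec <- numeric(k); pvec[a] <- 1
  for (i in seq_len(n_grid)) {
    p0 <- pvec
    pvec <- as.vector(pvec %*% step)
    # trapezoid on the instantaneous expected rates
    g <- g + dt * (sum(p0 * gain_rate) + sum(pvec * gain_rate)) / 2
    l <- l + dt * (sum(p0 * loss_rate) + sum(pvec * loss_rate)) / 2
  }
  list(gain = g, loss = l)
}

# Small dense matrix exponential: scaling and squaring over a truncated
# Taylor series.  Used where the compiled core is not in play.
expm_series <- function(A, order = 12L) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
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
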