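#' @useDynLib decrange, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Post-order traversal arrays for a binary tree: internal nodes in
# post-order (root last) with their two children and branch lengths.
postorder_arrays <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  kids <- vector("list", nt + nn)
  for (i in seq_len(nrow(edge)))
    kids[[edge[i, 1L]]] <- c(kids[[edge[i, 1L]]], i)
  root <- nt + 1L
  # iterative post-order DFS
  nodes <- integer(nn)
  child1 <- integer(nn); child2 <- integer(nn)
  blen1 <- numeric(nn); blen2 <- numeric(nn)
  npos <- 0L
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top$node
    ed <- kids[[v]]
    if (length(ed) != 2L)
      stop("likelihood engine requires a fully bifurcating tree; node ", v,
           " has ", length(ed), " children (resolve polytomies first)")
    if (top$stage == 1L) {
      stack[[length(stack) + 1L]] <- list(node = v, stage = 2L)
      for (i in ed) {
        c_ <- edge[i, 2L]
        if (c_ > nt)
          stack[[length(stack) + 1L]] <- list(node = c_, stage = 1L)
      }
    } else {
      npos <- npos + 1L
      nodes[npos] <- v
      child1[npos] <- edge[ed[1L], 2L]
      child2[npos] <- edge[ed[2L], 2L]
      blen1[npos] <- elen[ed[1L]]
      blen2[npos] <- elen[ed[2L]]
    }
  }
  list(nodes = nodes, child1 = child1, child2 = child2,
       blen1 = blen1, blen2 = blen2, ntip = nt, nnode = nt + nn,
       root = root)
}

# Root prior vector over states.
root_prior_vector <- function(space, root = c("uniform", "conditional"),
                              root_state = NULL) {
  root <- match.arg(root)
  prior <- numeric(space$k)
  if (root == "uniform") {
    nn <- nonnull_states(space)
    prior[nn] <- 1 / length(nn)
  } else {
    if (is.null(root_state))
      stop("'root_state' is required for the conditional root option")
    prior[state_index(space, root_state)] <- 1
  }
  prior
}

# Shared setup for loglik / marginals / event mapping.
dec_engine <- function(tree, ranges, params, space,
                       root = "uniform", root_state = NULL,
                       return_arrays = FALSE) {
  validate_chronogram(tree)
  ranges <- as_range_data(unclass(ranges), space, tree = tree)
  po <- postorder_arrays(tree)
  tip_idx <- state_index(space, unname(ranges[tree$tip.label]))
  tip_clv <- matrix(0, po$ntip, space$k)
  tip_clv[cbind(seq_len(po$ntip), tip_idx)] <- 1
  scen <- clado_probs(clado_scenarios(space, params$family, params$jump),
                      params$j)
  Q <- build_rate_matrix(params, space)
  prior <- root_prior_vector(space, root, root_state)
  res <- dec_downpass_cpp(Q, po$nodes - 1L, po$child1 - 1L, po$child2 - 1L,
                          po$blen1, po$blen2, tip_clv,
                          state_index(space, scen$parent) - 1L,
                          state_index(space, scen$left) - 1L,
                          state_index(space, scen$right) - 1L,
                          scen$prob, prior, return_arrays)
  list(res = res, po = po, scen = scen, Q = Q, prior = prior,
       tip_idx = tip_idx)
}

#' DEC-family log-likelihood on a chronogram
#'
#' Computes the log-likelihood of observed tip ranges under a DEC-family
#' model by post-order pruning: tip vectors are indicators of the observed
#' state, branch updates use the matrix exponential of the anagenetic rate
#' matrix, node updates convolve the daughters through the cladogenetic
#' scenario table, and the root conditional likelihoods are summed under
#' the chosen root convention.
#'
#' @param tree A binary chronogram (`phylo`).
#' @param ranges Range codings: named character vector or `range_data`,
#'   taxon -> range label; every tip must be coded.
#' @param params A [dec_params()] object.
#' @param space A [build_state_space()] object.
#' @param root Root convention: `"uniform"` (default) sums root conditional
#'   likelihoods weighted uniformly over allowed non-null states, with no
#'   cladogenesis event above the root; `"conditional"` conditions on a
#'   given `root_state`.
#' @param root_state Range label for `root = "conditional"`.
#' @return The log-likelihood (finite or `-Inf`).
#' @export
dec_loglik <- function(tree, ranges, params, space,
                       root = c("uniform", "conditional"),
                       root_state = NULL) {
  root <- match.arg(root)
  eng <- dec_engine(tree, ranges, params, space, root, root_state)
  lnl <- eng$res$loglik
  if (is.nan(lnl)) lnl <- -Inf
  lnl
}

#' Maximum-likelihood fit of a DEC-family model
#'
#' Maximizes the log-likelihood over `(d, e)` (and `j` when `jump = TRUE`)
#' by bounded quasi-Newton optimization (`L-BFGS-B`) on log-transformed
#' rates, from several deterministic starting points.
#'
#' @inheritParams dec_loglik
#' @param family Model family.
#' @param jump Fit the +J founder-event parameter?
#' @param n_starts Number of deterministic starts (default 5).
#' @param bounds Lower/upper bounds for `d` and `e` (per Ma).
#' @param init Optional list of additional starting points, each a
#'   numeric vector `c(d, e)` or `c(d, e, j)` on the natural scale.
#'   [model_test()] uses this to seed each +J fit from its base fit,
#'   which guarantees the nested pair satisfies `lnL(+J) >= lnL(base)`.
#' @return A `dec_fit` object: list with `params` (ML [dec_params()]),
#'   `loglik`, `k` (free-parameter count: 2 or 3), `n` (number of tips),
#'   `aicc`, `converged`, and `trace` (per-start results).
#' @export
fit_ml <- function(tree, ranges, space,
                   family = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                   jump = FALSE, root = c("uniform", "conditional"),
                   root_state = NULL, n_starts = 5L,
                   bounds = c(1e-7, 10), init = NULL) {
  family <- match.arg(family)
  root <- match.arg(root)
  big <- 1e10
  negll <- function(x) {
    p <- dec_params(d = exp(x[1L]), e = exp(x[2L]),
                    j = if (jump) x[3L] else 0,
                    family = family, jump = jump)
    v <- dec_loglik(tree, ranges, p, space, root = root,
                    root_state = root_state)
    if (!is.finite(v)) big else -v
  }
  de_starts <- list(c(0.01, 0.01), c(0.1, 0.1), c(0.001, 0.001),
                    c(0.05, 0.005), c(0.005, 0.05))
  j_starts <- c(0.1, 1, 0.02, 0.5, 2)
  n_starts <- max(1L, min(n_starts, length(de_starts)))
  lower <- c(log(bounds[1L]), log(bounds[1L]), if (jump) 0)
  upper <- c(log(bounds[2L]), log(bounds[2L]), if (jump) 3)
  x0s <- lapply(seq_len(n_starts), function(i)
    c(log(de_starts[[i]]), if (jump) j_starts[i]))
  for (ini in init) {
    ini <- pmin(pmax(ini, c(bounds[1L], bounds[1L], 0)[seq_along(ini)]),
                c(bounds[2L], bounds[2L], 3)[seq_along(ini)])
    x0 <- c(log(ini[1L]), log(ini[2L]),
            if (jump) (if (length(ini) >= 3L) ini[3L] else 0))
    x0s[[length(x0s) + 1L]] <- x0
  }
  fits <- vector("list", length(x0s))
  for (i in seq_along(x0s)) {
    fits[[i]] <- tryCatch(
      stats::optim(x0s[[i]], negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500L)),
      error = function(e) list(par = x0s[[i]], value = big,
                               convergence = 99L))
  }
  vals <- vapply(fits, `[[`, numeric(1L), "value")
  best <- fits[[which.min(vals)]]
  converged <- best$convergence == 0L && best$value < big
  par <- dec_params(d = exp(best$par[1L]), e = exp(best$par[2L]),
                    j = if (jump) best$par[3L] else 0,
                    family = family, jump = jump)
  trace <- data.frame(
    start = seq_along(x0s),
    d0 = vapply(x0s, function(x) exp(x[1L]), numeric(1L)),
    e0 = vapply(x0s, function(x) exp(x[2L]), numeric(1L)),
    loglik = -vals,
    convergence = vapply(fits, `[[`, numeric(1L), "convergence"))
  k <- if (jump) 3L else 2L
  n <- ape::Ntip(tree)
  structure(list(params = par, loglik = -best$value, k = k, n = n,
                 aicc = aicc(-best$value, k, n), converged = converged,
                 family = family, jump = jump, root = root,
                 trace = trace),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("%s%s fit: lnL = %.4f, AICc = %.4f (k = %d, n = %d)%s\n",
              x$family, if (x$jump) "+J" else "", x$loglik, x$aicc,
              x$k, x$n,
              if (!x$converged) "  [did not converge]" else ""))
  print(x$params)
  invisible(x)
}

# Accumulate val over idx into a length-k vector.
accum <- function(k, idx, val) {
  out <- numeric(k)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Marginal ancestral-range reconstruction
#'
#' Per-node marginal probabilities over range states, conditioning on all
#' tip data, via an up-down pass around the pruning algorithm.  The state
#' at a node is the range of the ancestral lineage immediately before it
#' speciates.
#'
#' @inheritParams dec_loglik
#' @param params Model parameters, typically the `params` element of a
#'   [fit_ml()] result.
#' @return An `ancestral_reconstruction` object: a matrix of probabilities
#'   (rows = all nodes in ape numbering, tips included as indicator rows;
#'   columns = state labels), with attributes `method = "ML-marginal"` and
#'   `loglik`.
#' @export
ancestral_marginals <- function(tree, ranges, params, space,
                                root = c("uniform", "conditional"),
                                root_state = NULL) {
  root <- match.arg(root)
  eng <- dec_engine(tree, ranges, params, space, root, root_state,
                    return_arrays = TRUE)
  po <- eng$po
  res <- eng$res
  k <- space$k
  scen <- eng$scen
  ip <- state_index(space, scen$parent)
  il <- state_index(space, scen$left)
  ir <- state_index(space, scen$right)
  nint <- length(po$nodes)
  U <- matrix(NA_real_, po$nnode, k)
  U[po$root, ] <- eng$prior
  marg <- matrix(0, po$nnode, k,
                 dimnames = list(NULL, space$labels))
  for (kk in rev(seq_len(nint))) {
    v <- po$nodes[kk]
    uv <- U[v, ]
    mv <- uv * res$clv[v, ]
    tot <- sum(mv)
    if (!(tot > 0)) stop("zero marginal likelihood at node ", v)
    marg[v, ] <- mv / tot
    B1 <- res$B1[kk, ]; B2 <- res$B2[kk, ]
    w <- uv[ip] * scen$prob
    u1 <- accum(k, il, w * B2[ir])           # outside, top of child-1 branch
    u2 <- accum(k, ir, w * B1[il])
    c1 <- po$child1[kk]; c2 <- po$child2[kk]
    if (c1 > po$ntip) {
      x <- as.vector(crossprod(res$P1[, , kk], u1))
      U[c1, ] <- if (max(x) > 0) x / max(x) else x
    }
    if (c2 > po$ntip) {
      x <- as.vector(crossprod(res$P2[, , kk], u2))
      U[c2, ] <- if (max(x) > 0) x / max(x) else x
    }
  }
  marg[seq_len(po$ntip), ] <- 0
  marg[cbind(seq_len(po$ntip), eng$tip_idx)] <- 1
  structure(marg, method = "ML-marginal", loglik = res$loglik,
            class = c("ancestral_reconstruction", "matrix", "array"))
}

#' Most probable state per node
#'
#' @param recon An [ancestral_marginals()] (or [run_bbm()] composite)
#'   probability matrix.
#' @return Data frame with `node`, `state` (label of the most probable
#'   range) and `probability`.
#' @export
map_states <- function(recon) {
  i <- apply(recon, 1L, which.max)
  data.frame(node = seq_len(nrow(recon)),
             state = colnames(recon)[i],
             probability = recon[cbind(seq_len(nrow(recon)), i)],
             stringsAsFactors = FALSE)
}
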