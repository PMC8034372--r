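#' Simulate an ultrametric pure-birth chronogram
#'
#' Forward Yule simulation conditioned on the number of tips: starting
#' from two lineages at the root, with `k` lineages the waiting time to
#' the next speciation is exponential with rate `k * birth_rate` and a
#' uniformly chosen lineage splits; after the `n`-th lineage appears, one
#' final exponential waiting time closes the tree at the present.  The
#' tree is then rescaled so the root age equals `root_age` (default 120
#' Ma, the age scale of the deepest theraphosid divergences).
#'
#' @param n_tips Number of tips (at least 3).
#' @param birth_rate Speciation rate per lineage per Ma (before
#'   rescaling).
#' @param root_age Root age in Ma after rescaling; `NULL` keeps the raw
#'   simulated depth.
#' @param seed Optional integer seed; the same seed reproduces the tree
#'   exactly.
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_chronogram <- function(n_tips, birth_rate = 0.05, root_age = 120,
                                seed = NULL) {
  if (n_tips < 3L) stop("'n_tips' must be at least 3")
  if (birth_rate <= 0) stop("'birth_rate' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  nnode <- 2L * n - 1L
  node_time <- numeric(nnode)
  parent <- integer(nnode)
  root <- n + 1L
  node_time[root] <- 0
  next_internal <- n + 2L
  active <- c(root, root)                 # parent node of each open lineage
  t_now <- 0
  k <- 2L
  while (k < n) {
    t_now <- t_now + stats::rexp(1L, birth_rate * k)
    i <- sample.int(k, 1L)
    v <- next_internal; next_internal <- next_internal + 1L
    node_time[v] <- t_now
    parent[v] <- active[i]
    active <- c(active[-i], v, v)
    k <- k + 1L
  }
  t_end <- t_now + stats::rexp(1L, birth_rate * n)
  parent[seq_len(n)] <- sample(active, n) # tip labels are exchangeable
  node_time[seq_len(n)] <- t_end
  child <- setdiff(seq_len(nnode), root)
  edge <- cbind(parent[child], child)
  elen <- node_time[child] - node_time[parent[child]]
  tree <- list(edge = edge, edge.length = elen,
               tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (!is.null(root_age)) {
    h <- tree_height(tree)
    tree$edge.length <- tree$edge.length * root_age / h
  }
  validate_chronogram(tree)
  tree
}

# Instantaneous transitions out of a state: targets and rates, consistent
# with build_rate_matrix().
anagenetic_moves <- function(i, Q) {
  j <- which(Q[i, ] > 0)
  j <- j[j != i]
  list(to = j, rate = Q[i, j])
}

#' Simulate an anagenetic history along one branch
#'
#' Exact (Gillespie) simulation of the DEC anagenetic CTMC from a starting
#' state over a branch of length `t`.
#'
#' @param state Starting state index.
#' @param t Branch length (Ma).
#' @param Q Rate matrix from [build_rate_matrix()].
#' @return List with `end` (final state index), `gains`, `losses` (event
#'   counts), `path` (visited state indices).
#' @export
simulate_branch_history <- function(state, t, Q) {
  path <- state
  now <- 0
  i <- state
  gains <- 0L; losses <- 0L
  card <- nchar(colnames(Q))
  repeat {
    out <- -Q[i, i]
    if (out <= 0) break
    now <- now + stats::rexp(1L, out)
    if (now > t) break
    mv <- anagenetic_moves(i, Q)
    jdx <- if (length(mv$to) == 1L) mv$to else
      mv$to[sample.int(length(mv$to), 1L, prob = mv$rate)]
    if (card[jdx] > card[i]) gains <- gains + 1L else losses <- losses + 1L
    i <- jdx
    path <- c(path, i)
  }
  list(end = i, gains = gains, losses = losses, path = path)
}

#' Simulate range evolution on a chronogram
#'
#' Generative counterpart of the DEC-family likelihood: the root state is
#' drawn uniformly from the allowed single-area ranges, ranges evolve
#' anagenetically by exact CTMC simulation along branches, and cladogenetic
#' daughter ranges are drawn from [clado_distribution()] at every internal
#' node.  If any lineage decays to the null range the whole simulation is
#' restarted (and the restart counted), so emitted tip data are always
#' observable ranges.
#'
#' @param tree A binary chronogram.
#' @param params A [dec_params()] object.
#' @param space A [build_state_space()] object.
#' @param seed Optional integer seed.
#' @param max_restarts Give up after this many consecutive null-range
#'   redraws of a single branch history.
#' @return A `simulation_record`: list with `seed`, `params`,
#'   `tip_ranges` (named character vector, the emitted data),
#'   `node_states` (character vector over all nodes: the range immediately
#'   before each node's cladogenesis; tips = their observed range),
#'   `branch_events` (data frame `parent`, `child`, `gains`, `losses`),
#'   `restarts` (total number of redrawn branch histories).
#' @export
simulate_ranges <- function(tree, params, space, seed = NULL,
                            max_restarts = 1000L) {
  validate_chronogram(tree)
  if (!is.null(seed)) set.seed(seed)
  po <- postorder_arrays(tree)
  Q <- build_rate_matrix(params, space)
  scen <- clado_probs(clado_scenarios(space, params$family, params$jump),
                      params$j)
  singles <- which(space$size == 1L & nzchar(space$labels))
  null_idx <- if (space$include_null) 1L else 0L
  edge <- tree$edge
  elen <- tree$edge.length
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  restarts <- 0L
  node_state <- integer(po$nnode)
  ev <- data.frame(parent = edge[, 1L], child = edge[, 2L],
                   gains = 0L, losses = 0L)
  node_state[po$root] <- singles[sample.int(length(singles), 1L)]
  # pre-order: draw cladogenesis then evolve daughters down their edges;
  # a branch history that decays to the (unobservable) null range is
  # redrawn, so emitted histories are conditioned on branch survival
  for (kk in rev(seq_along(po$nodes))) {
    v <- po$nodes[kk]
    s <- node_state[v]
    rows <- which(scen$parent == space$labels[s])
    r <- rows[sample.int(length(rows), 1L, prob = scen$prob[rows])]
    starts <- c(state_index(space, scen$left[r]),
                state_index(space, scen$right[r]))
    ed <- kids[[as.character(v)]]
    for (side in 1:2) {
      e <- ed[side]
      for (try in seq_len(max_restarts + 1L)) {
        h <- simulate_branch_history(starts[side], elen[e], Q)
        if (!null_idx || h$end != null_idx) break
        restarts <- restarts + 1L
        if (try > max_restarts)
          stop("branch history hit the null range ", max_restarts,
               " times in a row; lower 'e' or shorten the tree")
      }
      ev$gains[e] <- h$gains
      ev$losses[e] <- h$losses
      node_state[edge[e, 2L]] <- h$end
    }
  }
  tips <- space$labels[node_state[seq_len(po$ntip)]]
  names(tips) <- tree$tip.label
  structure(list(seed = seed, params = params, tip_ranges = tips,
                 node_states = space$labels[node_state],
                 branch_events = ev, restarts = restarts),
            class = "simulation_record")
}

#' Simulate topologically discordant gene trees
#'
#' Each simulated gene tree is the reference topology after a given number
#' of random nearest-neighbour-interchange (NNI) rearrangements, followed
#' by random deletion of a fraction of tips (at least 4 tips always
#' remain).
#'
#' @param reference A `phylo` with at least 6 tips.
#' @param n_trees Number of gene trees.
#' @param nni_moves Number of random NNI moves per tree.
#' @param missing_fraction Fraction of tips to delete per tree, in
#'   `[0, 0.8]`.
#' @param seed Optional integer seed.
#' @return Named list of `phylo` trees (`og1`, `og2`, ...).
#' @export
simulate_discordant_genetrees <- function(reference, n_trees,
                                          nni_moves = 0L,
                                          missing_fraction = 0,
                                          seed = NULL) {
  if (ape::Ntip(reference) < 6L) stop("reference needs at least 6 tips")
  if (missing_fraction < 0 || missing_fraction > 0.8)
    stop("'missing_fraction' must be in [0, 0.8]")
  if (nni_moves < 0) stop("'nni_moves' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    gt <- reference
    if (nni_moves > 0L) gt <- phangorn::rNNI(reference, moves = nni_moves)
    if (missing_fraction > 0) {
      nt <- ape::Ntip(gt)
      n_drop <- min(floor(missing_fraction * nt), nt - 4L)
      if (n_drop > 0L)
        gt <- ape::drop.tip(gt, sample(gt$tip.label, n_drop))
    }
    out[[i]] <- gt
  }
  names(out) <- paste0("og", seq_len(n_trees))
  out
}

#' Simulate a codon alignment with an elevated third-position rate
#'
#' Equal-rates (JC) sequence simulation on a tree, with an independent
#' per-codon-position rate: first and second positions evolve at
#' `base_rate` and third positions at
#' `base_rate * third_position_rate_multiplier`, emulating the faster,
#' saturation-prone third codon positions of protein-coding genes.
#'
#' @param tree A `phylo` with branch lengths (Ma).
#' @param length_codons Number of codons (at least 10).
#' @param third_position_rate_multiplier Rate multiplier for third
#'   positions (> 0).
#' @param base_rate Substitutions per site per Ma at positions 1-2.
#' @param seed Optional integer seed.
#' @return A codon-aligned `gene_alignment` over the tree's tips.
#' @export
simulate_codon_alignment <- function(tree, length_codons,
                                     third_position_rate_multiplier = 1,
                                     base_rate = 0.002, seed = NULL) {
  if (length_codons < 10L) stop("'length_codons' must be at least 10")
  if (third_position_rate_multiplier <= 0)
    stop("'third_position_rate_multiplier' must be positive")
  if (!is.null(seed)) set.seed(seed)
  sim_block <- function(rate) {
    dat <- phangorn::simSeq(tree, l = length_codons, type = "DNA",
                            rate = rate)
    m <- toupper(as.character(dat))
    m[, , drop = FALSE]
  }
  p1 <- sim_block(base_rate)
  p2 <- sim_block(base_rate)
  p3 <- sim_block(base_rate * third_position_rate_multiplier)
  mat <- matrix("", nrow(p1), 3L * length_codons,
                dimnames = list(rownames(p1), NULL))
  mat[, seq(1L, 3L * length_codons, by = 3L)] <- p1
  mat[, seq(2L, 3L * length_codons, by = 3L)] <- p2
  mat[, seq(3L, 3L * length_codons, by = 3L)] <- p3
  gene_alignment("sim", mat, codon_aligned = TRUE)
}

#' Study-shaped simulation preset
#'
#' The default study-emulation conditions for integration tests: 29 tips,
#' the five-area system, maximum range size 2, root age 120 Ma, and the
#' Asia + Americas range combination excluded (the proximity-based
#' exclusion named in the source analysis; exact replication requires the
#' full user-supplied exclusion list).
#'
#' @return List with `n_tips`, `areas`, `max_range_size`, `root_age`,
#'   `exclusions`, and a ready-made `space`.
#' @export
study_preset <- function() {
  areas <- area_set()
  exclusions <- "BD"
  list(n_tips = 29L, areas = areas, max_range_size = 2L,
       root_age = 120, exclusions = exclusions,
       space = build_state_space(areas, max_range_size = 2L,
                                 exclusions = exclusions))
}
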