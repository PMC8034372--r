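#' DEC-family model parameters
#'
#' @param d Dispersal (range-expansion) rate, events per area pair per Ma.
#' @param e Range-loss (local extinction) rate, per area per Ma.
#' @param j Founder-event (jump dispersal) weight, dimensionless, in
#'   `[0, 3]`; must be exactly 0 for models without the +J component.
#' @param family One of `"DEC"`, `"DIVALIKE"`, `"BAYAREALIKE"`.
#' @param jump Is the +J cladogenetic event part of the model?  When
#'   `FALSE`, `j` must be 0.
#' @return A `dec_params` object.
#' @export
dec_params <- function(d, e, j = 0, family = c("DEC", "DIVALIKE",
                                               "BAYAREALIKE"),
                       jump = j > 0) {
  family <- match.arg(family)
  if (d < 0 || e < 0) stop("rates 'd' and 'e' must be non-negative")
  if (j < 0 || j > 3) stop("'j' must lie in [0, 3]")
  if (!jump && j != 0) stop("'j' must be exactly 0 when jump = FALSE")
  structure(list(d = d, e = e, j = j, family = family, jump = jump),
            class = "dec_params")
}

#' @export
print.dec_params <- function(x, ...) {
  cat(sprintf("%s%s parameters: d = %g, e = %g%s\n", x$family,
              if (x$jump) "+J" else "", x$d, x$e,
              if (x$jump) sprintf(", j = %g", x$j) else ""))
  invisible(x)
}

split_label <- function(lab) strsplit(lab, "", fixed = TRUE)[[1L]]

# Enumerate the distinct cladogenetic scenarios (parent, left, right,
# category) of a model family over a state space.  Scenario weights depend
# only on j and are attached later by clado_probs().
clado_scenarios <- function(space, family = c("DEC", "DIVALIKE",
                                              "BAYAREALIKE"),
                            jump = FALSE) {
  family <- match.arg(family)
  codes <- space$areas$code
  allowed <- space$labels
  parents <- allowed[nzchar(allowed)]
  rows <- vector("list", length(parents))
  join <- function(ch) if (length(ch)) paste(ch, collapse = "") else ""
  for (pi in seq_along(parents)) {
    P <- parents[pi]
    ch <- split_label(P)
    m <- length(ch)
    L <- character(); R <- character(); cat_ <- character()
    add <- function(l, r, category) {
      if (l %in% allowed && r %in% allowed) {
        L <<- c(L, l); R <<- c(R, r); cat_ <<- c(cat_, category)
      }
    }
    if (family == "DEC") {
      if (m == 1L) {
        add(P, P, "sympatry")
      } else {
        for (a in ch) {            # subset sympatry: one daughter a single area
          add(P, a, "subset")
          add(a, P, "subset")
        }
        for (a in ch) {            # vicariance: one daughter a single area
          rest <- join(setdiff(ch, a))
          add(a, rest, "vicariance")
          add(rest, a, "vicariance")
        }
      }
    } else if (family == "DIVALIKE") {
      if (m == 1L) {
        add(P, P, "sympatry")
      } else {
        # any ordered disjoint bipartition of the parent range
        for (sz in seq_len(m - 1L)) {
          subs <- utils::combn(ch, sz, simplify = FALSE)
          for (s in subs) {
            l <- join(codes[sort(match(s, codes))])
            r <- join(setdiff(ch, s))
            add(l, r, "vicariance")
          }
        }
      }
    } else {                       # BAYAREALIKE: both daughters copy parent
      add(P, P, "sympatry")
    }
    if (jump) {
      for (a in setdiff(codes, ch)) {
        add(P, a, "jump")
        add(a, P, "jump")
      }
    }
    df <- unique(data.frame(parent = P, left = L, right = R,
                            category = cat_, stringsAsFactors = FALSE))
    if (!any(df$category != "jump"))
      stop("parent state '", P, "' has no non-jump cladogenetic scenario; ",
           "check the exclusion list")
    rows[[pi]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Attach normalized scenario probabilities: weight 1 per non-jump scenario,
# weight j per jump scenario, normalized within each parent state.
clado_probs <- function(scen, j) {
  w <- ifelse(scen$category == "jump", j, 1)
  tot <- stats::ave(w, scen$parent, FUN = sum)
  scen$prob <- w / tot
  scen
}

#' Cladogenetic event distribution for a parent range
#'
#' Enumerates the daughter-range scenarios a parent range can produce at
#' speciation under a DEC-family model, with their probabilities.  Under
#' DEC, a single-area parent is copied to both daughters (sympatry); a
#' widespread parent either passes a single area to one daughter and the
#' full range to the other (subset sympatry), splits so that one daughter
#' receives a single area and the other the remainder (classic vicariance),
#' or — with +J — founds a single new, unoccupied area in one daughter
#' (jump).  DIVALIKE allows vicariance by any disjoint bipartition plus
#' single-area sympatry; BAYAREALIKE copies the parent range to both
#' daughters.  Non-jump scenarios carry base weight 1 and jump scenarios
#' weight `j`, normalized to sum to 1 per parent.
#'
#' @param parent Parent range label (non-null).
#' @param params A [dec_params()] object.
#' @param space A [build_state_space()] object.
#' @return Data frame with columns `parent`, `left`, `right`, `category`
#'   (`sympatry`, `subset`, `vicariance`, `jump`) and `prob`.
#' @export
clado_distribution <- function(parent, params, space) {
  parent <- normalize_state_label(parent, space$areas$code)
  if (!nzchar(parent)) stop("parent range must be non-null")
  scen <- clado_scenarios(space, params$family, jump = params$jump)
  scen <- clado_probs(scen, params$j)
  out <- scen[scen$parent == parent, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anagenetic rate matrix of the DEC process
#'
#' Builds the instantaneous rate matrix over the state space: a range `S`
#' gains an unoccupied area `a` at rate `d * |S|` (every occupied area is a
#' dispersal source; no distance scaling), and loses an occupied area at
#' rate `e` per area (a singleton range decays to the null range, which is
#' absorbing).  Transitions into states removed from the space (excluded
#' combinations, ranges above the size cap) do not exist.
#'
#' @param params A [dec_params()] object (only `d` and `e` are used).
#' @param space A [build_state_space()] object.
#' @return A `k x k` matrix with rows summing to zero, with state labels as
#'   dimnames.
#' @export
build_rate_matrix <- function(params, space) {
  labs <- space$labels
  k <- space$k
  codes <- space$areas$code
  Q <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    s <- labs[i]
    if (!nzchar(s)) next                       # null range is absorbing
    ch <- split_label(s)
    for (a in setdiff(codes, ch)) {            # expansions
      tgt <- paste(codes[sort(match(c(ch, a), codes))], collapse = "")
      jdx <- match(tgt, labs)
      if (!is.na(jdx)) Q[i, jdx] <- params$d * length(ch)
    }
    for (a in ch) {                            # contractions
      tgt <- paste(setdiff(ch, a), collapse = "")
      jdx <- match(tgt, labs)                  # "" matches null if present
      if (!is.na(jdx)) Q[i, jdx] <- Q[i, jdx] + params$e
    }
    Q[i, i] <- -sum(Q[i, -i])
  }
  Q
}
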