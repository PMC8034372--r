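#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (here, the number of coded tips).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) stop("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Plain Akaike information criterion
#'
#' @inheritParams aicc
#' @return AIC value.
#' @export
aic <- function(loglik, k) -2 * loglik + 2 * k

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with `Delta` taken
#' relative to the smallest criterion value (which also stabilizes the
#' exponentials).
#'
#' @param ic Vector of information-criterion values (AICc or AIC); at least
#'   one finite value.
#' @return Vector of weights summing to 1.
#' @export
akaike_weights <- function(ic) {
  if (!length(ic) || !any(is.finite(ic)))
    stop("need at least one finite criterion value")
  delta <- ic - min(ic, na.rm = TRUE)
  w <- exp(-delta / 2)
  w / sum(w, na.rm = TRUE)
}

#' Likelihood-ratio test of the +J component
#'
#' The model with founder-event speciation nests the base model (`j = 0`),
#' so twice the log-likelihood gain is compared to a chi-square
#' distribution with one degree of freedom.
#'
#' @param loglik_base Maximized log-likelihood of the base model.
#' @param loglik_j Maximized log-likelihood of the +J model; must be at
#'   least `loglik_base - 1e-9` (nesting).
#' @return List with `statistic` and `p_value`.
#' @export
lrt_plus_j <- function(loglik_base, loglik_j) {
  stat <- 2 * (loglik_j - loglik_base)
  if (stat < -2e-9)
    stop("nesting violated: +J log-likelihood below base log-likelihood")
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Information-criterion comparison of a model set
#'
#' Builds the model-comparison table: AICc, delta-AICc, Akaike weights,
#' and — for base/+J pairs sharing a family — the nested likelihood-ratio
#' test with a significance flag at `alpha`.
#'
#' @param models Data frame with columns `model` (e.g. `"DEC"`, `"DEC+J"`),
#'   `loglik`, `k`, `n`; or a list of [fit_ml()] results.
#' @param alpha Significance level for the +J likelihood-ratio flag.
#' @return Data frame with columns `model`, `loglik`, `k`, `n`, `aicc`,
#'   `delta_aicc`, `weight`, `lrt_stat`, `lrt_p`, `significant` (the LRT
#'   columns are `NA` for base models and filled on the +J rows; the flag
#'   is also mirrored onto the base row, matching the convention of
#'   marking the pair).
#' @export
compare_models <- function(models, alpha = 0.05) {
  if (is.list(models) && !is.data.frame(models)) {
    models <- data.frame(
      model = vapply(models, function(f)
        paste0(f$family, if (f$jump) "+J" else ""), character(1L)),
      loglik = vapply(models, `[[`, numeric(1L), "loglik"),
      k = vapply(models, `[[`, numeric(1L), "k"),
      n = vapply(models, `[[`, numeric(1L), "n"),
      stringsAsFactors = FALSE)
  }
  out <- models
  out$aicc <- aicc(out$loglik, out$k, out$n)
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$weight <- akaike_weights(out$aicc)
  out$lrt_stat <- NA_real_
  out$lrt_p <- NA_real_
  out$significant <- NA
  is_j <- grepl("\\+J$", out$model, ignore.case = TRUE)
  for (i in which(is_j)) {
    base <- sub("\\+J$", "", out$model[i], ignore.case = TRUE)
    b <- which(!is_j & out$model == base)
    if (length(b) == 1L) {
      lrt <- lrt_plus_j(out$loglik[b], out$loglik[i])
      out$lrt_stat[i] <- lrt$statistic
      out$lrt_p[i] <- lrt$p_value
      out$significant[i] <- lrt$p_value < alpha
      out$significant[b] <- lrt$p_value < alpha
    }
  }
  out
}

#' Fit and compare the six DEC-family models
#'
#' Runs maximum-likelihood fits for DEC, DIVALIKE and BAYAREALIKE, each
#' with and without the +J founder-event parameter, and assembles the
#' model-comparison table.
#'
#' @inheritParams fit_ml
#' @param alpha Significance level for the +J likelihood-ratio flag.
#' @param ... Further arguments passed to [fit_ml()].
#' @return List with `table` (see [compare_models()]) and `fits` (named
#'   list of the six [fit_ml()] results).
#' @export
model_test <- function(tree, ranges, space, alpha = 0.05, ...) {
  fams <- c("DEC", "DIVALIKE", "BAYAREALIKE")
  fits <- list()
  for (fam in fams) {
    base <- fit_ml(tree, ranges, space, family = fam, jump = FALSE, ...)
    fits[[fam]] <- base
    # seed the +J fit from the base optimum so the pair always nests
    fits[[paste0(fam, "+J")]] <-
      fit_ml(tree, ranges, space, family = fam, jump = TRUE,
             init = list(c(base$params$d, base$params$e, 0)), ...)
  }
  list(table = compare_models(fits, alpha = alpha), fits = fits)
}
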