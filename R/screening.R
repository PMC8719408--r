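#' Bivariate Poisson screening regression
#'
#' Fits `log E[y] = log(denominator) + b0 + b1 * x` by maximum likelihood
#' (IRLS via [stats::glm()]) and returns the covariate effect with its Wald
#' test. This is the first step of the two-step covariate selection: each
#' candidate covariate is screened one at a time against each outcome with a
#' non-spatial Poisson model offset by the log live births.
#'
#' @param y non-negative integer event counts, one per record.
#' @param offset_log finite log denominators, one per record.
#' @param x numeric covariate with non-zero variance.
#' @param covariate,outcome optional labels carried into the result.
#' @return one-row data frame of class `screening_result`: `covariate`,
#'   `outcome`, `coefficient` (log rate ratio), `standard_error`, `ci_lower`,
#'   `ci_upper` (95% Wald), `wald_p`, `deviance`, `converged`.
#' @export
fit_bivariate_poisson <- function(y, offset_log, x, covariate = "x",
                                  outcome = "y") {
  if (any(y < 0) || any(!is.finite(y))) stop("counts must be finite and >= 0")
  if (any(!is.finite(offset_log))) stop("offsets must be finite")
  if (length(unique(x)) < 2L || stats::sd(x) == 0) {
    stop("covariate '", covariate, "' has zero variance")
  }
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::poisson(), offset = offset_log))
  if (!fit$converged) {
    warning("Poisson screening fit for '", covariate, "' did not converge")
  }
  b1 <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  z <- b1 / se
  structure(
    data.frame(covariate = covariate, outcome = outcome, coefficient = b1,
               standard_error = se,
               ci_lower = b1 - stats::qnorm(0.975) * se,
               ci_upper = b1 + stats::qnorm(0.975) * se,
               wald_p = 2 * stats::pnorm(-abs(z)),
               deviance = stats::deviance(fit),
               converged = fit$converged,
               row.names = NULL),
    class = c("screening_result", "data.frame"))
}

# long covariate records (one row per area-period) for a panel
panel_covariate_records <- function(panel) {
  d <- panel_dims(panel)
  out <- list()
  if (d[["P"]] > 0L) {
    for (p in seq_len(d[["P"]])) {
      out[[colnames(panel$X_s)[[p]]]] <-
        rep(panel$X_s[, p], times = d[["J"]])
    }
  }
  if (d[["Q"]] > 0L) {
    for (q in seq_len(d[["Q"]])) {
      out[[dimnames(panel$X_st)[[3L]][[q]]]] <- as.vector(panel$X_st[, , q])
    }
  }
  if (length(out) == 0L) stop("panel has no covariates to screen")
  as.data.frame(out)
}

#' Screen every candidate covariate against every outcome
#'
#' Runs [fit_bivariate_poisson()] for each (covariate, outcome) pair over the
#' observed area-period records, then applies [select_covariates()]. A
#' covariate is carried forward if selected for any outcome, since the joint
#' model pools the covariate block across outcomes.
#'
#' @param panel an `apo_panel` with covariates.
#' @param p_threshold Wald significance threshold (default 0.05).
#' @param collinearity_r absolute pairwise correlation above which two
#'   selected covariates are considered collinear (default 0.7).
#' @return list with `results` (all screening rows), `selection` (per
#'   covariate decision), `selected` (character vector).
#' @export
screen_covariates <- function(panel, p_threshold = 0.05,
                              collinearity_r = 0.7) {
  d <- panel_dims(panel)
  covs <- panel_covariate_records(panel)
  results <- list()
  for (k in seq_len(d[["K"]])) {
    obs_k <- panel$mask[, , k] & panel$n > 0
    y <- panel$Y[, , k][obs_k]
    off <- log(panel$n[obs_k])
    for (cv in names(covs)) {
      results[[length(results) + 1L]] <- fit_bivariate_poisson(
        y, off, covs[[cv]][as.vector(obs_k)], covariate = cv,
        outcome = panel$outcomes[[k]])
    }
  }
  results <- do.call(rbind, results)
  sel <- select_covariates(results, covs, p_threshold = p_threshold,
                           collinearity_r = collinearity_r)
  list(results = results, selection = sel,
       selected = sel$covariate[sel$selected])
}

#' Apply the significance and collinearity filters
#'
#' Keeps covariates whose best (smallest) Wald p across outcomes is below
#' `p_threshold`; then, among kept pairs whose absolute correlation exceeds
#' `collinearity_r`, drops the member with the larger p (ties: larger
#' deviance, then later lexicographic name). Deterministic given inputs.
#'
#' @param results screening rows from [fit_bivariate_poisson()] covering
#'   every candidate (any number of outcomes per covariate).
#' @param covariate_table data frame of per-record covariate values (used for
#'   the pairwise correlations).
#' @param p_threshold,collinearity_r see [screen_covariates()].
#' @return data frame: `covariate`, `wald_p` (best across outcomes),
#'   `deviance` (at the best p), `significant`, `dropped_collinear`,
#'   `selected`.
#' @export
select_covariates <- function(results, covariate_table, p_threshold = 0.05,
                              collinearity_r = 0.7) {
  if (is.null(results) || nrow(results) == 0L) stop("empty candidate list")
  split_res <- split(results, results$covariate)
  per_cov <- do.call(rbind, lapply(split_res, function(r) {
    best <- order(r$wald_p, r$deviance)[[1L]]
    data.frame(covariate = r$covariate[[best]], wald_p = r$wald_p[[best]],
               deviance = r$deviance[[best]])
  }))
  per_cov <- per_cov[order(per_cov$covariate), , drop = FALSE]
  rownames(per_cov) <- per_cov$covariate
  per_cov$significant <- per_cov$wald_p < p_threshold
  per_cov$dropped_collinear <- FALSE
  kept <- per_cov$covariate[per_cov$significant]
  if (length(kept) > 1L) {
    cmat <- abs(stats::cor(covariate_table[, kept, drop = FALSE]))
    repeat {
      diag(cmat) <- 0
      if (all(cmat <= collinearity_r, na.rm = TRUE)) break
      pair <- which(cmat == max(cmat), arr.ind = TRUE)[1L, ]
      a <- rownames(cmat)[[pair[[1L]]]]
      b <- colnames(cmat)[[pair[[2L]]]]
      pa <- per_cov[a, ]; pb <- per_cov[b, ]
      drop_cov <- if (pa$wald_p != pb$wald_p) {
        if (pa$wald_p > pb$wald_p) a else b
      } else if (pa$deviance != pb$deviance) {
        if (pa$deviance > pb$deviance) a else b
      } else {
        max(a, b)  # later lexicographic name loses
      }
      per_cov[drop_cov, "dropped_collinear"] <- TRUE
      kept <- setdiff(kept, drop_cov)
      if (length(kept) < 2L) break
      cmat <- cmat[kept, kept, drop = FALSE]
    }
  }
  per_cov$selected <- per_cov$significant & !per_cov$dropped_collinear
  rownames(per_cov) <- NULL
  per_cov
}
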