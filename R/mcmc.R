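#' MCMC chain protocol
#'
#' Defaults follow the study protocol: two chains of 80,000 iterations with a
#' 4,000-iteration burn-in. Thinning (default 10) bounds memory; proposal
#' scales adapt toward the target acceptance rate during burn-in only, so the
#' retained chain is a valid Markov chain.
#'
#' @param n_chains number of chains (default 2).
#' @param n_iter iterations per chain (default 80000).
#' @param burn_in burn-in iterations (default 4000; must be < `n_iter`).
#' @param thin thinning interval (default 10).
#' @param seed base integer seed; chain c uses `seed + c - 1` unless
#'   `chain_seeds` is given explicitly.
#' @param chain_seeds optional integer vector of per-chain seeds (identical
#'   seeds give identical chains).
#' @param adapt_interval iterations between proposal-scale adaptations during
#'   burn-in (default 100).
#' @param target_accept target acceptance rate for scalar random-walk updates
#'   (default 0.44).
#' @param store_pi keep the derived risk surface `pi[i,j,k]` per retained
#'   draw (default TRUE; needed for posterior-predictive validation).
#' @param interaction `"iid"` (Knorr-Held Type I) or `"rw1"` (Type II).
#' @param constraint `"product"` (default) or `"literal"` additive spatial
#'   weight constraint.
#' @param update named logical list switching parameter blocks on or off
#'   (`alpha`, `beta`, `gamma`, `u_s`, `u_s_k`, `u_t`, `u_t_k`, `nu`, `tau`);
#'   disabled blocks stay at their initial values. Used for degenerate-model
#'   and full-conditional checks.
#' @param init optional named list of initial values overriding the defaults
#'   (empirical pooled logit for `alpha`, zeros for fields and effects, ones
#'   for weights and precisions).
#' @return list of class `apo_chain_config`.
#' @export
chain_config <- function(n_chains = 2L, n_iter = 80000L, burn_in = 4000L,
                         thin = 10L, seed = 1L, chain_seeds = NULL,
                         adapt_interval = 100L, target_accept = 0.44,
                         store_pi = TRUE,
                         interaction = c("iid", "rw1"),
                         constraint = c("product", "literal"),
                         update = list(), init = NULL) {
  interaction <- match.arg(interaction)
  constraint <- match.arg(constraint)
  stopifnot(n_chains >= 1L, burn_in >= 0L, burn_in < n_iter, thin >= 1L)
  upd <- list(alpha = TRUE, beta = TRUE, gamma = TRUE, u_s = TRUE,
              u_s_k = TRUE, u_t = TRUE, u_t_k = TRUE, nu = TRUE, tau = TRUE)
  if (length(update)) {
    bad <- setdiff(names(update), names(upd))
    if (length(bad)) stop("unknown update block(s): ", paste(bad, collapse = ", "))
    upd[names(update)] <- update
  }
  if (is.null(chain_seeds)) chain_seeds <- seed + seq_len(n_chains) - 1L
  stopifnot(length(chain_seeds) == n_chains)
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = as.integer(seed), chain_seeds = as.integer(chain_seeds),
         adapt_interval = as.integer(adapt_interval),
         target_accept = target_accept, store_pi = store_pi,
         interaction = interaction, constraint = constraint,
         update = upd, init = init),
    class = "apo_chain_config")
}

sample_par_names <- function(dims, outcomes, area_ids, periods) {
  K <- dims[["K"]]; P <- dims[["P"]]; Q <- dims[["Q"]]
  N <- dims[["N"]]; J <- dims[["J"]]
  c(paste0("alpha[", seq_len(K), "]"),
    if (P > 0L) paste0("beta_s[", seq_len(P), "]"),
    if (Q > 0L) paste0("beta_st[", seq_len(Q), "]"),
    paste0("gamma_s[", seq_len(K), "]"),
    paste0("gamma_t[", seq_len(K), "]"),
    "tau_us", paste0("tau_usk[", seq_len(K), "]"),
    "tau_ut", paste0("tau_utk[", seq_len(K), "]"), "tau_nu",
    paste0("u_s[", seq_len(N), "]"),
    paste0("u_t[", seq_len(J), "]"),
    "log_posterior")
}

empirical_alpha <- function(panel) {
  d <- panel_dims(panel)
  vapply(seq_len(d[["K"]]), function(k) {
    obs <- panel$mask[, , k] & panel$n > 0
    sy <- sum(panel$Y[, , k][obs])
    sn <- sum(panel$n[obs])
    stats::qlogis((sy + 0.5) / (sn + 1))
  }, numeric(1))
}

#' Fit the shared-component model by Metropolis-within-Gibbs
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler: random-walk Metropolis
#' for intercepts, covariate effects, log scaling weights (proposed within
#' their sum-to-zero subspace) and every random-effect field site, and
#' conjugate Gamma draws for the block precisions given their quadratic
#' forms. Identifiability constraints are re-applied after every sweep with
#' intercept compensation. Fully reproducible given the seeds.
#'
#' @param data an `apo_panel`.
#' @param graph a `spatial_graph` consistent with the panel.
#' @param hyper a [hyperpriors()] object.
#' @param config a [chain_config()].
#' @return object of class `apo_samples`: `draws` (list of per-chain matrices
#'   with named columns, including the shared fields and `log_posterior`),
#'   `pi` (per-chain matrices of retained risk surfaces, if stored),
#'   `accept` (per-chain post-burn-in acceptance rates), `lp0` (initial
#'   log-posterior per chain), `init` (initial `apo_params`), plus the
#'   config, dimensions and labels.
#' @export
run_chains <- function(data, graph, hyper = hyperpriors(),
                       config = chain_config()) {
  stopifnot(inherits(data, "apo_panel"), inherits(graph, "spatial_graph"),
            inherits(config, "apo_chain_config"))
  d <- panel_dims(data)
  if (graph$n_areas != d[["N"]]) stop("graph and panel disagree on n_areas")
  N <- d[["N"]]; J <- d[["J"]]; K <- d[["K"]]
  nrep <- array(data$n, dim(data$Y))
  w <- ifelse(data$mask & nrep > 0, nrep, 0)
  lconst <- sum(lchoose(nrep[w > 0], data$Y[w > 0]))

  init <- list(alpha = empirical_alpha(data))
  if (!is.null(config$init)) init[names(config$init)] <- config$init

  ctrl <- list(n_iter = config$n_iter, burn_in = config$burn_in,
               thin = config$thin, adapt_interval = config$adapt_interval,
               target_accept = config$target_accept,
               store_pi = config$store_pi,
               interaction = if (config$interaction == "iid") 0L else 1L,
               literal = if (config$constraint == "literal") 1L else 0L,
               update = unlist(config$update))
  g <- list(edges = graph$edges, component = graph$component,
            rank_s = as.numeric(icar_rank(graph)))
  hy <- list(sd_alpha = hyper$sd_alpha, sd_beta = hyper$sd_beta,
             sd_loggamma = hyper$sd_loggamma, tau_shape = hyper$tau_shape,
             tau_rate = hyper$tau_rate)
  Xs <- if (d[["P"]] > 0L) data$X_s else matrix(numeric(0), N, 0)
  Xst <- if (d[["Q"]] > 0L) as.vector(data$X_st) else numeric(0)

  draws <- vector("list", config$n_chains)
  pis <- if (config$store_pi) vector("list", config$n_chains) else NULL
  accept <- vector("list", config$n_chains)
  lp0 <- numeric(config$n_chains)
  finals <- vector("list", config$n_chains)
  pn <- sample_par_names(d, data$outcomes, data$area_ids, data$periods)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$chain_seeds[[ch]])
    res <- mwg_chain(as.integer(c(N, J, K, d[["P"]], d[["Q"]])),
                     as.numeric(data$Y), as.numeric(w), as.numeric(Xs),
                     as.numeric(Xst), lconst, g, hy, ctrl, init)
    colnames(res$draws) <- pn
    draws[[ch]] <- res$draws
    if (config$store_pi) pis[[ch]] <- res$pi
    accept[[ch]] <- res$accept
    lp0[[ch]] <- res$lp0
    finals[[ch]] <- res$final
    live <- res$accept[!is.na(res$accept)]
    out <- live < 0.05 | live > 0.95
    if (any(out)) {
      warning("chain ", ch, ": post-adaptation acceptance rate outside ",
              "[0.05, 0.95] for block(s): ",
              paste(names(live)[out], collapse = ", "))
    }
  }
  init_params <- model_params(
    alpha = init$alpha,
    beta_s = if (!is.null(init$beta_s)) init$beta_s else numeric(d[["P"]]),
    beta_st = if (!is.null(init$beta_st)) init$beta_st else numeric(d[["Q"]]),
    gamma_s = if (!is.null(init$gamma_s)) init$gamma_s else rep(1, K),
    gamma_t = if (!is.null(init$gamma_t)) init$gamma_t else rep(1, K),
    u_s = if (!is.null(init$u_s)) init$u_s else numeric(N),
    u_s_k = if (!is.null(init$u_s_k)) matrix(init$u_s_k, N, K),
    u_t = if (!is.null(init$u_t)) init$u_t else numeric(J),
    u_t_k = if (!is.null(init$u_t_k)) matrix(init$u_t_k, J, K),
    nu = if (!is.null(init$nu)) matrix(init$nu, N, J),
    tau = list(
      us = if (!is.null(init$tau_us)) init$tau_us else 1,
      usk = if (!is.null(init$tau_usk)) init$tau_usk else rep(1, K),
      ut = if (!is.null(init$tau_ut)) init$tau_ut else 1,
      utk = if (!is.null(init$tau_utk)) init$tau_utk else rep(1, K),
      nu = if (!is.null(init$tau_nu)) init$tau_nu else 1),
    n_areas = N, n_periods = J)
  structure(
    list(draws = draws, pi = pis, accept = accept, lp0 = lp0,
         final = finals, init = init_params, config = config, dims = d,
         outcomes = data$outcomes, area_ids = data$area_ids,
         periods = data$periods, par_names = pn),
    class = "apo_samples")
}

#' @export
print.apo_samples <- function(x, ...) {
  cat(sprintf("apo_samples: %d chain(s) x %d retained draws (%d parameters)\n",
              length(x$draws), nrow(x$draws[[1L]]), ncol(x$draws[[1L]])))
  invisible(x)
}

#' Extract draws of one parameter across chains
#'
#' @param samples an `apo_samples`.
#' @param parameter a column name of the draws matrices, e.g. `"alpha[1]"`.
#' @return numeric matrix, retained draws x chains.
#' @export
param_draws <- function(samples, parameter) {
  if (!parameter %in% samples$par_names) {
    stop("unknown parameter: ", parameter)
  }
  vapply(samples$draws, function(m) m[, parameter], numeric(nrow(samples$draws[[1L]])))
}

#' Stack all chains into one draws matrix
#'
#' @param x an `apo_samples`.
#' @param ... unused.
#' @return matrix with one row per retained draw (chains concatenated).
#' @export
as.matrix.apo_samples <- function(x, ...) do.call(rbind, x$draws)

# stacked pi draws (rows: draws across chains; cols: flattened cells)
stacked_pi <- function(samples) {
  if (is.null(samples$pi)) {
    stop("risk surfaces were not stored; rerun with store_pi = TRUE")
  }
  do.call(rbind, samples$pi)
}

#' Posterior summary of the scalar parameters
#'
#' @param object an `apo_samples`.
#' @param probs quantiles (default 2.5%, 50%, 97.5%).
#' @param ... unused.
#' @return data frame: parameter, mean, quantiles.
#' @export
summary.apo_samples <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  m <- as.matrix(object)
  qs <- t(apply(m, 2L, stats::quantile, probs = probs))
  data.frame(parameter = colnames(m), mean = colMeans(m), qs,
             check.names = FALSE, row.names = NULL)
}
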