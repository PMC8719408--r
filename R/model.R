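#' Hyperprior settings
#'
#' Vague WinBUGS-era defaults: `Normal(0, sd_alpha^2)` on intercepts and
#' `Normal(0, sd_beta^2)` on covariate effects, `Gamma(tau_shape, tau_rate)`
#' on every random-effect precision, and `Normal(0, sd_loggamma^2)` on the log
#' scaling weights (a lognormal on the weights themselves, putting most mass
#' in roughly 0.2-5).
#'
#' @param sd_alpha,sd_beta standard deviations of the normal priors (default 10).
#' @param tau_shape,tau_rate Gamma shape and rate for precisions (default
#'   0.5 and 0.0005).
#' @param sd_loggamma standard deviation of the log scaling-weight prior
#'   (default 0.68).
#' @return list of class `apo_hyper`.
#' @export
hyperpriors <- function(sd_alpha = 10, sd_beta = 10, tau_shape = 0.5,
                        tau_rate = 0.0005, sd_loggamma = 0.68) {
  stopifnot(sd_alpha > 0, sd_beta > 0, tau_shape > 0, tau_rate > 0,
            sd_loggamma > 0)
  structure(list(sd_alpha = sd_alpha, sd_beta = sd_beta,
                 tau_shape = tau_shape, tau_rate = tau_rate,
                 sd_loggamma = sd_loggamma),
            class = "apo_hyper")
}

#' One complete parameter state of the shared-component model
#'
#' Holds the per-outcome baseline logits, covariate effects, positive scaling
#' weights of the shared spatial / temporal components, all random-effect
#' fields and the block precisions. Missing pieces default to zeros (fields,
#' effects) and ones (weights, precisions).
#'
#' @param alpha per-outcome intercepts (logit scale); its length sets K.
#' @param beta_s,beta_st covariate effect vectors (pooled across outcomes).
#' @param gamma_s,gamma_t per-outcome positive scaling weights.
#' @param u_s shared spatial field (length N); `u_s_k` an N x K matrix of
#'   outcome-specific spatial fields.
#' @param u_t shared temporal series (length J); `u_t_k` a J x K matrix.
#' @param nu N x J space-time interaction surface.
#' @param tau list of precisions: `us`, `usk` (length K), `ut`, `utk`
#'   (length K), `nu`.
#' @param n_areas,n_periods used to size defaulted fields.
#' @return list of class `apo_params`.
#' @export
model_params <- function(alpha, beta_s = numeric(0), beta_st = numeric(0),
                         gamma_s = NULL, gamma_t = NULL,
                         u_s = NULL, u_s_k = NULL, u_t = NULL, u_t_k = NULL,
                         nu = NULL, tau = NULL,
                         n_areas = NULL, n_periods = NULL) {
  K <- length(alpha)
  if (is.null(gamma_s)) gamma_s <- rep(1, K)
  if (is.null(gamma_t)) gamma_t <- rep(1, K)
  N <- if (!is.null(u_s)) length(u_s) else n_areas
  J <- if (!is.null(u_t)) length(u_t) else n_periods
  if (is.null(N) || is.null(J)) {
    stop("supply u_s/u_t or n_areas/n_periods to size the fields")
  }
  if (is.null(u_s)) u_s <- numeric(N)
  if (is.null(u_s_k)) u_s_k <- matrix(0, N, K)
  if (is.null(u_t)) u_t <- numeric(J)
  if (is.null(u_t_k)) u_t_k <- matrix(0, J, K)
  if (is.null(nu)) nu <- matrix(0, N, J)
  if (is.null(tau)) {
    tau <- list(us = 1, usk = rep(1, K), ut = 1, utk = rep(1, K), nu = 1)
  }
  u_s_k <- matrix(u_s_k, N, K)
  u_t_k <- matrix(u_t_k, J, K)
  nu <- matrix(nu, N, J)
  stopifnot(length(gamma_s) == K, length(gamma_t) == K, length(u_s) == N,
            length(u_t) == J, length(tau$usk) == K, length(tau$utk) == K)
  structure(
    list(alpha = alpha, beta_s = beta_s, beta_st = beta_st,
         gamma_s = gamma_s, gamma_t = gamma_t, u_s = u_s, u_s_k = u_s_k,
         u_t = u_t, u_t_k = u_t_k, nu = nu, tau = tau),
    class = "apo_params")
}

#' Check the identifiability constraints of a parameter state
#'
#' Verifies (to `tol`) that the scaling weights multiply to one (or sum to
#' zero under the literal constraint), that every spatial field sums to zero
#' per graph component, that temporal series and the interaction surface sum
#' to zero, and that all precisions are positive.
#'
#' @param params an `apo_params`.
#' @param graph a `spatial_graph`.
#' @param tol numeric tolerance (default 1e-8).
#' @param constraint `"product"` (default) or `"literal"` (printed additive
#'   spatial form).
#' @return `TRUE` invisibly, or an error describing the violated constraint.
#' @export
validate_params <- function(params, graph, tol = 1e-8,
                            constraint = c("product", "literal")) {
  constraint <- match.arg(constraint)
  K <- length(params$alpha)
  if (any(params$gamma_t <= 0)) stop("temporal scaling weights must be > 0")
  if (K > 1L) {
    if (abs(sum(log(params$gamma_t))) > tol) {
      stop("gamma_t does not satisfy the product-one constraint")
    }
    if (constraint == "product") {
      if (any(params$gamma_s <= 0)) stop("spatial scaling weights must be > 0")
      if (abs(sum(log(params$gamma_s))) > tol) {
        stop("gamma_s does not satisfy the product-one constraint")
      }
    } else if (abs(sum(params$gamma_s)) > tol) {
      stop("gamma_s does not satisfy the literal sum-to-zero constraint")
    }
  }
  for (cmp in seq_len(graph$n_components)) {
    m <- graph$component == cmp
    if (abs(sum(params$u_s[m])) > tol) {
      stop("shared spatial field does not sum to zero on component ", cmp)
    }
    if (any(abs(colSums(params$u_s_k[m, , drop = FALSE])) > tol)) {
      stop("a specific spatial field does not sum to zero on component ", cmp)
    }
  }
  if (abs(sum(params$u_t)) > tol) stop("shared temporal series does not sum to zero")
  if (any(abs(colSums(params$u_t_k)) > tol)) {
    stop("a specific temporal series does not sum to zero")
  }
  if (abs(sum(params$nu)) > tol) stop("interaction surface does not sum to zero")
  taus <- c(params$tau$us, params$tau$usk, params$tau$ut, params$tau$utk,
            params$tau$nu)
  if (any(!is.finite(taus)) || any(taus <= 0)) stop("precisions must be > 0")
  invisible(TRUE)
}

#' Linear predictor of the shared-component model
#'
#' `logit(pi[i,j,k]) = alpha_k + X_s[i,] beta_s + X_st[i,j,] beta_st +
#' gamma_s_k u_s[i] + u_s_k[i,k] + gamma_t_k u_t[j] + u_t_k[j,k] + nu[i,j]`.
#'
#' @param params an `apo_params`.
#' @param data an `apo_panel` (its covariates are used; counts are not).
#' @param i,j,k optional indices; when given, the scalar predictor for that
#'   cell is returned, otherwise the full `N x J x K` array.
#' @return logit-scale predictor (scalar or array).
#' @export
linear_predictor <- function(params, data, i = NULL, j = NULL, k = NULL) {
  d <- panel_dims(data)
  N <- d[["N"]]; J <- d[["J"]]; K <- d[["K"]]
  if (length(params$beta_s) != d[["P"]] || length(params$beta_st) != d[["Q"]]) {
    stop("covariate effect lengths do not match the panel's covariate blocks")
  }
  xb_s <- if (d[["P"]] > 0L) drop(data$X_s %*% params$beta_s) else numeric(N)
  xb_st <- matrix(0, N, J)
  if (d[["Q"]] > 0L) {
    for (q in seq_len(d[["Q"]])) {
      xb_st <- xb_st + data$X_st[, , q] * params$beta_st[[q]]
    }
  }
  if (!is.null(i)) {
    stopifnot(!is.null(j), !is.null(k), i >= 1, i <= N, j >= 1, j <= J,
              k >= 1, k <= K)
    return(params$alpha[[k]] + xb_s[[i]] + xb_st[i, j] +
             params$gamma_s[[k]] * params$u_s[[i]] + params$u_s_k[i, k] +
             params$gamma_t[[k]] * params$u_t[[j]] + params$u_t_k[j, k] +
             params$nu[i, j])
  }
  eta <- array(0, c(N, J, K))
  base <- xb_s + xb_st + params$nu  # N x J (xb_s recycled down columns)
  for (kk in seq_len(K)) {
    m <- base + params$gamma_s[[kk]] * params$u_s + params$u_s_k[, kk]
    m <- sweep(m, 2L,
               params$gamma_t[[kk]] * params$u_t + params$u_t_k[, kk], "+")
    eta[, , kk] <- m + params$alpha[[kk]]
  }
  eta
}

#' Binomial log-likelihood over observed cells
#'
#' Sum of the binomial log-pmf at `pi = plogis(linear_predictor)` over cells
#' with `mask` true and `n > 0`; other cells contribute 0.
#'
#' @param params an `apo_params`.
#' @param data an `apo_panel`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, data) {
  eta <- linear_predictor(params, data)
  d <- panel_dims(data)
  nrep <- array(data$n, dim(data$Y))
  use <- data$mask & nrep > 0
  if (any(data$Y[use] > nrep[use])) stop("event count exceeds denominator")
  sum(stats::dbinom(data$Y[use], nrep[use], stats::plogis(eta[use]), log = TRUE))
}

# precision-block term under the intrinsic (rank-deficient) convention:
# (rank/2) log tau - (tau/2) quad, without 2*pi constants
gmrf_term <- function(tau, quad, rank) 0.5 * rank * log(tau) - 0.5 * tau * quad

# spatial penalty: ICAR pairwise form plus a proper u^2 term per isolated area
spatial_quad <- function(field, graph) {
  icar_quadform(field, graph) + sum(field[graph$singletons]^2)
}

interaction_quad <- function(nu, interaction) {
  if (interaction == "iid") sum(nu^2)
  else sum(apply(nu, 1L, rw1_quad0))
}

interaction_rank <- function(N, J, interaction) {
  if (interaction == "iid") N * J - 1L else N * (J - 1L)
}

#' Joint log-prior of the shared-component model
#'
#' Sums the intrinsic CAR penalties for the shared and outcome-specific
#' spatial fields, RW1 penalties for the temporal series, the interaction
#' penalty (iid or per-area RW1), normal log-densities for intercepts,
#' covariate effects and log scaling weights, and Gamma log-densities for the
#' precisions. Rank-deficient blocks use the `(rank/2) log tau` convention
#' with rank = areas - components (+1 per isolated area, which carries a
#' proper exchangeable-normal term) so that the conjugate precision updates
#' are proper.
#'
#' @param params an `apo_params` (must satisfy the constraints; violations are
#'   an internal error).
#' @param graph a `spatial_graph`.
#' @param hyper a [hyperpriors()] object.
#' @param interaction `"iid"` or `"rw1"`.
#' @param constraint `"product"` or `"literal"`.
#' @return scalar log-prior.
#' @export
log_prior <- function(params, graph, hyper = hyperpriors(),
                      interaction = c("iid", "rw1"),
                      constraint = c("product", "literal")) {
  interaction <- match.arg(interaction)
  constraint <- match.arg(constraint)
  validate_params(params, graph, constraint = constraint)
  K <- length(params$alpha)
  N <- graph$n_areas
  J <- length(params$u_t)
  rank_s <- icar_rank(graph)
  rank_t <- J - 1L
  lp <- sum(stats::dnorm(params$alpha, 0, hyper$sd_alpha, log = TRUE)) +
    sum(stats::dnorm(c(params$beta_s, params$beta_st), 0, hyper$sd_beta,
                     log = TRUE))
  if (K > 1L) {
    lp <- lp + if (constraint == "product") {
      sum(stats::dnorm(c(log(params$gamma_s), log(params$gamma_t)), 0,
                       hyper$sd_loggamma, log = TRUE))
    } else {
      sum(stats::dnorm(params$gamma_s, 0, hyper$sd_loggamma, log = TRUE)) +
        sum(stats::dnorm(log(params$gamma_t), 0, hyper$sd_loggamma, log = TRUE))
    }
  }
  lp <- lp + gmrf_term(params$tau$us, spatial_quad(params$u_s, graph), rank_s)
  for (k in seq_len(K)) {
    lp <- lp + gmrf_term(params$tau$usk[[k]],
                         spatial_quad(params$u_s_k[, k], graph), rank_s)
  }
  lp <- lp + gmrf_term(params$tau$ut, rw1_quad0(params$u_t), rank_t)
  for (k in seq_len(K)) {
    lp <- lp + gmrf_term(params$tau$utk[[k]], rw1_quad0(params$u_t_k[, k]),
                         rank_t)
  }
  lp <- lp + gmrf_term(params$tau$nu, interaction_quad(params$nu, interaction),
                       interaction_rank(N, J, interaction))
  taus <- c(params$tau$us, params$tau$usk, params$tau$ut, params$tau$utk,
            params$tau$nu)
  lp + sum(stats::dgamma(taus, shape = hyper$tau_shape, rate = hyper$tau_rate,
                         log = TRUE))
}

#' Joint log-posterior
#'
#' `log_likelihood + log_prior`; finite for any constraint-satisfying state on
#' valid data. A non-finite result raises an error naming the offending block.
#'
#' @inheritParams log_prior
#' @param data an `apo_panel`.
#' @return scalar log-posterior.
#' @export
log_posterior <- function(params, data, graph, hyper = hyperpriors(),
                          interaction = c("iid", "rw1"),
                          constraint = c("product", "literal")) {
  ll <- log_likelihood(params, data)
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  lp <- log_prior(params, graph, hyper, interaction = interaction,
                  constraint = constraint)
  if (!is.finite(lp)) stop("non-finite log-prior")
  ll + lp
}

#' Project a parameter state onto the constrained parameterization
#'
#' Rescales the scaling weights to product one (absorbing the factor into the
#' shared field), recenters every random-effect field (per graph component
#' for spatial fields) and compensates the intercepts so the likelihood is
#' unchanged. Under `constraint = "literal"` the spatial weights are shifted
#' to sum to zero, with the shift absorbed into the outcome-specific spatial
#' fields. Idempotent; exact likelihood invariance requires a connected graph
#' (the compensation runs through the global intercept).
#'
#' @param params an `apo_params`.
#' @param graph a `spatial_graph`.
#' @param constraint `"product"` or `"literal"`.
#' @return the constrained `apo_params`.
#' @export
apply_constraints <- function(params, graph,
                              constraint = c("product", "literal")) {
  constraint <- match.arg(constraint)
  p <- params
  K <- length(p$alpha)
  if (K > 1L) {
    if (constraint == "product") {
      cs <- mean(log(p$gamma_s))
      p$gamma_s <- exp(log(p$gamma_s) - cs)
      p$u_s <- p$u_s * exp(cs)
    } else {
      ms <- mean(p$gamma_s)
      p$gamma_s <- p$gamma_s - ms
      p$u_s_k <- p$u_s_k + ms * matrix(p$u_s, length(p$u_s), K)
    }
    ct <- mean(log(p$gamma_t))
    p$gamma_t <- exp(log(p$gamma_t) - ct)
    p$u_t <- p$u_t * exp(ct)
  }
  # spatial fields: per-component centering, compensated through the intercept
  m_all <- mean(p$u_s)
  for (cmp in seq_len(graph$n_components)) {
    m <- graph$component == cmp
    p$u_s[m] <- p$u_s[m] - mean(p$u_s[m])
  }
  p$alpha <- p$alpha + p$gamma_s * m_all
  for (k in seq_len(K)) {
    mk <- mean(p$u_s_k[, k])
    for (cmp in seq_len(graph$n_components)) {
      m <- graph$component == cmp
      p$u_s_k[m, k] <- p$u_s_k[m, k] - mean(p$u_s_k[m, k])
    }
    p$alpha[[k]] <- p$alpha[[k]] + mk
  }
  mt <- mean(p$u_t)
  p$u_t <- p$u_t - mt
  p$alpha <- p$alpha + p$gamma_t * mt
  for (k in seq_len(K)) {
    mk <- mean(p$u_t_k[, k])
    p$u_t_k[, k] <- p$u_t_k[, k] - mk
    p$alpha[[k]] <- p$alpha[[k]] + mk
  }
  mn <- mean(p$nu)
  p$nu <- p$nu - mn
  p$alpha <- p$alpha + mn
  p
}
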