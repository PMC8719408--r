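#' Rook-contiguity lattice graph
#'
#' Stand-in spatial structure for the ~290 sub-counties: a connected
#' `n_rows x n_cols` grid with rook adjacency.
#'
#' @param n_rows,n_cols positive grid dimensions.
#' @return a `spatial_graph` with `n_rows * n_cols` areas, ids `r<row>c<col>`.
#' @export
generate_lattice <- function(n_rows, n_cols) {
  if (n_rows < 1L || n_cols < 1L) stop("lattice dimensions must be >= 1")
  idx <- function(r, c) (r - 1L) * n_cols + c
  ids <- character(n_rows * n_cols)
  edges <- list()
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      ids[idx(r, c)] <- sprintf("r%dc%d", r, c)
      if (c < n_cols) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
      if (r < n_rows) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
    }
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), ncol = 2)
  build_adjacency(cbind(ids[em[, 1L]], ids[em[, 2L]]), ids)
}

#' Sample an intrinsic CAR field
#'
#' Draws from the intrinsic CAR (ICAR) distribution restricted to the
#' sum-to-zero subspace of each connected component: the field is expanded in
#' the eigenvectors of the graph Laplacian with non-zero eigenvalues, with
#' coefficient variances `1 / (precision * eigenvalue)`. Isolated areas are
#' fixed at zero (their exchangeable-normal prior, centered, degenerates to
#' zero for a singleton).
#'
#' @param graph a `spatial_graph`.
#' @param precision positive ICAR precision.
#' @param seed optional integer seed.
#' @return numeric field of length `n_areas`, summing to zero per component.
#' @export
sample_icar_field <- function(graph, precision, seed = NULL) {
  if (!is.finite(precision) || precision <= 0) stop("precision must be > 0")
  if (!is.null(seed)) set.seed(seed)
  field <- numeric(graph$n_areas)
  for (cmp in seq_len(graph$n_components)) {
    members <- which(graph$component == cmp)
    if (length(members) == 1L) next  # isolated: centered singleton is 0
    L <- graph_laplacian(graph)[members, members, drop = FALSE]
    eig <- eigen(L, symmetric = TRUE)
    pos <- eig$values > 1e-9
    lam <- eig$values[pos]
    V <- eig$vectors[, pos, drop = FALSE]
    coefs <- stats::rnorm(length(lam)) / sqrt(precision * lam)
    x <- drop(V %*% coefs)
    field[members] <- x - mean(x)
  }
  field
}

#' Sample a random-walk-1 series
#'
#' Cumulative sum of `Normal(0, 1/precision)` increments, centered to sum to
#' zero.
#'
#' @param n_periods integer >= 2.
#' @param precision positive increment precision.
#' @param seed optional integer seed.
#' @return numeric series of length `n_periods` summing to zero.
#' @export
sample_rw1 <- function(n_periods, precision, seed = NULL) {
  if (n_periods < 2L) stop("n_periods must be >= 2")
  if (!is.finite(precision) || precision <= 0) stop("precision must be > 0")
  if (!is.null(seed)) set.seed(seed)
  x <- c(0, cumsum(stats::rnorm(n_periods - 1L, sd = 1 / sqrt(precision))))
  x - mean(x)
}

default_outcomes <- function(K) {
  base <- c("low_birth_weight", "preterm_birth", "stillbirth", "neonatal_death")
  if (K <= 4L) base[seq_len(K)] else c(base, paste0("outcome", 5:K))[seq_len(K)]
}

# geometric-mean-one normalization of positive weights
normalize_product_one <- function(g) g / exp(mean(log(g)))

#' Generator settings for the synthetic space-time cube
#'
#' Defaults emulate the study conditions: a 29 x 10 lattice (290 areas),
#' 4 annual periods, 4 outcomes sharing one live-birth denominator per
#' area-period drawn uniformly from 500-5000, baseline logits matching
#' national-scale rates of the four outcomes (about 4.7 and 2.3 per 100 and
#' 19 and 7 per 1000 live births), small covariate effects, and shared /
#' specific CAR and RW1 fields with product-one scaling weights.
#'
#' @param n_rows,n_cols lattice dimensions (defaults 29 x 10).
#' @param n_periods number of periods (default 4).
#' @param n_outcomes number of outcomes (default 4).
#' @param periods period labels (default `2016, ...`).
#' @param denom_range live births per area-period, uniform range.
#' @param alpha per-outcome baseline logits.
#' @param beta_s,beta_st covariate effects (their lengths set the number of
#'   time-invariant / space-time covariates; use `numeric(0)` for none).
#' @param gamma_s,gamma_t per-outcome positive scaling weights for the shared
#'   spatial / temporal components (normalized to product one).
#' @param tau_us,tau_usk,tau_ut,tau_utk,tau_nu random-effect precisions
#'   (shared spatial, specific spatial, shared temporal, specific temporal,
#'   interaction).
#' @param interaction `"iid"` (Knorr-Held Type I) or `"rw1"` (Type II).
#' @param missing_frac fraction of cells masked as missing (default 0).
#' @return a list of class `apo_sim_config`.
#' @export
apo_sim_config <- function(n_rows = 29L, n_cols = 10L, n_periods = 4L,
                           n_outcomes = 4L,
                           periods = seq(2016L, length.out = n_periods),
                           denom_range = c(500, 5000),
                           alpha = NULL, beta_s = c(0.06, -0.04),
                           beta_st = c(0.08, -0.07),
                           gamma_s = NULL, gamma_t = NULL,
                           tau_us = 4, tau_usk = 16, tau_ut = 100,
                           tau_utk = 400, tau_nu = 400,
                           interaction = c("iid", "rw1"),
                           missing_frac = 0) {
  interaction <- match.arg(interaction)
  K <- as.integer(n_outcomes)
  if (is.null(alpha)) {
    alpha <- c(-3.00, -3.75, -3.96, -4.97, rep(-4, max(0L, K - 4L)))[seq_len(K)]
  }
  if (is.null(gamma_s)) {
    gamma_s <- rep(c(1.4, 1.1, 0.9, 0.8), length.out = K)
  }
  if (is.null(gamma_t)) {
    gamma_t <- rep(c(1.3, 0.8, 1.2, 0.9), length.out = K)
  }
  if (K > 1L) {
    gamma_s <- normalize_product_one(gamma_s)
    gamma_t <- normalize_product_one(gamma_t)
  } else {
    gamma_s <- gamma_t <- 1
  }
  stopifnot(length(alpha) == K, length(gamma_s) == K, length(gamma_t) == K,
            all(gamma_s > 0), all(gamma_t > 0), n_periods >= 1L,
            denom_range[1] >= 0, denom_range[2] >= denom_range[1],
            missing_frac >= 0, missing_frac < 1)
  tau_usk <- rep(tau_usk, length.out = K)
  tau_utk <- rep(tau_utk, length.out = K)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         n_periods = as.integer(n_periods), n_outcomes = K,
         periods = periods, denom_range = denom_range, alpha = alpha,
         beta_s = beta_s, beta_st = beta_st, gamma_s = gamma_s,
         gamma_t = gamma_t, tau_us = tau_us, tau_usk = tau_usk,
         tau_ut = tau_ut, tau_utk = tau_utk, tau_nu = tau_nu,
         interaction = interaction, missing_frac = missing_frac),
    class = "apo_sim_config")
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant variable")
  (x - mean(x)) / s
}

#' Simulate a space-time cube from the shared-component model
#'
#' Simulates all random-effect fields from their priors, applies the
#' identifiability constraints, forms `logit(pi[i,j,k])` per the model
#' decomposition, and draws `Y ~ Binomial(n, pi)`. Covariates are a mix of one
#' spatially smooth (scaled ICAR draw) and one white-noise variable per block,
#' standardized. The full truth (parameters and realized risk surface) is
#' returned for recovery testing.
#'
#' @param config an [apo_sim_config()].
#' @param seed integer seed; regenerating with the same seed and config is
#'   bit-identical.
#' @return a list of class `apo_sim` with elements `panel` (`apo_panel`),
#'   `graph` (`spatial_graph`) and `truth` (true `model_params`, realized `pi`
#'   surface, clamping report, config, seed).
#' @export
generate_dataset <- function(config = apo_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "apo_sim_config"))
  set.seed(seed)
  graph <- generate_lattice(config$n_rows, config$n_cols)
  N <- graph$n_areas; J <- config$n_periods; K <- config$n_outcomes
  P <- length(config$beta_s); Q <- length(config$beta_st)

  n <- matrix(round(stats::runif(N * J, config$denom_range[1],
                                 config$denom_range[2])), N, J)

  X_s <- NULL
  if (P > 0L) {
    X_s <- matrix(0, N, P, dimnames = list(NULL, paste0("xs", seq_len(P))))
    for (p in seq_len(P)) {
      X_s[, p] <- if (p %% 2L == 1L && N > 1L) {
        standardize(sample_icar_field(graph, precision = 1))
      } else {
        standardize(stats::rnorm(N))
      }
    }
  }
  X_st <- NULL
  if (Q > 0L) {
    X_st <- array(0, c(N, J, Q), dimnames = list(NULL, NULL,
                                                 paste0("xst", seq_len(Q))))
    for (q in seq_len(Q)) {
      if (q %% 2L == 1L && N > 1L) {
        base <- sample_icar_field(graph, precision = 1)
        raw <- outer(base, rep(1, J)) + matrix(stats::rnorm(N * J, sd = 0.5), N, J)
      } else {
        raw <- matrix(stats::rnorm(N * J), N, J)
      }
      X_st[, , q] <- (raw - mean(raw)) / stats::sd(raw)
    }
  }

  u_s <- if (N > 1L) sample_icar_field(graph, config$tau_us) else 0
  u_s_k <- vapply(seq_len(K), function(k) {
    if (N > 1L) sample_icar_field(graph, config$tau_usk[[k]]) else 0
  }, numeric(N))
  u_t <- if (J > 1L) sample_rw1(J, config$tau_ut) else 0
  u_t_k <- vapply(seq_len(K), function(k) {
    if (J > 1L) sample_rw1(J, config$tau_utk[[k]]) else 0
  }, numeric(J))
  u_t_k <- matrix(u_t_k, J, K)
  if (config$interaction == "iid") {
    nu <- matrix(stats::rnorm(N * J, sd = 1 / sqrt(config$tau_nu)), N, J)
  } else {
    nu <- t(vapply(seq_len(N), function(i) {
      if (J > 1L) {
        c(0, cumsum(stats::rnorm(J - 1L, sd = 1 / sqrt(config$tau_nu))))
      } else 0
    }, numeric(J)))
    nu <- matrix(nu, N, J)
  }
  nu <- nu - mean(nu)

  params <- model_params(
    alpha = config$alpha, beta_s = config$beta_s, beta_st = config$beta_st,
    gamma_s = config$gamma_s, gamma_t = config$gamma_t,
    u_s = u_s, u_s_k = matrix(u_s_k, N, K), u_t = u_t, u_t_k = u_t_k,
    nu = nu,
    tau = list(us = config$tau_us, usk = config$tau_usk, ut = config$tau_ut,
               utk = config$tau_utk, nu = config$tau_nu))

  shell <- panel_data(array(0L, c(N, J, K)), n, X_s = X_s, X_st = X_st,
                      area_ids = graph$area_ids, periods = config$periods,
                      outcomes = default_outcomes(K))
  eta <- linear_predictor(params, shell)
  clamped <- sum(abs(eta) > 30)
  if (clamped > 0L) {
    warning(clamped, " cell(s) had |logit| > 30; clamped")
    eta <- pmin(pmax(eta, -30), 30)
  }
  pi <- stats::plogis(eta)
  Y <- array(stats::rbinom(N * J * K, size = as.vector(array(n, c(N, J, K))),
                           prob = as.vector(pi)), c(N, J, K))
  mask <- array(TRUE, c(N, J, K))
  if (config$missing_frac > 0) {
    drop_n <- round(config$missing_frac * N * J * K)
    mask[sample(N * J * K, drop_n)] <- FALSE
    Y[!mask] <- 0L
  }
  panel <- panel_data(Y, n, X_s = X_s, X_st = X_st, mask = mask,
                      area_ids = graph$area_ids, periods = config$periods,
                      outcomes = default_outcomes(K))
  structure(
    list(panel = panel, graph = graph,
         truth = list(params = params, pi = pi, clamped = clamped,
                      config = config, seed = seed)),
    class = "apo_sim")
}
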