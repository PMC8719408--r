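# Independent brute-force oracle: term-by-term enumeration of the joint
# log-posterior with explicit loops, sharing no code with the implementation
# beyond base density functions.
oracle_log_posterior <- function(params, panel, graph, hyper,
                                 interaction = "iid") {
  N <- dim(panel$Y)[1]; J <- dim(panel$Y)[2]; K <- dim(panel$Y)[3]
  ll <- 0
  for (i in 1:N) for (j in 1:J) for (k in 1:K) {
    if (!panel$mask[i, j, k] || panel$n[i, j] == 0) next
    eta <- params$alpha[k]
    if (length(params$beta_s)) {
      eta <- eta + sum(panel$X_s[i, ] * params$beta_s)
    }
    if (length(params$beta_st)) {
      eta <- eta + sum(panel$X_st[i, j, ] * params$beta_st)
    }
    eta <- eta + params$gamma_s[k] * params$u_s[i] + params$u_s_k[i, k] +
      params$gamma_t[k] * params$u_t[j] + params$u_t_k[j, k] + params$nu[i, j]
    p <- 1 / (1 + exp(-eta))
    y <- panel$Y[i, j, k]; nn <- panel$n[i, j]
    ll <- ll + lchoose(nn, y) + y * log(p) + (nn - y) * log(1 - p)
  }
  rank_s <- graph$n_areas - graph$n_components + length(graph$singletons)
  quad_sp <- function(u) {
    s <- 0
    for (e in seq_len(nrow(graph$edges))) {
      s <- s + (u[graph$edges[e, 1]] - u[graph$edges[e, 2]])^2
    }
    for (i in graph$singletons) s <- s + u[i]^2
    s
  }
  quad_rw <- function(x) if (length(x) < 2) 0 else sum((x[-1] - x[-length(x)])^2)
  lp <- sum(dnorm(params$alpha, 0, hyper$sd_alpha, log = TRUE)) +
    sum(dnorm(c(params$beta_s, params$beta_st), 0, hyper$sd_beta, log = TRUE))
  if (K > 1) {
    lp <- lp + sum(dnorm(log(params$gamma_s), 0, hyper$sd_loggamma, log = TRUE)) +
      sum(dnorm(log(params$gamma_t), 0, hyper$sd_loggamma, log = TRUE))
  }
  gmrf <- function(tau, quad, rank) rank / 2 * log(tau) - tau / 2 * quad
  lp <- lp + gmrf(params$tau$us, quad_sp(params$u_s), rank_s)
  for (k in 1:K) lp <- lp + gmrf(params$tau$usk[k], quad_sp(params$u_s_k[, k]),
                                 rank_s)
  lp <- lp + gmrf(params$tau$ut, quad_rw(params$u_t), J - 1)
  for (k in 1:K) lp <- lp + gmrf(params$tau$utk[k], quad_rw(params$u_t_k[, k]),
                                 J - 1)
  qn <- if (interaction == "iid") sum(params$nu^2) else {
    s <- 0; for (i in 1:N) s <- s + quad_rw(params$nu[i, ]); s
  }
  rn <- if (interaction == "iid") N * J - 1 else N * (J - 1)
  lp <- lp + gmrf(params$tau$nu, qn, rn)
  for (tau in c(params$tau$us, params$tau$usk, params$tau$ut, params$tau$utk,
                params$tau$nu)) {
    lp <- lp + dgamma(tau, shape = hyper$tau_shape, rate = hyper$tau_rate,
                      log = TRUE)
  }
  ll + lp
}
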