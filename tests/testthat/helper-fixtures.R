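# Small in-code fixtures shared across test files.

# path graph 1-2-3 (areas "a","b","c")
path3_graph <- function() {
  build_adjacency(rbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
}

# star: center "c0" with three leaves
star_graph <- function() {
  build_adjacency(rbind(c("c0", "l1"), c("c0", "l2"), c("c0", "l3")),
                  c("c0", "l1", "l2", "l3"))
}

# tiny simulated dataset used by several modules
tiny_sim <- function(seed = 11, n_rows = 3, n_cols = 3, ...) {
  generate_dataset(apo_sim_config(n_rows = n_rows, n_cols = n_cols, ...),
                   seed = seed)
}

# random Erdos-Renyi-ish graph on n nodes for property tests
random_graph <- function(n, p_edge = 0.3) {
  ids <- paste0("v", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  em <- cbind(ids[pairs[keep, 1]], ids[pairs[keep, 2]])
  if (sum(keep) == 0) em <- matrix(character(0), ncol = 2)
  build_adjacency(em, ids)
}

# independent edge-loop oracle for the ICAR penalty
icar_oracle <- function(field, graph) {
  s <- 0
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      s <- s + (field[graph$edges[e, 1]] - field[graph$edges[e, 2]])^2
    }
  }
  s
}

# random constraint-satisfying parameter state for a panel/graph
random_params <- function(sim, seed = 1) {
  set.seed(seed)
  d <- apomap:::panel_dims(sim$panel)
  K <- d[["K"]]; N <- d[["N"]]; J <- d[["J"]]
  raw <- model_params(
    alpha = rnorm(K, -3, 0.5),
    beta_s = rnorm(d[["P"]], 0, 0.1),
    beta_st = rnorm(d[["Q"]], 0, 0.1),
    gamma_s = exp(rnorm(K, 0, 0.3)),
    gamma_t = exp(rnorm(K, 0, 0.3)),
    u_s = rnorm(N, 0, 0.4),
    u_s_k = matrix(rnorm(N * K, 0, 0.2), N, K),
    u_t = rnorm(J, 0, 0.2),
    u_t_k = matrix(rnorm(J * K, 0, 0.1), J, K),
    nu = matrix(rnorm(N * J, 0, 0.05), N, J),
    tau = list(us = runif(1, 0.5, 4), usk = runif(K, 2, 20),
               ut = runif(1, 20, 200), utk = runif(K, 100, 600),
               nu = runif(1, 100, 600)))
  apply_constraints(raw, sim$graph)
}
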