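#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-or-more-chain diagnostic: with n retained draws per chain,
#' within-chain variance W (mean of per-chain variances) and between-chain
#' variance B (n times the variance of the chain means),
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate mixing;
#' identical chains give `sqrt((n - 1)/n) <= 1`.
#'
#' @param samples an `apo_samples` or a numeric matrix (draws x chains).
#' @param parameter parameter name when `samples` is an `apo_samples`.
#' @return the scalar Rhat.
#' @export
gelman_rubin <- function(samples, parameter = NULL) {
  x <- if (inherits(samples, "apo_samples")) {
    if (is.null(parameter)) stop("supply a parameter name")
    param_draws(samples, parameter)
  } else {
    as.matrix(samples)
  }
  if (ncol(x) < 2L) stop("Gelman-Rubin needs at least 2 chains")
  n <- nrow(x)
  if (n < 2L) stop("Gelman-Rubin needs at least 2 retained draws")
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) {
    return(if (B == 0) sqrt((n - 1) / n) else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Monte-Carlo error check (batch means)
#'
#' Estimates the Monte-Carlo standard error of the posterior mean with
#' `floor(sqrt(n))` batch means and compares it to the posterior standard
#' deviation; the chain passes the stability rule when the ratio is below 5%.
#' A constant chain is flagged degenerate and fails.
#'
#' @param samples an `apo_samples`, a numeric vector of draws, or a draws x
#'   chains matrix (chains are pooled).
#' @param parameter parameter name when `samples` is an `apo_samples`.
#' @param threshold pass threshold for mc_error/sd (default 0.05).
#' @return list: `mc_error`, `sd`, `ratio`, `pass`, `degenerate`, `n`,
#'   `n_batches`.
#' @export
mc_error_check <- function(samples, parameter = NULL, threshold = 0.05) {
  x <- if (inherits(samples, "apo_samples")) {
    as.vector(param_draws(samples, parameter))
  } else {
    as.vector(as.matrix(samples))
  }
  n <- length(x)
  if (n < 100L) stop("Monte-Carlo error check needs at least 100 draws")
  s <- stats::sd(x)
  if (s == 0) {
    return(list(mc_error = 0, sd = 0, ratio = NA_real_, pass = FALSE,
                degenerate = TRUE, n = n, n_batches = NA_integer_))
  }
  b <- floor(sqrt(n))
  m <- n %/% b
  bm <- colMeans(matrix(x[seq_len(b * m)], m, b))
  mc <- stats::sd(bm) / sqrt(b)
  list(mc_error = mc, sd = s, ratio = mc / s, pass = (mc / s) < threshold,
       degenerate = FALSE, n = n, n_batches = b)
}

#' Long-format trace data for every retained scalar parameter
#'
#' @param samples an `apo_samples`.
#' @param parameters optional subset of parameter names (default: all).
#' @return data frame: `chain`, `iteration` (retained-draw index),
#'   `parameter`, `value`.
#' @export
trace_data <- function(samples, parameters = NULL) {
  if (is.null(parameters)) parameters <- samples$par_names
  bad <- setdiff(parameters, samples$par_names)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (ch in seq_along(samples$draws)) {
    m <- samples$draws[[ch]][, parameters, drop = FALSE]
    out[[ch]] <- data.frame(
      chain = ch, iteration = rep(seq_len(nrow(m)), times = ncol(m)),
      parameter = rep(parameters, each = nrow(m)), value = as.vector(m))
  }
  do.call(rbind, out)
}

#' Write trace CSVs for monitoring
#'
#' @param samples an `apo_samples`.
#' @param path output CSV path.
#' @param parameters optional subset (default: all scalar parameters).
#' @export
export_traces <- function(samples, path, parameters = NULL) {
  utils::write.csv(trace_data(samples, parameters), path, row.names = FALSE)
  invisible(path)
}

#' Trace plots for selected parameters
#'
#' One panel per parameter, chains overlaid.
#'
#' @param samples an `apo_samples`.
#' @param parameters parameter names (default: intercepts and weights).
#' @param file optional png path; when given the plot is written there.
#' @export
plot_traces <- function(samples, parameters = NULL, file = NULL) {
  if (is.null(parameters)) {
    parameters <- grep("^(alpha|gamma)", samples$par_names, value = TRUE)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 250 * length(parameters))
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(length(parameters), 1L),
                       mar = c(2, 4, 2, 1))
  # restore par before any device teardown so no stray device is opened
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  for (p in parameters) {
    m <- param_draws(samples, p)
    graphics::matplot(m, type = "l", lty = 1, ylab = p, xlab = "")
  }
  invisible(NULL)
}

#' Convergence report across monitored parameters
#'
#' Gelman-Rubin and MC-error/SD for each requested parameter, with the
#' conventional `Rhat < 1.1` convergence flag and the 5% stability rule.
#'
#' @param samples an `apo_samples` with >= 2 chains.
#' @param parameters parameter names (default: intercepts, effects, weights,
#'   precisions).
#' @return data frame: parameter, rhat, converged, mc_ratio, stable.
#' @export
convergence_report <- function(samples, parameters = NULL) {
  if (is.null(parameters)) {
    parameters <- grep("^(alpha|beta|gamma|tau)", samples$par_names,
                       value = TRUE)
  }
  rows <- lapply(parameters, function(p) {
    r <- gelman_rubin(samples, p)
    mc <- mc_error_check(samples, p)
    data.frame(parameter = p, rhat = r, converged = is.finite(r) && r < 1.1,
               mc_ratio = mc$ratio, stable = isTRUE(mc$pass))
  })
  do.call(rbind, rows)
}
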