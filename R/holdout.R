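#' Hold out a random fraction of the space-time cube
#'
#' Uniformly samples observed (area, period, outcome) cells without
#' replacement, masks them out of the training panel, and keeps their
#' observed values aside for posterior-predictive comparison. The sampling
#' unit is the cell, uniform across outcomes; `stratify_by_outcome` draws the
#' fraction within each outcome instead.
#'
#' @param data an `apo_panel`.
#' @param fraction fraction of observed cells to hold out (0 < fraction < 1;
#'   default 0.2).
#' @param seed integer seed; the split is deterministic given it.
#' @param stratify_by_outcome logical (default FALSE).
#' @return list: `train` (panel with held-out cells masked), `heldout`
#'   (data frame: `i`, `j`, `k`, `area_id`, `period`, `outcome`, `Y`, `n`).
#' @export
holdout_split <- function(data, fraction = 0.2, seed = 1L,
                          stratify_by_outcome = FALSE) {
  stopifnot(inherits(data, "apo_panel"), fraction > 0, fraction < 1)
  d <- panel_dims(data)
  set.seed(seed)
  if (stratify_by_outcome) {
    held <- integer(0)
    for (k in seq_len(d[["K"]])) {
      idx_k <- which(data$mask & slice_mask(d, k))
      held <- c(held, sample(idx_k, round(fraction * length(idx_k))))
    }
  } else {
    idx <- which(data$mask)
    held <- sample(idx, round(fraction * length(idx)))
  }
  held <- sort(held)
  N <- d[["N"]]; J <- d[["J"]]
  k <- (held - 1L) %/% (N * J) + 1L
  r <- (held - 1L) %% (N * J)
  j <- r %/% N + 1L
  i <- r %% N + 1L
  heldout <- data.frame(
    i = i, j = j, k = k,
    area_id = data$area_ids[i], period = data$periods[j],
    outcome = data$outcomes[k],
    Y = data$Y[held], n = data$n[cbind(i, j)])
  train <- data
  train$mask[held] <- FALSE
  train$Y[held] <- 0L
  for (kk in seq_len(d[["K"]])) {
    if (!any(train$mask[, , kk])) {
      stop("holdout fraction leaves outcome '", data$outcomes[[kk]],
           "' with no observed cells")
    }
  }
  list(train = train, heldout = heldout)
}

slice_mask <- function(d, k) {
  m <- array(FALSE, c(d[["N"]], d[["J"]], d[["K"]]))
  m[, , k] <- TRUE
  m
}

#' Posterior-predictive comparison on held-out cells
#'
#' For each held-out cell, draws a replicate count `Y* ~ Binomial(n, pi)` per
#' retained posterior draw of the risk surface (fitted on the training
#' split), and reports the predictive median, the 2.5-97.5% interval, whether
#' the held-out observation falls inside it, overall interval coverage, and
#' the mean absolute error on the rate scale.
#'
#' @param samples an `apo_samples` fitted on the training split with
#'   `store_pi = TRUE`.
#' @param data the original `apo_panel` (for denominators).
#' @param heldout the held-out cell data frame from [holdout_split()].
#' @param seed optional seed for the predictive draws.
#' @return list of class `holdout_report`: `cells` (per-cell table),
#'   `coverage`, `mae_rate`, `n_cells`, `empty` flag.
#' @export
posterior_predictive_compare <- function(samples, data, heldout, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(heldout) == 0L) {
    return(structure(list(cells = heldout, coverage = NA_real_,
                          mae_rate = NA_real_, n_cells = 0L, empty = TRUE),
                     class = "holdout_report"))
  }
  zero_n <- heldout$n == 0
  if (any(zero_n)) {
    warning(sum(zero_n), " held-out cell(s) with n = 0 excluded")
    heldout <- heldout[!zero_n, , drop = FALSE]
  }
  pim <- stacked_pi(samples)
  d <- samples$dims
  rows <- lapply(seq_len(nrow(heldout)), function(r) {
    cidx <- cell_index(heldout$i[[r]], heldout$j[[r]], heldout$k[[r]], d)
    pi_draws <- pim[, cidx]
    ystar <- stats::rbinom(length(pi_draws), size = heldout$n[[r]],
                           prob = pi_draws)
    qs <- stats::quantile(ystar, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(pred_lower = qs[[1L]], pred_median = qs[[2L]],
               pred_upper = qs[[3L]],
               covered = heldout$Y[[r]] >= qs[[1L]] &
                 heldout$Y[[r]] <= qs[[3L]])
  })
  cells <- cbind(heldout, do.call(rbind, rows))
  structure(
    list(cells = cells, coverage = mean(cells$covered),
         mae_rate = mean(abs(cells$pred_median / cells$n -
                               cells$Y / cells$n)),
         n_cells = nrow(cells), empty = FALSE),
    class = "holdout_report")
}

#' @export
print.holdout_report <- function(x, ...) {
  if (x$empty) {
    cat("holdout_report: no held-out cells (coverage undefined)\n")
  } else {
    cat(sprintf(
      "holdout_report: %d cells, 95%% interval coverage %.3f, rate MAE %.5f\n",
      x$n_cells, x$coverage, x$mae_rate))
  }
  invisible(x)
}
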