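#' Assemble a space-time-cube panel
#'
#' The unit of analysis is the (area i, period j, outcome k) cell: `Y[i, j, k]`
#' events out of `n[i, j]` live births, the denominator being shared across
#' outcomes within an area-period. Covariates come in two blocks: time-invariant
#' (`X_s`, one value per area) and space-time varying (`X_st`, one value per
#' area-period).
#'
#' @param Y integer array `n_areas x n_periods x n_outcomes` of event counts.
#' @param n integer matrix `n_areas x n_periods` of live-birth denominators.
#' @param X_s optional numeric matrix `n_areas x P` of time-invariant
#'   covariates.
#' @param X_st optional numeric array `n_areas x n_periods x Q` of space-time
#'   covariates.
#' @param mask optional logical array like `Y`; `TRUE` marks cells present in
#'   the data. Defaults to all observed.
#' @param area_ids,periods,outcomes optional labels; defaults are generated.
#' @return an object of class `apo_panel`.
#' @export
panel_data <- function(Y, n, X_s = NULL, X_st = NULL, mask = NULL,
                       area_ids = NULL, periods = NULL, outcomes = NULL) {
  if (length(dim(Y)) != 3L) stop("Y must be a 3-d array (area x period x outcome)")
  N <- dim(Y)[[1L]]; J <- dim(Y)[[2L]]; K <- dim(Y)[[3L]]
  n <- as.matrix(n)
  if (!all(dim(n) == c(N, J))) stop("n must be an n_areas x n_periods matrix")
  if (is.null(mask)) mask <- array(TRUE, dim(Y))
  if (!all(dim(mask) == dim(Y))) stop("mask must have the dimensions of Y")
  mask <- array(as.logical(mask), dim(Y))
  if (any(!is.finite(n)) || any(n < 0)) stop("denominators must be finite and >= 0")
  obs <- mask & !is.na(Y)
  if (any(Y[obs] < 0)) stop("negative event counts")
  nrep <- array(n, dim(Y))
  if (any(Y[obs] > nrep[obs])) stop("event count exceeds its denominator")
  if (any(nrep[obs] == 0 & Y[obs] != 0)) stop("cells with n = 0 must have Y = 0")
  if (!is.null(X_s)) {
    X_s <- as.matrix(X_s)
    if (nrow(X_s) != N) stop("X_s must have one row per area")
    if (any(!is.finite(X_s))) stop("non-finite values in X_s")
    if (is.null(colnames(X_s))) colnames(X_s) <- paste0("xs", seq_len(ncol(X_s)))
  }
  if (!is.null(X_st)) {
    if (length(dim(X_st)) != 3L || !all(dim(X_st)[1:2] == c(N, J))) {
      stop("X_st must be an n_areas x n_periods x Q array")
    }
    if (any(!is.finite(X_st))) stop("non-finite values in X_st")
    if (is.null(dimnames(X_st)[[3L]])) {
      dimnames(X_st) <- list(NULL, NULL, paste0("xst", seq_len(dim(X_st)[[3L]])))
    }
  }
  if (is.null(area_ids)) area_ids <- paste0("area", seq_len(N))
  if (is.null(periods)) periods <- seq_len(J)
  if (is.null(outcomes)) outcomes <- paste0("outcome", seq_len(K))
  stopifnot(length(area_ids) == N, length(periods) == J, length(outcomes) == K)
  structure(
    list(Y = Y, n = n, X_s = X_s, X_st = X_st, mask = mask,
         area_ids = as.character(area_ids), periods = periods,
         outcomes = as.character(outcomes)),
    class = "apo_panel")
}

panel_dims <- function(panel) {
  c(N = dim(panel$Y)[[1L]], J = dim(panel$Y)[[2L]], K = dim(panel$Y)[[3L]],
    P = if (is.null(panel$X_s)) 0L else ncol(panel$X_s),
    Q = if (is.null(panel$X_st)) 0L else dim(panel$X_st)[[3L]])
}

#' @export
print.apo_panel <- function(x, ...) {
  d <- panel_dims(x)
  cat(sprintf(
    "apo_panel: %d areas x %d periods x %d outcomes (%d static, %d space-time covariates)\n",
    d[["N"]], d[["J"]], d[["K"]], d[["P"]], d[["Q"]]))
  cat(sprintf("  observed cells: %d of %d (%.1f%%)\n", sum(x$mask),
              length(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Write a panel to long-format CSV files
#'
#' The counts file has columns `area_id, period, outcome, events, live_births,
#' observed`; the covariates file (written when covariates are present) is long
#' with columns `area_id, period, covariate, value`, where `period` is empty
#' for time-invariant covariates.
#'
#' @param panel an `apo_panel`.
#' @param counts_path path for the counts CSV.
#' @param covariates_path optional path for the covariates CSV.
#' @export
write_panel_csv <- function(panel, counts_path, covariates_path = NULL) {
  d <- panel_dims(panel)
  grid <- expand.grid(i = seq_len(d[["N"]]), j = seq_len(d[["J"]]),
                      k = seq_len(d[["K"]]))
  df <- data.frame(
    area_id = panel$area_ids[grid$i],
    period = panel$periods[grid$j],
    outcome = panel$outcomes[grid$k],
    events = as.vector(panel$Y),
    live_births = as.vector(panel$n)[grid$i + d[["N"]] * (grid$j - 1L)],
    observed = as.vector(panel$mask))
  utils::write.csv(df, counts_path, row.names = FALSE, quote = FALSE)
  if (!is.null(covariates_path) && (d[["P"]] > 0L || d[["Q"]] > 0L)) {
    rows <- list()
    if (d[["P"]] > 0L) {
      for (p in seq_len(d[["P"]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          area_id = panel$area_ids, period = NA,
          covariate = colnames(panel$X_s)[[p]], value = panel$X_s[, p])
      }
    }
    if (d[["Q"]] > 0L) {
      for (q in seq_len(d[["Q"]])) {
        g <- expand.grid(i = seq_len(d[["N"]]), j = seq_len(d[["J"]]))
        rows[[length(rows) + 1L]] <- data.frame(
          area_id = panel$area_ids[g$i], period = panel$periods[g$j],
          covariate = dimnames(panel$X_st)[[3L]][[q]],
          value = as.vector(panel$X_st[, , q]))
      }
    }
    utils::write.csv(do.call(rbind, rows), covariates_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(counts_path)
}

#' Read a panel from long-format CSV files
#'
#' Inverse of [write_panel_csv()]. Cells absent from the counts file, or with
#' `observed` false, are masked out.
#'
#' @param counts_path counts CSV path.
#' @param covariates_path optional covariates CSV path.
#' @return an `apo_panel`.
#' @export
read_panel_csv <- function(counts_path, covariates_path = NULL) {
  df <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  need <- c("area_id", "period", "outcome", "events", "live_births")
  if (!all(need %in% names(df))) {
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  }
  area_ids <- unique(df$area_id)
  periods <- sort(unique(df$period))
  outcomes <- unique(df$outcome)
  N <- length(area_ids); J <- length(periods); K <- length(outcomes)
  i <- match(df$area_id, area_ids)
  j <- match(df$period, periods)
  k <- match(df$outcome, outcomes)
  Y <- array(0L, c(N, J, K))
  mask <- array(FALSE, c(N, J, K))
  n <- matrix(0, N, J)
  idx3 <- i + N * (j - 1L) + N * J * (k - 1L)
  Y[idx3] <- as.integer(df$events)
  obs <- if ("observed" %in% names(df)) as.logical(df$observed) else TRUE
  mask[idx3] <- obs
  n[i + N * (j - 1L)] <- df$live_births
  Y[!mask] <- 0L
  X_s <- NULL; X_st <- NULL
  if (!is.null(covariates_path)) {
    cv <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
    static <- cv[is.na(cv$period) | cv$period == "", ]
    dyn <- cv[!(is.na(cv$period) | cv$period == ""), ]
    if (nrow(static)) {
      covs <- unique(static$covariate)
      X_s <- matrix(NA_real_, N, length(covs), dimnames = list(NULL, covs))
      X_s[cbind(match(static$area_id, area_ids),
                match(static$covariate, covs))] <- static$value
    }
    if (nrow(dyn)) {
      covs <- unique(dyn$covariate)
      X_st <- array(NA_real_, c(N, J, length(covs)),
                    dimnames = list(NULL, NULL, covs))
      X_st[cbind(match(dyn$area_id, area_ids), match(dyn$period, periods),
                 match(dyn$covariate, covs))] <- dyn$value
    }
  }
  panel_data(Y, n, X_s = X_s, X_st = X_st, mask = mask,
             area_ids = area_ids, periods = periods, outcomes = outcomes)
}

# linear cell index into the flattened (area, period, outcome) cube
cell_index <- function(i, j, k, dims) {
  i + dims[["N"]] * (j - 1L) + dims[["N"]] * dims[["J"]] * (k - 1L)
}

#' Published national yearly counts of adverse pregnancy outcomes
#'
#' Facility-reported yearly totals of the four adverse pregnancy outcomes for
#' Kenya, 2016-2019, aggregated from sub-county routine reporting. Bundled as
#' reference input for the temporal-burden summaries (yearly totals and
#' percent changes).
#'
#' @return data frame with columns `outcome`, `year`, `count`.
#' @export
apo_reference_counts <- function() {
  path <- system.file("extdata", "apo_yearly_counts_kenya.csv",
                      package = "apomap", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published national live-birth total, 2016-2019
#'
#' Reported total live births over the four study years, used as the crude
#' denominator in the rate examples.
#'
#' @return a single number.
#' @export
apo_reference_live_births <- function() 2896659

#' Published national stillbirth rates (first and last year)
#'
#' Model-based stillbirth rates per 1000 live births in the first and last
#' study year, used to reproduce the reported rate decline.
#'
#' @return named numeric vector with elements `first` and `last`.
#' @export
apo_reference_stillbirth_rates <- function() c(first = 19.4, last = 18.1)
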