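#' Yearly totals of the outcome burden
#'
#' Sums event counts by outcome-period, by outcome (all periods) and by
#' period (all outcomes). For a panel, missing cells contribute 0 and the
#' observed completeness is reported alongside; a long data frame with
#' columns `outcome`, `year` (or `period`) and `count` is summarised the
#' same way.
#'
#' @param x an `apo_panel` or a long data frame.
#' @return list: `by` (outcome x period table), `outcome_totals`,
#'   `period_totals`, `grand_total`, `completeness`.
#' @export
yearly_totals <- function(x) UseMethod("yearly_totals")

#' @export
yearly_totals.apo_panel <- function(x) {
  by <- apply(x$Y, c(3L, 2L), sum)
  dimnames(by) <- list(x$outcomes, x$periods)
  finish_totals(by, completeness = mean(x$mask))
}

#' @export
yearly_totals.data.frame <- function(x) {
  pcols <- intersect(c("year", "period"), names(x))
  if (length(pcols) == 0L || !all(c("outcome", "count") %in% names(x))) {
    stop("need columns outcome, year/period, count")
  }
  pcol <- pcols[[1L]]
  by <- tapply(x$count, list(x$outcome, x[[pcol]]), sum, default = 0)
  by <- by[unique(x$outcome), , drop = FALSE]  # keep input outcome order
  finish_totals(by, completeness = 1)
}

finish_totals <- function(by, completeness) {
  list(by = by,
       outcome_totals = rowSums(by),
       period_totals = colSums(by),
       grand_total = sum(by),
       completeness = completeness)
}

#' Signed percent change between two values
#'
#' `100 * (last - first) / first`. Applied per posterior draw it yields the
#' uncertainty interval of the change.
#'
#' @param first baseline value, strictly positive.
#' @param last comparison value.
#' @return signed percent (full precision; round to one decimal for
#'   presentation).
#' @export
percent_change <- function(first, last) {
  if (any(!is.finite(first)) || any(!is.finite(last))) {
    stop("percent_change needs finite inputs")
  }
  if (any(first <= 0)) stop("percent change undefined for first <= 0")
  100 * (last - first) / first
}

#' Events per `scale` live births
#'
#' `scale * count / denominator`; conventionally per 100 live births for low
#' birth weight and pre-term birth, per 1000 for stillbirth and neonatal
#' death. Applied to posterior draws of the risk surface it yields
#' model-based rates with uncertainty intervals; applied to raw totals it is
#' a crude rate, which should be labelled as such.
#'
#' @param count event count (or posterior draw thereof).
#' @param denominator live births, strictly positive.
#' @param scale 100 or 1000 (any positive number accepted).
#' @return the rate.
#' @export
rate_per <- function(count, denominator, scale = 1000) {
  if (any(!is.finite(denominator)) || any(denominator <= 0)) {
    stop("rate denominator must be > 0")
  }
  stopifnot(scale > 0)
  scale * count / denominator
}

#' Per-area change in posterior-median rate between two periods
#'
#' Computes the signed difference in rate for each area between a first and
#' last period, the rank ordering, and the partition into declining /
#' increasing / unchanged areas with the extremes of each set.
#'
#' @param rates matrix of per-area rates (areas x periods, columns named by
#'   period) or a data frame with columns `area_id`, `period`, `rate`.
#' @param first_period,last_period period labels to compare.
#' @return list: `table` (area_id, first, last, difference, rank — rank 1 is
#'   the largest increase), `n_decline`, `n_increase`, `n_zero`, `extremes`.
#' @export
area_absolute_difference <- function(rates, first_period, last_period) {
  if (is.data.frame(rates)) {
    stopifnot(all(c("area_id", "period", "rate") %in% names(rates)))
    areas <- unique(rates$area_id)
    first <- rates$rate[match(paste(areas, first_period),
                              paste(rates$area_id, rates$period))]
    last <- rates$rate[match(paste(areas, last_period),
                             paste(rates$area_id, rates$period))]
  } else {
    rates <- as.matrix(rates)
    cn <- colnames(rates)
    if (is.null(cn)) cn <- as.character(seq_len(ncol(rates)))
    f <- match(as.character(first_period), cn)
    l <- match(as.character(last_period), cn)
    if (is.na(f) || is.na(l)) stop("period not found among rate columns")
    areas <- rownames(rates)
    if (is.null(areas)) areas <- paste0("area", seq_len(nrow(rates)))
    first <- rates[, f]
    last <- rates[, l]
  }
  if (any(is.na(first)) || any(is.na(last))) {
    stop("both periods must be present for every area")
  }
  diffs <- last - first
  tab <- data.frame(area_id = areas, first = first, last = last,
                    difference = diffs,
                    rank = rank(-diffs, ties.method = "first"),
                    row.names = NULL)
  tab <- tab[order(tab$rank), , drop = FALSE]
  decl <- tab[tab$difference < 0, , drop = FALSE]
  incr <- tab[tab$difference > 0, , drop = FALSE]
  list(table = tab,
       n_decline = nrow(decl), n_increase = nrow(incr),
       n_zero = sum(diffs == 0),
       extremes = list(
         largest_increase = if (nrow(incr)) incr[1L, ] else NULL,
         largest_decline = if (nrow(decl)) decl[nrow(decl), ] else NULL))
}

#' Posterior surface of the shared components
#'
#' Per-area posterior median and 95% interval of the shared spatial field
#' (the risk surface common to all outcomes), and per-period summaries of the
#' shared temporal trend. The spatial table is keyed by area id for joining
#' to a boundary file (e.g. a GeoJSON property).
#'
#' @param samples an `apo_samples`.
#' @param transform `"identity"` (logit-scale field, default) or `"exp"`
#'   (relative-risk-like scale).
#' @return list: `spatial` (area_id, median, lower, upper), `temporal`
#'   (period, median, lower, upper), `transform`.
#' @export
shared_component_surface <- function(samples,
                                     transform = c("identity", "exp")) {
  transform <- match.arg(transform)
  f <- if (transform == "exp") exp else identity
  m <- as.matrix(samples)
  qsum <- function(cols, labels, key) {
    qs <- t(apply(f(m[, cols, drop = FALSE]), 2L, stats::quantile,
                  probs = c(0.5, 0.025, 0.975)))
    out <- data.frame(labels, qs, row.names = NULL)
    names(out) <- c(key, "median", "lower", "upper")
    out
  }
  spatial <- qsum(grep("^u_s\\[", colnames(m), value = TRUE),
                  samples$area_ids, "area_id")
  temporal <- qsum(grep("^u_t\\[", colnames(m), value = TRUE),
                   samples$periods, "period")
  list(spatial = spatial, temporal = temporal, transform = transform)
}

#' Model-based rates per area, period and outcome
#'
#' Summarises the retained posterior risk surfaces into rates per `scale`
#' live births with 95% uncertainty intervals, plus the crude observed rate
#' per cell.
#'
#' @param samples an `apo_samples` with stored risk surfaces.
#' @param data the fitted `apo_panel`.
#' @param scale named vector of scales per outcome (default 1000 for all).
#' @return data frame: area_id, period, outcome, median, lower, upper
#'   (posterior rate), crude (observed rate, NA where masked or n = 0).
#' @export
posterior_rate_table <- function(samples, data, scale = NULL) {
  d <- panel_dims(data)
  if (is.null(scale)) scale <- stats::setNames(rep(1000, d[["K"]]), data$outcomes)
  pim <- stacked_pi(samples)
  qs <- t(apply(pim, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  grid <- expand.grid(i = seq_len(d[["N"]]), j = seq_len(d[["J"]]),
                      k = seq_len(d[["K"]]))
  sc <- scale[data$outcomes[grid$k]]
  nn <- data$n[cbind(grid$i, grid$j)]
  crude <- ifelse(as.vector(data$mask) & nn > 0,
                  sc * as.vector(data$Y) / nn, NA_real_)
  data.frame(
    area_id = data$area_ids[grid$i], period = data$periods[grid$j],
    outcome = data$outcomes[grid$k],
    median = sc * qs[, 1L], lower = sc * qs[, 2L], upper = sc * qs[, 3L],
    crude = crude, row.names = NULL)
}
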