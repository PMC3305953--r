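#' Mean of a PSA distribution specification
#'
#' @param spec one row of \code{\link{default_parameters}} (data frame row or
#'   list) with fields \code{dist}, \code{a}, \code{b}, \code{scale}.
#' @return Analytic mean: beta \eqn{\alpha/(\alpha+\beta)}; uniform
#'   \eqn{(lo+hi)/2}; scaled beta \eqn{s\,\alpha/(\alpha+\beta)}.
#' @export
dist_mean <- function(spec) {
  switch(as.character(spec$dist),
    beta = spec$a / (spec$a + spec$b),
    uniform = (spec$a + spec$b) / 2,
    scaled_beta = spec$scale * spec$a / (spec$a + spec$b),
    stop("dist_mean is undefined for kind '", spec$dist, "'"))
}

# inverse CDF of one spec at quantile u
dist_quantile <- function(spec, u) {
  switch(as.character(spec$dist),
    beta = stats::qbeta(u, spec$a, spec$b),
    uniform = stats::qunif(u, spec$a, spec$b),
    scaled_beta = spec$scale * stats::qbeta(u, spec$a, spec$b),
    stop("no quantile function for kind '", spec$dist, "'"))
}

#' Draw one joint parameter sample for probabilistic sensitivity analysis
#'
#' Every non-fixed row of the parameter table is sampled from its PSA
#' distribution. Rows sharing a \code{group} label are perfectly correlated:
#' one shared uniform quantile is mapped through each member's inverse CDF.
#' Natural-history parameters are not drawn here — they come jointly from
#' the calibration posterior (see \code{\link{run_psa}}), preserving their
#' correlation.
#'
#' @param table parameter table (\code{\link{default_parameters}}).
#' @return Named list of sampled values (fixed rows at base case), usable as
#'   \code{\link{parameter_values}} overrides.
#' @export
sample_draw <- function(table = default_parameters()) {
  vals <- stats::setNames(as.list(table$base), table$key)
  groups <- unique(stats::na.omit(table$group))
  gq <- stats::setNames(stats::runif(length(groups)), groups)
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    if (row$dist == "fixed") next
    u <- if (!is.na(row$group)) gq[[row$group]] else stats::runif(1)
    vals[[row$key]] <- dist_quantile(row, u)
  }
  vals
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of joint parameter uncertainty: per iteration one
#' draw of all varied parameters (\code{\link{sample_draw}}) plus one
#' natural-history parameter set resampled from the calibration posterior,
#' applied to every strategy (common random parameters across strategies).
#' Produces the per-iteration cost/QALY cloud, incremental results against
#' no screening, the cost-effectiveness acceptability curve over a
#' willingness-to-pay grid, and 95\% confidence ellipse parameters from the
#' bivariate normal fit to the incremental cloud.
#'
#' @param strategy_ids strategies to evaluate (preset ids, excluding
#'   \code{"none"}, which is always added as comparator).
#' @param posterior calibration posterior data frame (or \code{NULL} to keep
#'   natural history fixed at \code{template}).
#' @param template base \code{nh_params} supplying non-calibrated fields.
#' @param life_table life table.
#' @param table parameter table with PSA distributions.
#' @param n_iter iterations (the reference analysis uses 1200).
#' @param seed RNG seed.
#' @param wtp_grid willingness-to-pay grid, euro/QALY.
#' @param discount_rate annual discount rate.
#' @return List with \code{cloud} (iteration, strategy, cost, qaly, and
#'   increments vs no screening), \code{ceac} (wtp, strategy, probability
#'   optimal), and \code{ellipses} (per strategy: means, covariance of
#'   incremental QALY/cost).
#' @export
run_psa <- function(strategy_ids = c("gFOBT_55_74", "FIT_55_74", "FSIG_60"),
                    posterior = NULL, template = nh_params(),
                    life_table = generate_life_table(),
                    table = default_parameters(), n_iter = 1200L, seed = 1L,
                    wtp_grid = seq(0, 50000, by = 500),
                    discount_rate = NULL) {
  set.seed(seed)
  ids <- c("none", setdiff(strategy_ids, "none"))
  rows <- vector("list", n_iter * length(ids))
  k <- 0L
  for (it in seq_len(n_iter)) {
    draw <- sample_draw(table)
    values <- parameter_values(overrides = draw, table = table)
    if (!is.null(posterior)) {
      j <- sample.int(nrow(posterior), 1)
      params <- posterior_params(posterior, j, template)
    } else params <- template
    rate <- if (is.null(discount_rate)) values$discount_rate else discount_rate
    for (id in ids) {
      r <- simulate_strategy(id, params, life_table, values,
                             discount_rate = rate)
      k <- k + 1L
      rows[[k]] <- data.frame(iteration = it, strategy = id,
                              cost = r$cost, qaly = r$qaly)
    }
  }
  cloud <- do.call(rbind, rows)
  base <- cloud[cloud$strategy == "none", c("iteration", "cost", "qaly")]
  names(base)[2:3] <- c("cost0", "qaly0")
  cloud <- merge(cloud, base, by = "iteration")
  cloud$inc_cost <- cloud$cost - cloud$cost0
  cloud$inc_qaly <- cloud$qaly - cloud$qaly0
  cloud <- cloud[order(cloud$iteration, match(cloud$strategy, ids)),
                 c("iteration", "strategy", "cost", "qaly", "inc_cost", "inc_qaly")]

  ceac <- compute_ceac(cloud, wtp_grid)
  ell <- lapply(setdiff(ids, "none"), function(id) {
    d <- cloud[cloud$strategy == id, c("inc_qaly", "inc_cost")]
    list(strategy = id, mean = colMeans(d), cov = stats::cov(d))
  })
  names(ell) <- setdiff(ids, "none")
  list(cloud = cloud, ceac = ceac, ellipses = ell)
}

#' Cost-effectiveness acceptability curve from a PSA cloud
#'
#' At each willingness-to-pay threshold, the probability a strategy is
#' optimal is the fraction of iterations in which it has the highest net
#' monetary benefit (wtp x QALYs - cost) among all strategies (including no
#' screening).
#'
#' @param cloud PSA cloud from \code{\link{run_psa}}.
#' @param wtp_grid willingness-to-pay grid.
#' @return Data frame \code{(wtp, strategy, probability)}; probabilities sum
#'   to 1 over strategies at each threshold.
#' @export
compute_ceac <- function(cloud, wtp_grid = seq(0, 50000, by = 500)) {
  ids <- unique(cloud$strategy)
  iters <- unique(cloud$iteration)
  qal <- vapply(ids, function(id) cloud$qaly[cloud$strategy == id], numeric(length(iters)))
  cst <- vapply(ids, function(id) cloud$cost[cloud$strategy == id], numeric(length(iters)))
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * qal - cst
    best <- ids[max.col(nmb, ties.method = "first")]
    data.frame(wtp = w, strategy = ids,
               probability = as.vector(table(factor(best, levels = ids))) /
                 length(iters))
  })
  do.call(rbind, out)
}

#' One-way sensitivity analysis of a single parameter
#'
#' Re-simulates the strategy and the no-screening comparator with one
#' parameter set to each endpoint of its sensitivity range (everything else
#' at base case) and reports the ICER against no screening at each endpoint.
#' The discount rate and the never-attender fraction are supported alongside
#' the distribution-bearing parameters.
#'
#' @param strategy_id strategy preset id.
#' @param parameter parameter key from \code{\link{default_parameters}}.
#' @param lo,hi endpoints (defaults: the table's SA range).
#' @param params natural-history parameters.
#' @param life_table life table.
#' @param table parameter table.
#' @return Data frame with one row per endpoint: value, cost and QALY
#'   increments, ICER.
#' @export
one_way_sa <- function(strategy_id, parameter, lo = NULL, hi = NULL,
                       params = nh_params(),
                       life_table = generate_life_table(),
                       table = default_parameters()) {
  if (!parameter %in% table$key) stop("unknown parameter: ", parameter)
  row <- table[table$key == parameter, ]
  if (is.null(lo)) lo <- row$sa_lo
  if (is.null(hi)) hi <- row$sa_hi
  if (is.na(lo) || is.na(hi)) stop("no sensitivity range for ", parameter)
  out <- lapply(c(lo = lo, hi = hi), function(x) {
    values <- parameter_values(overrides = stats::setNames(list(x), parameter),
                            table = table)
    none <- simulate_strategy("none", params, life_table, values)
    r <- simulate_strategy(strategy_id, params, life_table, values)
    ic <- compute_icer(r, none)
    data.frame(parameter = parameter, value = x, delta_cost = ic$delta_cost,
               delta_qaly = ic$delta_qaly, icer = ic$icer)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tornado table over the one-way sensitivity parameters
#'
#' Runs \code{\link{one_way_sa}} for each requested parameter and orders the
#' result by the width of the ICER range (most influential first).
#'
#' @param strategy_id strategy preset id.
#' @param parameters parameter keys (default: a standard influential set —
#'   discount rate, test costs, cancer-management costs, uptake, test
#'   performance).
#' @inheritParams one_way_sa
#' @return Data frame \code{(parameter, lo, hi, icer_lo, icer_hi, width)}.
#' @export
tornado <- function(strategy_id,
                    parameters = c("discount_rate", "cost_fit_proc",
                                   "cost_fit_kit", "cost_col",
                                   "cost_crc_sympt_III", "cost_crc_screen_III",
                                   "fit_uptake", "fit_sens_crc",
                                   "fit_sens_adenoma", "fit_spec",
                                   "col_compliance", "u_cancer"),
                    params = nh_params(),
                    life_table = generate_life_table(),
                    table = default_parameters()) {
  rows <- lapply(parameters, function(pm) {
    sa <- one_way_sa(strategy_id, pm, params = params,
                     life_table = life_table, table = table)
    data.frame(parameter = pm, lo = sa$value[1], hi = sa$value[2],
               icer_lo = sa$icer[1], icer_hi = sa$icer[2],
               width = abs(sa$icer[2] - sa$icer[1]))
  })
  res <- do.call(rbind, rows)
  res[order(-res$width), ]
}
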