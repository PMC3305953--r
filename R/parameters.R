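#' Default model parameters: base-case values, ranges and PSA distributions
#'
#' Returns the full default parameter table of the evaluation: screening-test
#' operating characteristics, uptake and compliance, diagnostic-test
#' performance, surveillance parameters, complication probabilities, health
#' utilities, unit costs (2008 euro) and the discount rate — each with its
#' base-case value, one-way sensitivity-analysis range and probabilistic
#' sensitivity-analysis distribution. Distribution kinds are \code{beta}
#' (shape1/shape2 in \code{a}, \code{b}), \code{uniform} (\code{lo}, \code{hi}),
#' \code{scaled_beta} (\code{scale} times a beta) and \code{fixed}. Parameters
#' sharing a \code{group} label are treated as perfectly correlated in the
#' PSA (sampled from a single shared quantile).
#'
#' The published FIT cancer-sensitivity beta shape1 of 35.29 gives a mean of
#' 0.198, irreconcilable with its 71\% base case and 67--75\% range, while
#' shape1 = 350.29 reproduces both (mean 0.710); by default the distribution
#' is re-parameterised accordingly. Set \code{fit_beta_verbatim = TRUE} to
#' use the value 35.29 unchanged.
#'
#' @param fit_beta_verbatim keep the internally inconsistent FIT cancer
#'   sensitivity beta shape as printed instead of the re-parameterised
#'   default.
#' @return A data frame with columns \code{key}, \code{base}, \code{sa_lo},
#'   \code{sa_hi}, \code{dist}, \code{a}, \code{b}, \code{scale},
#'   \code{group}.
#' @export
default_parameters <- function(fit_beta_verbatim = FALSE) {
  r <- function(key, base, sa_lo = NA, sa_hi = NA, dist = "fixed",
                a = NA, b = NA, scale = NA, group = NA_character_) {
    data.frame(key = key, base = base, sa_lo = sa_lo, sa_hi = sa_hi,
               dist = dist, a = a, b = b, scale = scale, group = group)
  }
  fit_crc_a <- if (fit_beta_verbatim) 35.29 else 350.29
  tb <- rbind(
    # screening-test performance
    r("gfobt_sens_adenoma", 0.11, 0.10, 0.12, "beta", 11.40, 92.10, group = "gfobt_sens"),
    r("gfobt_sens_crc",     0.36, 0.31, 0.42, "beta", 105.00, 186.60, group = "gfobt_sens"),
    r("gfobt_spec",         0.97, 0.96, 0.98, "beta", 1083.40, 33.50),
    r("fit_sens_adenoma",   0.21, 0.19, 0.22, "beta", 594.62, 2236.92, group = "fit_sens"),
    r("fit_sens_crc",       0.71, 0.67, 0.75, "beta", fit_crc_a, 143.08, group = "fit_sens"),
    r("fit_spec",           0.95, 0.94, 0.96, "beta", 1732.57, 91.19),
    r("fsig_sens_adenoma_low",  0.65, 0.60, 0.70, "beta", 235.00, 126.54, group = "fsig_sens"),
    r("fsig_sens_adenoma_high", 0.74, 0.68, 0.78, "beta", 180.00, 63.24, group = "fsig_sens"),
    r("fsig_sens_crc",          0.90, 0.85, 0.95, "beta", 90.00, 10.00, group = "fsig_sens"),
    r("fsig_spec",              0.92, 0.90, 0.95, "beta", 250.00, 21.74),
    # uptake and compliance
    r("gfobt_uptake", 0.53, 0.32, 0.70, "uniform", 0.32, 0.70),
    r("fit_uptake",   0.53, 0.32, 0.70, "uniform", 0.32, 0.70),
    r("fsig_uptake",  0.39, 0.24, 0.67, "uniform", 0.24, 0.67),
    r("never_attender", 0.13, 0.00, 0.41),
    r("col_compliance", 0.86, 0.81, 0.90, "uniform", 0.81, 0.90),
    # diagnostic-test performance
    r("col_sens_adenoma_low",  0.77, 0.73, 0.80, "beta", 350.00, 104.55, group = "col_sens"),
    r("col_sens_adenoma_high", 0.98, 0.93, 0.99, "uniform", 0.93, 0.99, group = "col_sens"),
    r("col_sens_crc",          0.98, 0.95, 0.99, "uniform", 0.95, 0.99, group = "col_sens"),
    r("col_spec",              0.97, 0.96, 0.98, "beta", 970.00, 30.00),
    r("ctc_sens_adenoma_low",  0.53, 0.45, 0.60, "beta", 80.00, 70.94, group = "ctc_sens"),
    r("ctc_sens_adenoma_high", 0.85, 0.48, 1.00, "beta", 4.50, 0.79, group = "ctc_sens"),
    r("ctc_sens_crc",          0.85, 0.75, 0.95, "beta", 50.00, 8.82, group = "ctc_sens"),
    r("ctc_spec",              0.86, 0.80, 0.90, "beta", 140.00, 22.79),
    r("mean_adenomas_removed", 1.9),
    # surveillance
    r("frac_high_risk_surv", 0.29),
    r("surv_compliance", 0.86, 0.81, 0.90, "uniform", 0.81, 0.90),
    # complications
    r("fsig_perf",       0.00002, 0, 0.00051, "uniform", 0, 0.00051),
    r("fsig_perf_death", 0.06452, 0, 0.09070, "uniform", 0, 0.09070),
    r("fsig_bleed",      0.00029, 0.00002, 0.00054, "uniform", 0.00002, 0.00054),
    r("col_perf_polyp",   0.00216, 0.00168, 0.00298, "uniform", 0.00168, 0.00298),
    r("col_perf_nopolyp", 0.00107, 0.00010, 0.00249, "uniform", 0.00010, 0.00249),
    r("col_perf_death",   0.05195, 0, 0.09070, "uniform", 0, 0.09070),
    r("col_bleed",        0.00379, 0.00065, 0.00412, "uniform", 0.00065, 0.00412),
    # utilities
    r("u_cancer_free", 0.94),
    r("u_cancer", 0.80, 0.43, 0.94, "scaled_beta", 3.92, 0.69, scale = 0.94),
    # unit costs, euro 2008
    r("cost_gfobt_kit",  1.70, 1.36, 2.04, "uniform", 1.36, 2.04),
    r("cost_gfobt_proc", 7.81, 6.25, 9.37, "uniform", 6.25, 9.37),
    r("cost_fit_kit",    3.75, 3.00, 4.50, "uniform", 3.00, 4.50),
    r("cost_fit_proc",  11.60, 9.28, 13.92, "uniform", 9.28, 13.92),
    r("cost_fsig",  150, 120, 180, "uniform", 120, 180),
    r("cost_col",   650, 520, 780, "uniform", 520, 780),
    r("cost_ctc",   550, 440, 660, "uniform", 440, 660),
    r("cost_perforation", 10200, 8160, 12240, "uniform", 8160, 12240),
    r("cost_bleed",        3079, 2463, 3695, "uniform", 2463, 3695),
    r("cost_path_adenoma",   65, 52, 78, "uniform", 52, 78),
    r("cost_path_cancer",   530, 424, 636, "uniform", 424, 636),
    r("cost_crc_sympt_I",   23688, 18950, 28425, "uniform", 18950, 28425),
    r("cost_crc_sympt_II",  37180, 29744, 44616, "uniform", 29744, 44616),
    r("cost_crc_sympt_III", 48835, 39068, 58602, "uniform", 39068, 58602),
    r("cost_crc_sympt_IV",  36602, 29281, 43922, "uniform", 29281, 43922),
    r("cost_crc_screen_I",   22885, 18308, 27462, "uniform", 18308, 27462),
    r("cost_crc_screen_II",  36377, 29102, 43652, "uniform", 29102, 43652),
    r("cost_crc_screen_III", 48032, 38426, 57638, "uniform", 38426, 57638),
    r("cost_crc_screen_IV",  35799, 28639, 42959, "uniform", 28639, 42959),
    # analysis settings
    r("discount_rate", 0.04, 0.00, 0.06),
    r("ctc_fraction", 0.05)
  )
  rownames(tb) <- tb$key
  tb
}

#' Base-case parameter values as a named list
#'
#' Collapses \code{\link{default_parameters}} to its base-case column, with
#' optional overrides — the single source the screening, economics and
#' uncertainty layers read their inputs from.
#'
#' @param overrides named list/vector of values replacing base-case entries.
#' @param table parameter table (default \code{default_parameters()}).
#' @return Named list of parameter values.
#' @export
parameter_values <- function(overrides = NULL, table = default_parameters()) {
  v <- as.list(stats::setNames(table$base, table$key))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(v))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    v[names(overrides)] <- overrides
  }
  v
}
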