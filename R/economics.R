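#' Cost and utility schedules
#'
#' Builds the per-event cost schedule (2008 euro) and health-state utility
#' weights from a base-case (or PSA-sampled) value list. Lifetime
#' stage-specific cancer-management costs are held separately for
#' screen-detected and symptomatic cases and are charged once, at diagnosis.
#' The pathology cost of a polypectomy episode multiplies the per-adenoma
#' cost by the mean number of adenomas removed per person.
#'
#' @param values named value list from \code{\link{parameter_values}}.
#' @return \code{cost_schedule()}: list of unit costs; \code{utility_schedule()}:
#'   list with \code{u_cancer_free} and per-stage \code{u_cancer}.
#' @export
cost_schedule <- function(values = parameter_values()) {
  stages <- c("I", "II", "III", "IV")
  cs <- list(
    gfobt_kit = values$cost_gfobt_kit, gfobt_proc = values$cost_gfobt_proc,
    fit_kit = values$cost_fit_kit, fit_proc = values$cost_fit_proc,
    fsig = values$cost_fsig, col = values$cost_col, ctc = values$cost_ctc,
    perforation = values$cost_perforation, bleed = values$cost_bleed,
    path_adenoma_episode = values$cost_path_adenoma * values$mean_adenomas_removed,
    path_cancer = values$cost_path_cancer,
    crc_sympt = stats::setNames(unlist(values[paste0("cost_crc_sympt_", stages)]), stages),
    crc_screen = stats::setNames(unlist(values[paste0("cost_crc_screen_", stages)]), stages))
  if (any(unlist(cs) < 0)) stop("costs must be non-negative")
  cs
}

#' @rdname cost_schedule
#' @export
utility_schedule <- function(values = parameter_values()) {
  u <- list(u_cancer_free = values$u_cancer_free,
            u_cancer = stats::setNames(rep(values$u_cancer, 4),
                                       c("I", "II", "III", "IV")))
  if (any(unlist(u) < 0) || any(unlist(u) > 1)) stop("utilities must lie in [0, 1]")
  u
}

#' Discount factor with a fixed reference age
#'
#' Costs and health outcomes are discounted at \code{rate} per annum from a
#' reference age (base case: age 55, the screening start). Flows before the
#' reference age carry a factor of 1; incremental comparisons between
#' strategies are invariant to this convention because no strategy differs
#' before the reference age.
#'
#' @param age age (years) at which the flow occurs; vectorised.
#' @param rate annual discount rate (>= 0).
#' @param ref_age reference age (default 55).
#' @return Discount factor(s) \eqn{(1+rate)^{-(age-ref)}} for
#'   \code{age >= ref_age}, else 1.
#' @export
discount_factor <- function(age, rate, ref_age = 55) {
  if (rate < 0) stop("discount rate must be non-negative")
  ifelse(age >= ref_age, (1 + rate)^-(age - ref_age), 1)
}

# per-event cost of one row of an event tally (names = event types)
event_cost_vector <- function(event_names, costs) {
  stages <- c("I", "II", "III", "IV")
  map <- c(
    kits_dispatched_gfobt = costs$gfobt_kit,
    kits_processed_gfobt = costs$gfobt_proc,
    kits_dispatched_fit = costs$fit_kit,
    kits_processed_fit = costs$fit_proc,
    kits_processed_fit_reflex = costs$fit_proc,
    fsig_screen = costs$fsig,
    col_diagnostic = costs$col, col_surveillance = costs$col, ctc = costs$ctc,
    polypectomy = costs$path_adenoma_episode,
    polypectomy_fsig = costs$path_adenoma_episode,
    path_cancer = costs$path_cancer,
    bleed = costs$bleed, perforation = costs$perforation, perf_death = 0,
    stats::setNames(costs$crc_screen, paste0("diag_screen_", stages)),
    stats::setNames(costs$crc_screen, paste0("diag_surv_", stages)),
    stats::setNames(costs$crc_sympt, paste0("diag_sympt_", stages)))
  missing <- setdiff(event_names, names(map))
  if (length(missing)) stop("no cost defined for event type(s): ",
                            paste(missing, collapse = ", "))
  map[event_names]
}

#' Aggregate a trajectory and event tally into discounted cost and QALYs
#'
#' QALYs accrue per annual cycle as state occupancy at cycle start times the
#' state utility (clinical cancer states carry the cancer utility from
#' diagnosis until death; all other live states, including pre-clinical
#' cancer and surveillance, carry the cancer-free utility). Costs accrue per
#' cycle from the event tally; lifetime cancer-management costs are included
#' in the tally as diagnosis events. Both streams are discounted by
#' \code{\link{discount_factor}} at the age they occur.
#'
#' @param trajectory data frame of per-age occupancy over the public state
#'   space (first column \code{age}); the final row (model end) accrues
#'   nothing.
#' @param tally_by_age matrix of per-cycle event counts per person (rows
#'   named by age, columns by event type).
#' @param costs,utilities schedules from \code{\link{cost_schedule}} /
#'   \code{\link{utility_schedule}}.
#' @param rate annual discount rate.
#' @param ref_age discounting reference age.
#' @param half_cycle apply a half-cycle correction to QALY occupancy
#'   (average of cycle start and end); off by default.
#' @return Named vector \code{c(cost =, qaly =)} per person.
#' @export
accumulate <- function(trajectory, tally_by_age, costs, utilities, rate,
                       ref_age = 55, half_cycle = FALSE) {
  ss <- state_index()$ss
  occ <- as.matrix(trajectory[, ss$name, drop = FALSE])
  ages <- trajectory$age[-nrow(trajectory)]
  u <- ifelse(startsWith(ss$compartment, "crc_clinical"),
              utilities$u_cancer[ss$stage], utilities$u_cancer_free)
  u[!ss$alive] <- 0
  occ_cycle <- occ[-nrow(occ), , drop = FALSE]
  if (half_cycle) occ_cycle <- (occ_cycle + occ[-1, , drop = FALSE]) / 2
  df <- discount_factor(ages, rate, ref_age)
  qaly <- sum(df * (occ_cycle %*% u))

  cost <- 0
  if (!is.null(tally_by_age) && nrow(tally_by_age) > 0) {
    cvec <- event_cost_vector(colnames(tally_by_age), costs)
    dft <- discount_factor(as.numeric(rownames(tally_by_age)), rate, ref_age)
    cost <- sum(dft * (tally_by_age %*% cvec))
  }
  c(cost = cost, qaly = qaly)
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' @param a,b strategy results (lists with \code{cost} and \code{qaly} per
#'   person); \code{a} is compared against the less effective or comparator
#'   strategy \code{b}.
#' @return List with \code{icer} (euro per QALY; \code{NA} when the QALY
#'   difference is zero), \code{delta_cost}, \code{delta_qaly}, and
#'   \code{note} (\code{"ok"}, \code{"undefined"} for zero QALY difference,
#'   \code{"cost_saving"} for cheaper-and-more-effective, \code{"dominated"}
#'   for costlier-and-less-effective).
#' @export
compute_icer <- function(a, b) {
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  if (dq == 0) {
    return(list(icer = NA_real_, delta_cost = dc, delta_qaly = 0,
                note = "undefined"))
  }
  icer <- dc / dq
  note <- if (dq > 0 && dc < 0) "cost_saving"
          else if (dq < 0 && dc > 0) "dominated"
          else "ok"
  list(icer = icer, delta_cost = dc, delta_qaly = dq, note = note)
}

#' Efficiency frontier with strict and extended dominance
#'
#' Orders strategies by effectiveness, removes strictly dominated entries
#' (at least as costly and no more effective than another strategy), then
#' iteratively removes extended-dominated entries (incremental ICER against
#' the previous frontier point exceeding that of a later point) until the
#' frontier ICERs are strictly increasing — the lower convex hull of the
#' cost-effectiveness plane.
#'
#' @param results data frame with columns \code{id}, \code{cost},
#'   \code{qaly} (one row per strategy, including the comparator), or a list
#'   of strategy results.
#' @return Data frame sorted by QALYs with columns \code{id}, \code{cost},
#'   \code{qaly}, \code{status} (\code{on_frontier}, \code{dominated},
#'   \code{extended_dominated}) and \code{icer} (frontier ICER against the
#'   previous frontier point; \code{NA} off-frontier and for the origin).
#' @export
efficiency_frontier <- function(results) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(id = r$id, cost = r$cost, qaly = r$qaly)))
  }
  if (nrow(results) < 2) stop("need at least two strategies")
  d <- results[order(results$qaly, results$cost), ]
  d$status <- "on_frontier"
  for (i in seq_len(nrow(d))) {
    dom <- d$cost <= d$cost[i] & d$qaly >= d$qaly[i] &
      (d$cost < d$cost[i] | d$qaly > d$qaly[i])
    if (any(dom)) d$status[i] <- "dominated"
  }
  repeat {
    on <- which(d$status == "on_frontier")
    if (length(on) < 3) break
    ic <- diff(d$cost[on]) / diff(d$qaly[on])
    bad <- which(diff(ic) < 0)  # ICER vs previous exceeds ICER of next point
    if (!length(bad)) break
    d$status[on[bad[1] + 1L]] <- "extended_dominated"
  }
  d$icer <- NA_real_
  on <- which(d$status == "on_frontier")
  if (length(on) > 1) d$icer[on[-1]] <- diff(d$cost[on]) / diff(d$qaly[on])
  rownames(d) <- NULL
  d
}
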