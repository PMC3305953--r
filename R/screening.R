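#' Screening-test operating characteristics
#'
#' @param name one of \code{"gFOBT"}, \code{"FIT"}, \code{"FSIG"},
#'   \code{"COL"}, \code{"CTC"}.
#' @param values value list from \code{\link{parameter_values}}.
#' @return List with per-lesion-class sensitivities, specificity and
#'   \code{reach} (\code{"distal_only"} for flexible sigmoidoscopy,
#'   \code{"whole_colon"} otherwise). Faecal tests carry a single adenoma
#'   sensitivity applied to both risk classes.
#' @export
test_performance <- function(name = c("gFOBT", "FIT", "FSIG", "COL", "CTC"),
                             values = parameter_values()) {
  name <- match.arg(name)
  tp <- switch(name,
    gFOBT = list(sens_adenoma_low = values$gfobt_sens_adenoma,
                 sens_adenoma_high = values$gfobt_sens_adenoma,
                 sens_crc = values$gfobt_sens_crc,
                 specificity = values$gfobt_spec, reach = "whole_colon"),
    FIT = list(sens_adenoma_low = values$fit_sens_adenoma,
               sens_adenoma_high = values$fit_sens_adenoma,
               sens_crc = values$fit_sens_crc,
               specificity = values$fit_spec, reach = "whole_colon"),
    FSIG = list(sens_adenoma_low = values$fsig_sens_adenoma_low,
                sens_adenoma_high = values$fsig_sens_adenoma_high,
                sens_crc = values$fsig_sens_crc,
                specificity = values$fsig_spec, reach = "distal_only"),
    COL = list(sens_adenoma_low = values$col_sens_adenoma_low,
               sens_adenoma_high = values$col_sens_adenoma_high,
               sens_crc = values$col_sens_crc,
               specificity = values$col_spec, reach = "whole_colon"),
    CTC = list(sens_adenoma_low = values$ctc_sens_adenoma_low,
               sens_adenoma_high = values$ctc_sens_adenoma_high,
               sens_crc = values$ctc_sens_crc,
               specificity = values$ctc_spec, reach = "whole_colon"))
  pr <- unlist(tp[1:4])
  if (any(pr < 0 | pr > 1)) stop("test performance outside [0, 1]")
  c(list(name = name), tp)
}

#' Probability a test is positive in a given health state
#'
#' Diseased states within the test's reach return the lesion-class
#' sensitivity; normal epithelium — and lesions outside the reach of
#' flexible sigmoidoscopy (proximal lesions) — return one minus specificity.
#'
#' @param test a \code{\link{test_performance}} list.
#' @param state a state name from \code{\link{build_state_space}} (must be a
#'   live pre-diagnosis state).
#' @return Positivity probability.
#' @export
test_positivity <- function(test, state) {
  ss <- state_index()$ss
  row <- ss[ss$name == state, ]
  if (nrow(row) != 1) stop("unknown state: ", state)
  if (!row$prediagnosis) {
    stop("test positivity is defined only for live pre-diagnosis states")
  }
  if (row$compartment == "normal") return(1 - test$specificity)
  if (test$reach == "distal_only" && row$location == "proximal") {
    return(1 - test$specificity)
  }
  switch(sub("_.*", "", row$compartment),
         adenoma = if (row$compartment == "adenoma_low") test$sens_adenoma_low
                   else test$sens_adenoma_high,
         crc = test$sens_crc)
}

#' Screening strategy configuration
#'
#' @param id strategy label.
#' @param primary_test \code{"gFOBT"}, \code{"FIT"}, \code{"FSIG"} or
#'   \code{NA} (no screening).
#' @param reflex_test optional second-line test applied to primary-test
#'   positives (\code{"FIT"} after gFOBT).
#' @param start_age,end_age eligible age range.
#' @param interval years between rounds (\code{NA} = once-only).
#' @param uptake overall per-round participation among the eligible.
#' @param never_attender_fraction fraction refusing every invitation
#'   (faecal strategies only).
#' @param colonoscopy_compliance compliance with colonoscopy referral.
#' @param ctc_fraction fraction of referrals routed to CT colonography.
#' @return A \code{strategy_config} list.
#' @export
strategy_config <- function(id, primary_test, reflex_test = NA, start_age,
                            end_age, interval = NA, uptake,
                            never_attender_fraction = 0,
                            colonoscopy_compliance, ctc_fraction = 0.05) {
  if (!is.na(primary_test)) {
    if (start_age > end_age) stop("start_age must not exceed end_age")
    if (!is.na(interval) && interval < 1) stop("interval must be >= 1 year")
    pr <- c(uptake, never_attender_fraction, colonoscopy_compliance, ctc_fraction)
    if (any(pr < 0 | pr > 1)) stop("strategy probabilities must lie in [0, 1]")
    if (never_attender_fraction < 1 &&
        uptake / (1 - never_attender_fraction) > 1) {
      stop("uptake exceeds the potential-attender fraction")
    }
  }
  structure(list(id = id, primary_test = primary_test,
                 reflex_test = reflex_test, start_age = start_age,
                 end_age = end_age, interval = interval, uptake = uptake,
                 never_attender_fraction = never_attender_fraction,
                 colonoscopy_compliance = colonoscopy_compliance,
                 ctc_fraction = ctc_fraction),
            class = "strategy_config")
}

#' Named strategy presets
#'
#' The eight evaluated scenarios (three core, five age variants) plus the
#' no-screening comparator: biennial gFOBT with reflex FIT or biennial FIT
#' at 55--74 / 55--64 / 65--74, and once-only flexible sigmoidoscopy at 60
#' or 55.
#'
#' @param id preset name; see \code{strategy_presets()} for the list.
#' @param values value list supplying uptake/compliance parameters.
#' @return A \code{\link{strategy_config}}.
#' @export
strategy_preset <- function(id, values = parameter_values()) {
  mk_faecal <- function(id, test, a0, a1) {
    strategy_config(id, test, reflex_test = if (test == "gFOBT") "FIT" else NA,
                    start_age = a0, end_age = a1, interval = 2,
                    uptake = if (test == "gFOBT") values$gfobt_uptake else values$fit_uptake,
                    never_attender_fraction = values$never_attender,
                    colonoscopy_compliance = values$col_compliance,
                    ctc_fraction = values$ctc_fraction)
  }
  mk_fsig <- function(id, age) {
    strategy_config(id, "FSIG", start_age = age, end_age = age, interval = NA,
                    uptake = values$fsig_uptake, never_attender_fraction = 0,
                    colonoscopy_compliance = values$col_compliance,
                    ctc_fraction = values$ctc_fraction)
  }
  switch(id,
    none = strategy_config("none", NA, NA, NA, NA, NA, NA, 0, NA, 0),
    gFOBT_55_74 = mk_faecal(id, "gFOBT", 55, 74),
    gFOBT_55_64 = mk_faecal(id, "gFOBT", 55, 64),
    gFOBT_65_74 = mk_faecal(id, "gFOBT", 65, 74),
    FIT_55_74 = mk_faecal(id, "FIT", 55, 74),
    FIT_55_64 = mk_faecal(id, "FIT", 55, 64),
    FIT_65_74 = mk_faecal(id, "FIT", 65, 74),
    FSIG_60 = mk_fsig(id, 60),
    FSIG_55 = mk_fsig(id, 55),
    stop("unknown strategy preset: ", id))
}

#' @rdname strategy_preset
#' @export
strategy_presets <- function() {
  c("none", "gFOBT_55_74", "FIT_55_74", "FSIG_60",
    "gFOBT_55_64", "gFOBT_65_74", "FIT_55_64", "FIT_65_74", "FSIG_55")
}

#' Scheduled screening ages of a strategy
#'
#' Faecal strategies repeat every \code{interval} years from \code{start_age}
#' while the round age does not exceed \code{end_age - 1}; once-only
#' strategies screen at \code{start_age} alone.
#'
#' @param strategy a \code{\link{strategy_config}}.
#' @return Integer vector of round ages (empty for no screening).
#' @export
round_schedule <- function(strategy) {
  if (is.na(strategy$primary_test)) return(integer(0))
  if (is.na(strategy$interval)) return(as.integer(strategy$start_age))
  seq.int(strategy$start_age, strategy$end_age - 1L, by = strategy$interval)
}

## ---- expanded overlay representation --------------------------------------
## The pre-diagnosis cohort is a blocks x lesions matrix: the routine
## screening pool plus post-polypectomy surveillance tunnel blocks (risk
## schedule x years-since-exam x clear-exam count), each holding the 13 live
## pre-diagnosis lesion states. Clinical states are split by detection route
## (screen / surveillance / symptomatic) for costing and reporting.

ov_event_types <- c(
  "kits_dispatched_gfobt", "kits_processed_gfobt", "kits_dispatched_fit",
  "kits_processed_fit", "kits_processed_fit_reflex", "fsig_screen",
  "col_diagnostic", "col_surveillance", "ctc", "polypectomy",
  "polypectomy_fsig", "path_cancer", "bleed", "perforation", "perf_death",
  paste0("diag_screen_", c("I", "II", "III", "IV")),
  paste0("diag_surv_", c("I", "II", "III", "IV")),
  paste0("diag_sympt_", c("I", "II", "III", "IV")))

ov_blocks <- c("pool", "sh0", "sh1",
               paste0("si", rep(0:3, 2), "c", rep(0:1, each = 4)))
# lesion positions within a block (pre-diagnosis state order)
ov_l <- list(norm = 1L, adl = 2:3, adh = 4:5,
             pc = matrix(6:13, nrow = 4,
                         dimnames = list(c("I", "II", "III", "IV"),
                                         c("distal", "proximal"))))

.ov_int_rows <- grep("^si", ov_blocks)
.ov_high_rows <- match(c("sh0", "sh1"), ov_blocks)

# simultaneous timer shift as a block-permutation matrix (due cells absorb)
.ov_shift <- local({
  n <- length(ov_blocks)
  S <- matrix(0, n, n, dimnames = list(ov_blocks, ov_blocks))
  move <- c(sh0 = "sh1", sh1 = "sh1", si0c0 = "si1c0", si1c0 = "si2c0",
            si2c0 = "si3c0", si3c0 = "si3c0", si0c1 = "si1c1",
            si1c1 = "si2c1", si2c1 = "si3c1", si3c1 = "si3c1", pool = "pool")
  for (b in ov_blocks) S[b, move[[b]]] <- 1
  S
})

ov_init_state <- function() {
  si <- state_index()
  lesions <- si$ss$name[si$prediag]
  X <- matrix(0, length(ov_blocks), length(lesions),
              dimnames = list(ov_blocks, lesions))
  X["pool", ov_l$norm] <- 1
  list(X = X,
       clin = matrix(0, 4, 3, dimnames = list(c("I", "II", "III", "IV"),
                                              c("screen", "surv", "sympt"))),
       dead = c(dead_crc = 0, dead_perforation = 0, dead_other = 0))
}

empty_tally <- function() {
  stats::setNames(numeric(length(ov_event_types)), ov_event_types)
}

# precomputed per-strategy context: positivity vectors, diagnostic-test
# detection fractions, compliance and complication probabilities
ov_context <- function(strategy, values) {
  lesions <- state_index()$ss$name[state_index()$prediag]
  pos <- NULL
  if (!is.na(strategy$primary_test)) {
    tp <- test_performance(strategy$primary_test, values)
    pos <- vapply(lesions, function(s) test_positivity(tp, s), 0)
    if (!is.na(strategy$reflex_test)) {
      tp2 <- test_performance(strategy$reflex_test, values)
      pos2 <- vapply(lesions, function(s) test_positivity(tp2, s), 0)
      ctx_reflex <- pos                      # first-line positives take reflex
      pos <- pos * pos2                      # independent tests
      attr(pos, "first_line") <- ctx_reflex
    }
  }
  col <- test_performance("COL", values)
  ctc <- test_performance("CTC", values)
  list(strategy = strategy, values = values, pos = pos,
       fsig = if (!is.na(strategy$primary_test) &&
                  strategy$primary_test == "FSIG")
         test_performance("FSIG", values),
       col = col, ctc = ctc,
       fh = values$frac_high_risk_surv,
       comply = strategy$colonoscopy_compliance,
       ctcf = strategy$ctc_fraction,
       surv_comply = values$surv_compliance,
       f_col_polyp = 1 - values$col_perf_polyp * values$col_perf_death,
       f_col_rest = 1 - values$col_perf_nopolyp * values$col_perf_death)
}

# expected-value colonoscopy on a lesion-mass vector x (length 13).
# Returns outward flows net of fatal perforations plus event counts.
ov_colonoscopy <- function(x, cx) {
  v <- cx$values
  det_adl <- x[ov_l$adl] * cx$col$sens_adenoma_low
  det_adh <- x[ov_l$adh] * cx$col$sens_adenoma_high
  det_crc <- (x[ov_l$pc[, 1]] + x[ov_l$pc[, 2]]) * cx$col$sens_crc
  clear <- x
  clear[ov_l$adl] <- clear[ov_l$adl] - det_adl
  clear[ov_l$adh] <- clear[ov_l$adh] - det_adh
  clear[ov_l$pc] <- clear[ov_l$pc] * (1 - cx$col$sens_crc)
  n_col <- sum(x)
  n_polyp <- sum(det_adl, det_adh)
  rest <- n_col - n_polyp
  list(det_low = sum(det_adl) * cx$f_col_polyp,
       det_high = sum(det_adh) * cx$f_col_polyp,
       det_crc = det_crc * cx$f_col_rest,
       clear = clear * cx$f_col_rest,
       n_col = n_col, n_polyp = n_polyp,
       perforation = n_polyp * v$col_perf_polyp + rest * v$col_perf_nopolyp,
       bleed = n_col * v$col_bleed,
       perf_death = (n_polyp * v$col_perf_polyp + rest * v$col_perf_nopolyp) *
         v$col_perf_death)
}

# CT colonography with colonoscopy work-up of positives
ov_ctc_exam <- function(x, cx) {
  pos <- x * 0
  pos[ov_l$norm] <- x[ov_l$norm] * (1 - cx$ctc$specificity)
  pos[ov_l$adl] <- x[ov_l$adl] * cx$ctc$sens_adenoma_low
  pos[ov_l$adh] <- x[ov_l$adh] * cx$ctc$sens_adenoma_high
  pos[ov_l$pc] <- x[ov_l$pc] * cx$ctc$sens_crc
  res <- ov_colonoscopy(pos, cx)
  res$clear <- res$clear + (x - pos)  # CTC negatives return unexamined
  res$n_ctc <- sum(x)
  res
}

# route work-up findings into the state; route = "screen" or "surv"
ov_route_findings <- function(st, res, route, cx, tn) {
  st$X["pool", ov_l$norm] <- st$X["pool", ov_l$norm] + res$det_low
  st$X["sh0", ov_l$norm] <- st$X["sh0", ov_l$norm] + res$det_high * cx$fh
  st$X["si0c0", ov_l$norm] <- st$X["si0c0", ov_l$norm] +
    res$det_high * (1 - cx$fh)
  st$clin[, route] <- st$clin[, route] + res$det_crc
  st$dead["dead_perforation"] <- st$dead["dead_perforation"] + res$perf_death
  tn[paste0("diag_", route, "_", rownames(ov_l$pc))] <-
    tn[paste0("diag_", route, "_", rownames(ov_l$pc))] + res$det_crc
  tn["polypectomy"] <- tn["polypectomy"] + res$n_polyp
  tn["path_cancer"] <- tn["path_cancer"] + sum(res$det_crc)
  tn["perforation"] <- tn["perforation"] + res$perforation
  tn["bleed"] <- tn["bleed"] + res$bleed
  tn["perf_death"] <- tn["perf_death"] + res$perf_death
  list(st = st, tn = tn)
}

# referral cascade shared by faecal and sigmoidoscopy rounds
ov_workup <- function(st, referred, route, cx, tn) {
  st$X["pool", ] <- st$X["pool", ] + referred * (1 - cx$comply)
  to_col <- referred * cx$comply * (1 - cx$ctcf)
  to_ctc <- referred * cx$comply * cx$ctcf
  res <- ov_colonoscopy(to_col, cx)
  tn["col_diagnostic"] <- tn["col_diagnostic"] + res$n_col
  st$X["pool", ] <- st$X["pool", ] + res$clear
  out <- ov_route_findings(st, res, route, cx, tn)
  st <- out$st; tn <- out$tn
  if (sum(to_ctc) > 0) {
    res2 <- ov_ctc_exam(to_ctc, cx)
    tn["ctc"] <- tn["ctc"] + res2$n_ctc
    tn["col_diagnostic"] <- tn["col_diagnostic"] + res2$n_col
    st$X["pool", ] <- st$X["pool", ] + res2$clear
    out <- ov_route_findings(st, res2, route, cx, tn)
    st <- out$st; tn <- out$tn
  }
  list(st = st, tn = tn)
}

# one screening round (deterministic expected-value redistribution) at the
# given per-round attendance of the simulated sub-cohort
ov_screening_round <- function(st, cx, attendance) {
  tn <- empty_tally()
  v <- cx$values
  strategy <- cx$strategy
  x <- st$X["pool", ]
  test <- strategy$primary_test
  if (test %in% c("gFOBT", "FIT")) {
    key <- if (test == "gFOBT") "gfobt" else "fit"
    tn[paste0("kits_dispatched_", key)] <- sum(x)
    tested <- attendance * x
    tn[paste0("kits_processed_", key)] <- sum(tested)
    pos <- cx$pos
    if (!is.null(attr(pos, "first_line"))) {
      tn["kits_processed_fit_reflex"] <- sum(tested * attr(pos, "first_line"))
    }
    referred <- tested * as.vector(pos)
    st$X["pool", ] <- x - referred
    out <- ov_workup(st, referred, "screen", cx, tn)
    st <- out$st; tn <- out$tn
  } else if (test == "FSIG") {
    tested <- attendance * x
    n <- sum(tested)
    tn["fsig_screen"] <- n
    tn["perforation"] <- n * v$fsig_perf
    tn["bleed"] <- n * v$fsig_bleed
    tn["perf_death"] <- n * v$fsig_perf * v$fsig_perf_death
    st$dead["dead_perforation"] <- st$dead["dead_perforation"] +
      n * v$fsig_perf * v$fsig_perf_death
    tested <- tested * (1 - v$fsig_perf * v$fsig_perf_death)
    lesions <- colnames(st$X)
    pos <- vapply(lesions, function(s) test_positivity(cx$fsig, s), 0)
    # distal low-risk adenomas are removed at the sigmoidoscopy visit
    rm_low <- tested[ov_l$adl[1]] * cx$fsig$sens_adenoma_low
    tn["polypectomy_fsig"] <- rm_low
    referred <- tested * pos
    referred[ov_l$adl[1]] <- 0
    stay <- tested - referred
    stay[ov_l$adl[1]] <- stay[ov_l$adl[1]] - rm_low
    st$X["pool", ] <- (x - attendance * x) + stay
    st$X["pool", ov_l$norm] <- st$X["pool", ov_l$norm] + rm_low
    out <- ov_workup(st, referred, "screen", cx, tn)
    st <- out$st; tn <- out$tn
  } else stop("unknown primary test: ", test)
  list(st = st, tally = tn)
}

# annual surveillance exams for due tunnel cells. A clear exam moves the
# member onto the 3-yearly schedule with one clear exam banked; two clear
# exams 3 years apart exit to the routine screening pool; findings reset.
ov_surveillance_step <- function(st, cx) {
  tn <- empty_tally()
  due <- c(sh1 = "si0c1", si3c0 = "si0c1", si3c1 = "pool")
  for (cell in names(due)) {
    x <- st$X[cell, ]
    if (sum(x) == 0) next
    ex <- x * cx$surv_comply
    st$X[cell, ] <- x - ex
    res <- ov_colonoscopy(ex, cx)
    tn["col_surveillance"] <- tn["col_surveillance"] + res$n_col
    dest <- due[[cell]]
    st$X[dest, ] <- st$X[dest, ] + res$clear
    st$X["si0c0", ov_l$norm] <- st$X["si0c0", ov_l$norm] +
      res$det_low + res$det_high * (1 - cx$fh)
    st$X["sh0", ov_l$norm] <- st$X["sh0", ov_l$norm] + res$det_high * cx$fh
    st$clin[, "surv"] <- st$clin[, "surv"] + res$det_crc
    st$dead["dead_perforation"] <- st$dead["dead_perforation"] + res$perf_death
    tn[paste0("diag_surv_", rownames(ov_l$pc))] <-
      tn[paste0("diag_surv_", rownames(ov_l$pc))] + res$det_crc
    tn["polypectomy"] <- tn["polypectomy"] + res$n_polyp
    tn["path_cancer"] <- tn["path_cancer"] + sum(res$det_crc)
    tn["perforation"] <- tn["perforation"] + res$perforation
    tn["bleed"] <- tn["bleed"] + res$bleed
    tn["perf_death"] <- tn["perf_death"] + res$perf_death
  }
  list(st = st, tally = tn)
}

# natural-history progression and competing deaths within one cycle
ov_progress <- function(st, A, p_sympt, p_crc_death, q) {
  tn <- empty_tally()
  # clinical members present at cycle start face cancer death, then
  # competing other-cause death; this cycle's new arrivals do not
  d <- st$clin * p_crc_death
  st$dead["dead_crc"] <- st$dead["dead_crc"] + sum(d)
  st$dead["dead_other"] <- st$dead["dead_other"] + sum(st$clin - d) * q
  st$clin <- (st$clin - d) * (1 - q)
  tot <- sum(st$X)
  sympt <- (colSums(st$X[, ov_l$pc[, 1], drop = FALSE]) +
            colSums(st$X[, ov_l$pc[, 2], drop = FALSE])) * p_sympt * (1 - q)
  st$X <- (st$X %*% A) * (1 - q)
  st$dead["dead_other"] <- st$dead["dead_other"] + tot * q
  st$clin[, "sympt"] <- st$clin[, "sympt"] + sympt
  tn[paste0("diag_sympt_", rownames(ov_l$pc))] <- sympt
  list(st = st, tally = tn)
}

# aggregate the expanded state to the public 22-state occupancy
ov_to_public <- function(st) {
  si <- state_index()
  occ <- stats::setNames(numeric(si$n), si$ss$name)
  occ[si$prediag] <- st$X["pool", ]
  occ[si$surv] <- c(sum(st$X[.ov_int_rows, ]), sum(st$X[.ov_high_rows, ]))
  occ[si$clinical] <- rowSums(st$clin)
  occ[si$dead] <- st$dead
  occ
}

# embed a public 22-state cohort into the expanded representation
ov_from_public <- function(cohort, surv_blocks = c("si0c0", "sh0")) {
  si <- state_index()
  st <- ov_init_state()
  st$X["pool", ] <- cohort$occupancy[si$prediag]
  st$X[surv_blocks[1], ov_l$norm] <- cohort$occupancy[si$surv[1]]
  st$X[surv_blocks[2], ov_l$norm] <- cohort$occupancy[si$surv[2]]
  st$clin[, "sympt"] <- cohort$occupancy[si$clinical]
  st$dead[] <- cohort$occupancy[si$dead]
  st
}

#' Apply one screening round to a cohort (public state space)
#'
#' Spec-level wrapper over the expanded-representation round: embeds the
#' cohort's pre-diagnosis occupancy into the routine screening pool (any
#' surveillance mass enters a fresh tunnel), performs the deterministic
#' expected-value redistribution of one round, and aggregates back.
#'
#' @param cohort a \code{cohort_state} at a scheduled round age.
#' @param strategy a \code{\link{strategy_config}}.
#' @param values value list from \code{\link{parameter_values}}.
#' @param attendance per-round participation (defaults to overall uptake).
#' @return List with the redistributed \code{cohort} and an event
#'   \code{tally} (counts per cohort member).
#' @export
apply_screening_round <- function(cohort, strategy, values = parameter_values(),
                                  attendance = strategy$uptake) {
  if (!(cohort$age %in% round_schedule(strategy))) {
    stop("age ", cohort$age, " is not a scheduled round for ", strategy$id)
  }
  cx <- ov_context(strategy, values)
  out <- ov_screening_round(ov_from_public(cohort), cx, attendance)
  list(cohort = structure(list(age = cohort$age,
                               occupancy = ov_to_public(out$st)),
                          class = "cohort_state"),
       tally = out$tally)
}

#' Apply one year of adenoma surveillance to a cohort (public state space)
#'
#' Without tunnel bookkeeping in the public state space, embedded
#' surveillance mass is taken as due for examination this year
#' (intermediate-risk members at their final clear exam, so a clear result
#' exits them to the routine pool; high-risk members at a routine annual
#' exam).
#'
#' @inheritParams apply_screening_round
#' @return List with the updated \code{cohort} and event \code{tally}.
#' @export
apply_surveillance <- function(cohort, values = parameter_values()) {
  cx <- ov_context(strategy_preset("none"), values)
  cx$surv_comply <- values$surv_compliance
  out <- ov_surveillance_step(ov_from_public(cohort, c("si3c1", "sh1")), cx)
  list(cohort = structure(list(age = cohort$age,
                               occupancy = ov_to_public(out$st)),
                          class = "cohort_state"),
       tally = out$tally)
}

#' Simulate a screening strategy over the cohort lifetime
#'
#' Runs the natural-history cohort from age 30 to 100 with the screening and
#' surveillance overlay. The population is partitioned once into
#' never-attenders (who receive invitations but never participate) and
#' potential attenders who attend each round independently with probability
#' \code{uptake / (1 - never_attender_fraction)}. Within each annual cycle
#' the order of events is: screening round (if scheduled), surveillance
#' exams, natural-history progression, competing deaths, surveillance-clock
#' advance.
#'
#' @param strategy a \code{\link{strategy_config}} or preset id.
#' @param params natural-history parameters (\code{\link{nh_params}}).
#' @param life_table life table.
#' @param values value list from \code{\link{parameter_values}}.
#' @param discount_rate annual discount rate (default from \code{values}).
#' @param ref_age discounting reference age.
#' @param start_age,end_age simulation span.
#' @param half_cycle half-cycle correction switch for QALY accrual.
#' @return A \code{strategy_result} list: discounted and undiscounted cost
#'   and QALYs per person, lifetime event tally per 100,000, diagnoses by
#'   stage and detection route per 100,000, lifetime incidence and mortality
#'   rates, the public-state trajectory and the per-age tally.
#' @export
simulate_strategy <- function(strategy, params = nh_params(),
                              life_table = generate_life_table(),
                              values = parameter_values(),
                              discount_rate = values$discount_rate,
                              ref_age = 55, start_age = 30L, end_age = 100L,
                              half_cycle = FALSE) {
  if (is.character(strategy)) strategy <- strategy_preset(strategy, values)
  validate_nh_params(params)
  if (is.na(params$direct_scale)) {
    params <- resolve_direct_pathway(params, life_table)
  }
  si <- state_index()
  ages <- seq.int(start_age, end_age - 1L)
  rounds <- round_schedule(strategy)
  is_faecal <- !is.na(strategy$primary_test) &&
    strategy$primary_test %in% c("gFOBT", "FIT")
  f_nv <- if (is_faecal) strategy$never_attender_fraction else 0
  attendance <- if (is.na(strategy$primary_test)) 0 else
    strategy$uptake / (1 - f_nv)
  cx <- ov_context(strategy, values)

  A_band <- lapply(1:5, function(b) {
    nh_predeath_matrix(params, b)[si$prediag, si$prediag, drop = FALSE]
  })
  qs <- q_other_at(life_table, ages)
  bands <- age_band(ages)
  dispatch_key <- if (is_faecal)
    paste0("kits_dispatched_",
           if (strategy$primary_test == "gFOBT") "gfobt" else "fit")

  run_arm <- function(screened) {
    st <- ov_init_state()
    occ <- matrix(0, length(ages) + 1L, si$n,
                  dimnames = list(seq.int(start_age, end_age), si$ss$name))
    occ[1L, ] <- ov_to_public(st)
    tally <- matrix(0, length(ages), length(ov_event_types),
                    dimnames = list(ages, ov_event_types))
    any_surv <- FALSE
    for (t in seq_along(ages)) {
      a <- ages[t]
      if (a %in% rounds) {
        if (screened) {
          out <- ov_screening_round(st, cx, attendance)
          st <- out$st; tally[t, ] <- tally[t, ] + out$tally
          any_surv <- TRUE
        } else if (is_faecal) {
          # never-attenders are still invited: kit dispatch only
          tally[t, dispatch_key] <- sum(st$X["pool", ])
        }
      }
      if (screened && any_surv) {
        out <- ov_surveillance_step(st, cx)
        st <- out$st; tally[t, ] <- tally[t, ] + out$tally
      }
      out <- ov_progress(st, A_band[[bands[t]]], params$p_sympt,
                         params$p_crc_death, qs[t])
      st <- out$st; tally[t, ] <- tally[t, ] + out$tally
      if (screened && any_surv) st$X <- t(.ov_shift) %*% st$X
      occ[t + 1L, ] <- ov_to_public(st)
    }
    list(occ = occ, tally = tally, dead = st$dead)
  }

  att <- run_arm(screened = TRUE)
  if (f_nv > 0) {
    nv <- run_arm(screened = FALSE)
    occ <- (1 - f_nv) * att$occ + f_nv * nv$occ
    tally <- (1 - f_nv) * att$tally + f_nv * nv$tally
    dead <- (1 - f_nv) * att$dead + f_nv * nv$dead
  } else {
    occ <- att$occ; tally <- att$tally; dead <- att$dead
  }

  trajectory <- data.frame(age = as.integer(rownames(occ)), occ,
                           check.names = FALSE)
  costs <- cost_schedule(values)
  utils_ <- utility_schedule(values)
  disc <- accumulate(trajectory, tally, costs, utils_, discount_rate,
                     ref_age, half_cycle)
  undisc <- accumulate(trajectory, tally, costs, utils_, 0, ref_age, half_cycle)

  diag_cols <- function(route) paste0("diag_", route, "_", c("I", "II", "III", "IV"))
  diagnoses <- rbind(screen = colSums(tally[, diag_cols("screen"), drop = FALSE]),
                     surv = colSums(tally[, diag_cols("surv"), drop = FALSE]),
                     sympt = colSums(tally[, diag_cols("sympt"), drop = FALSE])) * 1e5
  colnames(diagnoses) <- c("I", "II", "III", "IV")
  structure(list(
    id = strategy$id, strategy = strategy,
    cost = unname(disc["cost"]), qaly = unname(disc["qaly"]),
    cost_undisc = unname(undisc["cost"]), qaly_undisc = unname(undisc["qaly"]),
    tally = colSums(tally) * 1e5, tally_by_age = tally,
    diagnoses = diagnoses,
    lifetime = list(
      incidence_per_100k = sum(diagnoses),
      mortality_per_100k = unname(dead["dead_crc"]) * 1e5,
      perf_deaths_per_100k = unname(dead["dead_perforation"]) * 1e5),
    trajectory = trajectory, params = params),
    class = "strategy_result")
}
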