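#' Natural-history parameter set
#'
#' Annual transition probabilities of the adenoma--carcinoma natural-history
#' model. Adenoma onset varies by 10-year age band; all other progression
#' probabilities are age-constant. A configurable fraction of cancers
#' (\code{p_direct}, base case 0.14) arises directly from normal epithelium
#' (stage I, without a prior adenoma); the annual direct-onset rate is
#' \code{direct_scale} times the age-band onset shape and is resolved by
#' \code{\link{resolve_direct_pathway}} so that the direct route supplies the
#' requested fraction of lifetime cancer onsets. New adenomas and direct
#' cancers split distal:proximal as \code{frac_distal} : 1 - \code{frac_distal}.
#'
#' The defaults are the package's synthetic "truth" set, tuned so the
#' no-screening model produces lifetime colorectal cancer incidence and
#' mortality, and a stage distribution at diagnosis, on the scale of a
#' western-European population (see the methods vignette).
#'
#' @param p_onset annual probability normal -> low-risk adenoma, one value
#'   per age band 30-39, 40-49, 50-59, 60-69, 70+.
#' @param p_low_high annual probability low-risk -> high-risk adenoma.
#' @param p_high_crc annual probability high-risk adenoma -> pre-clinical
#'   stage I cancer (same location).
#' @param p_prog annual stage-progression probabilities I->II, II->III,
#'   III->IV while pre-clinical.
#' @param p_sympt annual probability of symptomatic clinical presentation
#'   from pre-clinical stages I--IV.
#' @param p_crc_death annual probability of colorectal-cancer death in
#'   clinical stages I--IV; must be non-decreasing in stage.
#' @param p_direct target fraction of cancer onsets via the direct
#'   (non-adenoma) pathway.
#' @param frac_distal fraction of new lesions arising in the distal colon.
#' @param direct_scale resolved direct-pathway scale; \code{NA} until
#'   \code{\link{resolve_direct_pathway}} is run (done lazily by
#'   \code{\link{run_natural_history}}).
#' @return An \code{nh_params} list.
#' @export
nh_params <- function(p_onset = c(`30_39` = 0.00132, `40_49` = 0.00428,
                                  `50_59` = 0.00824, `60_69` = 0.01187,
                                  `70_plus` = 0.01450),
                      p_low_high = 0.0162,
                      p_high_crc = 0.1185,
                      p_prog = c(I_II = 0.35, II_III = 0.45, III_IV = 0.50),
                      p_sympt = c(I = 0.0396, II = 0.1542, III = 0.50,
                                  IV = 0.65),
                      p_crc_death = c(I = 0.0105, II = 0.0169, III = 0.0382,
                                      IV = 0.1658),
                      p_direct = 0.14,
                      frac_distal = 0.70,
                      direct_scale = NA_real_) {
  p <- structure(list(
    p_onset = p_onset, p_low_high = p_low_high, p_high_crc = p_high_crc,
    p_prog = p_prog, p_sympt = p_sympt, p_crc_death = p_crc_death,
    p_direct = p_direct, frac_distal = frac_distal,
    direct_scale = direct_scale), class = "nh_params")
  validate_nh_params(p)
  p
}

#' Validate a natural-history parameter set
#'
#' @param params an \code{nh_params} object.
#' @return \code{params}, invisibly; errors on invalid values.
#' @export
validate_nh_params <- function(params) {
  probs <- c(params$p_onset, params$p_low_high, params$p_high_crc,
             params$p_prog, params$p_sympt, params$p_crc_death,
             params$p_direct, params$frac_distal)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("invalid natural-history parameters: probabilities must lie in [0, 1]")
  }
  if (length(params$p_onset) != 5L) stop("p_onset needs 5 age-band values")
  if (length(params$p_prog) != 3L || length(params$p_sympt) != 4L ||
      length(params$p_crc_death) != 4L) {
    stop("p_prog, p_sympt, p_crc_death need lengths 3, 4, 4")
  }
  if (is.unsorted(params$p_crc_death)) {
    stop("p_crc_death must be non-decreasing in stage")
  }
  exits <- params$p_sympt + c(params$p_prog, 0)
  if (any(exits > 1)) {
    stop("pre-clinical exit probabilities (progression + presentation) exceed 1")
  }
  invisible(params)
}

# 10-year onset band index for an age (30-39 .. 70+)
age_band <- function(age) pmin(pmax(floor((age - 30) / 10), 0), 4) + 1L

# direct-onset annual probability at an age; shape follows the onset bands,
# with a flat fallback when the adenoma pathway is disabled entirely
direct_rate <- function(params, age) {
  k <- params$direct_scale
  if (is.na(k) || params$p_direct <= 0) return(rep(0, length(age)))
  shape <- params$p_onset[age_band(age)]
  if (sum(params$p_onset) == 0) shape <- rep(0.005, length(age))
  k * shape
}

# full transition matrix with other-cause mortality set to zero
nh_predeath_matrix <- function(params, band) {
  si <- state_index()
  P <- matrix(0, si$n, si$n, dimnames = list(si$ss$name, si$ss$name))
  fd <- params$frac_distal
  p_on <- unname(params$p_onset[band])
  k <- if (is.na(params$direct_scale)) 0 else params$direct_scale
  shape <- if (sum(params$p_onset) == 0) 0.005 else p_on
  p_dir <- if (params$p_direct > 0) k * shape else 0
  if (p_on + p_dir > 1) stop("invalid parameters: onset plus direct flow exceeds 1")

  P[si$normal, si$ad_low] <- p_on * c(fd, 1 - fd)
  P[si$normal, si$preclin["I", ]] <- p_dir * c(fd, 1 - fd)
  P[si$normal, si$normal] <- 1 - p_on - p_dir

  for (j in 1:2) { # distal, proximal
    P[si$ad_low[j], si$ad_high[j]] <- params$p_low_high
    P[si$ad_low[j], si$ad_low[j]] <- 1 - params$p_low_high
    P[si$ad_high[j], si$preclin["I", j]] <- params$p_high_crc
    P[si$ad_high[j], si$ad_high[j]] <- 1 - params$p_high_crc
    for (s in 1:4) {
      from <- si$preclin[s, j]
      P[from, si$clinical[s]] <- params$p_sympt[s]
      stayp <- 1 - params$p_sympt[s]
      if (s < 4) {
        P[from, si$preclin[s + 1, j]] <- params$p_prog[s]
        stayp <- stayp - params$p_prog[s]
      }
      P[from, from] <- stayp
    }
  }
  for (s in 1:4) {
    P[si$clinical[s], si$dead_crc] <- params$p_crc_death[s]
    P[si$clinical[s], si$clinical[s]] <- 1 - params$p_crc_death[s]
  }
  P[si$surv[1], si$surv[1]] <- 1
  P[si$surv[2], si$surv[2]] <- 1
  for (d in si$dead) P[d, d] <- 1
  P
}

# competing other-cause mortality: scale live destinations of live rows by
# (1 - q); colorectal-cancer death flows are left unscaled
apply_other_cause <- function(P, q, si = state_index()) {
  live <- si$live
  live_mass <- 1 - P[live, si$dead_crc]
  P[live, live] <- P[live, live] * (1 - q)
  P[live, si$dead_other] <- P[live, si$dead_other] * (1 - q) + q * live_mass
  P
}

#' Annual transition matrix at a given age
#'
#' Composes the state-specific natural-history transitions with competing
#' other-cause mortality from the life table: after disease transitions
#' (including colorectal-cancer death from clinical states), every live
#' destination is scaled by \code{1 - q_other(age)} and the remainder flows
#' to death from other causes.
#'
#' @param params an \code{nh_params} set (direct pathway resolved or not;
#'   an unresolved set has zero direct flow).
#' @param life_table a life table covering \code{age}.
#' @param age integer age in 30--100.
#' @return A row-stochastic matrix over \code{\link{build_state_space}}.
#' @export
transition_matrix <- function(params, life_table, age) {
  validate_nh_params(params)
  if (age < min(life_table$age) || age > max(life_table$age)) {
    stop("age outside life-table coverage")
  }
  P <- apply_other_cause(nh_predeath_matrix(params, age_band(age)),
                         q_other_at(life_table, age))
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop("invalid parameters: composed transition probability outside [0, 1]")
  }
  P
}

# reusable forward-simulation engine: per-band live-block transition
# matrices plus marker positions and the age/q series. The normal row's
# direct-pathway entries can be patched in place (nh_engine_set_direct)
# without rebuilding, which the flow-ratio resolver exploits.
nh_engine <- function(params, life_table, start_age = 30L, end_age = 100L) {
  si <- state_index()
  ages <- seq.int(start_age, end_age - 1L)
  live <- si$live
  pre <- lapply(1:5, function(b) {
    P <- nh_predeath_matrix(params, b)
    list(Tlive = P[live, live, drop = FALSE],
         p_dir = sum(P[si$normal, si$preclin["I", ]]))
  })
  pos <- match(c(si$normal, si$ad_high, as.vector(si$preclin), si$clinical), live)
  list(pre = pre, bands = age_band(ages), qs = q_other_at(life_table, ages),
       ages = ages, si = si, nl = length(live),
       i_norm = pos[1], i_adh = pos[2:3],
       i_pc = matrix(pos[4:11], nrow = 4), i_clin = pos[12:15])
}

# re-point the engine's direct normal-to-cancer flow at scale k
nh_engine_set_direct <- function(eng, params, k) {
  fd <- params$frac_distal
  shape <- if (sum(params$p_onset) == 0) rep(0.005, 5) else
    unname(params$p_onset)
  if (params$p_direct <= 0) k <- 0
  for (b in 1:5) {
    p_on <- unname(params$p_onset[b])
    p_dir <- k * shape[b]
    if (p_on + p_dir > 1) stop("invalid parameters: onset plus direct flow exceeds 1")
    Tl <- eng$pre[[b]]$Tlive
    Tl[eng$i_norm, eng$i_pc[1, ]] <- p_dir * c(fd, 1 - fd)
    Tl[eng$i_norm, eng$i_norm] <- 1 - p_on - p_dir
    eng$pre[[b]]$Tlive <- Tl
    eng$pre[[b]]$p_dir <- p_dir
  }
  eng
}

# core cohort engine: advances occupancy year by year and tallies flows.
# Works on the live-state block only (dead states are absorbing tallies) and
# reads flow terms in closed form from the parameters; equivalence with the
# reference transition_matrix() path is pinned by a test. Returns occupancy
# snapshots (ages start..end) and per-cycle flow counts per cohort entrant.
nh_forward <- function(params, life_table, start_age = 30L, end_age = 100L,
                       eng = NULL) {
  if (is.null(eng)) eng <- nh_engine(params, life_table, start_age, end_age)
  si <- eng$si
  ages <- eng$ages
  nl <- eng$nl
  bands <- eng$bands
  qs <- eng$qs
  i_norm <- eng$i_norm; i_adh <- eng$i_adh
  i_pc <- eng$i_pc; i_clin <- eng$i_clin
  pre <- eng$pre

  occ <- matrix(0, length(ages) + 1L, si$n,
                dimnames = list(seq.int(start_age, end_age), si$ss$name))
  occ[1L, si$normal] <- 1
  fl <- matrix(0, length(ages), 7L,
               dimnames = list(ages, c("inc_I", "inc_II", "inc_III", "inc_IV",
                                       "crc_deaths", "onset_direct", "onset_via")))
  v <- numeric(nl); v[i_norm] <- 1
  dead <- c(crc = 0, perf = 0, other = 0)
  live <- si$live
  for (t in seq_along(ages)) {
    b <- pre[[bands[t]]]
    q <- qs[t]
    fl[t, 1:4] <- (v[i_pc[, 1]] + v[i_pc[, 2]]) * params$p_sympt * (1 - q)
    d_crc <- sum(v[i_clin] * params$p_crc_death)
    fl[t, "crc_deaths"] <- d_crc
    fl[t, "onset_direct"] <- v[i_norm] * b$p_dir * (1 - q)
    fl[t, "onset_via"] <- sum(v[i_adh]) * params$p_high_crc * (1 - q)
    w <- as.vector(v %*% b$Tlive)
    dead["other"] <- dead["other"] + sum(w) * q
    dead["crc"] <- dead["crc"] + d_crc
    v <- w * (1 - q)
    occ[t + 1L, live] <- v
    occ[t + 1L, si$dead] <- dead
  }
  list(occ = occ, flows = fl, ages = ages, si = si)
}

#' Resolve the direct-pathway scale
#'
#' Fixes \code{direct_scale} so that, over a full no-screening cohort run,
#' the direct normal-to-cancer route supplies fraction \code{p_direct} of all
#' cancer onsets (flow-ratio constraint enforced at parameterisation time).
#'
#' @param params an \code{nh_params} set.
#' @param life_table life table used for the resolving run.
#' @param tol tolerance on the achieved direct fraction.
#' @param max_iter maximum fixed-point iterations.
#' @return \code{params} with \code{direct_scale} set.
#' @export
resolve_direct_pathway <- function(params, life_table, tol = 1e-4,
                                   max_iter = 25L, eng = NULL) {
  target <- params$p_direct
  if (target <= 0) { params$direct_scale <- 0; return(params) }
  if (is.null(eng)) eng <- nh_engine(params, life_table)
  k <- if (is.na(params$direct_scale) || params$direct_scale <= 0) 0.1 else
    params$direct_scale
  for (i in seq_len(max_iter)) {
    params$direct_scale <- k
    eng <- nh_engine_set_direct(eng, params, k)
    fw <- nh_forward(params, life_table, eng = eng)
    d <- sum(fw$flows[, "onset_direct"]); v <- sum(fw$flows[, "onset_via"])
    if (v <= 0) {
      # adenoma pathway inactive: every onset is direct, no ratio to solve
      return(params)
    }
    f <- d / (d + v)
    if (abs(f - target) < tol) return(params)
    # direct flow is near-linear in k: match odds
    k <- k * (target / (1 - target)) / (d / v)
  }
  warning("direct-pathway scale did not converge to tolerance")
  params
}

#' Run the natural-history model without screening
#'
#' Simulates the cohort from \code{start_age} (all mass disease-free) to
#' \code{end_age} in annual cycles and derives registry-style series and
#' lifetime tallies.
#'
#' @param params an \code{nh_params} set; the direct pathway is resolved
#'   automatically if \code{direct_scale} is \code{NA}.
#' @param life_table life table covering the simulated ages.
#' @param start_age,end_age simulation span (defaults 30 and 100).
#' @param eng prebuilt simulation engine for the same parameters (internal
#'   optimisation; leave \code{NULL}).
#' @return A list with:
#'   \item{trajectory}{data frame, one row per age, occupancy per state;}
#'   \item{series}{per-age clinical incidence per 100,000 alive (by stage and
#'     total), colorectal-cancer mortality per 100,000 alive, and adenoma /
#'     pre-clinical cancer prevalence among the alive;}
#'   \item{flows}{per-cycle event counts per cohort entrant;}
#'   \item{lifetime}{lifetime incidence and mortality per 100,000 entrants,
#'     stage distribution at diagnosis, direct-pathway onset fraction,
#'     other-cause deaths per 100,000;}
#'   \item{params}{the resolved parameter set used.}
#' @export
run_natural_history <- function(params, life_table, start_age = 30L,
                                end_age = 100L, eng = NULL) {
  validate_nh_params(params)
  if (is.null(eng)) eng <- nh_engine(params, life_table, start_age, end_age)
  if (is.na(params$direct_scale)) {
    params <- resolve_direct_pathway(params, life_table, eng = eng)
  }
  eng <- nh_engine_set_direct(eng, params, params$direct_scale)
  fw <- nh_forward(params, life_table, start_age, end_age, eng = eng)
  si <- fw$si
  alive <- rowSums(fw$occ[-nrow(fw$occ), si$live, drop = FALSE])
  inc <- fw$flows[, 1:4, drop = FALSE]
  ad_prev <- rowSums(fw$occ[-nrow(fw$occ), c(si$ad_low, si$ad_high),
                            drop = FALSE]) / alive
  pc_prev <- rowSums(fw$occ[-nrow(fw$occ), as.vector(si$preclin),
                            drop = FALSE]) / alive
  series <- data.frame(
    age = fw$ages, alive = alive,
    inc_rate_I = inc[, 1] / alive * 1e5, inc_rate_II = inc[, 2] / alive * 1e5,
    inc_rate_III = inc[, 3] / alive * 1e5, inc_rate_IV = inc[, 4] / alive * 1e5,
    inc_rate_total = rowSums(inc) / alive * 1e5,
    mort_rate = fw$flows[, "crc_deaths"] / alive * 1e5,
    adenoma_prev = ad_prev, preclin_prev = pc_prev)
  tot_inc <- sum(inc)
  onsets <- sum(fw$flows[, c("onset_direct", "onset_via")])
  lifetime <- list(
    incidence_per_100k = tot_inc * 1e5,
    mortality_per_100k = sum(fw$flows[, "crc_deaths"]) * 1e5,
    stage_dist = if (tot_inc > 0) colSums(inc) / tot_inc else rep(0, 4),
    direct_fraction = if (onsets > 0)
      sum(fw$flows[, "onset_direct"]) / onsets else NA_real_,
    other_deaths_per_100k = fw$occ[nrow(fw$occ), si$dead_other] * 1e5)
  list(trajectory = data.frame(age = as.integer(rownames(fw$occ)), fw$occ,
                               check.names = FALSE),
       series = series, flows = fw$flows, lifetime = lifetime, params = params)
}
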