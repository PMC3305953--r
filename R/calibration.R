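#' Calibration targets
#'
#' A set of observations the natural-history model is fitted to: age-banded
#' clinical cancer incidence by stage and cancer mortality (rates per
#' 100,000 alive), and adenoma / pre-clinical cancer prevalence at index
#' ages, each with an observation standard deviation for the normal
#' likelihood.
#'
#' @param observations data frame with columns \code{quantity} (one of
#'   \code{incidence_by_stage}, \code{mortality}, \code{adenoma_prevalence},
#'   \code{preclin_cancer_prevalence}), \code{age_lo}, \code{age_hi},
#'   \code{stage} (\code{NA} except for incidence), \code{value}, \code{sd}.
#' @return A validated \code{calibration_targets} data frame.
#' @export
calibration_targets <- function(observations) {
  need <- c("quantity", "age_lo", "age_hi", "stage", "value", "sd")
  if (!all(need %in% names(observations))) {
    stop("targets need columns: ", paste(need, collapse = ", "))
  }
  ok <- c("incidence_by_stage", "mortality", "adenoma_prevalence",
          "preclin_cancer_prevalence")
  if (!all(observations$quantity %in% ok)) stop("unknown target quantity")
  if (any(observations$sd <= 0)) stop("observation sd must be positive")
  if (any(observations$value < 0)) stop("observed values must be non-negative")
  structure(observations, class = c("calibration_targets", "data.frame"))
}

#' Read/write calibration targets as CSV
#'
#' @param path file path (columns \code{quantity,age_lo,age_hi,stage,value,sd}).
#' @export
read_targets <- function(path) calibration_targets(utils::read.csv(path))

#' @rdname read_targets
#' @param targets targets to write.
#' @export
write_targets <- function(targets, path) {
  d <- as.data.frame(targets)
  d$value <- sprintf("%.17g", d$value)  # bit-exact round trip
  d$sd <- sprintf("%.17g", d$sd)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# model-predicted value for every target row, from one natural-history run.
# Banded rates are person-year-weighted means over the band.
predict_targets <- function(run, targets) {
  s <- run$series
  alive <- s$alive
  inc <- cbind(s$inc_rate_I, s$inc_rate_II, s$inc_rate_III, s$inc_rate_IV)
  mort <- s$mort_rate
  adp <- s$adenoma_prev
  pcp <- s$preclin_prev
  i0 <- targets$age_lo - s$age[1] + 1L
  i1 <- targets$age_hi - s$age[1] + 1L
  qty <- targets$quantity
  stg <- targets$stage
  n <- nrow(targets)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- i0[i]:i1[i]
    w <- alive[r]
    out[i] <- switch(qty[i],
      incidence_by_stage = sum(inc[r, stg[i]] * w) / sum(w),
      mortality = sum(mort[r] * w) / sum(w),
      adenoma_prevalence = mean(adp[r]),
      preclin_cancer_prevalence = mean(pcp[r]))
  }
  out
}

# which nh_params entries are calibrated, and transforms to/from a flat vector
calib_par_names <- function() {
  c(paste0("p_onset", 1:5), "p_low_high", "p_high_crc",
    paste0("p_prog", 1:3), paste0("p_sympt", 1:4), paste0("p_crc_death", 1:4))
}

params_to_vector <- function(params) {
  stats::setNames(c(params$p_onset, params$p_low_high, params$p_high_crc,
                    params$p_prog, params$p_sympt, params$p_crc_death),
                  calib_par_names())
}

vector_to_params <- function(x, template = nh_params()) {
  template$p_onset[] <- x[1:5]
  template$p_low_high <- unname(x[6])
  template$p_high_crc <- unname(x[7])
  template$p_prog[] <- x[8:10]
  template$p_sympt[] <- x[11:14]
  template$p_crc_death[] <- x[15:18]
  template$direct_scale <- NA_real_  # re-resolve for the new rates
  template
}

#' Normal log-likelihood of a parameter set against calibration targets
#'
#' Runs the no-screening natural-history model and sums the normal
#' log-density of each observation's residual at its stated standard
#' deviation. Parameter sets violating the model's support (any probability
#' outside [0, 1], non-monotone stage-specific cancer death, or pre-clinical
#' exit probabilities above 1) score \code{-Inf}, which together with the
#' flat Beta(1,1) priors on [0, 1] makes the posterior proportional to the
#' likelihood on the valid region.
#'
#' @param params an \code{nh_params} set (or flat vector over
#'   \code{calib_par_names()}).
#' @param targets a \code{\link{calibration_targets}} table.
#' @param life_table life table.
#' @param template template \code{nh_params} supplying non-calibrated fields
#'   when \code{params} is a vector.
#' @return Scalar log-likelihood (\code{-Inf} for invalid parameters).
#' @export
log_likelihood <- function(params, targets, life_table,
                           template = nh_params()) {
  if (is.numeric(params)) {
    params <- try(vector_to_params(params, template), silent = TRUE)
    if (inherits(params, "try-error")) return(-Inf)
  } else {
    ok <- try(validate_nh_params(params), silent = TRUE)
    if (inherits(ok, "try-error")) return(-Inf)
  }
  run <- try(run_natural_history(params, life_table), silent = TRUE)
  if (inherits(run, "try-error")) return(-Inf)
  pred <- predict_targets(run, targets)
  sum(stats::dnorm(pred - targets$value, 0, targets$sd, log = TRUE))
}

#' One Metropolis--Hastings step
#'
#' Symmetric Gaussian random-walk proposal on the probability scale,
#' coordinate-wise scales \code{proposal_scale}. Under the flat Beta(1,1)
#' prior the acceptance probability is \code{min(1, exp(delta logL))};
#' proposals leaving the valid parameter region have zero prior support and
#' are always rejected (their likelihood is \code{-Inf}).
#'
#' @param current list with \code{theta} (parameter vector) and \code{ll}
#'   (its log-likelihood, finite).
#' @param proposal_scale numeric vector (recycled) of proposal SDs.
#' @param log_lik function mapping a parameter vector to a log-likelihood.
#' @return Updated \code{current} list with an \code{accepted} flag.
#' @export
mh_step <- function(current, proposal_scale, log_lik) {
  stopifnot(is.finite(current$ll))
  prop <- current$theta + stats::rnorm(length(current$theta), 0, proposal_scale)
  ll <- log_lik(prop)
  if (is.finite(ll) && log(stats::runif(1)) < ll - current$ll) {
    list(theta = prop, ll = ll, accepted = TRUE)
  } else {
    list(theta = current$theta, ll = current$ll, accepted = FALSE)
  }
}

#' MCMC configuration
#'
#' @param n_chains independent chains (default 3).
#' @param burn_in iterations discarded per chain (default 2000).
#' @param n_samples retained iterations per chain after burn-in.
#' @param proposal_scale initial proposal SD (scalar or per-parameter).
#' @param adapt tune proposal scales during burn-in toward 20--40\%
#'   acceptance (frozen afterwards).
#' @param seed RNG seed.
#' @return An \code{mcmc_config} list.
#' @export
mcmc_config <- function(n_chains = 3L, burn_in = 2000L, n_samples = 2000L,
                        proposal_scale = 0.02, adapt = TRUE, seed = 1L) {
  if (n_chains < 1 || burn_in < 0 || n_samples < 1) {
    stop("invalid MCMC configuration")
  }
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 proposal_scale = proposal_scale, adapt = adapt,
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' Calibrate natural-history parameters by Metropolis--Hastings MCMC
#'
#' Runs independent random-walk chains against the targets, discards burn-in,
#' pools the retained samples, and reports the highest-likelihood sampled
#' parameter set (used for base-case analyses) together with the pooled
#' posterior (used for probabilistic sensitivity analysis, preserving the
#' correlation between natural-history parameters).
#'
#' @param targets \code{\link{calibration_targets}}.
#' @param config \code{\link{mcmc_config}}.
#' @param life_table life table.
#' @param init starting \code{nh_params} (default package base case); chains
#'   are overdispersed by jittering the start.
#' @param calibrate names of calibrated coordinates (default: all of
#'   \code{calib_par_names()}); others stay at \code{init}'s values.
#' @return List with \code{map_params} (\code{nh_params}), \code{posterior}
#'   (data frame: one row per retained sample with parameter columns,
#'   \code{log_likelihood}, \code{chain}, \code{iteration}), and
#'   \code{acceptance} per chain.
#' @export
run_calibration <- function(targets, config = mcmc_config(),
                            life_table = generate_life_table(),
                            init = nh_params(),
                            calibrate = calib_par_names()) {
  set.seed(config$seed)
  theta0_full <- params_to_vector(init)
  free <- match(calibrate, names(theta0_full))
  if (anyNA(free)) stop("unknown parameter name in 'calibrate'")
  # warm-started likelihood: reuse the previous direct-pathway scale so the
  # flow-ratio constraint resolves in one or two forward runs per proposal
  warm <- new.env(parent = emptyenv())
  warm$k <- if (!is.na(init$direct_scale)) init$direct_scale else NA_real_
  ll_fun <- function(th_free) {
    full <- theta0_full
    full[free] <- th_free
    params <- try(validate_nh_params(vector_to_params(full, init)),
                  silent = TRUE)
    if (inherits(params, "try-error")) return(-Inf)
    fw <- try({
      eng <- nh_engine(params, life_table)
      target <- params$p_direct
      k <- if (!is.na(warm$k)) warm$k else 0.1
      fw <- NULL
      for (i in 1:25) {
        eng <- nh_engine_set_direct(eng, params, k)
        fw <- nh_forward(params, life_table, eng = eng)
        if (target <= 0) break
        d <- sum(fw$flows[, "onset_direct"]); vv <- sum(fw$flows[, "onset_via"])
        if (vv <= 0) break
        f <- d / (d + vv)
        if (abs(f - target) < 1e-4) break
        k <- k * (target / (1 - target)) / (d / vv)
      }
      warm$k <- k
      fw
    }, silent = TRUE)
    if (inherits(fw, "try-error")) return(-Inf)
    live <- state_index()$live
    alive <- rowSums(fw$occ[-nrow(fw$occ), live, drop = FALSE])
    s <- list(age = fw$ages, alive = alive,
              inc_rate_I = fw$flows[, 1] / alive * 1e5,
              inc_rate_II = fw$flows[, 2] / alive * 1e5,
              inc_rate_III = fw$flows[, 3] / alive * 1e5,
              inc_rate_IV = fw$flows[, 4] / alive * 1e5,
              mort_rate = fw$flows[, "crc_deaths"] / alive * 1e5,
              adenoma_prev = rowSums(fw$occ[-nrow(fw$occ),
                c(state_index()$ad_low, state_index()$ad_high),
                drop = FALSE]) / alive,
              preclin_prev = rowSums(fw$occ[-nrow(fw$occ),
                as.vector(state_index()$preclin), drop = FALSE]) / alive)
    pred <- predict_targets(list(series = s), targets)
    sum(stats::dnorm(pred - targets$value, 0, targets$sd, log = TRUE))
  }
  n_free <- length(free)
  chains <- vector("list", config$n_chains)
  acc <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    # overdispersed start: jitter until a finite-likelihood point is found
    cur <- NULL
    for (try_i in 1:50) {
      th <- theta0_full[free] *
        exp(stats::rnorm(n_free, 0, if (ch == 1 && try_i == 1) 0 else 0.1))
      ll <- ll_fun(th)
      if (is.finite(ll)) { cur <- list(theta = th, ll = ll); break }
    }
    if (is.null(cur)) stop("no finite-likelihood starting point found")
    scale <- rep_len(config$proposal_scale, n_free) *
      pmax(theta0_full[free], 0.01)
    draws <- matrix(NA_real_, config$n_samples, n_free,
                    dimnames = list(NULL, names(theta0_full)[free]))
    lls <- numeric(config$n_samples)
    n_acc <- 0L; n_tot <- 0L; win_acc <- 0L
    total <- config$burn_in + config$n_samples
    for (i in seq_len(total)) {
      cur <- mh_step(cur, scale, ll_fun)
      win_acc <- win_acc + cur$accepted
      if (config$adapt && i <= config$burn_in && i %% 50 == 0) {
        rate <- win_acc / 50
        if (rate < 0.20) scale <- scale * 0.8
        if (rate > 0.40) scale <- scale * 1.25
        win_acc <- 0L
      }
      if (i > config$burn_in) {
        j <- i - config$burn_in
        draws[j, ] <- cur$theta
        lls[j] <- cur$ll
        n_acc <- n_acc + cur$accepted; n_tot <- n_tot + 1L
      }
    }
    chains[[ch]] <- data.frame(draws, log_likelihood = lls, chain = ch,
                               iteration = seq_len(config$n_samples),
                               check.names = FALSE)
    acc[ch] <- n_acc / n_tot
  }
  posterior <- do.call(rbind, chains)
  best <- which.max(posterior$log_likelihood)
  full <- theta0_full
  full[free] <- unlist(posterior[best, seq_len(n_free)])
  map_params <- vector_to_params(full, init)
  map_params <- resolve_direct_pathway(map_params, life_table)
  list(map_params = map_params, posterior = posterior, acceptance = acc,
       free = names(theta0_full)[free])
}

#' Materialise a posterior row as a parameter set
#'
#' @param posterior posterior data frame from \code{\link{run_calibration}}.
#' @param row row index.
#' @param template template \code{nh_params} for non-calibrated fields.
#' @return An \code{nh_params} set (direct pathway unresolved).
#' @export
posterior_params <- function(posterior, row, template = nh_params()) {
  full <- params_to_vector(template)
  keep <- intersect(names(full), names(posterior))
  full[keep] <- unlist(posterior[row, keep])
  vector_to_params(full, template)
}

#' Split-chain Gelman--Rubin statistic
#'
#' @param x numeric matrix, one column per chain (equal lengths).
#' @return Potential scale-reduction factor.
#' @export
gelman_rubin <- function(x) {
  m <- ncol(x); n <- nrow(x)
  means <- colMeans(x)
  B <- n * stats::var(means)
  W <- mean(apply(x, 2, stats::var))
  sqrt(((n - 1) / n * W + B / n) / W)
}
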