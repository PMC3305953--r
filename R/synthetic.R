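#' Synthetic calibration scenario
#'
#' Bundles a known "true" natural-history parameter set, the Gompertz life
#' table shape, and an observation noise level: everything needed to
#' generate calibration targets with recorded truth for parameter-recovery
#' experiments.
#'
#' @param true_params the data-generating \code{\link{nh_params}}.
#' @param gompertz_a,gompertz_b life-table shape parameters.
#' @param cv observation coefficient of variation (sd = cv * value).
#' @param seed RNG seed for the observation noise.
#' @return A \code{synth_scenario} list.
#' @export
synth_scenario <- function(true_params = nh_params(), gompertz_a = 2.2e-5,
                           gompertz_b = 0.097, cv = 0.05, seed = 1L) {
  if (cv <= 0) stop("cv must be positive")
  structure(list(true_params = true_params, gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b, cv = cv, seed = as.integer(seed)),
            class = "synth_scenario")
}

#' Generate synthetic calibration targets from known truth
#'
#' Runs the natural-history model under the scenario's true parameters and
#' emits the default target layout — clinical cancer incidence by stage and
#' cancer mortality per 100,000 alive in 5-year age bands 50--84, and
#' adenoma / pre-clinical cancer prevalence at ages 55, 60 and 65 — each
#' perturbed by additive normal noise with sd = cv * value (noise-free when
#' \code{noise = FALSE}). A small sd floor keeps near-zero observations
#' usable in the normal likelihood.
#'
#' @param scenario a \code{\link{synth_scenario}}.
#' @param noise add observation noise (default TRUE).
#' @return List with \code{targets} (a \code{\link{calibration_targets}}
#'   table), \code{truth} (the resolved true parameters), and
#'   \code{life_table}.
#' @export
generate_targets <- function(scenario = synth_scenario(), noise = TRUE) {
  lt <- generate_life_table(scenario$gompertz_a, scenario$gompertz_b)
  run <- run_natural_history(scenario$true_params, lt)
  bands <- data.frame(age_lo = seq(50, 80, 5), age_hi = seq(54, 84, 5))
  obs <- list()
  for (i in seq_len(nrow(bands))) {
    for (s in 1:4) {
      obs[[length(obs) + 1L]] <- data.frame(
        quantity = "incidence_by_stage", age_lo = bands$age_lo[i],
        age_hi = bands$age_hi[i], stage = s, value = NA, sd = NA)
    }
    obs[[length(obs) + 1L]] <- data.frame(
      quantity = "mortality", age_lo = bands$age_lo[i],
      age_hi = bands$age_hi[i], stage = NA, value = NA, sd = NA)
  }
  for (a in c(55, 60, 65)) {
    obs[[length(obs) + 1L]] <- data.frame(
      quantity = "adenoma_prevalence", age_lo = a, age_hi = a, stage = NA,
      value = NA, sd = NA)
    obs[[length(obs) + 1L]] <- data.frame(
      quantity = "preclin_cancer_prevalence", age_lo = a, age_hi = a,
      stage = NA, value = NA, sd = NA)
  }
  tg <- do.call(rbind, obs)
  truthv <- predict_targets(run, tg)
  floor_sd <- ifelse(tg$quantity %in% c("adenoma_prevalence",
                                        "preclin_cancer_prevalence"),
                     1e-4, 0.5)
  tg$sd <- pmax(scenario$cv * truthv, floor_sd)
  if (noise) {
    set.seed(scenario$seed)
    tg$value <- pmax(truthv + stats::rnorm(nrow(tg), 0, tg$sd), 0)
  } else {
    tg$value <- truthv
  }
  list(targets = calibration_targets(tg), truth = run$params,
       life_table = lt)
}

#' Write the full synthetic fixture set
#'
#' Writes the life table, noise-free and noisy calibration targets, and the
#' true parameter set as plain CSVs.
#'
#' @param dir output directory (created if needed).
#' @param scenario a \code{\link{synth_scenario}}.
#' @return Invisibly, the written paths.
#' @export
write_fixtures <- function(dir, scenario = synth_scenario()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_targets(scenario)
  paths <- c(
    life_table = file.path(dir, "life_table.csv"),
    targets = file.path(dir, "calibration_targets.csv"),
    truth = file.path(dir, "true_params.csv"))
  write_life_table(gen$life_table, paths["life_table"])
  write_targets(gen$targets, paths["targets"])
  write_nh_params(gen$truth, paths["truth"])
  invisible(paths)
}

#' Read/write a natural-history parameter set as key,value CSV
#'
#' Keys are the flat calibrated-parameter names plus \code{p_direct},
#' \code{frac_distal} and the resolved \code{direct_scale}.
#'
#' @param params an \code{nh_params} set.
#' @param path file path.
#' @export
write_nh_params <- function(params, path) {
  v <- c(params_to_vector(params), p_direct = params$p_direct,
         frac_distal = params$frac_distal, direct_scale = params$direct_scale)
  utils::write.csv(data.frame(key = names(v),
                              value = sprintf("%.17g", unname(v))), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nh_params
#' @export
read_nh_params <- function(path) {
  d <- utils::read.csv(path)
  v <- stats::setNames(d$value, d$key)
  p <- vector_to_params(v[calib_par_names()])
  p$p_direct <- unname(v["p_direct"])
  p$frac_distal <- unname(v["frac_distal"])
  p$direct_scale <- unname(v["direct_scale"])
  p
}
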