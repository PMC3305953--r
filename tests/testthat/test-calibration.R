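test_that("normal log-likelihood follows its closed form", {
  gen <- generate_targets(synth_scenario(), noise = FALSE)
  tg <- gen$targets
  # residuals are zero when predictions equal targets
  ll0 <- log_likelihood(gen$truth, tg, gen$life_table)
  expect_equal(ll0, sum(-log(tg$sd * sqrt(2 * pi))), tolerance = 1e-8)
  # shifting one observation from 1 sd to 2 sd lowers the term by 1.5
  tg1 <- tg; tg1$value[5] <- tg1$value[5] + tg1$sd[5]
  tg2 <- tg; tg2$value[5] <- tg2$value[5] + 2 * tg2$sd[5]
  ll1 <- log_likelihood(gen$truth, tg1, gen$life_table)
  ll2 <- log_likelihood(gen$truth, tg2, gen$life_table)
  expect_equal(ll1 - ll2, 1.5, tolerance = 1e-8)
  # support violations score -Inf (flat Beta(1,1) prior on [0,1])
  th <- crcscreen:::params_to_vector(gen$truth)
  th["p_sympt1"] <- 1.4
  expect_identical(log_likelihood(th, tg, gen$life_table,
                                  template = gen$truth), -Inf)
  th2 <- crcscreen:::params_to_vector(gen$truth)
  th2["p_low_high"] <- -0.01
  expect_identical(log_likelihood(th2, tg, gen$life_table,
                                  template = gen$truth), -Inf)
})

test_that("Metropolis-Hastings steps accept and reject correctly", {
  set.seed(1)
  # flat target: equal likelihood proposals are always accepted
  cur <- list(theta = 0.5, ll = 0)
  acc <- replicate(200, mh_step(cur, 0.1, function(th) 0)$accepted)
  expect_true(all(acc))
  # proposals outside [0,1] have zero prior support: always rejected
  llb <- function(th) if (th < 0 || th > 1) -Inf else 0
  cur <- list(theta = 0.999, ll = 0)
  for (i in 1:100) {
    nxt <- mh_step(cur, 0.5, llb)
    expect_true(nxt$theta >= 0 && nxt$theta <= 1)
    cur <- nxt
  }
  # random-walk acceptance rate on a quadratic (Gaussian) toy target
  set.seed(2)
  cur <- list(theta = 0, ll = 0)
  lq <- function(th) -th^2 / 2
  acc <- logical(10000)
  for (i in 1:10000) {
    cur <- mh_step(cur, 2.4, lq)
    acc[i] <- cur$accepted
  }
  expect_gt(mean(acc), 0.1)
  expect_lt(mean(acc), 0.6)
})

test_that("MH posterior matches the conjugate beta posterior on binomial data", {
  # y successes in n trials, flat prior: posterior is Beta(y+1, n-y+1)
  y <- 9; n <- 30
  ll <- function(p) {
    if (p <= 0 || p >= 1) return(-Inf)
    y * log(p) + (n - y) * log(1 - p)
  }
  set.seed(3)
  cur <- list(theta = 0.3, ll = ll(0.3))
  draws <- numeric(20000)
  for (i in seq_along(draws)) {
    cur <- mh_step(cur, 0.15, ll)
    draws[i] <- cur$theta
  }
  draws <- draws[-(1:1000)]
  a <- y + 1; b <- n - y + 1
  post_mean <- a / (a + b)
  post_sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  n_eff <- ess(draws)
  expect_lt(abs(mean(draws) - post_mean), 3 * post_sd / sqrt(n_eff))
  expect_lt(abs(stats::sd(draws) - post_sd), 3 * post_sd / sqrt(2 * n_eff))
})

test_that("calibration recovers known truth from noise-free targets", {
  gen <- generate_targets(synth_scenario(), noise = FALSE)
  free <- c("p_onset3", "p_high_crc", "p_sympt1", "p_crc_death4")
  cal <- run_calibration(gen$targets,
                         mcmc_config(n_chains = 1, burn_in = 150,
                                     n_samples = 400, seed = 9),
                         gen$life_table, init = gen$truth, calibrate = free)
  truth <- crcscreen:::params_to_vector(gen$truth)[free]
  map <- crcscreen:::params_to_vector(cal$map_params)[free]
  expect_equal(unname(map), unname(truth), tolerance = 0.15)
  # the sampled maximum cannot beat the noise-free optimum by definition
  ll_truth <- log_likelihood(gen$truth, gen$targets, gen$life_table)
  expect_lte(max(cal$posterior$log_likelihood), ll_truth + 1e-6)
  expect_gte(max(cal$posterior$log_likelihood), ll_truth - 2)
})

test_that("chains are reproducible under a fixed seed and sized as configured", {
  gen <- generate_targets(synth_scenario(seed = 3))
  cfg <- mcmc_config(n_chains = 2, burn_in = 50, n_samples = 120, seed = 21)
  free <- c("p_onset3", "p_sympt1")
  c1 <- run_calibration(gen$targets, cfg, gen$life_table, init = gen$truth,
                        calibrate = free)
  c2 <- run_calibration(gen$targets, cfg, gen$life_table, init = gen$truth,
                        calibrate = free)
  expect_identical(c1$posterior, c2$posterior)
  # retained sample count: burn-in discarded, n_samples kept per chain
  expect_equal(nrow(c1$posterior), 2 * 120)
  expect_equal(range(c1$posterior$iteration), c(1, 120))
  expect_setequal(unique(c1$posterior$chain), 1:2)
  expect_true(all(is.finite(c1$posterior$log_likelihood)))
  # posterior rows materialise as valid parameter sets
  p <- posterior_params(c1$posterior, 7, template = gen$truth)
  expect_s3_class(p, "nh_params")
  expect_true(is.na(p$direct_scale))
})

test_that("pooled chains agree with a long chain on the binomial toy", {
  y <- 9; n <- 30
  ll <- function(p) if (p <= 0 || p >= 1) -Inf else
    y * log(p) + (n - y) * log(1 - p)
  run_chain <- function(seed, iters) {
    set.seed(seed)
    cur <- list(theta = runif(1, 0.2, 0.4), ll = ll(0.3))
    cur$ll <- ll(cur$theta)
    d <- numeric(iters)
    for (i in seq_along(d)) { cur <- mh_step(cur, 0.15, ll); d[i] <- cur$theta }
    d[-(1:500)]
  }
  chains <- vapply(1:3, run_chain, numeric(5500), iters = 6000)
  pooled <- as.vector(chains)
  long <- run_chain(99, 17000)
  a <- y + 1; b <- n - y + 1
  post_sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  se <- 3 * post_sd / sqrt(ess(pooled))
  expect_lt(abs(mean(pooled) - mean(long)), 2 * se)
  expect_lt(gelman_rubin(chains), 1.1)
})
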