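test_that("state space enumerates the model's compartments deterministically", {
  ss <- build_state_space()
  expect_true(all(c("adenoma_low/distal", "crc_preclin_III/proximal") %in% ss$name))
  expect_identical(ss, build_state_space())
  expect_false(anyDuplicated(ss$name) > 0)
  expect_equal(sum(ss$compartment == "normal"), 1)
  expect_equal(sum(startsWith(ss$compartment, "adenoma")), 4)
  expect_equal(sum(startsWith(ss$compartment, "crc_preclin")), 8)
  expect_equal(sum(startsWith(ss$compartment, "crc_clinical")), 4)
  expect_equal(sum(startsWith(ss$compartment, "surveillance")), 2)
  # three absorbing causes of death: cancer, perforation, other
  expect_equal(sum(!ss$alive), 3)
  expect_true(all(ss$location[startsWith(ss$compartment, "adenoma") |
                                startsWith(ss$compartment, "crc_preclin")] %in%
                    c("distal", "proximal")))
})

test_that("transition matrices are row-stochastic with competing mortality", {
  lt <- fx("lt")
  # all neoplasia transitions off: the only exit from normal is other death
  p0 <- null_params()
  lt2 <- lt; lt2$q_other[lt2$age == 50] <- 0.01
  P <- transition_matrix(p0, lt2, 50)
  expect_equal(P["normal", "normal"], 0.99)
  expect_equal(P["normal", "dead_other"], 0.01)
  for (a in c(30, 45, 62, 99)) {
    P <- transition_matrix(fx("params"), lt, a)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  # at 100 every live state is absorbed into a death state
  P <- transition_matrix(fx("params"), lt, 100)
  dead <- c("dead_crc", "dead_perforation", "dead_other")
  live <- setdiff(rownames(P), dead)
  expect_equal(unname(rowSums(P[live, dead])), rep(1, length(live)),
               tolerance = 1e-12)
  # invalid composition is rejected
  bad <- fx("params"); bad$p_sympt[1] <- 1.2
  expect_error(transition_matrix(bad, lt, 50), "\\[0, 1\\]|exceed")
})

test_that("advance_cycle conserves mass and respects absorption", {
  co <- initial_cohort(40)
  n <- length(co$occupancy)
  id <- diag(n)
  out <- advance_cycle(co, id)
  expect_equal(out$age, 41L)
  expect_equal(out$occupancy, co$occupancy)
  P <- transition_matrix(fx("params"), fx("lt"), 40)
  out <- advance_cycle(co, P)
  expect_equal(sum(out$occupancy), 1, tolerance = 1e-12)
  dead <- co; dead$occupancy[] <- 0; dead$occupancy["dead_other"] <- 1
  expect_equal(advance_cycle(dead, P)$occupancy[["dead_other"]], 1)
  expect_error(advance_cycle(co, diag(3)), "dimension")
})

test_that("cohort mass is conserved to 1e-12 over the full 70-cycle run", {
  tr <- as.matrix(fx("nh")$trajectory[, -1])
  expect_lt(max(abs(rowSums(tr) - 1)), 1e-12)
})

test_that("fast cohort engine agrees with the reference transition matrices", {
  p <- fx("params"); lt <- fx("lt")
  co <- initial_cohort(30)
  for (a in 30:99) co <- advance_cycle(co, transition_matrix(p, lt, a))
  final <- unlist(fx("nh")$trajectory[nrow(fx("nh")$trajectory), -1])
  expect_equal(unname(final), unname(co$occupancy), tolerance = 1e-12)
})

test_that("null model reproduces the closed-form life-table survival", {
  lt <- fx("lt")
  r <- run_natural_history(null_params(), lt)
  expect_equal(r$lifetime$incidence_per_100k, 0)
  expect_equal(r$lifetime$mortality_per_100k, 0)
  ages <- 30:100
  surv <- c(1, cumprod(1 - q_other_at(lt, 30:99)))
  expect_equal(unname(rowSums(as.matrix(
    r$trajectory[, setdiff(names(r$trajectory), c("age", "dead_crc",
                                                  "dead_perforation",
                                                  "dead_other"))]))),
    surv, tolerance = 1e-12)
})

test_that("direct-pathway scaling delivers the configured onset fraction", {
  r <- fx("nh")
  expect_equal(r$lifetime$direct_fraction, 0.14, tolerance = 0.01)
  # adenoma pathway disabled: every incident cancer arises directly
  p <- nh_params(p_onset = stats::setNames(rep(0, 5), names(nh_params()$p_onset)),
                 p_low_high = 0, p_high_crc = 0)
  rd <- run_natural_history(p, fx("lt"))
  expect_gt(rd$lifetime$incidence_per_100k, 0)
  expect_equal(rd$lifetime$direct_fraction, 1)
})

test_that("lifetime cancer mortality is monotone in stage-IV case fatality", {
  lt <- fx("lt")
  base <- fx("params")
  morts <- vapply(c(0.10, 0.1658, 0.35, 0.6), function(d4) {
    p <- base; p$p_crc_death[4] <- d4
    run_natural_history(p, lt)$lifetime$mortality_per_100k
  }, 0)
  expect_true(all(diff(morts) >= 0))
})

test_that("mean stage at presentation is non-decreasing in stage progression", {
  lt <- fx("lt")
  base <- fx("params")
  mean_stage <- vapply(c(0.6, 1.0, 1.4), function(sc) {
    p <- base; p$p_prog <- pmin(base$p_prog * sc, 1 - base$p_sympt[1:3])
    sd <- run_natural_history(p, lt)$lifetime$stage_dist
    sum(sd * 1:4)
  }, 0)
  expect_true(all(diff(mean_stage) >= -1e-9))
})

test_that("matrix-power solution matches step-by-step enumeration on a reduced chain", {
  # 5-state chain: normal -> adenoma -> preclinical -> clinical -> dead
  p <- c(a = 0.02, b = 0.05, c = 0.3, d = 0.2)
  M <- matrix(0, 5, 5)
  M[1, 1] <- 1 - p["a"]; M[1, 2] <- p["a"]
  M[2, 2] <- 1 - p["b"]; M[2, 3] <- p["b"]
  M[3, 3] <- 1 - p["c"]; M[3, 4] <- p["c"]
  M[4, 4] <- 1 - p["d"]; M[4, 5] <- p["d"]
  M[5, 5] <- 1
  v <- c(1, 0, 0, 0, 0)
  # independent oracle: enumerate occupancy year by year with explicit flows
  w <- v
  for (t in 1:40) {
    w <- c(w[1] * (1 - p["a"]),
           w[1] * p["a"] + w[2] * (1 - p["b"]),
           w[2] * p["b"] + w[3] * (1 - p["c"]),
           w[3] * p["c"] + w[4] * (1 - p["d"]),
           w[4] * p["d"] + w[5])
  }
  Mk <- diag(5)
  for (t in 1:40) Mk <- Mk %*% M
  expect_equal(as.vector(v %*% Mk), unname(w), tolerance = 1e-10)
})
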