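test_that("discount factors use the age-55 reference", {
  expect_equal(discount_factor(55, 0.04), 1)
  expect_equal(discount_factor(65, 0.04), 1.04^-10)
  expect_equal(discount_factor(65, 0.04), 0.67556, tolerance = 1e-5)
  expect_equal(discount_factor(40, 0.04), 1)
  expect_equal(discount_factor(80, 0), 1)
  expect_error(discount_factor(60, -0.01), "non-negative")
})

test_that("accumulate prices events and weights occupancy by utility", {
  v <- parameter_values()
  costs <- cost_schedule(v)
  utl <- utility_schedule(v)
  ss <- build_state_space()
  # one person cancer-free for exactly one year, no events
  tr <- data.frame(age = c(55, 56),
                   matrix(0, 2, nrow(ss), dimnames = list(NULL, ss$name)),
                   check.names = FALSE)
  tr[, "normal"] <- 1
  out <- accumulate(tr, NULL, costs, utl, rate = 0)
  expect_equal(unname(out["qaly"]), 0.94)
  expect_equal(unname(out["cost"]), 0)
  # one symptomatic stage III diagnosis per person at age 55
  tally <- matrix(0, 1, length(crcscreen:::ov_event_types),
                  dimnames = list("55", crcscreen:::ov_event_types))
  tally[1, "diag_sympt_III"] <- 1
  out <- accumulate(tr, tally, costs, utl, rate = 0.04)
  expect_equal(unname(out["cost"]), 48835)
  # a year with clinical cancer carries the cancer utility
  tr2 <- tr; tr2[, "normal"] <- 0; tr2[, "crc_clinical_II"] <- 1
  out2 <- accumulate(tr2, NULL, costs, utl, rate = 0)
  expect_equal(unname(out2["qaly"]), 0.80)
  # unknown event type errors
  bad <- matrix(1, 1, 1, dimnames = list("55", "teleportation"))
  expect_error(accumulate(tr, bad, costs, utl, 0), "no cost defined")
})

test_that("zero-rate accumulation equals undiscounted sums exactly", {
  r <- fx("fit")
  v <- parameter_values()
  out <- accumulate(r$trajectory, r$tally_by_age, cost_schedule(v),
                    utility_schedule(v), rate = 0)
  expect_identical(unname(out["cost"]), r$cost_undisc)
  expect_identical(unname(out["qaly"]), r$qaly_undisc)
  expect_lte(r$cost, r$cost_undisc)
  expect_lte(r$qaly, r$qaly_undisc)
})

test_that("ICERs follow the incremental definition with sign conventions", {
  a <- list(cost = 100, qaly = 2); b <- list(cost = 0, qaly = 1)
  ic <- compute_icer(a, b)
  expect_equal(ic$icer, 100)
  expect_equal(ic$note, "ok")
  expect_equal(compute_icer(a, list(cost = 50, qaly = 2))$note, "undefined")
  expect_true(is.na(compute_icer(a, list(cost = 50, qaly = 2))$icer))
  cs <- compute_icer(list(cost = 10, qaly = 2), list(cost = 20, qaly = 1))
  expect_equal(cs$note, "cost_saving")
  expect_lt(cs$icer, 0)
  dm <- compute_icer(list(cost = 20, qaly = 1), list(cost = 10, qaly = 2))
  expect_equal(dm$note, "dominated")
})

test_that("efficiency frontier applies strict and extended dominance", {
  d <- data.frame(id = c("o", "a", "b"), cost = c(0, 10, 5),
                  qaly = c(0, 0.5, 1.0))
  fr <- efficiency_frontier(d)
  expect_equal(fr$status[fr$id == "a"], "dominated")
  expect_equal(sort(fr$id[fr$status == "on_frontier"]), c("b", "o"))

  d2 <- data.frame(id = c("o", "a", "b"), cost = c(0, 8, 9),
                   qaly = c(0, 0.001, 1.0))
  fr2 <- efficiency_frontier(d2)
  expect_equal(fr2$status[fr2$id == "a"], "extended_dominated")
  expect_equal(frontier_oracle(d2), sort(fr2$id[fr2$status == "on_frontier"]))
  # frontier ICERs strictly increase along the frontier
  ic <- fr2$icer[fr2$status == "on_frontier"]
  ic <- ic[!is.na(ic)]
  expect_true(all(diff(ic) > 0) || length(ic) < 2)
})

test_that("frontier equals the brute-force oracle on random strategy sets", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    d <- data.frame(id = letters[1:n],
                    cost = round(runif(n, 0, 100), 2),
                    qaly = round(runif(n, 0, 2), 3))
    d$cost[1] <- 0; d$qaly[1] <- 0  # comparator
    fr <- efficiency_frontier(d)
    expect_equal(sort(fr$id[fr$status == "on_frontier"]),
                 sort(frontier_oracle(d)),
                 info = paste("replicate", rep))
    ic <- fr$icer[fr$status == "on_frontier"]; ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) > -1e-9))
  }
})

test_that("scaling all costs scales all ICERs; adding strategies preserves dominance", {
  set.seed(7)
  d <- data.frame(id = letters[1:6], cost = c(0, runif(5, 1, 50)),
                  qaly = c(0, runif(5, 0, 1)))
  fr <- efficiency_frontier(d)
  d2 <- d; d2$cost <- d2$cost * 3.5
  fr2 <- efficiency_frontier(d2)
  expect_equal(fr2$status, fr$status)
  expect_equal(fr2$icer, fr$icer * 3.5, tolerance = 1e-12)
  dominated <- fr$id[fr$status != "on_frontier"]
  d3 <- rbind(d, data.frame(id = "new", cost = 25, qaly = 0.5))
  fr3 <- efficiency_frontier(d3)
  expect_true(all(fr3$status[fr3$id %in% dominated] != "on_frontier"))
})
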