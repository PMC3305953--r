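# shared fixtures, built in code and cached across test files

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    cache[[name]] <- switch(name,
      lt = generate_life_table(),
      params = resolve_direct_pathway(nh_params(), fx("lt")),
      nh = run_natural_history(fx("params"), fx("lt")),
      none = simulate_strategy("none", fx("params"), fx("lt")),
      fit = simulate_strategy("FIT_55_74", fx("params"), fx("lt")),
      gfobt = simulate_strategy("gFOBT_55_74", fx("params"), fx("lt")),
      fsig = simulate_strategy("FSIG_60", fx("params"), fx("lt")),
      stop("unknown fixture ", name))
    cache[[name]]
  }
})

# parameter set with every neoplasia transition switched off
null_params <- function() {
  nh_params(p_onset = stats::setNames(rep(0, 5),
                                      c("30_39", "40_49", "50_59", "60_69",
                                        "70_plus")),
            p_low_high = 0, p_high_crc = 0,
            p_prog = c(I_II = 0, II_III = 0, III_IV = 0),
            p_sympt = c(I = 0, II = 0, III = 0, IV = 0),
            p_crc_death = c(I = 0, II = 0, III = 0, IV = 0),
            p_direct = 0, direct_scale = 0)
}

# brute-force lower-convex-hull frontier oracle for small strategy sets:
# a strategy is on the frontier iff no convex combination of the others is
# at least as effective and strictly cheaper (checked on a fine lambda grid
# via pairwise segments), equivalently via chull on the CE plane
frontier_oracle <- function(d) {
  d <- d[order(d$qaly, d$cost), ]
  n <- nrow(d)
  on <- rep(TRUE, n)
  # strict dominance
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && d$cost[j] <= d$cost[i] && d$qaly[j] >= d$qaly[i] &&
          (d$cost[j] < d$cost[i] || d$qaly[j] > d$qaly[i])) on[i] <- FALSE
    }
  }
  # extended dominance: strictly below-the-segment test between any two
  # remaining points, iterated to a fixed point
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (!on[i]) next
      for (j in seq_len(n)) {
        for (k in seq_len(n)) {
          if (i == j || i == k || j == k || !on[j] || !on[k]) next
          if (d$qaly[j] < d$qaly[i] && d$qaly[i] < d$qaly[k]) {
            lam <- (d$qaly[i] - d$qaly[j]) / (d$qaly[k] - d$qaly[j])
            mix_cost <- (1 - lam) * d$cost[j] + lam * d$cost[k]
            if (mix_cost < d$cost[i] - 1e-12) { on[i] <- FALSE; changed <- TRUE }
          }
        }
      }
    }
    if (!changed) break
  }
  sort(d$id[on])
}

# crude effective sample size from the autocorrelation function
ess <- function(x) {
  n <- length(x)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  m <- if (length(pos)) pos[1] else length(ac)
  n / (1 + 2 * sum(ac[seq_len(m)]))
}
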