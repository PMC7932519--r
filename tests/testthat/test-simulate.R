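# Synthetic cohort generator: schedules, latent dynamics, observation
# model, missingness, metadata, cohort assembly.

test_that("beep schedules respect the window, counts and determinism", {
  s <- generate_beep_schedule(n_days = 6, beeps_per_day = 10, seed = 7)
  expect_equal(nrow(s), 60)
  expect_true(all(s$time_of_day_min >= 450 & s$time_of_day_min <= 1350))
  # strictly increasing within each day
  expect_true(all(tapply(s$time_of_day_min, s$day,
                         function(x) all(diff(x) > 0))))
  expect_identical(s, generate_beep_schedule(6, 10, seed = 7))
  # mean within-day gap ~ 90 min over many schedules
  gaps <- unlist(lapply(1:40, function(i) {
    sc <- generate_beep_schedule(3, 10, seed = i)
    unlist(tapply(sc$time_of_day_min, sc$day, diff))
  }))
  expect_lt(abs(mean(gaps) - 90), 4)
  # single beep per day: one uniform draw in the window
  s1 <- generate_beep_schedule(n_days = 4, beeps_per_day = 1, seed = 2)
  expect_equal(nrow(s1), 4)
  expect_true(all(s1$beep_in_day == 1))
  expect_error(generate_beep_schedule(2, 2000, 450, 1350),
               "infeasible")
})

test_that("noise-free latent series sits at the person mean", {
  cfg <- sim_config("Stable", transition = matrix(0, 6, 6),
                    innovation_sd = rep(0, 6), person_sd = 0, family_sd = 0,
                    slope_sd = 0)
  sched <- generate_beep_schedule(2, 5, seed = 1)
  x <- simulate_latent_series(cfg, sched, seed = 1)
  expect_equal(dim(x), c(10, 6))
  expect_equal(unname(x[1, ]), unname(cfg$node_means), tolerance = 1e-12)
  expect_true(all(abs(sweep(x, 2, cfg$node_means)) < 1e-12))
})

test_that("latent lag-1 autocorrelation matches the AR(1) oracle", {
  # B = 0.5 I, no residual autocorrelation: within-day lag-1 correlation
  # of each node should approach 0.5 (closed-form AR(1) autocovariance).
  cfg <- sim_config("Stable", transition = diag(0.5, 6), resid_phi = 0,
                    person_sd = 0, family_sd = 0, slope_sd = 0,
                    n_days = 40, beeps_per_day = 10)
  sched <- generate_beep_schedule(40, 10, seed = 3)
  x <- do.call(rbind, lapply(1:6, function(s)
    simulate_latent_series(cfg, sched, seed = s)))
  day <- rep(rep(sched$day, times = 6), 1)
  rep_id <- rep(1:6, each = nrow(sched))
  blk <- paste(rep_id, day)
  ac <- vapply(1:6, function(j) {
    xs <- split(x[, j], blk)
    pairs <- do.call(rbind, lapply(xs, function(v)
      cbind(utils::head(v, -1), v[-1])))
    cor(pairs[, 1], pairs[, 2])
  }, numeric(1))
  expect_true(all(abs(ac - 0.5) < 0.06))
})

test_that("days are independent (overnight reset to the stationary law)", {
  cfg <- sim_config("Stable", n_days = 400, beeps_per_day = 2)
  sched <- generate_beep_schedule(400, 2, seed = 5)
  x <- simulate_latent_series(cfg, sched, seed = 11)
  last <- x[seq(2, 800, by = 2), ]
  first_next <- x[seq(3, 800, by = 2), ]
  last <- last[-nrow(last), ]
  r <- vapply(1:6, function(j) cor(last[, j], first_next[, j]), numeric(1))
  expect_true(all(abs(r) < 0.12))
})

test_that("empirical stationary SD matches the closed-form covariance", {
  cfg <- sim_config("Increase", resid_phi = 0.3, person_sd = 0,
                    family_sd = 0, slope_sd = 0, n_days = 300,
                    beeps_per_day = 10)
  sched <- generate_beep_schedule(300, 10, seed = 2)
  x <- simulate_latent_series(cfg, sched, seed = 9)
  analytic <- sqrt(diag(stationary_cov(cfg$transition, cfg$innovation_sd,
                                       cfg$phi_step)$z))
  expect_equal(unname(apply(x, 2, sd)), unname(analytic), tolerance = 0.06)
  # default calibration targets unit latent SD
  expect_equal(unname(analytic), rep(1, 6), tolerance = 1e-8)
})

test_that("non-stationary transition matrices are rejected", {
  expect_error(sim_config("Stable", transition = diag(1.05, 6)),
               "spectral radius")
  expect_error(stationary_cov(diag(1.2, 6), 1), "stationary")
})

test_that("likert observation rounds half-up, clips and keeps NA", {
  expect_identical(observe_likert(c(3.4, 3.5, -2, 9.3)), c(3L, 4L, 1L, 7L))
  m <- matrix(c(1.2, NA, 6.5, 7.9), 2, 2)
  out <- observe_likert(m)
  expect_identical(out, matrix(c(1L, NA, 7L, 7L), 2, 2))
  x <- matrix(sample(1:7, 30, TRUE), 5, 6)
  expect_identical(observe_likert(x), x)
})

test_that("missingness drops whole beeps at the configured rate", {
  pan <- random_panel(n_persons = 10, n_beeps = 60, seed = 4)
  expect_identical(apply_missingness(pan, 0), pan)
  out <- apply_missingness(pan, 0.25, seed = 1)
  miss <- is.na(out[, nodes6])
  # all-or-nothing per beep
  expect_true(all(rowSums(miss) %in% c(0L, 6L)))
  n <- nrow(pan)
  kept <- sum(rowSums(miss) == 0)
  bounds <- qbinom(c(1e-4, 1 - 1e-4), n, 0.75)
  expect_gte(kept, bounds[1]); expect_lte(kept, bounds[2])
  expect_identical(out, apply_missingness(pan, 0.25, seed = 1))
})

test_that("missingness thins consecutive complete pairs quadratically", {
  pan <- random_panel(n_persons = 30, n_beeps = 60, seed = 6)
  count_pairs <- function(p) {
    cmp <- stats::complete.cases(p[, nodes6])
    sum(vapply(split(seq_len(nrow(p)), p$person_id), function(ix) {
      d <- p[ix, ]
      ok <- cmp[ix]
      sum(ok[-1] & ok[-length(ok)] &
            diff(d$beep_number) == 1 & diff(d$day) == 0)
    }, numeric(1)))
  }
  n0 <- count_pairs(pan)
  rate <- 0.25
  out <- apply_missingness(pan, rate, seed = 2)
  n1 <- count_pairs(out)
  # pair survives with probability (1-rate)^2; allow binomial spread
  expect_lt(abs(n1 - n0 * (1 - rate)^2), 4 * sqrt(n0 * 0.5 * 0.5))
  expect_lt(n1 / n0, 1 - rate)   # super-linear loss
})

test_that("person metadata follows the group change-score distributions", {
  for (g in c("Stable", "Increase", "Decrease")) {
    m <- simulate_person_meta(2000, g, seed = 8)
    expect_true(all(m$scl_t0 >= 90 & m$scl_t0 <= 450))
    expect_true(all(m$scl_t1 >= 90 & m$scl_t1 <= 450))
    expect_true(all(m$jtv_sum >= 4 & m$jtv_sum <= 17))
    expect_identical(m$scl_change, m$scl_t1 - m$scl_t0)
  }
  # analytic oracle: mean of the change distribution after truncating
  # scl_t1 = t0 + change into [90, 450], averaged over the observed t0
  trunc_mean <- function(t0, mu, sigma) {
    a <- (90 - t0 - mu) / sigma
    b <- (450 - t0 - mu) / sigma
    mean(mu + sigma * (stats::dnorm(a) - stats::dnorm(b)) /
           (stats::pnorm(b) - stats::pnorm(a)))
  }
  mi <- simulate_person_meta(3000, "Increase", seed = 9)
  expect_lt(abs(mean(mi$scl_change) - 25.7), 1.7)
  ms <- simulate_person_meta(3000, "Stable", seed = 10)
  expect_lt(abs(mean(ms$scl_change) - trunc_mean(ms$scl_t0, -5.04, 4.95)),
            4 * 4.95 / sqrt(3000))
  expect_lt(abs(mean(ms$scl_change) - (-5.04)), 1)
  md <- simulate_person_meta(3000, "Decrease", seed = 11)
  expect_lt(abs(mean(md$scl_change) - trunc_mean(md$scl_t0, -41.48, 33.09)),
            4 * 33.09 / sqrt(3000))
  expect_lt(mean(md$scl_change), -25)
  expect_gt(mean(md$scl_t0), mean(ms$scl_t0) + 25)
})

test_that("cohorts assemble with family structure and known truth", {
  coh <- simulate_cohort(sim_config("Stable", n_families = 40), seed = 1)
  expect_equal(nrow(coh$meta), 80)
  expect_equal(nrow(coh$panel), 4800)
  expect_equal(length(unique(coh$panel$family_id)), 40)
  expect_identical(coh$truth$Stable, default_transition("Stable"))
  # deterministic given config + seed
  coh2 <- simulate_cohort(sim_config("Stable", n_families = 40), seed = 1)
  expect_identical(coh$panel, coh2$panel)
  expect_identical(coh$meta, coh2$meta)
  # two configs with one group label collide on person ids
  expect_error(simulate_cohort(list(sim_config("Stable"),
                                    sim_config("Stable")), seed = 1),
               "duplicate")
})

test_that("identical configs give identical ground-truth metrics and the
          Increase truth contains the down<->lonely 2-cycle", {
  b <- default_transition("Stable")
  cfgA <- sim_config("Stable", transition = b)
  cfgB <- sim_config("Increase", transition = b)
  expect_equal(negative_connectivity(cfgA$transition) -
                 negative_connectivity(cfgB$transition), 0)
  cyc <- find_reinforcing_cycles(default_transition("Increase"))
  expect_true("down->lonely->down" %in% cyc$cycle)
  expect_equal(cyc$strength[cyc$cycle == "down->lonely->down"], 0.25)
})

test_that("default configs produce within-person SDs near 1", {
  coh <- simulate_cohort(list(sim_config("Stable", n_families = 15),
                              sim_config("Increase", n_families = 15)),
                         seed = 3)
  pan <- coh$panel
  cmp <- stats::complete.cases(pan[, nodes6])
  for (v in nodes6) {
    sds <- tapply(pan[[v]][cmp], pan$person_id[cmp], sd)
    pooled <- sqrt(mean(sds^2, na.rm = TRUE))
    expect_gt(pooled, 0.7)
    expect_lt(pooled, 1.4)
  }
})
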