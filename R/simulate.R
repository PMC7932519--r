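# Synthetic ESM cohort generator with known VAR(1) ground truth.
#
# The generator emulates the study design the estimation pipeline expects:
# persons nested in twin families, 6 days x 10 semi-random beeps between
# 07:30 and 22:30 (~90 min mean gap), six 1-7 Likert affect items with
# within-person SD near 1.0, beep-level missingness, and per-group SCL-90
# symptom-change distributions.

#' Default lagged transition matrices
#'
#' Ground-truth 6x6 transition matrices for the three symptom-change
#' groups. Entry `[j, k]` is the effect of node `k` at beep t-1 on node
#' `j` at beep t. The Stable matrix has an interconnected positive cluster
#' whose activity dampens 'down', and no lagged connections among the
#' negative states. The Increase matrix shares the positive cluster but
#' adds a connected negative cluster with reciprocal positive
#' down<->lonely edges (a structure that can sustain a "vicious cycle").
#' The Decrease group reuses the Stable dynamics: its networks are never
#' analysed, only its symptom distribution matters.
#'
#' @param group `"Stable"`, `"Increase"` or `"Decrease"`.
#' @return A 6x6 numeric matrix with node names on both dimensions
#'   (rows = outcome at t, columns = predictor at t-1).
#' @examples
#' default_transition("Increase")["down", "lonely"]
#' @export
default_transition <- function(group = c("Stable", "Increase", "Decrease")) {
  group <- match.arg(group)
  nodes <- affect_nodes()
  B <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  diag(B) <- c(0.20, 0.20, 0.20, 0.15, 0.15, 0.15)
  # shared positive cluster
  B["relaxed", "cheerful"] <- 0.10
  B["cheerful", "relaxed"] <- 0.10
  B["energetic", "cheerful"] <- 0.10
  B["cheerful", "energetic"] <- 0.10
  if (group == "Increase") {
    B["irritated", "relaxed"] <- -0.10   # positive cluster dampens irritation
    B["lonely", "down"] <- 0.25          # reciprocal down<->lonely 2-cycle
    B["down", "lonely"] <- 0.25
    B["down", "irritated"] <- 0.10
    B["irritated", "lonely"] <- 0.10
  } else {
    B["down", "cheerful"] <- -0.10       # positive cluster dampens feeling down
  }
  B
}

#' Default node means per group
#'
#' Group-specific means of the six affect items on the 1-7 Likert scale.
#' Stable and Increase values follow the observed group means of the
#' cohort design this generator emulates; the Decrease group (never
#' network-analysed) is given slightly elevated negative affect consistent
#' with its higher baseline symptom load.
#'
#' @inheritParams default_transition
#' @return Named numeric 6-vector.
#' @export
default_node_means <- function(group = c("Stable", "Increase", "Decrease")) {
  group <- match.arg(group)
  m <- switch(group,
    Stable   = c(4.76, 5.03, 4.63, 2.24, 1.79, 1.69),
    Increase = c(4.53, 4.86, 4.34, 2.41, 1.91, 1.86),
    Decrease = c(4.40, 4.70, 4.20, 2.60, 2.20, 2.10))
  setNames(m, affect_nodes())
}

# Group-level SCL-90 and demographic parameters (baseline sum score,
# one-year change, JTV childhood-experience items, age, sex).
group_meta_params <- function(group) {
  switch(group,
    Stable   = list(t0_mean = 126.8,  t0_sd = 26.1,
                    change_mean = -5.04,  change_sd = 4.95,
                    jtv_mean = 15.6, jtv_sd = 1.6,
                    age_mean = 17.9, age_sd = 4.0, p_female = 0.69),
    Increase = list(t0_mean = 130.24, t0_sd = 34.0,
                    change_mean = 25.7,   change_sd = 22.5,
                    jtv_mean = 14.95, jtv_sd = 2.15,
                    age_mean = 16.9, age_sd = 3.6, p_female = 0.63),
    Decrease = list(t0_mean = 168.3,  t0_sd = 30.0,
                    change_mean = -41.48, change_sd = 33.09,
                    jtv_mean = 15.0, jtv_sd = 2.0,
                    age_mean = 17.8, age_sd = 3.8, p_female = 0.66),
    abort(sprintf("unknown group label '%s'", group)))
}

spectral_radius <- function(B) max(Mod(eigen(B, only.values = TRUE)$values))

#' Stationary covariance of the latent affect process
#'
#' Closed-form stationary covariance of the VAR(1) latent process
#' `z_t = B z_{t-1} + e_t`, where the residual `e_t` is itself AR(1) with
#' per-step correlation `phi_step` and marginal innovation covariance
#' `diag(innovation_sd^2)`. Solved exactly on the augmented state
#' `(z_t, e_t)` via vectorisation of the discrete Lyapunov equation.
#'
#' @param B 6x6 (or k x k) transition matrix, spectral radius < 1.
#' @param innovation_sd Marginal SD vector of the residual process.
#' @param phi_step Per-step AR(1) correlation of the residuals, in `[0, 1)`.
#' @return List with `z` (stationary covariance of the latent state) and
#'   `state` (covariance of the augmented `(z, e)` state).
#' @examples
#' S <- stationary_cov(diag(0.5, 2), c(1, 1))
#' S$z  # diag 1/(1 - 0.25)
#' @export
stationary_cov <- function(B, innovation_sd, phi_step = 0) {
  k <- nrow(B)
  stopifnot(ncol(B) == k, length(innovation_sd) %in% c(1L, k),
            phi_step >= 0, phi_step < 1)
  if (spectral_radius(B) >= 1) {
    abort("transition matrix is not stationary (spectral radius >= 1)")
  }
  innovation_sd <- rep(innovation_sd, length.out = k)
  Q <- diag(innovation_sd^2, k)            # marginal residual covariance
  Qu <- Q * (1 - phi_step^2)               # innovation of the residual AR(1)
  R <- diag(phi_step, k)
  # state s_t = (z_t, e_t): z_t = B z_{t-1} + R e_{t-1} + u_t ; e_t = R e_{t-1} + u_t
  A <- rbind(cbind(B, R), cbind(matrix(0, k, k), R))
  V <- rbind(cbind(Qu, Qu), cbind(Qu, Qu))
  n2 <- (2 * k)^2
  S <- matrix(solve(diag(n2) - kronecker(A, A), as.vector(V)), 2 * k, 2 * k)
  S <- (S + t(S)) / 2
  list(z = S[1:k, 1:k, drop = FALSE], state = S)
}

# Innovation SDs such that the latent stationary SD of every node equals
# `target_sd`. The stationary variance is linear in the innovation
# variances, so the calibration is a single 6x6 linear solve.
calibrate_innovation_sd <- function(B, target_sd = 1, phi_step = 0) {
  k <- nrow(B)
  target_sd <- rep(target_sd, length.out = k)
  M <- vapply(seq_len(k), function(i) {
    sd1 <- rep(0, k); sd1[i] <- 1
    diag(stationary_cov(B, sd1, phi_step)$z)
  }, numeric(k))
  q <- solve(M, target_sd^2)
  if (any(q <= 0)) {
    abort("innovation calibration failed: target SDs unattainable for this B")
  }
  sqrt(q)
}

#' Simulation configuration for one cohort group
#'
#' Bundles the design of the sampling scheme (days, beeps, time window),
#' the ground-truth dynamics (transition matrix, node means, innovation,
#' random-effect SDs, residual autocorrelation), the observation model
#' (missingness) and the symptom-group label.
#'
#' The residual AR(1) parameter `resid_phi` is the correlation per hour of
#' elapsed time; consecutive beeps ~90 minutes apart then correlate at
#' `resid_phi^1.5`. When `innovation_sd` is `NULL` it is calibrated so the
#' latent within-person SD of every node equals `target_within_sd`,
#' matching items selected for within-person SDs near 1.0.
#'
#' @param group_label Symptom-change group: `"Stable"`, `"Increase"`,
#'   `"Decrease"`.
#' @param n_families Number of families (clusters of twins).
#' @param persons_per_family Persons per family (default 2, twins).
#' @param n_days,beeps_per_day ESM sampling period (default 6 x 10).
#' @param day_start_min,day_end_min Daily window in minutes-of-day
#'   (default 450 = 07:30 to 1350 = 22:30).
#' @param mean_gap_min Target mean within-day gap (implied by the window
#'   and `beeps_per_day`; kept for documentation/validation).
#' @param transition 6x6 lagged transition matrix; default
#'   [default_transition()] for the group.
#' @param node_means Length-6 vector of node means on the Likert scale;
#'   default [default_node_means()] for the group.
#' @param innovation_sd Length-6 residual marginal SDs, or `NULL` to
#'   calibrate to `target_within_sd`.
#' @param target_within_sd Latent stationary within-person SD used when
#'   calibrating `innovation_sd` (default 1.0).
#' @param person_sd,family_sd Random-intercept SDs per node at the person
#'   and family level.
#' @param slope_sd SD of person-specific deviations of each lagged
#'   transition entry (diagonal covariance, matching the fitted model).
#' @param resid_phi Residual AR(1) correlation per hour, in `[0, 1)`.
#' @param trend_slope Fixed linear drift per beep number (Likert units).
#' @param missing_rate Probability that a whole beep (all six items) is
#'   missing, in `[0, 1)`.
#' @param seed Optional integer seed used when this config is simulated on
#'   its own.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config("Stable", n_families = 5)
#' cfg$transition["down", "cheerful"]
#' @export
sim_config <- function(group_label = c("Stable", "Increase", "Decrease"),
                       n_families = 40,
                       persons_per_family = 2,
                       n_days = 6,
                       beeps_per_day = 10,
                       day_start_min = 450,
                       day_end_min = 1350,
                       mean_gap_min = 90,
                       transition = NULL,
                       node_means = NULL,
                       innovation_sd = NULL,
                       target_within_sd = 1,
                       person_sd = 0.5,
                       family_sd = 0.3,
                       slope_sd = 0.05,
                       resid_phi = 0.2,
                       trend_slope = 0,
                       missing_rate = 0.25,
                       seed = NULL) {
  group_label <- match.arg(group_label)
  if (is.null(transition)) transition <- default_transition(group_label)
  if (is.null(node_means)) node_means <- default_node_means(group_label)
  nodes <- affect_nodes()
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(6, 6))) abort("transition must be 6x6")
  dimnames(transition) <- list(nodes, nodes)
  node_means <- setNames(rep(node_means, length.out = 6), nodes)
  if (spectral_radius(transition) >= 1) {
    abort("transition matrix is not stationary (spectral radius >= 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  if (resid_phi < 0 || resid_phi >= 1) abort("resid_phi must be in [0, 1)")
  if (day_start_min >= day_end_min) {
    abort("day_start_min must be smaller than day_end_min")
  }
  if ((day_end_min - day_start_min) < beeps_per_day) {
    abort("infeasible beep window: beeps do not fit between day start and end")
  }
  phi_step <- resid_phi^(mean_gap_min / 60)
  if (is.null(innovation_sd)) {
    innovation_sd <- calibrate_innovation_sd(transition, target_within_sd,
                                             phi_step)
  }
  innovation_sd <- setNames(rep(innovation_sd, length.out = 6), nodes)
  cfg <- list(
    group_label = group_label,
    n_families = as.integer(n_families),
    persons_per_family = as.integer(persons_per_family),
    n_days = as.integer(n_days),
    beeps_per_day = as.integer(beeps_per_day),
    day_start_min = day_start_min,
    day_end_min = day_end_min,
    mean_gap_min = mean_gap_min,
    transition = transition,
    node_means = node_means,
    innovation_sd = innovation_sd,
    person_sd = setNames(rep(person_sd, length.out = 6), nodes),
    family_sd = setNames(rep(family_sd, length.out = 6), nodes),
    slope_sd = slope_sd,
    resid_phi = resid_phi,
    phi_step = phi_step,
    trend_slope = trend_slope,
    missing_rate = missing_rate,
    seed = seed
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> group=%s | %d families x %d persons | %d days x %d beeps\n",
    x$group_label, x$n_families, x$persons_per_family, x$n_days,
    x$beeps_per_day))
  cat(sprintf("  spectral radius(B)=%.3f, resid_phi=%.2f/hr, missing=%.0f%%\n",
              spectral_radius(x$transition), x$resid_phi,
              100 * x$missing_rate))
  invisible(x)
}

#' Generate a semi-random beep schedule
#'
#' Each day's window is split into `beeps_per_day` equal blocks and one
#' time is drawn uniformly inside each block (stratified-interval jitter).
#' This yields strictly increasing within-day times whose mean gap equals
#' the block width (90 minutes for the default 07:30-22:30 window with 10
#' beeps) without requiring explicit collision handling.
#'
#' @inheritParams sim_config
#' @param seed Optional integer seed (schedules are deterministic given
#'   the seed).
#' @return A tibble with columns `day`, `beep_in_day`, `beep_number`,
#'   `time_of_day_min` (minutes-of-day) and `time_min` (minutes since the
#'   start of the sampling period).
#' @examples
#' sched <- generate_beep_schedule(seed = 7)
#' range(sched$time_of_day_min)
#' @export
generate_beep_schedule <- function(n_days = 6, beeps_per_day = 10,
                                   day_start_min = 450, day_end_min = 1350,
                                   mean_gap_min = 90, seed = NULL) {
  if (day_start_min >= day_end_min) {
    abort("infeasible window: day_start_min must be below day_end_min")
  }
  width <- (day_end_min - day_start_min) / beeps_per_day
  if (width < 1) {
    abort("infeasible window: beeps_per_day does not fit in the day window")
  }
  with_seed_(seed, {
    out <- purrr::map_dfr(seq_len(n_days), function(d) {
      starts <- day_start_min + (seq_len(beeps_per_day) - 1) * width
      tod <- sort(starts + runif(beeps_per_day, 0, width))
      tibble(day = d, beep_in_day = seq_len(beeps_per_day),
             time_of_day_min = tod)
    })
    out$beep_number <- seq_len(nrow(out))
    out$time_min <- (out$day - 1) * 1440 + out$time_of_day_min
    out[, c("day", "beep_in_day", "beep_number", "time_of_day_min",
            "time_min")]
  })
}

#' Simulate the latent affect series of one person
#'
#' Within each day the latent state follows
#' `x_t = mu_p + trend * t + z_t`, `z_t = B_p z_{t-1} + e_t`, with `e_t`
#' an AR(1) residual whose correlation between beeps separated by `dt`
#' hours is `resid_phi^dt`. The first beep of every day is drawn from the
#' person's stationary marginal (overnight reset), so consecutive days are
#' independent, mirroring the exclusion of overnight lags from the
#' analysis.
#'
#' @param config A [sim_config()].
#' @param schedule A beep schedule from [generate_beep_schedule()].
#' @param person_effects Optional list with `mu` (length-6 person mean
#'   vector) and `B` (person-specific 6x6 transition); defaults to the
#'   config's population values.
#' @param seed Optional integer seed.
#' @return A T x 6 numeric matrix of latent values (rows = beeps).
#' @export
simulate_latent_series <- function(config, schedule, person_effects = NULL,
                                   seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(person_effects)) {
    person_effects <- list(mu = config$node_means, B = config$transition)
  }
  B <- person_effects$B
  mu <- person_effects$mu
  if (spectral_radius(B) >= 1) {
    abort("person transition matrix is not stationary")
  }
  sc <- stationary_cov(B, config$innovation_sd, config$phi_step)
  # chol() needs strict positive definiteness; the zero-noise limit is the
  # deterministic fixed point.
  zero_noise <- all(config$innovation_sd == 0)
  L_state <- if (zero_noise) NULL else t(chol(sc$state + diag(1e-12, 12)))
  Q <- config$innovation_sd^2
  with_seed_(seed, {
    x <- matrix(NA_real_, nrow(schedule), 6,
                dimnames = list(NULL, affect_nodes()))
    for (d in unique(schedule$day)) {
      idx <- which(schedule$day == d)
      t_hr <- schedule$time_min[idx] / 60
      if (zero_noise) {
        z <- rep(0, 6); e <- rep(0, 6)
      } else {
        s <- as.vector(L_state %*% rnorm(12))
        z <- s[1:6]; e <- s[7:12]
      }
      x[idx[1], ] <- mu + config$trend_slope * schedule$beep_number[idx[1]] + z
      for (i in seq_along(idx)[-1]) {
        phi_dt <- config$resid_phi^(t_hr[i] - t_hr[i - 1])
        u_sd <- sqrt(pmax(Q * (1 - phi_dt^2), 0))
        e <- phi_dt * e + rnorm(6, 0, u_sd)
        z <- as.vector(B %*% z) + e
        x[idx[i], ] <- mu + config$trend_slope * schedule$beep_number[idx[i]] + z
      }
    }
    x
  })
}

#' Map latent values to the 1-7 Likert scale
#'
#' Round-half-up to the nearest integer, then clip into `[1, 7]`.
#' Missing values are preserved.
#'
#' @param latent Numeric matrix or vector of latent affect values.
#' @return Integer matrix/vector of the same shape.
#' @examples
#' observe_likert(c(3.4, 3.5, -2, 9.3))
#' @export
observe_likert <- function(latent) {
  out <- floor(latent + 0.5)       # round half up (not banker's rounding)
  out <- pmin(pmax(out, 1), 7)
  storage.mode(out) <- "integer"
  out
}

#' Apply beep-level missingness
#'
#' Each beep is dropped independently with probability `missing_rate`;
#' a dropped beep loses all six items together, matching a complete-case
#' analysis in which partial observations are discarded anyway.
#'
#' @param panel An ESM panel tibble with the six item columns.
#' @param missing_rate Probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The panel with dropped beeps set to `NA` in all item columns.
#' @export
apply_missingness <- function(panel, missing_rate, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  if (missing_rate == 0) return(panel)
  with_seed_(seed, {
    drop <- runif(nrow(panel)) < missing_rate
    panel[drop, affect_nodes()] <- NA_integer_
    panel
  })
}

# Integer draw from a normal, resampled (not clipped) into [lo, hi] to
# avoid boundary point masses.
rnorm_int_trunc <- function(n, mean, sd, lo, hi) {
  out <- integer(n)
  todo <- seq_len(n)
  for (iter in 1:1000) {
    out[todo] <- as.integer(round(rnorm(length(todo), mean, sd)))
    todo <- which(out < lo | out > hi)
    if (length(todo) == 0) return(out)
  }
  abort("truncated draw failed to converge; bounds too tight for mean/sd")
}

#' Simulate per-person symptom and covariate records
#'
#' Draws SCL-90 sum scores at baseline and follow-up, the JTV
#' childhood-experience sum, age and sex for `n` persons of one
#' symptom-change group. Baseline scores and one-year changes follow the
#' group-specific distributions (Stable change -5.04 +/- 4.95; Increase
#' +25.7 +/- 22.5; Decrease -41.48 +/- 33.09; Decrease baseline inflated),
#' rounded to integers and resampled into the 90-450 scale bounds. JTV
#' sums are resampled below the configured population median, emulating a
#' cohort already screened to the low-happy-childhood half.
#'
#' @param n Number of persons.
#' @param group_label `"Stable"`, `"Increase"` or `"Decrease"`.
#' @param jtv_median Population median of the 4-item JTV sum used for the
#'   screening rule (included persons score strictly below it).
#' @param seed Optional integer seed.
#' @return A tibble with columns `group`, `scl_t0`, `scl_t1`,
#'   `scl_change`, `jtv_sum`, `age`, `sex`.
#' @examples
#' simulate_person_meta(3, "Increase", seed = 1)
#' @export
simulate_person_meta <- function(n = 1, group_label = "Stable",
                                 jtv_median = 18, seed = NULL) {
  p <- group_meta_params(group_label)
  with_seed_(seed, {
    t0 <- rnorm_int_trunc(n, p$t0_mean, p$t0_sd, 90L, 450L)
    # resample the change so t1 stays on the 90-450 scale
    change <- integer(n)
    todo <- seq_len(n)
    for (iter in 1:1000) {
      change[todo] <- as.integer(round(rnorm(length(todo), p$change_mean,
                                             p$change_sd)))
      todo <- which(t0 + change < 90L | t0 + change > 450L)
      if (length(todo) == 0) break
    }
    if (length(todo) > 0) abort("could not keep follow-up score in bounds")
    jtv <- rnorm_int_trunc(n, p$jtv_mean, p$jtv_sd, 4L,
                           as.integer(jtv_median) - 1L)
    age <- round(pmax(rnorm(n, p$age_mean, p$age_sd), 14), 1)
    sex <- ifelse(runif(n) < p$p_female, "F", "M")
    tibble(group = group_label, scl_t0 = t0, scl_t1 = t0 + change,
           scl_change = change, jtv_sum = jtv, age = age, sex = sex)
  })
}

# Person-specific transition matrix: population B plus iid N(0, slope_sd^2)
# entrywise deviations (diagonal random-effects covariance), redrawn until
# stationary.
draw_person_transition <- function(B, slope_sd) {
  if (slope_sd == 0) return(B)
  for (iter in 1:100) {
    Bp <- B + matrix(rnorm(36, 0, slope_sd), 6, 6)
    if (spectral_radius(Bp) < 0.98) {
      dimnames(Bp) <- dimnames(B)
      return(Bp)
    }
  }
  abort("could not draw a stationary person transition; slope_sd too large")
}

#' Simulate a multi-group ESM cohort
#'
#' Generates the full study material for one or more [sim_config()]s:
#' a long-format beep-level panel, per-person metadata, and the
#' ground-truth transition matrices for parameter-recovery tests. Persons
#' within a family share a family-level intercept deviation per node.
#'
#' @param configs A single [sim_config()] or a list of them (one per
#'   group).
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   configs and seed.
#' @return An object of class `esm_cohort`: a list with
#'   \describe{
#'     \item{panel}{beep-level tibble (`person_id`, `family_id`, `group`,
#'       `day`, `beep_in_day`, `beep_number`, `time_min`, six item
#'       columns; `NA` = missing beep).}
#'     \item{meta}{per-person tibble with SCL-90, JTV, age, sex.}
#'     \item{truth}{named list of ground-truth transition matrices, one
#'       per group label.}
#'     \item{configs}{the configs used.}
#'   }
#' @examples
#' coh <- simulate_cohort(sim_config("Stable", n_families = 3), seed = 1)
#' dim(coh$panel)
#' @export
simulate_cohort <- function(configs, seed = NULL) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(all(vapply(configs, inherits, logical(1), "sim_config")))
  labels <- vapply(configs, `[[`, character(1), "group_label")
  if (anyDuplicated(labels)) {
    abort("duplicate person ids: two configs share a group label")
  }
  if (is.null(seed) && length(configs) == 1) seed <- configs[[1]]$seed
  with_seed_(seed, {
    panels <- list()
    metas <- list()
    for (cfg in configs) {
      lab <- cfg$group_label
      n_pers <- cfg$n_families * cfg$persons_per_family
      meta <- simulate_person_meta(n_pers, lab, seed = NULL)
      fam_idx <- rep(seq_len(cfg$n_families), each = cfg$persons_per_family)
      meta$family_id <- sprintf("%s_f%03d", tolower(substr(lab, 1, 3)),
                                fam_idx)
      meta$person_id <- sprintf("%s_p%d", meta$family_id,
                                sequence(rep(cfg$persons_per_family,
                                             cfg$n_families)))
      fam_eff <- matrix(rnorm(cfg$n_families * 6, 0,
                              rep(cfg$family_sd, each = cfg$n_families)),
                        cfg$n_families, 6)
      rows <- vector("list", n_pers)
      for (i in seq_len(n_pers)) {
        sched <- generate_beep_schedule(cfg$n_days, cfg$beeps_per_day,
                                        cfg$day_start_min, cfg$day_end_min,
                                        cfg$mean_gap_min, seed = NULL)
        mu_p <- cfg$node_means + fam_eff[fam_idx[i], ] +
          rnorm(6, 0, cfg$person_sd)
        B_p <- draw_person_transition(cfg$transition, cfg$slope_sd)
        lat <- simulate_latent_series(cfg, sched,
                                      list(mu = mu_p, B = B_p), seed = NULL)
        obs <- observe_likert(lat)
        pr <- dplyr::bind_cols(
          tibble(person_id = meta$person_id[i],
                 family_id = meta$family_id[i], group = lab),
          sched[, c("day", "beep_in_day", "beep_number", "time_min")],
          as_tibble(obs))
        rows[[i]] <- pr
      }
      pan <- bind_rows(rows)
      pan <- apply_missingness(pan, cfg$missing_rate, seed = NULL)
      panels[[lab]] <- pan
      metas[[lab]] <- meta[, c("person_id", "family_id", "group", "scl_t0",
                               "scl_t1", "scl_change", "jtv_sum", "age",
                               "sex")]
    }
    panel <- bind_rows(panels)
    meta <- bind_rows(metas)
    if (anyDuplicated(meta$person_id)) abort("duplicate person ids generated")
    structure(list(panel = panel, meta = meta,
                   truth = lapply(setNames(configs, labels),
                                  `[[`, "transition"),
                   configs = setNames(configs, labels)),
              class = "esm_cohort")
  })
}

#' @export
print.esm_cohort <- function(x, ...) {
  cat(sprintf("<esm_cohort> %d persons in %d groups, %d beep rows\n",
              nrow(x$meta), length(x$configs), nrow(x$panel)))
  invisible(x)
}

#' Write / read cohort tables as CSV
#'
#' Long-format panel CSV columns: `person_id`, `family_id`, `day`,
#' `beep_in_day`, `beep_number`, `time_min`, then the six item columns
#' (empty cell = missing beep). Metadata and network edge lists are plain
#' CSV as well.
#'
#' @param panel,meta,network Objects to write.
#' @param path File path.
#' @return The input, invisibly (writers); a tibble (readers).
#' @export
write_esm_panel <- function(panel, path) {
  cols <- c("person_id", "family_id", "day", "beep_in_day", "beep_number",
            "time_min", affect_nodes())
  stop_if_missing_cols(panel, setdiff(cols, "family_id"), "panel")
  readr::write_csv(panel[, intersect(c(cols, "group"), names(panel))], path,
                   na = "")
  invisible(panel)
}

#' @rdname write_esm_panel
#' @export
read_esm_panel <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
}

#' @rdname write_esm_panel
#' @export
write_person_meta <- function(meta, path) {
  readr::write_csv(meta, path, na = "")
  invisible(meta)
}
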