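# Preprocessing: missingness filter, centering, lag pairing, diagnostics.

test_that("the 30% missingness boundary is strictly-more-than", {
  base <- make_panel(matrix(4, 60, 6))
  drop_beeps <- function(p, k) {
    p[seq_len(k), nodes6] <- NA_integer_
    p
  }
  kept18 <- filter_by_missingness(drop_beeps(base, 18), scheduled_beeps = 60)
  expect_equal(unique(kept18$person_id), "p1")
  kept19 <- filter_by_missingness(drop_beeps(base, 19), scheduled_beeps = 60)
  expect_equal(nrow(kept19), 0)
  rep19 <- exclusion_report(kept19)
  expect_false(rep19$included)
  expect_equal(rep19$missing_fraction, 19 / 60)
})

test_that("inclusion matches a brute-force recount under random rates", {
  withr::with_seed(42, {
    pans <- purrr::map_dfr(1:30, function(i) {
      rate <- runif(1, 0, 0.6)
      p <- make_panel(matrix(sample(1:7, 360, TRUE), 60, 6),
                      person_id = sprintf("p%02d", i))
      drop <- runif(60) < rate
      p[drop, nodes6] <- NA_integer_
      p
    })
  })
  out <- filter_by_missingness(pans, 0.30, scheduled_beeps = 60)
  # independent recount straight from the raw table
  miss_by_person <- tapply(
    rowSums(is.na(pans[, nodes6])) > 0, pans$person_id, sum)
  expected <- names(miss_by_person)[miss_by_person <= 0.30 * 60]
  expect_setequal(unique(out$person_id), expected)
  # a person with zero observations is excluded and flagged
  allna <- make_panel(matrix(4, 60, 6), person_id = "pzz")
  allna[, nodes6] <- NA_integer_
  rep0 <- exclusion_report(
    filter_by_missingness(dplyr::bind_rows(pans, allna),
                          scheduled_beeps = 60))
  expect_true(rep0$zero_observations[rep0$person_id == "pzz"])
  expect_false(rep0$included[rep0$person_id == "pzz"])
})

test_that("person-mean centering removes levels and only levels", {
  pan <- make_panel(matrix(4, 20, 6))
  ctr <- person_mean_center(pan)
  expect_true(all(abs(as.matrix(ctr[, paste0(nodes6, "_c")])) < 1e-12))
  two <- make_panel(matrix(rep(c(3, 5), each = 6), 2, 6, byrow = TRUE))
  ctr2 <- person_mean_center(two)
  expect_equal(ctr2$cheerful_c, c(-1, 1))
  # translation invariance: shifting one person's ratings changes nothing
  pan2 <- random_panel(n_persons = 3, seed = 2)
  shifted <- pan2
  sel <- shifted$person_id == "p02"
  shifted[sel, nodes6] <- shifted[sel, nodes6] + 2
  c1 <- person_mean_center(pan2)
  c2 <- person_mean_center(shifted)
  expect_equal(as.matrix(c1[, paste0(nodes6, "_c")]),
               as.matrix(c2[, paste0(nodes6, "_c")]), tolerance = 1e-12)
})

test_that("centered means vanish per person and centering is idempotent", {
  pan <- apply_missingness(random_panel(n_persons = 6, n_beeps = 40,
                                        seed = 3), 0.2, seed = 1)
  ctr <- person_mean_center(pan)
  cmp <- stats::complete.cases(ctr[, nodes6])
  for (v in paste0(nodes6, "_c")) {
    m <- tapply(ctr[[v]][cmp], ctr$person_id[cmp], mean)
    expect_true(all(abs(m) < 1e-10))
  }
  # feeding already-centered values back reproduces them exactly
  recentred <- ctr
  recentred[, nodes6] <- ctr[, paste0(nodes6, "_c")]
  again <- person_mean_center(recentred)
  expect_equal(as.matrix(again[, paste0(nodes6, "_c")]),
               as.matrix(ctr[, paste0(nodes6, "_c")]), tolerance = 1e-12)
})

test_that("lag pairs stay within days and match exhaustive enumeration", {
  one_day <- person_mean_center(make_panel(matrix(sample(1:7, 60, TRUE),
                                                  10, 6)))
  expect_equal(nrow(build_lag_pairs(one_day)), 9)
  two_days <- person_mean_center(make_panel(matrix(sample(1:7, 120, TRUE),
                                                   20, 6)))
  d <- build_lag_pairs(two_days)
  expect_equal(nrow(d), 18)                      # 9 per day, none overnight
  expect_false(any(d$beep_number == 11))         # no pair crossing the night
  # enumeration oracle under random missingness
  pan <- apply_missingness(random_panel(n_persons = 8, n_beeps = 60,
                                        seed = 9), 0.3, seed = 4)
  design <- build_lag_pairs(person_mean_center(pan))
  brute <- 0
  for (pid in unique(pan$person_id)) {
    pp <- pan[pan$person_id == pid, ]
    pp <- pp[order(pp$beep_number), ]
    cmp <- stats::complete.cases(pp[, nodes6])
    for (i in 2:nrow(pp)) {
      if (cmp[i] && cmp[i - 1] &&
            pp$beep_number[i] - pp$beep_number[i - 1] == 1 &&
            pp$day[i] == pp$day[i - 1]) brute <- brute + 1
    }
  }
  expect_equal(nrow(design), brute)
  # monotonicity: extra missingness never adds rows
  pan2 <- apply_missingness(pan, 0.3, seed = 5)
  expect_lte(nrow(build_lag_pairs(person_mean_center(pan2))), nrow(design))
  # lagged predictors are the centered values of the previous beep
  ctr <- person_mean_center(pan)
  i <- 5
  prev <- ctr[ctr$person_id == design$person_id[i] &
                ctr$beep_number == design$beep_number[i] - 1, ]
  expect_equal(design$lag_down[i], prev$down_c)
})

test_that("cronbach alpha matches its closed forms", {
  x <- matrix(rnorm(60), 30, 2)
  x[, 2] <- x[, 1] + 3       # perfectly correlated pair, equal variances
  expect_equal(cronbach_alpha(x), 1, tolerance = 1e-12)
  y <- withr::with_seed(10, matrix(rnorm(4 * 20000), ncol = 4))
  expect_lt(abs(cronbach_alpha(y)), 0.03)   # independent items: ~0
  # exact pairwise correlation 0.5 with equal variances:
  # x_i = q0 + q_i with orthonormal centered q's -> alpha = 4*.5/(1+3*.5)
  q <- withr::with_seed(11, {
    m <- matrix(rnorm(50 * 5), 50, 5)
    m <- sweep(m, 2, colMeans(m))
    qr.Q(qr(m))
  })
  items <- sapply(2:5, function(j) q[, 1] + q[, j])
  expect_equal(cor(items)[lower.tri(cor(items))], rep(0.5, 6),
               tolerance = 1e-10)
  expect_equal(cronbach_alpha(items), 0.8, tolerance = 1e-10)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
  expect_error(cronbach_alpha(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("item diagnostics flag duplicates and match recomputation", {
  pan <- random_panel(n_persons = 8, n_beeps = 40, seed = 7)
  ga <- tibble::tibble(person_id = sprintf("p%02d", 1:8),
                       group = rep(c("Stable", "Increase"), each = 4))
  # identical groups: duplicate the panel under new ids/groups
  pan_b <- pan
  pan_b$person_id <- sub("^p", "q", pan_b$person_id)
  both <- dplyr::bind_rows(pan, pan_b)
  ga_dup <- tibble::tibble(
    person_id = c(unique(pan$person_id), unique(pan_b$person_id)),
    group = rep(c("A", "B"), each = 8))
  diag_dup <- item_diagnostics(both, ga_dup)
  expect_true(all(abs(diag_dup$items$mean_diff) < 1e-12))
  expect_true(all(abs(diag_dup$items$sd_ratio - 1) < 1e-12))
  # two equal items correlate perfectly and raise the r flag
  pan_eq <- pan
  pan_eq$relaxed <- pan_eq$cheerful
  diag_eq <- item_diagnostics(pan_eq, ga)
  r_cr <- diag_eq$correlations
  row <- r_cr[r_cr$item_a == "cheerful" & r_cr$item_b == "relaxed", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_false(row$r_ok)
  # SD ratio equals a direct recomputation
  dg <- item_diagnostics(pan, ga)
  ctr <- person_mean_center(pan)
  grp <- ga$group[match(ctr$person_id, ga$person_id)]
  for (v in nodes6) {
    sds <- vapply(c("Stable", "Increase"), function(g) {
      sel <- grp == g
      affectnet:::pooled_within_sd(ctr[[v]][sel], ctr$person_id[sel])
    }, numeric(1))
    expect_equal(dg$items$sd_ratio[dg$items$item == v],
                 max(sds) / min(sds), tolerance = 1e-12)
  }
  # label swap flips mean differences, flags unchanged
  ga_sw <- ga
  ga_sw$group <- ifelse(ga$group == "Stable", "Increase", "Stable")
  dg_sw <- item_diagnostics(pan, ga_sw)
  expect_equal(dg_sw$items$mean_diff, -dg$items$mean_diff,
               tolerance = 1e-10)
  expect_identical(dg_sw$items$sd_ratio_ok, dg$items$sd_ratio_ok)
  expect_identical(dg_sw$items$mean_ok, dg$items$mean_ok)
  # degenerate group sizes are rejected
  ga_one <- ga; ga_one$group[1:7] <- "Stable"
  expect_error(item_diagnostics(pan, ga_one), "fewer than 2")
})
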