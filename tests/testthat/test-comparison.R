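# Permutation comparison: p-value construction, determinism, units,
# exchangeability, tier agreement, reports.

test_that("metric differences and ratios follow the B-vs-A convention", {
  Wa <- matrix(0, 6, 6, dimnames = list(nodes6, nodes6))
  Wa["down", "lonely"] <- 0.13
  Wb <- matrix(0, 6, 6, dimnames = list(nodes6, nodes6))
  Wb["down", "lonely"] <- 0.29
  na <- matrix_network(Wa, group = "Stable")
  nb <- matrix_network(Wb, group = "Increase")
  md <- metric_difference(na, nb, network_metric("negative_connectivity"))
  expect_equal(md$value_a, 0.13)
  expect_equal(md$value_b, 0.29)
  expect_equal(md$difference, 0.16)
  expect_equal(md$ratio, 0.29 / 0.13)
  same <- metric_difference(na, na, network_metric("negative_connectivity"))
  expect_equal(same$difference, 0)
  expect_equal(same$ratio, 1)
  zero <- matrix_network(matrix(0, 6, 6))
  mz <- metric_difference(zero, nb, network_metric("negative_connectivity"))
  expect_true(is.na(mz$ratio) && mz$ratio_undefined)
  # every built-in metric equals direct recomputation through the module
  for (m in default_metric_set()) {
    md2 <- metric_difference(na, nb, m)
    expect_equal(md2$difference, m$fn(nb) - m$fn(na))
  }
})

test_that("permutation p-values use the add-one rule and are reproducible", {
  design <- small_two_group_design(n_fam = 6, seed = 1)
  pt <- permutation_test(design, n_perm = 99, seed = 11)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  expect_equal(pt$p_value,
               (1 + sum(abs(pt$perm_diffs) >= abs(pt$observed) - 1e-12)) /
                 (1 + pt$n_perm))
  pt2 <- permutation_test(design, n_perm = 99, seed = 11)
  expect_identical(pt$perm_diffs, pt2$perm_diffs)
  expect_identical(pt$p_value, pt2$p_value)
  pt3 <- permutation_test(design, n_perm = 99, seed = 12)
  expect_false(identical(pt$perm_diffs, pt3$perm_diffs))
  expect_error(permutation_test(design, n_perm = 0), "at least 1")
  expect_error(permutation_test(design, n_perm = 500, tier = "full"),
               "full_budget")
})

test_that("a metric constant across permutations gives p = 1", {
  design <- small_two_group_design(n_fam = 5, seed = 2)
  const_metric <- function(net) 0.7
  pt <- permutation_test(design, const_metric, n_perm = 49, seed = 1)
  expect_equal(pt$p_value, 1)
})

test_that("an exactly label-symmetric dataset gives p = 1", {
  coh <- simulate_cohort(sim_config("Stable", n_families = 6), seed = 3)
  pan_a <- coh$panel
  pan_b <- coh$panel
  pan_b$person_id <- sub("^sta", "dup", pan_b$person_id)
  pan_b$family_id <- sub("^sta", "dup", pan_b$family_id)
  pan_b$group <- "Increase"
  design <- dplyr::bind_rows(pan_a, pan_b) |>
    person_mean_center() |> build_lag_pairs()
  pt <- permutation_test(design, n_perm = 99, seed = 4)
  expect_equal(pt$observed, 0, tolerance = 1e-12)
  expect_equal(pt$p_value, 1)
})

test_that("family units keep twins together and person units split them", {
  design <- small_two_group_design(n_fam = 5, seed = 5)
  uf <- affectnet:::permutation_units(design, c("Stable", "Increase"),
                                      "family")
  expect_equal(length(uf$id), 10)          # 5 families per group
  expect_equal(anyDuplicated(uf$id), 0)
  up <- affectnet:::permutation_units(design, c("Stable", "Increase"),
                                      "person")
  expect_equal(length(up$id), 20)
  # a family spanning both groups breaks the family unit
  d_bad <- design
  one_stable <- d_bad$person_id[d_bad$group == "Stable"][1]
  d_bad$group[d_bad$person_id == one_stable] <- "Increase"
  expect_error(affectnet:::permutation_units(
    d_bad, c("Stable", "Increase"), "family"), "spans")
})

test_that("an injected negative-connectivity gap is detected", {
  b_null <- default_transition("Stable")
  b_gap <- b_null
  b_gap["down", "lonely"] <- 0.2
  b_gap["lonely", "down"] <- 0.2   # truth gap = 0.4 vs 0.0
  hits <- vapply(1:10, function(r) {
    design <- small_two_group_design(n_fam = 40, seed = 600 + r,
                                     stable_b = b_null,
                                     increase_b = b_gap)
    permutation_test(design, n_perm = 499, seed = r)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("fast and full tiers agree in the zero-random-effect limit", {
  cfgs <- list(
    sim_config("Stable", n_families = 20, person_sd = 0, family_sd = 0,
               slope_sd = 0, resid_phi = 0, missing_rate = 0),
    sim_config("Increase", n_families = 20, person_sd = 0, family_sd = 0,
               slope_sd = 0, resid_phi = 0, missing_rate = 0))
  design <- simulate_cohort(cfgs, seed = 9)$panel |>
    person_mean_center() |> build_lag_pairs()
  spec <- lagged_model_spec()
  m <- network_metric("negative_connectivity")
  diff_full <- m$fn(estimate_group_network(design, "Increase", spec)) -
    m$fn(estimate_group_network(design, "Stable", spec))
  diff_fast <- m$fn(estimate_group_network(design, "Increase",
                                           tier = "fast")) -
    m$fn(estimate_group_network(design, "Stable", tier = "fast"))
  expect_lt(abs(diff_full - diff_fast), 0.02)
})

test_that("compare_all assembles exactly the requested report", {
  design <- small_two_group_design(n_fam = 10, seed = 10)
  cmp <- compare_all(design, metrics = list(
    network_metric("negative_connectivity")),
    n_perm = 49, seed = 2, network_tier = "fast")
  expect_equal(nrow(cmp$tests), 1)
  expect_equal(nrow(cmp$descriptives), 1)
  tb <- tidy(cmp)
  expect_true(all(c("metric", "value_a", "value_b", "difference", "ratio",
                    "p_value") %in% names(tb)))
  expect_s3_class(autoplot(cmp), "ggplot")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_comparison_report(cmp, tmp)
  parsed <- jsonlite::read_json(tmp)
  expect_equal(parsed$metrics$negative_connectivity$p_value,
               cmp$tests$p_value[1], tolerance = 1e-12)
  # full default metric set: 6 statistical entries
  cmp6 <- compare_all(design, n_perm = 19, seed = 3, network_tier = "fast")
  expect_equal(nrow(cmp6$tests), 6)
  expect_setequal(cmp6$tests$metric,
                  c("negative_connectivity", "out_strength_cheerful",
                    "out_strength_relaxed", "out_strength_energetic",
                    "pa_to_na", "na_to_pa"))
})

test_that("multiverse stability is 100% for duplicated assignments and
          flags degenerate ones", {
  design <- small_two_group_design(n_fam = 10, seed = 12)
  persons <- unique(design[, c("person_id", "group")])
  ga <- tibble::tibble(person_id = persons$person_id,
                       group = persons$group, included = TRUE)
  rep1 <- multiverse_report(design, list(ga, ga, ga))
  expect_true(all(rep1$features$stability == 1))
  expect_equal(length(rep1$flagged), 0)
  # an assignment with an empty group is flagged and excluded
  ga_empty <- ga
  ga_empty$group[] <- "Stable"
  rep2 <- multiverse_report(design, list(ga, ga_empty))
  expect_equal(rep2$flagged, 2L)
  expect_true(all(rep2$features$n_assignments == 1))
  # a robustly injected cycle stays stable when the assignment is jittered
  design_c <- small_two_group_design(n_fam = 25, seed = 13)
  persons_c <- unique(design_c[, c("person_id", "group")])
  gac <- tibble::tibble(person_id = persons_c$person_id,
                        group = persons_c$group, included = TRUE)
  drop_some <- function(g, k) {
    g$included[seq_len(k)] <- FALSE
    g
  }
  rep4 <- multiverse_report(design_c,
                            list(gac, drop_some(gac, 4), drop_some(gac, 8)))
  feat <- rep4$features
  cyc_row <- feat[feat$feature == "Increase|cycle|down->lonely->down", ]
  expect_equal(nrow(cyc_row), 1)
  expect_gte(cyc_row$stability, 2 / 3)
})
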