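# Group comparison: descriptive metric differences, permutation tests
# with person- or family-level label shuffling, and multiverse stability.

#' Define a network metric for comparison
#'
#' A small spec object pairing a metric name with the function evaluating
#' it on an `affect_network`.
#'
#' @param type `"negative_connectivity"`, `"out_strength"` or
#'   `"cross_valence"`.
#' @param node Node for `out_strength`.
#' @param from,to Valences for `cross_valence`.
#' @param mode `"absolute"` or `"signed"`.
#' @param include_self_loops Self-loop handling (see the metric
#'   functions).
#' @return A `network_metric` list with `name` and `fn`.
#' @examples
#' m <- network_metric("out_strength", node = "cheerful")
#' m$name
#' @export
network_metric <- function(type = c("negative_connectivity", "out_strength",
                                    "cross_valence"),
                           node = NULL, from = "positive", to = "negative",
                           mode = "absolute", include_self_loops = FALSE) {
  type <- match.arg(type)
  spec <- switch(type,
    negative_connectivity = list(
      name = "negative_connectivity",
      fn = function(net) negative_connectivity(net, include_self_loops)),
    out_strength = {
      if (is.null(node)) abort("out_strength metric needs a node")
      list(name = paste0("out_strength_", node),
           fn = function(net) out_strength(net, node, mode,
                                           include_self_loops))
    },
    cross_valence = list(
      name = paste0(substr(from, 1, 1), "a_to_", substr(to, 1, 1), "a"),
      fn = function(net) cross_valence_effect(net, from, to, mode)))
  structure(spec, class = "network_metric")
}

#' Default metric set for group comparison
#'
#' Negative connectivity, out-strength of each positive node, and the two
#' cross-valence sums (PA->NA and NA->PA).
#'
#' @return A named list of [network_metric()] objects.
#' @export
default_metric_set <- function() {
  ms <- c(list(network_metric("negative_connectivity")),
          lapply(valence_nodes("positive"),
                 function(v) network_metric("out_strength", node = v)),
          list(network_metric("cross_valence", from = "positive",
                              to = "negative"),
               network_metric("cross_valence", from = "negative",
                              to = "positive")))
  setNames(ms, vapply(ms, `[[`, character(1), "name"))
}

as_metric <- function(metric) {
  if (inherits(metric, "network_metric")) return(metric)
  if (is.character(metric) && metric == "negative_connectivity") {
    return(network_metric("negative_connectivity"))
  }
  if (is.function(metric)) {
    return(structure(list(name = "custom", fn = metric),
                     class = "network_metric"))
  }
  abort("metric must be a network_metric, a function, or a known name")
}

#' Descriptive metric difference between two networks
#'
#' @param network_a,network_b `affect_network`s sharing node labels
#'   (conventionally A = Stable, B = Increase).
#' @param metric A [network_metric()] (or function of a network).
#' @return One-row tibble: `metric`, `value_a`, `value_b`,
#'   `difference` (B - A) and `ratio` (B / A, `NA` with a flag when the
#'   reference value is zero).
#' @export
metric_difference <- function(network_a, network_b, metric) {
  if (!identical(rownames(as_weight_matrix(network_a)),
                 rownames(as_weight_matrix(network_b)))) {
    abort("networks have mismatched node sets")
  }
  metric <- as_metric(metric)
  va <- metric$fn(network_a)
  vb <- metric$fn(network_b)
  tibble(metric = metric$name, value_a = va, value_b = vb,
         difference = vb - va,
         ratio = if (va == 0) NA_real_ else vb / va,
         ratio_undefined = va == 0)
}

# Units (persons or whole families) and their observed group labels.
permutation_units <- function(design, groups, unit) {
  d <- distinct(design[, c("person_id",
                           if ("family_id" %in% names(design)) "family_id",
                           "group")])
  d <- d[d$group %in% groups, ]
  if (unit == "family") {
    if (!"family_id" %in% names(d)) {
      abort("family-level permutation needs a family_id column")
    }
    u <- distinct(d[, c("family_id", "group")])
    if (anyDuplicated(u$family_id)) {
      abort("a family spans both groups; use unit = 'person'")
    }
    list(id = u$family_id, label = u$group)
  } else {
    list(id = d$person_id, label = d$group)
  }
}

#' Permutation test for a group difference in a network metric
#'
#' Shuffles group labels over permutation units (whole families by
#' default, so twins always move together; or persons), preserving the
#' observed group sizes, and re-estimates both group networks in every
#' replicate. The default `tier = "fast"` re-estimation uses the
#' two-stage estimator: per-person lagged regressions are computed once
#' and each replicate only re-averages them within the permuted groups,
#' which makes ten thousand replicates cheap. `tier = "full"` re-runs the
#' multilevel ladder and is only allowed up to `full_budget` replicates.
#'
#' The two-sided p-value uses the add-one rule
#' `p = (1 + #{|perm diff| >= |observed diff|}) / (1 + n_perm)`, so it is
#' never exactly zero.
#'
#' @param design Lag design containing both groups (column `group`).
#' @param metric A [network_metric()] or function of a network.
#' @param groups Character vector of the two group labels (A, B);
#'   the statistic is metric(B) - metric(A).
#' @param n_perm Number of permutations (default 10000).
#' @param unit `"family"` (default) or `"person"`.
#' @param tier `"fast"` (default) or `"full"`.
#' @param seed Integer seed; the permuted distribution is deterministic
#'   given the seed.
#' @param full_budget Maximum `n_perm` allowed with `tier = "full"`.
#' @param spec Model spec for `tier = "full"`.
#' @param min_rows Fast-tier minimum analysis rows per person.
#' @return A `permutation_result`; `tidy()` returns the permuted
#'   distribution, `glance()` the one-row summary.
#' @export
permutation_test <- function(design, metric = "negative_connectivity",
                             groups = c("Stable", "Increase"),
                             n_perm = 10000,
                             unit = c("family", "person"),
                             tier = c("fast", "full"),
                             seed = NULL, full_budget = 60,
                             spec = lagged_model_spec(), min_rows = 12) {
  unit <- match.arg(unit)
  tier <- match.arg(tier)
  metric <- as_metric(metric)
  if (n_perm < 1) abort("n_perm must be at least 1")
  if (length(groups) != 2) abort("exactly two groups are required")
  stop_if_missing_cols(design, "group", "lag design")
  if (!all(groups %in% design$group)) abort("both groups must be present")
  if (tier == "full" && n_perm > full_budget) {
    abort(paste0("tier='full' re-fits the multilevel ladder in every ",
                 "replicate; n_perm must stay within full_budget (",
                 full_budget, "). Use tier='fast' or lower n_perm."))
  }
  units <- permutation_units(design, groups, unit)
  if (min(table(factor(units$label, levels = groups))) < 2) {
    abort("each group needs at least two permutation units")
  }

  if (tier == "fast") {
    sub <- design[design$group %in% groups, , drop = FALSE]
    pca <- person_coef_array(sub, min_rows = min_rows)
    # map persons (stage-1 rows) to permutation units
    unit_of_person <- if (unit == "family") pca$family[pca$persons] else
      setNames(pca$persons, pca$persons)
    stat_for <- function(unit_labels) {
      lab <- unit_labels[match(unname(unit_of_person), units$id)]
      ia <- which(lab == groups[1]); ib <- which(lab == groups[2])
      if (length(ia) < 2 || length(ib) < 2) return(NA_real_)
      metric$fn(fast_network_from_array(pca, ib, groups[2])) -
        metric$fn(fast_network_from_array(pca, ia, groups[1]))
    }
  } else {
    stat_for <- function(unit_labels) {
      d <- design
      key <- if (unit == "family") d$family_id else d$person_id
      d$group <- unit_labels[match(key, units$id)]
      sb <- attr(design, "scheduled_beeps")
      attr(d, "scheduled_beeps") <- sb
      na <- estimate_group_network(d, groups[1], spec)
      nb <- estimate_group_network(d, groups[2], spec)
      metric$fn(nb) - metric$fn(na)
    }
  }

  observed <- stat_for(setNames(units$label, units$id)[units$id])
  perm <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_for(sample(units$label))
    }, numeric(1))
  })
  perm_ok <- perm[!is.na(perm)]
  p <- (1 + sum(abs(perm_ok) >= abs(observed) - 1e-12)) /
    (1 + length(perm_ok))
  structure(list(
    metric = metric$name,
    groups = groups,
    observed = observed,
    perm_diffs = perm_ok,
    p_value = p,
    n_perm = length(perm_ok),
    unit = unit,
    tier = tier,
    seed = seed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s: diff(%s - %s) = %.4f, p = %.4f (%d perms, %s, %s tier)\n",
    x$metric, x$groups[2], x$groups[1], x$observed, x$p_value, x$n_perm,
    x$unit, x$tier))
  invisible(x)
}

#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(metric = x$metric, perm = seq_along(x$perm_diffs),
         difference = x$perm_diffs)
}

#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(metric = x$metric, observed = x$observed, p_value = x$p_value,
         n_perm = x$n_perm, unit = x$unit, tier = x$tier)
}

# Join a group assignment into a lag design (included persons only).
apply_assignment <- function(design, assignment) {
  ga <- as_tibble(assignment)
  stop_if_missing_cols(ga, c("person_id", "group"), "assignment")
  if ("included" %in% names(ga)) ga <- ga[ga$included, ]
  sb <- attr(design, "scheduled_beeps")
  out <- design[design$person_id %in% ga$person_id, , drop = FALSE]
  out$group <- ga$group[match(out$person_id, ga$person_id)]
  attr(out, "scheduled_beeps") <- sb
  out
}

#' Full descriptive and statistical group comparison
#'
#' For each requested metric: the descriptive difference between the two
#' group networks (estimated at `network_tier`) and a permutation test
#' (at `tier`). Also reports each group's significant-edge list and
#' reinforcing-cycle inventory (negative and positive subsets).
#'
#' No multiple-testing correction is applied across metrics; each
#' permutation p-value is reported per metric.
#'
#' @param design Lag design.
#' @param assignment Optional [assign_groups()] result to (re)label the
#'   design.
#' @param metrics List of [network_metric()]s (default
#'   [default_metric_set()]).
#' @param groups The two groups to compare (A, B).
#' @param n_perm,unit,tier,seed Passed to [permutation_test()].
#' @param network_tier Estimator for the descriptive networks (`"full"`
#'   default).
#' @param alpha Significance level for edge filtering.
#' @param spec Model spec for full-tier fits.
#' @return A `network_comparison` object; `tidy()` returns the per-metric
#'   table (values, difference, ratio, p).
#' @export
compare_all <- function(design, assignment = NULL,
                        metrics = default_metric_set(),
                        groups = c("Stable", "Increase"), n_perm = 1000,
                        unit = "family", tier = "fast", seed = NULL,
                        network_tier = "full", alpha = 0.05,
                        spec = lagged_model_spec()) {
  if (!is.null(assignment)) design <- apply_assignment(design, assignment)
  stop_if_missing_cols(design, "group", "lag design")
  metrics <- if (inherits(metrics, "network_metric")) list(metrics) else
    metrics
  nets <- lapply(setNames(groups, groups), function(g) {
    estimate_group_network(design, g, spec, tier = network_tier)
  })
  descriptives <- purrr::map_dfr(metrics, function(m) {
    metric_difference(nets[[1]], nets[[2]], m)
  })
  seeds <- if (is.null(seed)) rep(list(NULL), length(metrics)) else
    as.list(seed + seq_along(metrics) - 1)
  tests <- purrr::map2_dfr(metrics, seeds, function(m, s) {
    glance(permutation_test(design, m, groups, n_perm = n_perm, unit = unit,
                            tier = tier, seed = s, spec = spec))
  })
  filtered <- lapply(nets, significant_subnetwork, alpha = alpha)
  edges <- purrr::map_dfr(groups, function(g) {
    e <- tidy(filtered[[g]])
    dplyr::bind_cols(tibble(group = g), e[e$significant, ])
  })
  cycles <- purrr::map_dfr(groups, function(g) {
    bind_rows(
      dplyr::bind_cols(tibble(group = g, subset = "negative"),
                       find_reinforcing_cycles(filtered[[g]], alpha = alpha)),
      dplyr::bind_cols(tibble(group = g, subset = "positive"),
                       find_reinforcing_cycles(
                         filtered[[g]], nodes = valence_nodes("positive"),
                         alpha = alpha)))
  })
  structure(list(networks = nets, descriptives = descriptives,
                 tests = tests, significant_edges = edges, cycles = cycles,
                 groups = groups, alpha = alpha,
                 settings = list(n_perm = n_perm, unit = unit, tier = tier,
                                 network_tier = network_tier, seed = seed)),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> %s vs %s\n", x$groups[1], x$groups[2]))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @method tidy network_comparison
#' @export
tidy.network_comparison <- function(x, ...) {
  left_join(x$descriptives,
            x$tests[, c("metric", "p_value", "n_perm")], by = "metric")
}

#' @method glance network_comparison
#' @export
glance.network_comparison <- function(x, ...) {
  tibble(group_a = x$groups[1], group_b = x$groups[2],
         n_metrics = nrow(x$descriptives),
         n_significant_edges = nrow(x$significant_edges),
         n_cycles = nrow(x$cycles),
         min_p = min(x$tests$p_value))
}

#' Write a comparison report as JSON
#'
#' Per-metric `{value_a, value_b, difference, ratio, p_value, n_perm}`
#' plus the significant-edge and cycle inventories.
#'
#' @param comparison A [compare_all()] result.
#' @param path Output path.
#' @return The comparison, invisibly.
#' @export
write_comparison_report <- function(comparison, path) {
  tb <- tidy(comparison)
  payload <- list(
    groups = comparison$groups,
    metrics = lapply(split(tb[, -1], tb$metric), function(d) as.list(d[1, ])),
    significant_edges = comparison$significant_edges,
    cycles = comparison$cycles,
    settings = comparison$settings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(comparison)
}

# Qualitative features of one estimated group network: significant edges
# (with sign) and reinforcing cycles.
network_features <- function(net, group, alpha) {
  f <- significant_subnetwork(net, alpha)
  e <- tidy(f)
  e <- e[e$significant, ]
  feats <- character()
  if (nrow(e) > 0) {
    feats <- sprintf("%s|edge|%s->%s|%s", group, e$from, e$to,
                     ifelse(e$b > 0, "+", "-"))
  }
  for (sub in c("negative", "positive")) {
    cy <- find_reinforcing_cycles(f, nodes = valence_nodes(sub),
                                  alpha = alpha)
    if (nrow(cy) > 0) {
      feats <- c(feats, sprintf("%s|cycle|%s", group, cy$cycle))
    }
  }
  feats
}

#' Multiverse stability of qualitative network features
#'
#' Re-estimates the two group networks under every group assignment in a
#' multiverse grid and summarises how often each qualitative feature (a
#' significant directed edge with its sign, or a reinforcing cycle)
#' appears across assignments.
#'
#' @param design Lag design covering all persons.
#' @param assignments A [multiverse_grid()] result (or list of
#'   assignments), at least two.
#' @param groups The two groups compared in each assignment.
#' @param tier Network estimator per assignment (`"fast"` default: the
#'   stability summary needs many refits).
#' @param alpha Edge significance level.
#' @param spec Model spec for full-tier fits.
#' @return A `multiverse_report`: `features` tibble (`feature`,
#'   `n_present`, `n_assignments`, `stability`), `per_assignment` summary,
#'   and indices of flagged (skipped) assignments.
#' @export
multiverse_report <- function(design, assignments,
                              groups = c("Stable", "Increase"),
                              tier = "fast", alpha = 0.05,
                              spec = lagged_model_spec()) {
  if (length(assignments) < 2) abort("need at least two assignments")
  res <- purrr::imap(assignments, function(ga, i) {
    d <- apply_assignment(design, ga)
    sizes <- table(factor(d$group, levels = groups))
    counts <- vapply(groups, function(g) {
      length(unique(d$person_id[d$group == g]))
    }, numeric(1))
    if (any(sizes == 0) || any(counts < 2)) {
      return(list(ok = FALSE, feats = character(),
                  label = attr(ga, "provenance") %||% as.character(i)))
    }
    feats <- unlist(lapply(groups, function(g) {
      net <- estimate_group_network(d, g, spec, tier = tier)
      network_features(net, g, alpha)
    }))
    list(ok = TRUE, feats = feats,
         label = attr(ga, "provenance") %||% as.character(i))
  })
  ok <- vapply(res, `[[`, logical(1), "ok")
  if (!any(ok)) abort("no assignment could be analysed")
  all_feats <- sort(unique(unlist(lapply(res[ok], `[[`, "feats"))))
  n_ok <- sum(ok)
  features <- purrr::map_dfr(all_feats, function(f) {
    pres <- vapply(res[ok], function(r) f %in% r$feats, logical(1))
    tibble(feature = f, n_present = sum(pres), n_assignments = n_ok,
           stability = mean(pres))
  })
  per_assignment <- purrr::map_dfr(res, function(r) {
    tibble(assignment = r$label, analysed = r$ok,
           n_features = length(r$feats))
  })
  structure(list(features = features, per_assignment = per_assignment,
                 flagged = which(!ok), alpha = alpha, tier = tier),
            class = "multiverse_report")
}

#' @export
print.multiverse_report <- function(x, ...) {
  cat(sprintf("<multiverse_report> %d assignments analysed, %d flagged\n",
              sum(x$per_assignment$analysed), length(x$flagged)))
  print(x$features, n = 20)
  invisible(x)
}

#' @method tidy multiverse_report
#' @export
tidy.multiverse_report <- function(x, ...) x$features
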