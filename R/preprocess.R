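# Preprocessing: participant inclusion, person-mean centering, same-day
# lag pairing, and item-level diagnostics.

#' Exclude participants with too many missing beeps
#'
#' A beep counts as observed only when all six affect items are present
#' (complete-case convention). A person is kept iff
#' `missing / scheduled <= max_missing_fraction`; strictly more is
#' excluded, so with 60 scheduled beeps 18 missing (30%) is kept and 19
#' is excluded.
#'
#' @param panel Beep-level ESM panel tibble.
#' @param max_missing_fraction Inclusion threshold (default 0.30).
#' @param scheduled_beeps Number of scheduled beeps per person; default is
#'   the maximum `beep_number` observed in the panel.
#' @return The panel restricted to included persons. The per-person
#'   exclusion report is attached as an attribute and retrieved with
#'   [exclusion_report()].
#' @examples
#' coh <- simulate_cohort(sim_config("Stable", n_families = 4), seed = 1)
#' kept <- filter_by_missingness(coh$panel)
#' exclusion_report(kept)
#' @export
filter_by_missingness <- function(panel, max_missing_fraction = 0.30,
                                  scheduled_beeps = NULL) {
  stop_if_missing_cols(panel, c("person_id", "beep_number", affect_nodes()),
                       "panel")
  if (is.null(scheduled_beeps)) scheduled_beeps <- max(panel$beep_number)
  if (scheduled_beeps <= 0) abort("scheduled_beeps must be positive")
  rep_tbl <- panel %>%
    mutate(.complete = complete_obs(panel)) %>%
    group_by(.data$person_id) %>%
    summarise(n_complete = sum(.data$.complete), .groups = "drop") %>%
    mutate(
      n_scheduled = .env$scheduled_beeps,
      n_missing = .data$n_scheduled - .data$n_complete,
      missing_fraction = .data$n_missing / .data$n_scheduled,
      zero_observations = .data$n_complete == 0,
      included = .data$n_missing <= .env$max_missing_fraction *
        .env$scheduled_beeps + 1e-9
    )
  keep <- rep_tbl$person_id[rep_tbl$included]
  out <- panel[panel$person_id %in% keep, , drop = FALSE]
  attr(out, "exclusion_report") <- rep_tbl
  out
}

#' @rdname filter_by_missingness
#' @param x A panel returned by [filter_by_missingness()].
#' @export
exclusion_report <- function(x) {
  rep_tbl <- attr(x, "exclusion_report")
  if (is.null(rep_tbl)) abort("no exclusion report attached to this object")
  rep_tbl
}

#' Person-mean center the affect items
#'
#' Subtracts each person's own mean (computed over that person's complete
#' observations) from their item scores, isolating within-person
#' fluctuations. Centered values are added as `<item>_c` columns; the raw
#' columns are kept.
#'
#' @param panel Beep-level ESM panel tibble.
#' @return The panel with six `<item>_c` columns added; the per-person
#'   means are attached and retrieved with [person_means()].
#' @export
person_mean_center <- function(panel) {
  stop_if_missing_cols(panel, c("person_id", affect_nodes()), "panel")
  if (nrow(panel) == 0) abort("panel is empty")
  cmp <- complete_obs(panel)
  means <- panel[cmp, c("person_id", affect_nodes())] %>%
    group_by(.data$person_id) %>%
    summarise(across(all_of(affect_nodes()), mean),
              n_complete = dplyr::n(), .groups = "drop")
  m <- means[match(panel$person_id, means$person_id), affect_nodes()]
  for (v in affect_nodes()) {
    panel[[paste0(v, "_c")]] <- panel[[v]] - m[[v]]
  }
  attr(panel, "person_means") <- means
  panel
}

#' @rdname person_mean_center
#' @param x A panel returned by [person_mean_center()].
#' @export
person_means <- function(x) {
  pm <- attr(x, "person_means")
  if (is.null(pm)) abort("no person means attached; run person_mean_center()")
  pm
}

#' Build the lagged design from a centered panel
#'
#' Pairs each complete observation at beep `t` with the complete
#' observation at beep `t-1` of the same person, requiring consecutive
#' beep numbers *within the same day*: lags over the night are excluded.
#' The outcome columns `y_<item>` hold the raw ratings at `t`; the
#' predictor columns `lag_<item>` hold the person-mean-centered ratings at
#' `t-1`. The time covariate is the beep number over the whole period
#' (`time_beep`), with a rescaled copy `time_scaled = time_beep /
#' scheduled_beeps` used internally for numerical conditioning.
#'
#' @param panel A centered panel from [person_mean_center()].
#' @param scheduled_beeps Total scheduled beeps (default: max beep number).
#' @return A `lag_design` tibble with one row per usable consecutive pair.
#' @examples
#' coh <- simulate_cohort(sim_config("Stable", n_families = 4), seed = 1)
#' design <- coh$panel |> person_mean_center() |> build_lag_pairs()
#' names(design)
#' @export
build_lag_pairs <- function(panel, scheduled_beeps = NULL) {
  nodes <- affect_nodes()
  ctr_cols <- paste0(nodes, "_c")
  stop_if_missing_cols(panel, c("person_id", "day", "beep_number", nodes),
                       "panel")
  if (!all(ctr_cols %in% names(panel))) {
    abort("panel has no centered columns; run person_mean_center() first")
  }
  if (is.null(scheduled_beeps)) scheduled_beeps <- max(panel$beep_number)
  panel <- panel %>%
    mutate(.complete = complete_obs(panel)) %>%
    arrange(.data$person_id, .data$beep_number)
  prev <- panel %>%
    group_by(.data$person_id) %>%
    mutate(across(all_of(c(ctr_cols, "beep_number", "day", ".complete")),
                  dplyr::lag, .names = "{.col}_prev")) %>%
    ungroup()
  ok <- prev$.complete & !is.na(prev$.complete_prev) & prev$.complete_prev &
    prev$beep_number - prev$beep_number_prev == 1L &
    prev$day == prev$day_prev
  rows <- prev[which(ok), , drop = FALSE]
  out <- tibble(
    person_id = rows$person_id,
    day = rows$day,
    beep_number = rows$beep_number,
    time_beep = rows$beep_number,
    time_scaled = rows$beep_number / scheduled_beeps
  )
  if ("family_id" %in% names(rows)) {
    out <- dplyr::bind_cols(tibble(family_id = rows$family_id), out)
    out <- out[, c("person_id", "family_id", setdiff(names(out),
                                                     c("person_id",
                                                       "family_id")))]
  }
  if ("group" %in% names(rows)) out$group <- rows$group
  if ("time_min" %in% names(rows)) {
    out$time_min <- rows$time_min
    out$time_hr <- rows$time_min / 60
  }
  for (v in nodes) out[[paste0("y_", v)]] <- rows[[v]]
  for (v in nodes) out[[paste0("lag_", v)]] <- rows[[paste0(v, "_c_prev")]]
  attr(out, "scheduled_beeps") <- scheduled_beeps
  class(out) <- c("lag_design", class(out))
  out
}

#' Internal consistency of an item set (Cronbach's alpha)
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(sum score))`.
#'
#' @param items A data frame or matrix of item responses (rows =
#'   respondents, columns = items), no missing values.
#' @return A single numeric value in `(-Inf, 1]`.
#' @examples
#' x <- matrix(rnorm(100), 50, 2); x[, 2] <- x[, 1]
#' cronbach_alpha(x)  # 1
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2 || nrow(m) < 2) abort("need >= 2 items and >= 2 respondents")
  if (anyNA(m)) abort("cronbach_alpha requires complete responses")
  total_var <- var(rowSums(m))
  if (total_var <= 0) abort("zero variance of the sum score; alpha undefined")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

# Pooled within-person SD: sqrt of within-person sums of squares over
# summed within-person degrees of freedom.
pooled_within_sd <- function(values, person) {
  df <- tibble(v = values, p = person)
  df <- df[!is.na(df$v), ]
  agg <- df %>%
    group_by(.data$p) %>%
    summarise(ss = sum((.data$v - mean(.data$v))^2), n = dplyr::n(),
              .groups = "drop") %>%
    filter(.data$n >= 2)
  sqrt(sum(agg$ss) / sum(agg$n - 1))
}

#' Item-level inclusion diagnostics
#'
#' Replicates the item selection checks applied to candidate ESM items:
#' pooled within-person SD per item (target band around 1.0), pairwise
#' within-person correlations (computed on person-mean-centered values
#' pooled over persons; flag at `|r| >= 0.5`), between-group tests of item
#' mean levels (Welch t-test on person means), and the max/min ratio of
#' group within-person SDs (flag above `sd_ratio_max`).
#'
#' @param panel Beep-level ESM panel.
#' @param group_assignment A [group_assignment][assign_groups] object or a
#'   tibble with `person_id` and `group`; at least two groups, each with
#'   at least two persons.
#' @param sd_band Acceptable band for the pooled within-person SD.
#' @param r_max Correlation flag threshold (default 0.5).
#' @param sd_ratio_max Maximum acceptable max/min SD ratio (default 1.12,
#'   i.e. 12%).
#' @param mean_alpha Significance level for the group mean-difference flag.
#' @return An `item_diagnostics` object: list of tibbles `items`,
#'   `correlations`, plus settings. `tidy()` returns the per-item table.
#' @export
item_diagnostics <- function(panel, group_assignment,
                             sd_band = c(0.7, 1.4), r_max = 0.5,
                             sd_ratio_max = 1.12, mean_alpha = 0.05) {
  ga <- as_tibble(group_assignment)
  stop_if_missing_cols(ga, c("person_id", "group"), "group_assignment")
  if ("included" %in% names(ga)) ga <- ga[ga$included, ]
  groups <- sort(unique(ga$group))
  if (length(groups) < 2) abort("need at least two groups")
  sizes <- table(ga$group)
  if (any(sizes < 2)) {
    abort(sprintf("group '%s' has fewer than 2 persons",
                  names(sizes)[which.min(sizes)]))
  }
  panel <- panel[panel$person_id %in% ga$person_id, , drop = FALSE]
  panel$group <- ga$group[match(panel$person_id, ga$person_id)]
  cpanel <- person_mean_center(panel)
  cmp <- complete_obs(cpanel)
  nodes <- affect_nodes()

  items <- purrr::map_dfr(nodes, function(v) {
    vals <- cpanel[[v]]
    pooled <- pooled_within_sd(vals, cpanel$person_id)
    by_group <- vapply(groups, function(g) {
      sel <- cpanel$group == g
      pooled_within_sd(vals[sel], cpanel$person_id[sel])
    }, numeric(1))
    pm <- cpanel[cmp, c("person_id", "group", v)] %>%
      group_by(.data$person_id, .data$group) %>%
      summarise(m = mean(.data[[v]]), .groups = "drop")
    tt <- t.test(pm$m[pm$group == groups[1]], pm$m[pm$group == groups[2]])
    tibble(item = v,
           pooled_within_sd = pooled,
           sd_ratio = max(by_group) / min(by_group),
           mean_diff = unname(tt$estimate[1] - tt$estimate[2]),
           mean_p = tt$p.value,
           sd_in_band = pooled >= sd_band[1] & pooled <= sd_band[2],
           sd_ratio_ok = max(by_group) / min(by_group) <= sd_ratio_max,
           mean_ok = tt$p.value > mean_alpha)
  })

  pairs <- utils::combn(nodes, 2)
  ctr <- as.matrix(cpanel[cmp, paste0(nodes, "_c")])
  colnames(ctr) <- nodes
  correlations <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    r <- cor(ctr[, a], ctr[, b])
    tibble(item_a = a, item_b = b, r = r, r_ok = abs(r) < r_max)
  })

  structure(list(items = items, correlations = correlations,
                 groups = groups,
                 settings = list(sd_band = sd_band, r_max = r_max,
                                 sd_ratio_max = sd_ratio_max,
                                 mean_alpha = mean_alpha)),
            class = "item_diagnostics")
}

#' @export
print.item_diagnostics <- function(x, ...) {
  cat(sprintf("<item_diagnostics> groups: %s\n",
              paste(x$groups, collapse = " vs ")))
  print(x$items, n = Inf)
  invisible(x)
}

#' @method tidy item_diagnostics
#' @export
tidy.item_diagnostics <- function(x, ...) x$items
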