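# Group composition: symptom change scores, childhood-experience
# screening, tertile split, and multiverse variants of the grouping rule.

#' One-year symptom change score
#'
#' Adds `scl_change = scl_t1 - scl_t0` to a per-person metadata table.
#' Persons missing either score get `NA` (they are flagged as
#' `ExcludedMissing` by [assign_groups()]).
#'
#' @param meta Metadata tibble with `scl_t0` and `scl_t1` (sum scores in
#'   `[90, 450]`).
#' @return `meta` with an `scl_change` column.
#' @examples
#' change_score(tibble::tibble(scl_t0 = 126, scl_t1 = 131))$scl_change
#' @export
change_score <- function(meta) {
  stop_if_missing_cols(meta, c("scl_t0", "scl_t1"), "meta")
  ok <- !is.na(meta$scl_t0) & !is.na(meta$scl_t1)
  bad <- ok & (meta$scl_t0 < 90 | meta$scl_t0 > 450 |
                 meta$scl_t1 < 90 | meta$scl_t1 > 450)
  if (any(bad)) abort("SCL-90 sum scores must lie in [90, 450]")
  meta$scl_change <- meta$scl_t1 - meta$scl_t0
  meta
}

#' Median split on childhood-experience scores
#'
#' Retains persons scoring *below* the cohort median of the JTV sum
#' (low happy-childhood experiences = at-risk half). Under the default
#' strict rule, persons at or above the median are excluded; `rule =
#' "weak"` keeps at-median scores.
#'
#' @param meta Metadata tibble with `jtv_sum`.
#' @param rule `"strict"` (below the median) or `"weak"` (at or below).
#' @return `meta` with a logical `jtv_included` column; the median used is
#'   attached as attribute `jtv_median`.
#' @examples
#' m <- tibble::tibble(jtv_sum = c(10, 12, 14, 16))
#' median_split_jtv(m)$jtv_included
#' @export
median_split_jtv <- function(meta, rule = c("strict", "weak")) {
  rule <- match.arg(rule)
  stop_if_missing_cols(meta, "jtv_sum", "meta")
  if (nrow(meta) < 2) abort("need at least two persons for a median split")
  med <- median(meta$jtv_sum, na.rm = TRUE)
  inc <- if (rule == "strict") meta$jtv_sum < med else meta$jtv_sum <= med
  inc[is.na(inc)] <- FALSE
  if (!any(inc)) {
    abort(paste0("median split retains nobody (all scores equal the ",
                 "median?); consider rule = 'weak' or check jtv_sum"))
  }
  meta$jtv_included <- inc
  attr(meta, "jtv_median") <- med
  meta
}

# Rank-based quantile assignment: persons are stably sorted on
# (change, person_id) and cut into groups at ranks round(n * p). Ties
# straddling a boundary are therefore split deterministically by id.
rank_assignment <- function(person_id, change, probs) {
  n <- length(change)
  ord <- order(change, person_id, method = "radix")
  b1 <- round(n * probs[1])
  b2 <- round(n * probs[2])
  lab <- character(n)
  lab[ord[seq_len(n) <= b1]] <- "Decrease"
  lab[ord[seq_len(n) > b1 & seq_len(n) <= b2]] <- "Stable"
  lab[ord[seq_len(n) > b2]] <- "Increase"
  lab
}

new_group_assignment <- function(tbl, cutoffs, provenance, extra = list()) {
  attr(tbl, "cutoffs") <- cutoffs
  attr(tbl, "provenance") <- provenance
  for (nm in names(extra)) attr(tbl, nm) <- extra[[nm]]
  class(tbl) <- c("group_assignment", class(tbl))
  tbl
}

#' @export
print.group_assignment <- function(x, ...) {
  co <- attr(x, "cutoffs")
  cat(sprintf("<group_assignment> (%s; cutoffs %.1f / %.1f)\n",
              attr(x, "provenance"), co[1], co[2]))
  print(table(x$group, dnn = NULL))
  invisible(x)
}

#' Split change scores into tertiles
#'
#' Orders persons by `(scl_change, person_id)` (stable sort) and cuts the
#' ranking into near-equal thirds: lowest third -> `Decrease`, middle ->
#' `Stable`, highest -> `Increase`. Group sizes differ by at most one
#' before ties; ties straddling a boundary are split by person id. The
#' empirical 1/3 and 2/3 quantiles (type 7) of the change score are
#' reported as the cutoffs used.
#'
#' @param meta Metadata tibble with `person_id` and `scl_change` (or
#'   `scl_t0`/`scl_t1`, from which the change is computed); at least three
#'   persons.
#' @return A `group_assignment` tibble (`person_id`, `group`, `included`)
#'   with attributes `cutoffs` and `provenance = "tertile"`.
#' @examples
#' m <- tibble::tibble(person_id = letters[1:3],
#'                     scl_change = c(-40, -5, 25))
#' tertile_split(m)$group
#' @export
tertile_split <- function(meta) {
  meta <- ensure_change(meta)
  ok <- !is.na(meta$scl_change)
  if (sum(ok) < 3) abort("need at least three persons with change scores")
  d <- meta[ok, ]
  lab <- rank_assignment(d$person_id, d$scl_change, c(1 / 3, 2 / 3))
  cutoffs <- unname(quantile(d$scl_change, c(1 / 3, 2 / 3), type = 7))
  tbl <- tibble(person_id = d$person_id, group = lab, included = TRUE)
  if (any(!ok)) {
    tbl <- bind_rows(tbl, tibble(person_id = meta$person_id[!ok],
                                 group = "ExcludedMissing",
                                 included = FALSE))
  }
  new_group_assignment(tbl, cutoffs, "tertile")
}

ensure_change <- function(meta) {
  if (!"scl_change" %in% names(meta)) meta <- change_score(meta)
  stop_if_missing_cols(meta, "person_id", "meta")
  meta
}

#' Compose analysis groups from symptom change and childhood screening
#'
#' The full grouping pipeline: (1) persons without both SCL-90 scores are
#' flagged `ExcludedMissing`; (2) the JTV median split flags the
#' happy-childhood half `ExcludedHighJTV`; (3) the remaining persons'
#' change scores are split into tertiles (`Decrease` / `Stable` /
#' `Increase`); (4) with `drop_decrease = TRUE` (default) the Decrease
#' tertile is marked not included, mirroring its exclusion for baseline
#' non-comparability. A baseline-comparability report (pairwise Welch
#' t-tests of `scl_t0` between tertile groups) is attached and retrieved
#' with [comparability_report()].
#'
#' @param meta Metadata tibble with `person_id`, `scl_t0`, `scl_t1`,
#'   `jtv_sum`.
#' @param drop_decrease Flag the Decrease tertile as excluded (default
#'   `TRUE`).
#' @param jtv_rule Median-split rule, see [median_split_jtv()]. Use
#'   `jtv_rule = "none"` when the cohort is already screened.
#' @param comparability_alpha Significance level used to flag baseline
#'   differences.
#' @return A `group_assignment` tibble (`person_id`, `group`, `included`)
#'   with attributes `cutoffs`, `provenance`, `jtv_median` and
#'   `comparability`.
#' @export
assign_groups <- function(meta, drop_decrease = TRUE,
                          jtv_rule = c("strict", "weak", "none"),
                          comparability_alpha = 0.05) {
  jtv_rule <- match.arg(jtv_rule)
  meta <- ensure_change(meta)
  jtv_median <- NA_real_
  if (jtv_rule != "none" && "jtv_sum" %in% names(meta)) {
    meta <- median_split_jtv(meta, jtv_rule)
    jtv_median <- attr(meta, "jtv_median")
  } else {
    meta$jtv_included <- TRUE
  }
  miss <- is.na(meta$scl_change)
  eligible <- meta[meta$jtv_included & !miss, ]
  if (nrow(eligible) < 3) abort("fewer than three eligible persons")
  ts <- tertile_split(eligible)
  tbl <- tibble(person_id = meta$person_id) %>%
    left_join(as_tibble(ts)[, c("person_id", "group")], by = "person_id") %>%
    mutate(group = case_when(
      !meta$jtv_included ~ "ExcludedHighJTV",
      miss ~ "ExcludedMissing",
      TRUE ~ .data$group
    ))
  tbl$included <- tbl$group %in% c("Stable", "Increase",
                                   if (!drop_decrease) "Decrease")
  retained <- unique(tbl$group[tbl$included])
  if (length(retained) < 2) abort("fewer than two retained groups")
  # baseline comparability: pairwise Welch tests of scl_t0 across tertiles
  t0 <- meta$scl_t0[match(tbl$person_id, meta$person_id)]
  grp <- tbl$group
  pairs <- utils::combn(intersect(c("Decrease", "Stable", "Increase"),
                                  unique(grp)), 2)
  comparability <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- t.test(t0[grp == a], t0[grp == b])
    tibble(group_a = a, group_b = b,
           mean_a = unname(tt$estimate[1]), mean_b = unname(tt$estimate[2]),
           diff = unname(tt$estimate[2] - tt$estimate[1]),
           p_value = tt$p.value,
           flagged = tt$p.value < comparability_alpha)
  })
  new_group_assignment(tbl, attr(ts, "cutoffs"), "tertile",
                       extra = list(jtv_median = jtv_median,
                                    comparability = comparability))
}

#' @rdname assign_groups
#' @param x A `group_assignment` from [assign_groups()].
#' @export
comparability_report <- function(x) {
  cr <- attr(x, "comparability")
  if (is.null(cr)) abort("no comparability report attached")
  cr
}

#' Enumerate multiverse variants of the grouping rule
#'
#' Builds one group assignment per cutoff specification so downstream
#' network estimation can be mapped over defensible grouping choices.
#' A specification is either `list(quantiles = c(l, u))` (percent or
#' proportion ranks; assigned by the same stable ranking as
#' [tertile_split()]) or `list(cutoffs = c(l, u))` (absolute change-score
#' cutpoints; ties at a cutpoint go to the lower group:
#' `change <= l` -> Decrease, `l < change <= u` -> Stable, else Increase).
#'
#' @param meta Metadata tibble with `person_id` and change scores.
#' @param specs List of specifications; default grid
#'   `{(25,75), (30,70), (33.3,66.7), (40,60)}` percent quantile pairs.
#' @param drop_decrease Flag Decrease as excluded in every assignment.
#' @return A list of `group_assignment` objects (class
#'   `multiverse_assignments`). Assignments with an empty group carry a
#'   `flags` attribute naming the empty group(s).
#' @examples
#' m <- tibble::tibble(person_id = sprintf("p%02d", 1:30),
#'                     scl_change = -15:14)
#' mv <- multiverse_grid(m)
#' length(mv)
#' @export
multiverse_grid <- function(meta,
                            specs = list(list(quantiles = c(25, 75)),
                                         list(quantiles = c(30, 70)),
                                         list(quantiles = c(33.3, 66.7)),
                                         list(quantiles = c(40, 60))),
                            drop_decrease = TRUE) {
  meta <- ensure_change(meta)
  ok <- !is.na(meta$scl_change)
  d <- meta[ok, ]
  out <- purrr::map(specs, function(sp) {
    if (!is.null(sp$quantiles)) {
      pr <- sp$quantiles
      if (any(pr > 1)) pr <- pr / 100
      if (pr[1] > pr[2]) abort("lower cutoff must not exceed upper cutoff")
      lab <- rank_assignment(d$person_id, d$scl_change, pr)
      cutoffs <- unname(quantile(d$scl_change, pr, type = 7))
      prov <- sprintf("quantiles %.1f/%.1f", 100 * pr[1], 100 * pr[2])
    } else if (!is.null(sp$cutoffs)) {
      co <- sp$cutoffs
      if (co[1] > co[2]) abort("lower cutoff must not exceed upper cutoff")
      lab <- ifelse(d$scl_change <= co[1], "Decrease",
                    ifelse(d$scl_change <= co[2], "Stable", "Increase"))
      cutoffs <- co
      prov <- sprintf("cutoffs %.1f/%.1f", co[1], co[2])
    } else {
      abort("each spec needs either $quantiles or $cutoffs")
    }
    tbl <- tibble(person_id = d$person_id, group = lab,
                  included = lab %in% c("Stable", "Increase",
                                        if (!drop_decrease) "Decrease"))
    ga <- new_group_assignment(tbl, cutoffs, prov)
    empty <- setdiff(c("Decrease", "Stable", "Increase"), unique(lab))
    if (length(empty) > 0) {
      attr(ga, "flags") <- sprintf("empty group: %s",
                                   paste(empty, collapse = ", "))
      warn(sprintf("multiverse spec '%s' leaves %s empty", prov,
                   paste(empty, collapse = ", ")))
    }
    ga
  })
  structure(out, class = "multiverse_assignments")
}
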