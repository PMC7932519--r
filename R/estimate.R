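# Multilevel lagged regression models and group network assembly.
#
# One model per affect state: the raw outcome at beep t regressed on all
# six person-mean-centered states at t-1 plus a time covariate, with a
# family-level random intercept, person-level random intercept and random
# slopes (diagonal covariance), and continuous-time AR(1) residuals.
# Fitted by maximum likelihood with nlme; a convergence ladder walks down
# to simpler structures when a fit fails.

#' Specification of the lagged multilevel model
#'
#' @param alpha Significance level used when filtering networks.
#' @param ar1 Model residuals as continuous-time AR(1) (default `TRUE`);
#'   uses clock time (`time_hr`) when available, observation order
#'   otherwise.
#' @param random_slopes Person-level random slopes for the six lagged
#'   states and time (diagonal covariance).
#' @param family_intercept Family-level random intercept.
#' @param method Likelihood: `"ML"` (default, keeps AIC comparable across
#'   rungs with equal fixed effects) or `"REML"`.
#' @param scale_time Rescale the beep-number time covariate by the
#'   scheduled beep count for conditioning; coefficients are reported back
#'   per beep either way.
#' @param aic_compare When the full model converges, also fit the next
#'   ladder rung and report whichever has the lower AIC.
#' @param max_iter Optimizer iteration cap.
#' @return A `lagged_model_spec` list.
#' @export
lagged_model_spec <- function(alpha = 0.05, ar1 = TRUE, random_slopes = TRUE,
                              family_intercept = TRUE, method = "ML",
                              scale_time = TRUE, aic_compare = FALSE,
                              max_iter = 100) {
  structure(list(alpha = alpha, ar1 = ar1, random_slopes = random_slopes,
                 family_intercept = family_intercept, method = method,
                 scale_time = scale_time, aic_compare = aic_compare,
                 max_iter = max_iter),
            class = "lagged_model_spec")
}

lag_cols <- function() paste0("lag_", affect_nodes())

# Model frame with stable short names; errors on degenerate columns.
prepare_fit_frame <- function(design, outcome, spec) {
  nodes <- affect_nodes()
  if (!outcome %in% nodes) {
    abort(sprintf("unknown outcome '%s'", outcome))
  }
  need <- c("person_id", paste0("y_", outcome), lag_cols(), "time_beep")
  stop_if_missing_cols(design, need, "lag design")
  df <- data.frame(
    person_id = factor(design$person_id),
    family_id = factor(if ("family_id" %in% names(design))
      design$family_id else design$person_id),
    y = design[[paste0("y_", outcome)]],
    design[, lag_cols(), drop = FALSE],
    time_s = if (spec$scale_time) design$time_scaled else design$time_beep,
    check.names = FALSE
  )
  if ("time_hr" %in% names(design)) df$time_hr <- design$time_hr
  if (anyNA(df)) abort("lag design contains missing values")
  for (v in lag_cols()) {
    if (sd(df[[v]]) == 0) {
      abort(sprintf("singular design: predictor '%s' is constant", v))
    }
    if (isTRUE(all.equal(df[[v]], df$y))) {
      abort(sprintf(
        "singular design: predictor '%s' duplicates the outcome at time t", v))
    }
  }
  X <- as.matrix(cbind(1, df[, lag_cols()], df$time_s))
  if (nrow(df) <= ncol(X) + 2) abort("fewer rows than model parameters")
  if (qr(X)$rank < ncol(X)) {
    abort("singular design: predictors are collinear")
  }
  df
}

fixed_formula <- function() {
  stats::as.formula(paste("y ~", paste(lag_cols(), collapse = " + "),
                          "+ time_s"))
}

ranef_formula <- function() {
  stats::as.formula(paste("~", paste(lag_cols(), collapse = " + "),
                          "+ time_s"))
}

cor_struct <- function(df, with_family) {
  grp <- if (with_family) "family_id/person_id" else "person_id"
  if ("time_hr" %in% names(df)) {
    nlme::corCAR1(form = stats::as.formula(paste("~ time_hr |", grp)))
  } else {
    nlme::corAR1(form = stats::as.formula(paste("~ 1 |", grp)))
  }
}

# One ladder rung. Throws on failure so the caller can descend.
fit_rung <- function(df, rung, spec) {
  ctrl <- nlme::lmeControl(maxIter = spec$max_iter,
                           msMaxIter = spec$max_iter,
                           opt = "optim", returnObject = FALSE)
  if (rung == "pooled") {
    fit <- lm(fixed_formula(), data = df)
    return(fit)
  }
  random <- switch(rung,
    full = ,
    no_ar1 = {
      r <- list(person_id = nlme::pdDiag(ranef_formula()))
      if (spec$family_intercept)
        r <- c(list(family_id = nlme::pdIdent(~1)), r)
      r
    },
    intercepts = {
      r <- list(person_id = ~1)
      if (spec$family_intercept)
        r <- c(list(family_id = ~1), r)
      r
    },
    person_intercept = list(person_id = ~1))
  correlation <- if (rung == "full") {
    cor_struct(df, with_family = spec$family_intercept)
  } else NULL
  nlme::lme(fixed_formula(), random = random, correlation = correlation,
            data = df, method = spec$method, control = ctrl)
}

ladder_rungs <- function(spec) {
  rungs <- c(if (spec$ar1 && spec$random_slopes) "full",
             if (spec$random_slopes) "no_ar1",
             "intercepts",
             if (spec$family_intercept) "person_intercept",
             "pooled")
  unique(rungs)
}

extract_coefs <- function(fit, df, scale_factor) {
  if (inherits(fit, "lme")) {
    est <- nlme::fixef(fit)
    se <- sqrt(diag(fit$varFix))
  } else {
    est <- coef(fit)
    vc <- sandwich::vcovCL(fit, cluster = df$person_id)
    se <- sqrt(diag(vc))
  }
  tb <- tibble(term = names(est), estimate = unname(est), se = unname(se))
  # report the time slope per beep, not per scaled unit
  idx <- tb$term == "time_s"
  tb$estimate[idx] <- tb$estimate[idx] / scale_factor
  tb$se[idx] <- tb$se[idx] / scale_factor
  tb$term[idx] <- "time"
  tb$term[tb$term == "(Intercept)"] <- "intercept"
  tb$term <- sub("^lag_", "", tb$term)
  tb$statistic <- tb$estimate / tb$se
  tb$p_value <- 2 * pnorm(-abs(tb$statistic))
  tb
}

#' Fit one multilevel lagged regression
#'
#' Fits `y_t ~ lagged states + time` for a single outcome node on (a
#' group subset of) a lag design, walking a convergence ladder of
#' progressively simpler structures when the maximum-likelihood fit
#' fails: full model (AR(1) residuals + random slopes) -> no AR(1) ->
#' intercepts only -> person intercept only -> pooled regression with
#' person-cluster robust standard errors. Fixed-effect p-values use a
#' normal reference for estimate/SE.
#'
#' @param design A [build_lag_pairs()] design (optionally filtered to one
#'   group).
#' @param outcome Outcome node name, one of [affect_nodes()].
#' @param spec A [lagged_model_spec()].
#' @return A `lagged_fit` object; `tidy()` gives the coefficient table,
#'   `glance()` the fit summary (log-likelihood, AIC, AR(1) phi, rung).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(sim_config("Stable", n_families = 10), seed = 1)
#' design <- coh$panel |> person_mean_center() |> build_lag_pairs()
#' fit <- fit_lagged_model(design, "cheerful")
#' tidy(fit)
#' }
#' @export
fit_lagged_model <- function(design, outcome,
                             spec = lagged_model_spec()) {
  df <- prepare_fit_frame(design, outcome, spec)
  if (nlevels(df$person_id) < 2) abort("need at least two persons")
  if (nlevels(df$family_id) < 2 && spec$family_intercept) {
    abort("need at least two families (or set family_intercept = FALSE)")
  }
  scale_factor <- if (spec$scale_time) {
    sb <- attr(design, "scheduled_beeps")
    if (is.null(sb)) sb <- max(design$time_beep)
    sb
  } else 1
  rungs <- ladder_rungs(spec)
  fit <- NULL; used <- NULL; errors <- character()
  for (rung in rungs) {
    fit <- tryCatch(fit_rung(df, rung, spec), error = function(e) e)
    if (!inherits(fit, "error")) { used <- rung; break }
    errors <- c(errors, sprintf("%s: %s", rung, conditionMessage(fit)))
  }
  if (inherits(fit, "error") || is.null(used)) {
    abort(paste0("all ladder rungs failed for outcome '", outcome, "':\n",
                 paste(errors, collapse = "\n")))
  }
  if (length(errors) > 0) {
    warn(sprintf("outcome '%s': fell back to rung '%s'", outcome, used))
  }
  # best-AIC rule between the full structure and the next rung
  if (identical(used, "full") && spec$aic_compare) {
    alt <- tryCatch(fit_rung(df, "no_ar1", spec), error = function(e) NULL)
    if (!is.null(alt) && AIC(alt) < AIC(fit)) { fit <- alt; used <- "no_ar1" }
  }
  phi <- NA_real_
  if (inherits(fit, "lme") && !is.null(fit$modelStruct$corStruct)) {
    phi <- unname(coef(fit$modelStruct$corStruct, unconstrained = FALSE)[1])
  }
  res <- if (inherits(fit, "lme")) {
    stats::resid(fit, type = "normalized")
  } else stats::rstandard(fit)
  res_s <- if (length(res) > 3000) sample(res, 3000) else res
  shap <- tryCatch(shapiro.test(res_s), error = function(e) NULL)
  varcomp <- if (inherits(fit, "lme")) {
    tryCatch(nlme::VarCorr(fit), error = function(e) NULL)
  } else NULL
  structure(list(
    outcome = outcome,
    coefficients = extract_coefs(fit, df, scale_factor),
    rung = used,
    phi = phi,
    sigma = stats::sigma(fit),
    logLik = as.numeric(logLik(fit)),
    aic = AIC(fit),
    n_rows = nrow(df),
    n_persons = nlevels(df$person_id),
    n_families = nlevels(df$family_id),
    varcomp = varcomp,
    residual_normality = if (is.null(shap)) NULL else
      list(statistic = unname(shap$statistic), p_value = shap$p.value),
    spec = spec,
    model = fit
  ), class = "lagged_fit")
}

#' @export
print.lagged_fit <- function(x, ...) {
  cat(sprintf("<lagged_fit> outcome '%s' (rung %s, n=%d rows, %d persons)\n",
              x$outcome, x$rung, x$n_rows, x$n_persons))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @method tidy lagged_fit
#' @export
tidy.lagged_fit <- function(x, ...) {
  dplyr::bind_cols(tibble(outcome = x$outcome), x$coefficients)
}

#' @method glance lagged_fit
#' @export
glance.lagged_fit <- function(x, ...) {
  tibble(outcome = x$outcome, rung = x$rung, logLik = x$logLik,
         AIC = x$aic, sigma = x$sigma, phi = x$phi, n_rows = x$n_rows,
         n_persons = x$n_persons,
         resid_normality_p = if (is.null(x$residual_normality)) NA_real_
           else x$residual_normality$p_value)
}

new_affect_network <- function(W, se, p, group, tier, n_persons, n_rows,
                               extra = list()) {
  nodes <- affect_nodes()
  dimnames(W) <- dimnames(se) <- dimnames(p) <- list(nodes, nodes)
  structure(c(list(W = W, se = se, p = p, nodes = nodes,
                   valence = affect_valence(), group = group, tier = tier,
                   n_persons = n_persons, n_rows = n_rows,
                   filtered = FALSE, alpha = NA_real_), extra),
            class = "affect_network")
}

#' Estimate the directed affect network of one group
#'
#' Runs the lagged model for each of the six outcomes and assembles the
#' 6x6 weight matrix `W` with `W[j, k]` = fixed effect of node `k` at
#' t-1 on node `j` at t (diagonal = autoregressions), alongside matching
#' SE and p-value matrices.
#'
#' `tier = "full"` uses the multilevel ladder ([fit_lagged_model()]).
#' `tier = "fast"` uses the two-stage estimator (per-person ordinary
#' lagged regressions averaged across persons, SEs from the
#' between-person spread), the estimator used inside permutation tests.
#'
#' @param design A lag design; must contain a `group` column when `group`
#'   is given.
#' @param group Group label to restrict to (`NULL` = use all rows).
#' @param spec A [lagged_model_spec()].
#' @param tier `"full"` or `"fast"`.
#' @return An `affect_network` object; `tidy()` gives the edge list,
#'   `glance()` a one-row summary with the headline metrics.
#' @export
estimate_group_network <- function(design, group = NULL,
                                   spec = lagged_model_spec(),
                                   tier = c("full", "fast")) {
  tier <- match.arg(tier)
  if (!is.null(group)) {
    stop_if_missing_cols(design, "group", "lag design")
    sb <- attr(design, "scheduled_beeps")
    design <- design[design$group == group, , drop = FALSE]
    attr(design, "scheduled_beeps") <- sb
    if (nrow(design) == 0) abort(sprintf("group '%s' is empty", group))
  }
  if (tier == "fast") {
    net <- estimate_network_fast(design, group = NULL)
    net$group <- group %||% "all"
    return(net)
  }
  nodes <- affect_nodes()
  fits <- lapply(nodes, function(v) {
    tryCatch(fit_lagged_model(design, v, spec),
             error = function(e) {
               abort(sprintf("network estimation failed for outcome '%s': %s",
                             v, conditionMessage(e)))
             })
  })
  names(fits) <- nodes
  W <- se <- p <- matrix(NA_real_, 6, 6)
  for (j in seq_along(nodes)) {
    cf <- fits[[j]]$coefficients
    idx <- match(nodes, cf$term)
    W[j, ] <- cf$estimate[idx]
    se[j, ] <- cf$se[idx]
    p[j, ] <- cf$p_value[idx]
  }
  side <- purrr::map_dfr(fits, glance)
  time_effects <- purrr::map_dfr(fits, function(f) {
    cf <- f$coefficients[f$coefficients$term == "time", ]
    tibble(outcome = f$outcome, estimate = cf$estimate, se = cf$se,
           p_value = cf$p_value)
  })
  new_affect_network(W, se, p, group = group %||% "all", tier = "full",
                     n_persons = fits[[1]]$n_persons, n_rows = nrow(design),
                     extra = list(fits_summary = side,
                                  time_effects = time_effects))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage 1 of the fast tier: per-person OLS of all six outcomes on the six
# lagged states + time, one QR per person. Persons with too few rows or a
# rank-deficient design are dropped.
person_coef_array <- function(design, min_rows = 12) {
  nodes <- affect_nodes()
  persons <- unique(design$person_id)
  keep <- character(); mats <- list(); fam <- character(); nrows <- integer()
  for (pid in persons) {
    d <- design[design$person_id == pid, , drop = FALSE]
    if (nrow(d) < min_rows) next
    tvar <- if ("time_scaled" %in% names(d)) d$time_scaled else d$time_beep
    X <- as.matrix(cbind(1, d[, lag_cols()], tvar))
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) next
    Y <- as.matrix(d[, paste0("y_", nodes)])
    cf <- qr.coef(qr_x, Y)             # 8 x 6 (predictors x outcomes)
    Bp <- t(cf[2:7, , drop = FALSE])   # 6x6: rows outcome, cols lagged state
    keep <- c(keep, pid)
    mats[[length(mats) + 1]] <- Bp
    fam <- c(fam, if ("family_id" %in% names(d)) d$family_id[1] else pid)
    nrows <- c(nrows, nrow(d))
  }
  if (length(keep) == 0) abort("no person has enough rows for the fast tier")
  arr <- array(unlist(mats), dim = c(6, 6, length(keep)))
  # persons x 36 layout so stage 2 reduces to column sums
  flat <- t(matrix(arr, 36, length(keep)))
  list(persons = keep, family = setNames(fam, keep), coef = arr,
       flat = flat, n_rows = setNames(nrows, keep))
}

# Stage 2: average person coefficient matrices; SE from between-person SD.
fast_network_from_array <- function(pca, idx, group) {
  n <- length(idx)
  m <- colMeans(pca$flat[idx, , drop = FALSE])
  ss <- colSums(pca$flat[idx, , drop = FALSE]^2)
  W <- matrix(m, 6, 6)
  se <- matrix(sqrt(pmax(ss - n * m^2, 0) / (n - 1)) / sqrt(n), 6, 6)
  p <- 2 * pt(-abs(W / se), df = n - 1)
  new_affect_network(W, se, p, group = group, tier = "fast",
                     n_persons = n, n_rows = sum(pca$n_rows[idx]))
}

estimate_network_fast <- function(design, group = NULL, min_rows = 12) {
  if (!is.null(group)) {
    design <- design[design$group == group, , drop = FALSE]
    if (nrow(design) == 0) abort(sprintf("group '%s' is empty", group))
  }
  pca <- person_coef_array(design, min_rows = min_rows)
  if (length(pca$persons) < 2) {
    abort("fast tier needs at least two usable persons")
  }
  fast_network_from_array(pca, seq_along(pca$persons), group %||% "all")
}

#' Keep only significant network paths
#'
#' Zeroes every edge whose p-value is at or above `alpha`; the unfiltered
#' weights stay available in `$W_unfiltered`.
#'
#' @param network An `affect_network`.
#' @param alpha Significance level (default 0.05; edges survive iff
#'   `p < alpha`).
#' @return The filtered `affect_network`.
#' @export
significant_subnetwork <- function(network, alpha = 0.05) {
  stopifnot(inherits(network, "affect_network"))
  if (all(is.na(network$p))) abort("network has no p-values")
  if (isTRUE(network$filtered)) return(network)
  out <- network
  out$W_unfiltered <- network$W
  out$W <- ifelse(network$p < alpha, network$W, 0)
  out$filtered <- TRUE
  out$alpha <- alpha
  out
}

#' @export
print.affect_network <- function(x, ...) {
  cat(sprintf("<affect_network> group=%s tier=%s (%d persons, %d rows)%s\n",
              x$group, x$tier, x$n_persons, x$n_rows,
              if (isTRUE(x$filtered))
                sprintf(" [filtered at p<%.2f]", x$alpha) else ""))
  print(round(x$W, 3))
  invisible(x)
}

#' @method tidy affect_network
#' @export
tidy.affect_network <- function(x, alpha = x$alpha, ...) {
  if (is.na(alpha)) alpha <- 0.05
  W <- if (isTRUE(x$filtered)) x$W_unfiltered else x$W
  grid <- expand.grid(to = x$nodes, from = x$nodes,
                      stringsAsFactors = FALSE)[, c("from", "to")]
  tibble(
    from = grid$from, to = grid$to,
    b = W[cbind(grid$to, grid$from)],
    se = x$se[cbind(grid$to, grid$from)],
    p_value = x$p[cbind(grid$to, grid$from)],
    significant = x$p[cbind(grid$to, grid$from)] < alpha
  ) %>% arrange(.data$from, .data$to)
}

#' @method glance affect_network
#' @export
glance.affect_network <- function(x, ...) {
  tibble(group = x$group, tier = x$tier, n_persons = x$n_persons,
         n_rows = x$n_rows,
         negative_connectivity = negative_connectivity(x),
         pa_to_na = cross_valence_effect(x, "positive", "negative"),
         na_to_pa = cross_valence_effect(x, "negative", "positive"))
}

#' Export a network as an edge list or DOT graph
#'
#' `write_network_edges()` writes `from,to,b,se,p,significant` CSV.
#' `network_to_dot()` renders a DOT digraph (solid edges for positive
#' weights, dashed for negative) for graphviz-compatible tools.
#'
#' @param network An `affect_network`.
#' @param path Output file (`network_to_dot()` returns the string when
#'   `path` is `NULL`).
#' @param alpha Significance level used for the `significant` column.
#' @return The network, invisibly (writer); DOT source (character).
#' @export
write_network_edges <- function(network, path, alpha = 0.05) {
  readr::write_csv(tidy(network, alpha = alpha), path)
  invisible(network)
}

#' @rdname write_network_edges
#' @export
network_to_dot <- function(network, path = NULL, alpha = 0.05) {
  edges <- tidy(network, alpha = alpha)
  edges <- edges[edges$b != 0, ]
  lines <- c(
    sprintf("digraph \"%s\" {", network$group),
    "  rankdir=LR;",
    sprintf("  \"%s\" [shape=circle];", network$nodes),
    sprintf("  \"%s\" -> \"%s\" [label=\"%.2f\", style=%s%s];",
            edges$from, edges$to, edges$b,
            ifelse(edges$b > 0, "solid", "dashed"),
            ifelse(edges$significant, ", penwidth=2", "")),
    "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
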