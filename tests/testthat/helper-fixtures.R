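# Shared fixtures, all built in code.

nodes6 <- affect_nodes()

# A fully observed hand-made panel: `values` is a T x 6 matrix (one row
# per beep); days of length `beeps_per_day`.
make_panel <- function(values, person_id = "p1", family_id = "f1",
                       beeps_per_day = 10, group = NULL) {
  values <- as.matrix(values)
  colnames(values) <- nodes6
  nb <- nrow(values)
  out <- tibble::tibble(
    person_id = person_id,
    family_id = family_id,
    day = (seq_len(nb) - 1) %/% beeps_per_day + 1L,
    beep_in_day = (seq_len(nb) - 1) %% beeps_per_day + 1L,
    beep_number = seq_len(nb),
    time_min = (seq_len(nb) - 1) * 90
  )
  if (!is.null(group)) out$group <- group
  dplyr::bind_cols(out, tibble::as_tibble(values))
}

# Random integer Likert panel for several persons.
random_panel <- function(n_persons = 4, n_beeps = 20, beeps_per_day = 10,
                         seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_persons), function(i) {
      vals <- matrix(sample(1:7, n_beeps * 6, replace = TRUE), n_beeps, 6)
      make_panel(vals, person_id = sprintf("p%02d", i),
                 family_id = sprintf("f%02d", (i + 1) %/% 2),
                 beeps_per_day = beeps_per_day)
    })
  })
}

# Small two-group cohort design for comparison tests.
small_two_group_design <- function(n_fam = 8, seed = 1,
                                   stable_b = NULL, increase_b = NULL) {
  cfgs <- list(
    sim_config("Stable", n_families = n_fam, transition = stable_b),
    sim_config("Increase", n_families = n_fam, transition = increase_b))
  coh <- simulate_cohort(cfgs, seed = seed)
  coh$panel |>
    person_mean_center() |>
    build_lag_pairs()
}

# Random weight/p matrices for metric oracle tests.
random_network_matrix <- function(seed = NULL, p_too = FALSE) {
  gen <- function() {
    W <- matrix(round(rnorm(36, 0, 0.3), 3), 6, 6,
                dimnames = list(nodes6, nodes6))
    W[sample(36, 10)] <- 0
    if (!p_too) return(W)
    p <- matrix(runif(36), 6, 6, dimnames = list(nodes6, nodes6))
    list(W = W, p = p)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Wrap a bare weight matrix (optionally with p-values) as a network.
matrix_network <- function(W, p = NULL, group = "test") {
  se <- matrix(0.01, 6, 6)
  if (is.null(p)) p <- matrix(0, 6, 6)
  affectnet:::new_affect_network(W, se, p, group = group, tier = "fast",
                                 n_persons = 10L, n_rows = 100L)
}
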