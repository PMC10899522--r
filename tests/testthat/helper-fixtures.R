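# Shared fixtures, built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

# Small, well-identified M4 cohort plus a reduced-settings fit, reused by
# the hba, inference and selection tests.
demo_fit <- function() {
  if (is.null(fixture_env$fit)) {
    spec <- cohort_spec(
      12, "sim",
      alpha_mu = c(-0.2, -0.2, 2, 2), alpha_sigma = rep(0.5, 4),
      beta_mu = rep(2.5, 4), beta_sigma = rep(0.5, 4),
      lambda_meanlog = log(0.3), lambda_sdlog = 0.5
    )
    sim <- simulate_cohort(spec, "M4", seed = 101)
    fit <- suppressWarnings(
      fit_hba(sim$data, "M4", config = mcmc_config(2, 600, 400, seed = 5))
    )
    fixture_env$spec <- spec
    fixture_env$sim <- sim
    fixture_env$fit <- fit
  }
  list(spec = fixture_env$spec, sim = fixture_env$sim,
       fit = fixture_env$fit)
}

# Classical mixed-ANOVA oracle via aov()'s error-stratum decomposition
# (only valid as a cross-check for equal group sizes, where Type I and
# Type III coincide).
oracle_anova <- function(summaries, response) {
  df <- summaries
  df$y <- df[[response]]
  df$participant_id <- factor(df$participant_id)
  df$group <- factor(df$group)
  df$role <- factor(df$role)
  df$frame <- factor(df$frame)
  av <- stats::aov(
    y ~ group * role * frame + Error(participant_id / (role * frame)),
    data = df)
  out <- list()
  for (stratum in summary(av)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] != "Residuals") {
        out[[terms[i]]] <- tab[i, "F value"]
      }
    }
  }
  out
}

# Map implementation effect names onto the oracle's term labels.
oracle_name <- function(effect) {
  map <- c("Group" = "group", "Role" = "role", "Frame" = "frame",
           "Role:Group" = "group:role", "Frame:Group" = "group:frame",
           "Role:Frame" = "role:frame", "Role:Frame:Group" = "group:role:frame")
  unname(map[effect])
}

# Random balanced deviation-summary table for ANOVA property tests.
random_summaries <- function(n_per_group, seed) {
  with_seed(seed, {
    grid <- expand.grid(role = c("first", "third"),
                        frame = c("gain", "loss"),
                        stringsAsFactors = FALSE)
    rows <- list()
    for (g in c("g1", "g2")) {
      for (s in seq_len(n_per_group)) {
        id <- sprintf("%s_%02d", g, s)
        base <- stats::rnorm(1, 0.5, 0.15)
        for (r in seq_len(nrow(grid))) {
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = id, group = g,
            role = grid$role[r], frame = grid$frame[r],
            selfish = base + stats::rnorm(1, 0, 0.1),
            equal = stats::runif(1))
        }
      }
    }
    do.call(rbind, rows)
  })
}

with_seed <- fairdg:::with_seed
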