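test_that("split R-hat separates converged from disjoint chains", {
  expect_error(rhat(matrix(1:10, ncol = 1)), "2 chains")
  expect_error(rhat(matrix(1:6, ncol = 2)), "4 draws")
  # constant chains: degenerate, flagged as NA
  expect_warning(r <- rhat(matrix(1, 100, 2)), "degenerate|constant")
  expect_true(is.na(r))
  # same stationary normal: converged
  m <- with_seed(1, matrix(stats::rnorm(2e4), 1e4, 2))
  expect_lt(rhat(m), 1.01)
  # means 5 sds apart: far from converged
  m2 <- with_seed(2, cbind(stats::rnorm(1e3), stats::rnorm(1e3, 5)))
  expect_gt(rhat(m2), 1.5)
})

test_that("shortest-window HDI matches an exhaustive search and edge cases", {
  x <- with_seed(3, stats::rnorm(1e4))
  h <- hdi(x, 0.95)
  expect_equal(h, c(-1.96, 1.96), tolerance = 0.08)
  # exhaustive oracle over every contiguous window of the sorted sample
  for (mass in c(0.5, 0.85, 0.95)) {
    s <- sort(with_seed(4, stats::rt(500, df = 3)))
    m <- ceiling(mass * length(s))
    best <- c(Inf, NA, NA)
    for (st in seq_len(length(s) - m + 1L)) {
      w <- s[st + m - 1L] - s[st]
      if (w < best[1]) best <- c(w, s[st], s[st + m - 1L])
    }
    expect_identical(hdi(s, mass), best[2:3])
  }
  expect_equal(hdi(rep(3.3, 100), 0.95), c(3.3, 3.3))
  expect_equal(hdi(x, 1), range(x))
  expect_error(hdi(numeric(0)), "empty")
})

test_that("the default MCMC configuration retains 6000 draws", {
  cfg <- mcmc_config()
  expect_equal(cfg$chains, 3L)
  expect_equal(cfg$warmup, 2000L)
  expect_equal(cfg$sampling, 2000L)
  expect_equal(cfg$chains * cfg$sampling, 6000L)
  expect_error(mcmc_config(chains = 0), "positive")
})

test_that("hierarchical fits return complete, well-shaped posteriors", {
  fx <- demo_fit()
  fit <- fx$fit
  n <- length(fit$participants)
  expect_equal(nrow(fit$draws), fit$config$chains * fit$config$sampling)
  expect_equal(dim(fit$pointwise_ll), c(nrow(fit$draws), nrow(fx$sim$data)))
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(is.finite(fit$pointwise_ll)))
  expect_equal(length(fit$rhat), ncol(fit$draws))
  # lambda draws respect the log link
  expect_true(all(fit$draws[, sprintf("lambda[%d]", seq_len(n))] > 0))
  # population sds are positive
  expect_true(all(fit$draws[, sprintf("sigma_alpha[%d]", 1:4)] > 0))
  s <- posterior_summary(fit, "mu_alpha[3]")
  expect_true(s$hdi[1] <= s$mean && s$mean <= s$hdi[2])
  expect_error(posterior_summary(fit, "nope"), "unknown parameter")
})

test_that("individual posterior means recover the generating parameters", {
  fx <- demo_fit()
  cm <- colMeans(fx$fit$draws)
  true <- fx$sim$truth[fx$sim$truth$parameter == "alpha", ]
  est <- vapply(seq_len(nrow(true)), function(r) {
    i <- match(true$participant_id[r], fx$fit$participants)
    cm[[sprintf("alpha[%d,%d]", i, true$k[r])]]
  }, numeric(1))
  expect_gt(stats::cor(true$value, est), 0.7)
})

test_that("individual estimates shrink from no pooling toward the group mean", {
  fx <- demo_fit()
  fit <- fx$fit
  cm <- colMeans(fit$draws)
  lab <- condition_labels(3)
  ok <- 0L
  checked <- seq_len(min(6L, length(fit$participants)))
  for (i in checked) {
    sub <- fit$data[fit$data$participant_id == fit$participants[i] &
                      fit$data$role == lab$role &
                      fit$data$frame == lab$frame, ]
    lam <- cm[[sprintf("lambda[%d]", i)]]
    nll <- function(th) {
      p <- param_set(lam, alpha = rep(th[1], 4), beta = rep(th[2], 4))
      -log_likelihood("M4", p, sub)
    }
    mle <- stats::optim(c(2, 2.5), nll)$par[1]
    post <- cm[[sprintf("alpha[%d,3]", i)]]
    grp <- cm[["mu_alpha[3]"]]
    if (abs(post - grp) <= abs(mle - grp) + 0.05) ok <- ok + 1L
  }
  expect_gte(ok / length(checked), 0.7)
})

test_that("posterior summaries are stable under participant reordering", {
  spec <- cohort_spec(6, "g", alpha_mu = c(0, 0, 1.5, 1.5),
                      alpha_sigma = rep(0.4, 4),
                      beta_mu = rep(1.5, 4), beta_sigma = rep(0.4, 4))
  sim <- simulate_cohort(spec, "M4", seed = 33)
  cfg <- mcmc_config(2, 400, 300, seed = 12)
  f1 <- suppressWarnings(fit_hba(sim$data, "M4", config = cfg))
  perm <- with_seed(1, sample(unique(sim$data$participant_id)))
  data2 <- do.call(rbind, lapply(perm, function(id)
    sim$data[sim$data$participant_id == id, ]))
  f2 <- suppressWarnings(fit_hba(data2, "M4", config = cfg))
  for (k in 1:4) {
    p <- sprintf("mu_alpha[%d]", k)
    expect_equal(mean(f1$draws[, p]), mean(f2$draws[, p]), tolerance = 0.35)
  }
})

test_that("fits reject multi-group data and missing conditions", {
  sim <- simulate_study(cohort_spec_children(2), cohort_spec_adults(2),
                        seed = 3)
  expect_error(fit_hba(sim$data, "M4",
                       config = mcmc_config(2, 10, 10)), "single group")
  one <- sim$data[sim$data$group == "children", ]
  nogain <- one[!(one$frame == "gain" & one$role == "first"), ]
  expect_error(fit_hba(nogain, "M4", config = mcmc_config(2, 10, 10)),
               "condition")
})
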