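test_that("schedules implement the counterbalanced block design", {
  sch <- make_schedule(1, token_pool = 12L, seed = 7)
  expect_equal(nrow(sch), 80L)
  expect_true(all(sch$total_tokens == 12L))
  expect_equal(as.vector(table(sch$block)), rep(20L, 4))
  # one condition per block, all four conditions present
  expect_equal(sort(unique(sch$k)), 1:4)
  expect_true(all(tapply(sch$k, sch$block, function(x) length(unique(x))) == 1))
  # each ratio appears 4x per block, hence 16x overall
  key <- paste(sch$r_self, sch$r_other)
  expect_equal(as.vector(table(key)), rep(16L, 5))
  for (b in 1:4) {
    expect_equal(as.vector(table(key[sch$block == b])), rep(4L, 5))
  }
})

test_that("condition orders follow the cycled Latin square", {
  sch <- make_schedule(4, seed = 3)
  orders <- sapply(1:4, function(i) {
    s <- sch[sch$participant_index == i, ]
    paste(s$k[!duplicated(s$block)], collapse = "")
  })
  expect_equal(length(unique(orders)), 4L)
  # every condition appears in every block position across the 4 rows
  mat <- do.call(rbind, strsplit(orders, ""))
  for (j in 1:4) expect_setequal(mat[, j], as.character(1:4))
  # cycling: participant 5 repeats row 1
  sch5 <- make_schedule(5, seed = 3)
  expect_equal(sch5$k[sch5$participant_index == 5][1],
               sch$k[sch$participant_index == 1][1])
})

test_that("schedules and cohorts are deterministic given the seed", {
  expect_identical(make_schedule(3, seed = 11), make_schedule(3, seed = 11))
  spec <- cohort_spec_children(n_participants = 3)
  a <- simulate_cohort(spec, "M4", seed = 9)
  b <- simulate_cohort(spec, "M4", seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
})

test_that("simulated agents reproduce the analytic choice limits", {
  sch <- make_schedule(1, token_pool = 12L, seed = 2)
  # selfish utility maximizer: keep all in gain, nothing in loss
  selfish <- param_set(1e3, alpha = rep(0, 4), beta = rep(0, 4))
  sim <- simulate_participant(selfish, "M4", sch, seed = 4)
  kf <- kept_fraction(sim$tokens_kept, sim$total_tokens)
  expect_true(all(kf[sim$frame == "gain"] == 1))
  expect_true(all(kf[sim$frame == "loss"] == 0))
  # strong inequity aversion with near-deterministic choice: equal split
  averse <- param_set(1e3, alpha = rep(5, 4), beta = rep(5, 4))
  sim2 <- simulate_participant(averse, "M4", sch, seed = 4)
  expect_equal(kept_fraction(sim2$tokens_kept, sim2$total_tokens),
               equal_fraction(sim2$r_self, sim2$r_other))
})

test_that("lambda = 0 agents choose uniformly over the option set", {
  sch <- do.call(rbind, replicate(10, make_schedule(1, 12L, seed = 8),
                                  simplify = FALSE))
  sch$round <- seq_len(nrow(sch))  # keep (block, round) keys distinct
  unif <- param_set(0, alpha = rep(2, 4), beta = rep(2, 4))
  sim <- simulate_participant(unif, "M4", sch, seed = 21)
  kf <- kept_fraction(sim$tokens_kept, sim$total_tokens)
  # uniform over 13 options: mean kept fraction 0.5, sd of mean known
  expect_equal(mean(kf), 0.5, tolerance = 4 * 0.3 / sqrt(nrow(sch)))
  counts <- tabulate(sim$tokens_kept + 1L, 13L)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("cohorts degenerate to the population mean as sigma -> 0", {
  spec <- cohort_spec(3, "g", alpha_mu = c(0, 0, 1, 1),
                      alpha_sigma = rep(1e-12, 4),
                      beta_mu = rep(1, 4), beta_sigma = rep(1e-12, 4),
                      lambda_sdlog = 0)
  sim <- simulate_cohort(spec, "M4", seed = 5)
  for (p in sim$params) {
    expect_equal(p$alpha, spec$alpha_mu, tolerance = 1e-6)
    expect_equal(p$beta, spec$beta_mu, tolerance = 1e-6)
    expect_equal(p$lambda, exp(spec$lambda_meanlog), tolerance = 1e-9)
  }
})

test_that("generated datasets satisfy every dataset invariant", {
  sim <- simulate_cohort(cohort_spec_adults(n_participants = 4), seed = 13)
  expect_silent(validate_dataset(sim$data))
  expect_true(all(sim$data$tokens_kept >= 0 &
                    sim$data$tokens_kept <= sim$data$total_tokens))
  key <- with(sim$data, paste(participant_id, block, round))
  expect_false(any(duplicated(key)))
  # ground truth covers every participant, weight and condition
  expect_equal(nrow(sim$truth), 4L * (4L + 4L + 1L))
})

test_that("M5 cohorts draw constrained weights via the log link", {
  spec <- cohort_spec(5, "g", alpha_mu = c(0, 0, 1, 1),
                      alpha_sigma = rep(0.3, 4),
                      beta_mu = rep(0.5, 4), beta_sigma = rep(0.3, 4))
  sim <- simulate_cohort(spec, "M5", seed = 3)
  for (p in sim$params) {
    expect_true(all(p$alpha > 0))
    expect_true(all(p$beta > 0))
  }
})
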