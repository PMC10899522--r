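# Minimal fit-shaped object with specified group-level mean draws, for
# contrast-convention tests that need no MCMC.
fake_fit <- function(group, mu_alpha, n_draws = 1200L) {
  draws <- matrix(rep(mu_alpha, each = n_draws), n_draws, 4L,
                  dimnames = list(NULL, sprintf("mu_alpha[%d]", 1:4)))
  structure(list(model = "M4", group = group, draws = draws),
            class = "dg_fit")
}

test_that("evidence categories implement the HDI decision rule", {
  up <- with_seed(1, stats::rnorm(2000, 3, 0.5))
  ev <- evidence_category(up)
  expect_equal(ev$category, "meaningful")
  expect_equal(ev$direction, "above")
  null <- with_seed(2, stats::rnorm(2000, 0, 1))
  expect_equal(evidence_category(null)$category, "none")
  expect_warning(evidence_category(stats::rnorm(100)), "1000 draws")
  expect_error(evidence_category(numeric(0)), "empty")
})

test_that("a 93%-positive mixture yields limited evidence", {
  draws <- with_seed(3, c(stats::rnorm(9300, 2, 0.05),
                          stats::rnorm(700, -2, 0.05)))
  ev <- evidence_category(draws)
  # 97.5% HDI must reach into the negative cluster; 85% HDI must not
  expect_lt(ev$hdi975[1], 0)
  expect_gt(ev$hdi85[1], 0)
  expect_equal(ev$category, "limited")
})

test_that("evidence is monotone under upward shifts of the draws", {
  rank_of <- c(none = 0, limited = 1, meaningful = 2)
  draws <- with_seed(4, stats::rnorm(4000, 0.8, 1))
  base <- rank_of[evidence_category(draws)$category]
  for (shift in c(0.5, 1, 3)) {
    shifted <- rank_of[evidence_category(draws + shift)$category]
    expect_gte(shifted, base)
    base <- shifted
  }
})

test_that("summed-over-frames contrasts reproduce the condition-mean sums", {
  # condition means k = (first/gain, first/loss, third/gain, third/loss)
  children <- fake_fit("children", c(-0.190, -0.241, 3.268, 3.348))
  adults <- fake_fit("adults", c(1.361, 1.478, 1.992, 2.077))
  expect_equal(mean(condition_contrast(children, "alpha", "role")$draws),
               -7.047, tolerance = 0.01)
  expect_equal(mean(condition_contrast(adults, "alpha", "role")$draws),
               -1.230, tolerance = 0.01)
  g1 <- group_contrast(children, adults, "alpha", "first")
  expect_equal(mean(g1$draws), -3.270, tolerance = 0.01)
  g3 <- group_contrast(children, adults, "alpha", "third")
  expect_equal(mean(g3$draws), 2.547, tolerance = 0.01)
  # frame contrast convention: (gain sum) - (loss sum)
  expect_equal(mean(condition_contrast(children, "alpha", "frame")$draws),
               (-0.190 + 3.268) - (-0.241 + 3.348), tolerance = 1e-10)
})

test_that("identical condition posteriors give a null contrast", {
  f <- fake_fit("g", rep(0, 4))
  f$draws <- f$draws + with_seed(5, stats::rnorm(length(f$draws), 0, 0.3))
  cc <- condition_contrast(f, "alpha", "role")
  expect_lt(abs(mean(cc$draws)), 0.1)
  expect_equal(cc$evidence$category, "none")
  # a fit differenced with itself (independent shuffles) centers on zero
  gc <- group_contrast(f, f, "alpha", "first", seed = 2)
  expect_lt(abs(mean(gc$draws)), 0.1)
})

test_that("posterior prediction is reproducible and matches the design", {
  fx <- demo_fit()
  rep1 <- posterior_predict(fx$fit, mode = "means", seed = 9)
  rep2 <- posterior_predict(fx$fit, mode = "means", seed = 9)
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1), nrow(fx$sim$data))
  expect_silent(validate_dataset(rep1))
  reps <- posterior_predict(fx$fit, mode = "draws", n_rep = 2, seed = 4)
  expect_length(reps, 2L)
  expect_false(identical(reps[[1]]$tokens_kept, reps[[2]]$tokens_kept))
})

test_that("the PPC round trip reproduces behavior within each condition", {
  fx <- demo_fit()
  rep1 <- posterior_predict(fx$fit, mode = "means", seed = 9)
  res <- ppc_correlations(fx$sim$data, rep1)
  expect_equal(nrow(res$by_participant), 4L)
  expect_true(all(res$by_participant$r >= 0.8))
  expect_true(all(!res$by_participant$undefined))
  # identical data: perfect correlation everywhere
  self_res <- ppc_correlations(fx$sim$data, fx$sim$data)
  expect_true(all(abs(self_res$by_participant$r - 1) < 1e-12))
  expect_true(all(abs(self_res$by_trial$r - 1) < 1e-12))
})

test_that("participant-permuted replicates destroy the across-participant match", {
  fx <- demo_fit()
  ids <- unique(fx$sim$data$participant_id)
  perm <- with_seed(6, setNames(sample(ids), ids))
  shuffled <- fx$sim$data
  shuffled$participant_id <- unname(perm[shuffled$participant_id])
  res <- ppc_correlations(fx$sim$data, shuffled)
  expect_lt(mean(abs(res$by_participant$r)), 0.6)
})

test_that("zero-variance cells are flagged as undefined correlations", {
  base <- expand.grid(participant_id = c("a", "b", "c"), round = 1:4,
                      stringsAsFactors = FALSE)
  base$group <- "g"; base$role <- "first"; base$frame <- "gain"
  base$block <- 1L; base$r_self <- 1L; base$r_other <- 1L
  base$total_tokens <- 4L; base$tokens_kept <- 2L
  res <- ppc_correlations(base, base)
  expect_true(all(res$by_participant$undefined))
  expect_true(all(is.na(res$by_participant$r)))
})
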