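# Trial schedules and generative agents emulating the 2 (Role) x 2 (Frame)
# within x 2 (Group) between design: 4 blocks (one per condition) x 20
# rounds, five exchange ratios 4x per block, block order from a balanced
# 4x4 Latin square cycled over participants.

latin_square_4 <- function() {
  # Williams design: each condition once per row/column, carryover balanced
  rbind(c(1L, 2L, 3L, 4L),
        c(2L, 4L, 1L, 3L),
        c(3L, 1L, 4L, 2L),
        c(4L, 3L, 2L, 1L))
}

#' Build a counterbalanced trial schedule
#'
#' Per participant: 4 blocks of 20 rounds, one block per condition, each
#' of the five exchange ratios appearing 4 times per block in a shuffled
#' order, token budgets drawn uniformly from `token_pool`. Condition
#' order follows the Latin-square row assigned by participant index.
#' Deterministic given its arguments.
#'
#' @param n_participants Number of participants (>= 1).
#' @param token_pool Positive integer budgets to draw from. The default
#'   multiples of 12 make the payoff-equalizing split a whole number of
#'   tokens for all five design ratios.
#' @param seed Master seed.
#' @return Data frame with columns `participant_index`, `block`, `round`,
#'   `role`, `frame`, `k`, `r_self`, `r_other`, `total_tokens`.
#' @export
make_schedule <- function(n_participants, token_pool = c(12L, 24L, 36L, 48L),
                          seed = 1L) {
  if (length(token_pool) == 0L || any(token_pool <= 0) ||
      any(token_pool != as.integer(token_pool))) {
    stop("token_pool must be a nonempty set of positive integers",
         call. = FALSE)
  }
  if (n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  ls4 <- latin_square_4()
  ratios <- dg_ratios()
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    out[[i]] <- with_seed(sub_seed(seed, i), {
      korder <- ls4[((i - 1L) %% 4L) + 1L, ]
      blocks <- lapply(seq_len(4L), function(b) {
        k <- korder[b]
        lab <- condition_labels(k)
        ridx <- sample(rep(seq_len(5L), 4L))  # 5 ratios x 4 reps, shuffled
        data.frame(
          participant_index = i, block = b, round = seq_len(20L),
          role = lab$role, frame = lab$frame, k = k,
          r_self = ratios$r_self[ridx], r_other = ratios$r_other[ridx],
          total_tokens = as.integer(
            token_pool[sample.int(length(token_pool), 20L,
                                  replace = TRUE)])
        )
      })
      do.call(rbind, blocks)
    })
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Specification of a simulated cohort
#'
#' Population (group-level) means and standard deviations per condition
#' for the inequity weights, and a log-normal specification for the
#' softmax inverse temperature. Individual parameters are drawn on the
#' scale the hierarchical model samples on: identity scale for
#' unconstrained weights, log scale (then exponentiated) for lambda and
#' for M5's positivity-constrained weights.
#'
#' @param n_participants Cohort size.
#' @param group Group label, e.g. `"children"` or `"adults"`.
#' @param alpha_mu,beta_mu,omega_mu Length-4 condition-k means (NULL for
#'   parameters the target model does not use).
#' @param alpha_sigma,beta_sigma,omega_sigma Length-4 positive sds.
#' @param lambda_meanlog,lambda_sdlog Mean and sd of log(lambda).
#' @param token_pool Budget pool for [make_schedule()].
#' @param seed Default master seed used when [simulate_cohort()] is not
#'   given one.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, group,
                        alpha_mu = NULL, alpha_sigma = NULL,
                        beta_mu = NULL, beta_sigma = NULL,
                        omega_mu = NULL, omega_sigma = NULL,
                        lambda_meanlog = log(0.3), lambda_sdlog = 0.5,
                        token_pool = c(12L, 24L, 36L, 48L), seed = 1L) {
  if (n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  for (s in list(alpha_sigma, beta_sigma, omega_sigma)) {
    if (!is.null(s) && any(s <= 0)) {
      stop("population sds must be strictly positive", call. = FALSE)
    }
  }
  if (lambda_sdlog < 0) stop("lambda_sdlog must be >= 0", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants), group = group,
         alpha_mu = alpha_mu, alpha_sigma = alpha_sigma,
         beta_mu = beta_mu, beta_sigma = beta_sigma,
         omega_mu = omega_mu, omega_sigma = omega_sigma,
         lambda_meanlog = lambda_meanlog, lambda_sdlog = lambda_sdlog,
         token_pool = token_pool, seed = seed),
    class = "cohort_spec"
  )
}

#' Default child-like cohort: advantage-seeking (negative alpha) as
#' first-party, strong advantageous-inequity aversion as third-party.
#'
#' Condition order of the length-4 vectors is k = 1..4 (first/gain,
#' first/loss, third/gain, third/loss).
#' @param n_participants Cohort size (default 34).
#' @param ... Overrides passed to [cohort_spec()].
#' @export
cohort_spec_children <- function(n_participants = 34L, ...) {
  defaults <- list(
    n_participants = n_participants, group = "children",
    alpha_mu = c(-0.190, -0.241, 3.268, 3.348),
    alpha_sigma = rep(0.5, 4),
    beta_mu = c(3.919, 2.809, 2.525, 2.735),
    beta_sigma = rep(0.5, 4)
  )
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

#' Default adult-like cohort: advantageous-inequity aversion in every
#' condition.
#' @param n_participants Cohort size (default 31).
#' @param ... Overrides passed to [cohort_spec()].
#' @export
cohort_spec_adults <- function(n_participants = 31L, ...) {
  defaults <- list(
    n_participants = n_participants, group = "adults",
    alpha_mu = c(1.361, 1.478, 1.992, 2.077),
    alpha_sigma = rep(0.5, 4),
    beta_mu = c(2.489, 2.784, 2.353, 2.476),
    beta_sigma = rep(0.5, 4)
  )
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

#' Simulate one participant's choices on a schedule
#'
#' Samples each trial's allocation from the softmax choice probabilities
#' under the participant's condition-k parameters.
#'
#' @param params A `dg_params` (see [param_set()]).
#' @param model Model id.
#' @param schedule Schedule rows for one participant ([make_schedule()]
#'   columns).
#' @param seed RNG seed.
#' @return The schedule with a `tokens_kept` column appended.
#' @export
simulate_participant <- function(params, model, schedule, seed = 1L) {
  stopifnot(inherits(params, "dg_params"))
  spec <- model_spec(model)
  if (!is.finite(params$lambda) || params$lambda < 0) {
    stop("lambda must be finite and nonnegative", call. = FALSE)
  }
  with_seed(seed, {
    kept <- integer(nrow(schedule))
    for (t in seq_len(nrow(schedule))) {
      row <- schedule[t, ]
      tr <- dg_trial(row$role, row$frame, row$r_self, row$r_other,
                     row$total_tokens, row$block, row$round)
      pk <- params_for_k(params, tr$k)
      pr <- choice_probs(spec$id, tr, params$lambda,
                         alpha = pk$alpha, beta = pk$beta, omega = pk$omega)
      kept[t] <- sample.int(length(pr), 1L, prob = pr) - 1L
    }
    out <- schedule
    out$tokens_kept <- kept
    out
  })
}

draw_participant_params <- function(spec, model) {
  mspec <- model_spec(model)
  draw4 <- function(mu, sigma, transform) {
    if (is.null(mu) || is.null(sigma)) {
      stop("cohort_spec lacks population means/sds for a parameter of ",
           mspec$id, call. = FALSE)
    }
    raw <- stats::rnorm(4L, mu, sigma)
    if (transform) exp(raw) else raw
  }
  args <- list(
    lambda = exp(stats::rnorm(1L, spec$lambda_meanlog, spec$lambda_sdlog)),
    model = mspec$id
  )
  for (p in mspec$params) {
    args[[p]] <- draw4(spec[[paste0(p, "_mu")]],
                       spec[[paste0(p, "_sigma")]],
                       transform = mspec$constrained)
  }
  do.call(param_set, args)
}

#' Simulate a full cohort with ground-truth parameters
#'
#' Draws each participant's condition-k parameters from the population
#' normal distributions of `spec` (on the hierarchical model's sampling
#' scale), simulates every trial, and returns the flat choice dataset
#' together with the generating parameters.
#'
#' @param spec A [cohort_spec()].
#' @param model Generative model id (default `"M4"`).
#' @param schedule Optional pre-built schedule for `spec$n_participants`
#'   participants; built from `spec` when `NULL`.
#' @param seed Master seed (defaults to `spec$seed`).
#' @return List with `data` (choice dataset), `truth` (long data frame:
#'   `participant_id`, `parameter`, `k`, `value`) and `params` (named
#'   list of `dg_params`).
#' @export
simulate_cohort <- function(spec, model = "M4", schedule = NULL,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  mspec <- model_spec(model)
  n <- spec$n_participants
  if (is.null(schedule)) {
    schedule <- make_schedule(n, spec$token_pool, seed = sub_seed(seed, 0L))
  }
  ids <- sprintf("%s_%02d", spec$group, seq_len(n))
  params <- vector("list", n)
  names(params) <- ids
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    params[[i]] <- with_seed(sub_seed(seed, i, salt = 1L),
                             draw_participant_params(spec, mspec$id))
    sched_i <- schedule[schedule$participant_index == i, ]
    sim <- simulate_participant(params[[i]], mspec$id, sched_i,
                                seed = sub_seed(seed, i, salt = 2L))
    sim$participant_id <- ids[i]
    sim$group <- spec$group
    rows[[i]] <- sim[, c("participant_id", "group", "role", "frame",
                         "block", "round", "r_self", "r_other",
                         "total_tokens", "tokens_kept")]
    tlist <- lapply(mspec$params, function(p) {
      data.frame(participant_id = ids[i], parameter = p, k = 1:4,
                 value = params[[i]][[p]])
    })
    truth[[i]] <- rbind(
      do.call(rbind, tlist),
      data.frame(participant_id = ids[i], parameter = "lambda",
                 k = NA_integer_, value = params[[i]]$lambda)
    )
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  validate_dataset(data)
  list(data = data,
       truth = do.call(rbind, truth),
       params = params)
}

#' Simulate the full two-group study
#'
#' Children and adult cohorts under their default (or supplied) specs,
#' combined into one dataset.
#'
#' @param children,adults Cohort specs.
#' @param model Generative model id.
#' @param seed Master seed; group substreams are derived from it.
#' @return List with combined `data` and per-group `truth` tables.
#' @export
simulate_study <- function(children = cohort_spec_children(),
                           adults = cohort_spec_adults(),
                           model = "M4", seed = 1L) {
  ch <- simulate_cohort(children, model, seed = sub_seed(seed, 1L, 9L))
  ad <- simulate_cohort(adults, model, seed = sub_seed(seed, 2L, 9L))
  list(data = rbind(ch$data, ad$data),
       truth = list(children = ch$truth, adults = ad$truth),
       params = list(children = ch$params, adults = ad$params))
}
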