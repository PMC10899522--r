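# Posterior predictive checks, HDI evidence categories and the
# condition/group contrasts on group-level parameters.

#' Categorize the evidence that a posterior quantity differs from zero
#'
#' Decision rule: "meaningful" if the 97.5% HDI excludes 0; "limited" if
#' the 97.5% HDI contains 0 but the 85% HDI excludes it; "none"
#' otherwise. The report also carries the posterior mean and 95% HDI for
#' display.
#'
#' @param draws Numeric vector of posterior draws (>= 1000 recommended; a
#'   warning is issued below that).
#' @param label Optional quantity name carried into the report.
#' @return List of class `dg_evidence`: `label`, `mean`, `hdi95`,
#'   `hdi975`, `hdi85`, `category`, `direction`.
#' @export
evidence_category <- function(draws, label = "quantity") {
  if (length(draws) == 0L) stop("empty draws", call. = FALSE)
  if (length(draws) < 1000L) {
    warning("fewer than 1000 draws; evidence categories may be unstable",
            call. = FALSE)
  }
  h975 <- hdi(draws, 0.975)
  h85 <- hdi(draws, 0.85)
  excl <- function(h) h[1] > 0 || h[2] < 0
  category <- if (excl(h975)) "meaningful" else if (excl(h85)) "limited"
              else "none"
  structure(
    list(label = label, mean = mean(draws), hdi95 = hdi(draws, 0.95),
         hdi975 = h975, hdi85 = h85, category = category,
         direction = if (mean(draws) > 0) "above" else "below"),
    class = "dg_evidence"
  )
}

#' @export
print.dg_evidence <- function(x, ...) {
  cat(sprintf("%s: mean = %.3f, 95%% HDI: [%.3f, %.3f] -- %s evidence (%s 0)\n",
              x$label, x$mean, x$hdi95[1], x$hdi95[2], x$category,
              if (x$direction == "above") "above" else "below"))
  invisible(x)
}

mu_draws <- function(fit, parameter) {
  cols <- sprintf("mu_%s[%d]", parameter, 1:4)
  miss <- setdiff(cols, colnames(fit$draws))
  if (length(miss)) {
    stop("fit has no group-level draws for parameter '", parameter, "'",
         call. = FALSE)
  }
  fit$draws[, cols]
}

#' Role or frame contrast of a group-level parameter
#'
#' Draw-wise contrast of the condition-k group means, summing over the
#' collapsed factor: role contrast = (k1 + k2) - (k3 + k4) (first minus
#' third, summed over frames); frame contrast = (k1 + k3) - (k2 + k4)
#' (gain minus loss, summed over roles).
#'
#' @param fit A `dg_fit`.
#' @param parameter `"alpha"`, `"beta"` or `"omega"` (as available).
#' @param axis `"role"` or `"frame"`.
#' @return List with the contrast `draws` and an `evidence`
#'   ([evidence_category()]) report.
#' @export
condition_contrast <- function(fit, parameter = "alpha",
                               axis = c("role", "frame")) {
  axis <- match.arg(axis)
  m <- mu_draws(fit, parameter)
  d <- if (axis == "role") (m[, 1] + m[, 2]) - (m[, 3] + m[, 4])
       else (m[, 1] + m[, 3]) - (m[, 2] + m[, 4])
  lab <- sprintf("%s %s contrast (%s)", fit$group, axis, parameter)
  list(draws = d, evidence = evidence_category(d, lab))
}

#' Group contrast of a parameter within a role
#'
#' Sums the two frame conditions of the requested role within each
#' group's fit, then differences the two groups draw-wise after an
#' independent within-fit shuffle (fixed seed), which preserves each
#' marginal posterior while removing any chain-order artifacts.
#'
#' @param fit_a,fit_b Fits of the same model to the two groups; contrast
#'   is A minus B. Unequal draw counts are resampled to match (warning).
#' @param parameter `"alpha"`, `"beta"` or `"omega"`.
#' @param role `"first"` or `"third"`.
#' @param seed Shuffle seed.
#' @return List with contrast `draws` and an `evidence` report.
#' @export
group_contrast <- function(fit_a, fit_b, parameter = "alpha",
                           role = c("first", "third"), seed = 1L) {
  role <- match.arg(role)
  if (fit_a$model != fit_b$model) {
    stop("group contrasts require fits of the same model", call. = FALSE)
  }
  ks <- if (role == "first") 1:2 else 3:4
  a <- rowSums(mu_draws(fit_a, parameter)[, ks])
  b <- rowSums(mu_draws(fit_b, parameter)[, ks])
  n <- max(length(a), length(b))
  if (length(a) != length(b)) {
    warning("unequal draw counts; resampling to match", call. = FALSE)
  }
  d <- with_seed(seed, {
    ai <- sample.int(length(a), n, replace = length(a) < n)
    bi <- sample.int(length(b), n, replace = length(b) < n)
    a[ai] - b[bi]
  })
  lab <- sprintf("%s-%s %s contrast @ %s", fit_a$group, fit_b$group,
                 parameter, role)
  list(draws = d, evidence = evidence_category(d, lab))
}

#' Simulate replicate datasets from a fitted model
#'
#' `mode = "means"` simulates once from each participant's posterior-mean
#' parameters; `mode = "draws"` samples `n_rep` joint posterior draws and
#' simulates one replicate dataset from each.
#'
#' @param fit A `dg_fit`.
#' @param schedule Schedule for the fitted participants; defaults to the
#'   trial structure of the fitted dataset itself.
#' @param mode `"means"` or `"draws"`.
#' @param n_rep Number of replicates in draws mode.
#' @param seed RNG seed.
#' @return A simulated choice dataset (`mode = "means"`) or a list of
#'   them (`mode = "draws"`).
#' @export
posterior_predict <- function(fit, schedule = NULL,
                              mode = c("means", "draws"), n_rep = 1L,
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "dg_fit"))
  spec <- model_spec(fit$model)
  n <- length(fit$participants)
  if (is.null(schedule)) {
    schedule <- fit$data
    schedule$participant_index <- match(schedule$participant_id,
                                        fit$participants)
  }
  if (!all(sort(unique(schedule$participant_index)) == seq_len(n))) {
    stop("schedule does not cover the fitted participants", call. = FALSE)
  }
  sim_one <- function(param_list, rep_seed) {
    rows <- lapply(seq_len(n), function(i) {
      sched_i <- schedule[schedule$participant_index == i, ]
      sim <- simulate_participant(param_list[[i]], spec$id, sched_i,
                                  seed = sub_seed(rep_seed, i, salt = 3L))
      sim$participant_id <- fit$participants[i]
      sim$group <- fit$group
      sim[, c("participant_id", "group", "role", "frame", "block",
              "round", "r_self", "r_other", "total_tokens", "tokens_kept")]
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  if (mode == "means") {
    return(sim_one(participant_posterior_means(fit), seed))
  }
  idx <- with_seed(seed, sample.int(nrow(fit$draws), n_rep, replace = TRUE))
  lapply(seq_len(n_rep), function(r) {
    s <- idx[r]
    plist <- lapply(seq_len(n), function(i) {
      args <- list(lambda = fit$draws[s, sprintf("lambda[%d]", i)],
                   model = spec$id)
      for (p in spec$params) {
        args[[p]] <- unname(fit$draws[s, sprintf("%s[%d,%d]", p, i, 1:4)])
      }
      do.call(param_set, args)
    })
    sim_one(plist, sub_seed(seed, r, salt = 5L))
  })
}

cell_key <- function(data) paste(data$role, data$frame, sep = "/")

#' Posterior predictive correlations between actual and simulated data
#'
#' Per condition: Pearson correlation of per-participant mean kept
#' fractions (across participants) and of per-round-position means
#' averaged over participants (across the block's trial positions), plus
#' a rerun of the mixed ANOVA on the simulated data when it contains
#' both groups ("behavioral recovery").
#'
#' @param actual,simulated Choice datasets with matched participants and
#'   design.
#' @param concatenate_trials If `TRUE`, the across-trials correlation
#'   uses all participant-trials concatenated instead of per-position
#'   means.
#' @return List of class `dg_ppc`: `by_participant` and `by_trial`
#'   correlation tables (with `undefined` flags for zero-variance cells)
#'   and `anova` (selfish + equal tables, or `NULL` for a single group).
#' @export
ppc_correlations <- function(actual, simulated, concatenate_trials = FALSE) {
  validate_dataset(actual)
  validate_dataset(simulated)
  if (nrow(actual) != nrow(simulated)) {
    stop("actual and simulated datasets must have matching designs",
         call. = FALSE)
  }
  actual$kf <- kept_fraction(actual$tokens_kept, actual$total_tokens)
  simulated$kf <- kept_fraction(simulated$tokens_kept,
                                simulated$total_tokens)
  conds <- unique(cell_key(actual))
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      c(r = NA_real_, undefined = 1)
    } else c(r = stats::cor(x, y), undefined = 0)
  }
  by_part <- by_trial <- NULL
  for (cond in conds) {
    ia <- cell_key(actual) == cond
    a <- actual[ia, ]; s <- simulated[cell_key(simulated) == cond, ]
    pa <- tapply(a$kf, a$participant_id, mean)
    ps <- tapply(s$kf, s$participant_id, mean)
    ps <- ps[names(pa)]
    rp <- safe_cor(pa, ps)
    if (concatenate_trials) {
      key <- paste(a$participant_id, a$round)
      skey <- paste(s$participant_id, s$round)
      rt <- safe_cor(a$kf, s$kf[match(key, skey)])
    } else {
      ta <- tapply(a$kf, a$round, mean)
      ts <- tapply(s$kf, s$round, mean)
      rt <- safe_cor(ta, ts[names(ta)])
    }
    by_part <- rbind(by_part, data.frame(
      condition = cond, n = length(pa), r = rp["r"],
      undefined = rp["undefined"] == 1))
    by_trial <- rbind(by_trial, data.frame(
      condition = cond, n = length(unique(a$round)), r = rt["r"],
      undefined = rt["undefined"] == 1))
  }
  rownames(by_part) <- rownames(by_trial) <- NULL
  anova_res <- NULL
  if (length(unique(simulated$group)) == 2L) {
    summ <- aggregate_deviations(simulated)
    anova_res <- list(selfish = mixed_anova(summ, "selfish"),
                      equal = mixed_anova(summ, "equal"))
  }
  structure(list(by_participant = by_part, by_trial = by_trial,
                 anova = anova_res),
            class = "dg_ppc")
}
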