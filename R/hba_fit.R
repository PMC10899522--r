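# Hierarchical Bayesian estimation of the inequity-aversion choice models.
#
# Individual-level parameters are sampled on an unconstrained scale and
# drawn from condition-specific population normals; positivity-constrained
# parameters (lambda always; alpha/beta under M5) use a log link. Group
# means get conjugate Gibbs updates; individual parameters and group sds
# get adaptive random-walk Metropolis updates whose proposal scales are
# tuned during warmup toward the 0.44 optimal scalar acceptance rate.

#' Priors of the hierarchical model
#'
#' Group-level means are given a `Normal(mu_mean, mu_sd)` prior and
#' group-level standard deviations a `half-Cauchy(0, sigma_scale)` (or
#' half-normal) prior, applied on the unconstrained sampling scale.
#'
#' @param mu_mean,mu_sd Mean prior location and scale (defaults 0 and 1).
#' @param sigma_scale Scale of the sd prior (default 2).
#' @param sigma_family `"half-cauchy"` (default) or `"half-normal"`.
#' @return List of class `prior_spec`.
#' @export
prior_spec <- function(mu_mean = 0, mu_sd = 1, sigma_scale = 2,
                       sigma_family = c("half-cauchy", "half-normal")) {
  sigma_family <- match.arg(sigma_family)
  if (mu_sd <= 0 || sigma_scale <= 0) {
    stop("prior scales must be strictly positive", call. = FALSE)
  }
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_scale = sigma_scale, sigma_family = sigma_family),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults match the study protocol: 3 chains of 2000 retained
#' iterations after 2000 warmup iterations, i.e. 6000 saved draws.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param warmup,sampling Iterations per chain.
#' @param seed Sampler master seed; chain seeds are derived from it.
#' @param thin Keep every `thin`-th post-warmup iteration (`sampling`
#'   draws are always retained, so `sampling * thin` iterations are run).
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, warmup = 2000L, sampling = 2000L,
                        seed = 1L, thin = 1L) {
  if (chains < 1L || warmup < 1L || sampling < 1L || thin < 1L) {
    stop("chains, warmup, sampling and thin must be positive",
         call. = FALSE)
  }
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling), seed = seed,
                 thin = as.integer(thin)),
            class = "mcmc_config")
}

log_half_prior <- function(sigma, priors) {
  if (priors$sigma_family == "half-cauchy") {
    log(2) - log(pi * priors$sigma_scale *
                   (1 + (sigma / priors$sigma_scale)^2))
  } else {
    log(2) + stats::dnorm(sigma, 0, priors$sigma_scale, log = TRUE)
  }
}

# Precompute per participant x condition option payoff matrices.
build_cells <- function(data, participants) {
  cells <- vector("list", length(participants))
  for (i in seq_along(participants)) {
    cells[[i]] <- vector("list", 4L)
    for (k in 1:4) {
      lab <- condition_labels(k)
      idx <- which(data$participant_id == participants[i] &
                     data$role == lab$role & data$frame == lab$frame)
      if (length(idx) == 0L) {
        stop("participant ", participants[i],
             " has no trials in condition k=", k, call. = FALSE)
      }
      sub <- data[idx, ]
      jmax <- max(sub$total_tokens) + 1L
      n <- nrow(sub)
      ms <- adv <- dis <- gen <- matrix(0, n, jmax)
      sgn <- ifelse(sub$frame == "loss", -1L, 1L)
      for (t in seq_len(n)) {
        ts <- 0:sub$total_tokens[t]
        m_s <- sgn[t] * sub$r_self[t] * ts
        m_o <- sgn[t] * sub$r_other[t] * (sub$total_tokens[t] - ts)
        j <- seq_along(ts)
        ms[t, j] <- m_s
        adv[t, j] <- pmax(m_s - m_o, 0)
        dis[t, j] <- pmax(m_o - m_s, 0)
        gen[t, j] <- abs(m_s - m_o)
      }
      cells[[i]][[k]] <- list(
        ms = ms, adv = adv, dis = dis, gen = gen,
        nopt = sub$total_tokens + 1L, choice = sub$tokens_kept + 1L,
        rowidx = idx
      )
    }
  }
  cells
}

cell_ll <- function(cell, alpha, beta, omega, lambda, mcode) {
  cell_loglik_cpp(cell$ms, cell$adv, cell$dis, cell$gen,
                  cell$nopt, cell$choice,
                  alpha, beta, omega, lambda, mcode)
}

#' Fit a utility model to one group's choices by hierarchical MCMC
#'
#' Each participant's condition-k weights are drawn from
#' `Normal(mu_k, sigma_k)` populations on the unconstrained scale (log
#' scale for lambda and for M5's constrained weights) with the priors of
#' [prior_spec()]. Groups (e.g. children and adults) are fitted
#' independently. Returns retained draws for all group- and
#' individual-level parameters, split-chain R-hat diagnostics and the
#' per-draw, per-trial pointwise log-likelihood matrix used for model
#' comparison.
#'
#' @param data Choice dataset from a single between-subject group.
#' @param model Model id (`"M1"`..`"M5"`).
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @return Object of class `dg_fit`: `draws` (matrix, saved draws x
#'   parameters), `chain` (chain index per draw), `pointwise_ll` (draws x
#'   trials, in dataset row order), `rhat` (named vector), plus metadata
#'   (`model`, `group`, `participants`, `config`, `priors`, `data`,
#'   `converged`).
#' @export
fit_hba <- function(data, model = "M4", priors = prior_spec(),
                    config = mcmc_config()) {
  spec <- model_spec(model)
  validate_dataset(data)
  if (length(unique(data$group)) != 1L) {
    stop("fit_hba expects data from a single group; fit groups separately",
         call. = FALSE)
  }
  participants <- unique(data$participant_id)
  n <- length(participants)
  cells <- build_cells(data, participants)
  mcode <- match(spec$id, names(dg_models()))

  chain_draws <- vector("list", config$chains)
  chain_ll <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    res <- NULL
    for (attempt in 1:3) {
      res <- tryCatch(
        run_chain(spec, cells, n, priors, config,
                  seed = sub_seed(config$seed, ch, salt = 17L * attempt),
                  mcode = mcode, n_rows = nrow(data)),
        error = function(e) e
      )
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error")) {
      stop("chain ", ch, " failed to initialize: ", conditionMessage(res),
           call. = FALSE)
    }
    chain_draws[[ch]] <- res$draws
    chain_ll[[ch]] <- res$pointwise
  }

  draws <- do.call(rbind, chain_draws)
  chain <- rep(seq_len(config$chains), each = config$sampling)
  rh <- apply_split_rhat(chain_draws)
  converged <- all(is.na(rh) | rh < 1.01)
  if (!converged) {
    warning("convergence not reached: max R-hat = ",
            round(max(rh, na.rm = TRUE), 3), call. = FALSE)
  }
  structure(
    list(model = spec$id, group = unique(data$group),
         participants = participants, config = config, priors = priors,
         draws = draws, chain = chain,
         pointwise_ll = do.call(rbind, chain_ll),
         rhat = rh, converged = converged, data = data),
    class = "dg_fit"
  )
}

#' @export
print.dg_fit <- function(x, ...) {
  cat(sprintf("Hierarchical fit of %s to group '%s' (%d participants)\n",
              x$model, x$group, length(x$participants)))
  cat(sprintf("  %d chains x %d saved draws (%d total); max R-hat = %.3f%s\n",
              x$config$chains, x$config$sampling, nrow(x$draws),
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

run_chain <- function(spec, cells, n, priors, config, seed, mcode, n_rows) {
  pnames <- spec$params
  constrained <- spec$constrained
  pidx <- match(pnames, c("alpha", "beta", "omega"))
  mu_sd2 <- priors$mu_sd^2
  with_seed(seed, {
    # --- initialization: jittered draws from the priors (sd clamped) ---
    mu <- list(); sigma <- list(); theta <- list()
    for (p in pnames) {
      mu[[p]] <- rnorm(4L, priors$mu_mean, priors$mu_sd / 2)
      sigma[[p]] <- runif(4L, 0.4, 1.2)
      theta[[p]] <- matrix(rnorm(n * 4L, rep(mu[[p]], each = n),
                                 rep(sigma[[p]], each = n)), n, 4L)
    }
    mu_lam <- rnorm(1L, -1, 0.3)
    sigma_lam <- runif(1L, 0.3, 0.8)
    loglam <- rnorm(n, mu_lam, sigma_lam)

    # natural-scale alpha/beta/omega matrices, kept in sync with theta
    nat <- list(alpha = matrix(0, n, 4L), beta = matrix(0, n, 4L),
                omega = matrix(0, n, 4L))
    for (p in pnames) {
      nat[[p]] <- if (constrained) exp(theta[[p]]) else theta[[p]]
    }

    ll_vec <- lapply(seq_len(n), function(i) vector("list", 4L))
    ll_sum <- matrix(0, n, 4L)
    for (i in seq_len(n)) for (k in 1:4) {
      v <- cell_ll(cells[[i]][[k]], nat$alpha[i, k], nat$beta[i, k],
                   nat$omega[i, k], exp(loglam[i]), mcode)
      if (any(!is.finite(v))) stop("non-finite initial likelihood")
      ll_vec[[i]][[k]] <- v
      ll_sum[i, k] <- sum(v)
    }

    # --- adaptive scales and acceptance counters ---
    sc_theta <- lapply(pnames, function(p) matrix(0.5, n, 4L))
    names(sc_theta) <- pnames
    ac_theta <- lapply(pnames, function(p) matrix(0, n, 4L))
    names(ac_theta) <- pnames
    sc_lam <- rep(0.3, n); ac_lam <- numeric(n)
    sc_sigma <- lapply(pnames, function(p) rep(0.5, 4L))
    names(sc_sigma) <- pnames
    ac_sigma <- lapply(pnames, function(p) numeric(4L))
    names(ac_sigma) <- pnames
    sc_siglam <- 0.5; ac_siglam <- 0
    sc_asis <- lapply(pnames, function(p) rep(0.3, 4L))
    names(sc_asis) <- pnames
    ac_asis <- lapply(pnames, function(p) numeric(4L))
    names(ac_asis) <- pnames
    sc_asis_lam <- 0.3; ac_asis_lam <- 0

    batch <- 25L; batch_no <- 0L
    n_iter <- config$warmup + config$sampling * config$thin
    pcols <- param_names(spec, n)
    draws <- matrix(NA_real_, config$sampling, length(pcols),
                    dimnames = list(NULL, pcols))
    pointwise <- matrix(NA_real_, config$sampling, n_rows)

    for (iter in seq_len(n_iter)) {
      for (i in seq_len(n)) {
        lam_i <- exp(loglam[i])
        for (pj in seq_along(pnames)) {
          p <- pnames[pj]
          th_p <- theta[[p]]; mu_p <- mu[[p]]; sg_p <- sigma[[p]]
          for (k in 1:4) {
            cur <- th_p[i, k]
            prop <- cur + sc_theta[[p]][i, k] * rnorm(1L)
            ab <- c(nat$alpha[i, k], nat$beta[i, k], nat$omega[i, k])
            ab[pidx[pj]] <- if (constrained) exp(prop) else prop
            v <- cell_ll(cells[[i]][[k]], ab[1L], ab[2L], ab[3L],
                         lam_i, mcode)
            logr <- sum(v) - ll_sum[i, k] +
              ((cur - mu_p[k])^2 - (prop - mu_p[k])^2) / (2 * sg_p[k]^2)
            if (is.finite(logr) && log(runif(1L)) < logr) {
              theta[[p]][i, k] <- prop
              nat[[p]][i, k] <- ab[pidx[pj]]
              ll_vec[[i]][[k]] <- v
              ll_sum[i, k] <- sum(v)
              ac_theta[[p]][i, k] <- ac_theta[[p]][i, k] + 1
            }
          }
        }
        # lambda (log scale), shared across the four conditions
        cur <- loglam[i]
        prop <- cur + sc_lam[i] * rnorm(1L)
        lam_p <- exp(prop)
        vlist <- vector("list", 4L)
        llp <- 0
        for (k in 1:4) {
          vlist[[k]] <- cell_ll(cells[[i]][[k]], nat$alpha[i, k],
                                nat$beta[i, k], nat$omega[i, k],
                                lam_p, mcode)
          llp <- llp + sum(vlist[[k]])
        }
        logr <- llp - sum(ll_sum[i, ]) +
          ((cur - mu_lam)^2 - (prop - mu_lam)^2) / (2 * sigma_lam^2)
        if (is.finite(logr) && log(runif(1L)) < logr) {
          loglam[i] <- prop
          for (k in 1:4) {
            ll_vec[[i]][[k]] <- vlist[[k]]
            ll_sum[i, k] <- sum(vlist[[k]])
          }
          ac_lam[i] <- ac_lam[i] + 1
        }
      }

      # --- group level ---
      norm_lp <- function(x, m, s) {
        -length(x) * log(s) - sum((x - m)^2) / (2 * s^2)
      }
      for (p in pnames) {
        for (k in 1:4) {
          # conjugate Gibbs draw for the population mean
          s2 <- sigma[[p]][k]^2
          v_post <- 1 / (n / s2 + 1 / mu_sd2)
          m_post <- v_post * (sum(theta[[p]][, k]) / s2 +
                                priors$mu_mean / mu_sd2)
          mu[[p]][k] <- rnorm(1L, m_post, sqrt(v_post))
          # Metropolis on log sd with half prior + Jacobian
          cur <- sigma[[p]][k]
          prop <- exp(log(cur) + sc_sigma[[p]][k] * rnorm(1L))
          logr <- norm_lp(theta[[p]][, k], mu[[p]][k], prop) -
            norm_lp(theta[[p]][, k], mu[[p]][k], cur) +
            log_half_prior(prop, priors) - log_half_prior(cur, priors) +
            log(prop) - log(cur)
          if (is.finite(logr) && log(runif(1L)) < logr) {
            sigma[[p]][k] <- prop
            ac_sigma[[p]][k] <- ac_sigma[[p]][k] + 1
          }
          # interweaved non-centered rescale: hold z = (theta - mu)/sigma
          # fixed and move sigma jointly with all individual values, which
          # decorrelates the population scale from the individual spread
          cur <- sigma[[p]][k]
          prop <- exp(log(cur) + sc_asis[[p]][k] * rnorm(1L))
          th_new <- mu[[p]][k] + (prop / cur) * (theta[[p]][, k] -
                                                   mu[[p]][k])
          nat_new <- if (constrained) exp(th_new) else th_new
          vlist <- vector("list", n)
          dll <- 0
          for (i in seq_len(n)) {
            ab <- c(nat$alpha[i, k], nat$beta[i, k], nat$omega[i, k])
            ab[pidx[match(p, pnames)]] <- nat_new[i]
            vlist[[i]] <- cell_ll(cells[[i]][[k]], ab[1L], ab[2L], ab[3L],
                                  exp(loglam[i]), mcode)
            dll <- dll + sum(vlist[[i]]) - ll_sum[i, k]
          }
          logr <- dll +
            log_half_prior(prop, priors) - log_half_prior(cur, priors) +
            log(prop) - log(cur)
          if (is.finite(logr) && log(runif(1L)) < logr) {
            sigma[[p]][k] <- prop
            theta[[p]][, k] <- th_new
            nat[[p]][, k] <- nat_new
            for (i in seq_len(n)) {
              ll_vec[[i]][[k]] <- vlist[[i]]
              ll_sum[i, k] <- sum(vlist[[i]])
            }
            ac_asis[[p]][k] <- ac_asis[[p]][k] + 1
          }
        }
      }
      s2 <- sigma_lam^2
      v_post <- 1 / (n / s2 + 1 / mu_sd2)
      m_post <- v_post * (sum(loglam) / s2 + priors$mu_mean / mu_sd2)
      mu_lam <- rnorm(1L, m_post, sqrt(v_post))
      cur <- sigma_lam
      prop <- exp(log(cur) + sc_siglam * rnorm(1L))
      logr <- norm_lp(loglam, mu_lam, prop) - norm_lp(loglam, mu_lam, cur) +
        log_half_prior(prop, priors) - log_half_prior(cur, priors) +
        log(prop) - log(cur)
      if (is.finite(logr) && log(runif(1L)) < logr) {
        sigma_lam <- prop
        ac_siglam <- ac_siglam + 1
      }
      # interweaved non-centered rescale for the lambda hierarchy
      cur <- sigma_lam
      prop <- exp(log(cur) + sc_asis_lam * rnorm(1L))
      ll_new <- mu_lam + (prop / cur) * (loglam - mu_lam)
      vmat <- lapply(seq_len(n), function(i) vector("list", 4L))
      dll <- 0
      for (i in seq_len(n)) {
        lam_i <- exp(ll_new[i])
        for (k in 1:4) {
          v <- cell_ll(cells[[i]][[k]], nat$alpha[i, k], nat$beta[i, k],
                       nat$omega[i, k], lam_i, mcode)
          vmat[[i]][[k]] <- v
          dll <- dll + sum(v) - ll_sum[i, k]
        }
      }
      logr <- dll +
        log_half_prior(prop, priors) - log_half_prior(cur, priors) +
        log(prop) - log(cur)
      if (is.finite(logr) && log(runif(1L)) < logr) {
        sigma_lam <- prop
        loglam <- ll_new
        for (i in seq_len(n)) for (k in 1:4) {
          ll_vec[[i]][[k]] <- vmat[[i]][[k]]
          ll_sum[i, k] <- sum(vmat[[i]][[k]])
        }
        ac_asis_lam <- ac_asis_lam + 1
      }

      # --- warmup adaptation in batches ---
      if (iter <= config$warmup && iter %% batch == 0L) {
        batch_no <- batch_no + 1L
        delta <- min(0.1, 1 / sqrt(batch_no))
        tune <- function(scale, acc) {
          scale * exp(ifelse(acc / batch > 0.44, delta, -delta))
        }
        for (p in pnames) {
          sc_theta[[p]] <- tune(sc_theta[[p]], ac_theta[[p]])
          ac_theta[[p]][] <- 0
          sc_sigma[[p]] <- tune(sc_sigma[[p]], ac_sigma[[p]])
          ac_sigma[[p]][] <- 0
          sc_asis[[p]] <- tune(sc_asis[[p]], ac_asis[[p]])
          ac_asis[[p]][] <- 0
        }
        sc_lam <- tune(sc_lam, ac_lam); ac_lam[] <- 0
        sc_siglam <- tune(sc_siglam, ac_siglam); ac_siglam <- 0
        sc_asis_lam <- tune(sc_asis_lam, ac_asis_lam); ac_asis_lam <- 0
      }

      # --- retention ---
      if (iter > config$warmup &&
          (iter - config$warmup) %% config$thin == 0L) {
        s <- (iter - config$warmup) %/% config$thin
        row <- numeric(length(pcols))
        pos <- 1L
        for (p in pnames) {
          row[pos:(pos + 3L)] <- mu[[p]]; pos <- pos + 4L
          row[pos:(pos + 3L)] <- sigma[[p]]; pos <- pos + 4L
        }
        row[pos] <- mu_lam; row[pos + 1L] <- sigma_lam; pos <- pos + 2L
        for (p in pnames) {
          row[pos:(pos + 4L * n - 1L)] <- as.vector(nat[[p]])
          pos <- pos + 4L * n
        }
        row[pos:(pos + n - 1L)] <- exp(loglam)
        draws[s, ] <- row
        for (i in seq_len(n)) for (k in 1:4) {
          pointwise[s, cells[[i]][[k]]$rowidx] <- ll_vec[[i]][[k]]
        }
      }
    }
    list(draws = draws, pointwise = pointwise)
  })
}

param_names <- function(spec, n) {
  out <- character(0)
  for (p in spec$params) {
    out <- c(out, sprintf("mu_%s[%d]", p, 1:4),
             sprintf("sigma_%s[%d]", p, 1:4))
  }
  out <- c(out, "mu_loglam", "sigma_loglam")
  for (p in spec$params) {
    out <- c(out, sprintf("%s[%d,%d]", p, rep(seq_len(n), times = 4L),
                          rep(1:4, each = n)))
  }
  c(out, sprintf("lambda[%d]", seq_len(n)))
}

apply_split_rhat <- function(chain_draws) {
  pcols <- colnames(chain_draws[[1]])
  out <- vapply(seq_along(pcols), function(j) {
    m <- vapply(chain_draws, function(d) d[, j], numeric(nrow(chain_draws[[1]])))
    rhat(m)
  }, numeric(1))
  names(out) <- pcols
  out
}

#' Split-chain Gelman-Rubin R-hat
#'
#' Each chain is split in half and the potential scale reduction factor
#' computed over the resulting sequences. Values near 1 (below 1.01)
#' indicate convergence. Constant chains have no defined R-hat and return
#' `NA` with a warning (degenerate posterior).
#'
#' @param x Matrix of draws, iterations x chains, or a `dg_fit` (returns
#'   its stored per-parameter R-hat vector).
#' @return Scalar R-hat (or named vector for a fit).
#' @export
rhat <- function(x) {
  if (inherits(x, "dg_fit")) return(x$rhat)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat requires at least 2 chains", call. = FALSE)
  if (nrow(x) < 4L) stop("R-hat requires at least 4 draws per chain",
                         call. = FALSE)
  half <- floor(nrow(x) / 2L)
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(nrow(x) - half + 1L):nrow(x), j])
  }))
  w <- mean(apply(splits, 2L, stats::var))
  if (!is.finite(w) || w == 0) {
    warning("R-hat undefined for (near-)constant chains", call. = FALSE)
    return(NA_real_)
  }
  b <- half * stats::var(colMeans(splits))
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing the requested posterior mass, found by
#' scanning all contiguous windows of the sorted draws.
#'
#' @param draws Numeric vector.
#' @param mass Target probability mass in (0, 1].
#' @return Numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (length(draws) == 0L) stop("empty draws", call. = FALSE)
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]", call. = FALSE)
  s <- sort(draws)
  n <- length(s)
  m <- min(n, max(1L, ceiling(mass * n)))
  if (m >= n) return(c(s[1L], s[n]))
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)
  c(s[i], s[i + m - 1L])
}

#' Posterior mean and HDI of a fitted parameter
#'
#' @param fit A `dg_fit`.
#' @param parameter Column name in `fit$draws`, e.g. `"mu_alpha[3]"` or
#'   `"alpha[2,1]"`.
#' @param mass HDI mass (default 0.95).
#' @return List with `mean`, `hdi` and `mass`.
#' @export
posterior_summary <- function(fit, parameter, mass = 0.95) {
  stopifnot(inherits(fit, "dg_fit"))
  if (!parameter %in% colnames(fit$draws)) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  d <- fit$draws[, parameter]
  list(mean = mean(d), hdi = hdi(d, mass), mass = mass)
}

#' Per-participant posterior-mean parameter sets
#'
#' @param fit A `dg_fit`.
#' @return Named list of `dg_params`, one per fitted participant.
#' @export
participant_posterior_means <- function(fit) {
  stopifnot(inherits(fit, "dg_fit"))
  spec <- model_spec(fit$model)
  n <- length(fit$participants)
  cm <- colMeans(fit$draws)
  out <- vector("list", n)
  names(out) <- fit$participants
  for (i in seq_len(n)) {
    args <- list(lambda = cm[sprintf("lambda[%d]", i)], model = spec$id)
    for (p in spec$params) {
      args[[p]] <- unname(cm[sprintf("%s[%d,%d]", p, i, 1:4)])
    }
    out[[i]] <- do.call(param_set, args)
  }
  out
}
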