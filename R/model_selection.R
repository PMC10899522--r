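# Information-criterion model comparison from pointwise log-likelihoods.

col_logsumexp <- function(m) {
  mx <- apply(m, 2L, max)
  mx + log(colSums(exp(sweep(m, 2L, mx))))
}

check_ll_matrix <- function(ll) {
  ll <- as.matrix(ll)
  if (any(!is.finite(ll))) {
    stop("pointwise log-likelihood matrix contains non-finite entries",
         call. = FALSE)
  }
  ll
}

#' Widely applicable information criterion
#'
#' `lppd = sum_i log mean_s exp(ll[s,i])`, `p_waic = sum_i var_s ll[s,i]`,
#' `WAIC = -2 (lppd - p_waic)`, computed with a log-sum-exp guard.
#'
#' @param ll Pointwise log-likelihood matrix (draws x trials), e.g.
#'   `fit$pointwise_ll` from [fit_hba()].
#' @return List with `waic`, `p_waic`, `lppd`, `elpd` and the per-trial
#'   `pointwise` elpd contributions.
#' @export
waic <- function(ll) {
  ll <- check_ll_matrix(ll)
  s <- nrow(ll)
  lppd_i <- col_logsumexp(ll) - log(s)
  p_i <- apply(ll, 2L, stats::var)
  elpd_i <- lppd_i - p_i
  list(waic = -2 * sum(elpd_i), p_waic = sum(p_i), lppd = sum(lppd_i),
       elpd = sum(elpd_i), pointwise = elpd_i)
}

# Zhang & Stephens (2009) profile-likelihood generalized Pareto fit with
# the usual weak prior regularization of the shape estimate.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  # profile log-likelihood over theta = -xi/sigma; heavy tails have
  # theta < 0 and positive shape k = mean log(1 - theta x)
  k_j <- vapply(theta, function(t) mean(log1p(-t * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  l_j[!is.finite(l_j)] <- -Inf
  w_j <- 1 / vapply(seq_len(m),
                    function(j) sum(exp(l_j - l_j[j])), numeric(1))
  w_j[!is.finite(w_j)] <- 0
  theta_hat <- sum(theta * w_j) / sum(w_j)
  k_hat <- mean(log1p(-theta_hat * x))
  sigma_hat <- -k_hat / theta_hat
  # weakly informative prior pulls k toward 0.5 (stabilizes small tails)
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

#' PSIS-LOO: Pareto-smoothed importance-sampling leave-one-out criterion
#'
#' For each trial the importance ratios `1/p(y_i | theta_s)` are tail-
#' smoothed by fitting a generalized Pareto distribution to the largest
#' 20% of log-ratios, replacing them with expected order statistics and
#' truncating at the raw maximum; the smoothed weights give the expected
#' log pointwise predictive density. Trials with Pareto k above 0.7 are
#' flagged as unreliable. A posterior concentrated at a point (zero
#' likelihood variance) is handled exactly and reproduces WAIC.
#'
#' @inheritParams waic
#' @return List with `looic`, `elpd`, `p_loo`, per-trial `pointwise` elpd
#'   and `pareto_k`, and `n_high_k` (trials with k > 0.7).
#' @export
psis_loo <- function(ll) {
  ll <- check_ll_matrix(ll)
  s <- nrow(ll)
  n <- ncol(ll)
  m_tail <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  lppd_i <- col_logsumexp(ll) - log(s)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (i in seq_len(n)) {
    lli <- ll[, i]
    lw <- -lli
    lw <- lw - max(lw)
    if (stats::sd(lw) == 0 || m_tail < 5L) {
      k_i[i] <- -Inf  # degenerate/exact case: no smoothing needed
    } else {
      ord <- order(lw)
      tail_ids <- ord[(s - m_tail + 1L):s]
      cut <- exp(lw[ord[s - m_tail]])
      exceed <- exp(lw[tail_ids]) - cut
      if (all(exceed <= 0)) {
        k_i[i] <- -Inf
      } else {
        fit <- gpd_fit(pmax(exceed, .Machine$double.eps))
        k_i[i] <- fit$k
        if (is.finite(fit$k) && fit$sigma > 0) {
          qq <- qgpd((seq_len(m_tail) - 0.5) / m_tail, fit$k, fit$sigma)
          sm <- log(cut + qq)
          lw[tail_ids[order(lw[tail_ids])]] <- sm
          lw <- pmin(lw, 0)  # truncate at the raw maximum
        }
      }
    }
    elpd_i[i] <- logsumexp(lw + lli) - logsumexp(lw)
  }
  list(looic = -2 * sum(elpd_i), elpd = sum(elpd_i),
       p_loo = sum(lppd_i) - sum(elpd_i),
       pointwise = elpd_i, pareto_k = k_i,
       n_high_k = sum(is.finite(k_i) & k_i > 0.7))
}

#' Akaike-type weights from information-criterion scores
#'
#' `w_m = exp(-Delta_m / 2) / sum exp(-Delta / 2)` with `Delta_m` the
#' score difference to the best (lowest-score) model. A 10-point score
#' difference therefore corresponds to an `exp(5) ~ 148:1` weight ratio.
#'
#' @param scores Named numeric vector of LOOIC or WAIC scores (>= 2).
#' @return Named weights summing to 1.
#' @export
information_weights <- function(scores) {
  if (length(scores) < 2L) {
    stop("weights require at least 2 models", call. = FALSE)
  }
  d <- scores - min(scores)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Stacking weights from pointwise elpd contributions
#'
#' Maximizes the summed log predictive density of the weighted model
#' mixture over the probability simplex (softmax-parameterized
#' quasi-Newton optimization).
#'
#' @param elpd_point Matrix, trials x models, of pointwise elpd values.
#' @return Named weights summing to 1.
#' @export
stacking_weights <- function(elpd_point) {
  elpd_point <- as.matrix(elpd_point)
  m <- ncol(elpd_point)
  if (m < 2L) stop("stacking requires at least 2 models", call. = FALSE)
  obj <- function(z) {
    w <- exp(c(z, 0)); w <- w / sum(w)
    lp <- apply(elpd_point, 1L, function(r) logsumexp(r + log(w)))
    -sum(lp)
  }
  opt <- stats::optim(rep(0, m - 1L), obj, method = "BFGS")
  w <- exp(c(opt$par, 0)); w <- w / sum(w)
  names(w) <- colnames(elpd_point)
  w
}

#' Compare fitted models by LOOIC and WAIC
#'
#' @param fits Named list of `dg_fit` objects (or of pointwise
#'   log-likelihood matrices) for the same dataset.
#' @param weights `"akaike"` (pseudo-BMA, default) or `"stacking"`.
#' @return Data frame of class `dg_comparison`, sorted by LOOIC: per
#'   model the LOOIC/WAIC scores, effective-parameter estimates, weights,
#'   Pareto-k summary and a `winner` flag (lowest LOOIC, ties broken by
#'   WAIC).
#' @export
compare_models <- function(fits, weights = c("akaike", "stacking")) {
  weights <- match.arg(weights)
  if (length(fits) < 2L) {
    stop("model comparison requires at least 2 fitted models",
         call. = FALSE)
  }
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) {
      if (inherits(f, "dg_fit")) f$model else stop("unnamed fits")
    }, character(1))
  }
  lls <- lapply(fits, function(f) {
    if (inherits(f, "dg_fit")) f$pointwise_ll else as.matrix(f)
  })
  loo_res <- lapply(lls, psis_loo)
  waic_res <- lapply(lls, waic)
  looic <- vapply(loo_res, `[[`, numeric(1), "looic")
  waics <- vapply(waic_res, `[[`, numeric(1), "waic")
  w_loo <- if (weights == "akaike") information_weights(looic) else
    stacking_weights(vapply(loo_res, `[[`,
                            numeric(length(loo_res[[1]]$pointwise)),
                            "pointwise"))
  w_waic <- information_weights(waics)
  tab <- data.frame(
    model = names(fits),
    looic = looic, waic = waics,
    p_loo = vapply(loo_res, `[[`, numeric(1), "p_loo"),
    p_waic = vapply(waic_res, `[[`, numeric(1), "p_waic"),
    looic_weight = w_loo, waic_weight = w_waic,
    max_pareto_k = vapply(loo_res, function(r) {
      if (all(!is.finite(r$pareto_k))) -Inf else max(r$pareto_k)
    }, numeric(1)),
    n_high_k = vapply(loo_res, `[[`, numeric(1), "n_high_k")
  )
  best <- order(tab$looic, tab$waic)[1L]
  tab$winner <- seq_len(nrow(tab)) == best
  tab <- tab[order(tab$looic), ]
  rownames(tab) <- NULL
  class(tab) <- c("dg_comparison", "data.frame")
  tab
}
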