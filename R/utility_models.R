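#' Registry of candidate utility models
#'
#' Five inequity-aversion utility specifications over the payoff pair
#' (m_self, m_other), each with condition-specific weights:
#' \describe{
#'   \item{M1}{advantageous-inequity aversion only:
#'     `U = m_self - alpha_k * max(m_self - m_other, 0)`}
#'   \item{M2}{disadvantageous-inequity aversion only:
#'     `U = m_self - beta_k * max(m_other - m_self, 0)`}
#'   \item{M3}{general (undifferentiated) inequity aversion:
#'     `U = m_self - omega_k * |m_self - m_other|`}
#'   \item{M4}{Fehr-Schmidt: both weights free,
#'     `U = m_self - alpha_k * max(m_self - m_other, 0)
#'               - beta_k * max(m_other - m_self, 0)`}
#'   \item{M5}{Fehr-Schmidt with `alpha_k > 0`, `beta_k > 0` (pure
#'     aversion; no advantage-seeking allowed)}
#' }
#' Negative `alpha_k` means advantage-seeking: being ahead adds utility.
#'
#' @return Named list of model specifications (id, free parameter names,
#'   positivity constraint flag).
#' @export
dg_models <- function() {
  list(
    M1 = list(id = "M1", params = "alpha",            constrained = FALSE),
    M2 = list(id = "M2", params = "beta",             constrained = FALSE),
    M3 = list(id = "M3", params = "omega",            constrained = FALSE),
    M4 = list(id = "M4", params = c("alpha", "beta"), constrained = FALSE),
    M5 = list(id = "M5", params = c("alpha", "beta"), constrained = TRUE)
  )
}

#' @keywords internal
model_spec <- function(model) {
  if (is.list(model) && !is.null(model$id)) model <- model$id
  reg <- dg_models()
  if (!is.character(model) || length(model) != 1L || !model %in% names(reg)) {
    stop("unknown model id; use one of ", paste(names(reg), collapse = ", "),
         call. = FALSE)
  }
  reg[[model]]
}

#' Per-participant model parameters
#'
#' Condition-indexed inequity weights plus one softmax inverse temperature
#' shared across conditions (the choice rule carries no condition
#' subscript on lambda). Weights are in utility per cent of inequity;
#' lambda is in 1/cents.
#'
#' @param lambda Inverse softmax temperature, `>= 0` (0 gives uniform
#'   random choice and is allowed for diagnostics and simulation).
#' @param alpha,beta,omega Length-4 numeric vectors indexed by condition
#'   k, or `NULL` for parameters the model does not use.
#' @param model Model id the set is intended for (validated).
#' @return List of class `dg_params`.
#' @export
param_set <- function(lambda, alpha = NULL, beta = NULL, omega = NULL,
                      model = "M4") {
  spec <- model_spec(model)
  if (!is.finite(lambda) || lambda < 0) {
    stop("lambda must be finite and nonnegative", call. = FALSE)
  }
  vals <- list(alpha = alpha, beta = beta, omega = omega)
  for (p in spec$params) {
    v <- vals[[p]]
    if (is.null(v) || length(v) != 4L || any(!is.finite(v))) {
      stop("model ", spec$id, " needs a finite length-4 '", p, "' vector",
           call. = FALSE)
    }
    if (spec$constrained && any(v <= 0)) {
      stop("model M5 constrains alpha and beta to be strictly positive",
           call. = FALSE)
    }
  }
  extra <- setdiff(names(Filter(Negate(is.null), vals)), spec$params)
  if (length(extra)) {
    stop("parameters ", paste(extra, collapse = ", "),
         " do not belong to model ", spec$id, call. = FALSE)
  }
  structure(list(model = spec$id, lambda = lambda,
                 alpha = alpha, beta = beta, omega = omega),
            class = "dg_params")
}

#' Utility of a payoff pair under a model
#'
#' @param model Model id (`"M1"`..`"M5"`).
#' @param m_self,m_other Signed payoffs in cents (vectors, recycled).
#' @param alpha,beta,omega Scalar condition-k weights (only those the
#'   model uses are consulted).
#' @return Numeric utility vector.
#' @export
utility <- function(model, m_self, m_other,
                    alpha = NULL, beta = NULL, omega = NULL) {
  spec <- model_spec(model)
  adv <- pmax(m_self - m_other, 0)
  dis <- pmax(m_other - m_self, 0)
  switch(spec$id,
    M1 = m_self - need_par(alpha, "alpha", spec) * adv,
    M2 = m_self - need_par(beta, "beta", spec) * dis,
    M3 = m_self - need_par(omega, "omega", spec) * abs(m_self - m_other),
    m_self - need_par(alpha, "alpha", spec) * adv -
      need_par(beta, "beta", spec) * dis
  )
}

need_par <- function(x, name, spec) {
  if (is.null(x) || any(!is.finite(x))) {
    stop("model ", spec$id, " requires parameter '", name, "'",
         call. = FALSE)
  }
  if (spec$constrained && any(x <= 0)) {
    stop("model M5 requires strictly positive '", name, "'", call. = FALSE)
  }
  x
}

#' Numerically stable log-sum-exp
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Softmax choice probabilities over a trial's choice set
#'
#' `P(j) = exp(lambda * U_j) / sum_j' exp(lambda * U_j')` over all T+1
#' allocations, computed through a log-sum-exp guard so arbitrarily large
#' `lambda * U` magnitudes cannot overflow. `lambda = 0` yields the
#' uniform distribution.
#'
#' @param model Model id.
#' @param trial A `dg_trial`.
#' @param lambda Inverse temperature `>= 0`.
#' @inheritParams utility
#' @return Probability vector of length `total_tokens + 1`, ordered as
#'   [choice_set()].
#' @export
choice_probs <- function(model, trial, lambda,
                         alpha = NULL, beta = NULL, omega = NULL) {
  stopifnot(inherits(trial, "dg_trial"))
  if (!is.finite(lambda) || lambda < 0) {
    stop("lambda must be finite and nonnegative", call. = FALSE)
  }
  cs <- choice_set(trial)
  po <- payoffs(trial, cs$tokens_kept)
  u <- utility(model, po$m_self, po$m_other,
               alpha = alpha, beta = beta, omega = omega)
  v <- lambda * u
  exp(v - logsumexp(v))
}

#' @keywords internal
params_for_k <- function(params, k) {
  list(alpha = if (is.null(params$alpha)) NULL else params$alpha[k],
       beta  = if (is.null(params$beta))  NULL else params$beta[k],
       omega = if (is.null(params$omega)) NULL else params$omega[k])
}

#' Log-likelihood of a choice dataset under fixed parameters
#'
#' Sums (or returns trial-wise, in dataset row order) the log softmax
#' probability of each observed allocation. `params` is either a single
#' `dg_params` applied to every participant or a named list of
#' `dg_params` keyed by participant id.
#'
#' @param model Model id.
#' @param params A `dg_params` or named list of them.
#' @param data A choice dataset (see [write_dataset()] for the dialect).
#' @param pointwise If `TRUE`, return the per-trial vector instead of the
#'   sum.
#' @return Scalar log-likelihood, or numeric vector of length `nrow(data)`.
#' @export
log_likelihood <- function(model, params, data, pointwise = FALSE) {
  spec <- model_spec(model)
  validate_dataset(data)
  one <- inherits(params, "dg_params")
  out <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    p <- if (one) params else params[[as.character(row$participant_id)]]
    if (is.null(p)) {
      stop("no parameters supplied for participant ", row$participant_id,
           call. = FALSE)
    }
    tr <- dg_trial(row$role, row$frame, row$r_self, row$r_other,
                   row$total_tokens, row$block, row$round)
    pk <- params_for_k(p, tr$k)
    pr <- choice_probs(spec$id, tr, p$lambda,
                       alpha = pk$alpha, beta = pk$beta, omega = pk$omega)
    out[i] <- log(pr[row$tokens_kept + 1L])
  }
  if (pointwise) out else sum(out)
}
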