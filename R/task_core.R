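#' The five exchange ratios of the study design
#'
#' Each token kept is worth `r_self` cents to the dictator and each token
#' sent is worth `r_other` cents to the recipient. The design crosses five
#' self:other ratios: 3:1, 2:1, 1:1, 1:2 and 1:3.
#'
#' @return A data frame with columns `r_self` and `r_other`, one row per
#'   design ratio.
#' @export
dg_ratios <- function() {
  data.frame(
    r_self  = c(3L, 2L, 1L, 1L, 1L),
    r_other = c(1L, 1L, 1L, 2L, 3L)
  )
}

#' @keywords internal
assert_ratio <- function(r_self, r_other, strict = FALSE) {
  if (any(!is.finite(r_self)) || any(!is.finite(r_other)) ||
      any(r_self <= 0) || any(r_other <= 0)) {
    stop("exchange ratio components must be positive", call. = FALSE)
  }
  if (strict) {
    des <- dg_ratios()
    ok <- paste(r_self, r_other) %in% paste(des$r_self, des$r_other)
    if (!all(ok)) {
      warning("exchange ratio outside the 5-ratio study design", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Condition index for a role/frame combination
#'
#' The four within-subject conditions are indexed k = 1..4:
#' 1 = first-party/gain, 2 = first-party/loss, 3 = third-party/gain,
#' 4 = third-party/loss.
#'
#' @param role `"first"` or `"third"`.
#' @param frame `"gain"` or `"loss"`.
#' @return Integer vector of condition indices in 1..4.
#' @export
condition_k <- function(role, frame) {
  role <- match_role(role)
  frame <- match_frame(frame)
  ifelse(role == "first", 0L, 2L) + ifelse(frame == "gain", 1L, 2L)
}

#' Role and frame labels for a condition index
#'
#' Inverse of [condition_k()].
#'
#' @param k Integer vector with values in 1..4.
#' @return Data frame with columns `k`, `role`, `frame`.
#' @export
condition_labels <- function(k = 1:4) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L) || any(k > 4L)) {
    stop("condition index k must be in 1..4", call. = FALSE)
  }
  data.frame(
    k = k,
    role  = c("first", "first", "third", "third")[k],
    frame = c("gain", "loss", "gain", "loss")[k]
  )
}

match_role <- function(role) {
  role <- as.character(role)
  out <- ifelse(role %in% c("first", "first_party"), "first",
         ifelse(role %in% c("third", "third_party"), "third", NA_character_))
  if (any(is.na(out))) stop("role must be 'first' or 'third'", call. = FALSE)
  out
}

match_frame <- function(frame) {
  frame <- as.character(frame)
  if (!all(frame %in% c("gain", "loss"))) {
    stop("frame must be 'gain' or 'loss'", call. = FALSE)
  }
  frame
}

#' Construct a single dictator-game trial
#'
#' @param role,frame Condition labels (see [condition_k()]).
#' @param r_self,r_other Positive cents-per-token exchange ratio.
#' @param total_tokens Nonnegative integer token budget T.
#' @param block,round Positive schedule indices.
#' @return A list of class `dg_trial`.
#' @export
dg_trial <- function(role, frame, r_self, r_other, total_tokens,
                     block = 1L, round = 1L) {
  role <- match_role(role); frame <- match_frame(frame)
  assert_ratio(r_self, r_other)
  total_tokens <- as.integer(total_tokens)
  if (is.na(total_tokens) || total_tokens < 0L) {
    stop("invalid trial: total_tokens must be a nonnegative integer",
         call. = FALSE)
  }
  if (block < 1L || round < 1L) {
    stop("block and round indices start at 1", call. = FALSE)
  }
  structure(
    list(role = role, frame = frame, k = condition_k(role, frame),
         r_self = as.integer(r_self), r_other = as.integer(r_other),
         total_tokens = total_tokens,
         block = as.integer(block), round = as.integer(round)),
    class = "dg_trial"
  )
}

#' Discrete choice set of a trial
#'
#' All whole-token splits of the budget: keeping T_s = 0, 1, ..., T tokens
#' and sending the remainder. This ordered set is the option set of the
#' softmax choice rule.
#'
#' @param trial A `dg_trial`.
#' @return Data frame with `tokens_kept` and `tokens_sent`, T+1 rows in
#'   ascending order of tokens kept.
#' @export
choice_set <- function(trial) {
  stopifnot(inherits(trial, "dg_trial"))
  ts <- 0:trial$total_tokens
  data.frame(tokens_kept = ts, tokens_sent = trial$total_tokens - ts)
}

#' Monetary payoffs of an allocation
#'
#' Tokens convert to cents at the trial's exchange ratio: `m_self =
#' r_self * tokens_kept`, `m_other = r_other * tokens_sent`. In the loss
#' frame tokens convert to losses, so both payoffs carry a negative sign;
#' the purely selfish optimum is then to keep nothing (0% kept) versus
#' everything (100% kept) in the gain frame. In the third-party role the
#' "self" payoff is the represented dictator's; the arithmetic is
#' unchanged.
#'
#' @param trial A `dg_trial`.
#' @param tokens_kept Integer vector of tokens kept; must lie in the
#'   trial's choice set.
#' @return Data frame with signed-cent columns `m_self`, `m_other`.
#' @export
payoffs <- function(trial, tokens_kept) {
  stopifnot(inherits(trial, "dg_trial"))
  tokens_kept <- as.integer(tokens_kept)
  if (any(is.na(tokens_kept)) || any(tokens_kept < 0L) ||
      any(tokens_kept > trial$total_tokens)) {
    stop("allocation outside the trial's choice set", call. = FALSE)
  }
  sgn <- if (trial$frame == "loss") -1L else 1L
  data.frame(
    m_self  = sgn * trial$r_self * tokens_kept,
    m_other = sgn * trial$r_other * (trial$total_tokens - tokens_kept)
  )
}

#' Fraction of the token budget kept
#'
#' Choices are analysed as the fraction T_s / T so rounds with different
#' budgets are comparable.
#'
#' @param tokens_kept,total_tokens Integer vectors (recycled).
#' @return Numeric vector in `[0, 1]`.
#' @export
kept_fraction <- function(tokens_kept, total_tokens) {
  if (any(total_tokens <= 0)) {
    stop("kept fraction undefined for a zero token budget", call. = FALSE)
  }
  if (any(tokens_kept < 0) || any(tokens_kept > total_tokens)) {
    stop("tokens_kept must lie in [0, total_tokens]", call. = FALSE)
  }
  tokens_kept / total_tokens
}

#' Kept fraction that equalizes the two payoffs
#'
#' Payoff equality `r_self * T_s = r_other * T_o` holds at the kept
#' fraction `r_other / (r_self + r_other)`; e.g. 75% at ratio 1:3 and 25%
#' at 3:1. Frame-independent: negating both payoffs preserves equality.
#'
#' @param r_self,r_other Positive exchange-ratio components (recycled).
#' @return Numeric vector in `(0, 1)`.
#' @export
equal_fraction <- function(r_self, r_other) {
  assert_ratio(r_self, r_other)
  r_other / (r_self + r_other)
}
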