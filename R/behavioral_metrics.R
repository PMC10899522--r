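# Model-free statistics: deviations of choices from the selfish and equal
# reference rules, aggregated per participant x condition and analysed
# with a 2 (Role) x 2 (Frame) within x 2 (Group) between mixed ANOVA.

#' Deviation from the purely selfish rule
#'
#' The payoff-maximizing choice keeps 100% of the budget in the gain
#' frame and 0% in the loss frame, so the deviation of a choice with kept
#' fraction c is `|1 - c|` (gain) or `c` (loss). Independent of the
#' exchange ratio and of the token budget's absolute size.
#'
#' @param tokens_kept,total_tokens Integer vectors (recycled).
#' @param frame `"gain"`/`"loss"` vector.
#' @return Numeric deviations in `[0, 1]`.
#' @export
selfish_deviation <- function(tokens_kept, total_tokens, frame) {
  frame <- match_frame(frame)
  c_frac <- kept_fraction(tokens_kept, total_tokens)
  ifelse(frame == "gain", abs(1 - c_frac), c_frac)
}

#' Deviation from the payoff-equalizing rule
#'
#' Absolute distance between the observed kept fraction and
#' [equal_fraction()] of the trial's ratio; identical in both frames.
#'
#' @param tokens_kept,total_tokens Integer vectors (recycled).
#' @param r_self,r_other Exchange-ratio components.
#' @return Numeric deviations in `[0, 1]`.
#' @export
equal_deviation <- function(tokens_kept, total_tokens, r_self, r_other) {
  abs(equal_fraction(r_self, r_other) - kept_fraction(tokens_kept, total_tokens))
}

#' Per-participant, per-condition deviation summaries
#'
#' Averages the selfish and equal deviations over each participant's
#' trials within every role x frame cell.
#'
#' @param data Choice dataset (see [write_dataset()]).
#' @return Data frame with one row per participant x role x frame:
#'   `participant_id`, `group`, `role`, `frame`, `selfish`, `equal`.
#' @export
aggregate_deviations <- function(data) {
  validate_dataset(data)
  data$selfish_dev <- selfish_deviation(data$tokens_kept, data$total_tokens,
                                        data$frame)
  data$equal_dev <- equal_deviation(data$tokens_kept, data$total_tokens,
                                    data$r_self, data$r_other)
  agg <- stats::aggregate(
    cbind(selfish = data$selfish_dev, equal = data$equal_dev),
    by = list(participant_id = data$participant_id, group = data$group,
              role = data$role, frame = data$frame),
    FUN = mean
  )
  counts <- table(agg$participant_id)
  if (any(counts != 4L)) {
    bad <- names(counts)[counts != 4L]
    stop("incomplete design: participant(s) missing condition cells: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  agg <- agg[order(agg$participant_id, agg$role, agg$frame), ]
  rownames(agg) <- NULL
  agg
}

# Per-subject orthogonal within-subject contrasts of the 2x2 cell means.
subject_contrasts <- function(summaries, response) {
  if (!response %in% c("selfish", "equal")) {
    stop("response must be 'selfish' or 'equal'", call. = FALSE)
  }
  ids <- unique(summaries$participant_id)
  grab <- function(id, role, frame) {
    v <- summaries[[response]][summaries$participant_id == id &
                                 summaries$role == role &
                                 summaries$frame == frame]
    if (length(v) != 1L) {
      stop("incomplete design for participant ", id, call. = FALSE)
    }
    v
  }
  out <- lapply(ids, function(id) {
    fg <- grab(id, "first", "gain"); fl <- grab(id, "first", "loss")
    tg <- grab(id, "third", "gain"); tl <- grab(id, "third", "loss")
    data.frame(
      participant_id = id,
      group = summaries$group[match(id, summaries$participant_id)],
      c_mean = (fg + fl + tg + tl) / 4,
      c_role = (fg + fl) / 2 - (tg + tl) / 2,      # first - third
      c_frame = (fg + tg) / 2 - (fl + tl) / 2,     # gain - loss
      c_rf = (fg - fl) - (tg - tl)
    )
  })
  do.call(rbind, out)
}

# One-df F tests on a per-subject contrast variable with a 2-level
# between factor: Type-III (unweighted) main effect and group interaction
# against the subject-level error of that stratum.
stratum_tests <- function(d, group, test_main = TRUE) {
  g <- unique(group)
  if (length(g) != 2L) {
    stop("exactly two between-subject groups are required", call. = FALSE)
  }
  n1 <- sum(group == g[1]); n2 <- sum(group == g[2])
  if (n1 < 2L || n2 < 2L) {
    stop("at least 2 participants per group are required", call. = FALSE)
  }
  m1 <- mean(d[group == g[1]]); m2 <- mean(d[group == g[2]])
  ss_err <- sum((d - ifelse(group == g[1], m1, m2))^2)
  df2 <- length(d) - 2L
  if (ss_err <= 0) {
    stop("degenerate data: zero residual variance in a stratum",
         call. = FALSE)
  }
  ms_err <- ss_err / df2
  eff <- function(ss) {
    f <- ss / ms_err
    data.frame(F = f, df1 = 1L, df2 = df2,
               p = stats::pf(f, 1L, df2, lower.tail = FALSE),
               pes = ss / (ss + ss_err))
  }
  ceff <- 1 / (1 / n1 + 1 / n2)
  out <- list()
  if (test_main) {
    L <- (m1 + m2) / 2
    out$main <- eff(4 * L^2 * ceff)
  }
  out$interaction <- eff((m1 - m2)^2 * ceff)
  out$err <- c(ss_err = ss_err, df2 = df2)
  out
}

#' Mixed-design ANOVA on deviation summaries
#'
#' Classical 2 (Role) x 2 (Frame) within x 2 (Group) between
#' decomposition, computed from sums of squares on per-subject orthogonal
#' contrasts: the between stratum tests Group on subject means; each
#' within stratum tests a within effect and its Group interaction against
#' the subject-level error of that stratum. Main effects are unweighted
#' (Type III), so unequal group sizes are handled; with 2-level factors
#' sphericity holds trivially. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param summaries Output of [aggregate_deviations()].
#' @param response `"selfish"` or `"equal"`.
#' @return Data frame with one row per effect (`Group`, `Role`,
#'   `Role:Group`, `Frame`, `Frame:Group`, `Role:Frame`,
#'   `Role:Frame:Group`): `F`, `df1`, `df2`, `p`, `pes`.
#' @export
mixed_anova <- function(summaries, response = c("selfish", "equal")) {
  response <- match.arg(response)
  sc <- subject_contrasts(summaries, response)
  between <- stratum_tests(sc$c_mean, sc$group, test_main = FALSE)
  role <- stratum_tests(sc$c_role, sc$group)
  frame <- stratum_tests(sc$c_frame, sc$group)
  rf <- stratum_tests(sc$c_rf, sc$group)
  out <- rbind(
    cbind(effect = "Group", between$interaction),
    cbind(effect = "Role", role$main),
    cbind(effect = "Role:Group", role$interaction),
    cbind(effect = "Frame", frame$main),
    cbind(effect = "Frame:Group", frame$interaction),
    cbind(effect = "Role:Frame", rf$main),
    cbind(effect = "Role:Frame:Group", rf$interaction)
  )
  rownames(out) <- NULL
  out
}

#' Simple-effects comparisons for the Role x Group interaction
#'
#' Group differences within each role (averaged over frames; two-sample
#' pooled-variance comparison on per-subject role means) and role
#' differences (third minus first) within each group (paired comparison
#' on per-subject role differences).
#'
#' @param summaries Output of [aggregate_deviations()].
#' @param response `"selfish"` or `"equal"`.
#' @param bonferroni Multiply p-values by the number of comparisons.
#' @return Data frame: `contrast`, `difference`, `se`, `df`, `p`.
#' @export
posthoc_pairwise <- function(summaries, response = c("selfish", "equal"),
                             bonferroni = FALSE) {
  response <- match.arg(response)
  sc <- subject_contrasts(summaries, response)
  g <- unique(sc$group)
  if (length(g) != 2L) {
    stop("group contrasts require exactly two groups", call. = FALSE)
  }
  role_mean <- function(which) {
    if (which == "first") sc$c_mean + sc$c_role / 2
    else sc$c_mean - sc$c_role / 2
  }
  rows <- list()
  for (role in c("first", "third")) {
    y <- role_mean(role)
    y1 <- y[sc$group == g[1]]; y2 <- y[sc$group == g[2]]
    n1 <- length(y1); n2 <- length(y2)
    sp2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    diff <- mean(y1) - mean(y2)
    tval <- diff / se
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = sprintf("%s-%s @ %s", g[1], g[2], role),
      difference = diff, se = se, df = n1 + n2 - 2L,
      p = 2 * stats::pt(abs(tval), n1 + n2 - 2L, lower.tail = FALSE)
    )
  }
  for (grp in g) {
    d <- -sc$c_role[sc$group == grp]  # third minus first
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    if (se == 0) {
      stop("degenerate data: zero variance in role differences for group ",
           grp, call. = FALSE)
    }
    tval <- mean(d) / se
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = sprintf("third-first @ %s", grp),
      difference = mean(d), se = se, df = n - 1L,
      p = 2 * stats::pt(abs(tval), n - 1L, lower.tail = FALSE)
    )
  }
  out <- do.call(rbind, rows)
  if (bonferroni) out$p <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Render an ANOVA table in the conventional report format
#'
#' One line per effect: `F(df1, df2) = ..., p = ..., partial eta^2 = ...`.
#'
#' @param anova_table Output of [mixed_anova()].
#' @return Character vector (invisibly); printed to the console.
#' @export
report_anova <- function(anova_table) {
  lines <- sprintf("%-18s F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f",
                   anova_table$effect, anova_table$df1, anova_table$df2,
                   anova_table$F, anova_table$p, anova_table$pes)
  cat(lines, sep = "\n")
  invisible(lines)
}
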