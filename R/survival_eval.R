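# Prognostic evaluation: Harrell's c-index, quartile grouping,
# Kaplan-Meier estimator, log-rank test.
#
# These primitives are implemented here so their tie and boundary
# conventions are pinned explicitly; the test suite cross-checks them
# against the survival package on tie-free data.

#' Harrell's concordance index
#'
#' The fraction of comparable patient pairs in which the higher-risk
#' score belongs to the patient who fails first. A pair is comparable
#' iff the shorter observed time is an event and the times differ (equal
#' times — in particular two events at the same time — are
#' non-comparable). Tied risk scores count 0.5. For protective markers
#' such as a TIL score, set `direction = "higher_score_lower_risk"`,
#' which negates the scores.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param score Risk scores (or protective scores; see `direction`).
#' @param direction `"higher_score_higher_risk"` (default) or
#'   `"higher_score_lower_risk"`.
#' @return The concordance index in `[0, 1]`.
#' @export
#' @examples
#' concordance_index(c(2, 4, 6), c(1, 1, 1), c(3, 2, 1))  # 1: perfect
concordance_index <- function(time, event, score,
                              direction = c("higher_score_higher_risk",
                                            "higher_score_lower_risk")) {
  direction <- match.arg(direction)
  n <- length(time)
  stopifnot(length(event) == n, length(score) == n)
  if (n < 2L)
    til_error("concordance needs at least 2 records", "til_domain_error")
  risk <- if (direction == "higher_score_lower_risk") -score else score
  earlier_event <- outer(time, time, "<") & (event == 1L)  # [i, j]: i fails first
  n_comp <- sum(earlier_event)
  if (n_comp == 0L)
    til_error("no comparable pairs", "til_domain_error")
  risk_diff <- outer(risk, risk, "-")
  concordant <- sum(earlier_event & risk_diff > 0) +
    0.5 * sum(earlier_event & risk_diff == 0)
  concordant / n_comp
}

#' Quantize scores into quartile groups
#'
#' Assigns Q1-Q4 labels using the 25th/50th/75th empirical percentiles
#' (linear interpolation, the common "type 7" convention) of the scores
#' themselves, or fixed cutoffs from a reference cohort. Intervals are
#' closed on the right: Q1 = (-Inf, p25], Q2 = (p25, p50],
#' Q3 = (p50, p75], Q4 = (p75, Inf).
#'
#' @param scores Numeric scores.
#' @param cutoffs Optional numeric length-3 vector `(p25, p50, p75)`;
#'   when supplied it is applied as-is, enabling scoring of new patients
#'   against a frozen reference cohort.
#' @return A list with `labels` (factor with levels Q1-Q4) and
#'   `cutoffs` (the cutoffs used).
#' @export
#' @examples
#' quartile_groups(1:8)$labels
quartile_groups <- function(scores, cutoffs = NULL) {
  if (is.null(cutoffs)) {
    if (length(unique(scores)) < 4L)
      til_error("need >= 4 distinct scores to estimate quartile cutoffs",
                "til_domain_error")
    cutoffs <- unname(stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7))
  }
  if (length(cutoffs) != 3L || is.unsorted(cutoffs))
    til_error("cutoffs must be a sorted length-3 vector", "til_domain_error")
  labels <- cut(scores, breaks = c(-Inf, cutoffs, Inf),
                labels = paste0("Q", 1:4), right = TRUE)
  list(labels = labels, cutoffs = cutoffs)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A data.frame with one row per distinct observed time:
#'   `time`, `at_risk`, `events`, `censored`, `survival`. Survival is
#'   non-increasing with `S(0) = 1`; rows with censorings only reduce
#'   the at-risk count but leave survival unchanged.
#' @export
km_estimator <- function(time, event) {
  n <- length(time)
  stopifnot(length(event) == n)
  if (n < 1L) til_error("need at least one record", "til_domain_error")
  times <- sort(unique(time))
  at_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  events <- vapply(times, function(t) sum(time == t & event == 1L), numeric(1))
  censored <- vapply(times, function(t) sum(time == t & event == 0L), numeric(1))
  survival <- cumprod(1 - events / at_risk)
  data.frame(time = times, at_risk = at_risk, events = events,
             censored = censored, survival = survival)
}

#' Log-rank test across two or more groups
#'
#' The standard test over the pooled distinct event times: at each event
#' time the observed events per group are compared with their
#' expectation under the null of identical survival, accumulating the
#' hypergeometric covariance; the statistic is the quadratic form over
#' the first `G - 1` groups with `G - 1` degrees of freedom.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Group labels (>= 2 non-empty groups).
#' @return A list with `chi_square`, `df`, `p_value`, `observed` and
#'   `expected` per-group event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  G <- nlevels(group)
  if (G < 2L)
    til_error("log-rank test needs at least 2 groups", "til_domain_error")
  lev <- levels(group)
  times <- sort(unique(time[event == 1L]))
  O <- setNames(numeric(G), lev)
  E <- setNames(numeric(G), lev)
  V <- matrix(0, G, G, dimnames = list(lev, lev))
  for (t in times) {
    at <- time >= t
    n <- sum(at)
    d <- sum(time == t & event == 1L)
    ng <- vapply(lev, function(g) sum(at & group == g), numeric(1))
    dg <- vapply(lev, function(g) sum(time == t & event == 1L & group == g),
                 numeric(1))
    O <- O + dg
    E <- E + ng * d / n
    if (n > 1) {
      mult <- d * (n - d) / (n - 1)
      V <- V + mult * (diag(ng * n, G) - outer(ng, ng)) / n^2
    }
  }
  z <- (O - E)[-G]
  Vsub <- V[-G, -G, drop = FALSE]
  chi <- if (all(abs(z) < 1e-12)) 0 else {
    inv <- tryCatch(solve(Vsub), error = function(e) MASS::ginv(Vsub))
    as.numeric(t(z) %*% inv %*% z)
  }
  list(chi_square = chi, df = G - 1L,
       p_value = stats::pchisq(chi, df = G - 1L, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Bootstrap standard error of the concordance index
#'
#' Resamples patients with replacement and recomputes the c-index;
#' returns the standard deviation over bootstrap replicates. Used to
#' attach a Monte-Carlo uncertainty to cohort-level concordance
#' estimates.
#'
#' @param time,event,score,direction As in [concordance_index()].
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Standard error (a single number).
#' @export
concordance_se <- function(time, event, score,
                           direction = "higher_score_lower_risk",
                           n_boot = 200L, seed = 1L) {
  n <- length(time)
  cs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(concordance_index(time[idx], event[idx], score[idx], direction),
               til_error = function(e) NA_real_)
    }, numeric(1))
  })
  stats::sd(cs, na.rm = TRUE)
}
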