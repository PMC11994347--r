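# Concordance, quartiles, Kaplan-Meier, log-rank.

test_that("concordance matches hand-worked and degenerate cases", {
  # perfect ranking: shorter survivors have higher risk
  expect_equal(concordance_index(c(2, 4, 6), c(1, 1, 1), c(3, 2, 1)), 1)
  # 4-subject case: 4 comparable pairs, 3 concordant
  expect_equal(concordance_index(c(2, 3, 5, 8), c(1, 0, 1, 1),
                                 c(3.0, 1.0, 0.5, 2.0)), 0.75)
  expect_error(concordance_index(c(1, 2), c(0, 0), c(1, 2)),
               class = "til_domain_error")
  expect_error(concordance_index(1, 1, 1), class = "til_domain_error")
})

test_that("concordance equals the brute-force oracle on random cohorts", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      n <- sample(3:50, 1)
      time <- round(rexp(n, 0.2), 2)
      event <- rbinom(n, 1, 0.7)
      score <- round(rnorm(n), 1)  # rounding induces score ties
    })
    oracle <- tryCatch(bf_cindex(time, event, score), error = function(e) NULL)
    if (is.null(oracle)) next
    expect_identical(concordance_index(time, event, score), oracle)
    # direction flag negates; antisymmetry when scores are tie-free
    expect_equal(concordance_index(time, event, score,
                                   "higher_score_lower_risk"),
                 bf_cindex(time, event, -score))
  }
  withr::with_seed(500, {
    time <- rexp(30); event <- rbinom(30, 1, 0.8); score <- rnorm(30)
  })
  expect_equal(concordance_index(time, event, score) +
                 concordance_index(time, event, -score), 1)
})

test_that("concordance agrees with the survival package on tie-free data", {
  skip_if_not_installed("survival")
  withr::with_seed(77, {
    time <- rexp(80); event <- rbinom(80, 1, 0.6); score <- rnorm(80)
  })
  ours <- concordance_index(time, event, score)
  ref <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)$concordance
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("quartile grouping pins the type-7 percentile convention", {
  qg <- quartile_groups(1:8)
  expect_equal(as.character(qg$labels),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  expect_equal(qg$cutoffs, c(2.75, 4.5, 6.25))
  # fixed reference cutoffs applied as-is
  fixed <- quartile_groups(c(0.1, 0.2, 0.3), cutoffs = c(10, 20, 30))
  expect_true(all(fixed$labels == "Q1"))
  # boundary: a score equal to a cutoff falls in the lower group
  expect_equal(as.character(quartile_groups(c(2.75, 2.76),
                                            cutoffs = c(2.75, 4.5, 6.25))$labels),
               c("Q1", "Q2"))
  # rank invariance under monotone transforms
  withr::with_seed(9, s <- runif(40))
  expect_equal(table(quartile_groups(s)$labels),
               table(quartile_groups(exp(4 * s))$labels))
  expect_error(quartile_groups(c(1, 1, 1, 2)), class = "til_domain_error")
})

test_that("Kaplan-Meier reduces to the empirical survival without censoring", {
  km <- km_estimator(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  withr::with_seed(10, time <- sort(sample(1:100, 25)))
  km2 <- km_estimator(time, rep(1L, 25))
  emp <- vapply(km2$time, function(t) mean(time > t), numeric(1))
  expect_equal(km2$survival, emp)
})

test_that("censoring changes at-risk counts but not survival", {
  expect_true(all(km_estimator(c(1, 2, 3), c(0, 0, 0))$survival == 1))
  km <- km_estimator(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))
  # oracle cross-check on a censored cohort
  withr::with_seed(11, {
    time <- round(rexp(40, 0.3), 1); event <- rbinom(40, 1, 0.6)
  })
  expect_equal(km_estimator(time, event)$survival, bf_km(time, event))
})

test_that("Kaplan-Meier agrees with survfit", {
  skip_if_not_installed("survival")
  withr::with_seed(13, {
    time <- round(rexp(60, 0.3), 1); event <- rbinom(60, 1, 0.5)
  })
  km <- km_estimator(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km$survival, summary(fit, times = km$time)$surv,
               tolerance = 1e-12)
})

test_that("log-rank: identical groups give statistic 0, p = 1", {
  time <- rep(c(1, 2, 3, 5), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  lr <- logrank_test(time, event, rep(c("a", "b"), each = 4))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(time, event, rep("a", 8)),
               class = "til_domain_error")
})

test_that("log-rank matches a hand O-E/V tabulation on separated groups", {
  # group A fails at 1..10, group B at 11..20, no censoring
  time <- c(1:10, 11:20)
  event <- rep(1L, 20)
  group <- rep(c("A", "B"), each = 10)
  lr <- logrank_test(time, event, group)
  O <- c(10, 10)
  E <- c(0, 0); V <- 0
  for (t in 1:20) {
    n <- sum(time >= t)
    nA <- sum(time >= t & group == "A")
    E[1] <- E[1] + nA / n
    E[2] <- E[2] + (n - nA) / n
    if (n > 1) V <- V + (n - 1) / (n - 1) * nA * (n - nA) / n^2
  }
  expect_equal(unname(lr$observed), O)
  expect_equal(unname(lr$expected), E)
  expect_equal(lr$chi_square, (O[1] - E[1])^2 / V)
  expect_lt(lr$p_value, 1e-4)
})

test_that("log-rank agrees with survdiff, including three groups", {
  skip_if_not_installed("survival")
  withr::with_seed(19, {
    time <- round(rexp(90, rep(c(0.1, 0.2, 0.3), each = 30)), 2)
    event <- rbinom(90, 1, 0.7)
  })
  group <- rep(c("a", "b", "c"), each = 30)
  lr <- logrank_test(time, event, group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-9)
  expect_equal(lr$df, 2L)
})

test_that("the log-rank chi-square is calibrated against a permutation oracle", {
  withr::with_seed(21, {
    n <- 40
    g <- rep(c("A", "B"), each = n / 2)
    tm <- rexp(n, rate = ifelse(g == "A", 0.12, 0.2))
    ev <- as.integer(runif(n) < 0.8)
    obs <- logrank_test(tm, ev, g)
    perm <- replicate(1000, logrank_test(tm, ev, sample(g))$chi_square)
  })
  p_perm <- mean(perm >= obs$chi_square)
  expect_lt(abs(p_perm - obs$p_value), 0.05)
})

test_that("bootstrap concordance SE is positive and shrinks with cohort size", {
  co <- generate_cohort(120, seed = 3)
  sv <- co$survival
  se_small <- concordance_se(sv$time[1:40], sv$event[1:40],
                             sv$true_density[1:40], n_boot = 100, seed = 1)
  se_large <- concordance_se(sv$time, sv$event, sv$true_density,
                             n_boot = 100, seed = 1)
  expect_gt(se_small, 0)
  expect_lt(se_large, se_small)
})
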