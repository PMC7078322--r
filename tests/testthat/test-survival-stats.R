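# A reproducible random cohort for cross-checks against the survival
# package.
random_cohort <- function(n, seed, ties = FALSE) {
  set.seed(seed)
  tibble::tibble(
    os = if (ties) sample(1:8, n, replace = TRUE) else rexp(n, 0.1) + 0.01,
    death = rbinom(n, 1, 0.7),
    x = rnorm(n),
    grp = rbinom(n, 1, 0.5)
  )
}

test_that("KM with no censoring equals the empirical survival function", {
  df <- tibble::tibble(os = c(1, 2, 3), death = 1)
  fit <- km_estimate(df, os, death)
  expect_equal(tidy(fit)$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(glance(fit)$median_os, 2)
  # Property at larger n: survival at t equals the fraction surviving past t.
  set.seed(1)
  times <- round(rexp(60, 0.1) + 0.5, 1)
  df2 <- tibble::tibble(os = times, death = 1)
  steps <- tidy(km_estimate(df2, os, death))
  expect_equal(steps$survival,
               vapply(steps$time, function(x) mean(times > x), numeric(1)))
})

test_that("KM handles censoring with the events-first tie convention", {
  df <- tibble::tibble(os = c(1, 2, 3), death = c(1, 0, 1))
  steps <- tidy(km_estimate(df, os, death))
  expect_equal(steps$survival[steps$time == 1], 2 / 3)
  expect_equal(steps$survival[steps$time == 3], 0)
  expect_equal(steps$n_risk[steps$time == 3], 1)
  # Event and censoring tied at t = 2: the event uses the full risk set.
  df_tie <- tibble::tibble(os = c(1, 2, 2, 3), death = c(1, 1, 0, 1))
  steps_tie <- tidy(km_estimate(df_tie, os, death))
  expect_equal(steps_tie$survival[steps_tie$time == 2], 3 / 4 * 2 / 3)
})

test_that("KM with everyone censored stays at 1 with median not reached", {
  df <- tibble::tibble(os = c(1, 2, 3), death = 0)
  fit <- km_estimate(df, os, death)
  expect_true(all(tidy(fit)$survival == 1))
  expect_true(is.na(glance(fit)$median_os))
  expect_error(km_estimate(df[0, ], os, death), "Empty")
})

test_that("grouped KM matches survival::survfit on a random cohort", {
  df <- random_cohort(80, 5)
  fit <- km_estimate(df, os, death, grp)
  sf <- survival::survfit(survival::Surv(os, death) ~ grp, data = df)
  ours <- tidy(fit)
  ref <- summary(sf)
  for (g in c(0, 1)) {
    m <- ours[ours$group == g & ours$n_event > 0, ]
    r <- data.frame(time = ref$time, surv = ref$surv,
                    grp = as.numeric(sub("grp=", "", ref$strata)))
    r <- r[r$grp == g, ]
    expect_equal(m$time, r$time)
    expect_equal(m$survival, r$surv, tolerance = 1e-12)
  }
})

test_that("log-rank matches the hand-computed two-group fixture", {
  df <- tibble::tibble(os = c(1, 2, 3, 4), death = 1,
                       arm = c("a", "a", "b", "b"))
  res <- logrank_test(df, os, death, arm)
  # Per-time O-E and variance sums: (0.5 + 0.6667)^2 / (0.25 + 0.2222).
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(res$df, 1L)
})

test_that("log-rank is zero for identical groups and label-symmetric", {
  df <- tibble::tibble(os = rep(c(1, 3, 5, 8), 2), death = 1,
                       arm = rep(c("a", "b"), each = 4))
  res <- logrank_test(df, os, death, arm)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  df2 <- random_cohort(60, 9)
  swapped <- dplyr::mutate(df2, grp = 1 - grp)
  expect_equal(logrank_test(df2, os, death, grp)$statistic,
               logrank_test(swapped, os, death, grp)$statistic)
  expect_error(logrank_test(dplyr::mutate(df2, grp = 1), os, death, grp),
               "2 groups")
})

test_that("log-rank agrees with survival::survdiff, with and without ties", {
  for (ties in c(FALSE, TRUE)) {
    df <- random_cohort(90, if (ties) 13 else 12, ties = ties)
    ours <- logrank_test(df, os, death, grp)$statistic
    ref <- survival::survdiff(survival::Surv(os, death) ~ grp,
                              data = df)$chisq
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("log-rank equals the Cox score test at beta = 0 without ties", {
  df <- random_cohort(70, 21)
  lr <- logrank_test(df, os, death, grp)$statistic
  score <- tdevtools:::cox_score_test(df$os, df$death, df$grp)
  expect_equal(lr, score, tolerance = 1e-8)
})

test_that("Cox estimates agree with a dense grid-search oracle on small fixtures", {
  fixtures <- list(
    list(t = c(1, 2, 3, 4), d = c(1, 1, 1, 1), x = c(1, 0, 1, 0)),
    list(t = c(2, 4, 1, 7, 5), d = c(1, 0, 1, 1, 1), x = c(0, 1, 1, 0, 1)),
    list(t = c(3, 1, 4, 1, 5, 9), d = c(1, 1, 0, 1, 1, 0),
         x = c(0.2, 1.5, -0.3, 0.8, -1, 0.5)),
    list(t = c(1, 2, 3, 4, 5, 6, 7, 8), d = c(1, 0, 1, 1, 0, 1, 1, 1),
         x = c(1, 1, 0, 1, 0, 0, 1, 0))
  )
  for (fx in fixtures) {
    df <- tibble::tibble(os = fx$t, death = fx$d, x = fx$x)
    fit <- cox_fit(df, os, death, x)
    oracle <- cox_grid_oracle(fx$t, fx$d, fx$x)
    expect_lt(abs(fit$coef[["x"]] - oracle), 1e-3)
  }
  # The worked 4-subject example: beta-hat ~ 0.940, HR ~ 2.56.
  fit4 <- cox_fit(tibble::tibble(os = 1:4, death = 1, x = c(1, 0, 1, 0)),
                  os, death, x)
  expect_equal(fit4$coef[["x"]], 0.9406, tolerance = 1e-3)
  expect_equal(fit4$hr[[1]], 2.5615, tolerance = 1e-3)
})

test_that("Cox symmetry and scale equivariance hold", {
  # Two groups with identical event-time multisets: beta = 0, HR = 1.
  df <- tibble::tibble(os = rep(c(2, 5, 9), 2), death = 1,
                       x = rep(c(0, 1), each = 3))
  fit <- cox_fit(df, os, death, x)
  expect_equal(fit$coef[["x"]], 0, tolerance = 1e-8)
  expect_equal(fit$hr[[1]], 1, tolerance = 1e-8)
  # Scaling the covariate by 10 scales beta by 1/10.
  df2 <- random_cohort(50, 33)
  f1 <- cox_fit(df2, os, death, x)
  f2 <- cox_fit(dplyr::mutate(df2, x = 10 * x), os, death, x)
  expect_equal(f2$coef[["x"]], f1$coef[["x"]] / 10, tolerance = 1e-7)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-9)
})

test_that("Cox matches survival::coxph for Breslow and Efron ties", {
  df <- random_cohort(120, 44, ties = TRUE)
  for (method in c("breslow", "efron")) {
    ours <- cox_fit(df, os, death, x, ties = method)
    ref <- survival::coxph(survival::Surv(os, death) ~ x, data = df,
                           ties = method)
    expect_equal(ours$coef[["x"]], unname(coef(ref)), tolerance = 1e-6)
    expect_equal(ours$se[["x"]], sqrt(vcov(ref)[1, 1]), tolerance = 1e-6)
    expect_equal(ours$loglik, ref$loglik[2], tolerance = 1e-6)
  }
  # Multivariable agreement.
  df$z <- rbinom(nrow(df), 1, 0.4)
  ours <- cox_fit(df, os, death, c(x, z))
  ref <- survival::coxph(survival::Surv(os, death) ~ x + z, data = df,
                         ties = "breslow")
  expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-6)
})

test_that("separation is flagged rather than silently reported", {
  # Perfectly separated groups: everyone with x = 1 dies first.
  df <- tibble::tibble(os = c(1, 2, 3, 10, 11, 12), death = 1,
                       x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(df, os, death, x)
  expect_true(fit$monotone)
  expect_false(fit$converged)
  expect_error(cox_fit(dplyr::mutate(df, x = 1), os, death, x), "constant")
  expect_error(cox_fit(dplyr::mutate(df, death = 0), os, death, x),
               "at least one event")
})

test_that("tidy and glance expose broom-style Cox output", {
  df <- random_cohort(60, 55)
  fit <- cox_fit(df, os, death, x)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "hr", "conf.low", "conf.high"))
  expect_true(td$conf.low < td$hr & td$hr < td$conf.high)
  expect_gt(td$hr, 0)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 60)
})

test_that("stepwise selection keeps a strong predictor and drops its duplicate", {
  set.seed(61)
  n <- 500
  x <- rnorm(n)
  noise <- rnorm(n)
  t_true <- rexp(n, 0.05 * exp(1 * x))
  df <- tibble::tibble(os = pmin(t_true, 30),
                       death = as.integer(t_true <= 30),
                       x = x, x_dup = x, noise = noise)
  res <- stepwise_cox(df, os, death, c(x, x_dup, noise))
  expect_true("x" %in% res$selected)
  expect_false("x_dup" %in% res$selected)   # zero incremental likelihood
})

test_that("stepwise with pure-noise candidates selects nothing most of the time", {
  empty <- vapply(1:40, function(i) {
    set.seed(700 + i)
    n <- 120
    df <- tibble::tibble(os = rexp(n, 0.1), death = rbinom(n, 1, 0.8),
                         a = rnorm(n), b = rnorm(n))
    length(stepwise_cox(df, os, death, c(a, b))$selected) == 0
  }, logical(1))
  # Roughly (1 - 0.05)^2 of replicates should end empty.
  expect_gte(mean(empty), 0.75)
})

test_that("Spearman matches the mid-rank fixture and is antisymmetric", {
  df <- tibble::tibble(x = c(1, 2, 2, 4), y = c(1, 3, 2, 4))
  res <- spearman_rho(df, x, y)
  expect_equal(res$estimate, 4.5 / sqrt(4.5 * 5), tolerance = 1e-12)
  expect_equal(spearman_rho(tibble::tibble(x = 1:5, y = 2 * (1:5)), x, y)$estimate, 1)
  flipped <- spearman_rho(dplyr::mutate(df, y = -y), x, y)
  expect_equal(flipped$estimate, -res$estimate)
  expect_error(spearman_rho(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "rank variance")
  # Against the base implementation on a random fixture.
  set.seed(3)
  big <- tibble::tibble(x = rpois(40, 5), y = rpois(40, 5) + rpois(40, 2))
  expect_equal(spearman_rho(big, x, y)$estimate,
               unname(cor(big$x, big$y, method = "spearman")),
               tolerance = 1e-12)
})

test_that("Mann-Whitney U matches exact enumeration on small samples", {
  df <- tibble::tibble(v = c(1, 2, 3, 4), g = c("x", "x", "y", "y"))
  res <- mann_whitney_u(df, v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)      # enumeration of all 6 orderings
  expect_equal(res$p_value, mwu_enum_oracle(c(1, 2), c(3, 4)))
  set.seed(4)
  x <- rnorm(5); y <- rnorm(6) + 0.5
  df2 <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), c(5, 6)))
  expect_equal(mann_whitney_u(df2, v, g)$p_value, mwu_enum_oracle(x, y),
               tolerance = 1e-12)
  # Identical samples: U = n1 n2 / 2.
  df3 <- tibble::tibble(v = rep(c(1, 2, 3), 2),
                        g = rep(c("a", "b"), each = 3))
  expect_equal(mann_whitney_u(df3, v, g)$statistic, 9 / 2)
})

test_that("Wilcoxon signed-ranks handles shifts, ties and zero differences", {
  df <- tibble::tibble(a = (1:6) + 0.5, b = as.numeric(1:6))
  res <- wilcoxon_signed_ranks(df, a, b)
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64)     # all-positive sign pattern of 2^6
  expect_warning(
    zero <- wilcoxon_signed_ranks(tibble::tibble(a = 1:4, b = 1:4), a, b),
    "zero"
  )
  expect_equal(zero$p_value, 1)
  # Large tied sample: agrees with the base implementation's normal path.
  set.seed(6)
  df2 <- tibble::tibble(a = rpois(60, 10), b = rpois(60, 8))
  df2 <- df2[df2$a != df2$b, ]
  ref <- wilcox.test(df2$a, df2$b, paired = TRUE, correct = TRUE)
  expect_equal(wilcoxon_signed_ranks(df2, a, b)$p_value, ref$p.value,
               tolerance = 1e-6)
})

test_that("AUC equals the normalised U statistic and handles ties", {
  df <- tibble::tibble(s = c(2, 1, 3, 4), l = c(0, 1, 0, 1))
  expect_equal(glance(roc_auc(df, s, l))$auc, 0.5)   # 2 of 4 concordant pairs
  perfect <- tibble::tibble(s = c(1, 2, 10, 11), l = c(0, 0, 1, 1))
  expect_equal(glance(roc_auc(perfect, s, l))$auc, 1)
  flat <- tibble::tibble(s = rep(1, 6), l = rep(c(0, 1), 3))
  expect_equal(glance(roc_auc(flat, s, l))$auc, 0.5)
  # AUC = U / (n1 n2) identity on a random fixture, pairs counted directly.
  set.seed(7)
  rand <- tibble::tibble(s = rpois(30, 4), l = rbinom(30, 1, 0.4))
  pos <- rand$s[rand$l == 1]; neg <- rand$s[rand$l == 0]
  pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  expect_equal(glance(roc_auc(rand, s, l))$auc, mean(pairs), tolerance = 1e-12)
  expect_error(roc_auc(tibble::tibble(s = 1:3, l = 1), s, l), "classes")
})

test_that("dichotomisation uses the count >= cutoff convention", {
  df <- tibble::tibble(tdev = c(0, 4, 5, 19, 20, 100))
  expect_equal(dichotomize(df, tdev, 20)$unfavourable,
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  ctc <- tibble::tibble(n = c(0, 4, 5))
  expect_equal(dichotomize(ctc, n, 5)$unfavourable, c(FALSE, FALSE, TRUE))
  expect_true(all(dichotomize(df, tdev, 0)$unfavourable))
})

test_that("binning is left-closed right-open with an open top bin", {
  df <- tibble::tibble(tdev = c(0, 4, 5, 19, 20, 99, 100, 400))
  binned <- bin_groups(df, tdev, c(5, 20, 100))
  expect_equal(as.integer(binned$count_bin), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_equal(levels(binned$count_bin),
               c("[0,5)", "[5,20)", "[20,100)", "[100,Inf)"))
  expect_error(bin_groups(df, tdev, c(5, 5)), "increasing")
})
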