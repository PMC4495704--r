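test_that("the c-statistic counts concordant pairs with half ties", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2),
                           c(1, 1, 0, 0))$estimate, 1)
  expect_equal(c_statistic(rep(0.4, 10), rep(c(0, 1), 5))$estimate, 0.5)
  expect_equal(c_statistic(c(0.1, 0.4, 0.35, 0.8),
                           c(0, 0, 1, 1))$estimate, 0.75)
  expect_error(c_statistic(c(0.1, 0.2), c(1, 1)), "both outcome")
})

test_that("the c-statistic equals brute-force pair counting and is
           rank-invariant", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(50:300, 1)
    p <- round(runif(n), 2)  # ties on purpose
    y <- rbinom(n, 1L, p)
    if (length(unique(y)) < 2L) next
    auc <- c_statistic(p, y)$estimate
    expect_equal(auc, bruteforce_auc(p, y), tolerance = 1e-12)
    # strictly increasing transforms leave it unchanged
    expect_equal(c_statistic(plogis(5 * p - 2), y)$estimate, auc,
                 tolerance = 1e-12)
  }
  # DeLong interval brackets the estimate
  p <- runif(500); y <- rbinom(500, 1L, p)
  cs <- c_statistic(p, y)
  expect_true(cs$ci[1] <= cs$estimate && cs$estimate <= cs$ci[2])
})

test_that("IDI is the difference in discrimination slopes", {
  y <- c(0, 0, 1, 1)
  p_old <- c(0.2, 0.2, 0.6, 0.6)
  p_new <- c(0.1, 0.3, 0.5, 0.9)
  res <- idi(p_new, p_old, y)
  expect_equal(res$slope_new, 0.5)
  expect_equal(res$slope_old, 0.4)
  expect_equal(res$estimate, 0.1, tolerance = 1e-12)

  # identity and antisymmetry
  expect_equal(idi(p_old, p_old, y)$estimate, 0)
  expect_equal(idi(p_old, p_new, y)$estimate, -res$estimate,
               tolerance = 1e-12)
  expect_error(idi(p_new[-1], p_old, y), "length")
})

test_that("omega is the ratio of group contribution variances", {
  set.seed(23)
  n <- 800L
  dat <- data.frame(a = rnorm(n), b = rnorm(n))
  dat$death <- rbinom(n, 1L, plogis(-1 + 0.8 * dat$a + 0.5 * dat$b))
  fit <- fit_mortality_model(dat, c("a", "b"))
  om <- omega_statistic(fit, "a", "b", n_boot = 0L)
  beta <- coef(fit)
  expect_equal(om$estimate,
               var(beta[["a"]] * dat$a) / var(beta[["b"]] * dat$b),
               tolerance = 1e-12)
  # reciprocal identity
  rev <- omega_statistic(fit, "b", "a", n_boot = 0L)
  expect_equal(om$estimate * rev$estimate, 1, tolerance = 1e-12)
  # grouped categorical terms expand to their dummies
  dat$g <- factor(sample(c("u", "v", "w"), n, replace = TRUE))
  fit2 <- fit_mortality_model(dat, c("a", "b", "g"))
  om2 <- omega_statistic(fit2, c("a", "g"), "b", n_boot = 0L)
  expect_true(is.finite(om2$estimate) && om2$estimate > 0)
  expect_error(omega_statistic(fit, "a", "a", n_boot = 0L), "disjoint")
  expect_error(omega_statistic(fit, character(), "a", n_boot = 0L),
               "non-empty")
})

test_that("the omega bootstrap interval is seeded and ordered", {
  set.seed(29)
  n <- 400L
  dat <- data.frame(a = rnorm(n), b = rnorm(n))
  dat$death <- rbinom(n, 1L, plogis(-1 + 0.7 * dat$a + 0.7 * dat$b))
  fit <- fit_mortality_model(dat, c("a", "b"))
  o1 <- omega_statistic(fit, "a", "b", n_boot = 30L, seed = 4L)
  o2 <- omega_statistic(fit, "a", "b", n_boot = 30L, seed = 4L)
  expect_equal(o1, o2)
  expect_lt(o1$ci[1], o1$ci[2])
})

test_that("Hosmer-Lemeshow groups conserve expected totals", {
  set.seed(37)
  n <- 100000L
  p <- plogis(rnorm(n, -2, 1))
  y <- rbinom(n, 1L, p)
  hl <- hosmer_lemeshow(p, y, g = 10L)
  expect_equal(nrow(hl), 10L)
  expect_equal(sum(hl$expected), sum(p), tolerance = 1e-9)
  expect_equal(sum(hl$n), n)
  expect_equal(sum(hl$observed), sum(y))
  # calibrated by construction: observed tracks expected per decile
  # (binomial 4-sigma bound per group)
  expect_true(all(abs(hl$observed - hl$expected) <
                    4 * sqrt(hl$n * hl$mean_p * (1 - hl$mean_p)) + 1))
  expect_true(all(abs(hl$observed - hl$expected) / hl$n < 0.02))

  # one group degenerates to the overall totals
  hl1 <- hosmer_lemeshow(p[1:100], y[1:100], g = 1L)
  expect_equal(hl1$n, 100L)
  expect_equal(hl1$observed, sum(y[1:100]))
  expect_error(hosmer_lemeshow(p[1:5], y[1:5], g = 10L), "at least")
})

test_that("index-value calibration merges sparse extreme values", {
  set.seed(41)
  idx <- c(sample(0:3, 970, replace = TRUE), rep(c(10L, 11L, 12L),
                                                 each = 4L))
  y <- rbinom(length(idx), 1L, 0.1)
  need <- ceiling(0.01 * length(idx))
  cb <- calibration_by_index(idx, y, min_fraction = 0.01)
  expect_true(all(cb$n >= need))
  top <- cb[nrow(cb), ]
  expect_equal(top$label, "10-12")
  expect_equal(top$n, 12L)

  # already-dense values stay unmerged
  idx2 <- rep(0:3, each = 50)
  cb2 <- calibration_by_index(idx2, rbinom(200, 1L, 0.2))
  expect_equal(cb2$label, as.character(0:3))
  # postcondition: every bin holds at least the minimum fraction
  expect_true(all(cb2$n >= 2))
  # Wald intervals bracket the observed rate
  expect_true(all(cb2$ci_low <= cb2$obs_rate &
                    cb2$obs_rate <= cb2$ci_high))
})

test_that("the validation battery is deterministic and ranks the models
           sensibly", {
  cohort <- shared_synth()
  feats <- extract_features(cohort)
  sub <- feats[1:12000, ]
  attr(sub, "feature_names") <- attr(feats, "feature_names")
  cons <- resolve_groups(sub,
                         lapply(default_group_policies(), `[[`,
                                "members"),
                         default_group_policies())$features
  rep1 <- run_validation(cons, published_index(), n_boot = 10L,
                         seed = 8L)
  rep2 <- run_validation(cons, published_index(), n_boot = 10L,
                         seed = 8L)
  expect_equal(rep1$c, rep2$c)
  expect_equal(rep1$omega, rep2$omega)

  # the index adds discrimination over demographics + CCI alone
  expect_gt(rep1$c$model4$estimate, rep1$c$model3$estimate)
  expect_gt(rep1$idi$estimate, 0)
  expect_equal(sum(rep1$hosmer_lemeshow$n), nrow(cons))
  expect_true(all(c("model1", "model2", "model3", "model4") %in%
                    names(rep1$c)))
})

test_that("subgroup analyses skip single-outcome strata with a warning", {
  cohort <- shared_synth()
  feats <- extract_features(cohort)
  sub <- feats[1:8000, ]
  attr(sub, "feature_names") <- attr(feats, "feature_names")
  cons <- resolve_groups(sub,
                         lapply(default_group_policies(), `[[`,
                                "members"),
                         default_group_policies())$features
  cons$odd_stratum <- c("rare", rep("common", nrow(cons) - 1L))
  expect_warning(
    rep_ <- run_validation(cons, published_index(),
                           subgroups = "odd_stratum", n_boot = 0L),
    "single outcome class")
  expect_true("odd_stratum=common" %in% names(rep_$subgroups))
  expect_false("odd_stratum=rare" %in% names(rep_$subgroups))
})
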