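test_that("rounding goes to the nearest integer, halves away from zero", {
  expect_equal(round_half_away(c(2.49, 2.5, 2.51, -2.49, -2.5, 0.4,
                                 -0.4, 0)),
               c(2L, 3L, 3L, -2L, -3L, 0L, 0L, 0L))
})

test_that("the reference coefficient follows the CCI = 1 gate", {
  # CCI = 1 not significant: half the CCI = 2 coefficient
  fit <- fake_fit(c("cci_category1", "cci_category2"),
                  c(0.03, 0.182), c(0.233, 1e-5))
  expect_equal(reference_coefficient(fit), 0.091)
  # CCI = 1 significant: its own coefficient
  fit2 <- fake_fit(c("cci_category1", "cci_category2"),
                   c(0.10, 0.182), c(0.001, 1e-5))
  expect_equal(reference_coefficient(fit2), 0.10)
  # neither significant: no anchor is defined
  fit3 <- fake_fit(c("cci_category1", "cci_category2"),
                   c(0.03, 0.05), c(0.4, 0.3))
  expect_error(reference_coefficient(fit3), "reference")
  # missing terms are reported
  expect_error(reference_coefficient(fake_fit("x", 1, 0.01)),
               "cci_category1")
})

test_that("points are the Sullivan quotients gated on significance", {
  fit <- fake_fit(
    c("intubation", "acid_fast", "sputum", "blood"),
    c(2.05, -0.04, 1.11, -0.26), c(1e-9, 0.206, 1e-9, 1e-9))
  pts <- assign_points(fit, 0.091,
                       procedure_terms = c("intubation", "acid_fast",
                                           "sputum", "blood"))
  expect_equal(pts[["intubation"]], 23L)
  expect_equal(pts[["sputum"]], 12L)
  expect_equal(pts[["blood"]], -3L)
  expect_false("acid_fast" %in% names(pts))
  # an exact .5 quotient rounds away from zero (1.25 / 0.5 = 2.5)
  half <- assign_points(fake_fit(c("h", "hn"), c(1.25, -1.25),
                                 c(0.01, 0.01)),
                        0.5, c("h", "hn"))
  expect_equal(half[["h"]], 3L)
  expect_equal(half[["hn"]], -3L)
})

test_that("point assignment is invariant to rescaling beta and the
           anchor together", {
  set.seed(13)
  for (i in 1:20) {
    beta <- runif(6, -2, 3)
    ref <- runif(1, 0.05, 0.3)
    cc <- runif(1, 0.1, 10)
    fit1 <- fake_fit(letters[1:6], beta, rep(1e-6, 6))
    fit2 <- fake_fit(letters[1:6], cc * beta, rep(1e-6, 6))
    p1 <- assign_points(fit1, ref, letters[1:6])
    p2 <- assign_points(fit2, cc * ref, letters[1:6])
    expect_equal(names(p1), names(p2))
    expect_equal(as.integer(p1), as.integer(p2))
  }
})

test_that("the published point table matches its printed summaries", {
  pt <- published_index()
  expect_length(pt, 19L)
  expect_equal(index_range(pt), c(min = -13L, max = 69L))
  expect_equal(pt[["sputum_suction"]], 12L)
  expect_equal(pt[["urinary_catheter_insertion"]], 5L)
  expect_equal(pt[["intratracheal_intubation"]], 23L)
  expect_equal(attr(pt, "reference_coefficient"), 0.091)
})

test_that("index scoring is an additive sum of day-0 procedure points", {
  pt <- published_index()
  none <- data.frame(intratracheal_intubation = 0L)
  expect_warning(s0 <- score_index(none, pt), "treated as 0")
  expect_equal(s0, 0L)

  all_cols <- as.data.frame(as.list(setNames(rep(1L, 19),
                                             names(pt))))
  pos_only <- all_cols
  pos_only[names(pt)[unclass(pt) < 0]] <- 0L
  expect_equal(score_index(pos_only, pt), 69L)

  mixed <- all_cols
  mixed[] <- 0L
  mixed[c("computed_tomography", "pulse_oximetry",
          "blood_tests_excl_coagulation", "radiography")] <- 1L
  expect_equal(score_index(mixed, pt), 3L + 3L - 3L - 2L)

  # additivity over disjoint procedure sets
  set.seed(3)
  for (i in 1:20) {
    pick <- sample(c(TRUE, FALSE), 19, replace = TRUE)
    a <- all_cols; a[] <- as.integer(pick)
    b <- all_cols; b[] <- as.integer(!pick)
    expect_equal(score_index(a, pt) + score_index(b, pt),
                 score_index(all_cols, pt))
  }
})

test_that("index_range splits negative and positive point sums", {
  expect_equal(index_range(point_table(integer())), c(min = 0L, max = 0L))
  expect_equal(index_range(point_table(c(a = -2L, b = 5L, c = 7L))),
               c(min = -2L, max = 12L))
})

test_that("point tables serialise to JSON and back", {
  pt <- published_index()
  path <- withr::local_tempfile(fileext = ".json")
  write_point_table(pt, path)
  back <- read_point_table(path)
  expect_equal(unclass(back)[names(pt)], unclass(pt)[names(pt)])
  expect_equal(attr(back, "reference_coefficient"), 0.091)
})

test_that("the logistic fit rejects degenerate designs", {
  feats <- make_features(n = 300L, p = c(f1 = 0.4))
  feats$f2 <- feats$f1
  expect_error(fit_mortality_model(feats, c("f1", "f2")), "aliased")
  feats$const <- 1L
  expect_error(fit_mortality_model(feats, c("f1", "const")), "constant")
  expect_error(fit_mortality_model(feats, c("f1", "nope")), "nope")
})

test_that("the logistic fit recovers known coefficients", {
  set.seed(77)
  n <- 20000L
  x1 <- rbinom(n, 1L, 0.3)
  x2 <- rbinom(n, 1L, 0.6)
  lp <- -2 + 0.8 * x1 - 0.4 * x2
  dat <- data.frame(death = rbinom(n, 1L, plogis(lp)), x1 = x1, x2 = x2)
  fit <- fit_mortality_model(dat, c("x1", "x2"))
  cf <- fit$coefficients
  for (row in list(c("x1", 0.8), c("x2", -0.4))) {
    est <- cf[cf$term == row[1], ]
    expect_lt(abs(est$estimate - as.numeric(row[2])), 3 * est$se)
    expect_equal(est$or, exp(est$estimate))
    expect_equal(est$ci_low, exp(est$estimate - 1.96 * est$se))
  }
  expect_equal(fit$n, n)
})

test_that("a null covariate's P value is approximately uniform", {
  set.seed(101)
  ps <- replicate(60, {
    n <- 400L
    dat <- data.frame(death = rbinom(n, 1L, 0.3),
                      noise = rbinom(n, 1L, 0.5))
    fit <- fit_mortality_model(dat, "noise")
    fit$coefficients$p[fit$coefficients$term == "noise"]
  })
  # mean of Uniform(0,1) is 0.5 with sd 1/sqrt(12 * 60) ~ 0.037
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lte(sum(ps < 0.05), qbinom(0.999, 60, 0.05) + 2)
})
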