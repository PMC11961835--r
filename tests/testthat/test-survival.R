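test_that("product-limit estimates match hand-enumerated risk sets", {
  k <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k$table$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(k$table$n_risk, c(3, 2, 1))

  expect_equal(km_fit(c(2, 5, 9), c(0, 0, 0))$table$survival, rep(1, 3))
  expect_equal(km_fit(4, 1)$table$survival, 0)
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
  expect_error(km_fit(c(-1, 2), c(1, 0)), "non-negative")
})

test_that("KM equals the risk-set oracle on random small samples", {
  for (seed in 1:100) {
    dat <- cshpet:::with_seed(seed, {
      n <- sample(1:12, 1)
      list(t = sample(1:6, n, replace = TRUE) + round(runif(n), 2),
           e = rbinom(n, 1, 0.6))
    })
    got <- km_fit(dat$t, dat$e)$table
    want <- oracle_km(dat$t, dat$e)
    expect_lt(max(abs(got$survival - want$survival)), 1e-12)
    # independent cross-check against the survival package
    sf <- survival::survfit(survival::Surv(dat$t, dat$e) ~ 1)
    ref <- summary(sf, times = got$time, extend = TRUE)$surv
    expect_lt(max(abs(got$survival - ref)), 1e-12)
  }
})

test_that("step lookup gives 2-year survival and warns on extrapolation", {
  k <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(survival_at(k, 2.5), 2 / 3)
  expect_identical(survival_at(k, 0), 1)
  expect_identical(survival_at(k, 0.5), 1)   # before the first event
  expect_warning(last <- survival_at(k, 10), "beyond last follow-up")
  expect_equal(last, 0)
  expect_error(survival_at(k, -1), "non-negative")
})

test_that("log-rank is zero for identical groups and matches the oracle", {
  t6 <- c(1, 2, 3, 1, 2, 3); e6 <- c(1, 0, 1, 1, 0, 1)
  lr <- logrank_test(t6, e6, c(1, 1, 1, 2, 2, 2))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)

  lr3 <- logrank_test(rep(t6, 3)[1:9], rep(e6, 3)[1:9], rep(1:3, each = 3))
  expect_equal(lr3$df, 2L)

  # fixed 6-subject two-group toy against the O/E enumeration oracle
  t2 <- c(2, 4, 6, 1, 3, 5); e2 <- c(1, 1, 0, 1, 1, 1)
  g2 <- c(1, 1, 1, 2, 2, 2)
  lr2 <- logrank_test(t2, e2, g2)
  expect_lt(abs(lr2$chi_square - oracle_logrank2(t2, e2, g2)), 1e-10)

  expect_error(logrank_test(t6, e6, rep(1, 6)), "2 non-empty groups")
})

test_that("log-rank matches enumeration and survdiff on random samples", {
  checked <- 0
  for (seed in 1:150) {
    dat <- cshpet:::with_seed(200 + seed, {
      n <- sample(4:8, 1)
      list(t = sample(1:5, n, replace = TRUE), e = rbinom(n, 1, 0.7),
           g = sample(1:2, n, replace = TRUE))
    })
    if (length(unique(dat$g)) < 2 || sum(dat$e) == 0) next
    lr <- logrank_test(dat$t, dat$e, dat$g)
    expect_lt(abs(lr$chi_square - oracle_logrank2(dat$t, dat$e, dat$g)),
              1e-10)
    sd <- survival::survdiff(survival::Surv(dat$t, dat$e) ~ dat$g)
    expect_lt(abs(lr$chi_square - sd$chisq), 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("Cox regression recovers a known hazard ratio", {
  dat <- cshpet:::with_seed(99, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    t_event <- rexp(n, rate = 0.02 * 2^x)
    censor <- runif(n, 5, 88)
    data.frame(followup_months = pmin(t_event, censor),
               lrr_event = as.integer(t_event <= censor), x = x)
  })
  fit <- cox_fit(dat, "x")
  expect_gt(fit$table$hr, 1.8)
  expect_lt(fit$table$hr, 2.2)
  expect_true(fit$table$ci_lo < fit$table$hr &&
                fit$table$hr < fit$table$ci_hi)

  dat0 <- dat; dat0$lrr_event <- 0L
  expect_error(cox_fit(dat0, "x"), "no events")
  datc <- dat; datc$x <- 1
  expect_error(cox_fit(datc, "x"), "constant")
})

test_that("Cox confidence intervals cover a null covariate", {
  covered <- vapply(1:100, function(i) {
    dat <- cshpet:::with_seed(3000 + i, {
      n <- 2000
      t_event <- rexp(n, rate = 0.02)
      censor <- runif(n, 5, 88)
      data.frame(followup_months = pmin(t_event, censor),
                 lrr_event = as.integer(t_event <= censor),
                 x = rbinom(n, 1, 0.5))
    })
    tab <- cox_fit(dat, "x")$table
    tab$ci_lo <= 1 && 1 <= tab$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("multivariate mode adjusts for the a-priori clinical trio", {
  sim <- simulate_cohort(cohort_spec(n_patients = 300, seed = 41))
  dat <- merge(sim$deltas, sim$cohort, by = "patient_id")
  dat$p16 <- factor(dat$p16); dat$tnm_stage <- factor(dat$tnm_stage)
  dat$chemo <- factor(dat$chemo)
  fit <- suppressWarnings(cox_fit(dat, "d_auc_csh", multivariate = TRUE))
  expect_setequal(fit$adjust, c("p16", "tnm_stage", "chemo"))
  # falling heterogeneity (positive delta) is protective by construction
  expect_lt(fit$table$hr, 1)
})

test_that("paired and unpaired nonparametric comparisons behave", {
  x <- cshpet:::with_seed(5, runif(50, 2, 10))
  same <- paired_compare(x, x)
  expect_equal(same$p_value, 1)
  expect_match(same$note, "zero")

  shifted <- paired_compare(x, x - 1)
  expect_lt(shifted$p_value, 0.001)
  expect_error(paired_compare(1, numeric(0)), "unpaired")
  expect_error(paired_compare(1, 1), "n >= 2")

  u <- group_compare(x, x)
  expect_equal(unname(u$U), length(x)^2 / 2)
  expect_error(group_compare(numeric(0), x), "empty")
})

test_that("Mann-Whitney U holds its size and has power for a 1-SD shift", {
  rejections <- vapply(1:1000, function(i) {
    ab <- cshpet:::with_seed(5000 + i, list(a = rnorm(200), b = rnorm(200)))
    group_compare(ab$a, ab$b)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)

  power <- vapply(1:200, function(i) {
    ab <- cshpet:::with_seed(7000 + i,
                             list(a = rnorm(100), b = rnorm(100) + 1))
    group_compare(ab$a, ab$b)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(power), 0.90)
})
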