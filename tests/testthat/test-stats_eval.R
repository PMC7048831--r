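test_that("one-way ANOVA matches hand computation and the t-squared identity", {
  r <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(r$F, 8) # SSB = 4, SSW = 1, df = (1, 2)
  expect_equal(r$df1, 1); expect_equal(r$df2, 2)
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  a <- c(1.2, 3.4, 2.2, 4.8, 3.3); b <- c(2.5, 5.1, 4.4, 6.0)
  r2 <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2)
  expect_equal(r2$p, tt$p.value)
  # invariance under shift, F unchanged under scaling
  expect_equal(one_way_anova(list(a + 10, b + 10))$F, r2$F)
  expect_equal(one_way_anova(list(3 * a, 3 * b))$F, r2$F)
  deg <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(deg$flag, "degenerate"); expect_equal(deg$p, 0)
})

test_that("feature association detects planted effects and is calibrated", {
  x <- c(rnorm(30), rnorm(30) + 2)
  labs <- rep(c("negative", "positive"), each = 30)
  expect_lt(feature_association(x, labs)$p, 0.01)
  expect_equal(feature_association(rep(1, 20), rep(c("a", "b"), 10))$F, 0)
  rej <- mean(sapply(1:200, function(s) withr::with_seed(s, {
    feature_association(rnorm(40), sample(rep(c("a", "b"), 20)))$p < 0.05
  })))
  expect_gte(rej, 0.02); expect_lte(rej, 0.08)
})

test_that("median-split survival comparison behaves at the identities", {
  # two statistically identical groups: log-rank chi-square near zero
  tm <- rep(c(5, 10, 15, 20, 25, 30), 4)
  ev <- rep(1, 24)
  cov <- rep(c(-1, 1), each = 12) + rep(seq(0, 0.011, length.out = 12), 2)
  r <- km_logrank_median_split(tm, ev, cov)
  expect_equal(r$chisq, 0, tolerance = 1e-8)
  expect_equal(r$p, 1, tolerance = 1e-6)
  # without censoring the KM curve equals the empirical survival function
  d <- withr::with_seed(2, rexp(40, 1 / 20))
  z <- withr::with_seed(3, rnorm(40))
  fit <- km_logrank_median_split(d, rep(1, 40), z)$fit
  s <- summary(fit)
  grp_sizes <- fit$n
  emp <- sapply(seq_along(s$time), function(i) {
    g <- s$strata[i]
    mean(d[if (g == levels(s$strata)[1]) z <= median(z) else z > median(z)] > s$time[i])
  })
  expect_equal(unname(s$surv), emp, tolerance = 1e-8)
})

test_that("log-rank test has power against a strong group hazard ratio", {
  power <- mean(sapply(1:60, function(s) withr::with_seed(s, {
    grp <- rep(0:1, each = 54)
    tmv <- rexp(108, rate = ifelse(grp == 1, 3 / 60, 1 / 60))
    cens <- rexp(108, 1 / 120)
    time <- pmin(tmv, cens); event <- as.integer(tmv <= cens)
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
    pchisq(sd_$chisq, 1, lower.tail = FALSE) < 0.05
  })))
  expect_gte(power, 0.8)
})

test_that("per-SD Cox hazard ratio is scale invariant and recovers effects", {
  z <- withr::with_seed(4, rnorm(108))
  d <- generate_survival(z, 0.5, 1 / 60, 1 / 120, 99)
  r1 <- cox_per_sd(d$time, d$event, z)
  r2 <- cox_per_sd(d$time, d$event, 2 * z + 5)
  expect_equal(r1$hr, r2$hr, tolerance = 1e-8)
  expect_true(r1$ci[1] < r1$hr && r1$hr < r1$ci[2])
  betas <- sapply(1:50, function(s) {
    zz <- withr::with_seed(300 + s, rnorm(108))
    dd <- generate_survival(zz, 0.5, 1 / 60, 1 / 120, 500 + s)
    cox_per_sd(dd$time, dd$event, zz)$beta
  })
  expect_lt(abs(mean(betas) - 0.5), 0.1)
  expect_error(cox_per_sd(d$time, d$event, rep(1, 108)), "constant")
})

test_that("feature-count sweep reports every candidate size once", {
  m <- matrix(runif(24, 0.6, 0.9), 3, 8,
              dimnames = list(NULL, c(2, 3, 5, 7, 9, 11, 13, 15)))
  sw <- feature_count_sweep(m)
  expect_equal(sw$size, c(2, 3, 5, 7, 9, 11, 13, 15))
  expect_equal(sw$mean_auc, unname(colMeans(m)))
  expect_equal(sw$two_sd, unname(2 * apply(m, 2, sd)))
  one <- feature_count_sweep(m[1, , drop = FALSE])
  expect_true(all(is.na(one$two_sd)))
  expect_equal(attr(one, "flag"), "single_repetition")
})
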