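test_that("worked closed-form repeatability examples", {
  # zero within-group variance: perfectly repeatable
  r1 <- suppressWarnings(repeatability_anova(c(1, 1, 3, 3),
                                             c("a", "a", "b", "b")))
  expect_equal(r1$tau, 1)
  # hand-computed 4-point example: MSA=4, MSW=0.5, n0=2 -> tau=0.7778
  r2 <- suppressWarnings(repeatability_anova(c(0, 1, 2, 3),
                                             c("a", "a", "b", "b")))
  expect_equal(r2$variance_among, 1.75)
  expect_equal(r2$variance_within, 0.5)
  expect_equal(r2$n0, 2)
  expect_equal(r2$tau, 0.7778, tolerance = 1e-4)
  # identical-distribution draws: estimate collapses to ~0 with the
  # negative-variance truncation path exercised along the way
  set.seed(5)
  taus <- replicate(40, repeatability_anova(rnorm(120),
                                            rep(1:30, each = 4))$tau)
  expect_lt(mean(taus), 0.08)
  expect_true(any(taus == 0))
})

test_that("tau agrees with one-way ANOVA from stats and is affine-invariant", {
  set.seed(8)
  g <- rep(1:12, times = sample(3:6, 12, replace = TRUE))
  v <- rnorm(length(g)) + rnorm(12)[g]
  r <- repeatability_anova(v, g)
  # mean squares match stats::anova on the identical model
  a <- anova(lm(v ~ factor(g)))
  msw <- a[["Mean Sq"]][2]
  expect_equal(r$variance_within, msw)
  expect_equal(r$p_value, a[["Pr(>F)"]][1])
  # affine transformation leaves the intraclass correlation unchanged
  r2 <- repeatability_anova(3.7 * v - 11, g)
  expect_equal(r2$tau, r$tau, tolerance = 1e-12)
})

test_that("balanced-design estimate matches the REML variance-components
           estimator", {
  set.seed(13)
  n_id <- 30; reps <- 4
  id <- rep(seq_len(n_id), each = reps)
  v <- rnorm(n_id, 0, 1)[id] + rnorm(n_id * reps, 0, 1)
  r <- repeatability_anova(v, id)
  fm <- lme4::lmer(v ~ 1 + (1 | id), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fm))
  icc_reml <- vc$vcov[1] / sum(vc$vcov)
  expect_lt(abs(r$tau - icc_reml), 0.02)
})

test_that("covariate adjustment recovers the intraclass correlation", {
  # generator-style data: known ICC 0.5 plus a linear Ta effect;
  # averaged over seeds, the single-study sampling error (~0.09 SE at 36
  # birds) washes out
  n_id <- 36; reps <- 4
  id <- rep(seq_len(n_id), each = reps)
  taus <- vapply(1:6, function(s) {
    set.seed(30 + s)
    ta <- runif(n_id * reps, 38, 44)
    v <- 0.3 + 0.013 * ta + rnorm(n_id, 0, 0.02)[id] +
      rnorm(n_id * reps, 0, 0.02)
    adjusted_repeatability(v, id, data.frame(ta = ta), bootstrap = 0)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 0.5), 0.1)
  set.seed(31)
  ta <- runif(n_id * reps, 38, 44)
  v <- 0.3 + 0.013 * ta + rnorm(n_id, 0, 0.02)[id] +
    rnorm(n_id * reps, 0, 0.02)
  # a covariate orthogonal to the grouping leaves tau unchanged
  set.seed(32)
  z <- rnorm(n_id * reps)
  z <- resid(lm(z ~ factor(id)))   # exactly orthogonal to individuals
  v2 <- rnorm(n_id, 0, 1)[id] + rnorm(n_id * reps, 0, 1)
  r_un <- repeatability_anova(resid(lm(v2 ~ 1)), id)
  r_ad <- adjusted_repeatability(v2, id, data.frame(z = z), bootstrap = 0)
  expect_lt(abs(r_ad$tau - r_un$tau), 0.03)
  # duplicated covariate column: rank-deficient design is an error
  expect_error(adjusted_repeatability(v, id,
                                      data.frame(ta = ta, ta2 = ta),
                                      bootstrap = 0),
               "rank-deficient")
})

test_that("degenerate groupings are rejected", {
  expect_error(repeatability_anova(1:5, rep("a", 5)), "two individuals")
  expect_error(repeatability_anova(c(1, 2), c("a", "b")), "replicate")
  expect_warning(repeatability_anova(c(1, 2, 2, 3), c("a", "a", "b", "b")),
                 "few individuals")
})
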