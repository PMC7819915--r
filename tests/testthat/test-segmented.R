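test_that("noiseless plateau-then-rise data are fitted exactly", {
  x <- seq(0, 10, by = 0.5)
  y <- ifelse(x < 5, 1, 1 + 0.5 * (x - 5))
  f <- fit_segmented(x, y, n_breakpoints = 1,
                     constraints = c("horizontal", "free"))
  expect_equal(f$breakpoints, 5, tolerance = 1e-4)
  expect_equal(f$slopes, c(0, 0.5), tolerance = 1e-4)
  expect_lt(f$sse, 1e-8)
  expect_equal(predict(f, c(2, 8)), c(1, 2.5), tolerance = 1e-4)
})

test_that("noiseless three-segment profile recovers both breakpoints", {
  x <- rep(seq(22, 44, by = 0.5), 3)
  truth <- scholander_truth()
  y <- truth_curves(truth, x)$mr
  f <- fit_segmented(x, y, n_breakpoints = 2,
                     constraints = c("free", "horizontal", "free"))
  expect_equal(f$breakpoints, c(34.87, 37.47), tolerance = 1e-2 / 34)
  expect_equal(f$slopes[1], -0.015, tolerance = 1e-4)
  expect_equal(f$slopes[3], 0.013, tolerance = 1e-4)
  expect_equal(unname(predict(f, 36)), 0.24, tolerance = 1e-6)
})

test_that("single-breakpoint SSE matches exhaustive fine-grid search", {
  set.seed(101)
  for (rep in 1:10) {
    n <- 30
    x <- sort(runif(n, 0, 10))
    bp <- runif(1, 3, 7)
    y <- 2 + 0.4 * x + 0.9 * pmax(x - bp, 0) + rnorm(n, 0, 0.3)
    f <- fit_segmented(x, y, n_breakpoints = 1)
    orc <- oracle_best_bp1(x, y, c("free", "free"))
    expect_lte(f$sse, orc$sse * (1 + 1e-8))
  }
})

test_that("continuity holds at every fitted breakpoint", {
  set.seed(7)
  x <- runif(120, 22, 44)
  y <- truth_curves(scholander_truth(), x)$mr + rnorm(120, 0, 0.02)
  f <- fit_segmented(x, y, n_breakpoints = 2,
                     constraints = c("free", "horizontal", "free"))
  eps <- 1e-9
  for (bp in f$breakpoints)
    expect_equal(predict(f, bp - eps), predict(f, bp + eps),
                 tolerance = 1e-6)
  # horizontal constraint is exact
  expect_identical(f$slopes[2], 0)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_segmented(rep(1, 20), rnorm(20), 1), "all equal")
  expect_error(fit_segmented(1:8, rnorm(8), 1), "too few")
  expect_error(fit_segmented(1:30, rnorm(30), 1, constraints = "free"),
               "one constraint per segment")
})

test_that("model selection keeps the simple model on linear data and
           finds the breakpoint when one exists", {
  set.seed(11)
  x <- rep(seq(0, 10, length.out = 25), 4)
  y_lin <- 1 + 0.3 * x + rnorm(length(x), 0, 0.2)
  expect_equal(select_model_type(x, y_lin)$n_breakpoints, 0)

  hits <- 0; horiz <- 0; n_rep <- 100
  for (r in seq_len(n_rep)) {
    y <- 1 + 0.5 * pmax(x - 5, 0) + rnorm(length(x), 0, 0.5)  # 10% of range
    sel <- select_model_type(x, y)
    if (sel$n_breakpoints == 1) {
      hits <- hits + 1
      if (sel$constraints[1] == "horizontal") horiz <- horiz + 1
    }
  }
  expect_gte(hits / n_rep, 0.95)
  # plateau-then-rise truth: the horizontal first segment is preferred
  expect_gte(horiz / max(hits, 1), 0.9)
})

test_that("cluster-bootstrap breakpoint SE shrinks with more birds", {
  truth <- scholander_truth()
  se_at <- function(nb, seed) {
    ss <- generate_steady_state(truth,
                                generator_config(n_birds = nb, seed = seed))
    f <- fit_segmented(ss$ta_c, ss$tb_c, n_breakpoints = 1,
                       constraints = c("horizontal", "free"),
                       cluster = ss$bird_id, bootstrap = 60, seed = seed)
    f$breakpoint_se
  }
  seeds <- c(3, 4, 5)
  ratio <- mean(vapply(seeds, function(s) se_at(18, s), numeric(1))) /
    mean(vapply(seeds, function(s) se_at(72, s), numeric(1)))
  expect_gte(ratio, 1.2)
  expect_lte(ratio, 2.9)
})

test_that("derive_profile validates fit shapes and reads truth exactly
           from noiseless fits", {
  x <- rep(seq(22, 44, by = 0.5), 3)
  truth <- scholander_truth()
  tc <- truth_curves(truth, x)
  mr <- fit_segmented(x, tc$mr, 2, c("free", "horizontal", "free"))
  tb <- fit_segmented(x, tc$tb, 1, c("horizontal", "free"))
  ehl <- fit_segmented(x, tc$ehl, 1, c("horizontal", "free"))
  prof <- derive_profile(mr, tb, ehl)
  expect_equal(prof$t_lc, truth$t_lc, tolerance = 1e-4)
  expect_equal(prof$t_uc, truth$t_uc, tolerance = 1e-4)
  expect_equal(prof$bmr, truth$bmr, tolerance = 1e-6)
  expect_equal(prof$mr_slope_below, truth$mr_slope_below, tolerance = 1e-4)
  expect_equal(prof$tb_plateau, truth$tb_plateau, tolerance = 1e-6)
  expect_equal(prof$tb_slope, truth$tb_slope, tolerance = 1e-4)
  expect_equal(prof$ehl_inflection, truth$ehl_inflection, tolerance = 1e-3)
  # wrong shape passed in: error names the offending fit
  expect_error(derive_profile(tb, tb, ehl), "mr_fit")
  mr_free <- fit_segmented(x, tc$mr, 2)
  expect_error(derive_profile(mr_free, tb, ehl), "horizontal")
})
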