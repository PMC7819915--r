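# a tiny hand-built trace: REF - bird dwell - REF, 2 s sampling
make_simple_trace <- function(vo2 = 0.7, vco2 = 0.6, ewl = 1.5,
                              drift = c(0, 0), dwell_s = 300,
                              flow = 500) {
  ex <- simulate_excurrent(vo2, vco2, ewl, flow, mode = "push_chamber")
  n <- dwell_s / 2
  tm <- seq(0, by = 2, length.out = 3 * n)
  third <- rep(1:3, each = n)
  fio2_t <- 0.2095 + seq(drift[1], drift[2], length.out = 3 * n)
  feo2 <- ifelse(third == 2, ex$feo2 + (fio2_t - 0.2095), fio2_t)
  data.frame(time_s = tm,
             channel = c("REF", "1", "REF")[third],
             feo2 = feo2,
             feco2 = ifelse(third == 2, ex$feco2, 0),
             ph2o_kpa = ifelse(third == 2, ex$ph2o, 0),
             flow_mlmin = flow, ta_c = 30)
}

test_that("demultiplex attaches bracketing references and masks washout", {
  tr <- make_simple_trace()
  segs <- demultiplex(tr, mux_map = c("1" = "birdA"))
  expect_named(segs, "birdA")
  seg <- segs$birdA[[1]]
  expect_false(seg$flag)
  expect_false(is.null(seg$ref_before))
  expect_false(is.null(seg$ref_after))
  t0 <- seg$data$time_s[1]
  expect_true(all(seg$data$masked == (seg$data$time_s < t0 + 60)))
  expect_error(demultiplex(tr, mux_map = c("9" = "birdZ")), "unmapped")
})

test_that("multichannel schedule accounts for every second of the run", {
  rates <- data.frame(bird_id = paste0("b", 1:8),
                      vo2 = seq(0.4, 1.1, by = 0.1),
                      vco2 = seq(0.35, 1.05, by = 0.1) * 0.9,
                      ewl = seq(1, 4.5, by = 0.5), ta = 30)
  tr <- generate_raw_trace(rates, n_cycles = 2, seed = 5)
  mux <- setNames(rates$bird_id, rates$bird_id)
  segs <- demultiplex(tr, mux)
  expect_length(segs, 8)
  # every bird appears n_cycles times; dwell bookkeeping is exact:
  # total = animal dwells + reference dwells, washout masked within dwells
  n_dwell <- sum(lengths(segs))
  expect_identical(n_dwell, 16L)
  sched <- attr(tr, "schedule")
  expect_identical(nrow(tr), length(sched) * 150L)
  animal_rows <- sum(tr$channel != "REF")
  expect_identical(animal_rows, n_dwell * 150L)
  masked_rows <- sum(vapply(unlist(segs, recursive = FALSE),
                            function(s) sum(s$data$masked), numeric(1)))
  expect_identical(masked_rows, n_dwell * 30)   # 60 s at 0.5 Hz
})

test_that("baseline correction removes affine drift exactly", {
  # references identical: correction is a constant offset
  tr0 <- make_simple_trace(drift = c(0, 0))
  seg <- baseline_correct(demultiplex(tr0, c("1" = "b"))$b[[1]])
  d <- seg$data[!seg$data$masked, ]
  expect_equal(mean(d$vo2), 0.7, tolerance = 1e-6)
  # affine analyzer drift in FeO2: recovered rates stay unbiased
  tr1 <- make_simple_trace(drift = c(0, 1e-4))
  seg1 <- baseline_correct(demultiplex(tr1, c("1" = "b"))$b[[1]])
  d1 <- seg1$data[!seg1$data$masked, ]
  expect_lt(abs(mean(d1$vo2) - 0.7) / 0.7, 0.01)
})

test_that("a segment with one reference is corrected with a warning", {
  tr <- make_simple_trace()
  tr <- tr[tr$time_s < 600, ]   # drop the trailing reference
  segs <- demultiplex(tr, c("1" = "b"))
  expect_true(segs$b[[1]]$flag)
  expect_warning(seg <- baseline_correct(segs$b[[1]]), "one reference")
  expect_equal(mean(seg$data$vo2[!seg$data$masked]), 0.7,
               tolerance = 1e-6)
})

test_that("steady-state window selection equals exhaustive enumeration", {
  set.seed(9)
  n <- 240
  d <- data.frame(time_s = seq(0, by = 2, length.out = n),
                  vo2 = 1 + 0.3 * sin(seq_len(n) / 15) + rnorm(n, 0, 0.05),
                  ewl = runif(n, 1, 2), ta_c = 30)
  for (crit in c("lowest_mean", "most_stable")) {
    w <- if (crit == "lowest_mean") 60 else 150
    sel <- select_steady_state(d, crit, width_s = w * 2)
    i <- oracle_window(d$vo2, w, crit)
    expect_equal(sel$window_start, d$time_s[i])
  }
  # monotone decreasing series: lowest-mean window is the last window
  d2 <- data.frame(time_s = seq(0, by = 2, length.out = 120),
                   vo2 = seq(2, 1, length.out = 120))
  sel2 <- select_steady_state(d2, "lowest_mean", width_s = 120)
  expect_equal(sel2$window_end, d2$time_s[120])
  # constant series: earliest window wins the tie
  d3 <- data.frame(time_s = seq(0, by = 2, length.out = 200),
                   vo2 = rep(1, 200))
  sel3 <- select_steady_state(d3, "most_stable", width_s = 300)
  expect_equal(sel3$window_start, 0)
  expect_error(select_steady_state(d3[1:10, ], "most_stable",
                                   width_s = 300), "shorter")
})

test_that("end-to-end trace processing recovers per-bird truth", {
  set.seed(21)
  rates <- data.frame(bird_id = paste0("b", 1:6),
                      vo2 = runif(6, 0.4, 1.2),
                      vco2 = NA, ewl = runif(6, 1, 4),
                      ta = round(runif(6, 23, 43)))
  rates$vco2 <- rates$vo2 * runif(6, 0.75, 0.95)
  tr <- generate_raw_trace(rates, n_cycles = 2,
                           drift_per_hr = c(feo2 = -1e-4, feco2 = 2e-5,
                                            ph2o = 0.01),
                           seed = 22)
  out <- process_trace(tr, setNames(rates$bird_id, rates$bird_id),
                       criterion = "lowest_mean", width_s = 120)
  truth <- merge(out, rates, by = "bird_id")
  # sensor noise 2e-5 on FeO2 at 500 ml/min is ~0.01 ml/min in VO2; a
  # 60-sample window mean must land within 2 noise SD for >= 95% of dwells
  err <- abs(truth$vo2_mlmin - truth$vo2)
  expect_gte(mean(err < 2 * 0.01), 0.95)
  expect_lt(max(abs(truth$ewl_mgmin - truth$ewl)), 0.05)
})
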