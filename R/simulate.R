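# Synthetic-data generation with known ground truth: forward mass-balance
# simulation of excurrent gas, steady-state physiological tables following
# a Scholander-Irving profile, multiplexed raw analyzer traces, and
# two-line mask-respirometry sessions.

#' Forward steady-state mass balance: excurrent readings from true rates
#'
#' Computes the excurrent dry-basis O2/CO2 fractions and water-vapour
#' pressure that an ideal analyzer chain would read for an animal with the
#' given true exchange rates, in the stated measurement configuration.
#' This is the forward counterpart that [gas_exchange_rates()] inverts.
#'
#' @param vo2,vco2 true rates, ml min^-1 STP.
#' @param ewl true evaporative water loss, mg min^-1.
#' @param fr metered dry flow, ml min^-1 STP (incurrent for
#'   `push_chamber`, excurrent for the pull modes).
#' @param mode measurement configuration (see [gas_sample()]).
#' @param fio2,fico2,pih2o,bp incurrent composition and barometric
#'   pressure.
#' @return A data frame with `feo2`, `feco2`, `ph2o` (kPa).
#' @export
simulate_excurrent <- function(vo2, vco2, ewl, fr,
                               mode = c("push_chamber", "pull_mask",
                                        "pull_chamber"),
                               fio2 = 0.2095, fico2 = 0, pih2o = 0,
                               bp = 101.325) {
  mode <- match.arg(mode)
  vh2o <- ewl / .MG_H2O_PER_ML   # ml min^-1 of vapour
  wi <- pih2o / bp
  if (mode == "push_chamber") {
    fi <- fr
    fe <- fi - vo2 + vco2
  } else {
    fe <- fr
    fi <- fe + vo2 - vco2
  }
  if (any(fe <= 0)) stop("dry excurrent flow driven non-positive")
  feo2  <- (fi * fio2 - vo2) / fe
  feco2 <- (fi * fico2 + vco2) / fe
  water_out <- fi * wi / (1 - wi) + vh2o
  we <- water_out / (fe + water_out)
  data.frame(feo2 = feo2, feco2 = feco2, ph2o = we * bp)
}

#' Ground-truth Scholander-Irving thermoregulatory profile
#'
#' Defaults describe a small passerine: a three-segment metabolic-rate
#' curve with a thermoneutral plateau, a body-temperature plateau with
#' hyperthermic rise, and an evaporative-heat-loss plateau with an
#' inflection near the upper critical temperature.
#'
#' @param t_lc,t_uc lower and upper critical temperature, degrees C.
#' @param bmr basal metabolic rate (plateau level), W.
#' @param mr_slope_below magnitude of the MR increase per degree of cooling
#'   below `t_lc`, W per degree C.
#' @param mr_slope_above MR increase per degree above `t_uc`, W per degree C.
#' @param tb_plateau,tb_threshold,tb_slope body-temperature plateau
#'   (degrees C), onset of regulated hyperthermia (degrees C) and rise rate
#'   above it (degrees C per degree C).
#' @param ehl_plateau,ehl_inflection,ehl_slope evaporative heat loss
#'   plateau (W), inflection ambient temperature (degrees C) and rise rate
#'   above it (W per degree C).
#' @return A list of class `scholander_truth`.
#' @export
scholander_truth <- function(t_lc = 34.87, t_uc = 37.47, bmr = 0.24,
                             mr_slope_below = 0.015, mr_slope_above = 0.013,
                             tb_plateau = 40.98, tb_threshold = 35.94,
                             tb_slope = 0.43,
                             ehl_plateau = 0.061, ehl_inflection = 37.45,
                             ehl_slope = 0.045) {
  if (t_lc >= t_uc) stop("t_lc must be below t_uc")
  if (ehl_plateau <= 0) stop("ehl_plateau must be positive")
  if (mr_slope_below < 0 || mr_slope_above < 0)
    stop("MR slopes are magnitudes; both must be >= 0")
  structure(list(t_lc = t_lc, t_uc = t_uc, bmr = bmr,
                 mr_slope_below = mr_slope_below,
                 mr_slope_above = mr_slope_above,
                 tb_plateau = tb_plateau, tb_threshold = tb_threshold,
                 tb_slope = tb_slope, ehl_plateau = ehl_plateau,
                 ehl_inflection = ehl_inflection, ehl_slope = ehl_slope),
            class = "scholander_truth")
}

#' Evaluate the true profile curves at ambient temperatures
#'
#' @param truth a [scholander_truth()].
#' @param ta ambient temperatures, degrees C.
#' @return A data frame with `ta`, `mr`, `tb`, `ehl` (noise-free truth).
#' @export
truth_curves <- function(truth, ta) {
  stopifnot(inherits(truth, "scholander_truth"))
  data.frame(
    ta = ta,
    mr = truth$bmr + truth$mr_slope_below * pmax(truth$t_lc - ta, 0) +
      truth$mr_slope_above * pmax(ta - truth$t_uc, 0),
    tb = truth$tb_plateau + truth$tb_slope * pmax(ta - truth$tb_threshold, 0),
    ehl = truth$ehl_plateau + truth$ehl_slope * pmax(ta - truth$ehl_inflection, 0)
  )
}

#' Configuration of the steady-state data generator
#'
#' The defaults emulate the study design the package is verified against:
#' 36 birds in four acclimation groups, ambient temperatures drawn from a
#' 22-44 degree C grid in 0.5-degree steps, two randomly chosen
#' temperatures per bird per measurement day over six days, Gaussian
#' residual noise and among-individual random intercepts for MR and Tb.
#' The MR variance components give a true intraclass correlation of
#' 0.016^2 / (0.016^2 + 0.020^2) = 0.390.
#'
#' @param n_birds number of individuals (default 36).
#' @param ta_min,ta_max,ta_step ambient-temperature grid, degrees C.
#' @param ta_per_day temperatures drawn per bird per day (default 2).
#' @param n_days measurement days per bird (default 6).
#' @param noise_sd named residual SDs: `mr` (W), `tb` (degrees C),
#'   `ehl` (W).
#' @param among_sd named among-individual SDs: `mr` (W), `tb` (degrees C).
#' @param mb_mean,mb_sd body-mass distribution, g.
#' @param seed integer seed; mandatory for reproducibility.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_birds = 36, ta_min = 22, ta_max = 44,
                             ta_step = 0.5, ta_per_day = 2, n_days = 6,
                             noise_sd = c(mr = 0.020, tb = 0.30,
                                          ehl = 0.008),
                             among_sd = c(mr = 0.016, tb = 0.25),
                             mb_mean = 15, mb_sd = 1, seed) {
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory for reproducible generation")
  if (any(noise_sd < 0) || any(among_sd < 0) || mb_sd < 0)
    stop("standard deviations must be non-negative")
  stopifnot(all(c("mr", "tb", "ehl") %in% names(noise_sd)),
            all(c("mr", "tb") %in% names(among_sd)))
  structure(list(n_birds = n_birds, ta_min = ta_min, ta_max = ta_max,
                 ta_step = ta_step, ta_per_day = ta_per_day,
                 n_days = n_days, noise_sd = noise_sd, among_sd = among_sd,
                 mb_mean = mb_mean, mb_sd = mb_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# acclimation-group labels in the sizes of the study design (8/10/9/9)
.assign_groups <- function(n_birds) {
  base <- c("23_adlib", "23_restricted", "40_adlib", "40_restricted")
  sizes <- c(8, 10, 9, 9)
  g <- rep(base, times = ceiling(n_birds * sizes / sum(sizes)))
  g[seq_len(n_birds)]
}

#' Generate a steady-state physiological table with known truth
#'
#' Each bird receives a random intercept for MR and Tb, is measured at
#' `ta_per_day` grid temperatures on each of `n_days` days, and its noisy
#' MR/Tb/EHL values are drawn around the truth curves. V̇O2, V̇CO2 and EWL
#' are back-computed from the noisy MR and EHL (RER drawn uniform
#' 0.75-0.95), so the calorimetric identities hold exactly row by row.
#'
#' @param truth a [scholander_truth()].
#' @param config a [generator_config()].
#' @return A steady-state data frame (columns `bird_id`, `group`,
#'   `acclimation`, `ta_c`, `mb_g`, `vo2_mlmin`, `vco2_mlmin`,
#'   `ewl_mgmin`, `mr_w`, `ehl_w`, `tb_c`) with the truth and config
#'   attached as attributes `truth` and `config`.
#' @export
generate_steady_state <- function(truth = scholander_truth(),
                                  config) {
  stopifnot(inherits(truth, "scholander_truth"),
            inherits(config, "generator_config"))
  set.seed(config$seed)
  grid <- seq(config$ta_min, config$ta_max, by = config$ta_step)
  nb <- config$n_birds
  u_mr <- stats::rnorm(nb, 0, config$among_sd[["mr"]])
  u_tb <- stats::rnorm(nb, 0, config$among_sd[["tb"]])
  mb <- stats::rnorm(nb, config$mb_mean, config$mb_sd)
  groups <- .assign_groups(nb)

  rows <- vector("list", nb)
  for (i in seq_len(nb)) {
    ta <- unlist(lapply(seq_len(config$n_days), function(d)
      sample(grid, config$ta_per_day)))
    tc <- truth_curves(truth, ta)
    n <- length(ta)
    mr <- tc$mr + u_mr[i] + stats::rnorm(n, 0, config$noise_sd[["mr"]])
    tb <- tc$tb + u_tb[i] + stats::rnorm(n, 0, config$noise_sd[["tb"]])
    ehl <- pmax(tc$ehl + stats::rnorm(n, 0, config$noise_sd[["ehl"]]), 0)
    mr <- pmax(mr, 0.01)
    rer <- stats::runif(n, 0.75, 0.95)
    vo2 <- mr * 60 / (16 + 5.164 * rer)
    rows[[i]] <- data.frame(
      bird_id = sprintf("bird%02d", i), group = groups[i],
      acclimation = "initial", ta_c = ta,
      mb_g = mb[i], vo2_mlmin = vo2, vco2_mlmin = rer * vo2,
      ewl_mgmin = ehl * 60 / 2.4, mr_w = mr, ehl_w = ehl, tb_c = tb)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  out
}

#' Generate a multiplexed raw analyzer trace with known rates
#'
#' Builds the 0.5 Hz trace a multiplexed two-analyzer chain would record
#' while cycling over up to ten animal chambers: 5-minute dwells per
#' channel, a reference (incurrent air) dwell at least every 20 minutes
#' (one reference precedes every block of three animal channels), optional
#' affine analyzer drift, and Gaussian sensor noise. True per-chamber
#' rates are attached for recovery checks.
#'
#' @param rates data frame with one row per chamber: columns `bird_id`,
#'   `vo2`, `vco2` (ml min^-1), `ewl` (mg min^-1), `ta` (degrees C).
#' @param n_cycles times the full channel schedule is repeated (default 2;
#'   the schedule starts and ends with a reference dwell).
#' @param dwell_s dwell per channel, s (default 300).
#' @param dt_s sampling interval, s (default 2, i.e. 0.5 Hz).
#' @param flow metered dry incurrent flow per chamber, ml min^-1.
#' @param mode measurement configuration (default `push_chamber`).
#' @param drift_per_hr named additive full-scale drift per hour applied to
#'   `feo2`, `feco2` and `ph2o` readings (defaults 0).
#' @param noise_sd named Gaussian sensor noise SDs for `feo2`, `feco2`
#'   (fractions) and `ph2o` (kPa).
#' @param fio2,fico2,pih2o,bp incurrent composition.
#' @param seed integer seed.
#' @return A data frame (`time_s`, `channel`, `feo2`, `feco2`,
#'   `ph2o_kpa`, `flow_mlmin`, `ta_c`) with attributes `truth` (the
#'   `rates` input) and `schedule`.
#' @export
generate_raw_trace <- function(rates, n_cycles = 2, dwell_s = 300,
                               dt_s = 2, flow = 500,
                               mode = "push_chamber",
                               drift_per_hr = c(feo2 = 0, feco2 = 0,
                                                ph2o = 0),
                               noise_sd = c(feo2 = 2e-5, feco2 = 1e-5,
                                            ph2o = 0.002),
                               fio2 = 0.2095, fico2 = 0, pih2o = 0,
                               bp = 101.325, seed = 1) {
  n_ch <- nrow(rates)
  if (n_ch > 10)
    stop("at most 10 chambers are supported")
  stopifnot(all(c("bird_id", "vo2", "vco2", "ewl", "ta") %in% names(rates)))
  set.seed(seed)
  # reference before every block of <= 3 animal dwells keeps the
  # reference cadence at or under 20 min; close with a final reference
  blocks <- split(seq_len(n_ch), ceiling(seq_len(n_ch) / 3))
  cycle <- unlist(lapply(blocks, function(b) c("REF", as.character(b))),
                  use.names = FALSE)
  schedule <- c(rep(cycle, n_cycles), "REF")

  per_dwell <- dwell_s / dt_s
  n_tot <- length(schedule) * per_dwell
  time <- seq(0, by = dt_s, length.out = n_tot)
  chan <- rep(schedule, each = per_dwell)

  ex <- simulate_excurrent(rates$vo2, rates$vco2, rates$ewl, fr = flow,
                           mode = mode, fio2 = fio2, fico2 = fico2,
                           pih2o = pih2o, bp = bp)
  idx <- suppressWarnings(as.integer(chan))   # NA for REF
  feo2 <- ifelse(is.na(idx), fio2, ex$feo2[idx])
  feco2 <- ifelse(is.na(idx), fico2, ex$feco2[idx])
  ph2o <- ifelse(is.na(idx), pih2o, ex$ph2o[idx])
  ta <- ifelse(is.na(idx), mean(rates$ta), rates$ta[idx])

  hr <- time / 3600
  feo2 <- feo2 + drift_per_hr[["feo2"]] * hr +
    stats::rnorm(n_tot, 0, noise_sd[["feo2"]])
  feco2 <- pmax(feco2 + drift_per_hr[["feco2"]] * hr +
                  stats::rnorm(n_tot, 0, noise_sd[["feco2"]]), 0)
  ph2o <- pmax(ph2o + drift_per_hr[["ph2o"]] * hr +
                 stats::rnorm(n_tot, 0, noise_sd[["ph2o"]]), 0)

  out <- data.frame(time_s = time,
                    channel = ifelse(is.na(idx), "REF",
                                     rates$bird_id[idx]),
                    feo2 = feo2, feco2 = feco2, ph2o_kpa = ph2o,
                    flow_mlmin = flow, ta_c = ta)
  attr(out, "truth") <- rates
  attr(out, "schedule") <- schedule
  attr(out, "system") <- list(mode = mode, fio2 = fio2, fico2 = fico2,
                              pih2o = pih2o, bp = bp, dwell_s = dwell_s,
                              dt_s = dt_s)
  out
}

#' Ground-truth evaporative-water-loss partition per temperature stratum
#'
#' Defaults make the cutaneous avenue dominant at 25 degrees C (61% of
#' total evaporative heat loss) and the respiratory avenue dominant at 40
#' degrees C (cutaneous share 21%), with cutaneous loss 25% higher at 40
#' than at 25 degrees C.
#'
#' @param ta_set stratum temperatures, degrees C.
#' @param rewl,cewl true respiratory and cutaneous water loss per stratum,
#'   mg min^-1.
#' @return A data frame of class `partition_truth`.
#' @export
partition_truth <- function(ta_set = c(25, 40),
                            rewl = c(1.01, 7.43),
                            cewl = c(1.58, 1.98)) {
  stopifnot(length(ta_set) == length(rewl),
            length(ta_set) == length(cewl),
            all(rewl >= 0), all(cewl >= 0))
  structure(data.frame(ta_set = ta_set, rewl = rewl, cewl = cewl),
            class = c("partition_truth", "data.frame"))
}

#' Generate a two-line mask-respirometry session table
#'
#' For each bird and temperature stratum, true respiratory and cutaneous
#' water-loss rates are drawn log-normally around the stratum truth, the
#' mask line (pulled at 500 ml min^-1, carrying the animal's breath) and
#' the chamber line (pulled at 200 ml min^-1, water signal only) are
#' forward-simulated, and optional analyzer noise is added.
#'
#' @param truth a [partition_truth()].
#' @param n_birds number of birds (default 36).
#' @param cv_among log-scale SD of among-bird variation (default 0.15).
#' @param mask_flow,chamber_flow metered dry flows, ml min^-1.
#' @param vo2_mask named true mask-line oxygen consumption per stratum,
#'   ml min^-1 (mask measurements run above resting rates).
#' @param noise_sd named analyzer noise (`feo2`, `feco2` fractions,
#'   `ph2o` kPa); default 0 for exact-recovery checks.
#' @param bp barometric pressure, kPa.
#' @param seed integer seed.
#' @return A long data frame, two rows (lines) per bird per stratum:
#'   `bird_id`, `ta_set_c`, `line` ("mask"/"chamber"), `feo2`, `feco2`,
#'   `ph2o_kpa`, `flow_mlmin`, `bp_kpa`; truth draws in attribute `truth`.
#' @export
generate_mask_session <- function(truth = partition_truth(), n_birds = 36,
                                  cv_among = 0.15, mask_flow = 500,
                                  chamber_flow = 200,
                                  vo2_mask = c(`25` = 1.6, `40` = 1.1),
                                  noise_sd = c(feo2 = 0, feco2 = 0,
                                               ph2o = 0),
                                  bp = 101.325, seed = 1) {
  stopifnot(inherits(truth, "partition_truth"))
  set.seed(seed)
  out <- list(); tru <- list(); k <- 0
  for (i in seq_len(n_birds)) {
    bird <- sprintf("bird%02d", i)
    for (j in seq_len(nrow(truth))) {
      ta <- truth$ta_set[j]
      rewl <- truth$rewl[j] * exp(stats::rnorm(1, 0, cv_among))
      cewl <- truth$cewl[j] * exp(stats::rnorm(1, 0, cv_among))
      vo2 <- vo2_mask[[as.character(ta)]] * exp(stats::rnorm(1, 0, 0.1))
      rer <- stats::runif(1, 0.75, 0.95)
      mask <- simulate_excurrent(vo2, rer * vo2, rewl, fr = mask_flow,
                                 mode = "pull_mask", bp = bp)
      cham <- simulate_excurrent(0, 0, cewl, fr = chamber_flow,
                                 mode = "pull_chamber", bp = bp)
      k <- k + 1
      out[[k]] <- data.frame(
        bird_id = bird, ta_set_c = ta,
        line = c("mask", "chamber"),
        feo2 = c(mask$feo2, cham$feo2) +
          stats::rnorm(2, 0, noise_sd[["feo2"]]),
        feco2 = pmax(c(mask$feco2, cham$feco2) +
                       stats::rnorm(2, 0, noise_sd[["feco2"]]), 0),
        ph2o_kpa = pmax(c(mask$ph2o, cham$ph2o) +
                          stats::rnorm(2, 0, noise_sd[["ph2o"]]), 0),
        flow_mlmin = c(mask_flow, chamber_flow), bp_kpa = bp)
      tru[[k]] <- data.frame(bird_id = bird, ta_set_c = ta,
                             rewl = rewl, cewl = cewl, vo2 = vo2)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- do.call(rbind, tru)
  res
}
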