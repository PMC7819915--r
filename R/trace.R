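# Processing of multiplexed raw respirometry traces: demultiplexing into
# per-animal dwell segments with bracketing reference (incurrent air)
# readings, baseline correction of analyzer drift by linear interpolation
# between references, per-sample rate computation, and extraction of the
# steady-state windows used for analysis.

.TRACE_COLS <- c("time_s", "channel", "feo2", "feco2", "ph2o_kpa",
                 "flow_mlmin", "ta_c")

# contiguous runs of equal channel -> segment index table
.trace_runs <- function(channel) {
  r <- rle(as.character(channel))
  end <- cumsum(r$lengths)
  data.frame(channel = r$values, start = c(1L, head(end, -1) + 1L),
             end = end, stringsAsFactors = FALSE)
}

# summary of one reference dwell: mean of its last `ref_window` seconds
# (the dwell's own washout transient is thereby discarded)
.ref_summary <- function(trace, start, end, ref_window = 180) {
  tt <- trace$time_s[start:end]
  keep <- tt > tt[length(tt)] - ref_window
  idx <- (start:end)[keep]
  list(time = mean(trace$time_s[idx]),
       fio2 = mean(trace$feo2[idx]),
       fico2 = mean(trace$feco2[idx]),
       pih2o = mean(trace$ph2o_kpa[idx]))
}

#' Demultiplex a raw trace into per-animal segments
#'
#' Splits the trace at multiplexer switches, attaches to every animal
#' dwell the nearest preceding and following reference (incurrent air)
#' summaries, and masks the first `washout_discard` seconds after each
#' switch, during which the analyzer chain still reads a mixture of the
#' previous channel's air.
#'
#' @param trace a raw-trace data frame (see [read_raw_trace()] for the
#'   column schema).
#' @param mux_map named character vector mapping channel ids to bird ids.
#'   Channels equal to `ref_channel` are references.
#' @param washout_discard seconds masked after each switch (default 60).
#' @param ref_channel reference channel label (default `"REF"`).
#' @param ref_window seconds of each reference dwell averaged for the
#'   incurrent summary (default 180, the last 3 minutes of a 5-minute
#'   dwell).
#' @return A named list (one element per bird) of segment lists. Each
#'   segment is a list with `data` (the dwell's rows plus a logical
#'   `masked` column), `ref_before`, `ref_after` (either may be `NULL`,
#'   in which case `flag` is `TRUE`) and `channel`.
#' @export
demultiplex <- function(trace, mux_map, washout_discard = 60,
                        ref_channel = "REF", ref_window = 180) {
  miss <- setdiff(.TRACE_COLS, names(trace))
  if (length(miss))
    stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(trace$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  runs <- .trace_runs(trace$channel)
  known <- c(names(mux_map), ref_channel)
  unknown <- setdiff(unique(runs$channel), known)
  if (length(unknown))
    stop("unmapped channel id(s): ", paste(unknown, collapse = ", "))

  is_ref <- runs$channel == ref_channel
  if (sum(is_ref) < 1) stop("trace contains no reference segment")
  refs <- lapply(which(is_ref), function(i)
    .ref_summary(trace, runs$start[i], runs$end[i], ref_window))
  ref_times <- vapply(refs, `[[`, numeric(1), "time")

  out <- stats::setNames(vector("list", length(mux_map)),
                         unname(mux_map))
  for (i in which(!is_ref)) {
    rows <- runs$start[i]:runs$end[i]
    seg_dat <- trace[rows, , drop = FALSE]
    t0 <- seg_dat$time_s[1]
    seg_dat$masked <- seg_dat$time_s < t0 + washout_discard
    before <- which(ref_times < t0)
    after <- which(ref_times > seg_dat$time_s[nrow(seg_dat)])
    seg <- list(
      data = seg_dat,
      ref_before = if (length(before)) refs[[max(before)]] else NULL,
      ref_after = if (length(after)) refs[[min(after)]] else NULL,
      channel = runs$channel[i])
    seg$flag <- is.null(seg$ref_before) || is.null(seg$ref_after)
    bird <- unname(mux_map[[runs$channel[i]]])
    out[[bird]] <- c(out[[bird]], list(seg))
  }
  out
}

#' Baseline-correct a segment and compute per-sample exchange rates
#'
#' Models analyzer drift as affine in time: the incurrent composition seen
#' by each sample is the linear interpolation between the summaries of the
#' bracketing reference dwells. With a single reference available the
#' correction degenerates to a constant (with a warning). Per-sample
#' rates are then obtained with [gas_exchange_rates()] against the
#' time-varying incurrent values.
#'
#' @param segment one segment from [demultiplex()].
#' @param mode measurement configuration (default `"push_chamber"`).
#' @param bp barometric pressure, kPa.
#' @return The segment with `data` gaining columns `fio2_t`, `fico2_t`,
#'   `pih2o_t`, `vo2`, `vco2`, `ewl`.
#' @export
baseline_correct <- function(segment, mode = "push_chamber",
                             bp = 101.325) {
  rb <- segment$ref_before; ra <- segment$ref_after
  if (is.null(rb) && is.null(ra))
    stop("segment has no bracketing reference")
  if (is.null(rb) || is.null(ra)) {
    warning("only one reference available; constant extrapolation used")
    one <- if (is.null(rb)) ra else rb
    rb <- ra <- one
  }
  d <- segment$data
  w <- if (ra$time > rb$time) (d$time_s - rb$time) / (ra$time - rb$time)
       else rep(0, nrow(d))
  d$fio2_t <- rb$fio2 + w * (ra$fio2 - rb$fio2)
  d$fico2_t <- rb$fico2 + w * (ra$fico2 - rb$fico2)
  d$pih2o_t <- rb$pih2o + w * (ra$pih2o - rb$pih2o)

  s <- data.frame(feo2 = d$feo2, feco2 = d$feco2, ph2o = d$ph2o_kpa,
                  fr = d$flow_mlmin, mode = mode, fio2 = d$fio2_t,
                  fico2 = d$fico2_t, pih2o = d$pih2o_t, bp = bp)
  r <- suppressWarnings(gas_exchange_rates(s))
  d$vo2 <- r$vo2; d$vco2 <- r$vco2; d$ewl <- r$ewl
  segment$data <- d
  segment
}

#' Select the steady-state analysis window of a segment
#'
#' Slides a fixed-width window (step one sample) over the unmasked part
#' of a corrected segment and returns the window minimizing either the
#' mean V̇O2 (`"lowest_mean"`, the resting-rate rule) or the within-window
#' variance of V̇O2 (`"most_stable"`). Ties go to the earliest window.
#' Concurrent EWL, Tb (if present) and Ta are averaged over the same
#' window.
#'
#' @param segment a baseline-corrected segment, or a data frame with
#'   columns `time_s`, `vo2` (optionally `ewl`, `ta_c`, `tb_c`,
#'   `masked`).
#' @param criterion `"lowest_mean"` or `"most_stable"`.
#' @param width_s window width in seconds (120 for the lowest-mean rule,
#'   300 for the most-stable rule).
#' @return A list of class `steady_state_selection`: `window_start`,
#'   `window_end` (s), `criterion`, `mean_vo2`, `mean_vco2`, `mean_ewl`,
#'   `mean_ta`, `mean_tb` (NA when absent).
#' @export
select_steady_state <- function(segment,
                                criterion = c("lowest_mean",
                                              "most_stable"),
                                width_s = if (criterion == "most_stable")
                                  300 else 120) {
  criterion <- match.arg(criterion)
  d <- if (is.data.frame(segment)) segment else segment$data
  if (!is.null(d$masked)) d <- d[!d$masked, , drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("segment too short")
  dt <- stats::median(diff(d$time_s))
  w <- round(width_s / dt)
  if (n < w) stop("segment shorter than the requested window (",
                  width_s, " s) after masking")
  v <- d$vo2
  cs <- c(0, cumsum(v)); cs2 <- c(0, cumsum(v^2))
  i <- seq_len(n - w + 1)
  mu <- (cs[i + w] - cs[i]) / w
  score <- if (criterion == "lowest_mean") mu
           else (cs2[i + w] - cs2[i]) / w - mu^2
  best <- which.min(score)   # earliest on ties
  idx <- best:(best + w - 1)
  avg <- function(col) if (is.null(d[[col]])) NA_real_
                       else mean(d[[col]][idx])
  structure(list(window_start = d$time_s[best],
                 window_end = d$time_s[best + w - 1],
                 criterion = criterion,
                 mean_vo2 = mu[best],
                 mean_vco2 = avg("vco2"),
                 mean_ewl = avg("ewl"),
                 mean_ta = avg("ta_c"),
                 mean_tb = avg("tb_c")),
            class = "steady_state_selection")
}

#' Process a raw trace end to end into a steady-state table
#'
#' Convenience chain: [demultiplex()], [baseline_correct()] and
#' [select_steady_state()] per dwell, returning one row per bird per
#' dwell with the window means and derived MR and EHL.
#'
#' @inheritParams demultiplex
#' @inheritParams baseline_correct
#' @inheritParams select_steady_state
#' @return A data frame: `bird_id`, `ta_c`, `vo2_mlmin`, `vco2_mlmin`,
#'   `ewl_mgmin`, `mr_w`, `ehl_w`, `window_start_s`, `flag`.
#' @export
process_trace <- function(trace, mux_map, criterion = "lowest_mean",
                          width_s = 120, washout_discard = 60,
                          mode = "push_chamber", bp = 101.325,
                          ref_channel = "REF") {
  segs <- demultiplex(trace, mux_map, washout_discard = washout_discard,
                      ref_channel = ref_channel)
  rows <- list()
  for (bird in names(segs)) {
    for (seg in segs[[bird]]) {
      seg <- baseline_correct(seg, mode = mode, bp = bp)
      ss <- select_steady_state(seg, criterion = criterion,
                                width_s = width_s)
      rer <- if (ss$mean_vo2 > 0) ss$mean_vco2 / ss$mean_vo2 else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        bird_id = bird, ta_c = ss$mean_ta,
        vo2_mlmin = ss$mean_vo2, vco2_mlmin = ss$mean_vco2,
        ewl_mgmin = ss$mean_ewl,
        mr_w = if (is.finite(rer))
          suppressWarnings(metabolic_rate(ss$mean_vo2, rer))
          else NA_real_,
        ehl_w = ehl_from_ewl(max(ss$mean_ewl, 0)),
        window_start_s = ss$window_start, flag = isTRUE(seg$flag))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
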