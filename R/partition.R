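# Partitioning of evaporative heat loss into respiratory and cutaneous
# avenues from two-line mask respirometry: the mask line (pulled through
# the head mask) carries the respiratory water signal and the breath
# gases, the chamber line carries the cutaneous water signal.

#' Partition evaporative heat loss from a two-line mask measurement
#'
#' Inverts both pull-mode lines with [gas_exchange_rates()]: respiratory
#' evaporative water loss (REWL) from the mask line, cutaneous (CEWL)
#' from the chamber line, each converted to heat at 2.4 J per mg. Because
#' the mask encloses the whole head, REWL includes evaporation from the
#' head skin and eye surfaces; no correction is applied.
#'
#' @param mask_line,chamber_line single-row [gas_sample()]s (or data
#'   frames with the same columns) in modes `pull_mask` and
#'   `pull_chamber` respectively.
#' @param bird_id,ta_set identifiers carried into the record.
#' @return A one-row data frame of class `partition_record`: `bird_id`,
#'   `ta_set_c`, `rewl`, `cewl` (mg min^-1), `rehl`, `cehl`, `tehl` (W),
#'   `rehl_cehl_ratio`, `cehl_fraction` (CEHL/TEHL), `vo2`, `mr_w`
#'   (NA when the mask line carries no O2 signal), `flag`.
#' @export
partition_ehl <- function(mask_line, chamber_line, bird_id = NA,
                          ta_set = NA) {
  if (!all(mask_line$mode == "pull_mask"))
    stop("mask_line must be in pull_mask mode")
  if (!all(chamber_line$mode == "pull_chamber"))
    stop("chamber_line must be in pull_chamber mode")
  m <- suppressWarnings(gas_exchange_rates(mask_line))
  ch <- suppressWarnings(gas_exchange_rates(chamber_line))
  rewl <- m$ewl; cewl <- ch$ewl
  flag <- m$flag | ch$flag | rewl < 0 | cewl < 0
  rehl <- ehl_from_ewl(pmax(rewl, 0))
  cehl <- ehl_from_ewl(pmax(cewl, 0))
  tehl <- rehl + cehl
  vo2 <- m$vo2
  mr <- ifelse(vo2 > 0,
               suppressWarnings(metabolic_rate(vo2, m$vco2 / vo2)),
               NA_real_)
  out <- data.frame(bird_id = bird_id, ta_set_c = ta_set,
                    rewl = rewl, cewl = cewl, rehl = rehl, cehl = cehl,
                    tehl = tehl,
                    rehl_cehl_ratio = ifelse(cehl > 0, rehl / cehl,
                                             NA_real_),
                    cehl_fraction = ifelse(tehl > 0, cehl / tehl,
                                           NA_real_),
                    vo2 = vo2, mr_w = mr, flag = flag)
  class(out) <- c("partition_record", class(out))
  out
}

#' Partition a whole mask-session table
#'
#' Applies [partition_ehl()] to every bird-by-temperature pair of a long
#' mask-session table (one `mask` and one `chamber` row each).
#'
#' @param session a mask-session data frame (see [read_mask_session()]).
#' @return A data frame of partition records, one row per bird per
#'   stratum.
#' @export
partition_session <- function(session, bp = NULL) {
  need <- c("bird_id", "ta_set_c", "line", "feo2", "feco2", "ph2o_kpa",
            "flow_mlmin")
  miss <- setdiff(need, names(session))
  if (length(miss))
    stop("mask session is missing column(s): ",
         paste(miss, collapse = ", "))
  bp_col <- if (!is.null(session$bp_kpa)) session$bp_kpa
            else rep(if (is.null(bp)) 101.325 else bp, nrow(session))
  key <- interaction(session$bird_id, session$ta_set_c, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(session)), key), function(idx) {
    s <- session[idx, ]; b <- bp_col[idx]
    im <- which(s$line == "mask"); ic <- which(s$line == "chamber")
    if (length(im) != 1 || length(ic) != 1)
      stop("bird ", s$bird_id[1], " at ", s$ta_set_c[1],
           " °C: need exactly one mask and one chamber line")
    mk <- function(i, mode) data.frame(
      feo2 = s$feo2[i], feco2 = s$feco2[i], ph2o = s$ph2o_kpa[i],
      fr = s$flow_mlmin[i], mode = mode, fio2 = 0.2095, fico2 = 0,
      pih2o = 0, bp = b[i])
    partition_ehl(mk(im, "pull_mask"), mk(ic, "pull_chamber"),
                  bird_id = s$bird_id[1], ta_set = s$ta_set_c[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize partition records per temperature stratum
#'
#' Per-stratum means, medians and quartiles of the two avenues and their
#' ratios. The cutaneous contribution to total evaporative heat loss is
#' reported two ways: `cehl_fraction_mean`, the mean of the per-bird
#' fractions, and `cehl_fraction_pooled`, the ratio of the summed means
#' (sum CEHL / sum TEHL); the two differ when birds vary in total loss.
#'
#' @param records output of [partition_session()] (or rbound
#'   [partition_ehl()] rows).
#' @return A data frame, one row per `ta_set_c` stratum.
#' @export
summarize_partition <- function(records) {
  strata <- sort(unique(records$ta_set_c))
  rows <- list()
  for (ta in strata) {
    r <- records[records$ta_set_c == ta & !records$flag, , drop = FALSE]
    if (!nrow(r)) {
      warning("stratum ", ta, " °C has no unflagged records; omitted")
      next
    }
    q <- function(v, p) unname(stats::quantile(v, p, na.rm = TRUE))
    rows[[length(rows) + 1]] <- data.frame(
      ta_set_c = ta, n = nrow(r),
      rehl_mean = mean(r$rehl), rehl_median = q(r$rehl, 0.5),
      rehl_q25 = q(r$rehl, 0.25), rehl_q75 = q(r$rehl, 0.75),
      cehl_mean = mean(r$cehl), cehl_median = q(r$cehl, 0.5),
      cehl_q25 = q(r$cehl, 0.25), cehl_q75 = q(r$cehl, 0.75),
      ratio_median = q(r$rehl_cehl_ratio, 0.5),
      cehl_fraction_mean = mean(r$cehl_fraction, na.rm = TRUE),
      cehl_fraction_pooled = sum(r$cehl) / sum(r$tehl))
  }
  if (!length(rows)) stop("no stratum with data")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
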