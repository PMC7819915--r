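# End-to-end thermoregulatory profile estimation from a steady-state
# table: the standard four segmented fits and their synthesis.

#' Fit the full thermoregulatory profile from a steady-state table
#'
#' Pools all birds (the default analysis once no group differences are
#' found) and fits: MR vs Ta with two breakpoints and a horizontal middle
#' segment (the thermoneutral plateau); Tb vs Ta and EHL vs Ta each with
#' one breakpoint and a horizontal first segment; and the per-observation
#' EHL/MR ratio vs Ta with the same plateau-then-rise shape. Breakpoint
#' and plateau SEs come from a cluster bootstrap over birds.
#'
#' @param ss steady-state data frame (see [read_steady_state()]).
#' @param bootstrap bootstrap replicates per fit (default 200; 0 skips
#'   SEs).
#' @param seed seed for the bootstraps.
#' @param fit_ehlmr also fit the EHL/MR ratio (default TRUE).
#' @param min_seg minimum observations per segment (default 5).
#' @return A list with the four `segmented_fit`s (`mr`, `tb`, `ehl`,
#'   `ehlmr`) and the derived `profile` (class `thermoreg_profile`).
#' @export
fit_thermoreg_profile <- function(ss, bootstrap = 200, seed = NULL,
                                  fit_ehlmr = TRUE, min_seg = 5) {
  need <- c("bird_id", "ta_c", "mr_w", "ehl_w", "tb_c")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("steady-state table is missing column(s): ",
         paste(miss, collapse = ", "))
  sd_seed <- function(k) if (is.null(seed)) NULL else seed + k
  mr <- fit_segmented(ss$ta_c, ss$mr_w, n_breakpoints = 2,
                      constraints = c("free", "horizontal", "free"),
                      cluster = ss$bird_id, bootstrap = bootstrap,
                      seed = sd_seed(1), min_seg = min_seg)
  tb <- fit_segmented(ss$ta_c, ss$tb_c, n_breakpoints = 1,
                      constraints = c("horizontal", "free"),
                      cluster = ss$bird_id, bootstrap = bootstrap,
                      seed = sd_seed(2), min_seg = min_seg)
  ehl <- fit_segmented(ss$ta_c, ss$ehl_w, n_breakpoints = 1,
                       constraints = c("horizontal", "free"),
                       cluster = ss$bird_id, bootstrap = bootstrap,
                       seed = sd_seed(3), min_seg = min_seg)
  ehlmr <- NULL
  if (fit_ehlmr)
    ehlmr <- fit_segmented(ss$ta_c, ss$ehl_w / ss$mr_w, n_breakpoints = 1,
                           constraints = c("horizontal", "free"),
                           cluster = ss$bird_id, bootstrap = bootstrap,
                           seed = sd_seed(4), min_seg = min_seg)
  list(mr = mr, tb = tb, ehl = ehl, ehlmr = ehlmr,
       profile = derive_profile(mr, tb, ehl, ehlmr))
}
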