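# Continuous segmented (piecewise-linear) least-squares regression with
# optional horizontal-segment constraints, breakpoint location by grid
# search over the midpoints of the sorted unique predictor values refined
# by golden-section search, model selection by nested F-tests, and
# cluster-bootstrap standard errors that resample individuals to respect
# repeated measures.

# Design matrix for fixed breakpoints. Parametrization: intercept = value
# at x0 = min(x); one "covered length" column per free-slope segment,
# z_s(x) = min(max(x - lo_s, 0), hi_s - lo_s). Continuity at every
# breakpoint is built in; a horizontal segment simply drops its column.
.seg_design <- function(x, psi, constraints, x0) {
  k <- length(psi)
  lo <- c(x0, psi)
  hi <- c(psi, Inf)
  cols <- list(`(level)` = rep(1, length(x)))
  for (s in seq_len(k + 1)) {
    if (constraints[s] == "horizontal") next
    cols[[paste0("slope", s)]] <- pmin(pmax(x - lo[s], 0), hi[s] - lo[s])
  }
  do.call(cbind, cols)
}

.seg_sse <- function(x, y, psi, constraints, x0) {
  X <- .seg_design(x, psi, constraints, x0)
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

# candidate breakpoints: midpoints between adjacent sorted unique x,
# keeping only those leaving >= min_seg points in every segment
.seg_candidates <- function(ux, min_seg) {
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  mids
}

.seg_feasible <- function(x_sorted, psi, min_seg) {
  counts <- tabulate(findInterval(x_sorted, vec = psi) + 1L,
                     nbins = length(psi) + 1L)
  all(counts >= min_seg) && all(diff(psi) > 0)
}

#' Fit a continuous segmented linear regression
#'
#' Least-squares piecewise-linear fit with 0, 1 or 2 breakpoints and
#' continuity enforced at each breakpoint. Breakpoints are located by
#' exhaustive search over the midpoints of the sorted unique `x` values
#' (all feasible pairs for two breakpoints), then refined by
#' golden-section search to `refine_tol`. Individual segments can be
#' constrained horizontal (slope exactly zero), the natural shape for
#' thermoneutral-zone plateaus.
#'
#' Standard errors of breakpoints, slopes and segment levels come from a
#' nonparametric cluster bootstrap: individuals (`cluster`) are resampled
#' with replacement and the whole search is re-run, so the SE reflects
#' repeated measures per bird. Without `cluster`, rows are resampled.
#'
#' @param x,y predictor (e.g. ambient temperature, degrees C) and response.
#' @param n_breakpoints 0, 1 or 2.
#' @param constraints character vector, one per segment
#'   (`n_breakpoints + 1`), each `"free"` or `"horizontal"`. Default all
#'   free.
#' @param cluster optional vector of individual ids for the cluster
#'   bootstrap.
#' @param bootstrap number of bootstrap replicates for SEs (0 = none).
#' @param seed seed for the bootstrap.
#' @param min_seg minimum observations per segment (default 5).
#' @param refine_tol golden-section tolerance on breakpoints (default
#'   1e-4).
#' @return An object of class `segmented_fit`: breakpoints (+`breakpoint_se`),
#'   per-segment `slopes` and `intercepts` (y = intercept + slope x within
#'   the segment), `fitted`, `residuals`, `sse`, `r2`, `residual_sd`,
#'   `n_obs`, `n_par`, and (if bootstrapped) the replicate parameter
#'   matrix `boot`.
#' @export
fit_segmented <- function(x, y, n_breakpoints = 1, constraints = NULL,
                          cluster = NULL, bootstrap = 0, seed = NULL,
                          min_seg = 5, refine_tol = 1e-4) {
  stopifnot(length(x) == length(y), n_breakpoints %in% 0:2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(cluster)) cluster <- cluster[ok]
  if (length(unique(x)) < 2) stop("x values are all equal")
  if (length(x) < (n_breakpoints + 1) * min_seg)
    stop("too few observations: need at least ", min_seg,
         " per prospective segment")
  if (is.null(constraints)) constraints <- rep("free", n_breakpoints + 1)
  if (length(constraints) != n_breakpoints + 1)
    stop("need one constraint per segment (", n_breakpoints + 1, ")")
  if (!all(constraints %in% c("free", "horizontal")))
    stop("constraints must be 'free' or 'horizontal'")

  fit <- .fit_segmented_core(x, y, n_breakpoints, constraints,
                             min_seg, refine_tol)

  boot <- NULL; bp_se <- NULL
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    cl <- if (is.null(cluster)) seq_along(x) else cluster
    ucl <- unique(cl)
    idx_by <- split(seq_along(x), match(cl, ucl))
    reps <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      take <- sample(length(ucl), replace = TRUE)
      idx <- unlist(idx_by[take], use.names = FALSE)
      reps[[b]] <- tryCatch(
        .seg_params(.fit_segmented_core(x[idx], y[idx], n_breakpoints,
                                        constraints, min_seg, refine_tol)),
        error = function(e) NULL)
    }
    reps <- reps[!vapply(reps, is.null, logical(1))]
    if (length(reps)) {
      boot <- do.call(rbind, reps)
      if (n_breakpoints > 0)
        bp_se <- apply(boot[, seq_len(n_breakpoints), drop = FALSE], 2,
                       stats::sd)
    }
  }
  fit$boot <- boot
  fit$breakpoint_se <- bp_se
  fit
}

# single deterministic fit (no bootstrap) on clean numeric x, y
.fit_segmented_core <- function(x, y, k, constraints, min_seg, refine_tol) {
  x0 <- min(x)
  xs <- sort(x)
  ux <- sort(unique(x))
  sse_at <- function(psi) .seg_sse(x, y, psi, constraints, x0)

  if (k == 0) {
    psi <- numeric(0)
  } else {
    mids <- .seg_candidates(ux, min_seg)
    if (k == 1) {
      feas <- mids[vapply(mids, function(p) .seg_feasible(xs, p, min_seg),
                          logical(1))]
      if (!length(feas)) stop("no feasible breakpoint position")
      # the SSE profile has a kink at every data point: treat each
      # inter-point cell as its own bracket and golden-section it, so the
      # search is effectively exhaustive over cells
      psi <- feas[1]; psi_sse <- sse_at(feas[1])
      for (m in feas) {
        i <- findInterval(m, ux)
        lower <- ux[i] + refine_tol / 10
        upper <- ux[i + 1] - refine_tol / 10
        if (upper <= lower) next
        for (cand in c(m, stats::optimize(sse_at, c(lower, upper),
                                          tol = refine_tol)$minimum)) {
          s <- sse_at(cand)
          if (s < psi_sse) { psi <- cand; psi_sse <- s }
        }
      }
    } else {
      pairs <- which(outer(mids, mids, "<"), arr.ind = TRUE)
      psse <- rep(Inf, nrow(pairs))
      for (r in seq_len(nrow(pairs))) {
        p <- c(mids[pairs[r, 1]], mids[pairs[r, 2]])
        if (.seg_feasible(xs, p, min_seg)) psse[r] <- sse_at(p)
      }
      if (!any(is.finite(psse))) stop("no feasible breakpoint pair")
      step <- stats::median(diff(ux))
      refine_pair <- function(psi) {
        # coordinate-wise golden-section refinement
        for (sweep in 1:10) {
          old <- psi
          for (j in 1:2) {
            lower <- if (j == 1) max(ux[min_seg], psi[1] - 2 * step)
                     else max(psi[1] + refine_tol, psi[2] - 2 * step)
            upper <- if (j == 1) min(psi[2] - refine_tol, psi[1] + 2 * step)
                     else min(ux[length(ux) - min_seg + 1],
                              psi[2] + 2 * step)
            if (upper <= lower) next
            obj <- function(p) {
              q <- psi; q[j] <- p
              # large finite penalty: optimize() warns on Inf
              if (!.seg_feasible(xs, q, min_seg)) return(1e300)
              sse_at(q)
            }
            cand <- stats::optimize(obj, c(lower, upper),
                                    tol = refine_tol)$minimum
            q <- psi; q[j] <- cand
            if (.seg_feasible(xs, q, min_seg) && sse_at(q) <= sse_at(psi))
              psi[j] <- cand
          }
          if (max(abs(psi - old)) < refine_tol) break
        }
        psi
      }
      top <- order(psse)[seq_len(min(3, sum(is.finite(psse))))]
      psi <- NULL; best_sse <- Inf
      for (r in top) {
        cand <- refine_pair(c(mids[pairs[r, 1]], mids[pairs[r, 2]]))
        s <- sse_at(cand)
        if (s < best_sse) { best_sse <- s; psi <- cand }
      }
    }
  }

  X <- .seg_design(x, psi, constraints, x0)
  lsf <- stats::lm.fit(X, y)
  coefs <- lsf$coefficients
  fitted <- as.vector(X %*% ifelse(is.na(coefs), 0, coefs))
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)

  slopes <- numeric(k + 1)
  free <- which(constraints == "free")
  slopes[free] <- coefs[paste0("slope", free)]
  slopes[is.na(slopes)] <- 0

  lo <- c(x0, psi)
  pred1 <- function(xx) {
    Xn <- .seg_design(xx, psi, constraints, x0)
    as.vector(Xn %*% ifelse(is.na(coefs), 0, coefs))
  }
  v_lo <- pred1(lo)
  intercepts <- v_lo - slopes * lo

  n_par <- 1 + length(free) + k   # level + free slopes + breakpoints
  structure(list(
    breakpoints = psi, breakpoint_se = NULL,
    slopes = slopes, intercepts = intercepts,
    constraints = constraints, n_breakpoints = k,
    coefficients = coefs, fitted = fitted, residuals = res,
    sse = sse, r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    residual_sd = sqrt(sse / max(length(x) - n_par, 1)),
    n_obs = length(x), n_par = n_par,
    x_range = range(x), x0 = x0, boot = NULL),
    class = "segmented_fit")
}

# standardized parameter vector for bootstrap summaries:
# breakpoints, per-segment slopes, per-segment levels (fitted value at
# the segment midpoint, clipped to the data range)
.seg_params <- function(fit) {
  k <- fit$n_breakpoints
  edges <- c(fit$x_range[1], fit$breakpoints, fit$x_range[2])
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  lev <- predict(fit, mids)
  out <- c(fit$breakpoints, fit$slopes, lev)
  names(out) <- c(if (k) paste0("bp", seq_len(k)),
                  paste0("slope", seq_len(k + 1)),
                  paste0("level", seq_len(k + 1)))
  out
}

#' @export
predict.segmented_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  x <- if (is.list(newdata)) newdata[[1]] else newdata
  X <- .seg_design(x, object$breakpoints, object$constraints, object$x0)
  co <- object$coefficients
  as.vector(X %*% ifelse(is.na(co), 0, co))
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented linear fit:", x$n_breakpoints, "breakpoint(s),",
      x$n_obs, "observations\n")
  if (x$n_breakpoints > 0) {
    bp <- sprintf("%.3f", x$breakpoints)
    if (!is.null(x$breakpoint_se))
      bp <- paste0(bp, " (SE ", sprintf("%.3f", x$breakpoint_se), ")")
    cat("  breakpoints:", paste(bp, collapse = ", "), "\n")
  }
  for (s in seq_along(x$slopes))
    cat(sprintf("  segment %d [%s]: slope %.5f, intercept %.4f\n", s,
                x$constraints[s], x$slopes[s], x$intercepts[s]))
  cat(sprintf("  SSE %.6g, R2 %.4f, residual SD %.4g\n",
              x$sse, x$r2, x$residual_sd))
  invisible(x)
}

#' Select the best segmented model by nested F-tests
#'
#' Fits each candidate shape and walks the candidates in order of
#' increasing parameter count, adopting a more complex candidate only when
#' the F-test against the currently held model is significant at `alpha`.
#' On non-significance the simpler model (fewer breakpoints, more
#' constraints) is retained.
#'
#' @param x,y data.
#' @param candidates list of candidate specifications, each a list with
#'   `n_breakpoints` and optional `constraints`. The default ladder is:
#'   straight line; one breakpoint with horizontal first segment; one
#'   breakpoint free; two breakpoints with horizontal middle segment.
#' @param alpha significance level for the nested F-test (default 0.05).
#' @param ... passed to [fit_segmented()] (e.g. `min_seg`).
#' @return The selected `segmented_fit`, with the comparison table in
#'   attribute `selection`.
#' @export
select_model_type <- function(x, y,
                              candidates = list(
                                list(n_breakpoints = 0),
                                list(n_breakpoints = 1,
                                     constraints = c("horizontal", "free")),
                                list(n_breakpoints = 1),
                                list(n_breakpoints = 2,
                                     constraints = c("free", "horizontal",
                                                     "free"))),
                              alpha = 0.05, ...) {
  if (!length(candidates)) stop("candidate set is empty")
  fits <- lapply(candidates, function(cc)
    tryCatch(fit_segmented(x, y, n_breakpoints = cc$n_breakpoints,
                           constraints = cc$constraints, ...),
             error = function(e) NULL))
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  if (!length(fits)) stop("no candidate model could be fitted")
  np <- vapply(fits, function(f) f$n_par, numeric(1))
  ord <- order(np)
  fits <- fits[ord]; np <- np[ord]

  n <- fits[[1]]$n_obs
  best <- fits[[1]]
  rows <- list()
  for (i in seq_along(fits)[-1]) {
    f <- fits[[i]]
    df1 <- f$n_par - best$n_par
    df2 <- n - f$n_par
    if (df1 <= 0 || df2 <= 0 || f$sse >= best$sse) {
      rows[[i]] <- c(NA, NA); next
    }
    Fstat <- ((best$sse - f$sse) / df1) / (f$sse / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    rows[[i]] <- c(Fstat, p)
    if (p < alpha) best <- f
  }
  sel <- data.frame(
    n_breakpoints = vapply(fits, function(f) f$n_breakpoints, numeric(1)),
    n_par = np,
    sse = vapply(fits, function(f) f$sse, numeric(1)),
    F = c(NA, vapply(rows[-1], `[`, numeric(1), 1)),
    p = c(NA, vapply(rows[-1], `[`, numeric(1), 2)))
  attr(best, "selection") <- sel
  best
}

#' Derive the thermoregulatory profile from four segmented fits
#'
#' Combines the fitted curves of metabolic rate (three segments,
#' horizontal middle), body temperature, evaporative heat loss and their
#' ratio (each two segments, horizontal first) into the characteristic
#' points of the Scholander-Irving model: critical temperatures, basal
#' metabolic rate, hyperthermia threshold, EHL inflection and the rising
#' slopes. MR slopes are reported as magnitudes (W per degree C of
#' cooling below the zone; W per degree C of warming above it).
#'
#' @param mr_fit `segmented_fit` of MR vs Ta: 2 breakpoints, middle
#'   segment horizontal.
#' @param tb_fit `segmented_fit` of Tb vs Ta: 1 breakpoint, first segment
#'   horizontal.
#' @param ehl_fit `segmented_fit` of EHL vs Ta: same shape as `tb_fit`.
#' @param ehlmr_fit optional `segmented_fit` of EHL/MR vs Ta, same shape;
#'   fitted directly on the per-observation ratio.
#' @return A list of class `thermoreg_profile` with elements `t_lc`,
#'   `t_uc`, `bmr`, `mr_slope_below`, `mr_slope_above`, `tb_plateau`,
#'   `tb_threshold`, `tb_slope`, `ehl_plateau`, `ehl_inflection`,
#'   `ehl_slope` and, when `ehlmr_fit` is given, `ehlmr_inflection` and
#'   `ehlmr_max` (fitted ratio at the highest observed Ta). Available
#'   bootstrap SEs are attached in `se`.
#' @export
derive_profile <- function(mr_fit, tb_fit, ehl_fit, ehlmr_fit = NULL) {
  chk <- function(fit, k, horiz, name) {
    if (!inherits(fit, "segmented_fit"))
      stop(name, " is not a segmented_fit")
    if (fit$n_breakpoints != k)
      stop(name, " must have ", k, " breakpoint(s), has ",
           fit$n_breakpoints)
    if (fit$constraints[horiz] != "horizontal")
      stop(name, ": segment ", horiz, " must be constrained horizontal")
  }
  chk(mr_fit, 2, 2, "mr_fit")
  chk(tb_fit, 1, 1, "tb_fit")
  chk(ehl_fit, 1, 1, "ehl_fit")
  if (!is.null(ehlmr_fit)) chk(ehlmr_fit, 1, 1, "ehlmr_fit")

  se_of <- function(fit, col) {
    if (is.null(fit$boot) || !col %in% colnames(fit$boot)) NA_real_
    else stats::sd(fit$boot[, col])
  }
  prof <- list(
    t_lc = mr_fit$breakpoints[1], t_uc = mr_fit$breakpoints[2],
    bmr = unname(predict(mr_fit, mean(mr_fit$breakpoints))),
    mr_slope_below = abs(mr_fit$slopes[1]),
    mr_slope_above = mr_fit$slopes[3],
    tb_plateau = unname(predict(tb_fit, tb_fit$x_range[1])),
    tb_threshold = tb_fit$breakpoints[1],
    tb_slope = tb_fit$slopes[2],
    ehl_plateau = unname(predict(ehl_fit, ehl_fit$x_range[1])),
    ehl_inflection = ehl_fit$breakpoints[1],
    ehl_slope = ehl_fit$slopes[2])
  se <- list(
    t_lc = se_of(mr_fit, "bp1"), t_uc = se_of(mr_fit, "bp2"),
    bmr = se_of(mr_fit, "level2"),
    tb_threshold = se_of(tb_fit, "bp1"),
    ehl_inflection = se_of(ehl_fit, "bp1"))
  if (!is.null(ehlmr_fit)) {
    prof$ehlmr_inflection <- ehlmr_fit$breakpoints[1]
    prof$ehlmr_max <- unname(predict(ehlmr_fit, ehlmr_fit$x_range[2]))
    se$ehlmr_inflection <- se_of(ehlmr_fit, "bp1")
  }
  prof$se <- se
  class(prof) <- "thermoreg_profile"
  prof
}

#' @export
print.thermoreg_profile <- function(x, ...) {
  fmt <- function(v, s) {
    if (!is.null(s) && is.finite(s)) sprintf("%.3f ± %.3f", v, s)
    else sprintf("%.3f", v)
  }
  cat("Thermoregulatory profile\n")
  cat("  TNZ:", fmt(x$t_lc, x$se$t_lc), "to", fmt(x$t_uc, x$se$t_uc),
      "°C\n")
  cat("  BMR:", fmt(x$bmr, x$se$bmr), "W\n")
  cat(sprintf("  MR slope below/above TNZ: %.4f / %.4f W °C⁻¹\n",
              x$mr_slope_below, x$mr_slope_above))
  cat("  Tb plateau:", sprintf("%.2f", x$tb_plateau), "°C; hyperthermia above",
      fmt(x$tb_threshold, x$se$tb_threshold),
      sprintf("°C (slope %.3f)\n", x$tb_slope))
  cat("  EHL plateau:", sprintf("%.4f", x$ehl_plateau), "W; inflection at",
      fmt(x$ehl_inflection, x$se$ehl_inflection),
      sprintf("°C (slope %.4f W °C⁻¹)\n", x$ehl_slope))
  if (!is.null(x$ehlmr_inflection))
    cat("  EHL/MR inflection:", fmt(x$ehlmr_inflection, x$se$ehlmr_inflection),
        sprintf("°C; ratio at max Ta %.2f\n", x$ehlmr_max))
  invisible(x)
}
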