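# ANOVA-based intraclass-correlation repeatability (the classical
# one-way variance-components estimator for repeated measures on
# individuals), with covariate adjustment by least-squares residuals and
# cluster-bootstrap standard errors.

#' Repeatability (intraclass correlation) from one-way ANOVA
#'
#' Estimates the fraction of variance attributable to consistent
#' among-individual differences. From the one-way ANOVA mean squares,
#' \deqn{s^2_A = (MS_A - MS_W)/n_0, \quad
#'       n_0 = (N - \sum n_i^2 / N)/(a - 1),}
#' and \eqn{\tau = s^2_A / (s^2_A + MS_W)}; the p-value is the ANOVA F
#' test of the among-group term. Negative variance estimates are
#' truncated to zero and flagged (`truncated`).
#'
#' @param values numeric response.
#' @param group_ids individual identifiers (repeated measures share an
#'   id).
#' @param bootstrap replicates for a cluster-bootstrap SE over
#'   individuals (0 = no SE).
#' @param seed seed for the bootstrap.
#' @return A list of class `repeatability`: `tau`, `se`, `p_value`,
#'   `n_groups`, `n0`, `variance_among`, `variance_within`,
#'   `truncated`.
#' @export
repeatability_anova <- function(values, group_ids, bootstrap = 0,
                                seed = NULL) {
  ok <- is.finite(values) & !is.na(group_ids)
  values <- values[ok]; group_ids <- group_ids[ok]
  g <- factor(group_ids)
  if (any(table(g) == 0)) stop("group with zero observations")
  a <- nlevels(g)
  N <- length(values)
  if (a < 2) stop("need at least two individuals")
  if (N - a < 1)
    stop("need at least two replicate measurements beyond the number of ",
         "individuals")
  if (a < 5)
    warning("very few individuals (", a, "); repeatability is unstable")

  ni <- as.vector(table(g))
  mi <- tapply(values, g, mean)
  m <- mean(values)
  msa <- sum(ni * (mi - m)^2) / (a - 1)
  msw <- sum((values - mi[g])^2) / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  s2a <- (msa - msw) / n0
  truncated <- s2a < 0
  if (truncated) s2a <- 0
  tau <- if (s2a + msw > 0) s2a / (s2a + msw) else 0
  p <- if (msw > 0)
    stats::pf(msa / msw, a - 1, N - a, lower.tail = FALSE)
  else 0

  se <- NA_real_
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    idx_by <- split(seq_len(N), g)
    taus <- vapply(seq_len(bootstrap), function(b) {
      take <- sample(a, replace = TRUE)
      idx <- unlist(idx_by[take], use.names = FALSE)
      newg <- rep(seq_along(take),
                  times = lengths(idx_by[take]))
      tryCatch(repeatability_anova(values[idx], newg)$tau,
               error = function(e) NA_real_)
    }, numeric(1))
    se <- stats::sd(taus, na.rm = TRUE)
  }
  structure(list(tau = tau, se = se, p_value = p, n_groups = a, n0 = n0,
                 variance_among = s2a, variance_within = msw,
                 truncated = truncated),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability tau = %.4f", x$tau))
  if (is.finite(x$se)) cat(sprintf(" ± %.4f", x$se))
  cat(sprintf(" (p = %.3g, %d individuals, n0 = %.2f)\n",
              x$p_value, x$n_groups, x$n0))
  if (x$truncated)
    cat("  note: among-individual variance truncated at 0\n")
  invisible(x)
}

#' Covariate-adjusted repeatability
#'
#' Removes fixed effects (covariates and factors) by ordinary least
#' squares, then estimates the intraclass correlation of the residuals
#' grouped by individual with [repeatability_anova()]. The SE comes from
#' a cluster bootstrap over individuals in which the adjustment and the
#' ANOVA are both re-run on every resample.
#'
#' @param values numeric response.
#' @param group_ids individual identifiers.
#' @param covariates data frame of adjustment variables (numeric
#'   covariates and/or factors); must be full rank.
#' @param bootstrap cluster-bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap.
#' @return A `repeatability` object (with `adjusted = TRUE`).
#' @export
adjusted_repeatability <- function(values, group_ids, covariates,
                                   bootstrap = 1000, seed = NULL) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(values))
  ok <- is.finite(values) & !is.na(group_ids) &
    stats::complete.cases(covariates)
  values <- values[ok]; group_ids <- group_ids[ok]
  covariates <- covariates[ok, , drop = FALSE]

  adjust <- function(v, cov) {
    X <- stats::model.matrix(~ ., data = cov)
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient adjustment design (collinear covariates)")
    stats::lm.fit(X, v)$residuals
  }
  base <- repeatability_anova(adjust(values, covariates), group_ids)

  se <- NA_real_
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    g <- factor(group_ids)
    idx_by <- split(seq_along(values), g)
    a <- nlevels(g)
    taus <- vapply(seq_len(bootstrap), function(b) {
      take <- sample(a, replace = TRUE)
      idx <- unlist(idx_by[take], use.names = FALSE)
      newg <- rep(seq_along(take), times = lengths(idx_by[take]))
      tryCatch(
        repeatability_anova(
          adjust(values[idx], droplevels(covariates[idx, , drop = FALSE])),
          newg)$tau,
        error = function(e) NA_real_)
    }, numeric(1))
    se <- stats::sd(taus, na.rm = TRUE)
  }
  base$se <- se
  base$adjusted <- TRUE
  base
}
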