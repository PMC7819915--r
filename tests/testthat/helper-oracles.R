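# Independent brute-force oracles used across the suite. These stay
# deliberately naive: they enumerate rather than optimize, so they cannot
# share a defect with the implementation they check.

# SSE of a continuous piecewise fit at a FIXED breakpoint vector, computed
# from scratch with lm() on hinge bases (free slopes) or constrained bases.
oracle_seg_sse <- function(x, y, psi, constraints) {
  k <- length(psi)
  lo <- c(min(x), psi)
  hi <- c(psi, Inf)
  X <- matrix(1, nrow = length(x), ncol = 1)
  for (s in seq_len(k + 1)) {
    if (constraints[s] == "horizontal") next
    X <- cbind(X, pmin(pmax(x - lo[s], 0), hi[s] - lo[s]))
  }
  sum(lm.fit(X, y)$residuals^2)
}

# exhaustive fine-grid search for the best single breakpoint
oracle_best_bp1 <- function(x, y, constraints = c("free", "free"),
                            step = 0.01, min_seg = 5) {
  xs <- sort(x)
  grid <- seq(xs[min_seg], xs[length(xs) - min_seg + 1], by = step)
  grid <- grid[vapply(grid, function(p)
    sum(x <= p) >= min_seg && sum(x > p) >= min_seg, logical(1))]
  sse <- vapply(grid, function(p) oracle_seg_sse(x, y, p, constraints),
                numeric(1))
  list(psi = grid[which.min(sse)], sse = min(sse))
}

# exhaustive window enumeration for steady-state selection
oracle_window <- function(vo2, w, criterion) {
  n <- length(vo2)
  scores <- vapply(seq_len(n - w + 1), function(i) {
    win <- vo2[i:(i + w - 1)]
    if (criterion == "lowest_mean") mean(win)
    else mean(win^2) - mean(win)^2
  }, numeric(1))
  which.min(scores)
}

# default study-design dataset used by several tests
default_dataset <- function(seed = 42) {
  generate_steady_state(scholander_truth(),
                        generator_config(seed = seed))
}
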