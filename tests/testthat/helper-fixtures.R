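# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A small synthetic cohort spec that keeps unit tests fast.
small_spec <- function(n_subjects = 2, n_runs = 3, seed = 1L, ...) {
  synthetic_spec(n_subjects = n_subjects, n_runs = n_runs, seed = seed, ...)
}

# A valid in-range run built from arbitrary (finite) signal columns.
run_from_signal <- function(X, rate = 50, ...) {
  X <- as.matrix(X)
  X <- 500 + 400 * X / max(abs(X), 1e-12)
  colnames(X) <- default_layout()$relevant19[seq_len(ncol(X))]
  sensor_run(X, rate = rate, ...)
}

# Smooth random series (low-pass filtered white noise), unit variance.
smooth_series <- function(n, rate = 50, cutoff = 5) {
  x <- fir_lowpass(rnorm(n + 100), rate = rate, cutoff = cutoff)[51:(50 + n)]
  as.numeric(scale(x))
}

# Independent brute-force delay oracle: explicit overlap sums over all
# lags, same contract (max |r|, ties toward smaller |lag|, then the
# negative lag).
oracle_delay <- function(a, b, max_lag) {
  n <- length(a)
  best <- NULL
  for (l in seq.int(-max_lag, max_lag)) {
    if (l >= 0) {
      x <- a[1:(n - l)]
      y <- b[(1 + l):n]
    } else {
      x <- a[(1 - l):n]
      y <- b[1:(n + l)]
    }
    m <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- sum(x * y) - sx * sy / m
    den <- sqrt((sum(x^2) - sx^2 / m) * (sum(y^2) - sy^2 / m))
    r <- abs(num / den)
    better <- is.null(best) || r > best$r + 1e-14 ||
      (abs(r - best$r) <= 1e-14 &&
         (abs(l) < abs(best$l) || (abs(l) == abs(best$l) && l < best$l)))
    if (better) best <- list(l = l, r = r)
  }
  best$l
}

# Planted weighted 12-node network: within-group weight `win`,
# between-group `bet`, groups of size 4.
planted_network <- function(win = 0.8, bet = -0.4) {
  g <- rep(1:3, each = 4)
  W <- ifelse(outer(g, g, `==`), win, bet)
  diag(W) <- 0
  rownames(W) <- colnames(W) <- default_layout()$graph12
  list(net = joint_network(W), groups = g)
}
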