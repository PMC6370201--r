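# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's cumulative-sum / banded-solve code
# paths: plain double loops, stats::cor / stats::lm, and dense linear algebra.

# Brute-force WCLC landscape: double loop over (window start, lag) with cor().
oracle_landscape_wclc <- function(a, b, W, max_lag, step) {
  n <- length(a)
  tg <- seq.int(0L, n - 1L, by = step)
  lg <- seq.int(-max_lag, max_lag, by = step)
  r2 <- matrix(NA_real_, length(tg), length(lg))
  for (i in seq_along(tg)) {
    for (j in seq_along(lg)) {
      t <- tg[i]; l <- lg[j]
      if (t + W <= n && t + l >= 0 && t + l + W <= n) {
        r <- stats::cor(a[(t + 1):(t + W)], b[(t + l + 1):(t + l + W)])
        r2[i, j] <- r * r
      }
    }
  }
  r2
}

# Least-squares WCLR oracle: explicit lm() fits of the baseline and full model.
oracle_wclr_lm <- function(a_win, b_win) {
  W <- length(b_win)
  y <- b_win[2:W]; bl <- b_win[1:(W - 1)]; ap <- a_win[2:W]
  r2b <- summary(stats::lm(y ~ bl))$r.squared
  r2f <- summary(stats::lm(y ~ bl + ap))$r.squared
  delta <- r2f - r2b
  f <- delta / ((1 - r2f) / (W - 4))
  list(delta_r2 = delta,
       p_value = stats::pf(f, 1, W - 4, lower.tail = FALSE))
}

# Dense generalized-ridge solve of the natural cubic smoothing spline system:
# f = (I + lambda * Q R^{-1} t(Q))^{-1} y with Q, R assembled densely.
oracle_spline_fit <- function(y, p) {
  n <- length(y)
  lambda <- (1 - p) / p
  Q <- matrix(0, n, n - 2)
  for (j in seq_len(n - 2)) Q[j:(j + 2), j] <- c(1, -2, 1)
  R <- diag(2 / 3, n - 2)
  for (j in seq_len(n - 3)) R[j, j + 1] <- R[j + 1, j] <- 1 / 6
  K <- Q %*% solve(R, t(Q))
  as.numeric(solve(diag(n) + lambda * K, y))
}

# Kappa straight from the 2x2 contingency counts.
oracle_kappa <- function(ref, det) {
  n <- length(ref)
  n11 <- sum(ref == 1 & det == 1); n10 <- sum(ref == 1 & det == 0)
  n01 <- sum(ref == 0 & det == 1); n00 <- sum(ref == 0 & det == 0)
  p_o <- (n11 + n00) / n
  p_e <- ((n11 + n10) / n) * ((n11 + n01) / n) +
    ((n01 + n00) / n) * ((n10 + n00) / n)
  if (p_e >= 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

# Kruskal-Wallis H by the textbook rank formula with tie correction.
oracle_kruskal_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# One raised-cosine bump added into `v` (1-based onset).
add_test_bump <- function(v, onset, width, amp) {
  tt <- (seq_len(width) - 0.5) / width
  idx <- onset + seq_len(width) - 1L
  keep <- idx >= 1 & idx <= length(v)
  v[idx[keep]] <- v[idx[keep]] + amp * 0.5 * (1 - cos(2 * pi * tt[keep]))
  v
}

# Minimal isolated-condition sync dyad with one pulse episode at [s, e).
make_pulse_dyad <- function(n = 2200, s = 1000, e = 1130, lag = 0,
                            amps_a = c(60, 40), amps_b = NULL,
                            id = "fix_sync_isolated") {
  if (is.null(amps_b)) amps_b <- amps_a
  a <- numeric(n); b <- numeric(n)
  width <- floor((e - s) / length(amps_a))
  for (k in seq_along(amps_a)) {
    on <- s + (k - 1L) * width + 1L
    a <- add_test_bump(a, on, width, amps_a[k])
    b <- add_test_bump(b, on + lag, width, amps_b[k])
  }
  dyad_sequence(id, "isolated", "sync",
                mets(a, 25, 10000, "patient"),
                mets(b, 25, 12000, "therapist"),
                interval_spec(s, e))
}

# Hand-built landscape for peak-picking unit tests: `blocks` is a list of
# lists(cols, lag_index, r2) painted onto an otherwise insignificant grid.
make_fake_landscape <- function(m = 400, W = 20, step = 2, max_lag = 20,
                                blocks = list()) {
  lg <- seq.int(-max_lag, max_lag, by = step)
  r2 <- matrix(0, m, length(lg))
  sig <- matrix(FALSE, m, length(lg))
  for (blk in blocks) {
    r2[blk$cols, blk$lag_index] <- blk$r2
    sig[blk$cols, blk$lag_index] <- TRUE
  }
  cfg <- analysis_config("WCLC", "raw", "none", bandwidth = W,
                         r2_cutoff = 0, max_lag = max_lag, step = step)
  structure(list(r2 = r2, sig = sig, p = 1 - sig,
                 time_grid = seq.int(0L, by = step, length.out = m),
                 lag_grid = lg, config = cfg,
                 n_frames = (m - 1L) * step + W),
            class = "r2_landscape")
}
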