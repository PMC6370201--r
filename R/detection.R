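# Windowed cross-lagged correlation (WCLC) and regression (WCLR):
# R-squared landscape over (window start, lag), significance testing,
# peak-picking of synchronization intervals, and the R-squared cutoff filter.

#' One cell of the factorial analysis grid
#'
#' Bundles every tunable of the identification pipeline. The validation grid
#' crosses `method` (2) x `transform` (4) x `smoothing` (3) x `bandwidth` (5)
#' x `r2_cutoff` (5) = 600 configurations; `max_lag`, `step`, `alpha` and the
#' noise level are held fixed.
#'
#' @param method `"WCLC"` (windowed cross-lagged correlation) or `"WCLR"`
#'   (windowed cross-lagged regression with an AR(1) control for the response).
#' @param transform a [transform_spec()] or its `kind` string.
#' @param smoothing a [smoothing_spec()] or its `kind` string.
#' @param bandwidth window length W in frames (grid levels 75, 125, 175, 250,
#'   750 at 25 fps).
#' @param r2_cutoff interval-level mean R-squared below which detected
#'   intervals are discarded (strict `>`); grid levels 0, .1, .2, .25, .3.
#' @param max_lag largest absolute lag examined, in frames (default 75 = 3 s).
#' @param step evaluation step in frames for both window starts and lags
#'   (default 2).
#' @param alpha significance level of the local association test (default .05).
#' @param noise_mean,noise_sd Gaussian noise injected after transform and
#'   smoothing (defaults 0 and 0.1) so zero-variance windows become defined.
#' @param min_duration shortest retained interval, frames (default 13, ~0.5 s).
#' @return an object of class `analysis_config` with a stable `id`.
#' @export
analysis_config <- function(method = c("WCLC", "WCLR"),
                            transform = "log1p",
                            smoothing = "none",
                            bandwidth = 125,
                            r2_cutoff = 0.25,
                            max_lag = 75, step = 2, alpha = 0.05,
                            noise_mean = 0, noise_sd = 0.1,
                            min_duration = 13) {
  method <- match.arg(method)
  if (is.character(transform)) transform <- transform_spec(transform)
  if (is.character(smoothing)) smoothing <- smoothing_spec(smoothing)
  stopifnot(inherits(transform, "transform_spec"),
            inherits(smoothing, "smoothing_spec"))
  w_min <- if (method == "WCLR") 6 else 4
  if (bandwidth < w_min) {
    stop(sprintf("bandwidth must be >= %d for %s", w_min, method),
         call. = FALSE)
  }
  if (max_lag < 0 || step < 1) stop("need max_lag >= 0 and step >= 1",
                                    call. = FALSE)
  if (r2_cutoff < 0 || r2_cutoff >= 1) stop("r2_cutoff must lie in [0, 1)",
                                            call. = FALSE)
  structure(list(
    method = method, transform = transform, smoothing = smoothing,
    bandwidth = as.integer(bandwidth), r2_cutoff = r2_cutoff,
    max_lag = as.integer(max_lag), step = as.integer(step), alpha = alpha,
    noise_mean = noise_mean, noise_sd = noise_sd,
    min_duration = as.integer(min_duration),
    id = paste(method, bandwidth, transform$kind, smoothing$kind, r2_cutoff,
               sep = "_")),
    class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> %s (max_lag %d, step %d, alpha %g)\n",
              x$id, x$max_lag, x$step, x$alpha))
  invisible(x)
}

# --- windowed moment machinery ------------------------------------------------

# Pearson correlation of x[t .. t+L-1] with y[t+off .. t+off+L-1] for every
# 1-based start t in `starts`, via cumulative sums; NA where a window would
# overrun either series. Series should be pre-centered for numerical accuracy.
windowed_corr <- function(x, y, starts, off, L) {
  nx <- length(x); ny <- length(y)
  valid <- starts >= 1L & starts + L - 1L <= nx &
    starts + off >= 1L & starts + off + L - 1L <= ny
  r <- rep(NA_real_, length(starts))
  if (!any(valid)) return(list(r = r, valid = valid))
  # cross product series z[i] = x[i] * y[i + off]
  i0 <- max(1L, 1L - off); i1 <- min(nx, ny - off)
  z <- numeric(nx)
  z[i0:i1] <- x[i0:i1] * y[(i0 + off):(i1 + off)]
  csx <- c(0, cumsum(x)); csx2 <- c(0, cumsum(x * x))
  csy <- c(0, cumsum(y)); csy2 <- c(0, cumsum(y * y))
  csz <- c(0, cumsum(z))
  t1 <- starts[valid]; t2 <- t1 + L
  u1 <- t1 + off; u2 <- u1 + L
  sx <- csx[t2] - csx[t1]; sxx <- csx2[t2] - csx2[t1]
  sy <- csy[u2] - csy[u1]; syy <- csy2[u2] - csy2[u1]
  sxy <- csz[t2] - csz[t1]
  vx <- L * sxx - sx * sx
  vy <- L * syy - sy * sy
  bad <- vx <= 1e-12 * L | vy <= 1e-12 * L
  if (any(bad)) {
    stop(sprintf(
      "zero-variance window at start frame %d: add noise before detection",
      t1[which(bad)[1L]] - 1L), call. = FALSE)
  }
  r[valid] <- pmin(1, pmax(-1, (L * sxy - sx * sy) / sqrt(vx * vy)))
  list(r = r, valid = valid)
}

# --- single-window associations ----------------------------------------------

#' Local association of one window pair (WCLC)
#'
#' Squared Pearson correlation of two aligned windows, with a two-sided t test
#' (`t = r * sqrt((W - 2) / (1 - r^2))`, W - 2 df) of the local association.
#'
#' @param a_win,b_win numeric windows of equal length W >= 4 with nonzero
#'   variance.
#' @return a list with `r2` and `p_value`.
#' @export
window_association_wclc <- function(a_win, b_win) {
  W <- length(a_win)
  if (W < 4 || length(b_win) != W) {
    stop("windows must have equal length >= 4", call. = FALSE)
  }
  wc <- windowed_corr(a_win - mean(a_win), b_win - mean(b_win),
                      starts = 1L, off = 0L, L = W)
  r <- wc$r[1L]
  r2 <- r * r
  p <- if (r2 >= 1) 0 else {
    tt <- abs(r) * sqrt((W - 2) / (1 - r2))
    2 * stats::pt(tt, df = W - 2, lower.tail = FALSE)
  }
  list(r2 = r2, p_value = p)
}

#' Local association of one window pair (WCLR)
#'
#' Windowed cross-lagged regression: the baseline model regresses `b_win` on
#' an intercept plus its own one-frame lag (autoregressive control against
#' spurious cross-correlation of autocorrelated series); the full model adds
#' `a_win` as predictor. Reported is the R-squared increment of the added
#' predictor with its F test on (1, W - 4) degrees of freedom (W - 1 usable
#' observations, 3 estimated parameters).
#'
#' @param a_win,b_win numeric windows of equal length W >= 6.
#' @return a list with `delta_r2` and `p_value`.
#' @export
window_association_wclr <- function(a_win, b_win) {
  W <- length(a_win)
  if (W < 6 || length(b_win) != W) {
    stop("windows must have equal length >= 6", call. = FALSE)
  }
  y <- b_win[2:W]; blag <- b_win[1:(W - 1)]; apr <- a_win[2:W]
  for (v in list(y, blag, apr)) {
    if (stats::var(v) <= 1e-12) {
      stop("singular design: constant window, add noise before detection",
           call. = FALSE)
    }
  }
  wclr_from_corr(stats::cor(y, apr), stats::cor(y, blag),
                 stats::cor(apr, blag), W)
}

# delta R^2 and F-test p from the three pairwise correlations
# (response vs added predictor, response vs AR(1) control, predictor pair).
wclr_from_corr <- function(r_ya, r_yb, r_ab, W) {
  denom <- 1 - r_ab * r_ab
  if (denom <= 1e-12) {
    stop("singular design: collinear predictors in WCLR window", call. = FALSE)
  }
  r2_full <- (r_ya * r_ya + r_yb * r_yb - 2 * r_ya * r_yb * r_ab) / denom
  r2_full <- min(1, max(0, r2_full))
  delta <- max(0, r2_full - r_yb * r_yb)
  df2 <- W - 4
  p <- if (r2_full >= 1) 0 else {
    f <- delta / ((1 - r2_full) / df2)
    stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  list(delta_r2 = delta, p_value = p)
}

# --- landscape ----------------------------------------------------------------

#' Compute the R-squared landscape over window starts and lags
#'
#' Slides a window of `config$bandwidth` frames along person A's series and,
#' for every lag on the lag grid, associates it with person B's window shifted
#' by that lag (positive lag: B's behavior trails A's). Window starts are
#' evaluated every `config$step` frames over the whole sequence; windows that
#' would overrun either series are left undefined (`NA`). The lag grid is
#' `seq(-max_lag, max_lag, by = step)`, symmetric with endpoints at the
#' maximum lag.
#'
#' @param a,b [mets()] objects or plain numeric vectors of equal length
#'   (already transformed, smoothed and noise-injected).
#' @param config an [analysis_config()].
#' @return an object of class `r2_landscape` with fields `r2`, `sig`,
#'   `p` (m x n matrices, rows = window starts, columns = lags), `time_grid`
#'   and `lag_grid` (0-based frames), and the generating `config`.
#' @export
compute_landscape <- function(a, b, config) {
  stopifnot(inherits(config, "analysis_config"))
  av <- if (inherits(a, "mets")) a$values else as.numeric(a)
  bv <- if (inherits(b, "mets")) b$values else as.numeric(b)
  n <- length(av)
  if (length(bv) != n) stop("series must have equal length", call. = FALSE)
  W <- config$bandwidth
  min_len <- W + config$max_lag
  if (n < min_len) {
    stop(sprintf("series of length %d too short: need >= %d (bandwidth + max_lag)",
                 n, min_len), call. = FALSE)
  }
  av <- av - mean(av); bv <- bv - mean(bv)  # numerical stabilization only
  time_grid <- seq.int(0L, n - 1L, by = config$step)
  lag_grid <- seq.int(-config$max_lag, config$max_lag, by = config$step)
  m <- length(time_grid); nl <- length(lag_grid)
  r2 <- matrix(NA_real_, m, nl)
  pmat <- matrix(NA_real_, m, nl)
  starts <- time_grid + 1L  # 1-based a-window starts
  for (j in seq_len(nl)) {
    off <- lag_grid[j]
    if (config$method == "WCLC") {
      wc <- windowed_corr(av, bv, starts, off, W)
      r <- wc$r
      r2[, j] <- r * r
      ok <- wc$valid & !is.na(r)
      tt <- abs(r[ok]) * sqrt((W - 2) / pmax(1 - r[ok]^2, 1e-300))
      pmat[ok, j] <- 2 * stats::pt(tt, df = W - 2, lower.tail = FALSE)
    } else {
      L <- W - 1L
      # y = b window starting at t+off+1; AR(1) control starts at t+off;
      # added predictor = a window starting at t+1 (all length W-1)
      r_yb <- windowed_corr(bv, bv, starts + off + 1L, -1L, L)
      r_ya <- windowed_corr(bv, av, starts + off + 1L, -off, L)
      r_ab <- windowed_corr(bv, av, starts + off, 1L - off, L)
      ok <- r_yb$valid & r_ya$valid & r_ab$valid &
        starts + W - 1L <= n  # a-window itself must fit
      if (any(ok)) {
        res <- wclr_cellwise(r_ya$r[ok], r_yb$r[ok], r_ab$r[ok], W)
        r2[ok, j] <- res$delta_r2
        pmat[ok, j] <- res$p_value
      }
    }
  }
  sig <- !is.na(pmat) & pmat < config$alpha
  structure(list(r2 = r2, sig = sig, p = pmat,
                 time_grid = time_grid, lag_grid = lag_grid,
                 config = config, n_frames = n),
            class = "r2_landscape")
}

# vectorized counterpart of wclr_from_corr (no singularity stop: collinear
# cells are set NA so a single degenerate window cannot abort a whole grid run)
wclr_cellwise <- function(r_ya, r_yb, r_ab, W) {
  denom <- 1 - r_ab * r_ab
  r2_full <- (r_ya^2 + r_yb^2 - 2 * r_ya * r_yb * r_ab) / denom
  r2_full <- pmin(1, pmax(0, r2_full))
  delta <- pmax(0, r2_full - r_yb^2)
  df2 <- W - 4
  f <- delta / pmax((1 - r2_full) / df2, 1e-300)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  bad <- denom <= 1e-12
  delta[bad] <- NA_real_; p[bad] <- NA_real_
  list(delta_r2 = delta, p_value = p)
}

#' @export
print.r2_landscape <- function(x, ...) {
  cat(sprintf(
    "<r2_landscape> %s: %d window starts x %d lags over %d frames (%.1f%% significant)\n",
    x$config$id, nrow(x$r2), ncol(x$r2), x$n_frames,
    100 * mean(x$sig[!is.na(x$r2)])))
  invisible(x)
}

# --- peak-picking -------------------------------------------------------------

#' Pick synchronization intervals from an R-squared landscape
#'
#' For every window-start column the significant cell with the highest
#' R-squared is selected; consecutive columns are chained into one interval
#' while the maximizing lag moves by at most `lag_jump` grid steps (short
#' non-significant gaps of up to `gap_tolerance` columns are bridged). Each
#' chain of window starts `[t1 .. tk]` is mapped back to the frame span
#' `[t1 + W - 1, tk + step)`: the left-most significant window overlaps the
#' synchronous episode only at its right edge and the right-most one at its
#' left edge, so this mapping undoes the ~W-frame left-smearing that marking
#' raw window starts would produce. Chains whose mapped span is shorter than
#' `config$min_duration` frames are dropped. The interval lag is the median of
#' the chained lags; `mean_r2` averages the picked cells.
#'
#' @param landscape an [compute_landscape()] result.
#' @param config the generating [analysis_config()] (defaults to the one
#'   stored in the landscape).
#' @param lag_jump largest allowed column-to-column move of the maximizing
#'   lag, in lag-grid steps (default 2).
#' @param gap_tolerance number of consecutive columns without a significant
#'   cell that may be bridged inside one interval (default 2).
#' @return a data frame with columns `start`, `end` (0-based, half-open frame
#'   span on A's timeline), `lag` (frames, positive = B trails A), `mean_r2`
#'   and `n_windows`; zero rows if nothing is picked.
#' @export
peak_pick <- function(landscape, config = landscape$config,
                      lag_jump = 2L, gap_tolerance = 2L) {
  stopifnot(inherits(landscape, "r2_landscape"))
  r2 <- landscape$r2; sig <- landscape$sig
  m <- nrow(r2)
  tg <- landscape$time_grid; lg <- landscape$lag_grid
  W <- config$bandwidth; step <- config$step
  best_j <- integer(m); best_r2 <- numeric(m)
  for (i in seq_len(m)) {
    cand <- which(sig[i, ] & !is.na(r2[i, ]))
    if (length(cand)) {
      j <- cand[which.max(r2[i, cand])]
      best_j[i] <- j; best_r2[i] <- r2[i, j]
    }
  }
  out <- list()
  chain_cols <- integer(0); chain_last <- 0L
  flush <- function() {
    if (!length(chain_cols)) return()
    t1 <- tg[chain_cols[1L]]
    chain_len <- tg[chain_cols[length(chain_cols)]] + step - t1
    if (chain_len - W + 1L >= config$min_duration) {
      # chain long enough to deconvolve the window width: the left-most
      # significant window overlapped the episode only at its right edge
      start <- t1 + W - 1L
      end <- tg[chain_cols[length(chain_cols)]] + step
    } else if (chain_len >= config$min_duration) {
      # short chain: localization within the window is ambiguous; report a
      # centered span of the chain's own length
      start <- t1 + (W - 1L) %/% 2L
      end <- start + chain_len
    } else {
      return()
    }
    out[[length(out) + 1L]] <<- data.frame(
      start = start, end = end,
      lag = stats::median(lg[best_j[chain_cols]]),
      mean_r2 = mean(best_r2[chain_cols]),
      n_windows = length(chain_cols))
  }
  for (i in seq_len(m)) {
    if (best_j[i] == 0L) next
    if (length(chain_cols) &&
        i - chain_last <= gap_tolerance + 1L &&
        abs(best_j[i] - best_j[chain_last]) <= lag_jump) {
      chain_cols <- c(chain_cols, i)
    } else {
      flush()
      chain_cols <- i
    }
    chain_last <- i
  }
  flush()
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      lag = numeric(0), mean_r2 = numeric(0),
                      n_windows = integer(0)))
  }
  do.call(rbind, out)
}

#' Filter detected intervals by the R-squared cutoff
#'
#' Keeps intervals whose interval-level `mean_r2` strictly exceeds
#' `r2_cutoff`; an interval sitting exactly on the cutoff is dropped. The
#' filter operates on whole intervals, not on individual landscape cells.
#'
#' @param intervals a data frame from [peak_pick()].
#' @param r2_cutoff numeric in `[0, 1)`.
#' @return the filtered data frame.
#' @export
filter_by_cutoff <- function(intervals, r2_cutoff) {
  intervals[intervals$mean_r2 > r2_cutoff, , drop = FALSE]
}

#' Identify movement synchronization intervals in a dyad
#'
#' Runs the full pipeline on one dyad: transform, smoothing, noise injection
#' (one derived seed per person so reruns with the same `master_seed`
#' reproduce the result exactly), landscape computation, peak-picking, and
#' the R-squared cutoff filter.
#'
#' @param dyad a [dyad_sequence()].
#' @param config an [analysis_config()].
#' @param master_seed integer; all noise seeds are derived from it together
#'   with the dyad id, person and config id.
#' @return a data frame of detected intervals (see [peak_pick()]).
#' @export
identify_msi <- function(dyad, config, master_seed = 1L) {
  stopifnot(inherits(dyad, "dyad_sequence"), inherits(config, "analysis_config"))
  pre <- preprocess_dyad(dyad, config, master_seed)
  landscape <- compute_landscape(pre$a, pre$b, config)
  filter_by_cutoff(peak_pick(landscape, config), config$r2_cutoff)
}

#' Preprocess a dyad for detection
#'
#' Applies the configured transform, smoothing and noise injection (in that
#' fixed order) to both series of a dyad.
#'
#' @inheritParams identify_msi
#' @return a list with numeric vectors `a` and `b`.
#' @export
preprocess_dyad <- function(dyad, config, master_seed = 1L) {
  tr <- apply_transform(dyad$a, dyad$b, config$transform)
  va <- smooth_series(tr$a$values, config$smoothing)
  vb <- smooth_series(tr$b$values, config$smoothing)
  seed_a <- derive_seed(master_seed, paste(dyad$id, "a", config$id, sep = "/"))
  seed_b <- derive_seed(master_seed, paste(dyad$id, "b", config$id, sep = "/"))
  list(a = add_noise(va, noise_spec(config$noise_mean, config$noise_sd, seed_a)),
       b = add_noise(vb, noise_spec(config$noise_mean, config$noise_sd, seed_b)))
}

#' Write an interval table as delimited text
#'
#' @param intervals a data frame from [peak_pick()] / [identify_msi()].
#' @param path output file.
#' @param sequence_id,condition,method metadata columns prepended to the table.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, sequence_id = NA, condition = NA,
                            method = NA) {
  k <- nrow(intervals)
  out <- cbind(data.frame(sequence_id = rep(sequence_id, k),
                          condition = rep(condition, k),
                          method = rep(method, k)),
               intervals[, c("start", "end", "lag", "mean_r2")])
  names(out) <- c("sequence_id", "condition", "method",
                  "start_frame", "end_frame", "lag_frames", "mean_r2")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
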