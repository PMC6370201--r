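# WCLC/WCLR associations, the R-squared landscape, peak-picking, and the
# cutoff filter.

test_that("WCLC window association matches hand-computed correlations", {
  x <- cumsum(rnorm(40))
  res <- window_association_wclc(x, x)
  expect_equal(res$r2, 1)
  expect_equal(res$p_value, 0)
  expect_equal(window_association_wclc(x, -x)$r2, 1)  # sign-blind by squaring
  res <- window_association_wclc(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r2, 0.64)  # hand Pearson r = 0.8
  expect_error(window_association_wclc(rep(2, 10), rnorm(10)),
               "zero-variance")
})

test_that("WCLC p-values follow the t reference distribution", {
  set.seed(31)
  for (W in c(10, 60)) {
    a <- rnorm(W); b <- rnorm(W)
    res <- window_association_wclc(a, b)
    r <- stats::cor(a, b)
    expect_equal(res$p_value, stats::cor.test(a, b)$p.value,
                 tolerance = 1e-12)
    expect_equal(res$r2, r^2, tolerance = 1e-12)
  }
})

test_that("WCLR association agrees with explicit least-squares fits", {
  set.seed(23)
  for (W in c(8, 30, 125)) {
    for (rep in 1:5) {
      a <- as.numeric(stats::arima.sim(list(ar = 0.4), W))
      b <- 0.5 * a + as.numeric(stats::arima.sim(list(ar = 0.6), W))
      res <- window_association_wclr(a, b)
      ora <- oracle_wclr_lm(a, b)
      expect_equal(res$delta_r2, max(0, ora$delta_r2), tolerance = 1e-10)
      expect_equal(res$p_value, ora$p_value, tolerance = 1e-8)
    }
  }
  expect_error(window_association_wclr(rep(1, 20), rnorm(20)), "singular")
})

test_that("WCLR detects an echoed white-noise window and stays null on
           independent AR(1) series", {
  set.seed(41)
  a <- rnorm(125)
  res <- window_association_wclr(a, a)
  expect_gt(res$delta_r2, 0.9)
  expect_lt(res$p_value, 0.001)
  deltas <- replicate(1000, {
    x <- as.numeric(stats::arima.sim(list(ar = 0.7), 125))
    y <- as.numeric(stats::arima.sim(list(ar = 0.7), 125))
    window_association_wclr(x, y)$delta_r2
  })
  expect_lt(mean(deltas), 0.05)
})

test_that("the landscape equals a brute-force double loop (WCLC)", {
  set.seed(53)
  n <- 400
  a <- add_noise(cumsum(rnorm(n)) / 5, noise_spec(seed = 1))
  b <- add_noise(c(rep(0, 30), a[1:(n - 30)]), noise_spec(seed = 2))
  cfg <- analysis_config("WCLC", "raw", "none", bandwidth = 75,
                         r2_cutoff = 0, max_lag = 40, step = 2)
  ls <- compute_landscape(a, b, cfg)
  oracle <- oracle_landscape_wclc(a, b, 75, 40, 2)
  expect_equal(dim(ls$r2), dim(oracle))
  expect_equal(ls$r2, oracle, tolerance = 1e-10)
})

test_that("the WCLR landscape equals the per-window association loop", {
  set.seed(59)
  n <- 260
  a <- add_noise(numeric(n), noise_spec(seed = 3))
  a <- a + add_test_bump(numeric(n), 100, 60, 5)
  b <- add_noise(c(rep(0, 10), a[1:(n - 10)]), noise_spec(seed = 4))
  cfg <- analysis_config("WCLR", "raw", "none", bandwidth = 40,
                         r2_cutoff = 0, max_lag = 16, step = 4)
  ls <- compute_landscape(a, b, cfg)
  am <- a - mean(a); bm <- b - mean(b)  # landscape centers internally
  max_dr <- 0; max_dp <- 0
  for (i in seq_along(ls$time_grid)) {
    for (j in seq_along(ls$lag_grid)) {
      t <- ls$time_grid[i]; l <- ls$lag_grid[j]
      if (t + 40 <= n && t + l >= 0 && t + l + 40 <= n) {
        ora <- window_association_wclr(am[(t + 1):(t + 40)],
                                       bm[(t + l + 1):(t + l + 40)])
        max_dr <- max(max_dr, abs(ls$r2[i, j] - ora$delta_r2))
        max_dp <- max(max_dp, abs(ls$p[i, j] - ora$p_value))
      } else {
        expect_true(is.na(ls$r2[i, j]))
      }
    }
  }
  expect_lt(max_dr, 1e-10)
  expect_lt(max_dp, 1e-8)
})

test_that("landscape grids have the documented dimensions", {
  set.seed(61)
  a <- add_noise(numeric(2950), noise_spec(seed = 1))
  b <- add_noise(numeric(2950), noise_spec(seed = 2))
  cfg <- analysis_config("WCLC", "raw", "none", 125, 0.25)
  ls <- compute_landscape(a, b, cfg)
  expect_equal(nrow(ls$r2), 1475)  # duration / step window starts attempted
  expect_equal(ncol(ls$r2), 76)    # symmetric lag grid, step 2, max lag 75
  expect_equal(range(ls$lag_grid), c(-75, 75))
  expect_error(compute_landscape(a[1:100], b[1:100], cfg), "too short")
})

test_that("a perfect echo yields r2 = 1 at the construction lag everywhere", {
  set.seed(67)
  L <- 10; n <- 300
  full <- cumsum(rnorm(n + L))
  a <- full[(L + 1):(n + L)]
  b <- full[1:n]  # b[t] = a[t - L] for every t
  cfg <- analysis_config("WCLC", "raw", "none", bandwidth = 50,
                         r2_cutoff = 0, max_lag = 20, step = 2)
  ls <- compute_landscape(a, b, cfg)
  j <- which(ls$lag_grid == L)
  vals <- ls$r2[, j]
  expect_true(all(abs(vals[!is.na(vals)] - 1) < 1e-9))
})

test_that("pure-noise landscapes rarely exceed the 0.25 cutoff", {
  a <- add_noise(numeric(1500), noise_spec(seed = 71))
  b <- add_noise(numeric(1500), noise_spec(seed = 72))
  cfg <- analysis_config("WCLC", "raw", "none", 125, 0.25)
  ls <- compute_landscape(a, b, cfg)
  ok <- !is.na(ls$r2)
  expect_lt(mean(ls$sig[ok] & ls$r2[ok] > 0.25), 0.01)
})

test_that("peak-picking maps blocks of significant cells to intervals", {
  # nothing significant -> no intervals
  empty <- make_fake_landscape(blocks = list())
  expect_equal(nrow(peak_pick(empty)), 0)

  # one contiguous block at a single lag: window starts 100..300
  one <- make_fake_landscape(blocks = list(
    list(cols = 51:151, lag_index = 13, r2 = 0.9)))
  iv <- peak_pick(one)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 100 + 20 - 1)  # deconvolved left edge
  expect_equal(iv$end, 300 + 2)
  expect_equal(iv$lag, one$lag_grid[13])
  expect_equal(iv$mean_r2, 0.9)

  # two blocks separated by more than the gap tolerance -> two intervals
  two <- make_fake_landscape(blocks = list(
    list(cols = 40:90, lag_index = 10, r2 = 0.8),
    list(cols = 120:170, lag_index = 10, r2 = 0.6)))
  iv <- peak_pick(two)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$mean_r2, c(0.8, 0.6))

  # a short block maps to a centered interval of its own length
  short <- make_fake_landscape(blocks = list(
    list(cols = 100:106, lag_index = 5, r2 = 0.7)))
  iv <- peak_pick(short)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$end - iv$start, 14)  # 7 columns x step 2
  expect_equal(iv$start, 198 + (20 - 1) %/% 2)

  # below the minimum duration -> dropped
  tiny <- make_fake_landscape(blocks = list(
    list(cols = 100:103, lag_index = 5, r2 = 0.7)))
  expect_equal(nrow(peak_pick(tiny)), 0)
})

test_that("the cutoff filter is strict and interval-level", {
  iv <- data.frame(start = c(0, 50, 100), end = c(20, 80, 130),
                   lag = c(0, 2, -4), mean_r2 = c(0.2, 0.25, 0.3),
                   n_windows = c(5, 5, 5))
  expect_equal(nrow(filter_by_cutoff(iv, 0)), 3)
  kept <- filter_by_cutoff(iv, 0.25)
  expect_equal(kept$mean_r2, 0.3)  # exact ties are dropped
})

test_that("identify_msi recovers echoes and respects cutoff monotonicity", {
  pair <- generate_base_pair(seed = 7, id = "seq01_sync_embedded")
  art <- make_artificial(make_isolated(pair$dyad), 50)
  cfg <- analysis_config("WCLC", "log1p", "none", 125, 0.25)
  iv <- identify_msi(art, cfg, master_seed = 3)
  expect_gte(nrow(iv), 1)
  main <- iv[which.max(iv$end - iv$start), ]
  expect_lte(abs(main$lag - 50), 2)
  expect_lte(abs(main$start - art$reference$start), 15)
  expect_lte(abs(main$end - art$reference$end), 15)

  # raising the cutoff never increases interval count or covered frames
  counts <- c(); frames <- c()
  for (co in c(0, 0.1, 0.2, 0.25, 0.3)) {
    cfg_c <- analysis_config("WCLC", "log1p", "none", 125, co)
    iv_c <- identify_msi(art, cfg_c, master_seed = 3)
    counts <- c(counts, nrow(iv_c))
    frames <- c(frames, sum(intervals_to_binary(iv_c,
                                                length(art$a$values))))
  }
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(frames) <= 0))
})

test_that("swapping the two persons negates the recovered lag", {
  pair <- generate_base_pair(seed = 19, id = "seq01_sync_embedded")
  art <- make_artificial(make_isolated(pair$dyad), 50)
  swapped <- dyad_sequence(art$id, art$condition, art$sync_label,
                           a = art$b, b = art$a, reference = art$reference)
  cfg <- analysis_config("WCLC", "log1p", "none", 125, 0.25)
  lag_fwd <- with(identify_msi(art, cfg, 3),
                  lag[which.max(end - start)])
  lag_rev <- with(identify_msi(swapped, cfg, 3),
                  lag[which.max(end - start)])
  expect_lte(abs(lag_fwd - 50), 2)
  expect_lte(abs(lag_rev + 50), 2)
})

test_that("identify_msi is deterministic given the master seed and finds
           nothing in an all-zero dyad at a high cutoff", {
  pair <- generate_base_pair(seed = 29, sync = FALSE,
                             id = "seq01_nosync_embedded")
  art <- make_artificial(make_isolated(pair$dyad), 50)
  cfg <- analysis_config("WCLC", "log1p", "none", 125, 0.3)
  iv1 <- identify_msi(art, cfg, master_seed = 11)
  iv2 <- identify_msi(art, cfg, master_seed = 11)
  expect_identical(iv1, iv2)
  expect_equal(nrow(iv1), 0)
})
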