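# Configuration grid, grid runner, and the statistical analysis layer.

test_that("grid enumeration is the Cartesian product with stable ids", {
  expect_length(enumerate_configs(methods = "WCLC", transforms = "raw",
                                  smoothings = "none", bandwidths = 125,
                                  cutoffs = 0.25)$configs, 1)
  g32 <- enumerate_configs(methods = c("WCLC", "WCLR"),
                           transforms = c("raw", "log1p"),
                           smoothings = c("none", "slight"),
                           bandwidths = c(75, 125), cutoffs = c(0, 0.25))
  expect_length(g32$configs, 32)
  expect_equal(nrow(g32$table), 32)
  expect_false(anyDuplicated(g32$table$config_id) > 0)
  set.seed(3)
  fams <- list(methods = c("WCLC", "WCLR"), transforms = c("raw", "log1p",
                                                           "anscombe"),
               smoothings = c("none", "high"), bandwidths = c(75, 250),
               cutoffs = c(0.1, 0.2, 0.3))
  g <- do.call(enumerate_configs, fams)
  expect_length(g$configs, prod(lengths(fams)))
  expect_error(enumerate_configs(methods = character(0)), "empty family")
})

test_that("cross tables give exact Fisher p for 2x2 and sane Cramer's V", {
  # perfectly associated 2x2 table [[10, 0], [0, 10]]
  res <- data.frame(method = rep(c("WCLC", "WCLR"), each = 10),
                    ir_sync = rep(c("poor", "good"), each = 10))
  ct <- crosstab_ir(res, "method", "ir_sync")
  expect_equal(ct$fisher_p, 2 / choose(20, 10))  # = 2/184756
  expect_equal(ct$cramers_v, 1)

  # counts independent by construction -> p well above .5
  res2 <- data.frame(method = rep(c("WCLC", "WCLR"), each = 20),
                     ir_sync = rep(rep(c("poor", "good"), each = 10), 2))
  expect_gt(crosstab_ir(res2, "method", "ir_sync")$fisher_p, 0.5)

  # r x c uses the seeded Monte-Carlo path and is reproducible
  set.seed(17)
  res3 <- data.frame(bandwidth = rep(c(75, 125, 750), each = 30),
                     ir_sync = sample(c("poor", "acceptable", "good"), 90,
                                      replace = TRUE))
  p1 <- crosstab_ir(res3, "bandwidth", "ir_sync", seed = 5)$fisher_p
  p2 <- crosstab_ir(res3, "bandwidth", "ir_sync", seed = 5)$fisher_p
  expect_identical(p1, p2)
  expect_error(crosstab_ir(res3[1:30, ], "bandwidth", "ir_sync"),
               "single level")
})

test_that("ordinal regression recovers direction, nulls, and separation", {
  set.seed(23)
  # construction where WCLR stochastically outranks WCLC (overlapping classes)
  n <- 120
  method <- rep(c("WCLC", "WCLR"), each = n / 2)
  band <- rep(c("75", "750"), n / 2)
  ir <- ifelse(method == "WCLR",
               sample(c("poor", "acceptable", "good"), n, TRUE,
                      c(0.10, 0.35, 0.55)),
               sample(c("poor", "acceptable", "good"), n, TRUE,
                      c(0.55, 0.35, 0.10)))
  res <- data.frame(method = method, transform = "raw", smoothing = "none",
                    bandwidth = band, r2_cutoff = "0.25", ir_sync = ir)
  fit <- ordinal_ir_regression(res, "ir_sync")
  wclr <- fit[fit$term == "methodWCLR", ]
  expect_gt(wclr$estimate, 0)
  expect_lt(wclr$p_value, 0.001)
  expect_false(wclr$separation)
  expect_contains(attr(fit, "dropped"),
                  c("transform", "smoothing", "r2_cutoff"))

  # a covariate independent of IR stays within two standard errors of zero
  covr <- fit[fit$term == "bandwidth750", ]
  expect_lt(abs(covr$estimate), 2 * covr$std_error)

  # deterministic dominance -> flagged separation
  res_sep <- res
  res_sep$ir_sync <- ifelse(method == "WCLR", "good", "poor")
  fit_sep <- ordinal_ir_regression(res_sep, "ir_sync")
  expect_true(fit_sep[fit_sep$term == "methodWCLR", "separation"])

  res_const <- res; res_const$ir_sync <- "good"
  expect_error(ordinal_ir_regression(res_const, "ir_sync"), "constant")
})

test_that("Kruskal-Wallis wrapper matches the hand rank formula", {
  v <- c(1, 2, 3, 4); g <- c("a", "a", "b", "b")
  kw <- kruskal_by_sequence(v, g)
  expect_equal(kw$H, oracle_kruskal_h(v, g), tolerance = 1e-12)
  set.seed(29)
  v2 <- c(rnorm(12), rnorm(10, 0.5), rnorm(11, -0.25))
  v2 <- round(v2, 1)  # force ties to exercise the tie correction
  g2 <- rep(c("s1", "s2", "s3"), c(12, 10, 11))
  kw2 <- kruskal_by_sequence(v2, g2)
  expect_equal(kw2$H, oracle_kruskal_h(v2, g2), tolerance = 1e-12)
  expect_equal(kw2$df, 2)

  # strong shift -> decisive rejection
  v3 <- c(rnorm(30), rnorm(30, 5))
  g3 <- rep(c("s1", "s2"), each = 30)
  expect_lt(kruskal_by_sequence(v3, g3)$p_value, 0.001)

  expect_warning(out <- kruskal_by_sequence(rep(1, 10), rep(c("a", "b"), 5)),
                 "identical")
  expect_equal(out$H, 0)
})

test_that("the Kruskal-Wallis null rejection rate is calibrated", {
  set.seed(31)
  rej <- mean(replicate(2000, {
    kruskal_by_sequence(rnorm(30), rep(c("a", "b", "c"), each = 10))$p_value <
      0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("the grid runner is deterministic and complete", {
  ds <- generate_dyad_dataset(n_sync = 2, n_nosync = 2, seed = 37)
  grid <- enumerate_configs(methods = "WCLC", transforms = c("log1p", "raw"),
                            smoothings = "none", bandwidths = 125,
                            cutoffs = 0.25)
  r1 <- run_grid(ds, grid, master_seed = 4)
  r2 <- run_grid(ds, grid, master_seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 2 * 3)  # configs x conditions
  expect_false(anyNA(r1$ir_combined))

  path <- file.path(tempdir(), "grid_results.tsv")
  write_study_results(r1, path)
  back <- read_study_results(path)
  expect_equal(back$kappa_mean, r1$kappa_mean, tolerance = 1e-12)
  expect_identical(back$ir_combined, r1$ir_combined)
})

test_that("qualitative parameter effects hold on synthetic data", {
  ds <- generate_dyad_dataset(n_sync = 5, n_nosync = 5, seed = 21)

  # R-squared cutoff .25 gives the (tied-)largest number of good outcomes:
  # without a cutoff, weak spurious chains survive and inflate pr_out
  good <- vapply(c(0, 0.1, 0.2, 0.25, 0.3), function(co) {
    ev <- evaluate_config(ds, analysis_config("WCLC", "log1p", "none", 125,
                                              co), "artificial", 5)
    ev$ir_combined == "good"
  }, logical(1))
  expect_true(good[4])
  expect_false(good[1])

  # small-to-medium bandwidths beat 750 frames on concordance
  km <- vapply(c(75, 125, 175, 750), function(W) {
    evaluate_config(ds, analysis_config("WCLC", "log1p", "none", W, 0.25),
                    "artificial", 5)$kappa_mean
  }, numeric(1))
  expect_gt(min(km[1:3]), km[4])
})

test_that("log transformation helps when synchronous pulse amplitudes differ", {
  set.seed(43)
  wins <- 0
  for (i in 1:20) {
    a <- add_test_bump(numeric(140), 1, 65, 80)
    a <- add_test_bump(a, 73, 65, 60)
    b <- add_test_bump(numeric(140), 1, 65, 6)  # first peak much weaker
    b <- add_test_bump(b, 73, 65, 60)
    r2_raw <- window_association_wclc(a + rnorm(140, 0, 0.1),
                                      b + rnorm(140, 0, 0.1))$r2
    r2_log <- window_association_wclc(log1p(a) + rnorm(140, 0, 0.1),
                                      log1p(b) + rnorm(140, 0, 0.1))$r2
    wins <- wins + (r2_log > r2_raw)
  }
  expect_gte(wins, 15)
})
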