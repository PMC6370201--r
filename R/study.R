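# Validation-study layer: the factorial configuration grid, the grid runner,
# and the statistical analysis of identification rates (cross tables with
# Fisher's exact test and Cramer's V, proportional-odds regression,
# Kruskal-Wallis tests by sequence).

#' Enumerate the factorial configuration grid
#'
#' Full Cartesian product of the parameter families in deterministic order
#' with stable ids; the defaults give the 2 x 4 x 3 x 5 x 5 = 600
#' configurations of the validation design.
#'
#' @param methods,transforms,smoothings,bandwidths,cutoffs level vectors
#'   (each non-empty).
#' @param ... fixed settings forwarded to every [analysis_config()]
#'   (e.g. `max_lag`, `step`, `alpha`, `noise_sd`).
#' @return an object of class `config_grid`: a list with `configs` (list of
#'   [analysis_config()]) and `table` (one row per configuration).
#' @export
enumerate_configs <- function(methods = c("WCLC", "WCLR"),
                              transforms = c("raw", "size", "log1p", "anscombe"),
                              smoothings = c("none", "slight", "high"),
                              bandwidths = c(75, 125, 175, 250, 750),
                              cutoffs = c(0, 0.1, 0.2, 0.25, 0.3),
                              ...) {
  fams <- list(methods = methods, transforms = transforms,
               smoothings = smoothings, bandwidths = bandwidths,
               cutoffs = cutoffs)
  for (nm in names(fams)) {
    if (!length(fams[[nm]])) stop(sprintf("empty family: %s", nm),
                                  call. = FALSE)
  }
  levels <- expand.grid(cutoff = cutoffs, bandwidth = bandwidths,
                        smoothing = smoothings, transform = transforms,
                        method = methods, stringsAsFactors = FALSE)
  configs <- vector("list", nrow(levels))
  for (i in seq_len(nrow(levels))) {
    configs[[i]] <- analysis_config(
      method = levels$method[i], transform = levels$transform[i],
      smoothing = levels$smoothing[i], bandwidth = levels$bandwidth[i],
      r2_cutoff = levels$cutoff[i], ...)
  }
  tab <- data.frame(config_id = vapply(configs, `[[`, "", "id"),
                    method = levels$method, transform = levels$transform,
                    smoothing = levels$smoothing,
                    bandwidth = levels$bandwidth, r2_cutoff = levels$cutoff)
  structure(list(configs = configs, table = tab), class = "config_grid")
}

#' @export
print.config_grid <- function(x, ...) {
  cat(sprintf("<config_grid> %d configurations\n", length(x$configs)))
  invisible(x)
}

#' Run a configuration grid over a dataset
#'
#' Evaluates every configuration on every condition present in the dataset:
#' one [identify_msi()] + scoring pass per (configuration, dyad). Each task is
#' pure with a seed derived from `master_seed`, so re-running with the same
#' seed reproduces the table exactly and the evaluation order is irrelevant.
#' A failure in a single (configuration, condition) cell is recorded as `NA`
#' summaries without aborting the run.
#'
#' @param dataset a `dyad_dataset`.
#' @param grid an [enumerate_configs()] result.
#' @param master_seed integer master seed.
#' @param verbose print per-configuration progress with timings.
#' @param checkpoint optional path: the table is re-written there after each
#'   configuration, so long runs can be inspected (and salvaged) midway.
#' @return a data frame (class `study_results`) with one row per
#'   configuration x condition: parameter levels, kappa and pr_out summaries,
#'   and the three identification-rate classes.
#' @export
run_grid <- function(dataset, grid, master_seed = 1L, verbose = FALSE,
                     checkpoint = NULL) {
  stopifnot(inherits(grid, "config_grid"))
  conditions <- unique(vapply(dataset, function(d) d$condition, ""))
  rows <- list()
  for (i in seq_along(grid$configs)) {
    config <- grid$configs[[i]]
    t0 <- proc.time()[["elapsed"]]
    for (cond in conditions) {
      ev <- tryCatch(
        evaluate_config(dataset, config, cond, master_seed),
        error = function(e) {
          warning(sprintf("config %s on %s failed: %s", config$id, cond,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      rows[[length(rows) + 1L]] <- data.frame(
        config_id = config$id, method = config$method,
        transform = config$transform$kind, smoothing = config$smoothing$kind,
        bandwidth = config$bandwidth, r2_cutoff = config$r2_cutoff,
        condition = cond,
        kappa_min = if (is.null(ev)) NA_real_ else ev$kappa_min,
        kappa_max = if (is.null(ev)) NA_real_ else ev$kappa_max,
        kappa_mean = if (is.null(ev)) NA_real_ else ev$kappa_mean,
        pr_out_min = if (is.null(ev)) NA_real_ else ev$pr_out_min,
        pr_out_max = if (is.null(ev)) NA_real_ else ev$pr_out_max,
        pr_out_mean = if (is.null(ev)) NA_real_ else ev$pr_out_mean,
        ir_sync = if (is.null(ev)) NA_character_ else ev$ir_sync,
        ir_nosync = if (is.null(ev)) NA_character_ else ev$ir_nosync,
        ir_combined = if (is.null(ev)) NA_character_ else ev$ir_combined)
    }
    if (verbose) {
      message(sprintf("[%d/%d] %s (%.1fs)", i, length(grid$configs),
                      config$id, proc.time()[["elapsed"]] - t0))
    }
    if (!is.null(checkpoint)) {
      write_study_results(do.call(rbind, rows), checkpoint)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_results", "data.frame")
  out
}

#' Write / read a study result table as delimited text
#'
#' Round-trips losslessly through tab-separated text.
#'
#' @param results a [run_grid()] table.
#' @param path file path.
#' @return `write_study_results` returns `path` invisibly;
#'   `read_study_results` the table.
#' @export
write_study_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_study_results
#' @export
read_study_results <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("study_results", "data.frame")
  out
}

#' Cross table of a parameter family against identification-rate class
#'
#' Counts configurations per (parameter level, IR class), tests the
#' association with Fisher's exact test (exact hypergeometric for 2 x 2
#' tables, seeded Monte-Carlo with 1e5 table draws otherwise) and reports
#' Cramer's V = sqrt(chi^2 / (N * (min(r, c) - 1))).
#'
#' @param results a [run_grid()] table, usually restricted to one condition.
#' @param parameter one of `"method"`, `"transform"`, `"smoothing"`,
#'   `"bandwidth"`, `"r2_cutoff"`.
#' @param outcome which IR column to tabulate (default `"ir_sync"`).
#' @param mc_draws Monte-Carlo replicates for r x c Fisher tests.
#' @param seed seed of the Monte-Carlo draw.
#' @return a list with `table`, `fisher_p` and `cramers_v`.
#' @export
crosstab_ir <- function(results, parameter,
                        outcome = c("ir_sync", "ir_nosync", "ir_combined"),
                        mc_draws = 1e5, seed = 1L) {
  outcome <- match.arg(outcome)
  stopifnot(parameter %in% names(results))
  lev <- factor(results[[parameter]])
  ir <- factor(results[[outcome]], levels = ir_levels)
  ir <- droplevels(ir)
  if (nlevels(lev) < 2L) {
    stop(sprintf("parameter '%s' has a single level; nothing to test",
                 parameter), call. = FALSE)
  }
  tab <- table(lev, ir)
  fisher_p <- if (all(dim(tab) == 2L)) {
    stats::fisher.test(tab)$p.value
  } else {
    with_seed(seed,
              stats::fisher.test(tab, simulate.p.value = TRUE,
                                 B = mc_draws)$p.value)
  }
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
  list(table = tab, fisher_p = fisher_p, cramers_v = v)
}

#' Proportional-odds regression of identification rate on grid parameters
#'
#' Fits an ordinal logistic regression (via [MASS::polr()]) of the ordered IR
#' class (poor < acceptable < good) on dummy-coded parameter families with
#' configurable reference levels. Positive coefficients indicate a positive
#' influence of the level on the identification rate. Parameter families with
#' a single observed level (as happens after sequential gating) are dropped
#' from the model, and if only two IR classes are observed the model
#' collapses to the equivalent binary logistic regression. Complete or quasi-complete separation is detected (by
#' coefficient magnitude or a failed Hessian) and flagged per term rather
#' than silently returning a diverged fit.
#'
#' @param results a [run_grid()] table restricted to one condition.
#' @param outcome IR column used as criterion.
#' @param reference_levels named list of reference levels per family; the
#'   defaults mirror the validation design (raw data, no smoothing, WCLC,
#'   bandwidth 75, cutoff 0.25).
#' @return a data frame with `term`, `estimate`, `std_error`, `p_value`,
#'   `separation`; attributes `log_lik`, `df` and `dropped` (families with
#'   one observed level).
#' @export
ordinal_ir_regression <- function(results,
                                  outcome = c("ir_sync", "ir_nosync",
                                              "ir_combined"),
                                  reference_levels = list(
                                    method = "WCLC", transform = "raw",
                                    smoothing = "none", bandwidth = "75",
                                    r2_cutoff = "0.25")) {
  outcome <- match.arg(outcome)
  ir <- factor(results[[outcome]], levels = ir_levels, ordered = TRUE)
  ir <- droplevels(ir)
  if (nlevels(ir) < 2L) {
    stop(paste("the identification rate is constant across configurations;",
               "an ordinal regression needs at least two observed classes"),
         call. = FALSE)
  }
  fams <- c("method", "transform", "smoothing", "bandwidth", "r2_cutoff")
  dat <- data.frame(ir = ir)
  used <- character(0); dropped <- character(0)
  for (f in fams) {
    v <- factor(as.character(results[[f]]))
    if (nlevels(v) < 2L) { dropped <- c(dropped, f); next }
    ref <- as.character(reference_levels[[f]])
    if (length(ref) && ref %in% levels(v)) v <- stats::relevel(v, ref)
    dat[[f]] <- v
    used <- c(used, f)
  }
  if (!length(used)) stop("no parameter family varies", call. = FALSE)
  fml <- stats::as.formula(paste("ir ~", paste(used, collapse = " + ")))
  if (nlevels(ir) >= 3L) {
    fit <- suppressWarnings(MASS::polr(fml, data = dat, Hess = TRUE))
    co <- fit$coefficients
    se <- tryCatch(sqrt(diag(stats::vcov(fit)))[names(co)],
                   error = function(e) {
                     stats::setNames(rep(NA_real_, length(co)), names(co))
                   })
    n_par <- length(co) + length(fit$zeta)
    ll <- -fit$deviance / 2
  } else {
    # with two observed classes the proportional-odds model collapses to a
    # binary logistic regression on P(higher class)
    dat$ir_bin <- as.integer(dat$ir == levels(dat$ir)[2L])
    fit <- suppressWarnings(
      stats::glm(stats::update(fml, ir_bin ~ .), data = dat,
                 family = stats::binomial()))
    co <- stats::coef(fit)[-1L]  # drop the intercept
    se <- sqrt(diag(stats::vcov(fit)))[names(co)]
    n_par <- length(stats::coef(fit))
    ll <- as.numeric(stats::logLik(fit))
  }
  tval <- co / se
  out <- data.frame(
    term = names(co), estimate = unname(co), std_error = unname(se),
    p_value = unname(2 * stats::pnorm(abs(tval), lower.tail = FALSE)),
    separation = unname(abs(co) > 10 | is.na(se) | se > 100))
  attr(out, "log_lik") <- ll
  attr(out, "df") <- n_par
  attr(out, "dropped") <- dropped
  out
}

#' Kruskal-Wallis test of a per-sequence score across sequences
#'
#' Tests whether the stimulus sequence influences the per-sequence score
#' (kappa_mean or pr_out_mean): rank-based H with tie correction and a
#' chi-square p-value, via [stats::kruskal.test()]. If every value is
#' identical, H = 0 is returned with a warning instead of an error.
#'
#' @param values numeric scores, one per (configuration, sequence).
#' @param sequence the sequence id of each score (grouping variable).
#' @return a list with `H`, `df`, `p_value` and `mean_ranks` per group.
#' @export
kruskal_by_sequence <- function(values, sequence) {
  sequence <- factor(sequence)
  if (nlevels(sequence) < 2L) stop("need >= 2 groups", call. = FALSE)
  ranks <- rank(values)
  mean_ranks <- tapply(ranks, sequence, mean)
  if (length(unique(values)) == 1L) {
    warning("all values identical; H = 0", call. = FALSE)
    return(list(H = 0, df = nlevels(sequence) - 1L, p_value = 1,
                mean_ranks = mean_ranks))
  }
  kt <- stats::kruskal.test(values, sequence)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, mean_ranks = mean_ranks)
}

#' Per-sequence scores of a configuration across a dataset
#'
#' Convenience helper for [kruskal_by_sequence()]: evaluates each
#' configuration on one condition and returns the long table of per-sequence
#' kappas (sync dyads) and pr_outs (nosync dyads).
#'
#' @inheritParams run_grid
#' @param condition which condition to score.
#' @return a data frame with `config_id`, `sequence`, `measure`
#'   (`"kappa"`/`"pr_out"`) and `value`.
#' @export
per_sequence_scores <- function(dataset, grid, condition = "artificial",
                                master_seed = 1L) {
  rows <- list()
  for (config in grid$configs) {
    ev <- evaluate_config(dataset, config, condition, master_seed)
    if (length(ev$kappas)) {
      rows[[length(rows) + 1L]] <- data.frame(
        config_id = config$id, sequence = names(ev$kappas),
        measure = "kappa", value = unname(ev$kappas))
    }
    if (length(ev$pr_outs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        config_id = config$id, sequence = names(ev$pr_outs),
        measure = "pr_out", value = unname(ev$pr_outs))
    }
  }
  do.call(rbind, rows)
}
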