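# Concordance layer: binary frame ratings, Cohen's kappa, over-identification
# rate (pr_out), ordinal identification-rate classes, and the sequential
# gating of configurations across conditions.

ir_levels <- c("poor", "acceptable", "good")

#' Convert an interval list to a binary per-frame rating
#'
#' Frames covered by the union of the `[start, end)` spans are marked 1,
#' all others 0. Overlapping intervals are not double counted.
#'
#' @param intervals a data frame with `start` / `end` columns (0-based,
#'   half-open), an [interval_spec()], or a list of them; `NULL` or a
#'   zero-row frame gives all zeros.
#' @param n_frames rating length.
#' @return an integer vector of 0/1 of length `n_frames`.
#' @export
intervals_to_binary <- function(intervals, n_frames) {
  rating <- integer(n_frames)
  if (is.null(intervals)) return(rating)
  if (inherits(intervals, "interval_spec")) intervals <- list(intervals)
  if (is.list(intervals) && !is.data.frame(intervals)) {
    intervals <- do.call(rbind, lapply(intervals, function(iv) {
      data.frame(start = iv$start, end = iv$end)
    }))
    if (is.null(intervals)) return(rating)
  }
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < 0 || e > n_frames || s >= e) {
      stop(sprintf("interval [%s, %s) out of range for %d frames", s, e,
                   n_frames), call. = FALSE)
    }
    rating[(s + 1L):e] <- 1L
  }
  rating
}

#' Cohen's kappa of two binary frame ratings
#'
#' Chance-corrected agreement from the 2 x 2 frame-level contingency table:
#' `kappa = (p_o - p_e) / (1 - p_e)`. In the degenerate case `p_e = 1` (both
#' raters constant) kappa is defined as 1 if the ratings are identical and 0
#' otherwise.
#'
#' @param reference,detected 0/1 vectors of equal length >= 1.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(reference, detected) {
  n <- length(reference)
  if (length(detected) != n || n < 1L) {
    stop("ratings must have equal length >= 1", call. = FALSE)
  }
  r <- reference != 0; d <- detected != 0
  p_o <- mean(r == d)
  p_e <- mean(r) * mean(d) + mean(!r) * mean(!d)
  if (p_e >= 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Proportion of frames flagged as synchronous
#'
#' Applied to no-sync sequences this is the over-identification rate: the
#' number of detected frames relative to the sequence length.
#'
#' @param detected 0/1 vector.
#' @return a proportion in `[0, 1]`.
#' @export
pr_out <- function(detected) {
  if (length(detected) < 1L) stop("empty rating", call. = FALSE)
  mean(detected != 0)
}

classify_sync <- function(kappa_min) {
  if (kappa_min > 0.60) "good" else if (kappa_min >= 0.40) "acceptable"
  else "poor"
}

classify_nosync <- function(pr_out_max) {
  if (pr_out_max <= 0.05) "good" else if (pr_out_max <= 0.10) "acceptable"
  else "poor"
}

#' Classify a configuration's identification rate
#'
#' The sync-side class follows the *minimum* kappa over the sync sequences
#' (good: > .60 on every sequence; acceptable: in \[.40, .60\]; poor:
#' < .40 — the band edge at .40 is classified acceptable and .60 is not yet
#' good) and the nosync-side class follows the *maximum* over-identification
#' rate (good: <= 5%; acceptable: in (5%, 10%\]; poor: > 10%). The combined
#' class is good only if both sides are good (and is the worse of the two
#' otherwise).
#'
#' @param kappas per-sequence kappas of the sync sequences.
#' @param pr_outs per-sequence over-identification rates of the nosync
#'   sequences.
#' @return an object of class `config_evaluation`: the inputs, their
#'   min/max/mean summaries, and `ir_sync`, `ir_nosync`, `ir_combined`.
#' @export
classify_ir <- function(kappas, pr_outs) {
  if (!length(kappas) || !length(pr_outs)) {
    stop("need at least one sync and one nosync sequence", call. = FALSE)
  }
  ir_sync <- classify_sync(min(kappas))
  ir_nosync <- classify_nosync(max(pr_outs))
  ir_combined <- ir_levels[min(match(ir_sync, ir_levels),
                               match(ir_nosync, ir_levels))]
  structure(list(
    kappas = kappas, pr_outs = pr_outs,
    kappa_min = min(kappas), kappa_max = max(kappas),
    kappa_mean = mean(kappas),
    pr_out_min = min(pr_outs), pr_out_max = max(pr_outs),
    pr_out_mean = mean(pr_outs),
    ir_sync = ir_sync, ir_nosync = ir_nosync, ir_combined = ir_combined),
    class = "config_evaluation")
}

#' @export
print.config_evaluation <- function(x, ...) {
  cat(sprintf(
    "<config_evaluation> kappa min/mean/max = %.3f/%.3f/%.3f (%s), pr_out max = %.3f (%s) -> %s\n",
    x$kappa_min, x$kappa_mean, x$kappa_max, x$ir_sync, x$pr_out_max,
    x$ir_nosync, x$ir_combined))
  invisible(x)
}

#' Evaluate one configuration on one condition of a dataset
#'
#' Runs [identify_msi()] on every dyad of `condition`, scores sync dyads by
#' Cohen's kappa against their reference interval and nosync dyads by the
#' over-identification rate, and classifies the identification rate.
#'
#' @param dataset a [generate_dyad_dataset()] result (or any `dyad_dataset`).
#' @param config an [analysis_config()].
#' @param condition which condition to evaluate.
#' @param master_seed forwarded to [identify_msi()].
#' @return a [classify_ir()] result with per-sequence values named by dyad id.
#' @export
evaluate_config <- function(dataset, config,
                            condition = c("artificial", "isolated", "embedded"),
                            master_seed = 1L) {
  condition <- match.arg(condition)
  kappas <- c(); pr_outs <- c()
  for (d in dataset) {
    if (d$condition != condition) next
    detected <- identify_msi(d, config, master_seed)
    n <- length(d$a$values)
    det_bin <- intervals_to_binary(detected, n)
    if (d$sync_label == "sync") {
      ref_bin <- intervals_to_binary(d$reference, n)
      kappas[d$id] <- cohens_kappa(ref_bin, det_bin)
    } else {
      pr_outs[d$id] <- pr_out(det_bin)
    }
  }
  classify_ir(kappas, pr_outs)
}

#' Sequential gating of configurations across conditions
#'
#' Stage 1 keeps the configurations with a good combined identification rate
#' in the artificial condition; stage 2 re-evaluates those on the naturally
#' isolated condition and keeps the good-or-acceptable ones; stage 3 carries
#' the stage-2 survivors to the naturally embedded condition.
#'
#' @param results a [run_grid()] table (rows = config x condition) with
#'   columns `config_id`, `condition`, `ir_combined`.
#' @return a list with character vectors `stage1`, `stage2`, `stage3`
#'   (config ids surviving each gate; `stage3` are the ids whose embedded
#'   results are consulted) and `embedded`, the embedded-condition rows of
#'   the stage-2 survivors.
#' @export
sequential_selection <- function(results) {
  art <- results[results$condition == "artificial", ]
  stage1 <- art$config_id[art$ir_combined == "good"]
  iso <- results[results$condition == "isolated" &
                   results$config_id %in% stage1, ]
  stage2 <- iso$config_id[iso$ir_combined %in% c("good", "acceptable")]
  emb <- results[results$condition == "embedded" &
                   results$config_id %in% stage2, ]
  list(stage1 = stage1, stage2 = stage2, stage3 = stage2, embedded = emb)
}
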