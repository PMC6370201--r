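# Synthetic dyadic motion-energy sequences with known ground-truth
# synchronization intervals, and the three complexity conditions of the
# validation design: naturally embedded (analogue), naturally isolated,
# and artificial (perfect echo).

#' Ground-truth synchronization interval
#'
#' @param start,end 0-based half-open frame span of the (designated) interval.
#' @param construction_lag echo lag in frames for artificially constructed
#'   pairs, `NA` otherwise.
#' @return an object of class `interval_spec`.
#' @export
interval_spec <- function(start, end, construction_lag = NA_integer_) {
  if (start < 0 || end <= start) stop("need 0 <= start < end", call. = FALSE)
  structure(list(start = as.integer(start), end = as.integer(end),
                 construction_lag = as.integer(construction_lag)),
            class = "interval_spec")
}

#' An aligned dyad of motion energy series
#'
#' @param id stable sequence identifier.
#' @param condition `"embedded"`, `"isolated"` or `"artificial"`.
#' @param sync_label `"sync"` or `"nosync"`.
#' @param a,b [mets()] objects of equal length and fps (a = patient,
#'   b = therapist).
#' @param reference an [interval_spec()]: the true synchronization interval
#'   for sync pairs, or the designated no-sync interval used to build the
#'   isolated condition.
#' @return an object of class `dyad_sequence`.
#' @export
dyad_sequence <- function(id, condition = c("embedded", "isolated", "artificial"),
                          sync_label = c("sync", "nosync"),
                          a, b, reference = NULL) {
  condition <- match.arg(condition)
  sync_label <- match.arg(sync_label)
  stopifnot(inherits(a, "mets"), inherits(b, "mets"))
  if (length(a$values) != length(b$values) || a$fps != b$fps) {
    stop("the two series must share length and fps", call. = FALSE)
  }
  if (sync_label == "sync" && is.null(reference)) {
    stop("sync sequences must carry a reference interval", call. = FALSE)
  }
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "interval_spec"))
    if (reference$end > length(a$values)) {
      stop("reference interval exceeds the sequence length", call. = FALSE)
    }
  }
  structure(list(id = id, condition = condition, sync_label = sync_label,
                 a = a, b = b, reference = reference),
            class = "dyad_sequence")
}

#' @export
print.dyad_sequence <- function(x, ...) {
  ref <- if (is.null(x$reference)) "none" else {
    sprintf("[%d,%d)", x$reference$start, x$reference$end)
  }
  cat(sprintf("<dyad_sequence> %s: %s/%s, %d frames @ %g fps, reference %s\n",
              x$id, x$condition, x$sync_label, length(x$a$values), x$a$fps, ref))
  invisible(x)
}

#' Generator parameters for synthetic dyad sequences
#'
#' Defaults encode the study conditions: ~118 s sequences at 25 fps
#' (SD 12.94 s, floored at 60 s), interval durations from a Gaussian with
#' mean 145 and SD 57.93 frames clipped to \[26, 282\], an echo lag of 50
#' frames for the artificial condition, ROI size ratios drawn from
#' \[1.03, 1.99\], and raised-cosine movement pulses of width 10-60 frames
#' and amplitude 5-80 motion-energy units. In embedded sync intervals the
#' therapist's response is a per-pulse amplitude-rescaled (0.3-1.5), slightly
#' lagged (up to +-37 frames, i.e. 1.5 s) copy of the patient's pulses, so a
#' large movement can be answered by a rather weak one.
#'
#' @param fps frames per second.
#' @param duration_mean_s,duration_sd_s,duration_min_s sequence duration
#'   distribution, seconds.
#' @param msi_mean,msi_sd,msi_min,msi_max interval duration distribution,
#'   frames.
#' @param pulse_width,pulse_amp ranges (min, max) of pulse width in frames and
#'   peak amplitude in motion-energy units.
#' @param background_rate background pulse onset rate per frame outside the
#'   interval (sparse, bursty movement; the default leaves well over 40% of
#'   out-of-pulse frames at exactly zero).
#' @param copy_lag_max largest within-interval response lag, frames.
#' @param copy_amp range of the per-pulse amplitude rescaling of the response.
#' @param echo_lag shift used by [make_artificial()], frames.
#' @param roi_ratio_range range of the larger-to-smaller ROI area ratio.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(fps = 25,
                             duration_mean_s = 118, duration_sd_s = 12.94,
                             duration_min_s = 60,
                             msi_mean = 145, msi_sd = 57.93,
                             msi_min = 26, msi_max = 282,
                             pulse_width = c(10, 60), pulse_amp = c(5, 80),
                             background_rate = 0.006,
                             copy_lag_max = 37, copy_amp = c(0.3, 1.5),
                             echo_lag = 50,
                             roi_ratio_range = c(1.03, 1.99)) {
  stopifnot(msi_min > 0, msi_max >= msi_min, echo_lag >= 0,
            duration_min_s > 0, background_rate >= 0)
  structure(as.list(environment()), class = "generator_params")
}

# one raised-cosine bump added in place; returns the modified series
add_bump <- function(values, onset, width, amp) {
  n <- length(values)
  width <- max(2L, as.integer(width))
  idx <- onset + seq_len(width) - 1L           # 1-based onset
  keep <- idx >= 1L & idx <= n
  tt <- (seq_len(width) - 0.5) / width
  values[idx[keep]] <- values[idx[keep]] +
    amp * 0.5 * (1 - cos(2 * pi * tt[keep]))
  values
}

# pulse train roughly tiling [from, to) (1-based, to exclusive); returns
# list(values, pulses = data.frame(onset, width, amp)) for reuse by the
# response construction
tile_pulses <- function(values, from, to, params) {
  pulses <- list()
  pos <- from
  while (pos < to) {
    w <- round(stats::runif(1, params$pulse_width[1], params$pulse_width[2]))
    w <- min(w, to - pos)
    if (w >= 2) {
      amp <- stats::runif(1, params$pulse_amp[1], params$pulse_amp[2])
      values <- add_bump(values, pos, w, amp)
      pulses[[length(pulses) + 1L]] <-
        data.frame(onset = pos, width = w, amp = amp)
    }
    pos <- pos + w + sample(0:8, 1)
  }
  list(values = values,
       pulses = if (length(pulses)) do.call(rbind, pulses) else
         data.frame(onset = integer(0), width = integer(0), amp = numeric(0)))
}

# sparse background pulses everywhere except the protected zone [z1, z2]
background_pulses <- function(n, z1, z2, params) {
  values <- numeric(n)
  n_pulses <- stats::rpois(1, params$background_rate * n)
  if (n_pulses == 0) return(values)
  for (k in seq_len(n_pulses)) {
    w <- round(stats::runif(1, params$pulse_width[1], params$pulse_width[2]))
    onset <- sample.int(n - w, 1)
    if (onset + w - 1L >= z1 && onset <= z2) next  # keep the interval clean
    values <- add_bump(values, onset, w,
                       stats::runif(1, params$pulse_amp[1], params$pulse_amp[2]))
  }
  values
}

#' Generate one embedded-condition dyad with a known interval
#'
#' Both persons receive sparse background pulse trains; within the reference
#' interval the patient moves with a pulse train tiling the interval and, for
#' sync pairs, the therapist answers with a lagged, per-pulse
#' amplitude-rescaled copy of those pulses. For nosync pairs both persons move
#' with independent pulses inside the designated interval. Outside pulses the
#' series are exactly zero (zero-inflated), so the later noise injection is
#' what makes local correlations defined.
#'
#' @param params a [generator_params()].
#' @param sync logical: embed true synchrony or independent movement.
#' @param seed integer seed; equal seeds reproduce the pair exactly.
#' @param id sequence identifier.
#' @return a list with `dyad` (a [dyad_sequence()], condition `"embedded"`)
#'   and `reference` (its [interval_spec()]).
#' @export
generate_base_pair <- function(params = generator_params(), sync = TRUE,
                               seed = 1L, id = "seq01") {
  stopifnot(inherits(params, "generator_params"))
  with_seed(seed, {
    fps <- params$fps
    len <- round(fps * max(params$duration_min_s,
                           stats::rnorm(1, params$duration_mean_s,
                                        params$duration_sd_s)))
    d <- round(min(max(stats::rnorm(1, params$msi_mean, params$msi_sd),
                       params$msi_min), params$msi_max))
    margin <- 300L
    if (len < d + 2L * margin) {
      stop("interval longer than the sequence allows", call. = FALSE)
    }
    s <- sample(margin:(len - d - margin), 1)    # 0-based interval start
    e <- s + d
    buffer <- 25L
    a_vals <- background_pulses(len, s + 1L - buffer, e + buffer, params)
    b_vals <- background_pulses(len, s + 1L - buffer, e + buffer, params)
    tiled <- tile_pulses(a_vals, s + 1L, e + 1L, params)  # 1-based tiling
    a_vals <- tiled$values
    if (sync) {
      u <- round(stats::runif(1, -params$copy_lag_max, params$copy_lag_max))
      for (k in seq_len(nrow(tiled$pulses))) {
        p <- tiled$pulses[k, ]
        scale <- stats::runif(1, params$copy_amp[1], params$copy_amp[2])
        jitter <- sample(-3:3, 1)
        b_vals <- add_bump(b_vals, p$onset + u + jitter, p$width,
                           p$amp * scale)
      }
    } else {
      b_vals <- tile_pulses(b_vals, s + 1L, e + 1L, params)$values
    }
    ratio <- stats::runif(1, params$roi_ratio_range[1],
                          params$roi_ratio_range[2])
    base_area <- 12000L
    areas <- if (stats::runif(1) < 0.5) {
      c(base_area, round(base_area * ratio))
    } else {
      c(round(base_area * ratio), base_area)
    }
    ref <- interval_spec(s, e)
    dyad <- dyad_sequence(
      id = id, condition = "embedded",
      sync_label = if (sync) "sync" else "nosync",
      a = mets(a_vals, fps, areas[1], "patient"),
      b = mets(b_vals, fps, areas[2], "therapist"),
      reference = ref)
    list(dyad = dyad, reference = ref)
  })
}

#' Derive the naturally isolated condition from an embedded pair
#'
#' Sets every value of both series outside the reference interval to zero,
#' keeping only the movements of the designated interval.
#'
#' @param embedded a [dyad_sequence()] with a reference interval.
#' @return a new [dyad_sequence()] with condition `"isolated"`.
#' @export
make_isolated <- function(embedded) {
  stopifnot(inherits(embedded, "dyad_sequence"))
  if (is.null(embedded$reference)) {
    stop("make_isolated() needs a reference interval", call. = FALSE)
  }
  ref <- embedded$reference
  n <- length(embedded$a$values)
  keep <- rep(FALSE, n)
  keep[(ref$start + 1L):ref$end] <- TRUE
  iso <- embedded
  iso$a$values[!keep] <- 0
  iso$b$values[!keep] <- 0
  iso$condition <- "isolated"
  iso$id <- sub("embedded", "isolated", iso$id, fixed = TRUE)
  iso
}

#' Derive the artificial condition from an isolated pair
#'
#' For sync pairs the therapist series is replaced by the patient series
#' shifted forward by `lag` frames (zero-filled head): perfect time-lagged
#' synchrony, i.e. echoing, with a known construction lag. For nosync pairs
#' the therapist series is replaced by all zeros.
#'
#' @param isolated a [dyad_sequence()] with condition `"isolated"`.
#' @param lag echo lag in frames (default 50).
#' @return a new [dyad_sequence()] with condition `"artificial"`.
#' @export
make_artificial <- function(isolated, lag = 50L) {
  stopifnot(inherits(isolated, "dyad_sequence"))
  if (isolated$condition != "isolated") {
    stop("make_artificial() expects an isolated-condition pair", call. = FALSE)
  }
  n <- length(isolated$a$values)
  lag <- as.integer(lag)
  if (lag >= n) stop("lag must be smaller than the sequence length",
                     call. = FALSE)
  art <- isolated
  if (isolated$sync_label == "sync") {
    shifted <- numeric(n)
    shifted[(lag + 1L):n] <- isolated$a$values[1:(n - lag)]
    art$b$values <- shifted
    art$reference$construction_lag <- lag
  } else {
    art$b$values <- numeric(n)
  }
  art$condition <- "artificial"
  art$id <- sub("isolated", "artificial", art$id, fixed = TRUE)
  art
}

#' Generate the full three-condition validation dataset
#'
#' Generates `n_sync + n_nosync` embedded base pairs and derives the isolated
#' and artificial condition from each, giving `3 * (n_sync + n_nosync)` dyads
#' (60 at the defaults) with stable ids of the form
#' `seq01_sync_embedded`. All randomness flows from `seed` through one
#' documented per-sequence derivation, so the dataset is reproducible.
#'
#' @param params a [generator_params()].
#' @param n_sync,n_nosync numbers of sync / nosync base sequences (10 each by
#'   default).
#' @param seed master seed.
#' @return a list of [dyad_sequence()] objects with class
#'   `dyad_dataset`.
#' @export
generate_dyad_dataset <- function(params = generator_params(),
                                  n_sync = 10L, n_nosync = 10L, seed = 1L) {
  stopifnot(n_sync + n_nosync >= 1L)
  out <- list()
  labels <- c(rep("sync", n_sync), rep("nosync", n_nosync))
  for (i in seq_along(labels)) {
    id <- sprintf("seq%02d_%s_embedded", i, labels[i])
    pair_seed <- derive_seed(seed, paste0("pair/", i, "/", labels[i]))
    emb <- generate_base_pair(params, sync = labels[i] == "sync",
                              seed = pair_seed, id = id)$dyad
    iso <- make_isolated(emb)
    art <- make_artificial(iso, params$echo_lag)
    out[[emb$id]] <- emb
    out[[iso$id]] <- iso
    out[[art$id]] <- art
  }
  structure(out, class = "dyad_dataset", seed = seed)
}

#' @export
print.dyad_dataset <- function(x, ...) {
  conds <- vapply(x, function(d) d$condition, "")
  labs <- vapply(x, function(d) d$sync_label, "")
  cat(sprintf("<dyad_dataset> %d dyads (%s)\n", length(x),
              paste(names(table(paste(conds, labs))), table(paste(conds, labs)),
                    sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Write a dataset manifest and per-person METS files
#'
#' The manifest is tab-separated with columns id, condition, sync_label,
#' n_frames, ref_start, ref_end, construction_lag; each dyad's two series go
#' to `<id>_a.tsv` / `<id>_b.tsv` (see [write_mets()]) and the generator
#' parameters to `params.json`.
#'
#' @param dataset a [generate_dyad_dataset()] result.
#' @param dir output directory (created if missing).
#' @param params optional [generator_params()] echoed to a JSON sidecar.
#' @return the manifest path, invisibly.
#' @export
write_dyad_dataset <- function(dataset, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(d) {
    data.frame(
      id = d$id, condition = d$condition, sync_label = d$sync_label,
      n_frames = length(d$a$values),
      ref_start = if (is.null(d$reference)) NA else d$reference$start,
      ref_end = if (is.null(d$reference)) NA else d$reference$end,
      construction_lag = if (is.null(d$reference)) NA else
        d$reference$construction_lag)
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (d in dataset) {
    write_mets(d$a, file.path(dir, paste0(d$id, "_a.tsv")))
    write_mets(d$b, file.path(dir, paste0(d$id, "_b.tsv")))
  }
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params), file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

#' Read a dataset written by [write_dyad_dataset()]
#'
#' @param dir directory containing `manifest.tsv` and the METS files.
#' @return a `dyad_dataset` list.
#' @export
read_dyad_dataset <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    ref <- if (is.na(row$ref_start)) NULL else {
      interval_spec(row$ref_start, row$ref_end,
                    if (is.na(row$construction_lag)) NA_integer_ else
                      row$construction_lag)
    }
    out[[row$id]] <- dyad_sequence(
      id = row$id, condition = row$condition, sync_label = row$sync_label,
      a = read_mets(file.path(dir, paste0(row$id, "_a.tsv"))),
      b = read_mets(file.path(dir, paste0(row$id, "_b.tsv"))),
      reference = ref)
  }
  structure(out, class = "dyad_dataset")
}
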