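# Preprocessing chain: acceleration magnitude -> decimation to 1 Hz -> LMS
# adaptive noise cancellation -> moving median (k = 3) -> 30-minute pre-ESM
# window extraction. Operates on raw_channel objects and produces segment
# objects carrying their derived labels and provenance.

#' Acceleration magnitude
#'
#' Euclidean norm of the three axes, `sqrt(ax^2 + ay^2 + az^2)`, a proxy for
#' overall motion intensity, quantised to multiples of the sensor precision
#' (1/2048 g). Quantisation is applied after the norm.
#'
#' @param ax,ay,az Equal-length numeric vectors (units of g).
#' @param precision Quantisation step in g; `NULL` disables quantisation.
#' @return Numeric vector of magnitudes.
#' @examples
#' accel_magnitude(3, 4, 0)  # 5
#' @export
accel_magnitude <- function(ax, ay, az, precision = 1 / 2048) {
  if (length(ay) != length(ax) || length(az) != length(ax)) {
    stopf("axis length mismatch: %d / %d / %d", length(ax), length(ay),
          length(az))
  }
  m <- sqrt(ax^2 + ay^2 + az^2)
  if (!is.null(precision)) m <- round(m / precision) * precision
  m
}

#' Decimate by keeping every n-th sample
#'
#' Retains 0-based indices 0, n, 2n, ... (the first sample is always kept;
#' the starting phase is configurable). Output length is `ceiling(len / n)`
#' at phase 0. `NA` (missing) samples pass through untouched.
#'
#' @param series Numeric vector.
#' @param n Positive integer decimation factor (GSR 40, ACCEL 20 to reach
#'   1 Hz).
#' @param phase 0-based index of the first retained sample, in `[0, n)`.
#' @return The decimated vector.
#' @export
decimate_every_nth <- function(series, n, phase = 0L) {
  if (!is_count(n)) stopf("decimation factor n must be a positive integer, got %s", n)
  phase <- as.integer(phase)
  if (phase < 0L || phase >= n) stopf("phase must lie in [0, n)")
  series[seq.int(1L + phase, length(series), by = n)]
}

#' LMS filter configuration
#'
#' @param order Number of filter taps.
#' @param mu Step size of the per-sample weight update `w <- w + mu * e * x`.
#' @param reference `"delayed_self"` (adaptive line enhancer: the reference is
#'   the input delayed by `delay` samples) or `"external"` (classical noise
#'   cancellation against a supplied reference channel).
#' @param delay Reference delay in samples (delayed-self mode).
#' @return An `lms_config` list.
#' @export
lms_config <- function(order = 8L, mu = 0.01,
                       reference = c("delayed_self", "external"),
                       delay = 1L) {
  reference <- match.arg(reference)
  if (!is_count(order)) stopf("order must be a positive integer")
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0) stopf("mu must be >= 0")
  if (!is_count(delay)) stopf("delay must be a positive integer")
  structure(list(order = as.integer(order), mu = mu, reference = reference,
                 delay = as.integer(delay)), class = "lms_config")
}

#' Adaptive noise cancellation by the LMS algorithm
#'
#' A linear filter over a reference signal predicts the current sample; the
#' weights are updated per sample by the standard least-mean-squares rule
#' `w <- w + mu * e * x` with `e = d - w.x`. In `delayed_self` mode
#' (adaptive line enhancer) the reference is the input's own recent past, the
#' filter converges on the predictable (physiological) component, and the
#' returned series is the prediction — the enhanced signal. In `external`
#' mode the reference carries the interference (e.g. motion), the filter
#' estimates the noise, and the returned series is the residual `d - w.x`.
#'
#' The input is standardised (z-scored) before filtering and the output
#' rescaled back, so `mu` has a consistent meaning across channels. Weights
#' start at zero; with `mu = 0` they never move, so the prediction stays at
#' its initial (zero) value.
#'
#' @param series Finite numeric vector.
#' @param cfg An [lms_config()].
#' @param reference Reference vector, required in `external` mode.
#' @param standardize Standardise before filtering (default `TRUE`).
#' @return Cleaned series, same length as the input. Attribute `weights`
#'   holds the final filter taps.
#' @export
lms_denoise <- function(series, cfg = lms_config(), reference = NULL,
                        standardize = TRUE) {
  stopifnot(inherits(cfg, "lms_config"))
  if (anyNA(series) || any(!is.finite(series))) {
    stopf("lms_denoise requires a finite series (interpolate gaps first)")
  }
  n <- length(series)
  if (cfg$reference == "external") {
    if (is.null(reference)) stopf("external reference mode needs a reference")
    if (length(reference) != n) stopf("reference length mismatch")
  }

  mu_sd <- c(0, 1)
  d <- series
  r <- if (cfg$reference == "external") reference else series
  if (standardize) {
    mu_sd <- c(mean(d), stats::sd(d))
    if (!is.finite(mu_sd[2]) || mu_sd[2] < .Machine$double.eps) mu_sd[2] <- 1
    d <- (d - mu_sd[1]) / mu_sd[2]
    r <- if (cfg$reference == "external") {
      rs <- stats::sd(reference)
      (reference - mean(reference)) / (if (is.finite(rs) && rs > .Machine$double.eps) rs else 1)
    } else d
  }

  p <- cfg$order
  lag0 <- cfg$delay
  w <- numeric(p)
  y <- numeric(n)
  bound <- 1e6
  # zero-padded reference so taps before the start read as 0
  pad <- p + lag0
  rp <- c(numeric(pad), r)
  tap <- pad - lag0 - seq_len(p) + 1L  # rp[t + tap] == r[t - delay - j + 1]
  for (t in seq_len(n)) {
    x <- rp[t + tap]
    yt <- sum(w * x)
    e <- d[t] - yt
    w <- w + cfg$mu * e * x
    wn <- sum(w * w)
    if (!is.finite(wn) || wn > bound) {
      stopf("LMS filter diverged (weight norm > %g); reduce mu = %g", bound,
            cfg$mu)
    }
    y[t] <- yt
  }
  out <- if (cfg$reference == "external") d - y else y
  out <- out * mu_sd[2] + mu_sd[1]
  attr(out, "weights") <- w
  out
}

#' Moving median filter, kernel 3
#'
#' Each output sample is the median of the 3-sample window centred on it;
#' edges use nearest-value replication (for a width-3 kernel this leaves the
#' end samples unchanged, since `median(a, a, b) = a`). Length is preserved
#' and every output value is one of the input values.
#'
#' @param series Numeric vector, length >= 1, no `NA`.
#' @return Filtered vector.
#' @export
median_filter3 <- function(series) {
  if (length(series) < 3L) return(series)
  as.numeric(stats::runmed(series, 3L, endrule = "keep"))
}

#' Extract the pre-ESM window from a 1 Hz channel
#'
#' Returns the `window_s` samples whose times cover
#' `[esm_timestamp - window_s, esm_timestamp)`, oldest first, ending at the
#' sample immediately before the prompt. Samples outside the recording span
#' and recording gaps count as missing; the window is flagged (not padded)
#' when its completeness falls below the threshold.
#'
#' @param channel A 1 Hz [raw_channel()].
#' @param esm_timestamp Prompt time (POSIX seconds).
#' @param window_s Window length in seconds (default 1800 = 30 min).
#' @param completeness_threshold Minimum fraction of non-missing samples for
#'   a usable window.
#' @return A list: `values` (length `window_s`, `NA` where missing),
#'   `completeness` in `[0, 1]`, and `ok` (whether the window is usable).
#' @export
extract_window <- function(channel, esm_timestamp, window_s = 1800L,
                           completeness_threshold = 1.0) {
  stopifnot(inherits(channel, "raw_channel"))
  if (abs(channel$sample_rate - 1) > 1e-9) {
    stopf("extract_window expects a 1 Hz channel, got %g Hz",
          channel$sample_rate)
  }
  offset <- esm_timestamp - channel$t0
  k_last <- ceiling(offset) - 1  # 0-based index of last sample strictly before the prompt
  idx <- seq(k_last - window_s + 1, k_last) + 1  # 1-based
  vals <- rep(NA_real_, window_s)
  inside <- idx >= 1L & idx <= length(channel$values)
  vals[inside] <- channel$values[idx[inside]]
  completeness <- mean(!is.na(vals))
  list(values = vals, completeness = completeness,
       ok = completeness >= completeness_threshold)
}

#' Preprocessing configuration
#'
#' @param gsr_decimation,accel_decimation Decimation factors to reach 1 Hz.
#' @param decimation_phase 0-based phase of the retained samples.
#' @param lms An [lms_config()]; `lms_enabled` switches the stage.
#' @param median_enabled Apply the kernel-3 moving median.
#' @param window_s Pre-ESM window length in seconds.
#' @param completeness_threshold Minimum usable-window completeness; at the
#'   default 1.0 only fully covered windows are kept. Below 1.0, remaining
#'   internal missing samples are linearly interpolated and flagged in the
#'   segment's completeness field.
#' @param standardize Per-subject, per-modality z-scoring over the full
#'   recording before windowing (model input scaling; switchable).
#' @param accel_precision Magnitude quantisation step in g.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(gsr_decimation = 40L, accel_decimation = 20L,
                              decimation_phase = 0L, lms = lms_config(),
                              lms_enabled = TRUE, median_enabled = TRUE,
                              window_s = 1800L, completeness_threshold = 1.0,
                              standardize = TRUE, accel_precision = 1 / 2048) {
  structure(list(gsr_decimation = as.integer(gsr_decimation),
                 accel_decimation = as.integer(accel_decimation),
                 decimation_phase = as.integer(decimation_phase),
                 lms = lms, lms_enabled = isTRUE(lms_enabled),
                 median_enabled = isTRUE(median_enabled),
                 window_s = as.integer(window_s),
                 completeness_threshold = completeness_threshold,
                 standardize = isTRUE(standardize),
                 accel_precision = accel_precision),
            class = "preprocess_config")
}

# Linearly interpolate internal NA runs; leading/trailing NAs remain.
interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  filled <- x
  inner <- seq(ok[1L], ok[length(ok)])
  filled[inner] <- stats::approx(ok, x[ok], xout = inner)$y
  filled
}

# Filter one 1 Hz series through LMS + median, respecting missing samples:
# gaps are temporarily interpolated for the filters, then re-masked.
filter_1hz <- function(values, config) {
  na_mask <- is.na(values)
  x <- interp_na(values)
  run <- !is.na(x)
  if (any(run)) {
    y <- x[run]
    if (config$lms_enabled) y <- as.numeric(lms_denoise(y, config$lms))
    if (config$median_enabled) y <- median_filter3(y)
    x[run] <- y
  }
  x[na_mask] <- NA_real_
  x
}

#' Construct a processed segment
#'
#' @param matrix T x 3 numeric matrix, columns `HR`, `GSR`, `ACCEL`, rows
#'   oldest to newest, ending at the sample immediately before the prompt.
#' @param subject_id,esm_timestamp Identity of the prompt.
#' @param labels One-row label data frame from [label_set()].
#' @param completeness Named per-column completeness fractions.
#' @param provenance List of preprocessing parameters and notes.
#' @return A `segment` object.
#' @export
segment <- function(matrix, subject_id, esm_timestamp, labels = NULL,
                    completeness = NULL, provenance = list()) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 3L)
  colnames(matrix) <- c("HR", "GSR", "ACCEL")
  structure(list(matrix = matrix, subject_id = as.character(subject_id),
                 esm_timestamp = as.numeric(esm_timestamp), labels = labels,
                 completeness = completeness, provenance = provenance),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> subject %s, prompt @ %.0f, T = %d\n", x$subject_id,
              x$esm_timestamp, nrow(x$matrix)))
  invisible(x)
}

#' Preprocess one subject's recording into labelled segments
#'
#' Runs the full per-modality chain — acceleration magnitude, decimation to
#' 1 Hz, LMS adaptive noise cancellation, kernel-3 moving median, optional
#' per-modality z-scoring — then extracts the pre-ESM window for every prompt
#' and attaches the derived labels. The applied chain is recorded in each
#' segment's provenance.
#'
#' @param channels Named list of [raw_channel()]s: `hr` (1 Hz), `gsr`
#'   (40 Hz), and either `accel_x`/`accel_y`/`accel_z` (20 Hz) or a
#'   precomputed `accel` magnitude channel.
#' @param esm ESM data frame for this subject (layout of [read_esm()]).
#' @param config A [preprocess_config()].
#' @return A list: `segments` (list of [segment()]s) and `report` (one row
#'   per prompt: timestamp, status, per-column completeness).
#' @export
preprocess_subject <- function(channels, esm, config = preprocess_config()) {
  names(channels) <- tolower(names(channels))
  have_axes <- all(c("accel_x", "accel_y", "accel_z") %in% names(channels))
  if (!"hr" %in% names(channels) || !"gsr" %in% names(channels) ||
      !(have_axes || "accel" %in% names(channels))) {
    stopf("subject %s: missing modality (need hr, gsr, accel)",
          if (length(channels)) channels[[1L]]$subject_id else "?")
  }

  hr <- channels$hr
  if (abs(hr$sample_rate - 1) > 1e-9) stopf("hr channel must be 1 Hz")

  gsr_1hz <- decimate_every_nth(channels$gsr$values, config$gsr_decimation,
                                config$decimation_phase)
  if (have_axes) {
    mag <- accel_magnitude(channels$accel_x$values, channels$accel_y$values,
                           channels$accel_z$values,
                           precision = config$accel_precision)
    accel_t0 <- channels$accel_x$t0
    accel_rate <- channels$accel_x$sample_rate
  } else {
    mag <- channels$accel$values
    accel_t0 <- channels$accel$t0
    accel_rate <- channels$accel$sample_rate
  }
  decim <- if (abs(accel_rate - 1) > 1e-9) config$accel_decimation else 1L
  accel_1hz <- decimate_every_nth(mag, decim,
                                  if (decim > 1L) config$decimation_phase else 0L)

  series <- list(
    HR = list(values = filter_1hz(hr$values, config), t0 = hr$t0),
    GSR = list(values = filter_1hz(gsr_1hz, config), t0 = channels$gsr$t0),
    ACCEL = list(values = filter_1hz(accel_1hz, config), t0 = accel_t0)
  )
  if (config$standardize) {
    series <- lapply(series, function(s) {
      v <- s$values
      sdev <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(sdev) || sdev < .Machine$double.eps) sdev <- 1
      s$values <- (v - mean(v, na.rm = TRUE)) / sdev
      s
    })
  }
  channels_1hz <- lapply(names(series), function(nm) {
    raw_channel(series[[nm]]$values,
                modality = if (nm == "ACCEL") "ACCEL_MAG" else nm,
                sample_rate = 1, t0 = series[[nm]]$t0,
                subject_id = hr$subject_id)
  })
  names(channels_1hz) <- names(series)

  prov <- list(chain = c("accel_magnitude", "decimate", if (config$lms_enabled) "lms",
                         if (config$median_enabled) "median3",
                         if (config$standardize) "zscore", "window"),
               window_s = config$window_s,
               completeness_threshold = config$completeness_threshold,
               lms = unclass(config$lms),
               decimation = c(gsr = config$gsr_decimation,
                              accel = config$accel_decimation,
                              phase = config$decimation_phase))

  segments <- list()
  report <- data.frame(esm_timestamp = numeric(0), status = character(0),
                       hr = numeric(0), gsr = numeric(0), accel = numeric(0))
  esm <- as.data.frame(esm)
  for (i in seq_len(nrow(esm))) {
    ts <- esm$timestamp[i]
    wins <- lapply(channels_1hz, extract_window, esm_timestamp = ts,
                   window_s = config$window_s,
                   completeness_threshold = config$completeness_threshold)
    comp <- vapply(wins, `[[`, numeric(1), "completeness")
    status <- if (all(vapply(wins, `[[`, logical(1), "ok"))) "ok" else "incomplete"
    report <- rbind(report, data.frame(esm_timestamp = ts, status = status,
                                       hr = comp[["HR"]], gsr = comp[["GSR"]],
                                       accel = comp[["ACCEL"]]))
    if (status != "ok") next
    cols <- lapply(wins, function(w) {
      v <- w$values
      if (anyNA(v)) v <- interp_na(v)
      v
    })
    m <- cbind(HR = cols$HR, GSR = cols$GSR, ACCEL = cols$ACCEL)
    if (anyNA(m)) {  # leading/trailing missing that interpolation cannot fill
      report$status[nrow(report)] <- "incomplete"
      next
    }
    segments[[length(segments) + 1L]] <- segment(
      m, subject_id = hr$subject_id, esm_timestamp = ts,
      labels = label_set(esm[i, , drop = FALSE]),
      completeness = comp, provenance = prov
    )
  }
  list(segments = segments, report = report)
}

#' Preprocess a whole study
#'
#' Applies [preprocess_subject()] to every subject of an in-memory study (as
#' produced by [simulate_study()]) or of a directory in the on-disk layout of
#' [simulate_dataset()]. Subjects with a missing modality are skipped and
#' reported, not errored.
#'
#' @param study A list of per-subject lists (`channels`, `esm`), or a
#'   directory path.
#' @param config A [preprocess_config()].
#' @return A list: `segments` (flat list across subjects) and `report`
#'   (per-prompt rows with subject ids).
#' @export
preprocess_study <- function(study, config = preprocess_config()) {
  if (is.character(study)) study <- read_study(study)
  segments <- list()
  reports <- list()
  for (subj in study) {
    res <- tryCatch(preprocess_subject(subj$channels, subj$esm, config),
                    error = function(e) e)
    sid <- tryCatch(subj$channels[[1L]]$subject_id, error = function(e) "?")
    if (inherits(res, "error")) {
      reports[[length(reports) + 1L]] <-
        data.frame(subject_id = sid, esm_timestamp = NA_real_,
                   status = paste("skipped:", conditionMessage(res)),
                   hr = NA_real_, gsr = NA_real_, accel = NA_real_)
      next
    }
    if (nrow(res$report)) {
      reports[[length(reports) + 1L]] <-
        cbind(subject_id = sid, res$report)
    }
    segments <- c(segments, res$segments)
  }
  list(segments = segments,
       report = if (length(reports)) do.call(rbind, reports) else
         data.frame(subject_id = character(0)))
}

#' Read a study directory
#'
#' Expects the layout written by [simulate_dataset()]: one folder per subject
#' holding `hr.csv`, `gsr.csv`, `accel_x/y/z.csv`, plus a top-level `esm.csv`.
#'
#' @param dir Study root directory.
#' @return A list of per-subject lists (`channels`, `esm`).
#' @export
read_study <- function(dir) {
  esm_all <- read_esm(file.path(dir, "esm.csv"))
  subj_dirs <- list.dirs(dir, recursive = FALSE)
  lapply(subj_dirs, function(sd) {
    sid <- basename(sd)
    chans <- list(
      hr = read_channel(file.path(sd, "hr.csv"), "HR", 1, subject_id = sid),
      gsr = read_channel(file.path(sd, "gsr.csv"), "GSR", 40, subject_id = sid),
      accel_x = read_channel(file.path(sd, "accel_x.csv"), "ACCEL_X", 20, subject_id = sid),
      accel_y = read_channel(file.path(sd, "accel_y.csv"), "ACCEL_Y", 20, subject_id = sid),
      accel_z = read_channel(file.path(sd, "accel_z.csv"), "ACCEL_Z", 20, subject_id = sid)
    )
    list(channels = chans,
         esm = esm_all[esm_all$subject_id == sid, , drop = FALSE])
  })
}
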