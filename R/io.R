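# Readers and writers for the tabular sensor / questionnaire formats and the
# processed-segment archive. Everything downstream consumes only the types
# defined here.

#' The ten short-form PANAS item names
#'
#' Four positive-affect items and six negative-affect items, each rated on a
#' 1-5 scale in every ESM prompt.
#' @format Character vectors of item names.
#' @export
panas_positive_items <- c("inspired", "active", "determined", "attentive")

#' @rdname panas_positive_items
#' @export
panas_negative_items <- c("upset", "hostile", "alert", "ashamed", "nervous",
                          "afraid")

#' @rdname panas_positive_items
#' @export
panas_items <- c("upset", "hostile", "alert", "ashamed", "inspired", "nervous",
                 "determined", "attentive", "afraid", "active")

channel_modalities <- c("HR", "GSR", "ACCEL_X", "ACCEL_Y", "ACCEL_Z",
                        "ACCEL_MAG")

#' Construct a raw sensor channel
#'
#' A `raw_channel` is one modality's regularly sampled stream: values on the
#' grid `t0 + (i-1)/sample_rate`, with missing spans held as `NA` runs plus an
#' explicit gap table (never silently interpolated).
#'
#' @param values Numeric vector; `NA` marks missing samples.
#' @param modality One of `"HR"`, `"GSR"`, `"ACCEL_X"`, `"ACCEL_Y"`,
#'   `"ACCEL_Z"`, `"ACCEL_MAG"`.
#' @param sample_rate Sampling rate in Hz (HR 1, GSR 40, ACCEL 20).
#' @param t0 Absolute time of the first sample (POSIX seconds).
#' @param subject_id Opaque subject identifier.
#' @return An object of class `raw_channel` with fields `subject_id`,
#'   `modality`, `sample_rate`, `t0`, `values` and a `gaps` data frame
#'   (`start`, `length`, in samples).
#' @export
raw_channel <- function(values, modality, sample_rate, t0 = 0,
                        subject_id = "unknown") {
  modality <- match.arg(toupper(modality), channel_modalities)
  if (!is_count(sample_rate) && !(is.numeric(sample_rate) && sample_rate > 0)) {
    stopf("sample_rate must be a positive number, got %s", sample_rate)
  }
  if (length(values) == 0L) stopf("a raw_channel needs at least one sample")
  values <- as.numeric(values)
  if (any(!is.finite(values) & !is.na(values))) {
    stopf("channel values must be finite or NA (explicit missing)")
  }
  structure(
    list(subject_id = as.character(subject_id), modality = modality,
         sample_rate = sample_rate, t0 = as.numeric(t0), values = values,
         gaps = find_gaps(values)),
    class = "raw_channel"
  )
}

# Runs of NA in a value vector, as (start, length) in 1-based sample indices.
find_gaps <- function(values) {
  r <- rle(is.na(values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' @export
print.raw_channel <- function(x, ...) {
  cat(sprintf("<raw_channel> subject %s, %s @ %g Hz, %d samples (%d missing), t0 = %.3f\n",
              x$subject_id, x$modality, x$sample_rate, length(x$values),
              sum(is.na(x$values)), x$t0))
  invisible(x)
}

#' Read one sensor channel from CSV
#'
#' Accepts either a two-column file (`timestamp`, `value`) or a one-column
#' file (`value`) with `t0` supplied. Timestamps must be strictly increasing;
#' jumps larger than one sampling interval become explicit missing runs in the
#' returned channel rather than being interpolated.
#'
#' @param path CSV file, one header row, comma-separated.
#' @param modality,sample_rate Declared modality and rate (see
#'   [raw_channel()]).
#' @param t0 Start time, required for one-column files; ignored otherwise.
#' @param subject_id Subject identifier to attach.
#' @return A [raw_channel()].
#' @export
read_channel <- function(path, modality, sample_rate, t0 = NULL,
                         subject_id = "unknown") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (nrow(df) == 0L) stopf("empty channel file: %s", path)
  if ("value" %in% names(df)) {
    vals_raw <- df$value
  } else if (ncol(df) >= 1L && !"timestamp" %in% names(df)) {
    vals_raw <- df[[1L]]
  } else {
    stopf("%s: expected a 'value' column", path)
  }
  vals <- suppressWarnings(as.numeric(vals_raw))
  bad <- which(is.na(vals) & !is.na(vals_raw) & vals_raw != "")
  if (length(bad)) {
    stopf("%s: malformed value at data row %d ('%s')", path, bad[1L],
          vals_raw[bad[1L]])
  }

  if ("timestamp" %in% names(df)) {
    ts <- suppressWarnings(as.numeric(df$timestamp))
    badt <- which(is.na(ts))
    if (length(badt)) stopf("%s: malformed timestamp at data row %d", path, badt[1L])
    dec <- which(diff(ts) <= 0)
    if (length(dec)) {
      stopf("%s: non-monotone timestamps at data row %d", path, dec[1L] + 1L)
    }
    t0 <- ts[1L]
    # Place samples on the regular grid implied by t0 and the rate; larger
    # spacings open gaps (NA runs).
    idx <- as.integer(round((ts - t0) * sample_rate)) + 1L
    if (any(diff(idx) < 1L)) {
      stopf("%s: timestamps inconsistent with %g Hz grid", path, sample_rate)
    }
    values <- rep(NA_real_, idx[length(idx)])
    values[idx] <- vals
  } else {
    if (is.null(t0)) stopf("%s has no timestamp column; supply t0", path)
    values <- vals
  }
  raw_channel(values, modality, sample_rate, t0, subject_id)
}

#' Write a channel to CSV
#'
#' Inverse of [read_channel()]: writes (`timestamp`, `value`) rows for the
#' non-missing samples only, so gaps survive a round trip.
#'
#' @param channel A [raw_channel()].
#' @param path Output file.
#' @export
write_channel <- function(channel, path) {
  stopifnot(inherits(channel, "raw_channel"))
  keep <- !is.na(channel$values)
  ts <- channel$t0 + (which(keep) - 1L) / channel$sample_rate
  utils::write.csv(
    data.frame(timestamp = sprintf("%.6f", ts),
               value = sprintf("%.10g", channel$values[keep])),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

esm_required_cols <- c("timestamp", panas_items, "valence", "arousal")

#' Read an ESM questionnaire table
#'
#' Expects one row per prompt with a timestamp, the ten PANAS items (matched
#' by name, case-insensitively, in any column order), and valence / arousal
#' ratings. Rows with any rating outside 1..5 are rejected, not silently
#' clipped; the rejects are tabulated in the attached report.
#'
#' @param path CSV file.
#' @return A data frame (class `esm_responses`) with columns `subject_id`,
#'   `timestamp`, the ten items, `valence`, `arousal`; attribute `report` is a
#'   data frame of rejected rows (`row`, `reason`).
#' @export
read_esm <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(esm_required_cols, names(df))
  if (length(missing_cols)) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (!"subject_id" %in% names(df)) df$subject_id <- "unknown"

  rating_cols <- c(panas_items, "valence", "arousal")
  ok <- rep(TRUE, nrow(df))
  reason <- character(nrow(df))
  for (cn in rating_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- is.na(v) | v < 1 | v > 5 | v != floor(v)
    newly <- bad & ok
    reason[newly] <- sprintf("%s out of range [1,5]", cn)
    ok <- ok & !bad
    df[[cn]] <- v
  }
  report <- data.frame(row = which(!ok), reason = reason[!ok],
                       stringsAsFactors = FALSE)
  out <- df[ok, c("subject_id", "timestamp", panas_items, "valence", "arousal")]
  out$timestamp <- as.numeric(out$timestamp)
  for (cn in rating_cols) out[[cn]] <- as.integer(out[[cn]])
  rownames(out) <- NULL
  structure(out, report = report, class = c("esm_responses", "data.frame"))
}

#' Write an ESM table to CSV
#'
#' @param esm A data frame in the layout returned by [read_esm()].
#' @param path Output file.
#' @export
write_esm <- function(esm, path) {
  utils::write.csv(as.data.frame(esm)[, c("subject_id", "timestamp",
                                          panas_items, "valence", "arousal")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a processed-segment archive
#'
#' The archive is a versioned hierarchical container (one entry per segment:
#' the T x 3 matrix plus label and provenance attributes) serialised to a
#' single file. Matrices, labels, subject ids and provenance round-trip
#' bit-exactly. All segments in one archive must share the window length T and
#' the column order (HR, GSR, ACCEL).
#'
#' @param segments A list of `segment` objects (see [preprocess_subject()]).
#' @param path Archive file path.
#' @return `path`, invisibly; `read_segment_archive()` returns the segment
#'   list with archive metadata in attribute `meta`.
#' @export
write_segment_archive <- function(segments, path) {
  if (!length(segments)) stopf("refusing to write an empty archive")
  if (!all(vapply(segments, inherits, logical(1), "segment"))) {
    stopf("all elements must be segment objects")
  }
  dims <- vapply(segments, function(s) nrow(s$matrix), integer(1))
  if (length(unique(dims)) != 1L) {
    stopf("segments have mixed window lengths T: %s",
          paste(sort(unique(dims)), collapse = ", "))
  }
  cols <- vapply(segments, function(s) paste(colnames(s$matrix), collapse = ","),
                 character(1))
  if (length(unique(cols)) != 1L) stopf("segments have inconsistent column order")
  saveRDS(list(format = "affectr_segment_archive", version = 1L,
               n = length(segments), T = dims[[1L]], segments = segments),
          path)
  invisible(path)
}

#' @rdname write_segment_archive
#' @export
read_segment_archive <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "affectr_segment_archive")) {
    stopf("%s is not a segment archive", path)
  }
  structure(obj$segments, meta = obj[c("version", "n", "T")])
}
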