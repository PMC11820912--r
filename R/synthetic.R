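# Synthetic multi-day recordings with ESM prompts and controllable
# class-dependent structure. The generative model is deliberately simple and
# fully specified (piecewise-stationary Gaussian / Poisson components with a
# binary latent affect state per prompt) so every downstream module can be
# exercised against known ground truth without any external data.

#' Simulation configuration
#'
#' Defaults emulate the recording structure of the multi-day ambulatory
#' study the pipeline targets: 88 subjects, 5 consecutive days of continuous
#' wrist recording (HR 1 Hz, GSR 40 Hz, tri-axial ACCEL 20 Hz), several ESM
#' prompts per day at random times. Effect sizes control how strongly the
#' per-prompt latent affect state (positive vs negative, Bernoulli
#' `state_prior`) shows in the signals during the pre-prompt window.
#'
#' @param n_subjects,n_days,esm_per_day Study shape.
#' @param day_seconds Continuous recording seconds per day.
#' @param esm_margin_s Minimum seconds between recording start (and between
#'   prompts) so each prompt has a clean pre-prompt window; also the span of
#'   the state-dependent effect before each prompt.
#' @param hr_baseline,hr_shift,hr_sigma,hr_drift_sd HR (bpm): baseline,
#'   additive shift in the positive state, white noise SD, slow random-walk
#'   drift increment SD.
#' @param gsr_tonic,gsr_event_rate,gsr_event_rate_ratio,gsr_event_amp,gsr_tau,gsr_sigma
#'   GSR (microsiemens): tonic level; phasic-event Poisson rate per minute in
#'   the negative state; positive/negative rate ratio; event amplitude;
#'   exponential decay constant (s); measurement noise SD.
#' @param accel_sigma,accel_var_ratio ACCEL (g): activity SD; positive/
#'   negative variance ratio of the shared activity latent.
#' @param artifact_rate,artifact_amp Single-sample spike artifacts per hour
#'   per channel, and their amplitude in channel-SD units.
#' @param state_prior P(positive affect) per prompt.
#' @param valence_probs,arousal_probs 2 x 5 matrices of state-conditional
#'   rating distributions (rows: negative, positive state).
#' @param panas_item_probs 2 x 5 matrix: rating distribution of state-
#'   congruent items (row 2) and state-incongruent items (row 1).
#' @param seed Base seed; each subject derives its own stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 88L, n_days = 5L, esm_per_day = 8L,
                       day_seconds = 86400, esm_margin_s = 1800,
                       hr_baseline = 65, hr_shift = 8, hr_sigma = 2,
                       hr_drift_sd = 0.02,
                       gsr_tonic = 2, gsr_event_rate = 1,
                       gsr_event_rate_ratio = 3, gsr_event_amp = 0.5,
                       gsr_tau = 3, gsr_sigma = 0.05,
                       accel_sigma = 0.05, accel_var_ratio = 2,
                       artifact_rate = 12, artifact_amp = 8,
                       state_prior = 0.5,
                       valence_probs = rbind(neg = c(0.15, 0.70, 0.10, 0.04, 0.01),
                                             pos = c(0.01, 0.04, 0.10, 0.70, 0.15)),
                       arousal_probs = rbind(neg = c(0.10, 0.70, 0.13, 0.05, 0.02),
                                             pos = c(0.02, 0.05, 0.13, 0.70, 0.10)),
                       panas_item_probs = rbind(low = c(0.50, 0.30, 0.15, 0.04, 0.01),
                                                high = c(0.02, 0.08, 0.20, 0.40, 0.30)),
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_days >= 1, esm_per_day >= 1,
            gsr_event_rate >= 0, gsr_event_rate_ratio > 0,
            accel_var_ratio > 0, artifact_rate >= 0,
            state_prior >= 0, state_prior <= 1,
            day_seconds / esm_per_day > esm_margin_s)
  structure(as.list(environment()), class = "sim_config")
}

sample_rating <- function(n, probs) {
  sample.int(5L, n, replace = TRUE, prob = probs)
}

# Piecewise state mask at a given rate: 1 inside the pre-prompt effect window
# of positive-state prompts, 0 elsewhere.
state_mask <- function(n, rate, esm_times, states, margin, t0) {
  mask <- numeric(n)
  for (k in which(states == 1L)) {
    i0 <- max(1L, floor((esm_times[k] - margin - t0) * rate) + 1L)
    i1 <- min(n, ceiling((esm_times[k] - t0) * rate))
    if (i1 >= i0) mask[i0:i1] <- 1
  }
  mask
}

add_spikes <- function(x, rate_per_hour, amp_sd_units, sample_rate) {
  hours <- length(x) / sample_rate / 3600
  n_spk <- stats::rpois(1L, rate_per_hour * hours)
  if (n_spk > 0L) {
    at <- sample.int(length(x), min(n_spk, length(x)))
    x[at] <- x[at] + sample(c(-1, 1), length(at), replace = TRUE) *
      amp_sd_units * stats::sd(x)
  }
  x
}

#' Simulate one subject
#'
#' Generates the three raw channels and the ESM table for one subject under
#' a binary latent affect state per prompt:
#' * HR (1 Hz): baseline + slow random-walk drift + `hr_shift` inside
#'   positive-state pre-prompt windows + Gaussian noise.
#' * GSR (40 Hz): tonic level + exponentially decaying phasic events with
#'   Poisson arrivals whose rate is `gsr_event_rate` per minute in the
#'   negative state and `gsr_event_rate * gsr_event_rate_ratio` in positive
#'   windows + noise, quantised to 0.01 microsiemens.
#' * ACCEL (20 Hz, three axes): a shared smooth activity latent (so the
#'   magnitude is the informative summary) with state-dependent variance,
#'   plus gravity on the z axis and small per-axis noise.
#' * Single-sample spike artifacts on every channel at `artifact_rate` per
#'   hour.
#' * ESM items drawn from the state-conditional distributions: in the
#'   positive state the four positive-affect items are high and the six
#'   negative-affect items low (and conversely), valence and arousal from
#'   `valence_probs` / `arousal_probs`.
#'
#' @param cfg A [sim_config()].
#' @param subject_id Subject identifier (also selects the subject's seed
#'   stream).
#' @param subject_index Integer used to derive the per-subject seed.
#' @return List: `channels` (named list of [raw_channel()]: `hr`, `gsr`,
#'   `accel_x/y/z`), `esm` (data frame), `states` (latent 0/1 per prompt),
#'   `gsr_events` (ground-truth phasic event times, for calibration tests).
#' @export
simulate_subject <- function(cfg, subject_id, subject_index = 1L) {
  with_seed(cfg$seed + 1000L * subject_index, {
    total_s <- cfg$n_days * cfg$day_seconds
    t0 <- 1.7e9 + subject_index * 1e6
    n_esm_day <- cfg$esm_per_day

    # prompt times: one per equal slot of the day, jittered, each at least
    # esm_margin_s after the previous boundary
    esm_times <- numeric(0)
    for (d in seq_len(cfg$n_days)) {
      slot <- cfg$day_seconds / n_esm_day
      base <- t0 + (d - 1) * cfg$day_seconds + (seq_len(n_esm_day) - 1) * slot
      esm_times <- c(esm_times,
                     base + cfg$esm_margin_s +
                       stats::runif(n_esm_day) * (slot - cfg$esm_margin_s))
    }
    n_esm <- length(esm_times)
    states <- stats::rbinom(n_esm, 1L, cfg$state_prior)

    # HR at 1 Hz
    n_hr <- total_s
    drift <- cumsum(stats::rnorm(n_hr, 0, cfg$hr_drift_sd))
    hr_mask <- state_mask(n_hr, 1, esm_times, states, cfg$esm_margin_s, t0)
    hr <- cfg$hr_baseline + drift + cfg$hr_shift * hr_mask +
      stats::rnorm(n_hr, 0, cfg$hr_sigma)
    hr <- add_spikes(hr, cfg$artifact_rate, cfg$artifact_amp, 1)

    # GSR at 40 Hz: piecewise-rate Poisson phasic events over the recording
    n_gsr <- total_s * 40L
    gsr <- rep(cfg$gsr_tonic, n_gsr) +
      cumsum(stats::rnorm(n_gsr, 0, 0.0005))          # slow tonic drift
    gsr_mask <- state_mask(n_gsr, 40, esm_times, states, cfg$esm_margin_s, t0)
    rate_min <- cfg$gsr_event_rate *
      ifelse(gsr_mask > 0, cfg$gsr_event_rate_ratio, 1)
    # thin a homogeneous process at the max rate
    lam_max <- max(rate_min) / 60
    n_cand <- stats::rpois(1L, lam_max * total_s)
    event_times <- numeric(0)
    if (n_cand > 0L && lam_max > 0) {
      cand <- sort(stats::runif(n_cand, 0, total_s))
      ci <- pmin(n_gsr, floor(cand * 40) + 1L)
      keep <- stats::runif(n_cand) < (rate_min[ci] / 60) / lam_max
      kernel <- cfg$gsr_event_amp *
        exp(-(seq_len(ceiling(cfg$gsr_tau * 5 * 40)) - 1L) / (cfg$gsr_tau * 40))
      for (i0 in ci[keep]) {
        i1 <- min(n_gsr, i0 + length(kernel) - 1L)
        gsr[i0:i1] <- gsr[i0:i1] + kernel[seq_len(i1 - i0 + 1L)]
      }
      event_times <- t0 + cand[keep]
    }
    gsr <- gsr + stats::rnorm(n_gsr, 0, cfg$gsr_sigma)
    gsr <- add_spikes(gsr, cfg$artifact_rate, cfg$artifact_amp, 40)
    gsr <- pmax(round(gsr, 2), 0)                     # 0.01 microsiemens resolution

    # ACCEL at 20 Hz: shared AR(1) activity latent, state-scaled variance
    n_acc <- total_s * 20L
    acc_mask <- state_mask(n_acc, 20, esm_times, states, cfg$esm_margin_s, t0)
    sd_t <- cfg$accel_sigma * ifelse(acc_mask > 0, sqrt(cfg$accel_var_ratio), 1)
    innov <- stats::rnorm(n_acc, 0, sd_t)
    activity <- as.numeric(stats::filter(innov, 0.95, method = "recursive"))
    q <- 1 / 2048
    mk_axis <- function(load, gravity) {
      v <- gravity + load * activity + stats::rnorm(n_acc, 0, cfg$accel_sigma / 4)
      v <- add_spikes(v, cfg$artifact_rate, cfg$artifact_amp, 20)
      round(v / q) * q
    }
    ax <- mk_axis(0.6, 0); ay <- mk_axis(0.5, 0); az <- mk_axis(0.4, 1)

    items <- matrix(0L, n_esm, 10L, dimnames = list(NULL, panas_items))
    for (k in seq_len(n_esm)) {
      hi <- cfg$panas_item_probs["high", ]; lo <- cfg$panas_item_probs["low", ]
      if (states[k] == 1L) {
        items[k, panas_positive_items] <- sample_rating(4L, hi)
        items[k, panas_negative_items] <- sample_rating(6L, lo)
      } else {
        items[k, panas_positive_items] <- sample_rating(4L, lo)
        items[k, panas_negative_items] <- sample_rating(6L, hi)
      }
    }
    vrow <- ifelse(states == 1L, "pos", "neg")
    esm <- data.frame(subject_id = as.character(subject_id),
                      timestamp = esm_times)
    esm <- cbind(esm, as.data.frame(items))
    esm$valence <- vapply(vrow, function(r) sample_rating(1L, cfg$valence_probs[r, ]), integer(1))
    esm$arousal <- vapply(vrow, function(r) sample_rating(1L, cfg$arousal_probs[r, ]), integer(1))

    list(channels = list(
           hr = raw_channel(hr, "HR", 1, t0, subject_id),
           gsr = raw_channel(gsr, "GSR", 40, t0, subject_id),
           accel_x = raw_channel(ax, "ACCEL_X", 20, t0, subject_id),
           accel_y = raw_channel(ay, "ACCEL_Y", 20, t0, subject_id),
           accel_z = raw_channel(az, "ACCEL_Z", 20, t0, subject_id)),
         esm = esm, states = states, gsr_events = event_times)
  })
}

#' Simulate a whole study in memory
#'
#' @param cfg A [sim_config()].
#' @return List of [simulate_subject()] results, one per subject, ids
#'   `"s01"`, `"s02"`, ...
#' @export
simulate_study <- function(cfg) {
  ids <- sprintf("s%02d", seq_len(cfg$n_subjects))
  out <- lapply(seq_len(cfg$n_subjects), function(i) {
    simulate_subject(cfg, ids[i], i)
  })
  names(out) <- ids
  out
}

#' Simulate a study to disk
#'
#' Writes the on-disk layout the readers consume: one folder per subject
#' with `hr.csv`, `gsr.csv`, `accel_x/y/z.csv`, plus a combined top-level
#' `esm.csv`. Total prompt count is
#' `n_subjects * n_days * esm_per_day`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; attribute `states` holds the per-subject
#'   latent states.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(cfg)
  esm_all <- list()
  states <- list()
  for (sid in names(study)) {
    sd <- file.path(out_dir, sid)
    dir.create(sd, showWarnings = FALSE)
    ch <- study[[sid]]$channels
    write_channel(ch$hr, file.path(sd, "hr.csv"))
    write_channel(ch$gsr, file.path(sd, "gsr.csv"))
    write_channel(ch$accel_x, file.path(sd, "accel_x.csv"))
    write_channel(ch$accel_y, file.path(sd, "accel_y.csv"))
    write_channel(ch$accel_z, file.path(sd, "accel_z.csv"))
    esm_all[[sid]] <- study[[sid]]$esm
    states[[sid]] <- study[[sid]]$states
  }
  write_esm(do.call(rbind, esm_all), file.path(out_dir, "esm.csv"))
  invisible(structure(out_dir, states = states))
}
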