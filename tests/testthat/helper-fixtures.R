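# Shared builders for test fixtures. Everything is generated in code; no
# binary fixtures live in the repository.

# The study conditions used for end-to-end checks: 12 subjects, one
# (shortened) recording day, 10 prompts/day, 300-s pre-prompt windows, so a
# full simulate -> preprocess -> train -> evaluate cycle runs in seconds.
desk_sim_config <- function(seed, hr_shift = 8, gsr_event_rate_ratio = 3,
                            accel_var_ratio = 2, n_subjects = 12L,
                            esm_per_day = 10L, day_seconds = 7200) {
  sim_config(n_subjects = n_subjects, n_days = 1L, esm_per_day = esm_per_day,
             day_seconds = day_seconds, esm_margin_s = 300,
             hr_shift = hr_shift, gsr_event_rate_ratio = gsr_event_rate_ratio,
             accel_var_ratio = accel_var_ratio, seed = seed)
}

desk_window_config <- function(...) preprocess_config(window_s = 300L, ...)

# Compact classifier sized for the 300-s desk windows.
desk_model_config <- function(n_classes, ...) {
  model_config(n_classes = n_classes, d_e = 8L, cnn_hidden = 16L,
               d_model = 32L, n_layers = 1L, n_heads = 4L, ffn_dim = 64L,
               dropout = 0.2, ...)
}

desk_train_config <- function(seed, ...) {
  train_config(batch_size = 16L, max_epochs = 100L, patience = 10L,
               seed = seed, ...)
}

# Simulate + preprocess the desk-scale study once.
desk_segments <- function(seed, ...) {
  preprocess_study(simulate_study(desk_sim_config(seed, ...)),
                   desk_window_config())$segments
}

# Hand-built labelled segments with a planted per-class mean shift on chosen
# columns; bypasses the generator/preprocessor for fast model-level tests.
toy_segments <- function(n_subjects = 6L, per_subject = 6L, T = 40L,
                         shift = 2, channels = "HR", n_classes = 2L,
                         seed = 1L) {
  set.seed(seed)
  segs <- list()
  for (s in seq_len(n_subjects)) {
    for (k in seq_len(per_subject)) {
      cls <- 1L + (length(segs) %% n_classes)
      m <- matrix(rnorm(T * 3), T, 3, dimnames = list(NULL, c("HR", "GSR", "ACCEL")))
      m[, channels] <- m[, channels] + shift * (cls - 1L)
      labels <- data.frame(panas_pos = 10L, panas_neg = 10L,
                           panas_class = cls - 1L,
                           valence_class = cls, arousal_class = cls,
                           valence_binary = cls - 1L, arousal_binary = cls - 1L)
      segs[[length(segs) + 1L]] <- segment(m, sprintf("t%02d", s),
                                           1e9 + length(segs) * 1000,
                                           labels = labels)
    }
  }
  segs
}

# Micro model/training configs for protocol-level tests where learning speed
# does not matter.
micro_model_config <- function(n_classes, n_layers = 1L, dropout = 0, ...) {
  model_config(n_classes = n_classes, d_e = 4L, cnn_hidden = 8L, d_model = 16L,
               n_layers = n_layers, n_heads = 2L, ffn_dim = 32L,
               dropout = dropout, ...)
}

micro_train_config <- function(seed = 1L, max_epochs = 3L, ...) {
  train_config(batch_size = 8L, max_epochs = max_epochs,
               patience = max(1L, max_epochs - 1L), seed = seed, ...)
}

# One-row ESM response as a named list.
esm_row <- function(items, valence = 3L, arousal = 3L) {
  stopifnot(length(items) == 10L)
  out <- as.list(items)
  names(out) <- affectr::panas_items
  c(out, list(valence = valence, arousal = arousal))
}
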