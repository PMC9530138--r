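# Shared fixtures: small simulation configs and a compact CNN sized for
# desk-scale test runs.

noiseless_config <- function(n_classes = 5, reps = 20, seed = 3) {
  sim_config(n_classes = n_classes, reps_per_class = reps, n_subjects = 1,
             noise_sd = 0, time_jitter_sd = 0, amp_jitter_sd = 0,
             drift_amplitude = 0, subject_amp_sd = 0, subject_shift_sd = 0,
             seed = seed)
}

noisy_config <- function(n_classes = 5, reps = 10, subjects = 1, seed = 3,
                         noise_sd = 0.05) {
  sim_config(n_classes = n_classes, reps_per_class = reps,
             n_subjects = subjects, noise_sd = noise_sd,
             time_jitter_sd = 0.02, amp_jitter_sd = 0.05,
             drift_amplitude = 0.02, subject_amp_sd = 0.1,
             subject_shift_sd = 0.02, seed = seed)
}

small_conv_spec <- function() {
  conv_spec(out_channels = c(4, 8, 8, 8, 8, 16, 16), fc_hidden = c(64, 32))
}

tiny_conv_spec <- function() {
  conv_spec(out_channels = c(2, 2, 2, 2, 2, 3, 3), fc_hidden = c(8, 6))
}

# Independent Savitzky-Golay oracle: solve the centered least-squares
# polynomial fit explicitly and read off the fitted value at the center.
savgol_oracle_weights <- function(window, polyorder) {
  h <- (window - 1) / 2
  A <- outer(-h:h, 0:polyorder, "^")
  proj <- A %*% solve(t(A) %*% A) %*% t(A)
  proj[h + 1, ]
}

record_labels <- function(records) {
  vapply(records, function(r) r$class_id, integer(1))
}
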