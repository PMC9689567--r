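# small, fast study configurations used across the unit tests
fast_config <- function(...) {
  synth_config(n_subjects = 4, n_lifts = 6, trial_duration_s = 90,
               fs = 64, ...)
}

# a feature table in the layout build_feature_table() produces, with
# arbitrary feature columns supplied as a named list of generators
make_feature_table <- function(n_subjects = 13, n_lifts = 20, features,
                               seed = 1) {
  set.seed(seed)
  grid <- expand.grid(lift_index = seq_len(n_lifts),
                      trial = c("NO_RISK", "RISK"),
                      subject = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  out <- tibble::tibble(subject = grid$subject, trial = grid$trial,
                        lift_index = grid$lift_index, label = grid$trial)
  for (f in names(features)) out[[f]] <- features[[f]](out)
  out
}

unit_sine <- function(freq, fs, dur) sin(2 * pi * freq * (0:(fs * dur - 1)) / fs)
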