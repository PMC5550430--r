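## Shared fixtures: one default geometry plus cheap builders used across files.

default_geom <- make_geometry()

## small movie from an explicit time x pixels matrix
matrix_movie <- function(X, nr, nc, frame_rate = 35, pitch = 0.05,
                         mask = NULL) {
  dff_movie(array(X, c(nrow(X), nr, nc)),
            (seq_len(nrow(X)) - 1) / frame_rate, pitch, mask = mask)
}

## one default-parameter interictal event movie
interictal_movie <- function(seed, noise_sd = NULL, jitter = FALSE,
                             defaults = generator_defaults()) {
  sc <- ictalwave:::single_event_script("interictal", defaults = defaults)
  render_event_movie(default_geom, sc, noise_sd = noise_sd,
                     jitter_focus = jitter, seed = seed)
}

## one default-parameter seizure movie long enough to cover the delay field
seizure_movie <- function(seed, duration_s = 8, noise_sd = NULL,
                          defaults = generator_defaults()) {
  sc <- ictalwave:::single_event_script("seizure", duration_s = duration_s,
                                        defaults = defaults)
  render_event_movie(default_geom, sc, duration_s = duration_s + 0.5,
                     noise_sd = noise_sd, seed = seed)
}
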