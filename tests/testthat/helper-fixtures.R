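# Shared fixture builders: tiny epoch sets constructed in code.

# A minimal eeg_epochs with hand-set data: trials x channels x timepoints.
make_epochs <- function(data, srate = 1000, t0 = -150, channels = NULL,
                        tasks = NULL, categories = NULL, veog_pair = NULL) {
  d <- dim(data)
  if (is.null(channels)) channels <- default_channels(d[2])
  times <- t0 + (seq_len(d[3]) - 1) * 1000 / srate
  labels <- data.frame(
    task = tasks %||% rep("basic", d[1]),
    category = categories %||% rep(c("bird", "nonbird_animal"), length.out = d[1]),
    stringsAsFactors = FALSE
  )
  eeg_epochs(data, times, srate, channels, labels, veog_pair)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random epochs for property checks.
random_epochs <- function(n = 20, ch = 4, nt = 30, srate = 100, seed = 1, ...) {
  set.seed(seed)
  make_epochs(array(rnorm(n * ch * nt), c(n, ch, nt)), srate = srate, ...)
}

# Small synthetic group dataset: per-participant bird/nonbird distance time
# courses from the generator, for group-level statistics.
tiny_design <- function(...) sim_design(n_trials = 120, channels = 16, srate = 100, ...)
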