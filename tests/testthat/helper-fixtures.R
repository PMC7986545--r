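# Shared fixtures: built in code, no files.

# protocol with a reduced tone grid for cheap unit tests
quick_protocol <- function(n_tones = 17L) {
  stim_protocol(tone_frequencies_hz = 140 * 2^seq(0, 8,
                                                  length.out = n_tones))
}

# a bare trial block from a list of spike-time vectors
block_of <- function(trains, t_start = 0, t_end = 1, onset = 0.2,
                     offset = 0.5, cid = "voc1_clean") {
  trial_block(cid, trains, t_start, t_end, onset, offset)
}

# n homogeneous-Poisson trains at `rate` Hz over [0, t_end]
poisson_trains <- function(n, rate, t_end = 1) {
  lapply(seq_len(n), function(i)
    sort(runif(rpois(1L, rate * t_end), 0, t_end)))
}

# small synthetic dataset shared by several test files (cached)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_dataset(generator_config(quick_protocol(),
                                              n_per_category = 2L,
                                              seed = 42L))
    cache
  }
})
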