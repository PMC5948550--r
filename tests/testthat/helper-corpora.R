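# Lazily built, memoized synthetic corpora and their pipeline scores, shared
# across test files to keep the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_default_corpus <- function() {
  memo("default_corpus", function() gen_corpus(default_corpus_mix(), seed = 11))
}

fixture_default_scores <- function() {
  memo("default_scores", function() {
    vapply(fixture_default_corpus()$recordings, score_recording, numeric(1))
  })
}

fixture_hard_corpus <- function() {
  memo("hard_corpus", function() gen_corpus(hard_corpus_mix(), seed = 11))
}

fixture_hard_scores <- function(veto) {
  key <- paste0("hard_scores_", veto)
  memo(key, function() {
    vapply(fixture_hard_corpus()$recordings, score_recording, numeric(1),
           config = detector_config(veto = veto))
  })
}

fixture_fall_run <- function() {
  memo("fall_run", function() {
    run_file(gen_recording(synth_spec("fall_forward", seed = 5)))
  })
}

fixture_jog_spike_run <- function() {
  memo("jog_spike_run", function() {
    pre <- synth_spec("jog", spike_amplitude_bits = 3000, seed = 5)
    run_file(gen_recording(pre))
  })
}
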