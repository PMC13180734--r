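# Shared fixtures, built lazily and cached for the whole test run.

# A small trained apnoea classifier (synthetic training windows).
get_test_classifier <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ts <- make_apnoea_training_set(15, seed = 101)
      cache <<- train_apnoea_classifier(ts$features, ts$labels, seed = 102)
    }
    cache
  }
})

# NRF basis on a light 250-Hz grid.
get_test_basis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_nrf_basis(fs = 250)
    cache
  }
})

# A noise-free breath train helper.
clean_ip <- function(duration_s, resp_rate = 60, apnoeas = apnoea_spec(),
                     shallow = NULL, seed = 1) {
  simulate_ip(duration_s, resp_rate, apnoeas = apnoeas,
              noise = ip_noise_spec(0, 0, 0, 0), shallow = shallow,
              seed = seed)
}

# Measure NRF slopes for one simulated occasion (reject + align + fit).
measure_slopes <- function(age, basis, seed, ...) {
  ev <- simulate_evoked(age, basis, seed = seed, ...)
  vis <- woody_align(reject_artifacts(ev$visual), basis = basis)
  tac <- woody_align(reject_artifacts(ev$tactile), basis = basis)
  fit_nrf_slopes(vis, tac, basis)
}
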