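# Shared fixture runs, built once per test session.

fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, seed = 1, noise_sd = 0) {
  key <- paste(name, seed, noise_sd, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fx <- make_fixture(name, seed = seed, noise_sd = noise_sd)
    res <- suppressWarnings(run_pipeline(fx$trials, fx$arena))
    fixture_cache[[key]] <- list(fx = fx, res = res)
  }
  fixture_cache[[key]]
}

# one scripted trial, reused across tests
scripted_trial <- function(casts, init_distance = -12, pre_bend = 0,
                           do_body_turn = TRUE, noise_sd = 0, seed = 7,
                           angle = 0.9) {
  arena <- light_spot(center = c(300, 300), radius = 119.4)
  ts <- turn_script(init_distance = init_distance, casts = casts,
                    do_body_turn = do_body_turn, pre_bend = pre_bend)
  sim <- with_test_seed(seed,
    simulate_trial(list(ts), arena, approach_angle = angle,
                   noise_sd = noise_sd, trial_id = "s"))
  sim$arena <- arena
  sim
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
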