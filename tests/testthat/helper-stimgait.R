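# Shared fixtures built in code. Trials are cached per test session so
# several test files can reuse one kinematic/neural simulation.

the_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(the_cache[[key]])) the_cache[[key]] <- fn()
  the_cache[[key]]
}

test_subject <- function(offset = 0) {
  sub <- example_subjects()[[1]]
  sub$clock_offset_s <- offset
  sub
}

# one clean 12-stride trial with neural channels and a 3.2 s clock offset
test_trial_neural <- function() {
  cached("trial_neural", function() {
    sub <- test_subject(offset = 3.2)
    surf <- build_surface(sub, 1)
    simulate_trial(sub, surf, sub$clinical_setting, n_strides = 12,
                   seed = 3, neural = TRUE)
  })
}

# one clean kinematics-only 20-stride trial
test_trial_kin <- function() {
  cached("trial_kin", function() {
    sub <- test_subject()
    surf <- build_surface(sub, 1)
    simulate_trial(sub, surf, sub$clinical_setting, n_strides = 20,
                   seed = 2, neural = FALSE)
  })
}

# small kinematics-only cohort
test_cohort_kin <- function() {
  cached("cohort_kin", function() {
    cc <- cohort_config(n_visits = 2, n_settings = 4, n_strides = 12,
                        neural = FALSE)
    simulate_cohort(cc, seed = 5)
  })
}

# nearest-event time difference for each ground-truth event of one label
event_errors <- function(detected, truth, label) {
  td <- detected$time_s[detected$label == label]
  tt <- truth$time_s[truth$label == label]
  vapply(tt, function(t) min(abs(td - t)), numeric(1))
}
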