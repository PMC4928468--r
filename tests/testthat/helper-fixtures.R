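# shared fixtures: built in code, no stored data

default_ctx <- function() clamp_context(v = -70, erev = -16)

# a mid-range parameter set used across model tests
fix_params <- function(...) {
  args <- list(w = 1.3, tau_r = 0.2, tau_d = 8, beta = 0.7, alpha_f = 1.1,
               alpha_b = 0.08, geph = 1.4, phi = 0.9, h = 0.8, h1 = 0.6,
               c1 = 2, t0 = 0)
  args[names(list(...))] <- list(...)
  do.call(gephyrin_params, args)
}

# random valid parameter set away from the singularity guards
random_params <- function() {
  repeat {
    p <- list(w = runif(1, 0.2, 3), tau_r = runif(1, 0.05, 0.5),
              tau_d = runif(1, 3, 20), beta = runif(1, 0.3, 3),
              alpha_f = runif(1, 0.3, 3), alpha_b = runif(1, 0.02, 0.3),
              geph = runif(1, 0.3, 3), phi = runif(1, 0.2, 1.8),
              h = runif(1, 0.3, 3), h1 = runif(1, 0.3, 3),
              c1 = runif(1, 0.5, 2), t0 = runif(1, 0, 2))
    if (abs(1 - p$alpha_b * p$tau_d) > 0.05 &&
        abs(1 - p$alpha_b * p$tau_r) > 0.05)
      return(do.call(gephyrin_params, p))
  }
}

# noiseless raw trace holding one event with a known holding offset
fix_trace <- function(truth = fix_params(t0 = 20), ctx = default_ctx(),
                      sigma = 0, offset = -40, dt = 0.05,
                      duration = 80, seed = NULL) {
  generate_trace(truth, ctx, noise_model(sigma = sigma, offset = offset),
                 time_grid(dt, round(duration / dt)), seed = seed,
                 id = "fix")
}

# largest accepted event of a trace, or NULL
primary_event <- function(trace, ...) {
  acc <- Filter(function(e) e$status == "accepted",
                preprocess_trace(trace, ...))
  if (!length(acc)) return(NULL)
  acc[[which.max(vapply(acc, function(e) e$peak_amplitude, numeric(1)))]]
}

reduced_cfg <- function()
  parse_config(file = system.file("extdata", "gephyrin_reduced.cfg",
                                  package = "sipscfit"))

full_cfg <- function()
  parse_config(file = system.file("extdata", "gephyrin.cfg",
                                  package = "sipscfit"),
               constants = fit_model_gephyrin()$constants)
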