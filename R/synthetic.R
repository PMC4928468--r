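## Synthetic sIPSC data with known ground truth.

#' Pseudo-Voigt peak-amplitude profile
#'
#' A weighted sum of a Lorentzian and a Gaussian of common width, used to
#' describe the distribution of event peak amplitudes:
#' `f(x) = a * (c / (1 + ((x - x0)/b)^2) + (1 - c) * exp(-0.5 * ((x - x0)/b)^2))`.
#'
#' @param a Peak height.
#' @param b Width (pA).
#' @param c Lorentzian fraction in `[0, 1]`.
#' @param x0 Mode location (pA).
#' @return An object of class `pseudo_voigt_params`.
#' @export
pseudo_voigt_params <- function(a, b, c, x0) {
  if (a <= 0 || b <= 0) stop("a and b must be > 0", call. = FALSE)
  if (c < 0 || c > 1) stop("c must be in [0, 1]", call. = FALSE)
  structure(list(a = a, b = b, c = c, x0 = x0),
            class = "pseudo_voigt_params")
}

#' @rdname pseudo_voigt_params
#' @param x Amplitudes (pA) at which to evaluate the profile.
#' @param p A `pseudo_voigt_params` object.
#' @export
pseudo_voigt <- function(x, p) {
  stopifnot(inherits(p, "pseudo_voigt_params"))
  u <- (x - p$x0) / p$b
  p$a * (p$c / (1 + u^2) + (1 - p$c) * exp(-0.5 * u^2))
}

#' Sample event peak amplitudes from a pseudo-Voigt profile
#'
#' Rejection sampling from the profile restricted (and renormalized) to
#' `range`.
#'
#' @param n Number of draws.
#' @param p A [pseudo_voigt_params()] object.
#' @param range Admissible amplitude interval (pA), positive width.
#' @param seed Optional seed for reproducible draws.
#' @return `n` amplitudes (pA).
#' @export
sample_peaks <- function(n, p, range = c(10, 100), seed = NULL) {
  stopifnot(inherits(p, "pseudo_voigt_params"))
  if (length(range) != 2 || !(range[1] < range[2]))
    stop("degenerate amplitude range", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # the profile is unimodal at x0: its maximum on [lo, hi] is at the point
  # closest to x0
  xm <- min(max(p$x0, range[1]), range[2])
  M <- pseudo_voigt(xm, p)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 100L)
    x <- stats::runif(m, range[1], range[2])
    u <- stats::runif(m, 0, M)
    out <- c(out, x[u <= pseudo_voigt(x, p)])
  }
  out[seq_len(n)]
}

#' Noise and artefact model for synthetic traces
#'
#' @param sigma White-noise SD (pA).
#' @param offset Holding/baseline current (pA), added to the whole trace.
#' @param drift Linear drift rate (pA/ms).
#' @param p_overlap Probability that a second event lands in the decay of
#'   the first.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 2, offset = -40, drift = 0, p_overlap = 0) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (p_overlap < 0 || p_overlap > 1)
    stop("p_overlap must be in [0, 1]", call. = FALSE)
  structure(list(sigma = sigma, offset = offset, drift = drift,
                 p_overlap = p_overlap), class = "noise_model")
}

#' Generate one synthetic sIPSC trace
#'
#' Analytic gephyrin-model current plus holding offset, linear drift and
#' Gaussian noise.  With probability `noise$p_overlap` a second event (same
#' kinetic parameters, amplitude rescaled by a uniform factor in
#' `[0.3, 1]`) is added at a uniform lag of 1-20 ms after the first peak.
#'
#' @param truth A [gephyrin_params()] ground-truth set.
#' @param ctx A [clamp_context()].
#' @param noise A [noise_model()].
#' @param grid A [time_grid()].
#' @param seed Optional seed (trace is bit-reproducible given it).
#' @param id,experiment,cell Metadata for the resulting trace.
#' @return A [raw_trace()] with attribute `"overlap"` (logical).
#' @export
generate_trace <- function(truth, ctx, noise, grid, seed = NULL,
                           id = NULL, experiment = NA_character_,
                           cell = NA_character_) {
  stopifnot(inherits(noise, "noise_model"), inherits(grid, "time_grid"))
  if (!is.null(seed)) set.seed(seed)
  tt <- grid_times(grid)
  cur <- eval_current_analytic(truth, ctx, tt)
  overlap <- FALSE
  if (noise$p_overlap > 0 && stats::runif(1) < noise$p_overlap) {
    overlap <- TRUE
    lag <- stats::runif(1, 1, 20)
    scale <- stats::runif(1, 0.3, 1)
    p2 <- truth
    p2$t0 <- truth$t0 + peak_time(truth) + lag
    p2$c1 <- truth$c1 * scale
    cur <- cur + eval_current_analytic(p2, ctx, tt)
  }
  x <- cur + noise$offset + noise$drift * tt
  if (noise$sigma > 0) x <- x + stats::rnorm(length(tt), 0, noise$sigma)
  out <- raw_trace(x, dt = grid$dt, experiment = experiment, cell = cell,
                   v_hold = ctx$v, id = id)
  attr(out, "overlap") <- overlap
  out
}

#' Specification of a synthetic dataset
#'
#' Defaults emulate the recordings the pipeline targets: 20 kHz-like
#' sampling (`dt` 0.05 ms) over 80 ms with a 20 ms pre-event baseline,
#' peak amplitudes 10-100 pA drawn from a pseudo-Voigt profile, rise time
#' constants 0.05-0.5 ms, decay 3-20 ms, white noise of 2 pA SD and a
#' uniform holding offset between -60 and -20 pA.
#'
#' @param n Number of traces.
#' @param amplitude Pseudo-Voigt profile of peak amplitudes
#'   ([pseudo_voigt_params()]).
#' @param amp_range Admissible amplitude interval (pA).
#' @param tau_r_range,tau_d_range,alpha_b_range,phi_range,geph_range,rate_range
#'   Uniform sampling intervals for the kinetic parameters (`rate_range`
#'   is shared by `beta`, `alpha_f`, `h`, `h1`).
#' @param t0_range Onset-time interval (ms into the trace).
#' @param sigma,offset_range,drift,p_overlap Noise model (per-trace offset
#'   drawn uniformly from `offset_range`).
#' @param dt,duration_ms Sampling interval and trace length (ms).
#' @param ctx A [clamp_context()].
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n = 50,
                       amplitude = pseudo_voigt_params(a = 0.2785,
                                                       b = 13.3410,
                                                       c = 0.4665,
                                                       x0 = 36.9253),
                       amp_range = c(10, 100),
                       tau_r_range = c(0.05, 0.5),
                       tau_d_range = c(3, 20),
                       alpha_b_range = c(0.02, 0.12),
                       phi_range = c(0.3, 1.7),
                       geph_range = c(0.5, 2),
                       rate_range = c(0.5, 2),
                       t0_range = c(20, 20.5),
                       sigma = 2, offset_range = c(-60, -20), drift = 0,
                       p_overlap = 0,
                       dt = 0.05, duration_ms = 80,
                       ctx = clamp_context()) {
  if (tau_r_range[2] >= tau_d_range[1])
    stop("tau_r range must lie below the tau_d range", call. = FALSE)
  structure(as.list(environment()), class = "synth_spec")
}

# sample one ground-truth parameter set; resamples until the closed-form
# singularity guards are comfortably satisfied
.sample_truth <- function(spec, target_peak) {
  ru <- function(r) stats::runif(1, r[1], r[2])
  for (i in 1:1000) {
    p <- list(w = 1, tau_r = ru(spec$tau_r_range),
              tau_d = ru(spec$tau_d_range), beta = ru(spec$rate_range),
              alpha_f = ru(spec$rate_range), alpha_b = ru(spec$alpha_b_range),
              geph = ru(spec$geph_range), phi = ru(spec$phi_range),
              h = ru(spec$rate_range), h1 = ru(spec$rate_range),
              c1 = 1, t0 = ru(spec$t0_range))
    if (abs(1 - p$alpha_b * p$tau_d) > 0.05 &&
        abs(1 - p$alpha_b * p$tau_r) > 0.05) break
  }
  truth <- do.call(gephyrin_params, p)
  # calibrate the amplitude through c1, leaving the kinetics untouched
  d <- steady_states(truth)
  tp <- peak_time(truth)
  shape_peak <- .current_shape(truth$alpha_b, truth$tau_r, truth$tau_d, tp)
  drive <- abs(spec$ctx$v - spec$ctx$erev)
  truth$c1 <- target_peak / (d$i_fact * shape_peak * drive)
  truth
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws peak amplitudes from the dataset spec's pseudo-Voigt profile, kinetic
#' parameters uniformly from their ranges, calibrates the amplitude of each
#' trace through the current scale `c1`, and synthesizes the traces with
#' noise, offset and (optionally) overlapping second events.  Regeneration
#' from the same `(spec, seed)` is bit-identical.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_dataset`: `traces` (list of
#'   [raw_trace()]), `truth` (data.frame of ground-truth parameters and
#'   noise settings per trace), `spec`, `seed`.
#' @export
generate_dataset <- function(spec = synth_spec(), seed = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n
  grid <- time_grid(spec$dt, round(spec$duration_ms / spec$dt))
  if (n == 0)
    return(structure(list(traces = list(),
                          truth = data.frame(), spec = spec, seed = seed),
                     class = "synthetic_dataset"))
  peaks <- sample_peaks(n, spec$amplitude, spec$amp_range,
                        seed = seed %% 2147483647)
  traces <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- (seed + i) %% 2147483647
    set.seed(si)
    truth <- .sample_truth(spec, peaks[i])
    offs <- stats::runif(1, spec$offset_range[1], spec$offset_range[2])
    nm <- noise_model(sigma = spec$sigma, offset = offs,
                      drift = spec$drift, p_overlap = spec$p_overlap)
    id <- sprintf("trace_%04d", i)
    tr <- generate_trace(truth, spec$ctx, nm, grid,
                         id = id, experiment = "synthA",
                         cell = sprintf("cell_%02d", 1 + (i - 1) %% 5))
    traces[[i]] <- tr
    truth_rows[[i]] <- data.frame(
      trace_id = id, target_peak = peaks[i],
      as.data.frame(truth[c("w", "tau_r", "tau_d", "beta", "alpha_f",
                            "alpha_b", "geph", "phi", "h", "h1", "c1",
                            "t0")]),
      i_fact = steady_states(truth)$i_fact,
      sigma = spec$sigma, offset = offs,
      overlap = attr(tr, "overlap"), seed = si,
      stringsAsFactors = FALSE)
  }
  structure(list(traces = traces, truth = do.call(rbind, truth_rows),
                 spec = spec, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d trace(s), seed %s\n",
              length(x$traces), format(x$seed)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' One trace CSV per event (the format [read_trace_csv()] reads) plus a
#' ground-truth manifest TSV.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in ds$traces)
    write_trace_csv(tr, file.path(dir, paste0(tr$meta$id, ".csv")))
  utils::write.table(ds$truth, file.path(dir, "truth_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
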