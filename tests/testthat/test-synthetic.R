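expC <- pseudo_voigt_params(a = 0.2785, b = 13.3410, c = 0.4665,
                            x0 = 36.9253)

test_that("pseudo-Voigt profile identities hold", {
  p <- pseudo_voigt_params(a = 2, b = 5, c = 0.3, x0 = 30)
  expect_equal(pseudo_voigt(30, p), 2)
  # pure Lorentzian: half height one width away from the mode
  pl <- pseudo_voigt_params(a = 2, b = 5, c = 1, x0 = 30)
  expect_equal(pseudo_voigt(c(25, 35), pl), c(1, 1))
  # pure Gaussian: a * exp(-1/2) one width away
  pg <- pseudo_voigt_params(a = 2, b = 5, c = 0, x0 = 30)
  expect_equal(pseudo_voigt(35, pg), 2 * exp(-0.5))
  # symmetry about the mode
  x <- seq(0, 25, by = 0.5)
  expect_equal(pseudo_voigt(30 + x, p), pseudo_voigt(30 - x, p))
  expect_error(pseudo_voigt_params(a = -1, b = 5, c = 0, x0 = 0), "a and b")
  expect_error(pseudo_voigt_params(a = 1, b = 5, c = 2, x0 = 0), "c must")
})

test_that("peak sampling reproduces the target distribution", {
  x <- sample_peaks(1e5, expC, range = c(10, 100), seed = 8)
  expect_identical(x, sample_peaks(1e5, expC, range = c(10, 100), seed = 8))
  expect_true(all(x >= 10 & x <= 100))
  # sample mode within ~1 pA of the profile mode
  h <- hist(x, breaks = seq(10, 100, by = 1), plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - 36.9253), 1.5)
  # chi-square goodness of fit against the normalized density
  y <- sample_peaks(1e4, expC, range = c(10, 100), seed = 9)
  breaks <- seq(10, 100, by = 5)
  obs <- hist(y, breaks = breaks, plot = FALSE)$counts
  dens <- function(u) pseudo_voigt(u, expC)
  Z <- stats::integrate(dens, 10, 100)$value
  expt <- vapply(seq_len(length(breaks) - 1), function(i)
    stats::integrate(dens, breaks[i], breaks[i + 1])$value / Z,
    numeric(1)) * 1e4
  keep <- expt >= 5
  chi2 <- sum((obs[keep] - expt[keep])^2 / expt[keep])
  expect_gt(stats::pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE),
            0.01)
  expect_error(sample_peaks(10, expC, range = c(50, 50)), "degenerate")
})

test_that("restricted amplitude mass matches the profile", {
  # fraction of sampled peaks in 20-30 pA vs the implied profile mass
  x <- sample_peaks(2e4, expC, range = c(10, 100), seed = 10)
  dens <- function(u) pseudo_voigt(u, expC)
  implied <- stats::integrate(dens, 20, 30)$value /
    stats::integrate(dens, 10, 100)$value
  expect_equal(mean(x >= 20 & x <= 30), implied, tolerance = 0.02)
})

test_that("generated traces are exact and reproducible", {
  truth <- fix_params(t0 = 20)
  ctx <- default_ctx()
  grid <- time_grid(0.05, 1600)
  clean <- generate_trace(truth, ctx, noise_model(sigma = 0, offset = 0),
                          grid)
  expect_identical(clean$samples,
                   eval_current_analytic(truth, ctx, grid_times(grid)))
  # peak magnitude ties out with the amplitude factor and peak time
  d <- steady_states(truth)
  shp <- abs(eval_current_analytic(truth, ctx,
                                   truth$t0 + peak_time(truth)))
  expect_equal(max(abs(clean$samples)), shp, tolerance = 1e-3)
  n1 <- generate_trace(truth, ctx, noise_model(sigma = 2, offset = -40,
                                               p_overlap = 0.5),
                       grid, seed = 4)
  n2 <- generate_trace(truth, ctx, noise_model(sigma = 2, offset = -40,
                                               p_overlap = 0.5),
                       grid, seed = 4)
  expect_identical(n1$samples, n2$samples)
  expect_identical(attr(n1, "overlap"), attr(n2, "overlap"))
})

test_that("dataset generation respects its spec and calibrates amplitudes", {
  expect_length(generate_dataset(synth_spec(n = 0), seed = 1)$traces, 0)
  spec <- synth_spec(n = 30, sigma = 0)
  ds <- generate_dataset(spec, seed = 5)
  expect_true(all(ds$truth$tau_r >= 0.05 & ds$truth$tau_r <= 0.5))
  expect_true(all(ds$truth$tau_d >= 3 & ds$truth$tau_d <= 20))
  expect_true(all(ds$truth$phi < 2))
  # bit-identical regeneration
  ds2 <- generate_dataset(spec, seed = 5)
  expect_identical(ds$truth, ds2$truth)
  expect_identical(ds$traces[[7]]$samples, ds2$traces[[7]]$samples)
  # amplitude calibration: noiseless measured peak equals the target
  for (i in c(1, 11, 25)) {
    peak <- max(abs(ds$traces[[i]]$samples - ds$truth$offset[i]))
    expect_equal(peak, ds$truth$target_peak[i], tolerance = 1e-3)
  }
  # the preprocessed peak agrees within one grid step's current change
  ev <- primary_event(ds$traces[[1]])
  expect_equal(ev$peak_amplitude, ds$truth$target_peak[1],
               tolerance = 0.01)
  expect_error(synth_spec(tau_r_range = c(0.05, 5)), "tau_r")
})

test_that("datasets round-trip through the trace file format", {
  ds <- generate_dataset(synth_spec(n = 3), seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "truth_manifest.tsv")))
  back <- read_trace_csv(file.path(dir, "trace_0002.csv"))
  expect_equal(back$samples, ds$traces[[2]]$samples, tolerance = 1e-12)
  expect_identical(back$meta$id, "trace_0002")
})
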