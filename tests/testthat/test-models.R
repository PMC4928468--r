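test_that("conductance pulse vanishes at onset and at infinity", {
  p <- fix_params(w = 1, tau_r = 1, tau_d = 2)
  expect_equal(eval_g(p, 0), 0)
  expect_lt(abs(eval_g(p, 1e5)), 1e-12)
  # direct scalar substitution: t' = 2 ln 2 gives exp terms 1/2 and 1/4
  expect_equal(eval_g(p, 2 * log(2)), 0.25, tolerance = 1e-12)
  expect_true(all(eval_g(fix_params(t0 = 5), c(0, 2, 4.99)) == 0))
})

test_that("parameter validation rejects invalid regions", {
  expect_error(gephyrin_params(tau_r = 8, tau_d = 2), "tau_r")
  expect_error(gephyrin_params(phi = 2), "phi")
  expect_error(gephyrin_params(w = -1), "positive")
  expect_error(gephyrin_params(alpha_b = 1 / 8, tau_d = 8), "singular")
  expect_error(gephyrin_params(t0 = -1), "t0")
})

test_that("steady states follow from the kinetic scheme", {
  # dNLG2/dt = 0 solved by hand: GEPH = 2, phi = 1 -> NLG2 = 1
  d <- steady_states(fix_params(geph = 2, phi = 1))
  expect_equal(d$nlg2_ss, 1)
  expect_equal(d$nlmax, 2)
  expect_equal(d$nhalf, 1)
  # unit parameters: amplitude factor = (2 - 1) / 2
  d1 <- steady_states(gephyrin_params(w = 1, tau_r = 0.2, tau_d = 8,
                                      beta = 1, alpha_f = 1, alpha_b = 0.3,
                                      geph = 1, phi = 1, h = 1, h1 = 1,
                                      c1 = 1))
  expect_equal(d1$i_fact, 0.5)
  expect_equal(steady_states(fix_params())$ry_ss,
               (0.8 / 0.6) * 1.4)
  # the steady state is a fixed point of the NLG2 equation
  p <- fix_params()
  d2 <- steady_states(p)
  expect_equal(d2$nlmax / (1 + d2$nhalf / d2$nlg2_ss) - p$phi * d2$nlg2_ss,
               0, tolerance = 1e-12)
  expect_error(steady_states(fix_params(phi = 2)), "phi")
})

test_that("closed-form current starts at zero, decays, and is inward", {
  p <- fix_params()
  ctx <- default_ctx()
  tt <- seq(0, 200, by = 0.05)
  cur <- eval_current_analytic(p, ctx, tt)
  expect_equal(cur[1], 0)
  expect_lt(abs(cur[length(tt)]) / max(abs(cur)), 1e-3)
  # driving force negative -> inward current over the event body
  expect_lt(min(cur), 0)
  expect_lt(cur[which.max(abs(cur))], 0)
})

test_that("current scaling laws hold at machine precision", {
  ctx <- default_ctx()
  tt <- seq(0, 60, by = 0.1)
  base <- eval_current_analytic(fix_params(), ctx, tt)
  # quadratic in the gephyrin level
  x4 <- eval_current_analytic(fix_params(geph = 2.8), ctx, tt)
  expect_equal(x4, 4 * base, tolerance = 1e-12)
  # linear in w, beta, alpha_f, c1, h; inverse in h1
  for (nm in c("w", "beta", "alpha_f", "c1", "h")) {
    arg <- list(); arg[[nm]] <- unclass(fix_params())[[nm]] * 3
    expect_equal(do.call(fix_params, arg) |>
                   eval_current_analytic(ctx, tt),
                 3 * base, tolerance = 1e-12)
  }
  expect_equal(eval_current_analytic(fix_params(h1 = 1.2), ctx, tt),
               base / 2, tolerance = 1e-12)
  # hyperbolic dependence on the NLG2/NRXN turnover rate
  fac <- function(phi) (2 - phi) / (2 * phi)
  expect_equal(eval_current_analytic(fix_params(phi = 0.5), ctx, tt),
               base * fac(0.5) / fac(0.9), tolerance = 1e-12)
})

test_that("parameter sets sharing the identifiable combination are indistinguishable", {
  ctx <- default_ctx()
  tt <- seq(0, 60, by = 0.05)
  p1 <- fix_params()
  # rescale (h, h1) and (beta, alpha_f, w, c1) leaving i_fact unchanged
  p2 <- fix_params(h = 0.8 * 5, h1 = 0.6 * 5, beta = 0.7 * 2, c1 = 1)
  expect_equal(steady_states(p1)$i_fact, steady_states(p2)$i_fact)
  expect_identical(eval_current_analytic(p1, ctx, tt),
                   eval_current_analytic(p2, ctx, tt))
})

test_that("the current is exactly invariant under the decay-rate swap", {
  # swapping alpha_b <-> 1/tau_d rescales the shape by a constant the
  # amplitude absorbs: a two-fold orbit of indistinguishable parameters
  ctx <- default_ctx()
  tt <- seq(0, 80, by = 0.05)
  p <- fix_params(alpha_b = 0.09, tau_d = 14, tau_r = 0.3)
  mu <- (1 / p$tau_r - p$alpha_b) / (1 / p$tau_r - 1 / p$tau_d)
  psw <- fix_params(alpha_b = 1 / p$tau_d, tau_d = 1 / p$alpha_b,
                    tau_r = 0.3, c1 = p$c1 / mu)
  i1 <- eval_current_analytic(p, ctx, tt)
  i2 <- eval_current_analytic(psw, ctx, tt)
  expect_lt(max(abs(i1 - i2)) / max(abs(i1)), 1e-12)
  # canonicalization maps both branches to the same representative
  c1 <- canonicalize_decay(p$alpha_b, p$tau_r, p$tau_d, 1)
  c2 <- canonicalize_decay(1 / p$tau_d, p$tau_r, 1 / p$alpha_b, 1 / mu)
  expect_equal(c1$alpha_b, c2$alpha_b, tolerance = 1e-12)
  expect_equal(c1$tau_d, c2$tau_d, tolerance = 1e-12)
  expect_equal(c1$i_fact, c2$i_fact, tolerance = 1e-12)
  expect_lte(c1$alpha_b * c1$tau_d, 1)
})

test_that("analytic current agrees with the numerical ODE oracle", {
  set.seed(421)
  ctx <- default_ctx()
  grid <- time_grid(0.2, 301)
  for (i in 1:10) {
    p <- random_params()
    ia <- eval_current_analytic(p, ctx, grid_times(grid))
    io <- integrate_ode(p, ctx, grid)
    expect_lt(max(abs(ia - io)) / max(abs(ia)), 1e-6)
  }
})

test_that("bi-exponential current is peak-normalized", {
  ctx <- default_ctx()
  p <- biexp_params(tau1 = 1.6, tau2 = 7.7, t_start = 0.2, weight = 1.2e-3)
  expect_equal(eval_biexp_current(p, ctx, 0.2), 0)
  tt <- seq(0, 60, by = 1e-3)
  g <- eval_biexp_current(p, ctx, tt) / (ctx$v - ctx$erev)
  tstar <- biexp_peak_time(1.6, 7.7)
  expect_equal(max(g), 1.2e-3, tolerance = 1e-6)
  expect_equal(tt[which.max(g)] - 0.2, tstar, tolerance = 2e-3)
  expect_error(biexp_params(tau1 = 3, tau2 = 2), "tau1")
})

test_that("peak time depends only on the shape parameters", {
  p <- fix_params()
  tp <- peak_time(p)
  # invariant under amplitude rescaling
  expect_equal(peak_time(fix_params(c1 = 40, geph = 0.5)), tp)
  # matches a dense-grid argmax
  tt <- seq(0, 40, by = 1e-3)
  cur <- eval_current_analytic(p, default_ctx(), tt)
  expect_equal(tp, tt[which.max(abs(cur))], tolerance = 2e-3)
  # monotone in tau_r with the other shape parameters fixed
  tps <- vapply(c(0.05, 0.1, 0.2, 0.35, 0.5),
                function(tr) peak_time(fix_params(tau_r = tr)), numeric(1))
  expect_true(all(diff(tps) > 0))
})

test_that("Nernst potential and chloride bookkeeping are correct", {
  expect_equal(nernst_potential(100, 100), 0)
  # sign flips with valence
  expect_equal(nernst_potential(140, 10, 32, z = 1),
               -nernst_potential(140, 10, 32, z = -1))
  expect_equal(solution_chloride(c(KCl = 70, MgCl2 = 1)), 72)
  expect_equal(solution_chloride(c(NaCl = 126, KCl = 2.5, CaCl2 = 2)),
               132.5)
  # chloride-free components contribute nothing
  expect_equal(solution_chloride(c(glucose = 10, KGluconate = 70)), 0)
})
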