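printed_cfg_path <- function()
  system.file("extdata", "biexp_printed.cfg", package = "sipscfit")

test_that("the printed double-exponential config parses verbatim", {
  cfg <- parse_config(file = printed_cfg_path())
  p <- cfg$params
  expect_equal(nrow(p), 4)
  expect_identical(p$name, c("syn[0].tau1", "syn[0].tau2", "nstim.start",
                             "nc[0].weight"))
  expect_equal(p$initial, c(1.6, 7.7, 0.2, 1.2e-3))
  expect_equal(p$lo, c(0, 2, 1e-5, 1e-5))
  expect_equal(p$hi, c(2, 10, 1e5, 1e5))
  expect_equal(nrow(cfg$dependencies), 0)
  expect_length(cfg$exclusions, 0)
  expect_length(cfg$warn_except, 0)
})

test_that("canonical serialization round-trips byte-identically", {
  cfg <- parse_config(file = printed_cfg_path())
  s1 <- serialize_config(cfg)
  s2 <- serialize_config(parse_config(s1))
  expect_identical(s1, s2)
  g <- full_cfg()
  expect_identical(serialize_config(g),
                   serialize_config(parse_config(
                     serialize_config(g),
                     constants = fit_model_gephyrin()$constants)))
})

test_that("malformed configs fail loudly with informative errors", {
  txt <- readLines(printed_cfg_path())
  # declared count 4 but only 3 parameter lines
  expect_error(parse_config(txt[-3]), "count mismatch")
  # bounds with lo >= hi
  bad <- sub("^0 2$", "3 2", txt)
  expect_error(parse_config(bad), "bound")
  # unresolvable name in an exclusion rule
  expect_error(parse_config(c(
    "//FITTING PARAMETERS AND INITIAL VALUES", "1", "0 x 1",
    "//CONSTRAINTS", "0 2",
    "//DEPENDENCY RULES FOR PARAMETERS NOT FITTED", "0",
    "//EXCLUSION RULES", "1", "nosuch < 1",
    "//PARAMETERS WARNING (ALL EXCEPT)", "0")), "unresolvable")
  # empty sections parse to empty lists
  empty <- c("//FITTING PARAMETERS AND INITIAL VALUES", "0",
             "//CONSTRAINTS",
             "//DEPENDENCY RULES FOR PARAMETERS NOT FITTED", "0",
             "//EXCLUSION RULES", "0",
             "//PARAMETERS WARNING (ALL EXCEPT)", "0")
  cfg <- parse_config(empty)
  expect_equal(nrow(cfg$params), 0)
})

test_that("exclusion rules evaluate arithmetic over bound names", {
  txt <- c("//FITTING PARAMETERS AND INITIAL VALUES", "2",
           "0 geph 1", "1 phi 1",
           "//CONSTRAINTS", "0.1 10", "0.1 3",
           "//DEPENDENCY RULES FOR PARAMETERS NOT FITTED", "1",
           "nhalf = geph/2",
           "//EXCLUSION RULES", "1",
           "geph < nhalf^*^phi",        # the printed typography for '*'
           "//PARAMETERS WARNING (ALL EXCEPT)", "0")
  cfg <- parse_config(txt)
  v3 <- apply_dependencies(cfg, list(geph = 1, phi = 3))
  expect_equal(v3$nhalf, 0.5)
  expect_true(eval_exclusion(cfg, v3))       # phi > 2: steady state invalid
  expect_false(eval_exclusion(cfg, apply_dependencies(
    cfg, list(geph = 1, phi = 1))))
  expect_error(eval_exclusion(cfg, list(geph = 1)), "unbound|phi")
  # no exclusion rules: never excluded
  expect_false(eval_exclusion(parse_config(file = printed_cfg_path()),
                              list()))
})

test_that("dependency rules apply in order and reject forward references", {
  cfg <- full_cfg()
  vals <- stats::setNames(as.list(cfg$params$initial), cfg$params$name)
  out <- apply_dependencies(cfg, vals)
  expect_equal(out[["syn[0].nhalf"]], out[["syn[0].geph"]] / 2)
  expect_equal(out[["syn[0].c1"]], 1)
  # dependency "nhalf = geph/2" with GEPH = 4
  vals[["syn[0].geph"]] <- 4
  expect_equal(apply_dependencies(cfg, vals)[["syn[0].nhalf"]], 2)
  # no dependencies: unchanged
  expect_identical(apply_dependencies(parse_config(file = printed_cfg_path()),
                                      list(a = 1)), list(a = 1))
  # forward reference is a dependency error
  fwd <- c("//FITTING PARAMETERS AND INITIAL VALUES", "1", "0 x 1",
           "//CONSTRAINTS", "0 2",
           "//DEPENDENCY RULES FOR PARAMETERS NOT FITTED", "2",
           "a = b", "b = x",
           "//EXCLUSION RULES", "0",
           "//PARAMETERS WARNING (ALL EXCEPT)", "0")
  expect_error(apply_dependencies(parse_config(fwd), list(x = 1)),
               "later")
})

test_that("the expression grammar is restricted", {
  expect_error(parse_config(c(
    "//FITTING PARAMETERS AND INITIAL VALUES", "1", "0 x 1",
    "//CONSTRAINTS", "0 2",
    "//DEPENDENCY RULES FOR PARAMETERS NOT FITTED", "1",
    "a = system('ls')",
    "//EXCLUSION RULES", "0",
    "//PARAMETERS WARNING (ALL EXCEPT)", "0")), "illegal|unresolvable")
})

test_that("swapping the config swaps the fitted model without code change", {
  ctx <- default_ctx()
  grid <- time_grid(0.05, 1600)
  # a bi-exponential event fitted with a biexp config (bounds bracketing
  # the truth) against the biexp model: only the config selects the model
  bp <- biexp_params(tau1 = 1.0, tau2 = 6, t_start = 22, weight = 0.9)
  cur <- eval_biexp_current(bp, ctx, grid_times(grid))
  tr <- raw_trace(cur - 40, dt = 0.05, id = "bix")
  ev <- primary_event(tr)
  cfg <- parse_config(c(
    "//FITTING PARAMETERS AND INITIAL VALUES", "4",
    "0 syn[0].tau1 1.6", "1 syn[0].tau2 7.7", "2 nstim.start 1",
    "3 nc[0].weight 0.5",
    "//CONSTRAINTS", "0.1 2", "2 10", "0 5", "0.01 5",
    "//DEPENDENCY RULES FOR PARAMETERS NOT FITTED", "0",
    "//EXCLUSION RULES", "0",
    "//PARAMETERS WARNING (ALL EXCEPT)", "0"))
  ens <- fit_trace(ev, cfg, fit_model_biexp(ctx), n_starts = 8,
                   max_eval = 2000, seed = 3)
  expect_identical(ens$status, "fitted")
  b <- best_fit(ens)
  expect_lt(b$rmse_frac, 0.01)
  expect_equal(b[["nc[0].weight"]], 0.9, tolerance = 0.05)
})
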