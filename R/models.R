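#' Voltage-clamp context
#'
#' Holding potential and synaptic reversal potential for a recording.  The
#' driving force `v - erev` converts the dimensionless gating variables of a
#' kinetic model into a current in pA.
#'
#' @param v Holding potential (mV).
#' @param erev Synaptic reversal potential (mV).  For GABA-A currents this is
#'   the chloride reversal potential, about -16 mV with a high-chloride
#'   pipette solution (see [nernst_potential()]).
#' @return An object of class `clamp_context`.
#' @examples
#' clamp_context(v = -70, erev = -16)
#' @export
clamp_context <- function(v = -70, erev = -16) {
  if (!is.finite(v) || !is.finite(erev))
    stop("holding and reversal potentials must be finite", call. = FALSE)
  if (v == erev)
    stop("driving force is zero: v == erev", call. = FALSE)
  structure(list(v = v, erev = erev), class = "clamp_context")
}

#' @export
print.clamp_context <- function(x, ...) {
  cat(sprintf("<clamp_context> v = %g mV, erev = %g mV (driving force %g mV)\n",
              x$v, x$erev, x$v - x$erev))
  invisible(x)
}

# guard for the removable singularities of the closed-form current
.sing_eps <- 1e-6

#' Parameters of the gephyrin-dependent transsynaptic model
#'
#' The kinetic scheme couples a conductance pulse `g(t)` to a transmitter
#' balance gated by the neuroligin-2/neurexin adhesion level (itself set by
#' the gephyrin cluster level `geph`) and to a receptor pool maintained by
#' insertion/removal rates `h`, `h1`.  Rates are per millisecond in
#' arbitrary units; `c1` carries the scaling to pA.
#'
#' @param w Peak synaptic conductance (arbitrary units).
#' @param tau_r,tau_d Rise and decay time constants of the conductance pulse
#'   (ms); `tau_r < tau_d` is required.
#' @param beta,alpha_f Forward transmitter-drive rates (1/ms).
#' @param alpha_b Transmitter clearance rate from the cleft (1/ms).
#' @param geph Gephyrin cluster level (arbitrary units).
#' @param phi Neuroligin-2/neurexin turnover rate (1/ms); must be below 2 or
#'   the steady-state adhesion level is non-positive.
#' @param h,h1 Receptor insertion and removal rates (1/ms).
#' @param c1 Current scale constant (maps arbitrary units to pA).
#' @param t0 Synaptic activation (onset) time (ms), non-negative.
#' @return An object of class `gephyrin_params`.
#' @seealso [steady_states()], [eval_current_analytic()]
#' @export
gephyrin_params <- function(w = 1, tau_r = 0.2, tau_d = 8, beta = 1,
                            alpha_f = 1, alpha_b = 0.1, geph = 1, phi = 1,
                            h = 1, h1 = 1, c1 = 1, t0 = 0) {
  p <- structure(list(w = w, tau_r = tau_r, tau_d = tau_d, beta = beta,
                      alpha_f = alpha_f, alpha_b = alpha_b, geph = geph,
                      phi = phi, h = h, h1 = h1, c1 = c1, t0 = t0),
                 class = "gephyrin_params")
  validate_gephyrin_params(p)
  p
}

#' Validate gephyrin-model parameters
#'
#' Checks positivity, `tau_r < tau_d`, `phi < 2`, and the singularity guards
#' `|1 - alpha_b * tau| > 1e-6` for both time constants (removable
#' singularities of the closed-form current).
#'
#' @param p A `gephyrin_params` object or a named list with the same fields.
#' @return `p`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_gephyrin_params <- function(p) {
  pos <- c("w", "tau_r", "tau_d", "beta", "alpha_f", "alpha_b", "geph",
           "phi", "h", "h1", "c1")
  vals <- unlist(p[c(pos, "t0")], use.names = TRUE)
  if (any(!is.finite(vals)))
    stop("gephyrin parameters must be finite", call. = FALSE)
  bad <- pos[unlist(p[pos]) <= 0]
  if (length(bad))
    stop("gephyrin parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (p$t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  if (p$tau_r >= p$tau_d)
    stop("tau_r must be smaller than tau_d", call. = FALSE)
  if (p$phi >= 2)
    stop("phi >= 2: steady-state NLG2 level would be non-positive ",
         "(excluded-parameter region)", call. = FALSE)
  if (abs(1 - p$alpha_b * p$tau_d) < .sing_eps ||
      abs(1 - p$alpha_b * p$tau_r) < .sing_eps)
    stop("singular parameters: |1 - alpha_b * tau| below guard", call. = FALSE)
  invisible(p)
}

#' Conductance pulse of the synaptic event
#'
#' `g(t) = w * (exp(-(t - t0)/tau_d) - exp(-(t - t0)/tau_r))` for
#' `t >= t0`, zero before onset.
#'
#' @param p A [gephyrin_params()] object.
#' @param t Time points (ms).
#' @return Conductance values (arbitrary units), same length as `t`.
#' @export
eval_g <- function(p, t) {
  validate_gephyrin_params(p)
  tp <- t - p$t0
  g <- ifelse(tp >= 0, p$w * (exp(-tp / p$tau_d) - exp(-tp / p$tau_r)), 0)
  as.numeric(g)
}

#' Steady states and the amplitude factor of the gephyrin model
#'
#' With the gephyrin cluster level held constant during an event, the
#' adhesion level and receptor pool settle at
#' `NLG2_ss = geph * (2 - phi) / (2 * phi)` and `Ry_ss = (h / h1) * geph`.
#' The time-independent amplitude factor of the closed-form current is
#' `i_fact = c1 * (h / h1) * NLG2_ss * geph * beta * alpha_f * w`, which is
#' quadratic in `geph` and hyperbolic in `phi`.
#'
#' @param p A [gephyrin_params()] object.
#' @return A list of class `derived_synapse` with fields `nlmax`, `nhalf`,
#'   `nlg2_ss`, `ry_ss`, `i_fact`.
#' @export
steady_states <- function(p) {
  validate_gephyrin_params(p)
  nlg2 <- p$geph * (2 - p$phi) / (2 * p$phi)
  ry <- (p$h / p$h1) * p$geph
  i_fact <- p$c1 * (p$h / p$h1) * nlg2 * p$geph * p$beta * p$alpha_f * p$w
  structure(list(nlmax = p$geph, nhalf = p$geph / 2, nlg2_ss = nlg2,
                 ry_ss = ry, i_fact = i_fact),
            class = "derived_synapse")
}

# shape factor of the closed-form current: the time course shared by all
# parameter sets with equal (alpha_b, tau_r, tau_d); zero before onset.
# This is N(t) / (beta * alpha_f * NLG2_ss * w) with N(0) = 0: rise
# governed by tau_r, main decay by tau_d, and a late low-amplitude
# counter-lobe carried by exp(-alpha_b t) (beyond the 20%-of-peak clip
# point for the parameter ranges of interest).
.current_shape <- function(alpha_b, tau_r, tau_d, tp) {
  A <- 1 - alpha_b * tau_d
  B <- 1 - alpha_b * tau_r
  s <- ((A - B) * exp(-alpha_b * tp) + B * exp(-tp / tau_d) -
          A * exp(-tp / tau_r)) / (A * B)
  s[tp < 0] <- 0
  s
}

#' Closed-form synaptic current
#'
#' Evaluates the analytic solution of the gephyrin kinetic scheme with
#' initial transmitter level `N(0) = 0`:
#' `I(t) = i_fact * shape(t - t0) * (v - erev)` with
#' `shape(t) = (((1 - ab*td) - (1 - ab*tr)) * exp(-ab*t)
#'   + (1 - ab*tr) * exp(-t/td) - (1 - ab*td) * exp(-t/tr))
#'   / ((1 - ab*td) * (1 - ab*tr))`
#' (`ab = alpha_b`, `tr = tau_r`, `td = tau_d`; see [steady_states()] for
#' `i_fact`).  The shape depends only on `(alpha_b, tau_r, tau_d)`; all
#' remaining parameters enter through the amplitude factor — the model's
#' identifiable combination.  The rise is governed by `tau_r`, the main
#' decay by `tau_d`, and the transmitter-clearance term `exp(-alpha_b t)`
#' shapes the slow part of the decay.  With `v < erev` the current is
#' inward (negative); its magnitude is the event amplitude.
#'
#' @param p A [gephyrin_params()] object.
#' @param ctx A [clamp_context()].
#' @param t Time points (ms).
#' @return Current (pA), zero before `t0`.
#' @export
eval_current_analytic <- function(p, ctx, t) {
  validate_gephyrin_params(p)
  d <- steady_states(p)
  tp <- t - p$t0
  as.numeric(d$i_fact * .current_shape(p$alpha_b, p$tau_r, p$tau_d, tp) *
               (ctx$v - ctx$erev))
}

#' Uniform sampling grid
#'
#' @param dt Sampling interval (ms).
#' @param n Number of samples (>= 2).
#' @param origin Time of the first sample (ms).
#' @return A `time_grid` object; `grid_times()` materializes the time axis.
#' @export
time_grid <- function(dt, n, origin = 0) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  structure(list(dt = dt, n = as.integer(n), origin = origin),
            class = "time_grid")
}

#' @rdname time_grid
#' @param grid A `time_grid` object.
#' @export
grid_times <- function(grid) grid$origin + grid$dt * (seq_len(grid$n) - 1)

#' Numerically integrated synaptic current
#'
#' Integrates the full three-state system (transmitter `N`, adhesion level
#' `NLG2`, receptor pool `Ry`) with `NLG2` and `Ry` initialized at their
#' steady states and `N(0) = 0`, and returns
#' `I(t) = c1 * N * Ry * (v - erev)`.  The transmitter balance is
#' `dN/dt = beta * alpha_f * NLG2 * gdot(t) - alpha_b * N` with the
#' time-constant-normalized conductance pulse
#' `gdot(t) = w * (exp(-t'/tau_r)/tau_r - exp(-t'/tau_d)/tau_d)`, the
#' drive for which the closed-form current of [eval_current_analytic()]
#' is the exact solution; this routine is its independent numerical
#' check.
#'
#' @param p A [gephyrin_params()] object.
#' @param ctx A [clamp_context()].
#' @param grid A [time_grid()].
#' @param rtol,atol Integrator tolerances passed to [deSolve::ode()].
#' @return Current (pA) on the grid.
#' @export
integrate_ode <- function(p, ctx, grid, rtol = 1e-10, atol = 1e-12) {
  validate_gephyrin_params(p)
  d <- steady_states(p)
  tt <- grid_times(grid)
  # integrate from t0 (current is identically 0 before onset)
  rhs <- function(t, y, parms) {
    gdot <- p$w * (exp(-t / p$tau_r) / p$tau_r - exp(-t / p$tau_d) / p$tau_d)
    dN <- p$beta * p$alpha_f * gdot * y[["NLG2"]] - p$alpha_b * y[["N"]]
    dNLG2 <- d$nlmax / (1 + d$nhalf / y[["NLG2"]]) - p$phi * y[["NLG2"]]
    dRy <- p$h * p$geph - p$h1 * y[["Ry"]]
    list(c(dN, dNLG2, dRy))
  }
  tp <- tt - p$t0
  tpos <- tp[tp >= 0]
  cur <- numeric(length(tt))
  if (length(tpos)) {
    tode <- unique(c(0, tpos))
    sol <- tryCatch(
      deSolve::ode(c(N = 0, NLG2 = d$nlg2_ss, Ry = d$ry_ss), tode, rhs,
                   parms = NULL, rtol = rtol, atol = atol),
      warning = function(w) stop("ODE integration failed: ",
                                 conditionMessage(w), call. = FALSE))
    N <- sol[match(tpos, sol[, "time"]), "N"]
    Ry <- sol[match(tpos, sol[, "time"]), "Ry"]
    cur[tp >= 0] <- p$c1 * N * Ry * (ctx$v - ctx$erev)
  }
  cur
}

#' Parameters of the bi-exponential synaptic model
#'
#' The classic two-time-constant conductance, peak-normalized so the
#' conductance maximum equals `weight`.
#'
#' @param tau1,tau2 Rise and decay time constants (ms), `tau1 < tau2`.
#' @param t_start Activation time (ms).
#' @param weight Peak conductance scale.
#' @return An object of class `biexp_params`.
#' @export
biexp_params <- function(tau1 = 1.6, tau2 = 7.7, t_start = 0.2,
                         weight = 1.2e-3) {
  if (!all(is.finite(c(tau1, tau2, t_start, weight))))
    stop("bi-exponential parameters must be finite", call. = FALSE)
  if (tau1 <= 0 || tau1 >= tau2)
    stop("need 0 < tau1 < tau2", call. = FALSE)
  if (weight <= 0) stop("weight must be > 0", call. = FALSE)
  if (t_start < 0) stop("t_start must be >= 0", call. = FALSE)
  structure(list(tau1 = tau1, tau2 = tau2, t_start = t_start,
                 weight = weight), class = "biexp_params")
}

#' Time of the conductance peak of a double exponential
#'
#' `t* = log(tau2/tau1) * tau1 * tau2 / (tau2 - tau1)` after onset.
#'
#' @param tau1,tau2 Rise and decay time constants (ms).
#' @return Peak time after onset (ms).
#' @export
biexp_peak_time <- function(tau1, tau2) {
  log(tau2 / tau1) * tau1 * tau2 / (tau2 - tau1)
}

#' Bi-exponential synaptic current
#'
#' @param p A [biexp_params()] object.
#' @param ctx A [clamp_context()].
#' @param t Time points (ms).
#' @return Current (pA); the conductance peak equals `weight`.
#' @export
eval_biexp_current <- function(p, ctx, t) {
  stopifnot(inherits(p, "biexp_params"))
  tp <- t - p$t_start
  tstar <- biexp_peak_time(p$tau1, p$tau2)
  norm <- 1 / (exp(-tstar / p$tau2) - exp(-tstar / p$tau1))
  g <- ifelse(tp >= 0,
              norm * p$weight * (exp(-tp / p$tau2) - exp(-tp / p$tau1)), 0)
  as.numeric(g * (ctx$v - ctx$erev))
}

#' Time to peak of the gephyrin-model current
#'
#' Finds the maximum of the current magnitude after onset by bracketed
#' root-finding on the time derivative of the shape factor.  The peak time
#' depends only on `alpha_b`, `tau_r` and `tau_d`, not on the amplitude
#' factor.
#'
#' @param p A [gephyrin_params()] object.
#' @param tol Root-finding tolerance (ms).
#' @return Time from onset to the current peak (ms).
#' @export
peak_time <- function(p, tol = 1e-9) {
  validate_gephyrin_params(p)
  A <- 1 - p$alpha_b * p$tau_d
  B <- 1 - p$alpha_b * p$tau_r
  dshape <- function(tp)
    (-p$alpha_b * (A - B) * exp(-p$alpha_b * tp) -
       (B / p$tau_d) * exp(-tp / p$tau_d) +
       (A / p$tau_r) * exp(-tp / p$tau_r)) / (A * B)
  hi <- p$tau_r
  limit <- 1e4 * max(p$tau_d, 1 / p$alpha_b)
  while (dshape(hi) > 0 && hi < limit) hi <- hi * 2
  if (dshape(hi) > 0)
    stop("failed to bracket the current peak", call. = FALSE)
  stats::uniroot(dshape, lower = hi / 2, upper = hi, tol = tol)$root
}

#' Canonical representative of the decay-parameter orbit
#'
#' The closed-form current is exactly invariant under swapping the two
#' decay rates, `alpha_b <-> 1/tau_d`, combined with an amplitude
#' rescaling: `shape(1/tau_d, tau_r, 1/alpha_b) = mu * shape(alpha_b,
#' tau_r, tau_d)` with `mu = (1/tau_r - alpha_b) / (1/tau_r - 1/tau_d)`.
#' `(alpha_b, tau_d, i_fact)` is therefore identifiable only up to this
#' two-fold orbit; this helper maps a parameter set to the representative
#' with `alpha_b * tau_d <= 1` (clearance slower than conductance decay,
#' the regime in which `exp(-alpha_b t)` is the slow tail), which is the
#' form in which recovered and true parameters should be compared.
#'
#' @param alpha_b,tau_r,tau_d Decay-shape parameters (vectorized).
#' @param i_fact Amplitude factor (same length).
#' @return A data.frame with canonical `alpha_b`, `tau_d`, `i_fact`
#'   (`tau_r` is unchanged by the symmetry).
#' @export
canonicalize_decay <- function(alpha_b, tau_r, tau_d, i_fact) {
  swap <- alpha_b * tau_d > 1
  s <- 1 / tau_r
  mu <- (s - alpha_b) / (s - 1 / tau_d)
  data.frame(
    alpha_b = ifelse(swap, 1 / tau_d, alpha_b),
    tau_d = ifelse(swap, 1 / alpha_b, tau_d),
    i_fact = ifelse(swap, i_fact / mu, i_fact))
}

#' Nernst equilibrium potential
#'
#' `E = (R * T) / (z * F) * log(c_out / c_in)`, in mV.
#'
#' @param c_out,c_in Extracellular and intracellular concentrations (same
#'   units, typically mM).
#' @param temperature_c Temperature in degrees Celsius.
#' @param z Ionic valence (use `-1` for chloride).
#' @return Equilibrium potential (mV).
#' @examples
#' # chloride reversal with a high-chloride pipette at 32 C
#' nernst_potential(132.5, 72, temperature_c = 32, z = -1)
#' @export
nernst_potential <- function(c_out, c_in, temperature_c = 32, z = 1) {
  if (c_out <= 0 || c_in <= 0)
    stop("concentrations must be positive", call. = FALSE)
  R <- 8.31446261815324     # J / (mol K)
  Fd <- 96485.33212331      # C / mol
  Tk <- temperature_c + 273.15
  1000 * R * Tk / (z * Fd) * log(c_out / c_in)
}

#' Total chloride concentration of a salt solution
#'
#' Sums the chloride contributed by each salt (e.g. `MgCl2` contributes two
#' chloride ions per formula unit).  Salt names are matched
#' case-insensitively; salts without chloride contribute zero.
#'
#' @param salts Named numeric vector of salt concentrations (mM), e.g.
#'   `c(KCl = 70, MgCl2 = 1)`.
#' @return Total chloride concentration (mM).
#' @examples
#' solution_chloride(c(KCl = 70, MgCl2 = 1))                      # pipette
#' solution_chloride(c(NaCl = 126, KCl = 2.5, CaCl2 = 2))         # ACSF
#' @export
solution_chloride <- function(salts) {
  stoich <- c(nacl = 1, kcl = 1, mgcl2 = 2, cacl2 = 2, cholinecl = 1,
              choline = 0, hcl = 1, cscl = 1)
  nm <- tolower(gsub("[^A-Za-z0-9]", "", names(salts)))
  unknown <- setdiff(nm, names(stoich))
  k <- stoich[nm]
  k[is.na(k)] <- 0
  if (length(unknown))
    k[nm %in% unknown] <- 0  # chloride-free components (sugars, buffers...)
  sum(salts * k)
}

#' Total model evaluations implied by a fitting campaign
#'
#' The bookkeeping product traces x starts x average optimizer steps, i.e.
#' the number of independent model simulations a full run performs.
#'
#' @param n_traces Number of event traces.
#' @param n_starts Randomized initial conditions per trace.
#' @param avg_steps Average optimizer iteration steps per start.
#' @return Total model evaluations (numeric).
#' @examples
#' implied_evaluations(4712, 100, 2000)
#' @export
implied_evaluations <- function(n_traces, n_starts = 100, avg_steps = 2000) {
  as.numeric(n_traces) * n_starts * avg_steps
}
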