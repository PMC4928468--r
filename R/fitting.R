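## Multi-start fitting of preprocessed events against a configurable model.

#' Fittable model definitions
#'
#' A fit model bundles the canonical parameter list of a kinetic scheme, its
#' default values, the NEURON-style name aliases used by configuration
#' files, and the function evaluating the model current on a time grid.
#' `fit_model_gephyrin()` wraps the closed-form gephyrin-dependent current
#' ([eval_current_analytic()]); `fit_model_biexp()` wraps the built-in
#' bi-exponential scheme ([eval_biexp_current()]).  Swapping the model (and
#' its config file) is the only change needed to fit a different kinetic
#' scheme.
#'
#' @param ctx A [clamp_context()] used for the driving force.
#' @return A list of class `fit_model` with fields `name`, `defaults`,
#'   `aliases`, `constants` and `current(values, t)`.
#' @export
fit_model_gephyrin <- function(ctx = clamp_context()) {
  structure(list(
    name = "gephyrin",
    ctx = ctx,
    defaults = list(w = 1, tau_r = 0.2, tau_d = 8, beta = 1, alpha_f = 1,
                    alpha_b = 0.1, geph = 1, phi = 1, h = 1, h1 = 1,
                    c1 = 1, t0 = 0),
    aliases = c("syn[0].w" = "w", "syn[0].taur" = "tau_r",
                "syn[0].tau_r" = "tau_r", "syn[0].taud" = "tau_d",
                "syn[0].tau_d" = "tau_d", "syn[0].beta" = "beta",
                "syn[0].alphaf" = "alpha_f", "syn[0].alphab" = "alpha_b",
                "syn[0].geph" = "geph", "syn[0].phi" = "phi",
                "syn[0].h" = "h", "syn[0].h1" = "h1", "syn[0].c1" = "c1",
                "nstim.start" = "t0"),
    constants = c("syn[0].nhalf", "syn[0].nlmax", "nhalf", "nlmax"),
    current = function(values, t) {
      p <- do.call(gephyrin_params, values)
      eval_current_analytic(p, ctx, t)
    },
    # validation + closed form inlined for the optimizer's inner loop
    mag = function(v, t) {
      if (v$w <= 0 || v$tau_r <= 0 || v$beta <= 0 || v$alpha_f <= 0 ||
          v$alpha_b <= 0 || v$geph <= 0 || v$h <= 0 || v$h1 <= 0 ||
          v$c1 <= 0 || v$t0 < 0 || v$tau_r >= v$tau_d || v$phi <= 0 ||
          v$phi >= 2 || abs(1 - v$alpha_b * v$tau_d) < .sing_eps ||
          abs(1 - v$alpha_b * v$tau_r) < .sing_eps)
        return(NULL)
      nlg2 <- v$geph * (2 - v$phi) / (2 * v$phi)
      i_fact <- v$c1 * (v$h / v$h1) * nlg2 * v$geph * v$beta * v$alpha_f *
        v$w
      abs(i_fact * (ctx$v - ctx$erev)) *
        .current_shape(v$alpha_b, v$tau_r, v$tau_d, t - v$t0)
    }), class = "fit_model")
}

#' @rdname fit_model_gephyrin
#' @export
fit_model_biexp <- function(ctx = clamp_context()) {
  structure(list(
    name = "biexp",
    ctx = ctx,
    defaults = list(tau1 = 1.6, tau2 = 7.7, t_start = 0.2, weight = 1.2e-3),
    aliases = c("syn[0].tau1" = "tau1", "syn[0].tau2" = "tau2",
                "nstim.start" = "t_start", "nc[0].weight" = "weight"),
    constants = character(),
    current = function(values, t) {
      p <- do.call(biexp_params, values)
      eval_biexp_current(p, ctx, t)
    }), class = "fit_model")
}

# translate raw config names to canonical model parameters and build the
# full value list (defaults overridden by fitted/dependent values)
.model_values <- function(model, raw_values) {
  vals <- model$defaults
  for (nm in names(raw_values)) {
    canon <- if (nm %in% names(model$aliases)) model$aliases[[nm]]
             else if (nm %in% names(model$defaults)) nm
             else NA_character_
    if (!is.na(canon)) vals[[canon]] <- as.numeric(raw_values[[nm]])
    # names that map to no model parameter (e.g. derived constants used in
    # rules, like nhalf) are carried in the raw space only
  }
  vals
}

# model current magnitude on the event grid; NULL if the parameter vector
# is outside the model's domain
.safe_model_mag <- function(model, raw_values, t) {
  vals <- .model_values(model, raw_values)
  if (!is.null(model$mag)) return(model$mag(vals, t))
  cur <- tryCatch(model$current(vals, t), error = function(e) NULL)
  if (is.null(cur)) NULL else abs(cur)
}

#' RMSE cost between a model current and an event
#'
#' Root-mean-squared error over the retained (clipped) samples of the
#' event.  In `running_mean` mode the data are replaced by their centered
#' running mean (window equal to the preprocessing moving window) before
#' the residual is formed.
#'
#' @param model_current Model current magnitudes on the event grid (pA).
#' @param event An [event_trace()].
#' @param mode `"raw"` or `"running_mean"`.
#' @param window Running-mean window in samples (default: the
#'   preprocessing moving window for the event's sampling interval).
#' @return RMSE in pA.
#' @export
compute_cost <- function(model_current, event,
                         mode = c("raw", "running_mean"), window = NULL) {
  mode <- match.arg(mode)
  data <- event$samples
  if (length(model_current) != length(data))
    stop("model and event are not on the same grid (", length(model_current),
         " vs ", length(data), " samples)", call. = FALSE)
  if (mode == "running_mean") {
    if (is.null(window))
      window <- moving_window_samples(event$dt, length(data))
    data <- .running_mean(data, window)
  }
  sqrt(mean((model_current - data)^2))
}

# centered running mean with shrinking windows at the edges
.running_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  h <- k %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Flag boundary-pinned parameter values
#'
#' An accepted fit is suspicious when a parameter sits against its allowed
#' range: the event then carries no information about that parameter (or
#' the model is misspecified).  A value within `tol` of the bound range of
#' either bound is flagged.  Parameters listed in the config's warning
#' section (`ALL EXCEPT` semantics) are exempt.
#'
#' @param values Named vector of fitted parameter values (config order).
#' @param cfg A [parse_config()] result.
#' @param tol Relative tolerance, as a fraction of `hi - lo` (default 0.01).
#' @return Character vector of flagged parameter names (possibly empty).
#' @export
flag_outliers <- function(values, cfg, tol = 0.01) {
  p <- cfg$params
  checked <- setdiff(p$name, cfg$warn_except)
  flagged <- character()
  for (nm in checked) {
    i <- match(nm, p$name)
    rng <- p$hi[i] - p$lo[i]
    v <- as.numeric(values[[nm]])
    if (v <= p$lo[i] + tol * rng || v >= p$hi[i] - tol * rng)
      flagged <- c(flagged, nm)
  }
  flagged
}

# deterministic per-(trace, start) seed; kept below 2^31
.start_seed <- function(base_seed, trace_index, start_index) {
  (base_seed + 10000 * trace_index + start_index) %% 2147483647
}

#' Fit one event with multi-start principal-axis optimization
#'
#' For each randomized start, draws an initial parameter vector uniformly
#' within the config bounds (redrawing vectors hit by an exclusion rule),
#' applies the dependency rules, minimizes the RMSE with
#' [praxis_minimize()], and accepts the result when its RMSE is below
#' `rmse_threshold` times the event's peak amplitude.  Accepted results
#' with a boundary-pinned parameter are flagged as warnings.  An event for
#' which no start is accepted is reported unfittable (empty ensemble).
#'
#' @param event An accepted [event_trace()].
#' @param cfg A [parse_config()] result.
#' @param model A [fit_model_gephyrin()] / [fit_model_biexp()] style model.
#' @param n_starts Number of randomized initial conditions (default 100).
#' @param max_eval Objective-evaluation budget per start (default 3000).
#' @param rmse_threshold Acceptance threshold as a fraction of the peak
#'   amplitude (default 0.10).
#' @param cost_mode `"raw"` or `"running_mean"` (see [compute_cost()]).
#' @param abs_tol_frac Early-stop target for each start: optimization ends
#'   once the RMSE falls below this fraction of the peak amplitude
#'   (default `1e-6`, three decades below the acceptance threshold; the
#'   fit is then indistinguishable from the data at machine-relevant
#'   precision).
#' @param seed Base seed; the start at index `j` for trace `trace_index`
#'   uses seed `seed + 10000 * trace_index + j`, so results are independent
#'   of execution order.
#' @param trace_index Integer index of the trace in its dataset (seeding).
#' @return An object of class `fit_ensemble`: `trace_id`, `results` (one
#'   row per accepted start: parameters in config order, `rmse`,
#'   `rmse_frac`, `n_eval`, `converged`), `best` (row index of the
#'   lowest-RMSE result), `warnings` (init id, parameter), `status`
#'   (`"fitted"` or `"unfittable"`).
#' @export
fit_trace <- function(event, cfg, model, n_starts = 100, max_eval = 3000,
                      rmse_threshold = 0.10,
                      cost_mode = c("raw", "running_mean"),
                      abs_tol_frac = 1e-6,
                      seed = 1, trace_index = 0) {
  cost_mode <- match.arg(cost_mode)
  stopifnot(inherits(event, "event_trace"), inherits(cfg, "fit_config"),
            inherits(model, "fit_model"))
  if (!identical(event$status, "accepted"))
    stop("only accepted events can be fitted (status: ", event$status, ")",
         call. = FALSE)
  p <- cfg$params
  t <- event$dt * (seq_along(event$samples) - 1)
  peak <- event$peak_amplitude
  penalty <- 1e6 * peak

  # precompute the raw-name -> canonical-parameter translation once; the
  # objective below is the optimizer's hot path
  template <- as.list(stats::setNames(p$initial, p$name))
  full0 <- apply_dependencies(cfg, template)   # also validates the rules
  canon_of <- vapply(names(full0), function(nm) {
    if (nm %in% names(model$aliases)) model$aliases[[nm]]
    else if (nm %in% names(model$defaults)) nm
    else NA_character_
  }, character(1))
  keep <- !is.na(canon_of)
  src_names <- names(full0)[keep]
  dst_names <- unname(canon_of[keep])
  np <- nrow(p)
  data_vec <- event$samples
  if (cost_mode == "running_mean")
    data_vec <- .running_mean(data_vec,
                              moving_window_samples(event$dt,
                                                    length(data_vec)))
  has_excl <- length(cfg$exclusions) > 0

  dep_names <- cfg$dependencies$name
  dep_exprs <- cfg$dep_compiled

  objective <- function(x) {
    raw <- template
    raw[seq_len(np)] <- x
    for (k in seq_along(dep_names))        # rules validated on full0 above
      raw[[dep_names[k]]] <- eval(dep_exprs[[k]]$expr, raw, baseenv())
    if (has_excl && eval_exclusion(cfg, raw)) return(penalty)
    vals <- model$defaults
    vals[dst_names] <- raw[src_names]
    mag <- if (!is.null(model$mag)) model$mag(vals, t) else {
      cur <- tryCatch(model$current(vals, t), error = function(e) NULL)
      if (is.null(cur)) NULL else abs(cur)
    }
    if (is.null(mag)) return(penalty)
    sqrt(mean((mag - data_vec)^2))
  }

  rows <- list()
  warns <- list()
  for (j in seq_len(n_starts)) {
    set.seed(.start_seed(seed, trace_index, j))
    x0 <- NULL
    for (try in 1:1000) {
      cand <- p$lo + stats::runif(nrow(p)) * (p$hi - p$lo)
      raw <- as.list(stats::setNames(cand, p$name))
      raw <- tryCatch(apply_dependencies(cfg, raw), error = function(e) NULL)
      if (!is.null(raw) && !eval_exclusion(cfg, raw)) { x0 <- cand; break }
    }
    if (is.null(x0)) next   # exclusion rules reject the whole box
    res <- praxis_minimize(objective, x0, p$lo, p$hi, max_eval = max_eval,
                           abs_tol = abs_tol_frac * peak)
    vals <- stats::setNames(res$par, p$name)
    full <- tryCatch(apply_dependencies(cfg, as.list(vals)),
                     error = function(e) NULL)
    if (is.null(full) || eval_exclusion(cfg, full)) next
    rmse <- res$value
    if (!is.finite(rmse) || rmse >= rmse_threshold * peak) next
    flagged <- flag_outliers(vals, cfg)
    if (length(flagged))
      warns[[length(warns) + 1]] <-
        data.frame(init_id = j, parameter = flagged,
                   stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- c(list(init_id = j), as.list(vals),
                                  list(rmse = rmse, rmse_frac = rmse / peak,
                                       n_eval = res$n_eval,
                                       converged = res$converged))
  }
  results <- if (length(rows))
    do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE,
                          check.names = FALSE))
  else {
    cols <- c("init_id", p$name, "rmse", "rmse_frac", "n_eval", "converged")
    stats::setNames(data.frame(matrix(numeric(0), ncol = length(cols))), cols)
  }
  structure(list(
    trace_id = if (!is.null(event$meta$id)) event$meta$id else NA_character_,
    results = results,
    best = if (nrow(results)) which.min(results$rmse) else NA_integer_,
    warnings = if (length(warns)) do.call(rbind, warns)
               else data.frame(init_id = integer(), parameter = character(),
                               stringsAsFactors = FALSE),
    n_starts = n_starts,
    rmse_threshold = rmse_threshold,
    status = if (nrow(results)) "fitted" else "unfittable"
  ), class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf("<fit_ensemble> trace %s: %s, %d/%d start(s) accepted",
              x$trace_id, x$status, nrow(x$results), x$n_starts))
  if (!is.na(x$best))
    cat(sprintf(", best rmse_frac %.4f", x$results$rmse_frac[x$best]))
  cat("\n")
  invisible(x)
}

#' Best-fit row of an ensemble
#'
#' @param ens A [fit_trace()] result.
#' @return One-row data.frame (or `NULL` for an unfittable trace).
#' @export
best_fit <- function(ens) {
  stopifnot(inherits(ens, "fit_ensemble"))
  if (is.na(ens$best)) NULL else ens$results[ens$best, , drop = FALSE]
}

#' Write fitting outputs
#'
#' Emits the ensembles TSV (trace id, init id, one column per parameter,
#' rmse, rmse_frac), the best-fits TSV, a warnings log (trace id, reason),
#' and a JSON run report (counts, thresholds, seeds, config hash).
#'
#' @param ensembles List of [fit_trace()] results.
#' @param events The corresponding event traces (for rejection reasons).
#' @param dir Output directory (created if needed).
#' @param cfg_text Canonical config text (hashed into the report).
#' @param seed,n_starts,max_eval,rmse_threshold Run parameters recorded in
#'   the report.
#' @return `dir`, invisibly.
#' @export
write_fit_outputs <- function(ensembles, events = NULL, dir,
                              cfg_text = NULL, seed = NA, n_starts = NA,
                              max_eval = NA, rmse_threshold = 0.10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ens_tab <- do.call(rbind, lapply(ensembles, function(e) {
    if (!nrow(e$results)) return(NULL)
    cbind(trace_id = e$trace_id, e$results)
  }))
  best_tab <- do.call(rbind, lapply(ensembles, function(e) {
    b <- best_fit(e)
    if (is.null(b)) NULL else cbind(trace_id = e$trace_id, b)
  }))
  empty <- data.frame(trace_id = character())
  utils::write.table(if (is.null(ens_tab)) empty else ens_tab,
                     file.path(dir, "ensembles.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(if (is.null(best_tab)) empty else best_tab,
                     file.path(dir, "best_fits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  warn_rows <- list()
  for (ev in events) {
    if (!identical(ev$status, "accepted"))
      warn_rows[[length(warn_rows) + 1]] <-
        data.frame(trace_id = if (!is.null(ev$meta$id)) ev$meta$id else NA,
                   reason = sub("^rejected_", "", ev$status),
                   stringsAsFactors = FALSE)
  }
  for (e in ensembles) {
    if (identical(e$status, "unfittable"))
      warn_rows[[length(warn_rows) + 1]] <-
        data.frame(trace_id = e$trace_id, reason = "unfittable",
                   stringsAsFactors = FALSE)
    if (nrow(e$warnings))
      warn_rows[[length(warn_rows) + 1]] <-
        data.frame(trace_id = e$trace_id,
                   reason = paste0("outlier:", e$warnings$parameter),
                   stringsAsFactors = FALSE)
  }
  warns <- if (length(warn_rows)) do.call(rbind, warn_rows)
           else data.frame(trace_id = character(), reason = character())
  utils::write.table(warns, file.path(dir, "warnings.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  report <- list(
    n_traces = length(ensembles),
    n_fitted = sum(vapply(ensembles, function(e) e$status == "fitted",
                          logical(1))),
    n_rejected_preprocess = if (is.null(events)) NA_integer_ else
      sum(vapply(events, function(ev) ev$status != "accepted", logical(1))),
    rmse_threshold = rmse_threshold,
    n_starts = n_starts, max_eval = max_eval, seed = seed,
    config_md5 = if (is.null(cfg_text)) NA_character_ else {
      tf <- tempfile()
      on.exit(unlink(tf), add = TRUE)
      writeLines(cfg_text, tf, sep = "")
      unname(tools::md5sum(tf))
    }
  )
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
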