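## Multilevel statistics over fitted parameter ensembles.

#' Spearman rank-correlation matrix with highlight mask
#'
#' Pairwise Spearman correlations between fitted-parameter columns, with a
#' mask marking coefficients whose absolute value exceeds `threshold`
#' (default 0.2) — the degeneracy signature of the kinetic model: parameter
#' pairs that compensate each other inside the identifiable amplitude
#' combination show up as strong rank correlations.
#'
#' @param tab Data.frame or matrix of numeric columns (one row per best
#'   fit).
#' @param threshold Highlight threshold on `|rho|`.
#' @return List with `rho` (symmetric matrix, unit diagonal) and `mask`
#'   (logical matrix, diagonal `FALSE`).
#' @export
spearman_matrix <- function(tab, threshold = 0.2) {
  tab <- as.data.frame(tab)
  num <- vapply(tab, is.numeric, logical(1))
  tab <- tab[num]
  if (nrow(tab) < 3)
    stop("need at least 3 rows", call. = FALSE)
  const <- vapply(tab, function(x) stats::sd(x) == 0, logical(1))
  if (any(const))
    stop("constant column(s): correlation undefined for ",
         paste(names(tab)[const], collapse = ", "), call. = FALSE)
  rho <- stats::cor(tab, method = "spearman")
  mask <- abs(rho) > threshold
  diag(mask) <- FALSE
  list(rho = rho, mask = mask)
}

#' Grouped values at one analysis level
#'
#' @param name Name of the analysed quantity (e.g. `"alpha_b"`,
#'   `"i_fact"`).
#' @param groups Named list of numeric vectors (label -> values).
#' @param level `"experiment"`, `"cell"` or `"trace"`.
#' @return An object of class `grouped_values`.
#' @export
grouped_values <- function(name, groups,
                           level = c("experiment", "cell", "trace")) {
  level <- match.arg(level)
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a nonempty named list", call. = FALSE)
  if (!all(vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop("group values must be finite", call. = FALSE)
  structure(list(name = name, groups = groups, level = level),
            class = "grouped_values")
}

# Dunn's post hoc z statistic on ranks, with tie correction
.dunn_pairs <- function(values, g, p_adjust = "bonferroni") {
  N <- length(values)
  r <- rank(values)
  labs <- levels(g)
  k <- length(labs)
  nn <- tabulate(g)
  rbar <- tapply(r, g, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pr <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pr))
  for (q in seq_len(ncol(pr))) {
    i <- pr[1, q]; j <- pr[2, q]
    se <- sqrt(s2 * (1 / nn[i] + 1 / nn[j]))
    z[q] <- (rbar[i] - rbar[j]) / se
    p[q] <- 2 * stats::pnorm(abs(z[q]), lower.tail = FALSE)
  }
  list(pairs = pr, z = z, p = stats::p.adjust(p, method = p_adjust))
}

# Tukey-type post hoc on mean ranks (studentized range on the rank scale)
.tukey_pairs <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  labs <- levels(g)
  k <- length(labs)
  nn <- tabulate(g)
  rbar <- tapply(r, g, mean)
  pr <- utils::combn(k, 2)
  q <- p <- numeric(ncol(pr))
  for (m in seq_len(ncol(pr))) {
    i <- pr[1, m]; j <- pr[2, m]
    se <- sqrt(N * (N + 1) / 24 * (1 / nn[i] + 1 / nn[j]))
    q[m] <- abs(rbar[i] - rbar[j]) / se
    p[m] <- stats::ptukey(q[m], nmeans = k, df = Inf, lower.tail = FALSE)
  }
  list(pairs = pr, z = q, p = p)
}

#' Grouped distribution comparison (Kruskal-Wallis + post hoc)
#'
#' Omnibus Kruskal-Wallis one-way analysis of variance on ranks followed,
#' when the omnibus test is significant, by pairwise comparisons with
#' Dunn's method (rank-based z with family-wise adjustment) or a
#' Tukey-type studentized-range test on mean ranks.  Being rank-based, the
#' outcome is invariant under any common strictly monotone transform of
#' the values.
#'
#' @param gv A [grouped_values()] object with at least 2 groups of at
#'   least 2 values each.
#' @param posthoc `"dunn"` or `"tukey"`.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Family-wise adjustment inside Dunn's method (a
#'   [stats::p.adjust()] method; default `"bonferroni"`).
#' @return An object of class `comparison_matrix`: `labels`, `p_omnibus`,
#'   `p` (symmetric pairwise matrix), `significant` (logical matrix,
#'   diagonal `FALSE`), `method`, `alpha`.
#' @export
group_compare <- function(gv, posthoc = c("dunn", "tukey"), alpha = 0.05,
                          p_adjust = "bonferroni") {
  posthoc <- match.arg(posthoc)
  stopifnot(inherits(gv, "grouped_values"))
  if (length(gv$groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(gv$groups) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  values <- unlist(gv$groups, use.names = FALSE)
  g <- factor(rep(names(gv$groups), lengths(gv$groups)),
              levels = names(gv$groups))
  kw <- stats::kruskal.test(values, g)
  labs <- levels(g)
  k <- length(labs)
  pm <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  diag(pm) <- 1
  ph <- if (posthoc == "dunn") .dunn_pairs(values, g, p_adjust)
        else .tukey_pairs(values, g)
  for (q in seq_len(ncol(ph$pairs))) {
    i <- ph$pairs[1, q]; j <- ph$pairs[2, q]
    pm[i, j] <- pm[j, i] <- ph$p[q]
  }
  sig <- pm < alpha
  diag(sig) <- FALSE
  # pairwise flags only meaningful under a significant omnibus test
  if (is.na(kw$p.value) || kw$p.value >= alpha) sig[] <- FALSE
  structure(list(labels = labs, p_omnibus = kw$p.value, p = pm,
                 significant = sig,
                 method = paste0("kruskal-wallis + ", posthoc,
                                 if (posthoc == "dunn")
                                   paste0(" (", p_adjust, ")") else ""),
                 alpha = alpha),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix> %s, alpha = %g, omnibus p = %.3g\n",
              x$method, x$alpha, x$p_omnibus))
  cat(sprintf("  %d significant pair(s) of %d\n",
              sum(x$significant[upper.tri(x$significant)]),
              sum(upper.tri(x$significant))))
  invisible(x)
}

#' Fit a pseudo-Voigt profile to a peak-amplitude histogram
#'
#' Least-squares fit of the 4-parameter profile to histogram bin heights
#' (fixed-width 5 pA bins by default when raw amplitudes are supplied),
#' reporting the Pearson correlation between fitted curve and bin heights.
#'
#' @param amplitudes Raw peak amplitudes (pA); ignored when `mids`/
#'   `heights` are given.
#' @param mids,heights Histogram bin centers and heights (proportions).
#' @param bin_width Bin width in pA for raw amplitudes (default 5).
#' @return List with `params` ([pseudo_voigt_params()]), `R` (Pearson
#'   correlation), `fitted`, `mids`, `heights`.
#' @export
fit_pseudo_voigt <- function(amplitudes = NULL, mids = NULL, heights = NULL,
                             bin_width = 5) {
  if (is.null(mids) || is.null(heights)) {
    if (is.null(amplitudes))
      stop("supply amplitudes or a histogram", call. = FALSE)
    breaks <- seq(floor(min(amplitudes) / bin_width) * bin_width,
                  ceiling(max(amplitudes) / bin_width) * bin_width,
                  by = bin_width)
    if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_width)
    h <- graphics::hist(amplitudes, breaks = breaks, plot = FALSE)
    mids <- h$mids
    heights <- h$counts / sum(h$counts)
  }
  if (sum(heights > 0) < 8)
    stop("need at least 8 histogram bins with mass", call. = FALSE)
  dat <- data.frame(x = mids, y = heights)
  i0 <- which.max(heights)
  half <- heights >= heights[i0] / 2
  start <- list(a = max(heights), b = max(diff(range(mids[half])) / 2,
                                          bin_width / 2),
                c = 0.5, x0 = mids[i0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * (c / (1 + ((x - x0) / b)^2) +
                 (1 - c) * exp(-0.5 * ((x - x0) / b)^2)),
      data = dat, start = start,
      lower = c(a = 1e-12, b = 1e-6, c = 0, x0 = min(mids)),
      upper = c(a = Inf, b = Inf, c = 1, x0 = max(mids)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("pseudo-Voigt fit failed: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  fitted <- stats::predict(fit)
  list(params = pseudo_voigt_params(cf[["a"]], cf[["b"]], cf[["c"]],
                                    cf[["x0"]]),
       R = stats::cor(fitted, heights),
       fitted = fitted, mids = mids, heights = heights)
}

#' Time-to-peak versus peak-amplitude diagnostics
#'
#' Pearson correlation between the analytic time to peak of each fitted
#' event and its peak amplitude.  Events whose amplitude was assigned
#' independently of the kinetics (as in the synthetic generator, or for
#' somatic synapses unaffected by dendritic filtering) show no
#' correlation.
#'
#' @param time_to_peak Times to peak (ms), e.g. from [peak_time()] on the
#'   best-fit parameters.
#' @param amplitude Event peak amplitudes (pA).
#' @return List with `r`, `p`, `n`.
#' @export
time_to_peak_stats <- function(time_to_peak, amplitude) {
  if (length(time_to_peak) != length(amplitude))
    stop("mismatched lengths", call. = FALSE)
  if (length(time_to_peak) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(time_to_peak) == 0 || stats::sd(amplitude) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(time_to_peak, amplitude, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(time_to_peak))
}

#' Write analysis outputs
#'
#' Correlation and comparison matrices as TSV plus a JSON summary.
#'
#' @param dir Output directory.
#' @param spearman A [spearman_matrix()] result (optional).
#' @param comparisons Named list of [group_compare()] results (optional).
#' @param pv A [fit_pseudo_voigt()] result (optional).
#' @param ttp A [time_to_peak_stats()] result (optional).
#' @return `dir`, invisibly.
#' @export
write_analysis_outputs <- function(dir, spearman = NULL, comparisons = NULL,
                                   pv = NULL, ttp = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list()
  if (!is.null(spearman)) {
    utils::write.table(spearman$rho, file.path(dir, "spearman_rho.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(spearman$mask, file.path(dir, "spearman_mask.tsv"),
                       sep = "\t", quote = FALSE)
    summary$n_highlighted <- sum(spearman$mask[upper.tri(spearman$mask)])
  }
  for (nm in names(comparisons)) {
    cm <- comparisons[[nm]]
    utils::write.table(cm$p, file.path(dir, paste0("compare_", nm, "_p.tsv")),
                       sep = "\t", quote = FALSE)
    utils::write.table(cm$significant,
                       file.path(dir, paste0("compare_", nm, "_sig.tsv")),
                       sep = "\t", quote = FALSE)
    summary$comparisons[[nm]] <- list(method = cm$method,
                                      p_omnibus = cm$p_omnibus,
                                      alpha = cm$alpha)
  }
  if (!is.null(pv))
    summary$pseudo_voigt <- c(unclass(pv$params), list(R = pv$R))
  if (!is.null(ttp)) summary$time_to_peak <- ttp
  jsonlite::write_json(summary, file.path(dir, "analysis_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
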