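## Plain-text configuration dialect for fitting runs.
##
## A config file has five fixed sections introduced by //-header lines:
##   //FITTING PARAMETERS AND INITIAL VALUES   (count, then "idx name initial")
##   //CONSTRAINTS                             (one "lo hi" line per parameter)
##   //DEPENDENCY RULES FOR PARAMETERS NOT FITTED (count, then "name = expr")
##   //EXCLUSION RULES                         (count, then boolean expressions)
##   //PARAMETERS WARNING (ALL EXCEPT)         (count, then names)
## Any other //-line is a comment.  Expressions use names, numeric literals,
## + - * / ^, comparisons and parentheses; "^*^" is accepted for "*".

.cfg_headers <- c(
  params   = "//FITTING PARAMETERS AND INITIAL VALUES",
  bounds   = "//CONSTRAINTS",
  deps     = "//DEPENDENCY RULES FOR PARAMETERS NOT FITTED",
  excl     = "//EXCLUSION RULES",
  warn     = "//PARAMETERS WARNING (ALL EXCEPT)"
)

.tok_pattern <- paste0(
  "([A-Za-z_][A-Za-z0-9_.\\[\\]]*)",          # names (NEURON-style allowed)
  "|([0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?)",    # numbers
  "|(\\.[0-9]+([eE][+-]?[0-9]+)?)",
  "|(<=|>=|==|!=|<|>)",                       # comparisons
  "|([-+*/^()])"                              # arithmetic
)

# tokenize an expression; error on anything outside the restricted grammar
.tokenize_expr <- function(text) {
  text <- gsub("^*^", "*", text, fixed = TRUE)   # typography artifact
  m <- gregexpr(.tok_pattern, text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  rest <- text
  regmatches(rest, list(m)) <- list(rep("", length(toks)))
  if (grepl("[^[:space:]]", rest))
    stop("illegal characters in expression: '", trimws(text), "'",
         call. = FALSE)
  toks
}

.expr_names <- function(toks)
  toks[grepl("^[A-Za-z_]", toks)]

# compile a restricted expression: list(expr = language, names = character)
.compile_expr <- function(text) {
  toks <- .tokenize_expr(text)
  code <- vapply(toks, function(tk) {
    if (grepl("^[A-Za-z_]", tk)) paste0("`", tk, "`") else tk
  }, character(1))
  ex <- tryCatch(parse(text = paste(code, collapse = " "))[[1]],
                 error = function(e) stop("malformed expression: '",
                                          trimws(text), "'", call. = FALSE))
  list(expr = ex, names = .expr_names(toks))
}

# evaluate a restricted expression against a name -> value map
.eval_expr <- function(text, values) {
  ex <- if (is.character(text)) .compile_expr(text) else text
  unbound <- setdiff(ex$names, names(values))
  if (length(unbound))
    stop("unbound name(s) in expression: ",
         paste(unbound, collapse = ", "), call. = FALSE)
  eval(ex$expr, envir = values, enclos = baseenv())
}

.parse_num <- function(x, what, line) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop("malformed ", what, " at line ", line, ": '", x, "'", call. = FALSE)
  v
}

#' Parse a fitting configuration file
#'
#' Reads the plain-text configuration dialect: fitted parameters with
#' initial values and bounds, dependency rules for parameters not fitted,
#' exclusion rules (boolean expressions that reject a parameter vector), and
#' a warning set (parameter names exempted from outlier warnings; an empty
#' set means all fitted parameters are checked).
#'
#' @param text Config file content as a character scalar or vector of lines;
#'   alternatively use `file`.
#' @param file Path to a config file.
#' @param constants Extra names (model constants) that expressions may
#'   reference besides declared parameters and dependency targets.
#' @return An object of class `fit_config` with fields `params`
#'   (data.frame: index, name, initial, lo, hi), `dependencies` (data.frame:
#'   name, expr), `exclusions` (character), `warn_except` (character).
#' @seealso [serialize_config()], [eval_exclusion()], [apply_dependencies()]
#' @export
parse_config <- function(text = NULL, file = NULL, constants = character()) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply text or file", call. = FALSE)
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(text)

  # locate section headers in fixed order; other //-lines are comments
  hdr_idx <- match(.cfg_headers, lines)
  if (any(is.na(hdr_idx)))
    stop("missing section header(s): ",
         paste(.cfg_headers[is.na(hdr_idx)], collapse = "; "), call. = FALSE)
  if (is.unsorted(hdr_idx, strictly = TRUE))
    stop("config sections out of order", call. = FALSE)

  section <- function(k) {
    from <- hdr_idx[k] + 1
    to <- if (k < length(hdr_idx)) hdr_idx[k + 1] - 1 else length(lines)
    if (to < from) return(data.frame(line = integer(), text = character()))
    idx <- from:to
    keep <- nzchar(lines[idx]) & !startsWith(lines[idx], "//")
    data.frame(line = idx[keep], text = lines[idx][keep],
               stringsAsFactors = FALSE)
  }

  take_count <- function(sec, what) {
    if (nrow(sec) == 0)
      stop("missing count line in ", what, " section", call. = FALSE)
    n <- suppressWarnings(as.integer(sec$text[1]))
    if (is.na(n) || n < 0)
      stop("malformed count at line ", sec$line[1], " in ", what,
           " section", call. = FALSE)
    list(n = n, rest = sec[-1, , drop = FALSE])
  }

  ## fitted parameters
  ps <- take_count(section(1), "parameters")
  if (nrow(ps$rest) != ps$n)
    stop("parameter count mismatch: declared ", ps$n, ", found ",
         nrow(ps$rest), call. = FALSE)
  params <- data.frame(index = integer(), name = character(),
                       initial = numeric(), stringsAsFactors = FALSE)
  if (ps$n > 0) {
    fields <- strsplit(ps$rest$text, "[[:space:]]+")
    ok <- lengths(fields) == 3
    if (any(!ok))
      stop("malformed parameter line at line ", ps$rest$line[!ok][1],
           call. = FALSE)
    params <- data.frame(
      index = as.integer(vapply(fields, `[`, "", 1)),
      name = vapply(fields, `[`, "", 2),
      initial = .parse_num(vapply(fields, `[`, "", 3), "initial value",
                           ps$rest$line[1]),
      stringsAsFactors = FALSE)
    if (!identical(sort(params$index), 0:(ps$n - 1)))
      stop("parameter indices must be 0..n-1 without gaps", call. = FALSE)
    params <- params[order(params$index), , drop = FALSE]
    if (anyDuplicated(params$name))
      stop("duplicated parameter name", call. = FALSE)
  }

  ## bounds: one "lo hi" line per parameter
  bs <- section(2)
  if (nrow(bs) != ps$n)
    stop("constraints count mismatch: expected ", ps$n, " bound lines, ",
         "found ", nrow(bs), call. = FALSE)
  if (ps$n > 0) {
    fields <- strsplit(bs$text, "[[:space:]]+")
    ok <- lengths(fields) == 2
    if (any(!ok))
      stop("malformed bounds line at line ", bs$line[!ok][1], call. = FALSE)
    params$lo <- .parse_num(vapply(fields, `[`, "", 1), "bound", bs$line[1])
    params$hi <- .parse_num(vapply(fields, `[`, "", 2), "bound", bs$line[1])
    bad <- params$lo >= params$hi
    if (any(bad))
      stop("lower bound not below upper bound for parameter '",
           params$name[bad][1], "'", call. = FALSE)
    bad <- params$initial < params$lo | params$initial > params$hi
    if (any(bad))
      stop("initial value outside bounds for parameter '",
           params$name[bad][1], "'", call. = FALSE)
  } else {
    params$lo <- numeric(0); params$hi <- numeric(0)
  }

  ## dependencies: count, then "name = expr"
  ds <- take_count(section(3), "dependency")
  if (nrow(ds$rest) != ds$n)
    stop("dependency count mismatch: declared ", ds$n, ", found ",
         nrow(ds$rest), call. = FALSE)
  deps <- data.frame(name = character(), expr = character(),
                     stringsAsFactors = FALSE)
  if (ds$n > 0) {
    parts <- regmatches(ds$rest$text,
                        regexec("^([^=<>!]+)=(.+)$", ds$rest$text))
    ok <- lengths(parts) == 3
    if (any(!ok))
      stop("malformed dependency at line ", ds$rest$line[!ok][1],
           call. = FALSE)
    deps <- data.frame(name = trimws(vapply(parts, `[`, "", 2)),
                       expr = trimws(vapply(parts, `[`, "", 3)),
                       stringsAsFactors = FALSE)
    if (anyDuplicated(deps$name))
      stop("duplicated dependency target", call. = FALSE)
  }

  ## exclusion rules: count, then boolean expressions
  es <- take_count(section(4), "exclusion")
  if (nrow(es$rest) != es$n)
    stop("exclusion count mismatch: declared ", es$n, ", found ",
         nrow(es$rest), call. = FALSE)
  exclusions <- if (es$n > 0) trimws(es$rest$text) else character()

  ## warning set: count, then names (parameters exempt from outlier checks)
  ws <- take_count(section(5), "warning")
  if (nrow(ws$rest) != ws$n)
    stop("warning count mismatch: declared ", ws$n, ", found ",
         nrow(ws$rest), call. = FALSE)
  warn_except <- if (ws$n > 0) trimws(ws$rest$text) else character()

  ## compile expressions once; name resolution: expressions may reference
  ## declared parameters, dependency targets, and registered constants
  known <- c(params$name, deps$name, constants)
  dep_compiled <- vector("list", nrow(deps))
  for (i in seq_len(nrow(deps))) {
    dep_compiled[[i]] <- .compile_expr(deps$expr[i])
    bad <- setdiff(dep_compiled[[i]]$names, known)
    if (length(bad))
      stop("unresolvable name(s) in dependency '", deps$name[i], "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  excl_compiled <- vector("list", length(exclusions))
  for (i in seq_along(exclusions)) {
    excl_compiled[[i]] <- .compile_expr(exclusions[i])
    bad <- setdiff(excl_compiled[[i]]$names, known)
    if (length(bad))
      stop("unresolvable name(s) in exclusion rule '", exclusions[i], "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- structure(list(params = params, dependencies = deps,
                        exclusions = exclusions, warn_except = warn_except,
                        dep_compiled = dep_compiled,
                        excl_compiled = excl_compiled),
                   class = "fit_config")
  bad <- setdiff(warn_except, params$name)
  if (length(bad))
    stop("warning set names not among fitted parameters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cfg
}

.fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 15, trim = TRUE, scientific = NA)
    s
  }, character(1))
}

#' Serialize a fitting configuration to canonical text
#'
#' Writes the canonical form of the dialect: fixed section headers, counts,
#' one line per entry.  `parse_config(serialize_config(cfg))` reproduces
#' `cfg`, and serialization is idempotent (byte-identical round trip on the
#' canonical form).
#'
#' @param cfg A [parse_config()] result.
#' @return A single string (lines joined by newline, trailing newline).
#' @export
serialize_config <- function(cfg) {
  stopifnot(inherits(cfg, "fit_config"))
  p <- cfg$params
  out <- c(
    .cfg_headers[["params"]],
    nrow(p),
    if (nrow(p)) paste(p$index, p$name, .fmt_num(p$initial)),
    .cfg_headers[["bounds"]],
    if (nrow(p)) paste(.fmt_num(p$lo), .fmt_num(p$hi)),
    .cfg_headers[["deps"]],
    nrow(cfg$dependencies),
    if (nrow(cfg$dependencies))
      paste(cfg$dependencies$name, "=", cfg$dependencies$expr),
    .cfg_headers[["excl"]],
    length(cfg$exclusions),
    cfg$exclusions,
    .cfg_headers[["warn"]],
    length(cfg$warn_except),
    cfg$warn_except
  )
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
print.fit_config <- function(x, ...) {
  cat(sprintf("<fit_config> %d fitted parameter(s), %d dependency rule(s), %d exclusion rule(s)\n",
              nrow(x$params), nrow(x$dependencies), length(x$exclusions)))
  if (nrow(x$params)) {
    p <- x$params
    cat(sprintf("  [%d] %s  init %g  in [%g, %g]\n",
                p$index, format(p$name), p$initial, p$lo, p$hi), sep = "")
  }
  invisible(x)
}

#' Evaluate exclusion rules against a parameter vector
#'
#' A parameter vector is excluded when any exclusion expression evaluates to
#' `TRUE`.
#'
#' @param cfg A [parse_config()] result.
#' @param values Named numeric vector or list mapping parameter names (and
#'   any constants/dependency targets referenced) to values.
#' @return `TRUE` if the vector is excluded.
#' @export
eval_exclusion <- function(cfg, values) {
  stopifnot(inherits(cfg, "fit_config"))
  values <- as.list(values)
  for (i in seq_along(cfg$exclusions)) {
    v <- .eval_expr(cfg$excl_compiled[[i]], values)
    if (!is.logical(v) || length(v) != 1 || is.na(v))
      stop("exclusion rule did not evaluate to a single boolean: '",
           cfg$exclusions[i], "'", call. = FALSE)
    if (v) return(TRUE)
  }
  FALSE
}

#' Apply dependency rules to a parameter vector
#'
#' Sets non-fitted parameters from their expressions, evaluated in
#' declaration order.  An expression may reference fitted parameters,
#' constants already present in `values`, and dependency targets assigned
#' earlier in the list; referencing a target declared later is a dependency
#' error (forward/cyclic reference).
#'
#' @inheritParams eval_exclusion
#' @return `values` augmented with the dependency targets.
#' @export
apply_dependencies <- function(cfg, values) {
  stopifnot(inherits(cfg, "fit_config"))
  values <- as.list(values)
  deps <- cfg$dependencies
  later <- deps$name
  for (i in seq_len(nrow(deps))) {
    later <- setdiff(later, deps$name[i])
    ex <- cfg$dep_compiled[[i]]
    fwd <- intersect(ex$names, later)
    if (length(fwd))
      stop("dependency '", deps$name[i], "' references target(s) assigned ",
           "later: ", paste(fwd, collapse = ", "), call. = FALSE)
    values[[deps$name[i]]] <- .eval_expr(ex, values)
  }
  values
}
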