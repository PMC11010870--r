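# Utilities over Boolean rule expressions.  Rules are stored as R language
# objects restricted to the grammar: node symbols, constants 0/1, `!`, `&`,
# `|` and parentheses.  This restriction is enforced at parse time so that
# every downstream routine (evaluation, simplification, dependency
# extraction) can assume the small grammar.

#' Parse a Boolean rule from text
#'
#' Accepts the BoolNet operator dialect (`!`, `&`, `|`, parentheses,
#' constants `0`/`1`) and returns the rule as an R language object.
#'
#' @param text single character string with the rule body.
#' @return a language object (or numeric constant) in the restricted grammar.
#' @keywords internal
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty rule expression", call. = FALSE)
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop("cannot parse rule expression: '", text, "' (", conditionMessage(e),
         ")", call. = FALSE)
  })
  check_rule_grammar(expr, text)
  expr
}

# Recursive whitelist walk; errors on anything outside the Boolean grammar.
check_rule_grammar <- function(expr, text) {
  if (is.symbol(expr)) return(invisible(TRUE))
  if (is.numeric(expr) || is.logical(expr)) {
    if (!(as.numeric(expr) %in% c(0, 1)))
      stop("rule constant must be 0 or 1 in '", text, "'", call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.call(expr)) {
    op <- as.character(expr[[1L]])
    if (op == "(" || op == "!") {
      check_rule_grammar(expr[[2L]], text)
      return(invisible(TRUE))
    }
    if (op %in% c("&", "|")) {
      check_rule_grammar(expr[[2L]], text)
      check_rule_grammar(expr[[3L]], text)
      return(invisible(TRUE))
    }
    stop("operator '", op, "' not allowed in rule '", text,
         "' (use !, &, |, parentheses, 0/1)", call. = FALSE)
  }
  stop("unsupported construct in rule '", text, "'", call. = FALSE)
}

#' Node names referenced by a rule
#' @keywords internal
rule_symbols <- function(expr) {
  if (is.symbol(expr)) return(as.character(expr))
  if (is.call(expr)) {
    op <- as.character(expr[[1L]])
    parts <- if (op %in% c("(", "!")) list(expr[[2L]]) else
      list(expr[[2L]], expr[[3L]])
    return(unique(unlist(lapply(parts, rule_symbols))))
  }
  character(0)
}

# Substitute a named list/vector of 0/1 constants for symbols.
substitute_constants <- function(expr, values) {
  if (is.symbol(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(values)) return(as.numeric(values[[nm]]))
    return(expr)
  }
  if (is.call(expr)) {
    for (i in seq_along(expr)[-1L])
      expr[[i]] <- substitute_constants(expr[[i]], values)
    return(expr)
  }
  expr
}

# Boolean constant-folding simplifier: resolves constants through !, &, |,
# drops redundant parentheses and double negation, collapses x&x / x|x.
# Deliberately does not attempt full logic minimisation; constant
# propagation is all attractor-preserving reduction needs.
simplify_rule <- function(expr) {
  if (is.numeric(expr) || is.logical(expr)) return(as.numeric(expr))
  if (is.symbol(expr)) return(expr)
  op <- as.character(expr[[1L]])
  if (op == "(") {
    inner <- simplify_rule(expr[[2L]])
    return(inner)
  }
  if (op == "!") {
    a <- simplify_rule(expr[[2L]])
    if (is.numeric(a)) return(1 - a)
    if (is.call(a) && as.character(a[[1L]]) == "!") return(a[[2L]])
    return(call("!", wrap_operand(a)))
  }
  a <- simplify_rule(expr[[2L]])
  b <- simplify_rule(expr[[3L]])
  if (op == "&") {
    if (is.numeric(a)) return(if (a == 0) 0 else b)
    if (is.numeric(b)) return(if (b == 0) 0 else a)
    if (identical(a, b)) return(a)
    return(call("&", a, b))
  }
  if (op == "|") {
    if (is.numeric(a)) return(if (a == 1) 1 else b)
    if (is.numeric(b)) return(if (b == 1) 1 else a)
    if (identical(a, b)) return(a)
    return(call("|", a, b))
  }
  stop("internal: unexpected operator '", op, "'")
}

# Keep deparse/reparse stable: parenthesise | inside ! and & contexts.
wrap_operand <- function(expr) {
  if (is.call(expr) && as.character(expr[[1L]]) %in% c("&", "|"))
    return(call("(", expr))
  expr
}

#' Deparse a rule to single-line BoolNet text
#' @keywords internal
deparse_rule <- function(expr) {
  paste(deparse(expr, width.cutoff = 500L), collapse = " ")
}

#' Evaluate one rule over a batch of states
#'
#' @param expr rule language object.
#' @param state_env named list of logical vectors (one per node), all the
#'   same length m.
#' @param m number of states in the batch.
#' @return integer vector of length m with values 0/1.
#' @keywords internal
eval_rule_batch <- function(expr, state_env, m) {
  v <- eval(expr, envir = state_env)
  as.integer(rep_len(as.logical(v), m))
}
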