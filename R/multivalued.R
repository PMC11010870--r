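# Nested level-indicator encoding of multi-valued nodes.  A node X with
# levels 0..L becomes indicator nodes X_geq_1 .. X_geq_L with
# X_geq_l => X_geq_(l-1) maintained by construction, so the decoded level
# of any reachable state is the highest satisfied indicator.

#' Booleanize a network with multi-valued nodes
#'
#' Each multi-valued node declares a maximum level `L >= 2` and one
#' Boolean condition per level 1..L (the condition under which the node's
#' next value is at least that level).  Conditions must be nested
#' (threshold-like): `cond_l` must imply `cond_(l-1)` over all regulator
#' assignments, otherwise an error explains the violation.  Level `l` of
#' node `X` becomes the indicator `X_geq_l` with update rule
#' `(cond_l & X_geq_(l-1)) | X_geq_(l+1)`, which can only rise through
#' and fall to adjacent levels, preserving the nesting invariant along
#' every asynchronous trajectory started from a nested state.
#'
#' Conditions may reference multi-valued nodes via their indicator names.
#'
#' @param boolean_rules named character vector of rules for the ordinary
#'   Boolean nodes (may reference indicator names).
#' @param multi named list: for each multi-valued node, a character
#'   vector of level conditions (element `l` = condition for level >= l);
#'   length = maximum level, >= 2.
#' @param weights optional named numeric phenotype weights on the
#'   multi-valued nodes; each is distributed uniformly over that node's
#'   indicators so the summed preference equals `weight * level / L`.
#' @return list with `net` (a [boolean_network()]) and `weights` (the
#'   distributed indicator weights, or NULL).
#' @export
booleanize_multivalued <- function(boolean_rules, multi, weights = NULL) {
  if (!length(multi)) stop("no multi-valued declarations", call. = FALSE)
  if (is.null(names(multi)) || any(!nzchar(names(multi))))
    stop("multi-valued declarations must be named", call. = FALSE)
  rules <- as.list(boolean_rules)
  for (x in names(multi)) {
    conds <- multi[[x]]
    L <- length(conds)
    if (L < 2L)
      stop("multi-valued node '", x, "' must declare max level >= 2",
           call. = FALSE)
    parsed <- lapply(conds, parse_rule)
    check_nested_conditions(x, parsed)
    ind <- indicator_names(x, L)
    for (l in seq_len(L)) {
      lower <- if (l > 1L) ind[l - 1L] else NULL
      higher <- if (l < L) ind[l + 1L] else NULL
      core <- paste0("(", conds[l], ")")
      if (!is.null(lower)) core <- paste0(core, " & ", lower)
      if (!is.null(higher)) core <- paste0("(", core, ") | ", higher)
      rules[[ind[l]]] <- core
    }
  }
  net <- boolean_network(stats::setNames(as.character(rules),
                                         names(rules)))
  w_out <- NULL
  if (!is.null(weights)) {
    missing <- setdiff(names(weights), names(multi))
    if (length(missing))
      stop("weights on non-multi-valued node(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    w_out <- numeric(0)
    for (x in names(weights)) {
      L <- length(multi[[x]])
      w_out <- c(w_out, stats::setNames(
        rep(weights[[x]] / L, L), indicator_names(x, L)))
    }
  }
  list(net = net, weights = w_out)
}

indicator_names <- function(x, L) paste0(x, "_geq_", seq_len(L))

# cond_l must imply cond_(l-1): checked over all assignments of the
# union of referenced regulators.
check_nested_conditions <- function(x, parsed) {
  regs <- unique(unlist(lapply(parsed, rule_symbols)))
  k <- length(regs)
  if (k > 16L)
    stop("nesting check refused: conditions for '", x, "' reference ",
         k, " regulators", call. = FALSE)
  m <- max(1L, 2L^k)
  if (k) {
    grid <- as.matrix(expand.grid(rep(list(0:1), k)))
    colnames(grid) <- regs
    env <- lapply(seq_len(k), function(j) as.logical(grid[, j]))
    names(env) <- regs
  } else env <- list()
  vals <- vapply(parsed, eval_rule_batch, integer(m), state_env = env,
                 m = m)
  vals <- matrix(vals, nrow = m)
  for (l in seq_along(parsed)[-1L]) {
    viol <- vals[, l] > vals[, l - 1L]
    if (any(viol))
      stop("level conditions for '", x, "' are not nested: level ", l,
           " can hold while level ", l - 1L, " does not (non-threshold ",
           "logic); multi-valued encoding requires cond_l => cond_(l-1)",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Decode the level of a multi-valued node from a Boolean state
#'
#' @param state named 0/1 vector over indicator nodes (a full network
#'   state works).
#' @param node the multi-valued node's base name.
#' @param L its maximum level.
#' @return integer level in 0..L (the highest satisfied indicator).
#' @export
decode_level <- function(state, node, L) {
  ind <- indicator_names(node, L)
  missing <- setdiff(ind, names(state))
  if (length(missing))
    stop("state lacks indicator(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- as.integer(state[ind])
  if (any(diff(v) > 0L))
    stop("state violates the nesting invariant for '", node, "'",
         call. = FALSE)
  sum(v)
}
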