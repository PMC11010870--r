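# Asynchronous update semantics, state-transition graphs, attractor
# identification by constant-node reduction, basin approximation and
# phenotype preference.
#
# States are 0/1 integer vectors in node declaration order; a state's key
# is its 0/1 string in that order (bijective, order-stable).

state_keys <- function(S) {
  # S: m x n integer matrix of 0/1
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
  do.call(paste0, as.data.frame(S))
}

key_to_state <- function(key, nodes) {
  bits <- as.integer(strsplit(key, "", fixed = TRUE)[[1L]])
  stats::setNames(bits, nodes)
}

keys_to_matrix <- function(keys, nodes) {
  if (!length(keys))
    return(matrix(integer(0), 0L, length(nodes),
                  dimnames = list(NULL, nodes)))
  m <- t(vapply(strsplit(keys, "", fixed = TRUE),
                function(b) as.integer(b), integer(length(nodes))))
  colnames(m) <- nodes
  m
}

# Evaluate all rules over a batch of states: returns m x n matrix of the
# synchronous image (each column = that node's rule applied to every row).
next_values <- function(net, S) {
  m <- nrow(S)
  env <- lapply(seq_len(ncol(S)), function(j) as.logical(S[, j]))
  names(env) <- net$nodes
  out <- matrix(0L, m, ncol(S), dimnames = list(NULL, net$nodes))
  for (j in seq_along(net$nodes))
    out[, j] <- eval_rule_batch(net$rules[[j]], env, m)
  out
}

# Clamp pinned bits in a batch of states.
clamp_pins <- function(net, S) {
  pins <- pinned_values(net)
  if (length(pins)) for (nm in names(pins)) S[, nm] <- pins[[nm]]
  S
}

#' Asynchronous successor states
#'
#' Under the asynchronous scheme a single node is updated per step.  The
#' successors of `s` are the states obtained by flipping each node whose
#' rule value at `s` differs from its current state.  A state with no
#' successors is a fixed point.  Pinned nodes never flip.
#'
#' @param net a [boolean_network()].
#' @param s named 0/1 vector (full assignment in node order) or a state
#'   key string.
#' @return a list of named 0/1 state vectors (possibly empty).
#' @export
async_successors <- function(net, s) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.character(s)) s <- key_to_state(s, net$nodes)
  s <- as.integer(s[net$nodes])
  S <- matrix(s, 1L, n_nodes(net), dimnames = list(NULL, net$nodes))
  nx <- next_values(net, S)
  flip <- which(nx[1L, ] != s)
  flip <- setdiff(flip, match(names(pinned_values(net)), net$nodes))
  lapply(flip, function(j) {
    t <- s; t[j] <- 1L - t[j]
    stats::setNames(t, net$nodes)
  })
}

new_stg <- function(nodes, states, S, edges) {
  structure(list(nodes = nodes, states = states, state_matrix = S,
                 edges = edges), class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("<state transition graph: ", length(x$states), " states, ",
      nrow(x$edges), " single-flip edges>\n", sep = "")
  invisible(x)
}

# Exhaustive asynchronous STG over the given free nodes (others absent).
# Returns integer edge list over state indices 1..2^n; index i encodes the
# state with bits of i-1, node 1 = least significant bit.
exhaustive_stg <- function(net) {
  n <- n_nodes(net)
  if (n > 24L)
    stop("exhaustive enumeration refused for ", n, " nodes", call. = FALSE)
  S <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(S) <- net$nodes
  storage.mode(S) <- "integer"
  nx <- next_values(net, S)
  pins <- match(names(pinned_values(net)), net$nodes)
  from <- integer(0); to <- integer(0); node <- integer(0)
  for (j in seq_len(n)) {
    if (j %in% pins) next
    chg <- which(nx[, j] != S[, j])
    if (!length(chg)) next
    from <- c(from, chg)
    to <- c(to, bitwXor(chg - 1L, bitwShiftL(1L, j - 1L)) + 1L)
    node <- c(node, rep.int(j, length(chg)))
  }
  new_stg(net$nodes, state_keys(S), S,
          data.frame(from = from, to = to, node = node))
}

#' Build the reachable state-transition graph from seed states
#'
#' Breadth-first closure of the seeds under [async_successors()], in a
#' deterministic iteration order.  States listed in `absorbing` are kept
#' but not expanded (their outgoing edges are omitted), which is how
#' merged-transition-map segments stop at the attractor states of their
#' own landscape.
#'
#' @param net a [boolean_network()].
#' @param seeds state keys (0/1 strings) or a matrix/vector of states.
#' @param absorbing optional character vector of state keys to treat as
#'   absorbing.
#' @param budget maximum number of states to expand before raising a
#'   capacity error (default `2^22`).
#' @return an object of class `stg` with fields `states` (keys in
#'   discovery order), `state_matrix`, and `edges` (data.frame `from`,
#'   `to`, `node`; indices into `states`).
#' @export
build_reachable_stg <- function(net, seeds, absorbing = character(0),
                                budget = 2^22) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.matrix(seeds)) seeds <- state_keys(clamp_pins(net, seeds))
  else if (is.numeric(seeds))
    seeds <- state_keys(clamp_pins(
      net, matrix(as.integer(seeds), 1L, dimnames = list(NULL, net$nodes))))
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("seeds must be nonempty", call. = FALSE)
  nodes <- net$nodes
  n <- length(nodes)
  index <- new.env(parent = emptyenv())
  keys <- character(0)
  add_states <- function(k) {
    new <- k[!vapply(k, exists, logical(1), envir = index)]
    new <- unique(new)
    for (kk in new) assign(kk, length(keys) + match(kk, new), envir = index)
    keys <<- c(keys, new)
    new
  }
  add_states(seeds)
  frontier <- setdiff(seeds, absorbing)
  e_from <- integer(0); e_to <- integer(0); e_node <- integer(0)
  pins <- match(names(pinned_values(net)), nodes)
  while (length(frontier)) {
    if (length(keys) > budget)
      stop("state budget exceeded (", budget,
           " states); raise `budget` or reduce the model", call. = FALSE)
    S <- keys_to_matrix(frontier, nodes)
    nx <- next_values(net, S)
    fi <- vapply(frontier, get, integer(1), envir = index)
    new_keys <- character(0)
    for (j in seq_len(n)) {
      if (j %in% pins) next
      chg <- which(nx[, j] != S[, j])
      if (!length(chg)) next
      T2 <- S[chg, , drop = FALSE]
      T2[, j] <- 1L - T2[, j]
      tk <- state_keys(T2)
      new_keys <- c(new_keys, tk)
      e_from <- c(e_from, fi[chg])
      e_to <- c(e_to, tk)          # resolve to indices after insertion
      e_node <- c(e_node, rep.int(j, length(chg)))
    }
    fresh <- add_states(unique(new_keys))
    frontier <- setdiff(fresh, absorbing)
  }
  to_idx <- if (length(e_to))
    vapply(e_to, get, integer(1), envir = index) else integer(0)
  new_stg(nodes, keys, keys_to_matrix(keys, nodes),
          data.frame(from = e_from, to = to_idx, node = e_node))
}

#' Reduce a network by constant-node propagation
#'
#' Iteratively detects nodes whose (simplified) rule is a constant,
#' substitutes those constants into the remaining rules, simplifies, and
#' repeats to a fixed point.  This is the standard attractor-preserving
#' simplification: every forced node takes its constant value in every
#' attractor of the asynchronous dynamics.
#'
#' @param net a [boolean_network()].
#' @return a list with `residual` (a `boolean_network` over the
#'   non-constant nodes, or `NULL` if none remain) and `fixed` (named
#'   integer vector of forced assignments, possibly empty).
#' @export
reduce_by_constants <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  rules <- lapply(net$rules, simplify_rule)
  nodes <- net$nodes
  fixed <- integer(0)
  repeat {
    is_const <- vapply(rules, is.numeric, logical(1))
    newly <- setdiff(names(rules)[is_const], names(fixed))
    if (!length(newly)) break
    vals <- stats::setNames(vapply(rules[newly], as.integer, integer(1)),
                            newly)
    fixed <- c(fixed, vals)
    keep <- setdiff(names(rules), newly)
    rules <- lapply(rules[keep], function(r)
      simplify_rule(substitute_constants(r, vals)))
  }
  residual_nodes <- setdiff(nodes, names(fixed))
  fixed <- fixed[order(match(names(fixed), nodes))]
  if (!length(residual_nodes))
    return(list(residual = NULL, fixed = fixed))
  res <- boolean_network(stats::setNames(rules[residual_nodes],
                                         residual_nodes))
  pins <- pinned_values(net)
  pins <- pins[names(pins) %in% residual_nodes]
  if (length(pins)) attr(res, "pinned") <- pins
  list(residual = res, fixed = fixed)
}

new_attractor <- function(id, nodes, S, basin_fraction = NA_real_,
                          preference = NA_real_) {
  keys <- sort(state_keys(S))
  S <- keys_to_matrix(keys, nodes)
  structure(list(id = id, nodes = nodes, states = keys, state_matrix = S,
                 kind = if (length(keys) == 1L) "point" else "complex",
                 basin_fraction = basin_fraction, preference = preference),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat("<attractor ", x$id, ": ", x$kind, ", ", length(x$states),
      " state(s)", sep = "")
  if (!is.na(x$basin_fraction))
    cat(sprintf(", basin %.3f", x$basin_fraction))
  if (!is.na(x$preference))
    cat(sprintf(", preference %+.3f", x$preference))
  cat(">\n  ")
  cat(paste(utils::head(x$states, 4L), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("Attractor set:", length(x), "attractor(s) over",
      length(attr(x, "nodes")), "nodes\n")
  for (a in x) print(a)
  invisible(x)
}

#' Identify every attractor of an asynchronous Boolean network
#'
#' The network is first simplified by [reduce_by_constants()]; the
#' attractors of the residual network are then found exactly as the
#' terminal strongly connected components of its full asynchronous
#' state-transition graph, and re-expanded with the forced assignments.
#' Every reported attractor is verified closed under [async_successors()].
#'
#' For residual networks larger than `exhaustive_limit` free nodes, supply
#' `seeds`: the search is then restricted to the reachable STG from those
#' states (terminal SCCs of a reachability closure are genuine attractors).
#'
#' @param net a [boolean_network()].
#' @param exhaustive_limit maximum residual size for full enumeration
#'   (default 24).
#' @param seeds optional seed state keys/matrix for reachability-based
#'   search on large residuals.
#' @param budget state budget forwarded to [build_reachable_stg()].
#' @return an object of class `attractor_set`: a list of `attractor`
#'   objects with stable ids (`A1`, `A2`, ... ordered by minimal state
#'   key), plus attributes `nodes` and `fixed`.
#' @export
find_attractors <- function(net, exhaustive_limit = 24L, seeds = NULL,
                            budget = 2^22) {
  stopifnot(inherits(net, "boolean_network"))
  red <- reduce_by_constants(net)
  nodes <- net$nodes
  if (is.null(red$residual)) {
    atts <- list(new_attractor(
      "A1", nodes,
      matrix(red$fixed[nodes], 1L, dimnames = list(NULL, nodes))))
    return(structure(atts, class = "attractor_set", nodes = nodes,
                     fixed = red$fixed))
  }
  res <- red$residual
  if (n_nodes(res) <= exhaustive_limit && is.null(seeds)) {
    stg <- exhaustive_stg(res)
  } else if (!is.null(seeds)) {
    if (is.character(seeds)) seeds <- keys_to_matrix(seeds, nodes)
    seeds <- seeds[, res$nodes, drop = FALSE]
    seeds <- state_keys(clamp_pins(res, seeds))
    stg <- build_reachable_stg(res, seeds, budget = budget)
  } else {
    stop("residual network has ", n_nodes(res), " free nodes (> ",
         exhaustive_limit, "); supply seed states for reachability-based ",
         "search", call. = FALSE)
  }
  term <- terminal_sccs(stg)
  atts <- vector("list", length(term))
  for (i in seq_along(term)) {
    Sres <- stg$state_matrix[term[[i]], , drop = FALSE]
    # re-expand with forced assignments, full node order
    S <- matrix(0L, nrow(Sres), length(nodes),
                dimnames = list(NULL, nodes))
    if (length(red$fixed)) S[, names(red$fixed)] <-
        matrix(red$fixed, nrow(Sres), length(red$fixed), byrow = TRUE)
    S[, res$nodes] <- Sres
    atts[[i]] <- new_attractor("tmp", nodes, S)
  }
  ord <- order(vapply(atts, function(a) a$states[1L], character(1)))
  atts <- atts[ord]
  for (i in seq_along(atts)) atts[[i]]$id <- paste0("A", i)
  out <- structure(atts, class = "attractor_set", nodes = nodes,
                   fixed = red$fixed)
  verify_attractors(net, out)
  out
}

# Terminal SCCs of an stg: returns list of integer state-index vectors.
terminal_sccs <- function(stg) {
  m <- length(stg$states)
  if (!nrow(stg$edges)) return(as.list(seq_len(m)))
  ig <- igraph::graph_from_edgelist(
    cbind(stg$edges$from, stg$edges$to), directed = TRUE)
  if (igraph::vcount(ig) < m) ig <- igraph::add_vertices(ig, m - igraph::vcount(ig))
  memb <- igraph::components(ig, mode = "strong")$membership
  leaves <- memb[stg$edges$from] != memb[stg$edges$to]
  nonterminal <- unique(memb[stg$edges$from][leaves])
  term <- setdiff(unique(memb), nonterminal)
  lapply(term, function(cc) which(memb == cc))
}

# Closure check: no asynchronous successor leaves the attractor state set.
verify_attractors <- function(net, atts) {
  for (a in atts) {
    S <- a$state_matrix
    nx <- next_values(net, S)
    pins <- match(names(pinned_values(net)), net$nodes)
    for (j in seq_len(ncol(S))) {
      if (j %in% pins) next
      chg <- which(nx[, j] != S[, j])
      if (!length(chg)) next
      T2 <- S[chg, , drop = FALSE]
      T2[, j] <- 1L - T2[, j]
      if (!all(state_keys(T2) %in% a$states))
        stop("internal error: attractor ", a$id,
             " is not closed under asynchronous updates")
    }
  }
  invisible(TRUE)
}

#' Phenotype preference of an attractor
#'
#' The preference is the weighted sum, over marker nodes, of the mean
#' marker state across the attractor's states (uniform over states); a
#' point attractor reduces to the single state's weighted sum.  With
#' `normalize = TRUE` in the spec the sum is divided by the total absolute
#' weight, so preferences lie in \[-1, 1\].
#'
#' @param att an `attractor`.
#' @param spec a [phenotype_spec()].
#' @return a real number.
#' @export
phenotype_preference <- function(att, spec) {
  stopifnot(inherits(att, "attractor"), inherits(spec, "phenotype_spec"))
  missing <- setdiff(spec$markers, att$nodes)
  if (length(missing))
    stop("marker node(s) not in network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  means <- colMeans(att$state_matrix[, spec$markers, drop = FALSE])
  val <- sum(spec$weights * means)
  if (spec$normalize) val <- val / sum(abs(spec$weights))
  val
}

# Attach preferences to an attractor_set.
score_attractors <- function(atts, spec) {
  for (i in seq_along(atts))
    atts[[i]]$preference <- phenotype_preference(atts[[i]], spec)
  atts
}

#' Estimate basins of attraction by trajectory sampling
#'
#' Samples distinct initial states uniformly (without replacement) and
#' follows one uniformly-random asynchronous trajectory from each until an
#' attractor state is hit; the basin fraction of an attractor is the
#' fraction of initial states that converged to it.  When the state space
#' is no larger than `n_samples` (over the free, unpinned nodes), exact
#' exhaustive mode is used instead: absorption probabilities from the
#' uniform initial distribution are computed by first-step analysis, and
#' the fractions sum to 1 exactly.
#'
#' At each trajectory step one node is chosen uniformly among those whose
#' rule value differs from their state (states with none are absorbing);
#' choosing among eligible flips only is hitting-probability-equivalent to
#' choosing among all nodes and re-drawing no-ops.
#'
#' @param net a [boolean_network()].
#' @param attractors an `attractor_set` for `net` (see
#'   [find_attractors()]).
#' @param n_samples number of initial states (default 10000).
#' @param seed RNG seed (integer) for reproducible sampling.
#' @param max_steps trajectory step budget (default `10000 * n_nodes`).
#' @return the `attractor_set` with `basin_fraction` filled in; attribute
#'   `censored` holds the fraction of trajectories that exhausted the step
#'   budget (error if > 1%).
#' @export
estimate_basins <- function(net, attractors, n_samples = 10000L,
                            seed = NULL, max_steps = NULL) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(attractors, "attractor_set"))
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  nodes <- net$nodes
  pins <- pinned_values(net)
  free <- setdiff(nodes, names(pins))
  nf <- length(free)
  if (is.null(max_steps)) max_steps <- 10000L * length(nodes)
  att_of <- attractor_lookup(attractors)

  if (nf == 0L) {
    # fully pinned: the single admissible state is its own attractor
    key <- state_keys(clamp_pins(
      net, matrix(0L, 1L, length(nodes), dimnames = list(NULL, nodes))))
    hit <- att_of[[key]]
    for (i in seq_along(attractors))
      attractors[[i]]$basin_fraction <- as.numeric(i == hit)
    attr(attractors, "censored") <- 0
    return(attractors)
  }
  if (nf <= 24L && 2^nf <= n_samples) {
    # exhaustive mode: exact absorption probabilities from uniform start
    stg <- exhaustive_stg_clamped(net, free)
    groups <- lapply(attractors, function(a) match(a$states, stg$states))
    init <- rep(1 / length(stg$states), length(stg$states))
    p <- absorption_from_stg(stg, groups, init)$p_absorb
    for (i in seq_along(attractors))
      attractors[[i]]$basin_fraction <- p[i]
    attr(attractors, "censored") <- 0
    return(attractors)
  }

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  S <- sample_distinct_states(net, free, n_samples)
  m <- nrow(S)
  converged <- integer(m)     # attractor index per sample, 0 = running
  active <- seq_len(m)
  hit <- att_of[state_keys(S[active, , drop = FALSE])]
  converged[active[!is.na(hit)]] <- hit[!is.na(hit)]
  active <- active[is.na(hit)]
  steps <- 0L
  while (length(active) && steps < max_steps) {
    steps <- steps + 1L
    A <- S[active, , drop = FALSE]
    nx <- next_values(net, A)
    if (length(pins)) for (nm in names(pins)) nx[, nm] <- pins[[nm]]
    elig <- nx != A
    nelig <- rowSums(elig)
    stuck <- nelig == 0L
    if (any(stuck)) {
      # fixed point not listed among the attractors: should not happen
      k <- state_keys(A[stuck, , drop = FALSE])
      stop("trajectory reached unlisted fixed point(s): ",
           paste(utils::head(k, 3L), collapse = ", "))
    }
    pick <- pick_uniform(elig)
    idx <- cbind(seq_len(nrow(A)), pick)
    A[idx] <- 1L - A[idx]
    S[active, ] <- A
    hit <- att_of[state_keys(A)]
    done <- !is.na(hit)
    converged[active[done]] <- hit[done]
    active <- active[!done]
  }
  censored <- length(active) / m
  if (censored > 0.01)
    stop(sprintf(paste0("%.1f%% of trajectories failed to converge within",
                        " the step budget"), 100 * censored), call. = FALSE)
  counts <- tabulate(converged, nbins = length(attractors))
  for (i in seq_along(attractors))
    attractors[[i]]$basin_fraction <- counts[i] / m
  attr(attractors, "censored") <- censored
  attractors
}

# map state key -> attractor index
attractor_lookup <- function(attractors) {
  keys <- unlist(lapply(attractors, `[[`, "states"))
  idx <- rep(seq_along(attractors),
             vapply(attractors, function(a) length(a$states), integer(1)))
  stats::setNames(idx, keys)
}

# uniform choice of one TRUE column per row of a logical matrix
pick_uniform <- function(elig) {
  n <- ncol(elig)
  r <- stats::runif(nrow(elig))
  cum <- t(apply(elig, 1L, cumsum))
  tot <- cum[, n]
  target <- ceiling(r * tot * (1 - 1e-12))
  target[target < 1L] <- 1L
  pick <- integer(nrow(elig))
  for (i in seq_len(nrow(elig)))
    pick[i] <- which(cum[i, ] >= target[i])[1L]
  pick
}

# distinct uniform states over free nodes, pins clamped
sample_distinct_states <- function(net, free, n_samples) {
  nodes <- net$nodes
  nf <- length(free)
  if (nf <= 24L && 2^nf <= n_samples) {
    G <- as.matrix(expand.grid(rep(list(0:1), nf)))
  } else {
    want <- min(n_samples, if (nf <= 24L) 2^nf else Inf)
    seen <- character(0)
    G <- matrix(integer(0), 0L, nf)
    while (nrow(G) < want) {
      draw <- matrix(stats::rbinom((want - nrow(G) + 16L) * nf, 1L, 0.5),
                     ncol = nf)
      k <- do.call(paste0, as.data.frame(draw))
      fresh <- !duplicated(k) & !(k %in% seen)
      G <- rbind(G, draw[fresh, , drop = FALSE])
      seen <- c(seen, k[fresh])
    }
    G <- G[seq_len(want), , drop = FALSE]
  }
  S <- matrix(0L, nrow(G), length(nodes), dimnames = list(NULL, nodes))
  S[, free] <- as.matrix(G)
  storage.mode(S) <- "integer"
  clamp_pins(net, S)
}

# exhaustive STG over free nodes with pins clamped (pins constant).
exhaustive_stg_clamped <- function(net, free) {
  nodes <- net$nodes
  nf <- length(free)
  G <- as.matrix(expand.grid(rep(list(0:1), nf)))
  S <- matrix(0L, nrow(G), length(nodes), dimnames = list(NULL, nodes))
  S[, free] <- G
  storage.mode(S) <- "integer"
  S <- clamp_pins(net, S)
  nx <- next_values(net, S)
  from <- integer(0); to <- integer(0); node <- integer(0)
  for (j in seq_along(nodes)) {
    nm <- nodes[j]
    if (!(nm %in% free)) next
    jf <- match(nm, free)
    chg <- which(nx[, j] != S[, j])
    if (!length(chg)) next
    from <- c(from, chg)
    to <- c(to, bitwXor(chg - 1L, bitwShiftL(1L, jf - 1L)) + 1L)
    node <- c(node, rep.int(j, length(chg)))
  }
  new_stg(nodes, state_keys(S), S,
          data.frame(from = from, to = to, node = node))
}

#' Summarise an attractor set as a data frame
#'
#' @param attractors an `attractor_set`.
#' @return data.frame with id, kind, size, basin_fraction, preference and
#'   the first state key.
#' @export
attractor_summary <- function(attractors) {
  data.frame(
    id = vapply(attractors, `[[`, character(1), "id"),
    kind = vapply(attractors, `[[`, character(1), "kind"),
    n_states = vapply(attractors, function(a) length(a$states), integer(1)),
    basin_fraction = vapply(attractors, `[[`, numeric(1), "basin_fraction"),
    preference = vapply(attractors, `[[`, numeric(1), "preference"),
    state = vapply(attractors, function(a) a$states[1L], character(1)),
    stringsAsFactors = FALSE)
}
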