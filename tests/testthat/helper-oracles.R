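# Independent brute-force oracles.  These deliberately avoid the
# package's vectorised evaluation and graph-construction code paths:
# states are enumerated one by one and rules evaluated with plain eval()
# on single assignments.

# Evaluate one rule on a single named 0/1 state.
oracle_eval <- function(net, node, state) {
  env <- lapply(as.list(state), function(v) v != 0)
  as.integer(isTRUE(as.logical(eval(net$rules[[node]], envir = env))))
}

# Full asynchronous STG by per-state enumeration.  Returns list(keys,
# edges) with edges as a 2-column matrix of state indices.
oracle_full_stg <- function(net) {
  nodes <- net$nodes
  pins <- mtmap::pinned_values(net)
  free <- setdiff(nodes, names(pins))
  combos <- expand.grid(rep(list(0:1), length(free)))
  colnames(combos) <- free
  states <- matrix(0L, nrow(combos), length(nodes),
                   dimnames = list(NULL, nodes))
  states[, free] <- as.matrix(combos)
  if (length(pins)) for (nm in names(pins)) states[, nm] <- pins[[nm]]
  keys <- apply(states, 1L, paste0, collapse = "")
  e_from <- integer(0); e_to <- integer(0)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    for (nd in free) {
      v <- oracle_eval(net, nd, s)
      if (v != s[[nd]]) {
        # expand.grid bit order over free nodes: column k adds 2^(k-1)
        j <- bitwXor(i - 1L, bitwShiftL(1L, match(nd, free) - 1L)) + 1L
        e_from <- c(e_from, i); e_to <- c(e_to, j)
      }
    }
  }
  edges <- if (length(e_from)) cbind(e_from, e_to) else NULL
  list(keys = keys, edges = edges)
}

# Attractors as terminal SCCs of the brute-force STG; returns a sorted
# list of sorted key vectors.
oracle_attractors <- function(net) {
  stg <- oracle_full_stg(net)
  m <- length(stg$keys)
  if (is.null(stg$edges)) {
    memb <- seq_len(m)
    nonterm <- integer(0)
  } else {
    ig <- igraph::graph_from_edgelist(stg$edges, directed = TRUE)
    if (igraph::vcount(ig) < m)
      ig <- igraph::add_vertices(ig, m - igraph::vcount(ig))
    memb <- igraph::components(ig, mode = "strong")$membership
    cross <- memb[stg$edges[, 1L]] != memb[stg$edges[, 2L]]
    nonterm <- unique(memb[stg$edges[, 1L]][cross])
  }
  term <- setdiff(unique(memb), nonterm)
  sets <- lapply(term, function(cc) sort(stg$keys[memb == cc]))
  sets[order(vapply(sets, `[`, character(1), 1L))]
}

# Comparable representation of an attractor_set.
att_key_sets <- function(atts) {
  sets <- lapply(atts, function(a) sort(a$states))
  sets[order(vapply(sets, `[`, character(1), 1L))]
}

# Brute-force signed dependencies of one node: enumerate all regulator
# assignments one at a time.
oracle_signed_edges <- function(net, node) {
  regs <- intersect(net$nodes, all.vars(net$rules[[node]]))
  out <- NULL
  for (r in regs) {
    others <- setdiff(regs, r)
    inc <- dec <- FALSE
    combos <- if (length(others))
      expand.grid(rep(list(0:1), length(others))) else
      data.frame(row.names = 1L)
    for (i in seq_len(nrow(combos))) {
      s0 <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
      if (length(others)) s0[others] <- unlist(combos[i, ])
      s1 <- s0
      s0[r] <- 0L; s1[r] <- 1L
      v0 <- oracle_eval(net, node, s0)
      v1 <- oracle_eval(net, node, s1)
      if (v1 > v0) inc <- TRUE
      if (v1 < v0) dec <- TRUE
    }
    if (inc) out <- rbind(out, data.frame(from = r, to = node, sign = 1L))
    if (dec) out <- rbind(out, data.frame(from = r, to = node, sign = -1L))
  }
  out
}

# All simple directed paths between two vertices, by DFS; returns list of
# node-name vectors sorted by nondecreasing length.
oracle_simple_paths <- function(g, from, to) {
  adj <- split(g$edges$to, g$edges$from)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    for (nxt in unique(adj[[last]])) {
      if (nxt == to) out[[length(out) + 1L]] <<- c(path, nxt)
      else if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  if (from != to) walk(from)
  out[order(lengths(out))]
}

# Minimum feedback vertex set size by exhaustive subset search.
oracle_fvs_size <- function(g) {
  ig <- mtmap::as_igraph_signed(g)
  nodes <- g$nodes
  for (k in 0:length(nodes)) {
    subsets <- utils::combn(nodes, k, simplify = FALSE)
    for (s in subsets) {
      h <- igraph::delete_vertices(ig, s)
      el <- igraph::as_edgelist(h)
      if (nrow(el) && any(el[, 1L] == el[, 2L])) next
      if (igraph::is_dag(h)) return(k)
    }
  }
  length(nodes)
}

# Independent conflict-pair census: enumerate positive cycles of length
# <= cap by explicit tuple loops, then test mutual net-negative
# connections of length <= 2 with interior nodes outside both loops.
oracle_conflict_pairs <- function(g, cap = 3L) {
  nodes <- g$nodes
  sgn <- function(a, b) {
    s <- g$edges$sign[g$edges$from == a & g$edges$to == b]
    if (!length(s)) return(NA_real_)
    if (all(s > 0)) 1 else if (all(s < 0)) -1 else 0
  }
  cyc <- list()
  for (a in nodes) {
    s <- sgn(a, a)
    if (!is.na(s) && s > 0) cyc[[length(cyc) + 1L]] <- a
  }
  if (cap >= 2L) for (a in nodes) for (b in nodes) {
    if (match(a, nodes) >= match(b, nodes)) next
    s1 <- sgn(a, b); s2 <- sgn(b, a)
    if (!is.na(s1) && !is.na(s2) && s1 * s2 > 0)
      cyc[[length(cyc) + 1L]] <- c(a, b)
  }
  if (cap >= 3L) for (a in nodes) for (b in nodes) for (d in nodes) {
    if (anyDuplicated(c(a, b, d))) next
    if (match(a, nodes) > match(b, nodes) ||
        match(a, nodes) > match(d, nodes)) next
    if (match(b, nodes) > match(d, nodes)) next
    # consider both rotations a->b->d->a and a->d->b->a
    for (ord in list(c(a, b, d), c(a, d, b))) {
      ss <- c(sgn(ord[1], ord[2]), sgn(ord[2], ord[3]), sgn(ord[3], ord[1]))
      if (!any(is.na(ss)) && prod(ss) > 0)
        cyc[[length(cyc) + 1L]] <- ord
    }
  }
  sets <- unique(lapply(cyc, sort))
  neg_path <- function(A, B) {
    for (a in A) for (b in B) {
      s <- sgn(a, b)
      if (!is.na(s) && s < 0) return(TRUE)
    }
    mids <- setdiff(nodes, c(A, B))
    for (a in A) for (m in mids) for (b in B) {
      s1 <- sgn(a, m); s2 <- sgn(m, b)
      if (!is.na(s1) && !is.na(s2) && s1 * s2 < 0) return(TRUE)
    }
    FALSE
  }
  count <- 0L
  if (length(sets) >= 2L) for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (j <= i) next
    A <- sets[[i]]; B <- sets[[j]]
    if (length(intersect(A, B))) next
    if (neg_path(A, B) && neg_path(B, A)) count <- count + 1L
  }
  count
}

# shared small fixtures
toggle_net <- function() mtmap::make_toggle()
conflict_fixture <- function(...) mtmap::make_conflict_network(...)
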