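# Multi-stable motifs (SCCs with >= 2 distinct stable projections),
# interconnecting nodes between motif pairs, conflict-pattern census, and
# degree-preserving randomisation.

#' Identify multi-stable motifs
#'
#' A multi-stable motif is a minimal self-contained positive-feedback
#' unit of the signed interaction graph that takes at least two distinct
#' stable patterns across the supplied attractors.  Candidate units are
#' built from simple cycles with positive sign product (the structures
#' capable of multi-stability), processed in order of increasing length:
#' a cycle disjoint from all units founds a new one, a cycle overlapping
#' exactly one unit is merged into it, and a cycle spanning two or more
#' existing units is discarded — such spanning double-negative loops are
#' precisely the inter-motif conflict structures, not motifs themselves
#' (two mutually inhibiting motifs always compose into a positive cycle,
#' so a maximal-SCC decomposition would fuse them).  Each retained unit
#' is strongly connected by construction.  Units are kept if the
#' projections of the attractor states onto their nodes contain at least
#' two distinct patterns (every state of a complex attractor is
#' projected).  Supply the original attractors together with all
#' attractors reachable under regulation to mirror the intended usage.
#'
#' @param net a [boolean_network()].
#' @param attractors an `attractor_set` (or list of them, concatenated).
#' @param g optional precomputed [derive_signed_graph()] result.
#' @param max_cycle_len maximum cycle length examined (default 6).
#' @return list of `multistable_motif` objects: `nodes` (motif members)
#'   and `stable_projections` (distinct 0/1 strings over those nodes).
#' @export
find_multistable_motifs <- function(net, attractors, g = NULL,
                                    max_cycle_len = 6L) {
  stopifnot(inherits(net, "boolean_network"))
  if (inherits(attractors, "attractor_set")) attractors <- unclass(attractors)
  atts <- list()
  for (a in attractors) {
    if (inherits(a, "attractor")) atts[[length(atts) + 1L]] <- a
    else for (b in a) atts[[length(atts) + 1L]] <- b
  }
  if (is.null(g)) g <- derive_signed_graph(net)
  cycles <- positive_cycles(g, max_cycle_len)
  cycles <- cycles[order(lengths(cycles))]
  units <- list()
  for (cyc in cycles) {
    hits <- which(vapply(units, function(u) length(intersect(u, cyc)) > 0L,
                         logical(1)))
    if (length(hits) == 0L) units[[length(units) + 1L]] <- cyc
    else if (length(hits) == 1L)
      units[[hits]] <- union(units[[hits]], cyc)
    # >= 2 hits: spanning inter-motif loop, discarded
  }
  out <- list()
  for (u in units) {
    members <- u[order(match(u, net$nodes))]
    proj <- unique(unlist(lapply(atts, function(a)
      state_keys(a$state_matrix[, members, drop = FALSE]))))
    if (length(proj) >= 2L)
      out[[length(out) + 1L]] <- structure(
        list(nodes = members, stable_projections = sort(proj)),
        class = "multistable_motif")
  }
  out
}

#' @export
print.multistable_motif <- function(x, ...) {
  cat("<multi-stable motif {", paste(x$nodes, collapse = ", "), "}: ",
      length(x$stable_projections), " stable projections>\n", sep = "")
  invisible(x)
}

#' Interconnecting nodes between two motifs
#'
#' Enumerates the k shortest loopless directed paths from the nodes of
#' motif `a` to the nodes of motif `b` and vice versa (Yen's algorithm,
#' via igraph), and ranks the interior nodes of those paths by the number
#' of covering paths, then by the length of the shortest covering path.
#' Each path's net sign is the product of its edge signs (a dual-signed
#' dependency counts as ambiguous, sign 0).
#'
#' @param g a [signed_graph()].
#' @param a,b `multistable_motif` objects (or character node vectors).
#' @param k number of shortest paths per direction (default 10).
#' @return list with `interconnectors` (data.frame `node`, `n_paths`,
#'   `min_length`, ranked) and `paths` (data.frame per path: direction,
#'   length, net_sign, path string).  Empty ranking if no path exists.
#' @export
interconnecting_nodes <- function(g, a, b, k = 10L) {
  stopifnot(inherits(g, "signed_graph"))
  na <- if (inherits(a, "multistable_motif")) a$nodes else as.character(a)
  nb <- if (inherits(b, "multistable_motif")) b$nodes else as.character(b)
  # path search runs on the simple digraph: dual-signed dependencies are
  # one connection (their ambiguity is kept in the net-sign lookup)
  ig <- igraph::graph_from_data_frame(
    unique(g$edges[, c("from", "to")]), directed = TRUE,
    vertices = data.frame(name = g$nodes))
  sgn <- net_sign_lookup(g)
  collect <- function(from_set, to_set, direction) {
    res <- list()
    for (u in from_set) for (v in to_set) {
      if (u == v) next
      ps <- tryCatch(
        suppressWarnings(
          igraph::k_shortest_paths(ig, from = u, to = v, k = k)$vpaths),
        error = function(e) list())
      for (p in ps) {
        nm <- igraph::as_ids(p)
        interior <- setdiff(nm[-c(1L, length(nm))], c(na, nb))
        res[[length(res) + 1L]] <- list(
          direction = direction, nodes = nm, interior = interior,
          length = length(nm) - 1L,
          net_sign = path_net_sign(nm, sgn))
      }
    }
    if (length(res) > k) {
      ord <- order(vapply(res, `[[`, integer(1), "length"))
      res <- res[ord][seq_len(k)]
    }
    res
  }
  paths <- c(collect(na, nb, "a_to_b"), collect(nb, na, "b_to_a"))
  if (!length(paths))
    return(list(interconnectors = data.frame(
      node = character(0), n_paths = integer(0), min_length = integer(0)),
      paths = data.frame()))
  interior <- unlist(lapply(paths, `[[`, "interior"))
  if (!length(interior)) {
    rank_df <- data.frame(node = character(0), n_paths = integer(0),
                          min_length = integer(0))
  } else {
    lens <- unlist(lapply(paths, function(p)
      rep.int(p$length, length(p$interior))))
    agg <- stats::aggregate(lens, by = list(node = interior),
                            FUN = function(x) c(n = length(x),
                                                m = min(x)))
    rank_df <- data.frame(node = agg$node,
                          n_paths = as.integer(agg$x[, "n"]),
                          min_length = as.integer(agg$x[, "m"]),
                          stringsAsFactors = FALSE)
    rank_df <- rank_df[order(-rank_df$n_paths, rank_df$min_length,
                             rank_df$node), ]
    rownames(rank_df) <- NULL
  }
  path_df <- data.frame(
    direction = vapply(paths, `[[`, character(1), "direction"),
    length = vapply(paths, `[[`, integer(1), "length"),
    net_sign = vapply(paths, `[[`, numeric(1), "net_sign"),
    path = vapply(paths, function(p) paste(p$nodes, collapse = ">"),
                  character(1)),
    stringsAsFactors = FALSE)
  list(interconnectors = rank_df, paths = path_df)
}

# lookup: "from|to" -> net sign (+1, -1, or 0 when both signs present)
net_sign_lookup <- function(g) {
  key <- paste(g$edges$from, g$edges$to, sep = "|")
  tapply(g$edges$sign, key, function(s)
    if (all(s > 0)) 1 else if (all(s < 0)) -1 else 0)
}

path_net_sign <- function(nm, sgn) {
  if (length(nm) < 2L) return(1)
  s <- sgn[paste(nm[-length(nm)], nm[-1L], sep = "|")]
  prod(as.numeric(s))
}

#' Count conflicting motif-pair structures
#'
#' Censuses the structural signature of competitive stabilisation: two
#' node-disjoint positive feedback loops (length <= `max_motif_size`)
#' connected in both directions by net-negative directed paths of length
#' <= 2 whose interior nodes lie outside both loops.  Implemented by
#' pattern join: positive cycles are enumerated first, indexed, and then
#' joined on mutually inhibiting connecting paths.  Distinct pairs of
#' loop node sets are counted, including overlapping instances of other
#' pairs.
#'
#' @param g a [signed_graph()].
#' @param max_motif_size maximum loop length (default 3).
#' @param max_pairs budget on the number of loop pairs examined
#'   (default 1e6; exceeded -> capacity error).
#' @return integer count.
#' @export
count_conflict_motif_pairs <- function(g, max_motif_size = 3L,
                                       max_pairs = 1e6) {
  stopifnot(inherits(g, "signed_graph"))
  loops <- positive_cycles(g, max_motif_size)
  if (length(loops) < 2L) return(0L)
  if (length(loops)^2 > max_pairs)
    stop("conflict-pair census budget exceeded: ", length(loops),
         " positive loops", call. = FALSE)
  sets <- lapply(loops, sort)
  sets <- unique(sets)
  count <- 0L
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (j <= i) next
      A <- sets[[i]]; B <- sets[[j]]
      if (length(intersect(A, B))) next
      if (has_negative_path(g, A, B) && has_negative_path(g, B, A))
        count <- count + 1L
    }
  }
  count
}

# all simple directed cycles of length <= maxlen with positive sign
# product (self-loops count as length 1); returns list of node vectors.
positive_cycles <- function(g, maxlen) {
  edges <- g$edges
  sgn <- net_sign_lookup(g)
  adj <- split(edges$to, edges$from)
  out <- list()
  nodes <- g$nodes
  # DFS from each start node, only visiting nodes >= start (canonical)
  for (start in nodes) {
    stack <- list(list(path = start, sign = 1))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- cur$path[length(cur$path)]
      for (nxt in unique(adj[[last]])) {
        s <- as.numeric(sgn[paste(last, nxt, sep = "|")])
        if (nxt == start) {
          if (cur$sign * s > 0) out[[length(out) + 1L]] <- cur$path
          next
        }
        if (nxt %in% cur$path) next
        if (match(nxt, nodes) < match(start, nodes)) next
        if (length(cur$path) >= maxlen) next
        stack[[length(stack) + 1L]] <-
          list(path = c(cur$path, nxt), sign = cur$sign * s)
      }
    }
  }
  out
}

# is there a directed path of length <= 2 from set A to set B whose net
# sign is negative, with any interior node outside both sets?
has_negative_path <- function(g, A, B) {
  e <- g$edges
  direct <- e$sign < 0 & e$from %in% A & e$to %in% B
  if (any(direct)) return(TRUE)
  e1 <- e[e$from %in% A & !(e$to %in% A) & !(e$to %in% B), , drop = FALSE]
  if (!nrow(e1)) return(FALSE)
  e2 <- e[e$to %in% B, , drop = FALSE]
  if (!nrow(e2)) return(FALSE)
  m <- merge(data.frame(mid = e1$to, s1 = e1$sign),
             data.frame(mid = e2$from, s2 = e2$sign))
  any(m$s1 * m$s2 < 0)
}

#' Degree-preserving randomisation of a signed graph
#'
#' Performs `ceiling(swap_fraction * n_edges)` successful double-edge
#' swaps: two edges (u -> x), (v -> y) with distinct sources and distinct
#' targets exchange their targets, each edge keeping its sign.  Swaps
#' that would create a self-loop or duplicate an existing
#' (source, target, sign) edge are rejected.  In- and out-degree
#' sequences are preserved exactly.
#'
#' @param g a [signed_graph()].
#' @param swap_fraction fraction of edges to swap, in (0, 1].
#' @param seed RNG seed.
#' @param max_tries rejection budget per requested swap (default 100).
#' @return a randomised [signed_graph()].
#' @export
randomize_degree_preserving <- function(g, swap_fraction = 0.3,
                                        seed = 1L, max_tries = 100L) {
  stopifnot(inherits(g, "signed_graph"))
  if (!(swap_fraction > 0 && swap_fraction <= 1))
    stop("swap_fraction must be in (0, 1]", call. = FALSE)
  edges <- g$edges
  ne <- nrow(edges)
  if (ne < 2L) stop("not enough edges to swap", call. = FALSE)
  target_swaps <- ceiling(swap_fraction * ne)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  key <- function(f, t, s) paste(f, t, s)
  existing <- new.env(parent = emptyenv())
  for (i in seq_len(ne))
    assign(key(edges$from[i], edges$to[i], edges$sign[i]), TRUE,
           envir = existing)
  done <- 0L
  tries <- 0L
  while (done < target_swaps) {
    tries <- tries + 1L
    if (tries > max_tries * target_swaps)
      stop("degree-preserving randomisation failed: too few legal swaps",
           call. = FALSE)
    ij <- sample.int(ne, 2L)
    i <- ij[1L]; j <- ij[2L]
    u <- edges$from[i]; x <- edges$to[i]; su <- edges$sign[i]
    v <- edges$from[j]; y <- edges$to[j]; sv <- edges$sign[j]
    if (u == v || x == y) next
    if (u == y || v == x) next                      # would self-loop
    k1 <- key(u, y, su); k2 <- key(v, x, sv)
    if (exists(k1, envir = existing, inherits = FALSE) ||
        exists(k2, envir = existing, inherits = FALSE)) next
    rm(list = c(key(u, x, su), key(v, y, sv)), envir = existing)
    assign(k1, TRUE, envir = existing)
    assign(k2, TRUE, envir = existing)
    edges$to[i] <- y
    edges$to[j] <- x
    done <- done + 1L
  }
  signed_graph(g$nodes, edges)
}

#' Curate a signed directed interaction network from tables
#'
#' Merges interaction tables, keeps only signed and directed rows,
#' optionally intersects with a cross-validation whitelist of
#' (source, target) pairs, and returns the largest weakly connected
#' component.
#'
#' @param tables a data.frame, a list of data.frames, or file path(s) to
#'   TSV files with header columns `source`, `target`, `sign`
#'   (+1/-1/0/NA), `is_directed` (logical/0-1), `confidence` (optional).
#' @param whitelist optional data.frame with `source`, `target` columns;
#'   only listed pairs are kept.
#' @return a [signed_graph()] restricted to the largest weakly connected
#'   component.
#' @export
curate_interaction_network <- function(tables, whitelist = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  tabs <- lapply(tables, function(t) {
    if (is.character(t))
      t <- utils::read.delim(t, stringsAsFactors = FALSE)
    t
  })
  required <- c("source", "target", "sign", "is_directed")
  for (t in tabs) {
    missing <- setdiff(required, names(t))
    if (length(missing))
      stop("interaction table lacks required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- do.call(rbind, lapply(tabs, function(t)
    t[, intersect(c(required, "confidence"), names(t)), drop = FALSE][
      , required, drop = FALSE]))
  tab$sign <- suppressWarnings(as.integer(tab$sign))
  directed <- as.logical(tab$is_directed) %in% TRUE |
    tab$is_directed %in% c(1, "1")
  keep <- !is.na(tab$sign) & tab$sign %in% c(-1L, 1L) & directed
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab))
    stop("empty after filtering: no signed, directed interactions",
         call. = FALSE)
  if (!is.null(whitelist)) {
    wk <- paste(whitelist$source, whitelist$target)
    tab <- tab[paste(tab$source, tab$target) %in% wk, , drop = FALSE]
    if (!nrow(tab))
      stop("empty after filtering: no interactions on the whitelist",
           call. = FALSE)
  }
  tab <- tab[!duplicated(paste(tab$source, tab$target, tab$sign)), ]
  nodes <- unique(c(tab$source, tab$target))
  g <- signed_graph(nodes, data.frame(from = tab$source, to = tab$target,
                                      sign = tab$sign))
  ig <- as_igraph_signed(g)
  comp <- igraph::components(ig, mode = "weak")
  biggest <- which.max(comp$csize)
  keep_nodes <- names(comp$membership)[comp$membership == biggest]
  sub <- g$edges[g$edges$from %in% keep_nodes &
                   g$edges$to %in% keep_nodes, , drop = FALSE]
  signed_graph(keep_nodes, sub)
}
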