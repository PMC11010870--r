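# Comparator target-search strategies and the control-effectiveness
# metric: systematic perturbation screening (the exhaustive oracle) and
# feedback vertex set control.

#' Control effectiveness of a pin set
#'
#' The basin-weighted average phenotypic preference of the pinned
#' network's attractors minus the same quantity for a reference network
#' (by default the unperturbed network).
#'
#' @param net the unperturbed [boolean_network()].
#' @param pins a [perturbation()].
#' @param spec a [phenotype_spec()].
#' @param n_samples,seed basin estimation controls (default 10000).
#' @param baseline reference: `"unperturbed"` (default) or a
#'   `perturbation` to use as the reference pin set (e.g. the given
#'   target alone, for synergy-specific reporting).
#' @return object of class `control_assessment`: `pins`, `effectiveness`,
#'   `baseline_preference`, `controlled_preference`.
#' @export
control_effectiveness <- function(net, pins, spec, n_samples = 10000L,
                                  seed = NULL, baseline = "unperturbed") {
  stopifnot(inherits(net, "boolean_network"))
  if (!inherits(pins, "perturbation")) pins <- perturbation(pins)
  if (!length(pins)) stop("pins must be nonempty", call. = FALSE)
  check_markers(net, spec)
  ref_net <- if (inherits(baseline, "perturbation"))
    apply_perturbation(net, baseline) else net
  base_pref <- basin_weighted_preference(ref_net, spec, n_samples, seed)
  ctrl_net <- apply_perturbation(net, pins)
  ctrl_pref <- basin_weighted_preference(ctrl_net, spec, n_samples, seed)
  structure(list(pins = pins, effectiveness = ctrl_pref - base_pref,
                 baseline_preference = base_pref,
                 controlled_preference = ctrl_pref),
            class = "control_assessment")
}

#' @export
print.control_assessment <- function(x, ...) {
  cat("<control assessment: ",
      paste(names(x$pins), unclass(x$pins), sep = "=", collapse = ", "),
      ": effectiveness ", sprintf("%+.4f", x$effectiveness),
      " (", sprintf("%.4f", x$baseline_preference), " -> ",
      sprintf("%.4f", x$controlled_preference), ")>\n", sep = "")
  invisible(x)
}

basin_weighted_preference <- function(net, spec, n_samples, seed) {
  atts <- find_attractors(net)
  atts <- score_attractors(atts, spec)
  atts <- estimate_basins(net, atts, n_samples = n_samples, seed = seed)
  sum(vapply(atts, function(a) a$basin_fraction * a$preference,
             numeric(1)))
}

#' Systematic perturbation screening (SPS)
#'
#' The brute-force oracle: every candidate node (all nodes except the
#' phenotype markers and the given target) is pinned ON and OFF alongside
#' the given target, and the control effectiveness of each two-node pin
#' set is measured.  Results are sorted by effectiveness, ties broken by
#' node name then type, and are deterministic for a fixed seed.
#'
#' @param net a [boolean_network()].
#' @param given length-2: node name and type (`"ON"`/`"OFF"`).
#' @param spec a [phenotype_spec()].
#' @param n_samples,seed basin estimation controls.
#' @param baseline forwarded to [control_effectiveness()].
#' @return data.frame `node`, `type`, `effectiveness`, best-first.
#' @export
sps_search <- function(net, given, spec, n_samples = 10000L, seed = NULL,
                       baseline = "unperturbed") {
  stopifnot(inherits(net, "boolean_network"))
  gnode <- as.character(given[[1L]])
  gval <- if (given[[2L]] %in% c("ON", 1, "1")) 1L else 0L
  check_markers(net, spec)
  cands <- setdiff(net$nodes, c(gnode, spec$markers))
  rows <- list()
  for (cand in cands) for (val in c(1L, 0L)) {
    pins <- perturbation(stats::setNames(c(gval, val), c(gnode, cand)))
    eff <- control_effectiveness(net, pins, spec, n_samples = n_samples,
                                 seed = seed, baseline = baseline)
    rows[[length(rows) + 1L]] <- data.frame(
      node = cand, type = if (val == 1L) "ON" else "OFF",
      effectiveness = eff$effectiveness, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$effectiveness, out$node, out$type), ]
  rownames(out) <- NULL
  out
}

#' Minimal feedback vertex set
#'
#' A minimum-cardinality node set whose removal makes the directed graph
#' acyclic.  Self-looped nodes are always included.  Exact search by
#' cycle-based branch and bound for graphs up to `exact_limit` nodes;
#' larger graphs fall back to a greedy max-degree heuristic and flag the
#' result.
#'
#' @param g a [signed_graph()] or igraph object.
#' @param exact_limit node-count bound for the exact search (default 30).
#' @return character vector of node names; attribute `exact` says whether
#'   the result is provably minimum.
#' @export
minimal_fvs <- function(g, exact_limit = 30L) {
  ig <- if (inherits(g, "signed_graph")) as_igraph_signed(g) else g
  ig <- igraph::simplify(ig, remove.multiple = TRUE, remove.loops = FALSE)
  nodes <- igraph::V(ig)$name
  # self-loops are forced
  el <- igraph::as_edgelist(ig)
  forced <- unique(el[el[, 1L] == el[, 2L], 1L])
  ig2 <- igraph::delete_vertices(ig, forced)
  core <- prune_acyclic_parts(ig2)
  if (igraph::vcount(core) == 0L) {
    out <- forced
    attr(out, "exact") <- TRUE
    return(out)
  }
  if (length(nodes) <= exact_limit) {
    best <- fvs_branch_bound(core, character(0),
                             best = igraph::V(core)$name)
    out <- c(forced, best)
    attr(out, "exact") <- TRUE
  } else {
    out <- c(forced, fvs_greedy(core))
    attr(out, "exact") <- FALSE
  }
  out
}

# strip vertices not on any cycle (iteratively remove in/out degree 0)
prune_acyclic_parts <- function(ig) {
  repeat {
    deg_in <- igraph::degree(ig, mode = "in")
    deg_out <- igraph::degree(ig, mode = "out")
    drop <- names(which(deg_in == 0L | deg_out == 0L))
    if (!length(drop)) return(ig)
    ig <- igraph::delete_vertices(ig, drop)
  }
}

find_any_cycle <- function(ig) {
  ig <- prune_acyclic_parts(ig)
  if (igraph::vcount(ig) == 0L) return(NULL)
  # girth-style search: shortest cycle through successive vertices
  best <- NULL
  for (v in igraph::V(ig)$name) {
    outs <- igraph::neighbors(ig, v, mode = "out")$name
    for (w in outs) {
      if (w == v) return(v)
      sp <- tryCatch(suppressWarnings(
        igraph::shortest_paths(ig, from = w, to = v, mode = "out")$vpath[[1L]]),
        error = function(e) NULL)
      if (!is.null(sp) && length(sp)) {
        cyc <- igraph::as_ids(sp)
        if (is.null(best) || length(cyc) < length(best)) best <- cyc
      }
    }
    if (!is.null(best) && length(best) <= 2L) break
  }
  best
}

fvs_branch_bound <- function(ig, chosen, best) {
  if (length(chosen) >= length(best)) return(best)
  cyc <- find_any_cycle(ig)
  if (is.null(cyc)) {
    return(if (length(chosen) < length(best)) chosen else best)
  }
  for (v in cyc) {
    cand <- fvs_branch_bound(igraph::delete_vertices(ig, v),
                             c(chosen, v), best)
    if (length(cand) < length(best)) best <- cand
  }
  best
}

fvs_greedy <- function(ig) {
  out <- character(0)
  repeat {
    ig <- prune_acyclic_parts(ig)
    if (igraph::vcount(ig) == 0L) return(out)
    deg <- igraph::degree(ig, mode = "all")
    v <- names(which.max(deg))
    out <- c(out, v)
    ig <- igraph::delete_vertices(ig, v)
  }
}

#' Average control effectiveness over all two-node pairs of a target set
#'
#' Pins every pair from `suggested` to the values those nodes take in the
#' desired attractor and averages the control effectiveness over the
#' `choose(n, 2)` pairs.
#'
#' @param net a [boolean_network()].
#' @param suggested character vector of >= 2 node names.
#' @param spec a [phenotype_spec()].
#' @param desired an `attractor` supplying the pin values (its first
#'   state is used).
#' @param n_samples,seed,baseline forwarded to
#'   [control_effectiveness()].
#' @return list with `mean_effectiveness` and `per_pair` data.frame.
#' @export
evaluate_pair_sets <- function(net, suggested, spec, desired,
                               n_samples = 10000L, seed = NULL,
                               baseline = "unperturbed") {
  suggested <- unique(as.character(suggested))
  if (length(suggested) < 2L)
    stop("need at least two suggested nodes", call. = FALSE)
  stopifnot(inherits(desired, "attractor"))
  vals <- desired$state_matrix[1L, ]
  pairs <- utils::combn(suggested, 2L)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    nn <- pairs[, p]
    pins <- perturbation(stats::setNames(vals[nn], nn))
    eff <- control_effectiveness(net, pins, spec, n_samples = n_samples,
                                 seed = seed, baseline = baseline)
    rows[[length(rows) + 1L]] <- data.frame(
      node1 = nn[1L], node2 = nn[2L],
      effectiveness = eff$effectiveness, stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, rows)
  list(mean_effectiveness = mean(per_pair$effectiveness),
       per_pair = per_pair)
}
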