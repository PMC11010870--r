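# The merged transition map (MTM): the union of state-transition segments
# linking the original attractor landscape with the landscape of the
# target-pinned network, its factorisation into path ensembles, and the
# weighted-flipping-frequency ranking of synergistic partner targets.

#' Build the merged transition map for a pinned target
#'
#' Computes the attractors (and basins, and phenotype preferences) of the
#' original and the target-pinned ("regulated") network, then assembles:
#' for each original attractor a *regulated segment* — the reachable
#' asynchronous STG of the pinned network seeded from that attractor's
#' states (pinned bits clamped), absorbed at the regulated attractors —
#' and for each regulated attractor a *reversal segment* — the reachable
#' STG of the unpinned network seeded from that attractor's states,
#' absorbed at the original attractors.  Regulated segments model drug
#' onset, reversal segments drug withdrawal; together they carry every
#' state-transition path the perturbation can trigger.
#'
#' @param net the unperturbed [boolean_network()].
#' @param pert a [perturbation()] pinning the given target node(s).
#' @param spec a [phenotype_spec()].
#' @param n_samples initial states for basin estimation (default 10000).
#' @param seed RNG seed for basin sampling.
#' @param exhaustive_limit,budget capacity controls forwarded to
#'   [find_attractors()] and [build_reachable_stg()].
#' @return an object of class `mtm` with fields `net`, `pinned_net`,
#'   `pert`, `spec`, `original` and `regulated` (attractor sets with
#'   basins and preferences), and `segments` (each: `label` in
#'   `"regulated"`/`"reversal"`, `source` attractor id, `stg`,
#'   `absorbing` keys).
#' @export
build_mtm <- function(net, pert, spec, n_samples = 10000L, seed = NULL,
                      exhaustive_limit = 24L, budget = 2^22) {
  stopifnot(inherits(net, "boolean_network"))
  if (!inherits(pert, "perturbation")) pert <- perturbation(pert)
  check_markers(net, spec)
  pinned_net <- apply_perturbation(net, pert)

  original <- find_attractors(net, exhaustive_limit = exhaustive_limit)
  original <- score_attractors(original, spec)
  original <- estimate_basins(net, original, n_samples = n_samples,
                              seed = seed)
  regulated <- find_attractors(pinned_net,
                               exhaustive_limit = exhaustive_limit)
  regulated <- score_attractors(regulated, spec)
  regulated <- estimate_basins(pinned_net, regulated,
                               n_samples = n_samples, seed = seed)

  reg_states <- unlist(lapply(regulated, `[[`, "states"))
  orig_states <- unlist(lapply(original, `[[`, "states"))

  segments <- list()
  for (a in original) {
    seeds <- state_keys(clamp_pins(pinned_net, a$state_matrix))
    stg <- build_reachable_stg(pinned_net, seeds, absorbing = reg_states,
                               budget = budget)
    segments[[length(segments) + 1L]] <- list(
      label = "regulated", source = a$id, seeds = unique(seeds),
      stg = stg, absorbing = intersect(stg$states, reg_states))
  }
  for (r in regulated) {
    seeds <- r$states   # unpinning: state carried over unchanged
    stg <- build_reachable_stg(net, seeds, absorbing = orig_states,
                               budget = budget)
    segments[[length(segments) + 1L]] <- list(
      label = "reversal", source = r$id, seeds = unique(seeds),
      stg = stg, absorbing = intersect(stg$states, orig_states))
  }
  structure(list(net = net, pinned_net = pinned_net, pert = pert,
                 spec = spec, original = original, regulated = regulated,
                 segments = segments),
            class = "mtm")
}

#' @export
print.mtm <- function(x, ...) {
  cat("Merged transition map\n")
  cat("  perturbation: ",
      paste(names(x$pert), unclass(x$pert), sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  original landscape: ", length(x$original), " attractor(s); ",
      "regulated landscape: ", length(x$regulated), " attractor(s)\n",
      sep = "")
  for (s in x$segments)
    cat("  segment [", s$label, "] from ", s$source, ": ",
        length(s$stg$states), " states, ", nrow(s$stg$edges), " edges\n",
        sep = "")
  invisible(x)
}

#' Factorise an MTM into path ensembles
#'
#' Treats each segment's destination-landscape attractor states as
#' absorbing and computes, by absorbing-Markov-chain first-step analysis
#' with uniform branch probabilities, the probability of absorption into
#' each destination attractor and the expected per-node flip counts
#' conditional on that destination.  Each (source, destination, label)
#' triple becomes a path ensemble annotated with its phenotypic
#' preference sign `pp` (sign of the preference change), transition-type
#' sign (`+1` regulated, `-1` reversal) and significance (the source
#' attractor's basin fraction on its own landscape).  Ensembles with
#' `pp = 0` are retained and simply contribute zero to downstream scores.
#'
#' @param mtm an [build_mtm()] result.
#' @return object of class `path_ensembles`: a data.frame-like list with
#'   one row per ensemble (`source`, `dest`, `label`, `p_absorb`, `pp`,
#'   `type_sign`, `significance`) plus a `flips` matrix (ensembles x
#'   nodes) of conditional expected flip counts.
#' @export
factorize_ensembles <- function(mtm) {
  stopifnot(inherits(mtm, "mtm"))
  nodes <- mtm$net$nodes
  pref_o <- stats::setNames(
    vapply(mtm$original, `[[`, numeric(1), "preference"),
    vapply(mtm$original, `[[`, character(1), "id"))
  pref_r <- stats::setNames(
    vapply(mtm$regulated, `[[`, numeric(1), "preference"),
    vapply(mtm$regulated, `[[`, character(1), "id"))
  basin_o <- stats::setNames(
    vapply(mtm$original, `[[`, numeric(1), "basin_fraction"),
    names(pref_o))
  basin_r <- stats::setNames(
    vapply(mtm$regulated, `[[`, numeric(1), "basin_fraction"),
    names(pref_r))

  rows <- list()
  flips <- list()
  for (seg in mtm$segments) {
    dest_set <- if (seg$label == "regulated") mtm$regulated else
      mtm$original
    dest_pref <- if (seg$label == "regulated") pref_r else pref_o
    src_pref <- if (seg$label == "regulated") pref_o else pref_r
    significance <- if (seg$label == "regulated")
      basin_o[[seg$source]] else basin_r[[seg$source]]
    type_sign <- if (seg$label == "regulated") 1 else -1

    groups <- lapply(dest_set, function(d) {
      idx <- match(d$states, seg$stg$states)
      idx[!is.na(idx)]
    })
    nonempty <- vapply(groups, length, integer(1)) > 0L
    groups <- groups[nonempty]
    dests <- vapply(dest_set, `[[`, character(1), "id")[nonempty]
    if (!length(groups))
      stop("malformed segment: no reachable absorbing attractor states",
           call. = FALSE)

    init <- numeric(length(seg$stg$states))
    si <- match(seg$seeds, seg$stg$states)
    init[si] <- 1 / length(si)
    res <- absorption_from_stg(seg$stg, groups, init, flips = TRUE)
    for (g in seq_along(groups)) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = seg$source, dest = dests[g], label = seg$label,
        p_absorb = res$p_absorb[g],
        pp = sign(dest_pref[[dests[g]]] - src_pref[[seg$source]]),
        type_sign = type_sign, significance = significance,
        stringsAsFactors = FALSE)
      flips[[length(flips) + 1L]] <- res$flips[g, ]
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fm <- do.call(rbind, flips)
  colnames(fm) <- nodes
  structure(list(table = tab, flips = fm, nodes = nodes,
                 pinned = names(mtm$pert), markers = mtm$spec$markers),
            class = "path_ensembles")
}

#' @export
print.path_ensembles <- function(x, ...) {
  cat("Path ensembles (", nrow(x$table), "):\n", sep = "")
  print(cbind(x$table,
              total_flips = round(rowSums(x$flips), 3)))
  invisible(x)
}

#' Weighted flipping frequency of each node
#'
#' For every node n the score sums, over all path ensembles, the product
#' of the ensemble's significance (source basin fraction), absorption
#' probability, the node's conditional expected flip count, the
#' phenotypic-preference sign (+1 desired path, -1 undesired) and the
#' transition-type sign (+1 regulated, -1 reversal):
#' `wff(n) = sum_e significance_e * p_e * E[flips_n | e] * pp_e * type_e`.
#'
#' @param ensembles a [factorize_ensembles()] result.
#' @return object of class `target_scores`: `wff` (named vector),
#'   `decomposition` (ensembles x nodes matrix of signed contributions)
#'   and the ensemble table.
#' @export
weighted_flipping_frequency <- function(ensembles) {
  stopifnot(inherits(ensembles, "path_ensembles"))
  tab <- ensembles$table
  w <- tab$significance * tab$p_absorb * tab$pp * tab$type_sign
  decomposition <- ensembles$flips * w
  wff <- colSums(decomposition)
  structure(list(wff = wff, decomposition = decomposition,
                 table = tab, nodes = ensembles$nodes,
                 pinned = ensembles$pinned, markers = ensembles$markers,
                 flips = ensembles$flips),
            class = "target_scores")
}

#' @export
print.target_scores <- function(x, ...) {
  cat("Weighted flipping frequencies:\n")
  print(round(sort(x$wff, decreasing = TRUE), 4))
  invisible(x)
}

#' Rank synergistic partner targets
#'
#' Orders candidate nodes by weighted flipping frequency.  The default
#' ranking uses the magnitude `|wff|` (the per-ensemble decomposition is
#' retained for audit); `mode = "signed"` ranks by the signed value and
#' `mode = "undesired"` by the flip mass carried by undesired-path
#' ensembles only.  The given (pinned) target, phenotype markers and any
#' other pinned inputs are excluded from the candidate set.  Ties break
#' lexicographically by node name.
#'
#' @param scores a [weighted_flipping_frequency()] result.
#' @param k number of targets to return (default 5).
#' @param mode ranking functional (see above).
#' @param exclude additional node names to exclude.
#' @return data.frame `node`, `score`, `wff`, ordered best-first.
#' @export
rank_synergistic_targets <- function(scores, k = 5L,
                                     mode = c("magnitude", "signed",
                                              "undesired"),
                                     exclude = character(0)) {
  stopifnot(inherits(scores, "target_scores"))
  mode <- match.arg(mode)
  drop <- unique(c(scores$pinned, scores$markers, exclude))
  cand <- setdiff(scores$nodes, drop)
  if (!length(cand))
    stop("no eligible candidate nodes after exclusions", call. = FALSE)
  key <- switch(mode,
    magnitude = abs(scores$wff),
    signed = scores$wff,
    undesired = {
      tab <- scores$table
      undes <- tab$pp < 0
      if (any(undes))
        colSums((scores$flips * tab$significance * tab$p_absorb)[
          undes, , drop = FALSE])
      else stats::setNames(numeric(length(scores$nodes)), scores$nodes)
    })
  key <- key[cand]
  if (all(key == 0))
    warning("all candidate scores are zero; ranking is arbitrary",
            call. = FALSE)
  ord <- order(-key, cand)
  out <- data.frame(node = cand[ord], score = unname(key[ord]),
                    wff = unname(scores$wff[cand][ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Export an MTM as GraphML
#'
#' States become graph vertices (keyed by their 0/1 string); edges carry
#' the segment label, source attractor and uniform branch probability.
#'
#' @param mtm an [build_mtm()] result.
#' @param path output file path.
#' @export
export_mtm_graphml <- function(mtm, path) {
  stopifnot(inherits(mtm, "mtm"))
  eds <- list()
  for (seg in mtm$segments) {
    pe <- transition_probabilities(seg$stg)
    if (!nrow(pe)) next
    eds[[length(eds) + 1L]] <- data.frame(
      from = seg$stg$states[pe$from], to = seg$stg$states[pe$to],
      label = seg$label, source_attractor = seg$source,
      prob = pe$prob, flipped = seg$stg$nodes[pe$node],
      stringsAsFactors = FALSE)
  }
  eds <- do.call(rbind, eds)
  verts <- unique(c(eds$from, eds$to,
                    unlist(lapply(mtm$segments, function(s) s$stg$states))))
  ig <- igraph::graph_from_data_frame(eds, directed = TRUE,
                                      vertices = data.frame(name = verts))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
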