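# Absorbing Markov chain analysis on state-transition graphs.
#
# Branch probabilities are uniform over each transient state's outgoing
# edges.  Quantities are computed by first-step analysis:
#   h_g(s)  = P(absorbed in group g | start at s)     solve (I-Q) h = R 1_g
#   u(s)    = expected visits to transient s          solve (I-Q)' u = init
# The expected number of traversals of an edge (s -> s') that end in
# absorption at group g is u(s) * p(s,s') * h_g(s'), because absorption
# after the step depends only on s'.  Summing over the edges that flip a
# given node yields that node's expected flip count jointly with
# absorption in g; dividing by the absorption probability conditions it.

#' Uniform branch probabilities of a segment
#'
#' Every transient state distributes its transition probability evenly
#' over its outgoing edges; absorbing states have none.
#'
#' @param seg an `stg` (optionally with an `absorbing` attribute, as
#'   produced inside [build_mtm()]).
#' @return the segment's edge data.frame with a `prob` column added.
#' @export
transition_probabilities <- function(seg) {
  stopifnot(inherits(seg, "stg"))
  edges <- seg$edges
  if (!nrow(edges)) {
    edges$prob <- numeric(0)
    return(edges)
  }
  outdeg <- tabulate(edges$from, nbins = length(seg$states))
  edges$prob <- 1 / outdeg[edges$from]
  edges
}

# groups: list of integer vectors of absorbing state indices (disjoint).
# init: probability vector over all states of the stg.
# Returns list(p_absorb = numeric, flips = groups x nodes matrix of
# conditional expected flip counts, or NULL unless flips = TRUE).
absorption_from_stg <- function(stg, groups, init, flips = FALSE) {
  m <- length(stg$states)
  stopifnot(length(init) == m, abs(sum(init) - 1) < 1e-9)
  absorbing <- sort(unique(unlist(groups)))
  transient <- setdiff(seq_len(m), absorbing)
  edges <- stg$edges
  edges <- edges[edges$from %in% transient, , drop = FALSE]
  outdeg <- tabulate(edges$from, nbins = m)
  if (length(transient) && any(outdeg[transient] == 0L))
    stop("malformed segment: transient state(s) with no outgoing edge ",
         "cannot reach the absorbing set", call. = FALSE)
  ng <- length(groups)
  nn <- length(stg$nodes)
  group_of <- integer(m)
  for (g in seq_len(ng)) group_of[groups[[g]]] <- g

  if (!length(transient)) {
    p <- vapply(seq_len(ng), function(g) sum(init[groups[[g]]]), numeric(1))
    fl <- if (flips) matrix(0, ng, nn, dimnames = list(NULL, stg$nodes))
    return(list(p_absorb = p, flips = fl))
  }

  t_index <- match(seq_len(m), transient)      # NA for absorbing
  prob <- 1 / outdeg[edges$from]
  into_trans <- !is.na(t_index[edges$to])
  Q <- Matrix::sparseMatrix(
    i = t_index[edges$from[into_trans]],
    j = t_index[edges$to[into_trans]],
    x = prob[into_trans],
    dims = c(length(transient), length(transient)))
  A <- Matrix::Diagonal(length(transient)) - Q

  # h_g on all states: 1 on group g, 0 on other absorbing, solved on T
  H <- matrix(0, m, ng)
  for (g in seq_len(ng)) H[groups[[g]], g] <- 1
  into_abs <- !into_trans
  rhs <- matrix(0, length(transient), ng)
  if (any(into_abs)) {
    ia <- which(into_abs)
    ga <- group_of[edges$to[ia]]
    keep <- ga > 0L
    ia <- ia[keep]; ga <- ga[keep]
    ti <- t_index[edges$from[ia]]
    pr <- prob[ia]
    for (g in unique(ga)) {
      sel <- ga == g
      rhs[, g] <- rhs[, g] +
        as.numeric(tapply_sum(ti[sel], pr[sel], length(transient)))
    }
  }
  Ht <- as.matrix(Matrix::solve(A, rhs))
  H[transient, ] <- Ht

  p_absorb <- as.numeric(crossprod(H, init))

  fl <- NULL
  if (flips) {
    u <- as.numeric(Matrix::solve(Matrix::t(A), init[transient]))
    fl <- matrix(0, ng, nn, dimnames = list(NULL, stg$nodes))
    w <- u[t_index[edges$from]] * prob          # traversal weight per edge
    for (g in seq_len(ng)) {
      wg <- w * H[edges$to, g]
      if (!any(wg > 0)) next
      per_node <- tapply_sum(edges$node, wg, nn)
      fl[g, ] <- per_node
    }
    pos <- p_absorb > 0
    fl[pos, ] <- fl[pos, , drop = FALSE] / p_absorb[pos]
    fl[!pos, ] <- 0
  }
  list(p_absorb = p_absorb, flips = fl)
}

tapply_sum <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}
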