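# Seeded generators of synthetic Boolean networks embodying the
# structures the method analyses: bistable positive-feedback motifs,
# mutual inhibition mediated by an interconnecting node, a perturbation
# input upstream of both motifs, and phenotype markers.

#' Minimal bistable unit
#'
#' The two-node toggle `A = !B`, `B = !A`: two point attractors `10` and
#' `01` with equal basins.
#'
#' @return a [boolean_network()].
#' @export
make_toggle <- function() {
  boolean_network(c(A = "!B", B = "!A"))
}

#' Generate a motif-conflict network with ground-truth annotation
#'
#' Constructs a network in which a perturbation input `P` (the given
#' drug target, nominally OFF) drives two positive-feedback motifs: the
#' "yellow" motif `Y1..Ya` whose activity produces the desired marker
#' `M`, and the "green" motif `G1..Gb` producing the resistance marker
#' `R`.  The motifs mutually inhibit one another: the yellow terminal
#' inhibits the green motif directly, while the green motif inhibits
#' yellow through a chain of interconnecting nodes `I1..Id`, an
#' inhibition that is only engaged while the perturbation is applied
#' (the drug-induced bypass responsible for adaptive resistance).
#' Pinning `P = 1` activates both motifs and their conflict resolves
#' stochastically into a yellow-win (desired) or a green-win (resistant)
#' attractor — the heterogeneous response the merged-transition-map
#' analysis targets.  Pinning the terminal interconnector OFF alongside
#' `P` removes the conflict and leaves a single desired attractor.
#'
#' The construction is deterministic for a given spec; `seed` is
#' recorded in the annotation for provenance.
#'
#' @param motif_sizes integer pair: chain length of each motif (>= 2).
#' @param interconnect_depth number of interconnecting nodes (>= 1).
#' @param marker_layout `"yellow"` (default) or `"green"`: which motif
#'   drives the desired marker (green swaps the motif roles).
#' @param seed integer recorded in the annotation.
#' @return a list with `net` (a [boolean_network()]), `phenotype`
#'   (a [phenotype_spec()]) and `annotation` (designed motif node sets,
#'   interconnectors, perturbation, and the intended optimal pair).
#' @export
make_conflict_network <- function(motif_sizes = c(2L, 2L),
                                  interconnect_depth = 1L,
                                  marker_layout = c("yellow", "green"),
                                  seed = 1L) {
  marker_layout <- match.arg(marker_layout)
  a <- as.integer(motif_sizes[1L]); b <- as.integer(motif_sizes[2L])
  d <- as.integer(interconnect_depth)
  if (a < 2L || b < 2L) stop("motif sizes must be >= 2", call. = FALSE)
  if (d < 1L) stop("interconnect_depth must be >= 1", call. = FALSE)
  yl <- if (marker_layout == "yellow") "Y" else "G"
  gl <- if (marker_layout == "yellow") "G" else "Y"
  Y <- paste0(yl, seq_len(a))
  G <- paste0(gl, seq_len(b))
  I <- paste0("I", seq_len(d))
  rules <- c(P = "0")
  # desired-side positive cycle, OR-injection of P; the interconnect's
  # inhibition of its terminal is engaged only under the perturbation
  rules[Y[1L]] <- paste0("P | ", Y[a])
  if (a > 2L) for (j in 2:(a - 1L)) rules[Y[j]] <- Y[j - 1L]
  rules[Y[a]] <- paste0(Y[a - 1L], " & !(P & ", I[d], ")")
  # resistant-side positive cycle, OR-injection of P, inhibited directly
  # by the desired-side terminal
  rules[G[1L]] <- paste0("P | ", G[b])
  if (b > 2L) for (j in 2:(b - 1L)) rules[G[j]] <- G[j - 1L]
  rules[G[b]] <- paste0(G[b - 1L], " & !", Y[a])
  # interconnect chain relaying the resistant terminal towards yellow
  rules[I[1L]] <- G[b]
  if (d > 1L) for (j in 2:d) rules[I[j]] <- I[j - 1L]
  rules["M"] <- paste0(Y[a], " & !", G[b])
  rules["R"] <- G[b]
  net <- boolean_network(rules)
  pheno <- phenotype_spec(M = 1, R = -1)
  pinned <- apply_perturbation(net, perturbation(P = 1))
  reg <- find_attractors(pinned)
  if (length(reg) < 2L)
    stop("degenerate conflict fixture: fewer than 2 regulated attractors",
         call. = FALSE)
  list(
    net = net,
    phenotype = pheno,
    annotation = list(
      seed = as.integer(seed),
      perturbation = list(node = "P", type = "ON"),
      motifs = stats::setNames(list(Y, G),
                               if (marker_layout == "yellow")
                                 c("yellow", "green") else
                                 c("green", "yellow")),
      interconnectors = I,
      markers = c(M = 1, R = -1),
      optimal_pair = list(node = I[d], type = "OFF")))
}

#' Generate the four-motif exemplar network
#'
#' A richer, figure-style fixture: the conflict core of
#' [make_conflict_network()] plus a "purple" motif driven by the
#' perturbation but not interacting with the others, and a "blue" motif
#' not regulated by the perturbation whose bistability survives only when
#' the green motif loses.  With `P` pinned ON the network converges to
#' exactly three attractors: two with the yellow motif winning (blue
#' free), one with the green motif winning (blue forced ON).
#'
#' @return a list as in [make_conflict_network()].
#' @export
make_exemplar_network <- function() {
  fx <- make_conflict_network()
  rules <- vapply(fx$net$nodes, function(nm)
    deparse_rule(fx$net$rules[[nm]]), character(1))
  rules <- c(rules,
             U1 = "P | U2", U2 = "U1",      # purple: driven, isolated
             B1 = "B2 | G2", B2 = "B1")     # blue: not driven by P
  net <- boolean_network(rules)
  ann <- fx$annotation
  ann$motifs$purple <- c("U1", "U2")
  ann$motifs$blue <- c("B1", "B2")
  list(net = net, phenotype = fx$phenotype, annotation = ann)
}

#' Generate a random Boolean network
#'
#' Each node receives a random regulator set (in-degree `1 +
#' Poisson(mean_degree - 1)`, capped at `max_degree`, so the mean tracks
#' the request) and a random truth-table rule with ON-bias `bias`,
#' rendered as a disjunctive normal form over the regulators.  Seeded
#' and fully deterministic for a given seed.
#'
#' @param n number of nodes (>= 2).
#' @param mean_degree target mean in-degree (default 2).
#' @param bias probability of output 1 per truth-table row (default 0.5).
#' @param seed integer RNG seed.
#' @param max_degree cap on the in-degree (default 3, keeps rules small).
#' @return a [boolean_network()].
#' @export
make_random_boolean_network <- function(n, mean_degree = 2, bias = 0.5,
                                        seed = 1L, max_degree = 3L) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  nodes <- paste0("N", seq_len(n))
  rules <- character(n)
  for (i in seq_len(n)) {
    k <- min(max_degree, n - 1L,
             1L + stats::rpois(1L, lambda = max(0, mean_degree - 1)))
    regs <- sample(setdiff(nodes, nodes[i]), k)
    tt <- stats::rbinom(2^k, 1L, bias)
    rules[i] <- truth_table_to_rule(regs, tt)
  }
  boolean_network(stats::setNames(rules, nodes))
}

# DNF rendering of a truth table over regulators (row order: regulator 1
# varies fastest, 0 before 1).
truth_table_to_rule <- function(regs, tt) {
  k <- length(regs)
  if (all(tt == 0L)) return("0")
  if (all(tt == 1L)) return("1")
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  terms <- apply(grid[tt == 1L, , drop = FALSE], 1L, function(row) {
    lits <- ifelse(row == 1L, regs, paste0("!", regs))
    if (k == 1L) lits else paste0("(", paste(lits, collapse = " & "), ")")
  })
  paste(terms, collapse = " | ")
}
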