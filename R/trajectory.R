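# Random asynchronous trajectory simulation: the Monte Carlo counterpart
# of the absorbing-chain analysis, and the source of per-path flip ratios.

#' Sample one asynchronous trajectory
#'
#' Starting from `s0`, repeatedly flips one uniformly-chosen eligible node
#' until a state in `absorbing` is reached (or no node is eligible).
#'
#' @param net a [boolean_network()].
#' @param s0 initial state (named 0/1 vector or key string); pinned bits
#'   are clamped.
#' @param absorbing character vector of absorbing state keys; defaults to
#'   stopping only at fixed points.
#' @param max_steps step budget (default `10000 * n_nodes`).
#' @return object of class `trajectory`: list with `states` (matrix, one
#'   row per visited state including the start), `keys`, `flipped`
#'   (integer vector of flipped node indices, one per transition).
#' @export
sample_trajectory <- function(net, s0, absorbing = character(0),
                              max_steps = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  nodes <- net$nodes
  if (is.character(s0)) s0 <- key_to_state(s0, nodes)
  S <- matrix(as.integer(s0[nodes]), 1L, dimnames = list(NULL, nodes))
  S <- clamp_pins(net, S)
  if (is.null(max_steps)) max_steps <- 10000L * length(nodes)
  pins <- match(names(pinned_values(net)), nodes)
  path <- S
  flipped <- integer(0)
  repeat {
    if (state_keys(S) %in% absorbing) break
    nx <- next_values(net, S)
    elig <- setdiff(which(nx[1L, ] != S[1L, ]), pins)
    if (!length(elig)) break
    j <- if (length(elig) == 1L) elig else sample(elig, 1L)
    S[1L, j] <- 1L - S[1L, j]
    path <- rbind(path, S)
    flipped <- c(flipped, j)
    if (length(flipped) >= max_steps)
      stop("trajectory exceeded step budget", call. = FALSE)
  }
  structure(list(states = path, keys = state_keys(path), flipped = flipped,
                 nodes = nodes), class = "trajectory")
}

#' Per-node state-flipping ratio of a trajectory
#'
#' The number of state flips of each node divided by the total number of
#' state transitions along the path; the ratios are in \[0, 1\] and sum
#' to 1 over nodes (each transition flips exactly one node).
#'
#' @param path a `trajectory` from [sample_trajectory()].
#' @return named numeric vector over nodes.
#' @export
flip_ratio <- function(path) {
  stopifnot(inherits(path, "trajectory"))
  m <- length(path$flipped)
  if (m == 0L)
    stop("trajectory has no transitions; flip ratio undefined",
         call. = FALSE)
  counts <- tabulate(path$flipped, nbins = length(path$nodes))
  stats::setNames(counts / m, path$nodes)
}

#' Batch Monte Carlo trajectories with flip accounting
#'
#' Runs one random asynchronous trajectory from each row of `starts`
#' until a state in `absorbing` is reached, counting per-node flips.
#' Used as the independent stochastic oracle for the absorbing-chain
#' expected flip counts.
#'
#' @param net a [boolean_network()].
#' @param starts matrix of initial states (rows) or character keys.
#' @param absorbing character vector of absorbing state keys.
#' @param seed optional RNG seed.
#' @param max_steps per-trajectory step budget (default `10000 *
#'   n_nodes`).
#' @return list with `final` (absorbing key per trajectory), `flips`
#'   (trajectories x nodes matrix), `transitions` (steps per trajectory).
#' @export
simulate_trajectories <- function(net, starts, absorbing, seed = NULL,
                                  max_steps = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  nodes <- net$nodes
  if (is.character(starts)) starts <- keys_to_matrix(starts, nodes)
  S <- clamp_pins(net, starts)
  storage.mode(S) <- "integer"
  m <- nrow(S)
  if (is.null(max_steps)) max_steps <- 10000L * length(nodes)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  pins <- pinned_values(net)
  flips <- matrix(0L, m, length(nodes), dimnames = list(NULL, nodes))
  transitions <- integer(m)
  final <- character(m)
  active <- seq_len(m)
  done <- state_keys(S) %in% absorbing
  final[active[done]] <- state_keys(S)[done]
  active <- active[!done]
  steps <- 0L
  while (length(active)) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop(length(active), " trajectories exceeded the step budget",
           call. = FALSE)
    A <- S[active, , drop = FALSE]
    nx <- next_values(net, A)
    if (length(pins)) for (nm in names(pins)) nx[, nm] <- pins[[nm]]
    elig <- nx != A
    nelig <- rowSums(elig)
    if (any(nelig == 0L))
      stop("trajectory reached a fixed point outside the absorbing set",
           call. = FALSE)
    pick <- pick_uniform(elig)
    idx <- cbind(seq_len(nrow(A)), pick)
    A[idx] <- 1L - A[idx]
    fidx <- cbind(active, pick)
    flips[fidx] <- flips[fidx] + 1L
    transitions[active] <- transitions[active] + 1L
    S[active, ] <- A
    k <- state_keys(A)
    hit <- k %in% absorbing
    final[active[hit]] <- k[hit]
    active <- active[!hit]
  }
  list(final = final, flips = flips, transitions = transitions)
}
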