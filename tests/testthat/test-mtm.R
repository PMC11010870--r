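# Merged transition map construction, path-ensemble factorisation,
# weighted flipping frequencies and ranking.

toggle_mtm <- function() {
  build_mtm(make_toggle(), perturbation(A = 1), phenotype_spec(A = 1))
}

test_that("MTM segments link the two landscapes as specified", {
  m <- toggle_mtm()
  expect_length(m$original, 2L)
  expect_length(m$regulated, 1L)
  labels <- vapply(m$segments, `[[`, character(1), "label")
  expect_identical(sort(unique(labels)), c("regulated", "reversal"))
  # one regulated segment per original attractor, one reversal per
  # regulated attractor
  expect_identical(sum(labels == "regulated"), 2L)
  expect_identical(sum(labels == "reversal"), 1L)
  # regulated segments absorb at regulated-landscape attractor states
  reg_states <- unlist(lapply(m$regulated, `[[`, "states"))
  for (seg in m$segments[labels == "regulated"])
    expect_true(all(seg$absorbing %in% reg_states))
})

test_that("branch probabilities are uniform over outgoing edges", {
  tg <- make_toggle()
  stg <- build_reachable_stg(tg, "00")
  pe <- transition_probabilities(stg)
  expect_equal(pe$prob, rep(0.5, 2))
  # probabilities out of every transient state sum to 1
  fx <- make_conflict_network()
  pinned <- apply_perturbation(fx$net, perturbation(P = 1))
  reg <- find_attractors(pinned)
  stg2 <- build_reachable_stg(pinned, strrep("0", 8L),
                              absorbing = unlist(lapply(reg, `[[`, "states")))
  pe2 <- transition_probabilities(stg2)
  sums <- tapply(pe2$prob, pe2$from, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("toggle factorisation reproduces the two-branch hand values", {
  # from (0,0), absorbing at the two fixed points, each branch has
  # probability 1/2 and flips exactly the node that moved
  tg <- make_toggle()
  stg <- build_reachable_stg(tg, "00", absorbing = c("10", "01"))
  groups <- list(match("10", stg$states), match("01", stg$states))
  init <- numeric(3); init[match("00", stg$states)] <- 1
  res <- mtmap:::absorption_from_stg(stg, groups, init, flips = TRUE)
  expect_equal(res$p_absorb, c(0.5, 0.5))
  expect_equal(res$flips[1, ], c(A = 1, B = 0))
  expect_equal(res$flips[2, ], c(A = 0, B = 1))
})

test_that("ensemble invariants hold on toggle and conflict MTMs", {
  for (m in list(toggle_mtm(),
                 build_mtm(make_conflict_network()$net,
                           perturbation(P = 1),
                           phenotype_spec(M = 1, R = -1)))) {
    ens <- factorize_ensembles(m)
    tab <- ens$table
    # absorption probabilities sum to 1 per (source, label)
    sums <- tapply(tab$p_absorb, paste(tab$source, tab$label), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    # flips are nonnegative; pinned nodes never flip in regulated
    # segments
    expect_true(all(ens$flips >= -1e-12))
    pinned <- names(m$pert)
    expect_true(all(ens$flips[tab$label == "regulated", pinned] == 0))
    # pp is the sign of the preference change
    pref <- c(
      stats::setNames(vapply(m$original, `[[`, numeric(1), "preference"),
                      paste0("o", vapply(m$original, `[[`, character(1), "id"))),
      stats::setNames(vapply(m$regulated, `[[`, numeric(1), "preference"),
                      paste0("r", vapply(m$regulated, `[[`, character(1), "id"))))
    for (i in seq_len(nrow(tab))) {
      src <- pref[[paste0(if (tab$label[i] == "regulated") "o" else "r",
                          tab$source[i])]]
      dst <- pref[[paste0(if (tab$label[i] == "regulated") "r" else "o",
                          tab$dest[i])]]
      expect_identical(tab$pp[i], sign(dst - src))
    }
  }
})

test_that("trivial segments absorb immediately with zero flips", {
  # pinning A=1 leaves the attractor (1,0) stable: its regulated segment
  # is source = dest with probability 1 and no flips
  m <- toggle_mtm()
  ens <- factorize_ensembles(m)
  tab <- ens$table
  triv <- tab$label == "regulated" & tab$source == "A2"
  expect_equal(tab$p_absorb[triv], 1)
  expect_true(all(ens$flips[triv, ] == 0))
})

test_that("expected flips match Monte Carlo trajectories within 3 SE", {
  fx <- make_conflict_network()
  net <- fx$net
  pinned <- apply_perturbation(net, perturbation(P = 1))
  reg <- find_attractors(pinned)
  reg_states <- unlist(lapply(reg, `[[`, "states"))
  m <- build_mtm(net, perturbation(P = 1), fx$phenotype)
  ens <- factorize_ensembles(m)
  # heterogeneous source: the all-off original attractor
  src <- "00000000"
  n_traj <- 4000L
  sim <- simulate_trajectories(
    pinned, rep(src, n_traj), absorbing = reg_states, seed = 99)
  lut <- stats::setNames(rep(seq_along(reg),
                             vapply(reg, function(a) length(a$states),
                                    integer(1))),
                         reg_states)
  dest_id <- vapply(reg, `[[`, character(1), "id")[lut[sim$final]]
  tab <- ens$table
  for (d in unique(dest_id)) {
    sel <- dest_id == d
    row <- which(tab$label == "regulated" & tab$source == "A1" &
                   tab$dest == d)
    p_hat <- mean(sel)
    expect_lt(abs(p_hat - tab$p_absorb[row]),
              3 * sqrt(p_hat * (1 - p_hat) / n_traj) + 1e-6)
    for (nd in net$nodes) {
      f <- sim$flips[sel, nd]
      se <- stats::sd(f) / sqrt(sum(sel))
      expect_lt(abs(mean(f) - ens$flips[row, nd]), 3 * se + 1e-6)
    }
  }
})

test_that("weighted flipping frequency is the signed ensemble sum", {
  m <- toggle_mtm()
  ens <- factorize_ensembles(m)
  sc <- weighted_flipping_frequency(ens)
  tab <- ens$table
  manual <- colSums(ens$flips * tab$significance * tab$p_absorb *
                      tab$pp * tab$type_sign)
  expect_equal(sc$wff, manual)
  expect_equal(colSums(sc$decomposition), sc$wff)
  # equal preferences at both ends => pp = 0 everywhere => zero wff
  e2 <- factorize_ensembles(
    build_mtm(boolean_network(c(A = "A", B = "B")),
              perturbation(A = 1), phenotype_spec(B = 1)))
  expect_true(all(e2$table$pp == 0))
  expect_true(all(weighted_flipping_frequency(e2)$wff == 0))
})

test_that("wff is equivariant under node relabeling", {
  fx <- make_conflict_network()
  rules <- vapply(fx$net$nodes, function(n)
    mtmap:::deparse_rule(fx$net$rules[[n]]), character(1))
  # reverse declaration order (a pure relabeling of positions)
  net2 <- boolean_network(rev(rules))
  spec <- phenotype_spec(M = 1, R = -1)
  w1 <- weighted_flipping_frequency(
    factorize_ensembles(build_mtm(fx$net, perturbation(P = 1), spec)))$wff
  w2 <- weighted_flipping_frequency(
    factorize_ensembles(build_mtm(net2, perturbation(P = 1), spec)))$wff
  expect_equal(w1[sort(names(w1))], w2[sort(names(w2))])
})

test_that("ranking excludes the given target and markers, breaks ties", {
  fx <- make_conflict_network()
  spec <- phenotype_spec(M = 1, R = -1)
  sc <- weighted_flipping_frequency(
    factorize_ensembles(build_mtm(fx$net, perturbation(P = 1), spec)))
  rk <- rank_synergistic_targets(sc, k = 10)
  expect_false(any(c("P", "M", "R") %in% rk$node))
  expect_identical(rk$node[1L], "I1")
  # modes give finite, ordered scores
  for (mode in c("magnitude", "signed", "undesired")) {
    r <- rank_synergistic_targets(sc, k = 3, mode = mode)
    expect_true(all(diff(r$score) <= 1e-12))
  }
  expect_error(rank_synergistic_targets(sc, exclude = setdiff(
    fx$net$nodes, c("P", "M", "R"))), "no eligible")
  # degenerate all-zero scores are flagged
  sc0 <- weighted_flipping_frequency(factorize_ensembles(
    build_mtm(boolean_network(c(A = "A", B = "B", C = "C")),
              perturbation(A = 1), phenotype_spec(B = 1))))
  expect_warning(rank_synergistic_targets(sc0, k = 1), "zero")
})

test_that("flip ratio normalises per-node flips by path length", {
  tg <- make_toggle()
  set.seed(1)
  tr <- sample_trajectory(tg, c(A = 0, B = 0))
  fr <- flip_ratio(tr)
  expect_equal(sum(fr), 1)
  expect_true(all(fr >= 0 & fr <= 1))
  # Hamming-1 path: single node carries the whole ratio
  p1 <- apply_perturbation(tg, perturbation(A = 1, B = 0))
  tr2 <- sample_trajectory(
    boolean_network(c(A = "1", B = "B")), c(A = 0, B = 0))
  expect_equal(flip_ratio(tr2), c(A = 1, B = 0))
  # zero-length trajectories are an error
  tr3 <- sample_trajectory(tg, c(A = 1, B = 0))
  expect_error(flip_ratio(tr3), "no transitions")
})

test_that("MTM GraphML export contains the segment structure", {
  m <- toggle_mtm()
  path <- withr::local_tempfile(fileext = ".graphml")
  export_mtm_graphml(m, path)
  ig <- igraph::read_graph(path, format = "graphml")
  all_states <- unique(unlist(lapply(m$segments,
                                     function(s) s$stg$states)))
  expect_identical(igraph::vcount(ig), as.numeric(length(all_states)))
  expect_true(all(igraph::E(ig)$label %in% c("regulated", "reversal")))
  expect_true(all(igraph::E(ig)$prob > 0 & igraph::E(ig)$prob <= 1))
})
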