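# Asynchronous dynamics: successors, reachable STGs, constant-node
# reduction, attractor identification, basins, phenotype preference.

test_that("async successors flip exactly the eligible nodes", {
  tg <- make_toggle()
  succ <- async_successors(tg, c(A = 0, B = 0))
  keys <- sort(vapply(succ, paste0, character(1), collapse = ""))
  expect_identical(keys, c("01", "10"))
  expect_length(async_successors(tg, c(A = 1, B = 0)), 0L)
  # every successor differs in exactly one unpinned node
  net <- make_conflict_network()$net
  s <- c(P = 0, Y1 = 1, Y2 = 0, G1 = 1, G2 = 0, I1 = 1, M = 1, R = 1)
  for (t in async_successors(net, s))
    expect_identical(sum(t != s[net$nodes]), 1L)
})

test_that("reachable STG is the BFS closure with absorbing cut-off", {
  tg <- make_toggle()
  stg <- build_reachable_stg(tg, "00")
  expect_setequal(stg$states, c("00", "10", "01"))
  expect_identical(nrow(stg$edges), 2L)
  # a fixed-point seed closes immediately
  stg2 <- build_reachable_stg(tg, "10")
  expect_identical(stg2$states, "10")
  expect_identical(nrow(stg2$edges), 0L)
  # absorbing states are kept but not expanded
  stg3 <- build_reachable_stg(tg, "00", absorbing = c("10", "01"))
  expect_setequal(stg3$states, c("00", "10", "01"))
  expect_identical(nrow(stg3$edges), 2L)
  # budget violations surface as explicit capacity errors
  big <- make_random_boolean_network(12, seed = 1)
  expect_error(build_reachable_stg(big, strrep("0", 12), budget = 4),
               "budget")
})

test_that("constant-node reduction propagates forced values", {
  tg <- make_toggle()
  red <- reduce_by_constants(apply_perturbation(tg, perturbation(A = 1)))
  expect_null(red$residual)
  expect_identical(red$fixed, c(A = 1L, B = 0L))

  # no constants: network unchanged
  red2 <- reduce_by_constants(tg)
  expect_length(red2$fixed, 0L)
  expect_identical(red2$residual$nodes, tg$nodes)

  chain <- boolean_network(c(A = "1", B = "A", C = "!B"))
  red3 <- reduce_by_constants(chain)
  expect_null(red3$residual)
  expect_identical(red3$fixed, c(A = 1L, B = 1L, C = 0L))
})

test_that("reduction preserves attractors on random networks", {
  for (seed in 1:10) {
    net <- make_random_boolean_network(sample(4:9, 1), seed = seed + 100)
    pinned <- apply_perturbation(
      net, perturbation(stats::setNames(seed %% 2L, net$nodes[1L])))
    for (n in list(net, pinned)) {
      red <- reduce_by_constants(n)
      expect_identical(att_key_sets(find_attractors(n)),
                       oracle_attractors(n))
    }
  }
})

test_that("attractors equal terminal SCCs of the brute-force STG", {
  tg <- make_toggle()
  atts <- find_attractors(tg)
  expect_identical(att_key_sets(atts), list("01", "10"))
  expect_identical(vapply(atts, `[[`, character(1), "kind"),
                   c("point", "point"))

  # 3-node negative loop: one complex attractor, no fixed point
  osc <- boolean_network(c(A = "!C", B = "A", C = "B"))
  aosc <- find_attractors(osc)
  expect_length(aosc, 1L)
  expect_identical(aosc[[1]]$kind, "complex")
  expect_identical(att_key_sets(aosc), oracle_attractors(osc))

  # randomized property: exact match against the independent oracle
  for (seed in 1:20) {
    net <- make_random_boolean_network(sample(4:10, 1), mean_degree = 2,
                                       seed = seed)
    expect_identical(att_key_sets(find_attractors(net)),
                     oracle_attractors(net))
  }
})

test_that("every reported attractor is closed under async updates", {
  for (seed in 21:30) {
    net <- make_random_boolean_network(sample(4:10, 1), seed = seed)
    for (a in find_attractors(net)) {
      for (k in a$states) {
        succ <- async_successors(net, k)
        for (s in succ)
          expect_true(paste0(s, collapse = "") %in% a$states)
      }
    }
  }
})

test_that("seeded attractor search finds the reachable attractors", {
  net <- make_conflict_network()$net
  pinned <- apply_perturbation(net, perturbation(P = 1))
  full <- find_attractors(pinned)
  seeded <- find_attractors(pinned, exhaustive_limit = 0L,
                            seeds = strrep("0", 8L))
  expect_identical(att_key_sets(seeded), att_key_sets(full))
})

test_that("basin estimation is exact in exhaustive mode", {
  tg <- make_toggle()
  atts <- estimate_basins(tg, find_attractors(tg), n_samples = 10000)
  expect_identical(vapply(atts, `[[`, numeric(1), "basin_fraction"),
                   c(0.5, 0.5))
  expect_identical(attr(atts, "censored"), 0)

  # single attractor gets the whole state space
  one <- boolean_network(c(A = "1", B = "A"))
  b1 <- estimate_basins(one, find_attractors(one), n_samples = 100)
  expect_equal(b1[[1]]$basin_fraction, 1)
})

test_that("sampled basins agree across seeds within Monte Carlo error", {
  # 15 free nodes forces sampling; two runs with different seeds agree
  # within 3 binomial standard errors
  net <- make_random_boolean_network(15, mean_degree = 2, seed = 7)
  atts <- find_attractors(net)
  n <- 2000L
  b1 <- estimate_basins(net, atts, n_samples = n, seed = 11)
  b2 <- estimate_basins(net, atts, n_samples = n, seed = 12)
  for (i in seq_along(atts)) {
    p1 <- b1[[i]]$basin_fraction
    p2 <- b2[[i]]$basin_fraction
    se <- sqrt(max(p1 * (1 - p1), 1e-4) / n)
    expect_lt(abs(p1 - p2), 3 * se + 3 * se)
  }
  # determinism under a fixed seed
  b3 <- estimate_basins(net, atts, n_samples = n, seed = 11)
  expect_identical(vapply(b1, `[[`, numeric(1), "basin_fraction"),
                   vapply(b3, `[[`, numeric(1), "basin_fraction"))
})

test_that("phenotype preference averages marker activity over states", {
  tg <- make_toggle()
  atts <- find_attractors(tg)
  spec <- phenotype_spec(A = 1)
  prefs <- sort(vapply(atts, phenotype_preference, numeric(1),
                       spec = spec))
  expect_identical(prefs, c(0, 1))

  # complex attractor: uniform average across its states
  osc <- boolean_network(c(A = "!C", B = "A", C = "B"))
  a <- find_attractors(osc)[[1]]
  expect_equal(phenotype_preference(a, phenotype_spec(A = 1)),
               mean(a$state_matrix[, "A"]))

  # opposing markers: desired attractor scores +1 unnormalised
  net <- boolean_network(c(anti = "anti", pro = "!anti"))
  spec2 <- phenotype_spec(anti = 1, pro = -1, normalize = FALSE)
  a2 <- find_attractors(net)
  scored <- sort(vapply(a2, phenotype_preference, numeric(1), spec2))
  expect_identical(scored, c(-1, 1))
})
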