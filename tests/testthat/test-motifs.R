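# Multi-stable motif detection, interconnecting nodes, conflict-pair
# census, degree-preserving randomisation and table curation.

test_that("the toggle is a single two-node multi-stable motif", {
  tg <- make_toggle()
  atts <- find_attractors(tg)
  mots <- find_multistable_motifs(tg, atts)
  expect_length(mots, 1L)
  expect_setequal(mots[[1]]$nodes, c("A", "B"))
  expect_identical(mots[[1]]$stable_projections, c("01", "10"))
})

test_that("acyclic networks have no motifs", {
  chain <- boolean_network(c(A = "A", B = "A", C = "!B"))
  atts <- find_attractors(chain)
  mots <- find_multistable_motifs(chain, atts)
  # the self-input A is the only feedback unit
  expect_true(all(vapply(mots, function(m) identical(m$nodes, "A"),
                         logical(1))))
  dag <- signed_graph(c("A", "B", "C"),
                      data.frame(from = c("A", "B"), to = c("B", "C"),
                                 sign = c(1L, -1L)))
  expect_identical(count_conflict_motif_pairs(dag), 0L)
})

test_that("conflict fixture yields its two designed motifs", {
  fx <- make_conflict_network()
  ao <- find_attractors(fx$net)
  ar <- find_attractors(apply_perturbation(fx$net, perturbation(P = 1)))
  mots <- find_multistable_motifs(fx$net, c(unclass(ao), unclass(ar)))
  sets <- lapply(mots, `[[`, "nodes")
  expect_length(mots, 2L)
  expect_true(any(vapply(sets, setequal, logical(1),
                         fx$annotation$motifs[[1]])))
  expect_true(any(vapply(sets, setequal, logical(1),
                         fx$annotation$motifs[[2]])))
  # every reported motif is strongly connected (independent check)
  g <- derive_signed_graph(fx$net)
  ig <- as_igraph_signed(g)
  for (s in sets) {
    sub <- igraph::induced_subgraph(ig, s)
    expect_equal(igraph::components(sub, mode = "strong")$no, 1)
  }
})

test_that("interconnectors are interior nodes of k-shortest paths", {
  fx <- make_conflict_network()
  g <- derive_signed_graph(fx$net)
  ao <- find_attractors(fx$net)
  mots <- find_multistable_motifs(fx$net, ao)
  ylw <- mots[[which(vapply(mots, function(m) "Y1" %in% m$nodes,
                            logical(1)))]]
  grn <- mots[[which(vapply(mots, function(m) "G1" %in% m$nodes,
                            logical(1)))]]
  ic <- interconnecting_nodes(g, grn, ylw, k = 10)
  expect_identical(ic$interconnectors$node[1L], "I1")
  # all paths simple and sorted by nondecreasing length per direction
  for (d in unique(ic$paths$direction)) {
    lens <- ic$paths$length[ic$paths$direction == d]
    expect_true(all(diff(sort(lens)) >= 0))
  }
  # net signs multiply edge signs: mutual inhibition is net-negative
  expect_true(all(ic$paths$net_sign == -1))

  # unique two-hop path
  g2 <- signed_graph(c("a", "i", "b"),
                     data.frame(from = c("a", "i"), to = c("i", "b"),
                                sign = c(1L, -1L)))
  ic2 <- interconnecting_nodes(g2, "a", "b")
  expect_identical(ic2$interconnectors$node, "i")
  # disconnected motifs give an empty ranking, not an error
  g3 <- signed_graph(c("a", "b"), data.frame(from = character(0),
                                             to = character(0),
                                             sign = integer(0)))
  ic3 <- interconnecting_nodes(g3, "a", "b")
  expect_identical(nrow(ic3$interconnectors), 0L)
})

test_that("k-shortest paths agree with brute-force enumeration", {
  for (seed in 1:8) {
    net <- make_random_boolean_network(sample(4:7, 1), mean_degree = 2,
                                       seed = seed + 40)
    g <- derive_signed_graph(net)
    from <- net$nodes[1L]; to <- net$nodes[2L]
    ig <- igraph::graph_from_data_frame(
      unique(g$edges[, c("from", "to")]), directed = TRUE,
      vertices = data.frame(name = g$nodes))
    got <- tryCatch(
      suppressWarnings(
        igraph::k_shortest_paths(ig, from = from, to = to, k = 5)$vpaths),
      error = function(e) list())
    want <- oracle_simple_paths(g, from, to)
    got_n <- lapply(got, igraph::as_ids)
    expect_identical(length(got_n), min(5L, length(want)))
    if (length(got_n)) {
      # sorted lengths match the k shortest of the enumeration
      expect_identical(sort(lengths(got_n)),
                       sort(lengths(want))[seq_along(got_n)])
      # all returned paths are simple and real
      for (p in got_n) {
        expect_false(anyDuplicated(p) > 0)
        expect_true(any(vapply(want, identical, logical(1), p)))
      }
    }
  }
})

test_that("conflict-pair census matches brute force on small graphs", {
  fx <- make_conflict_network()
  g <- derive_signed_graph(fx$net)
  expect_gte(count_conflict_motif_pairs(g), 1L)
  expect_identical(count_conflict_motif_pairs(g),
                   oracle_conflict_pairs(g))
  for (seed in 1:10) {
    net <- make_random_boolean_network(sample(4:8, 1), mean_degree = 2,
                                       seed = seed + 60)
    gg <- derive_signed_graph(net)
    expect_identical(count_conflict_motif_pairs(gg),
                     oracle_conflict_pairs(gg))
  }
  # invariance under relabeling
  perm <- c(P = "q8", Y1 = "n1", Y2 = "n2", G1 = "n3", G2 = "n4",
            I1 = "n5", M = "n6", R = "n7")
  e2 <- g$edges
  e2$from <- unname(perm[e2$from]); e2$to <- unname(perm[e2$to])
  g2 <- signed_graph(unname(perm[g$nodes]), e2)
  expect_identical(count_conflict_motif_pairs(g2),
                   count_conflict_motif_pairs(g))
})

test_that("double-edge swaps preserve degree sequences exactly", {
  fx <- make_conflict_network(motif_sizes = c(3L, 3L))
  g <- derive_signed_graph(fx$net)
  for (frac in c(0.1, 0.3, 0.5)) {
    r <- randomize_degree_preserving(g, swap_fraction = frac, seed = 5)
    expect_identical(table(factor(r$edges$from, g$nodes)),
                     table(factor(g$edges$from, g$nodes)))
    expect_identical(table(factor(r$edges$to, g$nodes)),
                     table(factor(g$edges$to, g$nodes)))
    expect_identical(nrow(r$edges), nrow(g$edges))
    # no self-loops introduced, edge set actually changed
    expect_false(any(r$edges$from == r$edges$to))
    expect_false(identical(r$edges[order(r$edges$from, r$edges$to), ],
                           g$edges[order(g$edges$from, g$edges$to), ]))
  }
  # determinism under a fixed seed
  r1 <- randomize_degree_preserving(g, 0.3, seed = 11)
  r2 <- randomize_degree_preserving(g, 0.3, seed = 11)
  expect_identical(r1$edges, r2$edges)
  # graphs with no legal swap error out
  tiny <- signed_graph(c("a", "b"),
                       data.frame(from = c("a", "b"), to = c("b", "a"),
                                  sign = c(1L, 1L)))
  expect_error(randomize_degree_preserving(tiny, 0.5, seed = 1),
               "swap")
})

test_that("interaction-table curation filters and keeps the largest component", {
  tab <- data.frame(
    source = c("a", "b", "c", "x", "u", "v"),
    target = c("b", "c", "a", "a", "v", "w"),
    sign = c(1, -1, 1, NA, 1, 1),
    is_directed = c(1, 1, 1, 1, 1, 0),
    confidence = "A")
  g <- curate_interaction_network(tab)
  # x->a unsigned and v->w undirected are dropped; u-v is the smaller
  # component
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_identical(nrow(g$edges), 3L)

  expect_error(curate_interaction_network(
    data.frame(source = "a", target = "b", sign = NA, is_directed = 1)),
    "empty after filtering")
  expect_error(curate_interaction_network(
    data.frame(source = "a", target = "b")), "required column")

  # whitelist cross-validation keeps only listed pairs
  g2 <- curate_interaction_network(
    tab, whitelist = data.frame(source = c("a", "b", "c"),
                                target = c("b", "c", "a")))
  expect_setequal(g2$nodes, c("a", "b", "c"))

  # file round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  g3 <- curate_interaction_network(path)
  expect_identical(g3$nodes, g$nodes)
})
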