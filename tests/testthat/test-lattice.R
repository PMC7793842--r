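test_that("intersection closure adds exactly the missing meets", {
  ab <- toy_alphabet(3)
  # three pairwise overlapping doubletons: every singleton gets created
  pats <- sets_to_patterns(list(ab[c(1, 2)], ab[c(2, 3)], ab[c(1, 3)]), ab)
  cl <- intersection_closure(pats)
  expect_equal(nrow(cl), 6)
  expect_equal(sum(cl$artificial), 3)
  expect_setequal(cl$pattern[cl$artificial], c("100", "010", "001"))

  # nested sets need nothing
  nested <- sets_to_patterns(list(ab[c(1, 2)], ab[1:3]), ab)
  expect_equal(nrow(intersection_closure(nested)), 2)

  # empty intersections are discarded, no root is invented
  ab4 <- toy_alphabet(4)
  disj <- sets_to_patterns(list(ab4[c(1, 2)], ab4[c(3, 4)]), ab4)
  expect_equal(nrow(intersection_closure(disj)), 2)

  expect_error(intersection_closure(character(0)), class = "hgpm_parameter_error")
  expect_error(intersection_closure(c("10", "10")), class = "hgpm_parameter_error")
})

test_that("closure matches the brute-force fixpoint on random families", {
  ab <- toy_alphabet(10)
  set.seed(77)
  for (rep in 1:25) {
    sets <- random_sets(sample(3:20, 1), ab)
    got <- intersection_closure(sets_to_patterns(sets, ab))
    want <- oracle_closure(sets)
    expect_setequal(got$pattern, sets_to_patterns(want, ab))
    # artificial flag: exactly the sets not in the input
    in_pats <- sets_to_patterns(sets, ab)
    expect_identical(got$artificial, !(got$pattern %in% in_pats))
  }
})

test_that("cover edges are the unique transitive reduction", {
  ab <- toy_alphabet(3)
  chain <- sets_to_patterns(list(ab[1], ab[c(1, 2)], ab[1:3]), ab)
  ed <- cover_edges(chain)
  expect_equal(nrow(ed), 2)               # the long edge {a}->{a,b,c} is gone
  expect_false(any(ed$from == chain[1] & ed$to == chain[3]))

  ab4 <- toy_alphabet(4)
  antichain <- sets_to_patterns(list(ab4[c(1, 2)], ab4[c(3, 4)]), ab4)
  expect_equal(nrow(cover_edges(antichain)), 0)

  set.seed(99)
  ab10 <- toy_alphabet(10)
  for (rep in 1:10) {
    sets <- random_sets(sample(10:50, 1), ab10, p = 0.35)
    pats <- sets_to_patterns(sets, ab10)
    got <- cover_edges(pats)
    want <- oracle_cover_edges(patterns_to_sets(pats, ab10))
    want_df <- data.frame(
      from = sets_to_patterns(lapply(want, `[[`, "from"), ab10),
      to = sets_to_patterns(lapply(want, `[[`, "to"), ab10))
    want_df <- want_df[order(want_df$from, want_df$to, method = "radix"), ]
    rownames(want_df) <- NULL
    expect_identical(got, want_df)
  }
})

test_that("build_graph assembles a valid counted DAG", {
  ab <- toy_alphabet(3)
  counted <- counted_from_sets(list(ab[c(1, 2)], ab[c(2, 3)], ab[c(1, 3)]),
                               c(4, 2, 2), ab)
  g <- build_graph(counted, toy_catalog(ab), metadata = list(threshold = 2L))
  expect_s3_class(g, "hgpm_graph")
  expect_equal(nrow(g$nodes), 6)
  expect_equal(sum(g$nodes$origin == "observed"), 3)
  expect_equal(sum(g$nodes$origin == "artificial"), 3)
  expect_equal(nrow(g$edges), 6)
  expect_true(all(g$nodes$appearance_count[g$nodes$origin == "artificial"] == 0))
  expect_true(validate_graph(g))

  stats <- graph_stats(g)
  expect_equal(stats$n_observed + stats$n_artificial, stats$n_total)

  single <- build_graph(counted_from_sets(list(ab[1:2]), 3, ab), toy_catalog(ab))
  expect_equal(nrow(single$nodes), 1)
  expect_equal(nrow(single$edges), 0)
})

test_that("graph equals brute-force oracle on many random instances", {
  ab <- toy_alphabet(12)
  catalog <- toy_catalog(ab)
  set.seed(123)
  for (rep in 1:30) {
    sets <- random_sets(sample(5:40, 1), ab, p = 0.3)
    counted <- counted_from_sets(sets, sample(1:50, length(sets), replace = TRUE), ab)
    g <- build_graph(counted, catalog)

    fam <- oracle_closure(sets)
    expect_setequal(g$nodes$pattern, sets_to_patterns(fam, ab))
    want_edges <- oracle_cover_edges(fam)
    got_pairs <- paste(g$edges$from, g$edges$to)
    want_pairs <- paste(
      node_id_for_test(sets_to_patterns(lapply(want_edges, `[[`, "from"), ab)),
      node_id_for_test(sets_to_patterns(lapply(want_edges, `[[`, "to"), ab)))
    expect_setequal(got_pairs, want_pairs)
  }
})

test_that("graph construction is permutation-invariant", {
  ab <- toy_alphabet(8)
  catalog <- toy_catalog(ab)
  set.seed(7)
  sets <- random_sets(15, ab)
  counts <- sample(1:20, 15, replace = TRUE)
  base <- build_graph(counted_from_sets(sets, counts, ab), catalog)
  for (i in 1:10) {
    perm <- sample(length(sets))
    g <- build_graph(counted_from_sets(sets[perm], counts[perm], ab), catalog)
    expect_identical(g$nodes$pattern, base$nodes$pattern)
    expect_identical(g$edges, base$edges)
    expect_identical(g$nodes$appearance_count, base$nodes$appearance_count)
  }
})

test_that("meet node returns the exact intersection or NULL", {
  ab <- toy_alphabet(5)
  sets <- list(ab[c(1, 2, 3)], ab[c(1, 2, 4)], ab[5])
  g <- build_graph(counted_from_sets(sets, c(2, 2, 2), ab), toy_catalog(ab))
  a <- sets_to_patterns(sets[1], ab)
  b <- sets_to_patterns(sets[2], ab)
  m <- meet_node(g, a, b)
  expect_equal(m$pattern, sets_to_patterns(list(ab[c(1, 2)]), ab))
  expect_equal(m$origin, "artificial")

  # a subset of b: the meet is a itself
  sub <- meet_node(g, m$node_id, a)
  expect_equal(sub$node_id, m$node_id)

  expect_null(meet_node(g, a, sets_to_patterns(sets[3], ab)))
  expect_error(meet_node(g, "nffff", a), class = "hgpm_lookup_error")
})

test_that("reference models become exempt nodes with matched counts", {
  ab <- toy_alphabet(4)
  counted <- counted_from_sets(list(ab[c(1, 2)], ab[c(1, 2, 3)], ab[4]),
                               c(5, 3, 0), ab,
                               reference = c(FALSE, FALSE, TRUE))
  g <- build_graph(counted, toy_catalog(ab))
  ref <- g$nodes[g$nodes$origin == "reference", ]
  expect_equal(nrow(ref), 1)
  expect_equal(ref$appearance_count, 0)   # never seen in the trajectory
  expect_true(validate_graph(g))
})

test_that("merged multi-system graphs track per-system provenance", {
  ab <- paste0("HBA|RES", sprintf("%02d", 1:5))
  catalog <- toy_catalog(ab, mode = "projected")
  mk <- function(sets, system, counts) {
    pats <- sets_to_patterns(sets, ab)
    out <- data.frame(pattern = pats, appearance_count = as.integer(counts),
                      observed = TRUE, reference = FALSE, stringsAsFactors = FALSE)
    out$frames <- lapply(seq_along(sets), function(i) {
      data.frame(system_id = system, run_id = paste0(system, "_run1"),
                 frame_index = seq_len(counts[i]) - 1L, stringsAsFactors = FALSE)
    })
    out
  }
  # disjoint observed vectors sharing one feature
  c1 <- mk(list(ab[c(1, 2)], ab[c(1, 2, 3)]), "sysA", c(4, 2))
  c2 <- mk(list(ab[c(1, 4)], ab[c(1, 4, 5)]), "sysB", c(3, 2))
  g <- merge_graphs(list(sysA = c1, sysB = c2), catalog)
  expect_true(validate_graph(g))
  obs <- g$nodes[g$nodes$origin == "observed", ]
  expect_true(all(lengths(obs$systems) == 1))

  # the shared feature appears as a common ancestor of both systems' nodes
  anc <- find_node(g, ab[1])
  expect_false(is.null(anc))
  ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                      vertices = g$nodes$node_id)
  reach <- names(igraph::subcomponent(ig, anc$node_id, mode = "out"))
  expect_true(all(obs$node_id %in% reach))

  # identical ensembles fed as two systems: every observed node lists both
  g2 <- merge_graphs(list(sysA = c1, sysB = mk(list(ab[c(1, 2)], ab[c(1, 2, 3)]),
                                               "sysB", c(4, 2))), catalog)
  obs2 <- g2$nodes[g2$nodes$origin == "observed", ]
  expect_true(all(vapply(obs2$systems, function(s)
    setequal(s, c("sysA", "sysB")), logical(1))))
  expect_equal(obs2$appearance_count, c(8L, 4L))
  expect_true(all(vapply(obs2$system_counts, function(sc)
    setequal(names(sc), c("sysA", "sysB")), logical(1))))

  # ligand-aware catalogs are rejected
  expect_error(merge_graphs(list(sysA = c1), toy_catalog(ab, "ligand_aware")),
               class = "hgpm_mode_error")
})

test_that("every node reaches all its observed supersets through edges", {
  ab <- toy_alphabet(8)
  set.seed(15)
  sets <- random_sets(20, ab)
  g <- build_graph(counted_from_sets(sets, rep(2, 20), ab), toy_catalog(ab))
  ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                      vertices = g$nodes$node_id)
  for (i in seq_len(nrow(g$nodes))) {
    reach <- names(igraph::subcomponent(ig, g$nodes$node_id[i], mode = "out"))
    sup <- g$nodes$node_id[vapply(g$nodes$pattern, function(p)
      hgpm:::pat_is_subset(g$nodes$pattern[i], p), logical(1))]
    expect_setequal(reach, sup)
  }
})
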