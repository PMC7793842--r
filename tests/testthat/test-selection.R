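toy_graph <- function() {
  ab <- toy_alphabet(4)
  counted <- counted_from_sets(
    list(ab[1], ab[c(1, 2)], ab[c(1, 2, 3)], ab[c(1, 2, 4)]),
    c(2, 9, 4, 4), ab)
  build_graph(counted, toy_catalog(ab))
}

test_that("find_node matches exact feature sets only", {
  g <- toy_graph()
  ab <- toy_alphabet(4)
  hit <- find_node(g, ab[c(1, 2)])
  expect_equal(hit$appearance_count, 9)
  expect_null(find_node(g, ab[c(2, 3)]))            # not a node
  expect_null(find_node(g, "HBD|XX|NOPE1"))         # not even in catalog

  # pattern queries work too
  expect_equal(find_node(g, "1100")$node_id, hit$node_id)

  proj <- pharmacophore_model("s", "r", 0L, "HBA|ARG63", mode = "projected")
  expect_error(find_node(g, proj), class = "hgpm_mode_error")
})

test_that("highest-frequency node selection breaks ties as documented", {
  g <- toy_graph()
  expect_equal(highest_frequency_node(g)$appearance_count, 9)

  # tie on count: larger feature set wins
  ab <- toy_alphabet(4)
  tie <- counted_from_sets(list(ab[c(1, 2, 3)], ab[c(1, 2)]), c(5, 5), ab)
  hf <- highest_frequency_node(build_graph(tie, toy_catalog(ab)))
  expect_equal(hf$feature_count, 3)

  only_art <- toy_graph()
  only_art$nodes$origin[] <- "artificial"
  expect_error(highest_frequency_node(only_art), class = "hgpm_lookup_error")
})

test_that("superset selection is inclusive, observed-only, and antitone", {
  g <- toy_graph()
  ab <- toy_alphabet(4)
  anchor <- find_node(g, ab[1])
  sel <- superset_selection(g, anchor)
  expect_equal(nrow(sel), 4)                     # whole observed chain + anchor
  expect_true(anchor$node_id %in% sel$node_id)

  maximal <- find_node(g, ab[c(1, 2, 3)])
  expect_equal(superset_selection(g, maximal)$node_id, maximal$node_id)

  # bigger anchor => smaller selection, always containing the anchor
  mid <- find_node(g, ab[c(1, 2)])
  sel_mid <- superset_selection(g, mid)
  expect_true(all(sel_mid$node_id %in% sel$node_id))
  expect_lte(nrow(sel_mid), nrow(sel))

  # brute-force subset scan oracle on a random instance
  ab10 <- toy_alphabet(10)
  set.seed(4)
  sets <- random_sets(50, ab10)
  g2 <- build_graph(counted_from_sets(sets, rep(2, 50), ab10), toy_catalog(ab10))
  a <- g2$nodes$node_id[which.min(g2$nodes$feature_count)]
  sel2 <- superset_selection(g2, a, observed_only = FALSE)
  apat <- g2$nodes$pattern[match(a, g2$nodes$node_id)]
  aset <- patterns_to_sets(apat, ab10)[[1]]
  want <- g2$nodes$node_id[vapply(patterns_to_sets(g2$nodes$pattern, ab10),
                                  function(s) all(aset %in% s), logical(1))]
  expect_setequal(sel2$node_id, want)

  expect_error(superset_selection(g, "nbad"), class = "hgpm_lookup_error")
})

test_that("representative model is the first frame in run-major order", {
  ab <- toy_alphabet(2)
  counted <- counted_from_sets(list(ab[1:2]), 1, ab)
  counted$frames[[1]] <- data.frame(system_id = "sys",
                                    run_id = c("run2", "run1"),
                                    frame_index = c(17L, 40L),
                                    stringsAsFactors = FALSE)
  g <- build_graph(counted, toy_catalog(ab))
  rep1 <- representative_models(g, g$nodes)
  expect_equal(rep1$run_id, "run1")
  expect_equal(rep1$frame_index, 40L)

  # property: minimal ordering key among the node frames, on simulated data
  models <- simulate_trajectory(trajectory_params(example_feature_table(),
                                                  n_frames = 150, seed = 12))
  catalog <- build_catalog(models)
  cu <- count_unique(vectorize(models, catalog))
  g2 <- build_graph(filter_by_count(cu, min_count = 2), catalog)
  obs <- g2$nodes[g2$nodes$origin == "observed", ]
  reps <- representative_models(g2, obs)
  for (i in seq_len(nrow(obs))) {
    f <- obs$frames[[i]]
    keys <- paste(f$run_id, sprintf("%09d", f$frame_index))
    expect_equal(paste(reps$run_id[i], sprintf("%09d", reps$frame_index[i])),
                 min(keys))
  }

  art <- g2$nodes[g2$nodes$origin == "artificial", ][1, ]
  expect_error(representative_models(g2, art), class = "hgpm_no_representative")
})

make_hit_table <- function(hits_by_model, labels) {
  mols <- names(labels)
  do.call(rbind, lapply(names(hits_by_model), function(mid) {
    data.frame(molecule_id = mols, label = unname(labels[mols]), model_id = mid,
               hit = as.integer(mols %in% hits_by_model[[mid]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("consensus score counts the models retrieving each molecule", {
  labels <- c(m1 = "active", m2 = "active", m3 = "decoy", m4 = "decoy")
  ht <- make_hit_table(list(A = c("m1", "m3"), B = c("m1"), C = c("m2")), labels)
  sc <- consensus_score(ht, c("A", "B", "C"))
  expect_equal(unname(sc[c("m1", "m2", "m3", "m4")]), c(2, 1, 1, 0))

  # single-model selection reduces to that model's hit list
  sc_b <- consensus_score(ht, "B")
  expect_equal(names(sc_b[sc_b > 0]), "m1")

  # empty hit list when no selected model hits
  ht0 <- make_hit_table(list(A = character(0)), labels)
  expect_true(all(consensus_score(ht0, "A") == 0))

  expect_error(consensus_score(ht, c("A", "Z")), class = "hgpm_lookup_error")
  expect_error(consensus_score(ht, character(0)), class = "hgpm_parameter_error")
})

test_that("truncated ROC AUC follows the documented conventions", {
  labels <- c(a1 = "active", a2 = "active", d1 = "decoy", d2 = "decoy")

  # nothing retrieved: 0 at every percentage
  zero <- c(a1 = 0, a2 = 0, d1 = 0, d2 = 0)
  for (p in c(1, 5, 10, 50, 100)) {
    expect_equal(truncated_roc_auc(zero, labels, p), 0)
  }

  # perfect ranking of everything: 1 at 100%
  perfect <- c(a1 = 4, a2 = 3, d1 = 2, d2 = 1)
  expect_equal(truncated_roc_auc(perfect, labels, 100), 1)

  # interleaved distinct scores, percent 100: step-curve area 0.75
  inter <- c(a1 = 4, d1 = 3, a2 = 2, d2 = 1)
  expect_equal(truncated_roc_auc(inter, labels, 100), 0.75)

  # only actives retrieved: FPR at cutoff is 0 -> convention 1.0
  expect_equal(truncated_roc_auc(c(a1 = 1, a2 = 1, d1 = 0, d2 = 0), labels, 100), 1)

  expect_error(truncated_roc_auc(perfect, c(a1 = "active", a2 = "active",
                                            d1 = "active", d2 = "active"), 100),
               class = "hgpm_undefined_metric")
  expect_error(truncated_roc_auc(perfect, labels, 0), class = "hgpm_parameter_error")
})

test_that("truncated ROC AUC equals the all-thresholds sweep oracle", {
  set.seed(66)
  for (rep in 1:200) {
    N <- sample(5:200, 1)
    nA <- sample(1:(N - 1), 1)
    labels <- c(rep("active", nA), rep("decoy", N - nA))
    names(labels) <- sprintf("mol%03d", seq_len(N))
    # integer scores with many ties, plenty of zeros
    scores <- sample(0:6, N, replace = TRUE)
    names(scores) <- names(labels)
    p <- sample(c(1, 5, 10, 25, 50, 100), 1)
    expect_equal(truncated_roc_auc(scores, labels, p),
                 oracle_truncated_auc(scores, labels, p), tolerance = 1e-12)
  }
})

test_that("AUC at 100% is monotone under decoy/active swaps and unbiased", {
  set.seed(10)
  labels <- c(rep("active", 10), rep("decoy", 10))
  names(labels) <- sprintf("m%02d", 1:20)
  for (rep in 1:50) {
    scores <- stats::setNames(sample(seq(20)), names(labels))
    auc <- truncated_roc_auc(scores, labels, 100)
    # find an adjacent (decoy above active) pair and swap their scores
    ord <- names(sort(scores, decreasing = TRUE))
    pair <- NULL
    for (i in seq_len(19)) {
      if (labels[ord[i]] == "decoy" && labels[ord[i + 1]] == "active") {
        pair <- c(ord[i], ord[i + 1]); break
      }
    }
    if (is.null(pair)) next
    swapped <- scores
    swapped[pair] <- scores[rev(pair)]
    expect_gte(truncated_roc_auc(swapped, labels, 100), auc)
  }

  # random scores, balanced labels: mean AUC ~ 0.5
  aucs <- replicate(400, {
    scores <- stats::setNames(stats::runif(20, 0.01, 1), names(labels))
    truncated_roc_auc(scores, labels, 100)
  })
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("metric coloring maps green to 1, red to 0, gray to artificial", {
  ab <- toy_alphabet(3)
  g <- build_graph(counted_from_sets(list(ab[c(1, 2)], ab[c(2, 3)], ab[c(1, 3)]),
                                     c(3, 2, 2), ab), toy_catalog(ab))
  obs <- g$nodes$node_id[g$nodes$origin == "observed"]
  art <- g$nodes$node_id[g$nodes$origin == "artificial"]
  metric <- stats::setNames(c(1, 0, 0.5, 1), c(obs[1:3], art[1]))
  col <- color_by_metric(g, metric)
  expect_equal(col$color[col$node_id == obs[1]], "#00FF00")
  expect_equal(col$color[col$node_id == obs[2]], "#FF0000")
  mid <- col$color[col$node_id == obs[3]]     # midpoint: between red and green
  expect_false(mid %in% c("#FF0000", "#00FF00", "#808080"))
  expect_equal(col$color[col$node_id == art[1]], "#808080")  # artificial stays gray
  # nodes missing from the metric are gray
  expect_true(all(col$color[!col$node_id %in% names(metric)] == "#808080"))
  expect_warning(color_by_metric(g, stats::setNames(2, obs[1])), "normalizing")
})
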