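test_that("contrast score matches the enumeration oracle", {
  # no enrichment: same frequency in both partitions
  expect_lte(contrast_score(10, 20, 50, 100), 1)
  # zero foreground matches: tail is 1 by construction
  expect_equal(contrast_score(0, 10, 5, 100), 0, tolerance = 1e-12)
  # perfect separation against the exact enumerated tail
  expect_equal(contrast_score(10, 10, 0, 100),
               enum_contrast_score(10, 10, 0, 100), tolerance = 1e-10)
  # spot grid
  for (case in list(c(7, 12, 3, 40), c(5, 5, 1, 9), c(2, 8, 6, 14))) {
    expect_equal(contrast_score(case[1], case[2], case[3], case[4]),
                 enum_contrast_score(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-10)
  }
  expect_error(contrast_score(1, 0, 1, 5), "domain-error")
  expect_error(contrast_score(6, 5, 1, 5), "domain-error")
})

test_that("pattern selection recovers planted columns and stays quiet on null", {
  cfg <- sampler_config(min_node_size = 10)

  # perfect signal: exactly the 5 planted columns, modal residues match
  g <- gen_hierarchical_msa(two_leaf_spec(strength = 1.0, seed = 2))
  fgA <- g$truth$id[g$truth$node == "leafA"]
  bgA <- g$truth$id[g$truth$node == "leafB"]
  pat <- select_pattern(g$msa, fgA, bgA, cfg)
  truthA <- g$patterns[g$patterns$node == "leafA", ]
  expect_setequal(pat$column, truthA$column)
  expect_true(all(mapply(grepl,
                         truthA$residue[match(pat$column, truthA$column)],
                         pat$residues)))

  # strength 0.9: at least 4 of 5 recovered
  g9 <- gen_hierarchical_msa(two_leaf_spec(n_per_leaf = 200, strength = 0.9,
                                           seed = 6))
  fg9 <- g9$truth$id[g9$truth$node == "leafA"]
  bg9 <- g9$truth$id[g9$truth$node == "leafB"]
  pat9 <- select_pattern(g9$msa, fg9, bg9, cfg)
  truth9 <- g9$patterns[g9$patterns$node == "leafA", ]
  expect_gte(sum(truth9$column %in% pat9$column), 4)

  # null: foreground and background from the same distribution
  xnull <- random_msa(200, 60, seed = 13)
  patn <- select_pattern(xnull, 1:100, 101:200, cfg)
  expect_lte(nrow(patn), 2)

  expect_error(select_pattern(g$msa, fgA, character(0), cfg), "domain-error")
  expect_error(select_pattern(g$msa, fgA, fgA, cfg), "domain-error")
})

test_that("sampler recovers a planted two-leaf partition exactly", {
  g <- gen_hierarchical_msa(two_leaf_spec(n_per_leaf = 50, strength = 1.0,
                                          seed = 8))
  h <- sample_hierarchy(g$msa, sampler_config(min_node_size = 15, seed = 3,
                                              n_sweeps = 10))
  ari <- mclust::adjustedRandIndex(leaf_assignment(h), g$truth$node)
  expect_equal(ari, 1.0)
})

test_that("sampler with max_children 0 yields the bare root; depth 0 errors", {
  x <- random_msa(60, 30, seed = 5)
  h <- sample_hierarchy(x, sampler_config(max_children = 0, n_sweeps = 2))
  expect_length(h$nodes, 1)
  expect_equal(nrow(h$nodes[["1"]]$pattern), 0)
  expect_equal(hierarchy_objective(x, h), 0)
  expect_error(sampler_config(max_depth = 0), "spec-error")
})

test_that("best-so-far objective is non-decreasing and membership stays a partition", {
  g <- gen_hierarchical_msa(default_hierarchy_spec(n_per_leaf = 60, seed = 2))
  h <- sample_hierarchy(g$msa, sampler_config(min_node_size = 15, seed = 4,
                                              n_sweeps = 8))
  expect_true(all(diff(h$trace) >= 0))
  all_members <- sort(unlist(lapply(h$nodes, `[[`, "members"),
                             use.names = FALSE))
  expect_identical(all_members, seq_len(n_sequences(g$msa)))
})

test_that("truth partition outscores random partitions of the same shape", {
  g <- gen_hierarchical_msa(two_leaf_spec(n_per_leaf = 40, strength = 1.0,
                                          seed = 10))
  x <- g$msa
  cfg <- sampler_config(min_node_size = 10)
  truth_groups <- split(seq_len(n_sequences(x)), g$truth$node)
  obj_truth <- hierarchy_objective(x, manual_hierarchy(x, truth_groups),
                                   cfg, recompute = TRUE)
  set.seed(77)
  worse <- vapply(1:100, function(i) {
    perm <- sample(n_sequences(x))
    rand_groups <- list(perm[1:40], perm[41:80])
    hierarchy_objective(x, manual_hierarchy(x, rand_groups), cfg,
                        recompute = TRUE)
  }, 0)
  expect_true(all(obj_truth >= worse))
})

test_that("null alignments almost never earn a split", {
  accepted <- 0L
  for (sd in 1:20) {
    x <- random_msa(150, 80, seed = 400 + sd)
    h <- sample_hierarchy(x, sampler_config(seed = sd, n_sweeps = 6))
    if (length(h$nodes) > 1) accepted <- accepted + 1L
  }
  expect_lte(accepted / 20, 0.1)
})

test_that("classification descends to the planted leaf and held-out accuracy is high", {
  g <- gen_hierarchical_msa(two_leaf_spec(n_per_leaf = 60, strength = 1.0,
                                          seed = 14))
  h <- sample_hierarchy(g$msa, sampler_config(min_node_size = 15, seed = 2,
                                              n_sweeps = 8))
  # a foreground member classifies to its own leaf
  i <- which(g$truth$node == "leafA")[1]
  path <- classify_sequence(h, g$msa, g$msa$seqs[i])
  expect_identical(path[1], 1L)
  expect_true(i %in% h$nodes[[as.character(path[length(path)])]]$members)

  # a pure background sequence stops at the root
  set.seed(31)
  bgseq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        n_columns(g$msa), replace = TRUE), collapse = "")
  expect_identical(classify_sequence(h, g$msa, bgseq), 1L)

  # held-out sequences from the same planted process: >= 90% to the true leaf
  ho <- gen_hierarchical_msa(two_leaf_spec(n_per_leaf = 30, strength = 0.95,
                                           seed = 15))
  node_of_leaf <- function(leaf) {
    members <- which(g$truth$node == leaf)
    ids <- leaf_assignment(h)[members]
    as.integer(names(which.max(table(ids))))
  }
  expected <- vapply(ho$truth$node, node_of_leaf, 0L)
  got <- vapply(ho$msa$seqs, function(s) {
    p <- classify_sequence(h, g$msa, s); p[length(p)]
  }, 0L)
  expect_gte(mean(got == expected), 0.9)

  expect_error(classify_sequence(h, g$msa, "ACD"), "alignment-error")
})

test_that("hierarchy serializations agree with the object", {
  g <- gen_hierarchical_msa(two_leaf_spec(seed = 18))
  h <- sample_hierarchy(g$msa, sampler_config(min_node_size = 15, seed = 1,
                                              n_sweeps = 6))
  js <- jsonlite::fromJSON(hierarchy_json(h), simplifyVector = FALSE)
  expect_equal(length(js$nodes), length(h$nodes))
  nwk <- hierarchy_newick(h)
  expect_match(nwk, "^\\(.*\\)1;$")
  pt <- pattern_table(h)
  expect_equal(nrow(pt),
               sum(vapply(h$nodes, function(nd) nrow(nd$pattern), 0L)))
})
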