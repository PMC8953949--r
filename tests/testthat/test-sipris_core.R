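test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeom_tail(0, 5, 6, 20), 1.0)
  expect_equal(hypergeom_tail(5, 5, 5, 5), 1.0)   # forced draw
  expect_equal(hypergeom_tail(4, 5, 6, 20), enum_hyper_tail(4, 5, 6, 20),
               tolerance = 1e-12)
  expect_error(hypergeom_tail(6, 5, 6, 20), "domain-error")
  expect_error(hypergeom_tail(2, 25, 6, 20), "domain-error")
})

test_that("initial-cluster scan finds the front-loaded prefix", {
  # all m marks first: k* = m, raw p = 1 / C(N, m)
  N <- 20L; m <- 6L
  orl <- ordered_residue_list(as.character(1:N),
                              c(rep(TRUE, m), rep(FALSE, N - m)))
  sc <- ica_scan(orl)
  expect_identical(sc$k_star, m)
  expect_equal(sc$raw_p, 1 / choose(N, m), tolerance = 1e-12)

  # evenly spread marks: equals brute force over all prefixes
  orl2 <- ordered_residue_list(as.character(1:8),
                               rep(c(FALSE, TRUE), 4))
  sc2 <- ica_scan(orl2)
  brute <- vapply(1:8, function(k) {
    x <- sum(rep(c(FALSE, TRUE), 4)[1:k])
    enum_hyper_tail(x, 4, k, 8)
  }, 0)
  expect_equal(sc2$prefix_p, brute, tolerance = 1e-12)
  expect_identical(sc2$k_star, which.min(brute))
  expect_equal(sc2$raw_p, min(brute), tolerance = 1e-12)

  # single mark dead last: nothing clusters
  orl3 <- ordered_residue_list(as.character(1:10),
                               c(rep(FALSE, 9), TRUE))
  sc3 <- ica_scan(orl3)
  expect_identical(sc3$k_star, 10L)
  expect_equal(sc3$raw_p, 1.0)

  expect_error(ica_scan(ordered_residue_list("1", FALSE)), "domain-error")
})

test_that("scan statistic ignores unmarked labels and is front-monotone", {
  set.seed(51)
  for (rep in 1:10) {
    N <- 30
    marks <- rep(FALSE, N); marks[sample.int(N, 6)] <- TRUE
    a <- ica_scan(ordered_residue_list(as.character(1:N), marks))
    b <- ica_scan(ordered_residue_list(sprintf("x%d", N:1), marks))
    expect_identical(a$raw_p, b$raw_p)
    # adding a mark at the very front can only help
    marks2 <- c(TRUE, marks)
    c2 <- ica_scan(ordered_residue_list(as.character(0:N), marks2))
    expect_lte(c2$raw_p, a$raw_p + 1e-15)
  }
})

test_that("permutation p-value hits its floor under perfect front-loading", {
  orl <- ordered_residue_list(as.character(1:100),
                              c(rep(TRUE, 10), rep(FALSE, 90)))
  res <- ica_pvalue(orl, n_perm = 999, seed = 7)
  expect_equal(res$adjusted_p, 1 / 1000)
  expect_error(ica_pvalue(orl, n_perm = 10), "n_perm")
})

test_that("permutation estimate agrees with exhaustive small-N enumeration", {
  N <- 8; K <- 3
  marks <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  orl <- ordered_residue_list(as.character(1:N), marks)
  obs <- ica_scan(orl)$raw_p
  # exact: enumerate all C(8,3) mark placements
  combos <- combn(N, K)
  raws <- apply(combos, 2, function(pos) {
    m <- rep(FALSE, N); m[pos] <- TRUE
    ica_scan(ordered_residue_list(as.character(1:N), m))$raw_p
  })
  p_exact <- mean(raws <= obs + 1e-15)
  res <- ica_pvalue(orl, n_perm = 999, seed = 3)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$adjusted_p - p_exact), 3 * mc_se + 1 / 1000)
})

test_that("interface test ranks planted residues first", {
  g <- gen_complex_structure(default_complex_spec(seed = 3))
  res <- interface_sipris(g$structure, "A", "B",
                          as.character(g$truth$planted),
                          n_perm = 499, seed = 9)
  expect_lte(res$adjusted_p, 0.01)

  # pattern set = the k nearest residues to chain B gives k* = k
  iface <- interface_residues(g$structure, "A", "B")
  ord <- order(iface$min_dist, iface$resno)
  k <- 5
  nearest <- iface$resid[ord][1:k]
  res_k <- interface_sipris(g$structure, "A", "B", nearest,
                            n_perm = 199, seed = 1)
  expect_identical(res_k$k_star, as.integer(k))

  expect_error(interface_sipris(g$structure, "A", "B", "999"),
               "domain-error")
})

test_that("core clustering recovers a planted spatial cluster", {
  g <- gen_complex_structure(default_complex_spec(seed = 5))
  res <- core_clustering(g$structure, "A", as.character(g$truth$planted),
                         n_perm = 499, seed = 2)
  expect_lte(res$adjusted_p, 0.01)
  # the best growth ordering front-loads the planted residues
  first8 <- res$ordering[1:8]
  expect_gte(sum(first8 %in% as.character(g$truth$planted)), 7)

  # all residues marked: no enrichment is possible
  allm <- core_clustering(g$structure, "A", as.character(1:60),
                          n_perm = 99, seed = 1)
  expect_equal(allm$raw_p, 1.0)
})

test_that("cluster results serialize to JSON and TSV", {
  orl <- ordered_residue_list(as.character(1:20),
                              c(rep(TRUE, 4), rep(FALSE, 16)))
  res <- ica_pvalue(orl, n_perm = 99, seed = 1)
  tj <- tempfile(fileext = ".json")
  write_cluster_result(res, tj)
  js <- jsonlite::read_json(tj)
  expect_equal(js$adjusted_p, res$adjusted_p)
  tt <- tempfile(fileext = ".tsv")
  write_cluster_result(res, tt)
  expect_equal(nrow(read.delim(tt)), 20)
})
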