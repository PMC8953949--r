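test_that("planted MSA carries the pattern at the planted strength", {
  # strength 1: every foreground sequence carries the residue
  g1 <- gen_hierarchical_msa(two_leaf_spec(strength = 1.0, seed = 3))
  m <- msa_matrix(g1$msa)
  for (k in seq_len(nrow(g1$patterns))) {
    p <- g1$patterns[k, ]
    fg <- which(g1$truth$node == p$node)
    expect_true(all(m[fg, p$column] == p$residue))
  }

  # strength 0.9, n = 200: empirical frequency within 3 binomial SEs
  sp <- two_leaf_spec(n_per_leaf = 200, strength = 0.9, seed = 5)
  g2 <- gen_hierarchical_msa(sp)
  m2 <- msa_matrix(g2$msa)
  pexp <- 0.9 + 0.1 / 20          # background can also emit the residue
  se <- sqrt(pexp * (1 - pexp) / 200)
  for (k in seq_len(nrow(g2$patterns))) {
    p <- g2$patterns[k, ]
    fg <- which(g2$truth$node == p$node)
    fhat <- mean(m2[fg, p$column] == p$residue)
    expect_lt(abs(fhat - pexp), 3 * se)
  }

  # strength 0: all columns are i.i.d. background (chi-square GOF)
  sp0 <- two_leaf_spec(n_per_leaf = 150, strength = 0, seed = 7)
  g0 <- gen_hierarchical_msa(sp0)
  m0 <- msa_matrix(g0$msa)
  counts <- table(factor(as.vector(m0), levels = strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  gof <- chisq.test(counts, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted MSA generation is deterministic and a true partition", {
  sp <- two_leaf_spec(seed = 11)
  g1 <- gen_hierarchical_msa(sp)
  g2 <- gen_hierarchical_msa(sp)
  expect_identical(g1$msa$seqs, g2$msa$seqs)
  expect_identical(g1$truth, g2$truth)
  # exactly one label per sequence, and a valid msa
  expect_equal(nrow(g1$truth), n_sequences(g1$msa))
  expect_true(all(table(g1$truth$id) == 1))
  expect_s3_class(msa(g1$msa$ids, g1$msa$seqs), "msa")
})

test_that("lineage-overlapping pattern columns are rejected", {
  node <- function(id, parent, n, cols, res)
    list(id = id, parent = parent, n_sequences = n, pattern_columns = cols,
         pattern_residues = res, pattern_strength = 1)
  expect_error(planted_hierarchy_spec(list(
    node("root", NA, 0, 5L, "W"),
    node("leaf", "root", 10, 5L, "K")), sequence_length = 20),
    "spec-error")
})

test_that("toy complex geometry honors the planted spec", {
  # without relocation, the chains approach to ~ interface_offset
  spec0 <- planted_complex_spec(seed = 4)
  g0 <- gen_complex_structure(spec0)
  A0 <- chain_ca(g0$structure, "A"); B0 <- chain_ca(g0$structure, "B")
  dm0 <- apply(A0, 1, function(p) min(sqrt(colSums((t(B0) - p)^2))))
  expect_equal(min(dm0), spec0$interface_offset, tolerance = 0.05)

  spec <- default_complex_spec(seed = 4)
  g <- gen_complex_structure(spec)
  s <- g$structure
  A <- chain_ca(s, "A"); B <- chain_ca(s, "B")
  dm <- apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2))))

  # planted residues fit in a sphere: pairwise distances <= 2 * radius
  P <- A[g$truth$planted, ]
  expect_lte(max(dist(P)), 2 * spec$cluster_radius)

  # planted residues sit near chain B relative to the rest of chain A
  expect_true(all(dm[g$truth$planted] <= quantile(dm, 0.75)))

  # consecutive (non-relocated) residues step ~3.8 A
  keep <- setdiff(seq_len(nrow(A) - 1),
                  unique(c(g$truth$planted, g$truth$planted - 1)))
  steps <- sqrt(rowSums((A[keep + 1, , drop = FALSE] -
                         A[keep, , drop = FALSE])^2))
  expect_true(all(abs(steps - 3.8) < 1e-6))
})

test_that("complex generator is deterministic and validates its spec", {
  g1 <- gen_complex_structure(default_complex_spec(seed = 9))
  g2 <- gen_complex_structure(default_complex_spec(seed = 9))
  expect_identical(g1$structure$atoms, g2$structure$atoms)

  g0 <- gen_complex_structure(planted_complex_spec(seed = 1))
  expect_length(g0$truth$planted, 0)

  expect_error(planted_complex_spec(n_residues = c(10, 10),
                                    planted_cluster = 1:11), "spec-error")
  expect_error(planted_complex_spec(n_residues = c(10, 10),
                                    planted_cluster = c(1, 12)), "spec-error")
})

test_that("simulated binding curves follow the saturation model", {
  # half saturation and saturation limit, noiseless
  sp <- binding_sim_spec(Amax = 2, Kd = 10, hill_h = 1,
                         concentrations = c(10, 10000), noise_sd = 0)
  cv <- gen_binding_curve(sp)
  expect_equal(cv$A[1], 1.0)
  expect_lt(abs(cv$A[2] - 2) / 2, 0.001)

  # direct formula agreement over a grid
  sp2 <- binding_sim_spec(Amax = 1.3, Kd = 10, hill_h = 1,
                          concentrations = 1:100, noise_sd = 0)
  cv2 <- gen_binding_curve(sp2)
  expect_equal(cv2$A, 1.3 / (1 + 10 / (1:100)), tolerance = 1e-12)

  # determinism with noise
  spn <- binding_sim_spec(noise_sd = 0.05, seed = 21)
  expect_identical(gen_binding_curve(spn)$A, gen_binding_curve(spn)$A)
})
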