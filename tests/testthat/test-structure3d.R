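# fixed-width ATOM record writer for handcrafted fixtures
atom_line <- function(serial, elety, alt, resname, chain, resno, x, y, z,
                      occ = 1.0) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, elety, alt, resname, chain, resno, x, y, z, occ, 0)
}

test_that("PDB reading keeps coordinates, skips HETATM, resolves altLocs", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    atom_line(1, " N", " ", "ALA", "A", 1, 1.0, 2.0, 3.0),
    atom_line(2, " CA", " ", "ALA", "A", 1, 1.5, 2.5, 3.5),
    atom_line(3, " CA", "A", "GLY", "A", 2, 9.0, 9.0, 9.0, 0.4),
    atom_line(4, " CA", "B", "GLY", "A", 2, 8.0, 8.0, 8.0, 0.6),
    "HETATM    5  O   HOH A   3       0.000   0.000   0.000  1.00  0.00",
    "END"), tf)
  s <- read_structure(tf)
  expect_identical(chains(s), "A")
  a <- s$atoms
  expect_equal(nrow(a), 3)               # HETATM gone, one altLoc kept
  expect_equal(sort(unique(a$resid)), c("1", "2"))
  expect_equal(a$x[a$elety == "N"], 1.0)
  # highest-occupancy conformer wins
  expect_equal(a$x[a$resid == "2"], 8.0)

  tf2 <- tempfile(fileext = ".pdb")
  writeLines("END", tf2)
  expect_error(read_structure(tf2), "empty-structure")
})

test_that("synthetic complexes round-trip through PDB text", {
  g <- gen_complex_structure(default_complex_spec(seed = 6))
  tf <- tempfile(fileext = ".pdb")
  write_structure(g$structure, tf)
  s2 <- read_structure(tf)
  expect_identical(chains(s2), chains(g$structure))
  expect_equal(s2$atoms$resno, g$structure$atoms$resno)
  # PDB fixed-point format carries 3 decimals
  for (cc in c("x", "y", "z"))
    expect_equal(s2$atoms[[cc]], g$structure$atoms[[cc]], tolerance = 1e-3)
})

test_that("interface membership equals a brute-force distance check", {
  # two far chains: empty interface
  far <- structure3d(data.frame(
    chain = c("A", "B"), resno = c(1, 1), resname = "ALA", elety = "CA",
    x = c(0, 100), y = 0, z = 0))
  expect_length(attr(interface_residues(far, "A", "B", 5), "members"), 0)

  # 4.9 A apart at cutoff 5: boundary is inclusive
  near <- structure3d(data.frame(
    chain = c("A", "B"), resno = c(7, 1), resname = "ALA", elety = "CA",
    x = c(0, 4.9), y = 0, z = 0))
  expect_identical(attr(interface_residues(near, "A", "B", 5), "members"), "7")

  # toy 6-residue complex vs exhaustive pairwise distances
  set.seed(40)
  df <- data.frame(
    chain = rep(c("A", "B"), each = 6), resno = rep(1:6, 2),
    resname = "ALA", elety = "CA",
    x = rnorm(12, rep(c(0, 6), each = 6), 3),
    y = rnorm(12, 0, 3), z = rnorm(12, 0, 3))
  s <- structure3d(df)
  ifa <- interface_residues(s, "A", "B", cutoff = 6)
  A <- as.matrix(df[df$chain == "A", c("x", "y", "z")])
  B <- as.matrix(df[df$chain == "B", c("x", "y", "z")])
  brute <- vapply(1:6, function(i)
    min(sqrt(colSums((t(B) - A[i, ])^2))), 0)
  expect_equal(ifa$min_dist, brute, tolerance = 1e-12)
  expect_setequal(attr(ifa, "members"), as.character(which(brute <= 6)))

  # symmetry: the set of contacting pairs is direction-independent
  ifb <- interface_residues(s, "B", "A", cutoff = 6)
  expect_equal(min(ifa$min_dist), min(ifb$min_dist), tolerance = 1e-12)
  expect_equal(sum(outer(1:6, 1:6, function(i, j)
    sqrt(rowSums((A[i, , drop = FALSE] - B[j, , drop = FALSE])^2)) <= 6)),
    sum(outer(1:6, 1:6, function(j, i)
      sqrt(rowSums((B[j, , drop = FALSE] - A[i, , drop = FALSE])^2)) <= 6)))

  expect_error(interface_residues(s, "A", "C"), "key-error")
})

test_that("sequence-to-structure maps are colinear and handle gaps", {
  g <- gen_complex_structure(default_complex_spec(seed = 2))
  s <- g$structure
  full <- chain_sequence(s, "A")

  # identity map
  mp <- map_seq_to_structure(full, s, "A")
  expect_equal(attr(mp, "coverage"), 1.0)
  expect_identical(mp$seq_pos, seq_len(nchar(full)))
  expect_identical(mp$resid, as.character(1:60))

  # drop 5 interior residues from the structure: map skips exactly those
  drop <- 20:24
  a <- s$atoms[!(s$atoms$chain == "A" & s$atoms$resno %in% drop), ]
  s2 <- structure3d(a)
  mp2 <- map_seq_to_structure(full, s2, "A")
  expect_identical(setdiff(seq_len(60), mp2$seq_pos), drop)
  expect_true(all(diff(mp2$seq_pos) > 0), all(diff(mp2$resno) > 0))

  # a garbage sequence triggers the low-identity warning
  set.seed(3)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                       replace = TRUE), collapse = "")
  expect_warning(map_seq_to_structure(junk, s, "A"), "identity")
})

test_that("residue transfer reads the destination at the aligned column", {
  x <- msa(c("src", "dst", "other"),
           c("AC-DEF", "GCQD-F", "AAAAAA"))
  # identity transfer
  self <- transfer_residues(x, "src", "src", 1:5)
  expect_identical(self$dst_residue, c("A", "C", "D", "E", "F"))
  # hand-worked lookups: src ungapped positions 1..5 sit in columns 1,2,4,5,6
  tr <- transfer_residues(x, "src", "dst", c(1, 3, 4, 5))
  expect_identical(tr$column, c(1L, 4L, 5L, 6L))
  expect_identical(tr$dst_residue, c("G", "D", NA, "F"))
  expect_identical(tr$dst_pos, c(1L, 4L, NA, 5L))
  expect_error(transfer_residues(x, "src", "dst", 6), "domain-error")
  expect_error(transfer_residues(x, "nope", "dst", 1), "not found")
})

test_that("Kabsch superposition is exact on rigid motions and matches Horn", {
  set.seed(12)
  P <- matrix(rnorm(24), 8, 3)
  expect_lt(superpose(P, P)$rmsd, 1e-9)

  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(R), 2, c(-4, 2, 7), "+")
  fit <- superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # perturbed 4-point asymmetric set: agree with the quaternion oracle
  P4 <- matrix(c(0, 0, 0, 3, 0, 0, 0, 2, 0, 1, 1, 4), 4, 3, byrow = TRUE)
  Q4 <- sweep(P4 %*% t(R), 2, c(1, -1, 2), "+") +
    matrix(c(0.1, -0.05, 0.02, 0.07, 0.03, -0.1, -0.02, 0.08,
             0.05, -0.04, 0.06, -0.03), 4, 3)
  expect_equal(superpose(P4, Q4)$rmsd, quaternion_superpose(P4, Q4),
               tolerance = 1e-9)

  # RMSD invariant to rigid pre-transformation of the mobile set
  th2 <- -0.6
  R2 <- matrix(c(1, 0, 0, 0, cos(th2), -sin(th2), 0, sin(th2), cos(th2)),
               3, 3, byrow = TRUE)
  P4b <- sweep(P4 %*% t(R2), 2, c(5, 5, -5), "+")
  expect_equal(superpose(P4b, Q4)$rmsd, superpose(P4, Q4)$rmsd,
               tolerance = 1e-9)

  expect_error(superpose(P4[1:2, ], Q4[1:2, ]), "degenerate-geometry")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "degenerate-geometry")
})
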