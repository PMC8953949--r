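# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::phyper) so that agreement is a real
# cross-check.

# Exact upper hypergeometric tail P(X >= x) by direct enumeration of the
# counting formula: sum_i C(K,i) C(N-K, n-i) / C(N,n).
enum_hyper_tail <- function(x, K, n, N) {
  if (x <= 0) return(1)
  i <- seq(from = x, to = min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Contrast score oracle: the package's pseudocount convention applied to
# the enumerated tail.
enum_contrast_score <- function(fg_matches, fg_total, bg_matches, bg_total) {
  K <- fg_matches + bg_matches + 1
  N <- fg_total + bg_total + 1
  max(0, -log10(enum_hyper_tail(fg_matches, K, fg_total, N)))
}

# Horn's quaternion method for least-squares rigid superposition: an
# implementation independent of the SVD route used by the package.
quaternion_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm); Y <- sweep(target, 2, ct)
  S <- t(X) %*% Y
  A <- matrix(0, 4, 4)
  A[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  A[1, 2] <- A[2, 1] <- S[2, 3] - S[3, 2]
  A[1, 3] <- A[3, 1] <- S[3, 1] - S[1, 3]
  A[1, 4] <- A[4, 1] <- S[1, 2] - S[2, 1]
  A[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  A[2, 3] <- A[3, 2] <- S[1, 2] + S[2, 1]
  A[2, 4] <- A[4, 2] <- S[1, 3] + S[3, 1]
  A[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  A[3, 4] <- A[4, 3] <- S[2, 3] + S[3, 2]
  A[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(A, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fit <- sweep(X %*% t(R), 2, ct, "+")
  sqrt(mean(rowSums((fit - target)^2)))
}

# Random equal-width alignment for property tests.
random_msa <- function(n, L, seed, gap_prob = 0) {
  set.seed(seed)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- replicate(n, {
    v <- sample(letters20, L, replace = TRUE)
    if (gap_prob > 0) v[runif(L) < gap_prob] <- "-"
    paste(v, collapse = "")
  })
  msa(sprintf("s%03d", seq_len(n)), rows)
}

# Tiny two-leaf planted spec used by several bpps tests.
two_leaf_spec <- function(n_per_leaf = 50, strength = 1.0, seed = 1L) {
  node <- function(id, parent, n, cols, res)
    list(id = id, parent = parent, n_sequences = n,
         pattern_columns = cols, pattern_residues = res,
         pattern_strength = strength)
  planted_hierarchy_spec(list(
    node("root", NA, 0, integer(0), character(0)),
    node("leafA", "root", n_per_leaf, c(3, 9, 15, 21, 27),
         c("W", "H", "C", "M", "Y")),
    node("leafB", "root", n_per_leaf, c(5, 11, 17, 23, 29),
         c("K", "E", "P", "G", "D"))),
    sequence_length = 40, seed = seed)
}

# A hand-built hierarchy over an msa, for objective comparisons: root plus
# one node per group in `groups` (a list of row-index vectors).
manual_hierarchy <- function(x, groups) {
  n <- n_sequences(x)
  h <- fdrscope:::new_hierarchy(x$ids, setdiff(seq_len(n), unlist(groups)))
  for (g in groups) {
    id <- h$next_id
    h$next_id <- h$next_id + 1L
    h$nodes[[as.character(id)]] <- list(
      id = id, parent = 1L, children = integer(0),
      members = g, pattern = fdrscope:::empty_pattern())
    h$nodes[["1"]]$children <- c(h$nodes[["1"]]$children, id)
  }
  h
}
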