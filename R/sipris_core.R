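# Initial-cluster statistics: do marked (pattern) residues concentrate at
# the front of an ordered residue list? The raw statistic is the minimum
# over prefix sizes of a hypergeometric tail; significance comes from
# permuting the marks, which also absorbs the minimum-over-prefixes (and,
# for core clustering, minimum-over-seed-orderings) multiplicity.

#' Upper hypergeometric tail
#'
#' `P(X >= x)` for a hypergeometric draw: population `N`, `K` marked,
#' `n` drawn. Computed in log space; vectorized over `x` and `n`.
#'
#' @param x Observed marked count(s).
#' @param K Marked in the population.
#' @param n Draw size(s).
#' @param N Population size.
#' @return Probability in (0, 1].
#' @export
hypergeom_tail <- function(x, K, n, N) {
  if (K > N || any(n > N) || K < 0 || any(n < 0) ||
      any(x < 0) || any(x > pmin(K, n)))
    stop("domain-error: need 0 <= x <= min(K, n) <= N", call. = FALSE)
  exp(phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Ordered residue list
#'
#' The input to the initial-cluster scan: residues of one chain in a
#' defined order (by interface distance, or by cluster-growth step) with
#' a mark per residue (pattern residue or not).
#'
#' @param resid Character vector of residue identifiers, in scan order.
#' @param marks Logical vector, same length.
#' @param chain Chain id (annotation only).
#' @return An `ordered_residue_list`.
#' @export
ordered_residue_list <- function(resid, marks, chain = NA_character_) {
  stopifnot(length(resid) == length(marks), !anyNA(marks))
  if (anyDuplicated(resid))
    stop("domain-error: residue identifiers must be unique", call. = FALSE)
  structure(list(resid = as.character(resid), marks = as.logical(marks),
                 chain = chain),
            class = "ordered_residue_list")
}

# prefix tail-probability lookup: P[x + 1, k] = P(X >= x | k drawn)
prefix_tail_table <- function(K, N) {
  ks <- seq_len(N)
  P <- matrix(1, nrow = K + 1, ncol = N)
  for (x in seq_len(K))
    P[x + 1, ] <- exp(phyper(x - 1, K, N - K, ks,
                             lower.tail = FALSE, log.p = TRUE))
  P
}

# min over prefixes for a 0/1 mark vector already in scan order; prefixes
# holding no mark carry no clustering evidence and are ineligible
.scan_min <- function(marks01, P) {
  x <- cumsum(marks01)
  p <- P[cbind(x + 1L, seq_along(x))]
  elig <- p
  elig[x == 0L] <- Inf
  k <- which.min(elig)        # smallest eligible prefix on ties
  list(k_star = k, x_star = x[k], raw_p = p[k])
}

#' Initial-cluster scan
#'
#' For each prefix size `k` of the ordered list, computes the
#' hypergeometric tail probability of seeing at least the observed number
#' of marks among the first `k` residues; returns the minimizing prefix
#' (smallest `k` on ties) and the minimum tail probability. This raw
#' minimum is an optimized statistic, not a p-value; calibrate it with
#' [ica_pvalue()].
#'
#' @param orl An [ordered_residue_list()] with at least one mark.
#' @return List with `k_star`, `x_star`, `raw_p` and the full `prefix_p`
#'   vector.
#' @export
ica_scan <- function(orl) {
  stopifnot(inherits(orl, "ordered_residue_list"))
  N <- length(orl$marks)
  K <- sum(orl$marks)
  if (K == 0) stop("domain-error: no marked residues", call. = FALSE)
  P <- prefix_tail_table(K, N)
  out <- .scan_min(as.integer(orl$marks), P)
  x <- cumsum(as.integer(orl$marks))
  out$prefix_p <- P[cbind(x + 1L, seq_len(N))]
  out
}

#' Permutation-calibrated initial-cluster p-value
#'
#' Adjusted p = `(1 + #permutations with raw minimum <= observed) /
#' (n_perm + 1)`, permuting the mark positions uniformly. Exact under
#' exchangeability of residue positions; never smaller than
#' `1/(n_perm+1)`. Deterministic given `seed`.
#'
#' @param orl An [ordered_residue_list()].
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A `cluster_result`: `k_star`, `x_star`, `raw_p`,
#'   `adjusted_p`, `n_perm`, `seed`, plus the ordering and marks.
#' @export
ica_pvalue <- function(orl, n_perm = 999, seed = 1L) {
  stopifnot(inherits(orl, "ordered_residue_list"))
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  N <- length(orl$marks)
  K <- sum(orl$marks)
  if (K == 0) stop("domain-error: no marked residues", call. = FALSE)
  P <- prefix_tail_table(K, N)
  m01 <- as.integer(orl$marks)
  obs <- .scan_min(m01, P)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pm <- m01[sample.int(N)]
      if (.scan_min(pm, P)$raw_p <= obs$raw_p + 1e-15) hits <- hits + 1L
    }
    structure(list(k_star = obs$k_star, x_star = obs$x_star,
                   raw_p = obs$raw_p,
                   adjusted_p = (1 + hits) / (n_perm + 1),
                   n_perm = n_perm, seed = seed,
                   resid = orl$resid, marks = orl$marks,
                   chain = orl$chain),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(paste0("cluster_result: %d/%d marks in best prefix of %d",
                     " (raw min p = %.3g, adjusted p = %.3g, %d perms)\n"),
              x$x_star, sum(x$marks), x$k_star, x$raw_p, x$adjusted_p,
              x$n_perm))
  invisible(x)
}

#' Interface clustering test for pattern residues
#'
#' Orders the residues of chain `a` by ascending minimum distance to
#' chain `b` (ties by author number), marks the pattern residues, and
#' runs the permutation-calibrated initial-cluster test: are pattern
#' residues concentrated at the interface end of the ordering?
#'
#' @param s A [structure3d].
#' @param a,b Chain ids (pattern residues live on `a`).
#' @param pattern_residues Character vector of chain-`a` residue
#'   identifiers (author numbers, insertion codes appended).
#' @param n_perm,seed Passed to [ica_pvalue()].
#' @return A `cluster_result` (see [ica_pvalue()]); the ordering is kept
#'   in `$resid`.
#' @export
interface_sipris <- function(s, a, b, pattern_residues, n_perm = 999,
                             seed = 1L) {
  iface <- interface_residues(s, a, b)
  pattern_residues <- as.character(pattern_residues)
  missing <- setdiff(pattern_residues, iface$resid)
  if (length(missing))
    stop("domain-error: pattern residues not in chain ", a, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  ord <- order(iface$min_dist, iface$resno, iface$ins)
  orl <- ordered_residue_list(iface$resid[ord],
                              iface$resid[ord] %in% pattern_residues,
                              chain = a)
  ica_pvalue(orl, n_perm = n_perm, seed = seed)
}

# single-linkage growth ordering from each seed residue; returns an
# N x N matrix of residue-index permutations (one column per seed)
growth_orderings <- function(D, resno) {
  N <- nrow(D)
  ORD <- matrix(0L, N, N)
  for (s0 in seq_len(N)) {
    inset <- rep(FALSE, N)
    ord <- integer(N)
    ord[1] <- s0; inset[s0] <- TRUE
    # dmin[j] = distance from j to nearest cluster member
    dmin <- D[, s0]
    for (step in 2:N) {
      dmin[inset] <- Inf
      cand <- which(dmin == min(dmin))
      nxt <- cand[order(resno[cand])][1]   # ties by author number
      ord[step] <- nxt; inset[nxt] <- TRUE
      dmin <- pmin(dmin, D[, nxt])
    }
    ORD[, s0] <- ord
  }
  ORD
}

#' Core clustering test for pattern residues
#'
#' Builds, for every seed residue of the chain, a sequentially grown
#' structural cluster (single linkage on Calpha distances, ties by
#' author number) - using no interface or pattern information - then
#' scans each growth ordering for an initial segment enriched in pattern
#' residues. The best raw minimum over all seeds is calibrated by
#' permuting the marks and repeating the full best-over-seeds scan, so
#' the seed-selection multiplicity is paid inside the null.
#'
#' @param s A [structure3d].
#' @param chain Chain id.
#' @param pattern_residues Character vector of residue identifiers.
#' @param n_perm,seed Permutation settings.
#' @return A `cluster_result` with extra fields `best_seed` (residue id
#'   whose growth ordering scored best) and `ordering` (that ordering's
#'   residue ids).
#' @export
core_clustering <- function(s, chain, pattern_residues, n_perm = 999,
                            seed = 1L) {
  ca <- chain_ca(s, chain)
  r <- chain_residues(s, chain)
  r <- r[r$resid %in% chain_atoms(s, chain)$resid[
    chain_atoms(s, chain)$calpha], ]
  N <- nrow(ca)
  if (N < 3) stop("chain must have >= 3 residues with Calpha",
                  call. = FALSE)
  pattern_residues <- as.character(pattern_residues)
  missing <- setdiff(pattern_residues, r$resid)
  if (length(missing))
    stop("domain-error: pattern residues not in chain ", chain, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  D <- cross_dist(ca, ca)
  if (max(D) < 1e-9)
    stop("degenerate geometry: all residues coincide", call. = FALSE)
  ORD <- growth_orderings(D, r$resno)
  marks <- r$resid %in% pattern_residues
  K <- sum(marks)
  if (K == 0) stop("domain-error: no marked residues", call. = FALSE)
  P <- prefix_tail_table(K, N)
  best_over_seeds <- function(m01) {
    Mm <- matrix(m01[ORD], N, N)
    X <- apply(Mm, 2, cumsum)
    Pm <- matrix(P[cbind(as.vector(X) + 1L, rep(seq_len(N), N))], N, N)
    Pm[X == 0L] <- Inf          # unmarked prefixes are ineligible
    list(p = min(Pm), which = which.min(Pm))
  }
  m01 <- as.integer(marks)
  obs <- best_over_seeds(m01)
  k_star <- (obs$which - 1L) %% N + 1L
  seed_idx <- (obs$which - 1L) %/% N + 1L
  x_star <- cumsum(m01[ORD[, seed_idx]])[k_star]
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pm <- m01[sample.int(N)]
      if (best_over_seeds(pm)$p <= obs$p + 1e-15) hits <- hits + 1L
    }
    structure(list(k_star = as.integer(k_star), x_star = x_star,
                   raw_p = obs$p,
                   adjusted_p = (1 + hits) / (n_perm + 1),
                   n_perm = n_perm, seed = seed,
                   resid = r$resid, marks = marks, chain = chain,
                   best_seed = r$resid[seed_idx],
                   ordering = r$resid[ORD[, seed_idx]]),
              class = "cluster_result")
  })
}

#' Export a cluster result
#'
#' @param x A `cluster_result`.
#' @param path File path; `.json` writes JSON, anything else TSV of the
#'   ordering and marks.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(x, path) {
  stopifnot(inherits(x, "cluster_result"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(k_star = x$k_star, x_star = x$x_star, raw_p = x$raw_p,
           adjusted_p = x$adjusted_p, n_perm = x$n_perm, seed = x$seed,
           chain = x$chain, resid = x$resid, marks = x$marks),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(data.frame(rank = seq_along(x$resid), resid = x$resid,
                           mark = x$marks),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
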