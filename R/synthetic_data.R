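# Planted-truth generators: hierarchical MSAs, toy two-chain complexes,
# saturation-binding curves. Every downstream stage is testable against the
# planted truth these emit, with no external data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Specification of a planted subgroup hierarchy
#'
#' Describes a tree of subgroups over which sequences are generated.
#' Each node may carry pattern columns: at those columns, sequences whose
#' lineage passes through the node emit the node's pattern residue with
#' probability `pattern_strength` (otherwise a background draw). Pattern
#' columns must be disjoint along every root-to-leaf lineage.
#'
#' @param nodes A list of node descriptions; each is a list with elements
#'   `id` (character), `parent` (character or `NA` for the root),
#'   `n_sequences` (sequences drawn directly at this node; usually only
#'   leaves are positive), `pattern_columns` (integer vector, may be
#'   empty), `pattern_residues` (one amino-acid letter per pattern
#'   column), `pattern_strength` (probability in (0, 1]).
#' @param sequence_length Alignment width.
#' @param background_frequencies Named length-20 probability vector over
#'   the amino acids; default uniform. A BLOSUM-like preset is available
#'   via [blosum_background()].
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A `planted_hierarchy_spec`.
#' @export
planted_hierarchy_spec <- function(nodes, sequence_length,
                                   background_frequencies = NULL,
                                   seed = 1L) {
  if (is.null(background_frequencies))
    background_frequencies <- setNames(rep(1 / 20, 20), AA20)
  stopifnot(abs(sum(background_frequencies) - 1) < 1e-8,
            setequal(names(background_frequencies), AA20),
            sequence_length >= 1)
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("spec-error: duplicate node ids", call. = FALSE)
  parents <- vapply(nodes, function(n) as.character(n$parent %||% NA), "")
  if (sum(is.na(parents)) != 1L)
    stop("spec-error: exactly one root (parent NA) required", call. = FALSE)
  for (n in nodes) {
    pc <- n$pattern_columns %||% integer(0)
    pr <- n$pattern_residues %||% character(0)
    if (length(pc) != length(pr))
      stop("spec-error: pattern_columns/pattern_residues length mismatch at ",
           n$id, call. = FALSE)
    if (length(pc) && (any(pc < 1) || any(pc > sequence_length)))
      stop("spec-error: pattern column out of range at ", n$id, call. = FALSE)
    st <- n$pattern_strength %||% 1
    if (st < 0 || st > 1)  # 0 = no signal, useful for null fixtures
      stop("spec-error: pattern_strength must be in [0,1]", call. = FALSE)
    if ((n$n_sequences %||% 0) < 0)
      stop("spec-error: negative n_sequences", call. = FALSE)
  }
  # lineage disjointness of pattern columns
  byid <- setNames(nodes, ids)
  for (nm in ids) {
    cols <- integer(0); cur <- nm
    while (!is.na(cur)) {
      cols <- c(cols, byid[[cur]]$pattern_columns %||% integer(0))
      cur <- as.character(byid[[cur]]$parent %||% NA)
    }
    if (anyDuplicated(cols))
      stop("spec-error: pattern columns overlap along the lineage of ", nm,
           call. = FALSE)
  }
  structure(list(nodes = byid, sequence_length = sequence_length,
                 background_frequencies = background_frequencies,
                 seed = seed),
            class = "planted_hierarchy_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Amino-acid background frequencies in the BLOSUM62 style
#'
#' Marginal amino-acid frequencies of the kind used to build substitution
#' matrices; an alternative to the uniform default for more realistic
#' column composition.
#' @return Named length-20 probability vector.
#' @export
blosum_background <- function() {
  f <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
         G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
         M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
         S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)
  f / sum(f)
}

#' Default two-level planted hierarchy
#'
#' Root with two families, each split into two subfamilies; 200 sequences
#' per leaf, alignment width 100, five pattern columns per non-root node
#' at strength 0.95. This is the reference condition for partition
#' recovery experiments.
#'
#' @param n_per_leaf Sequences per leaf (default 200).
#' @param pattern_strength Probability a foreground sequence carries the
#'   planted residue (default 0.95).
#' @param seed Integer seed.
#' @return A [planted_hierarchy_spec()].
#' @export
default_hierarchy_spec <- function(n_per_leaf = 200, pattern_strength = 0.95,
                                   seed = 1L) {
  node <- function(id, parent, n, cols, res)
    list(id = id, parent = parent, n_sequences = n,
         pattern_columns = cols, pattern_residues = res,
         pattern_strength = pattern_strength)
  nodes <- list(
    node("root", NA, 0, integer(0), character(0)),
    node("fam1", "root", 0, c(5, 15, 25, 35, 45), c("W", "H", "C", "M", "Y")),
    node("fam2", "root", 0, c(10, 20, 30, 40, 50), c("K", "E", "P", "G", "D")),
    node("fam1.1", "fam1", n_per_leaf, c(55, 60, 65, 70, 75),
         c("R", "N", "F", "T", "L")),
    node("fam1.2", "fam1", n_per_leaf, c(56, 61, 66, 71, 76),
         c("I", "Q", "S", "V", "A")),
    node("fam2.1", "fam2", n_per_leaf, c(80, 84, 88, 92, 96),
         c("Y", "W", "M", "C", "H")),
    node("fam2.2", "fam2", n_per_leaf, c(81, 85, 89, 93, 97),
         c("D", "G", "K", "P", "E")))
  planted_hierarchy_spec(nodes, sequence_length = 100, seed = seed)
}

#' Generate an alignment with a planted subgroup hierarchy
#'
#' Each sequence is drawn column-wise from the background frequencies,
#' except at the pattern columns of the nodes on its root-to-leaf lineage,
#' where the node's pattern residue is emitted with probability
#' `pattern_strength`. Deterministic given `spec$seed`.
#'
#' @param spec A [planted_hierarchy_spec()].
#' @return A list with `msa` (an [msa]) and `truth`: a data frame
#'   (`id`, `node`) assigning every sequence to exactly one generating
#'   node, and `patterns`, a data frame of the planted
#'   (`node`, `column`, `residue`, `strength`) rows.
#' @export
gen_hierarchical_msa <- function(spec) {
  stopifnot(inherits(spec, "planted_hierarchy_spec"))
  with_seed(spec$seed, {
    L <- spec$sequence_length
    bg <- spec$background_frequencies
    ids <- character(0); seqs <- character(0); node_of <- character(0)
    for (nd in spec$nodes) {
      nseq <- nd$n_sequences %||% 0
      if (nseq == 0) next
      # lineage pattern columns for this node
      cols <- integer(0); res <- character(0); str <- numeric(0)
      cur <- nd$id
      while (!is.na(cur)) {
        nn <- spec$nodes[[cur]]
        cols <- c(cols, nn$pattern_columns %||% integer(0))
        res <- c(res, nn$pattern_residues %||% character(0))
        str <- c(str, rep(nn$pattern_strength %||% 1,
                          length(nn$pattern_columns %||% integer(0))))
        cur <- as.character(nn$parent %||% NA)
      }
      m <- matrix(sample(AA20, nseq * L, replace = TRUE, prob = bg),
                  nrow = nseq)
      if (length(cols)) {
        for (k in seq_along(cols)) {
          hit <- runif(nseq) <= str[k]
          m[hit, cols[k]] <- res[k]
        }
      }
      ids <- c(ids, sprintf("%s_seq%04d", nd$id, seq_len(nseq)))
      seqs <- c(seqs, apply(m, 1, paste, collapse = ""))
      node_of <- c(node_of, rep(nd$id, nseq))
    }
    if (!length(seqs)) stop("spec-error: no node draws any sequences",
                            call. = FALSE)
    pats <- do.call(rbind, lapply(spec$nodes, function(nn) {
      pc <- nn$pattern_columns %||% integer(0)
      if (!length(pc)) return(NULL)
      data.frame(node = nn$id, column = pc,
                 residue = nn$pattern_residues,
                 strength = nn$pattern_strength %||% 1,
                 stringsAsFactors = FALSE)
    }))
    rownames(pats) <- NULL
    list(msa = msa(ids, seqs),
         truth = data.frame(id = ids, node = node_of,
                            stringsAsFactors = FALSE),
         patterns = pats)
  })
}

#' Specification of a toy two-chain complex
#'
#' @param n_residues Length-2 integer vector: residues in chains A and B.
#' @param planted_cluster Indices (1-based along chain A) of residues to
#'   relocate into a compact cluster at the interface; may be empty.
#' @param cluster_radius Radius (Angstrom) of the sphere the planted
#'   residues are placed in.
#' @param interface_offset Closest approach (Angstrom) between the chains.
#' @param seed Integer seed.
#' @return A `planted_complex_spec`.
#' @export
planted_complex_spec <- function(n_residues = c(60, 60),
                                 planted_cluster = integer(0),
                                 cluster_radius = 5,
                                 interface_offset = 8,
                                 seed = 1L) {
  stopifnot(length(n_residues) == 2, all(n_residues >= 3),
            cluster_radius > 0, interface_offset > 0)
  planted_cluster <- as.integer(planted_cluster)
  if (length(planted_cluster) > n_residues[1])
    stop("spec-error: planted cluster larger than chain A", call. = FALSE)
  if (length(planted_cluster) &&
      (min(planted_cluster) < 1 || max(planted_cluster) > n_residues[1]))
    stop("spec-error: planted cluster index out of chain A range",
         call. = FALSE)
  structure(list(n_residues = as.integer(n_residues),
                 planted_cluster = planted_cluster,
                 cluster_radius = cluster_radius,
                 interface_offset = interface_offset,
                 geometry_model = "random-globule", seed = seed),
            class = "planted_complex_spec")
}

#' Default planted complex
#'
#' Two 60-residue chains at 8 Angstrom closest approach, with 8 chain-A
#' residues planted in a 5-Angstrom-radius cluster at the interface
#' midpoint: the reference condition for interface/core clustering
#' experiments.
#' @param seed Integer seed.
#' @return A [planted_complex_spec()].
#' @export
default_complex_spec <- function(seed = 1L) {
  with_seed(seed, {
    planted <- sort(sample.int(60, 8))
    planted_complex_spec(n_residues = c(60, 60), planted_cluster = planted,
                         cluster_radius = 5, interface_offset = 8,
                         seed = seed)
  })
}

# compact self-avoiding pseudo-Calpha walk: 3.8 A steps, soft repulsion,
# centripetal bias keeps it globular
globule_walk <- function(n, step = 3.8, min_sep = 3.2, bias = 0.6) {
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    centroid <- colMeans(xyz[seq_len(i - 1), , drop = FALSE])
    ok <- FALSE
    for (try in 1:60) {
      d <- rnorm(3)
      pull <- centroid - xyz[i - 1, ]
      np <- sqrt(sum(pull^2))
      if (np > 1e-9) d <- d + bias * pull / np * min(1, np / 10)
      d <- d / sqrt(sum(d^2))
      cand <- xyz[i - 1, ] + step * d
      prev <- xyz[seq_len(i - 1), , drop = FALSE]
      if (i == 2 || min(sqrt(rowSums(sweep(prev[-(i - 1), , drop = FALSE],
                                           2, cand)^2))) >= min_sep) {
        ok <- TRUE; break
      }
    }
    if (!ok) cand <- xyz[i - 1, ] + step * d  # accept last candidate
    xyz[i, ] <- cand
  }
  xyz
}

#' Generate a toy two-chain complex with a planted interface cluster
#'
#' Chains are pseudo-Calpha traces from a compact self-avoiding random
#' walk (3.8 Angstrom steps); chain B is translated along x so the
#' closest approach equals `interface_offset`; planted-cluster residues
#' of chain A are then relocated uniformly inside a sphere of
#' `cluster_radius` centered on the interface midpoint. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [planted_complex_spec()].
#' @return List with `structure` (a [structure3d] with chains `A`, `B`)
#'   and `truth` (list with `planted` residue numbers on chain A).
#' @export
gen_complex_structure <- function(spec) {
  stopifnot(inherits(spec, "planted_complex_spec"))
  with_seed(spec$seed, {
    nA <- spec$n_residues[1]; nB <- spec$n_residues[2]
    A <- globule_walk(nA)
    B <- globule_walk(nB)
    # push B to +x, then solve the shift giving the requested approach
    spanA <- max(A[, 1]); spanB <- min(B[, 1])
    t0 <- spanA - spanB + spec$interface_offset + 60
    mindist <- function(t) {
      Bt <- sweep(B, 2, c(t, 0, 0), "+")
      min(cross_dist_min(A, Bt))
    }
    f <- function(t) mindist(t) - spec$interface_offset
    # f is increasing in t; bracket and bisect
    lo <- 0; hi <- t0
    if (f(lo) > 0) lo <- -t0
    t_star <- uniroot(f, c(lo, hi), tol = 1e-6)$root
    B <- sweep(B, 2, c(t_star, 0, 0), "+")
    # interface midpoint = midpoint of the closest residue pair
    dm <- cross_dist(A, B)
    ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    mid <- (A[ij[1], ] + B[ij[2], ]) / 2
    if (length(spec$planted_cluster)) {
      k <- length(spec$planted_cluster)
      # uniform in the sphere
      u <- matrix(rnorm(3 * k), k, 3)
      u <- u / sqrt(rowSums(u^2)) * (runif(k)^(1 / 3) * spec$cluster_radius)
      A[spec$planted_cluster, ] <- sweep(u, 2, mid, "+")
    }
    # varied residue identities so chain sequences are informative for
    # sequence-to-structure mapping
    rnA <- sample(names(AA3TO1), nA, replace = TRUE)
    rnB <- sample(names(AA3TO1), nB, replace = TRUE)
    atoms <- rbind(
      data.frame(chain = "A", resno = seq_len(nA), ins = "",
                 resname = rnA, elety = "CA",
                 x = A[, 1], y = A[, 2], z = A[, 3], occ = 1,
                 stringsAsFactors = FALSE),
      data.frame(chain = "B", resno = seq_len(nB), ins = "",
                 resname = rnB, elety = "CA",
                 x = B[, 1], y = B[, 2], z = B[, 3], occ = 1,
                 stringsAsFactors = FALSE))
    list(structure = structure3d(atoms),
         truth = list(planted = spec$planted_cluster, midpoint = mid))
  })
}

cross_dist <- function(A, B) {
  # full Euclidean distance matrix between two point sets
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

cross_dist_min <- function(A, B) min(cross_dist(A, B))

#' Specification of a simulated saturation-binding curve
#'
#' @param Amax Absorbance at saturation (OD units).
#' @param Kd Equilibrium dissociation constant (nM), > 0.
#' @param hill_h Hill slope; 1 gives the simple one-site model.
#' @param concentrations Ligand concentrations (nM), all > 0. Default: a
#'   two-fold dilution series of 12 points from 0.25 nM.
#' @param noise_sd Gaussian noise standard deviation on absorbance.
#' @param seed Integer seed.
#' @return A `binding_sim_spec`.
#' @export
binding_sim_spec <- function(Amax = 1, Kd = 20, hill_h = 1,
                             concentrations = 0.25 * 2^(0:11),
                             noise_sd = 0, seed = 1L) {
  stopifnot(Amax > 0, Kd > 0, hill_h >= 0, noise_sd >= 0,
            all(concentrations > 0))
  structure(list(Amax = Amax, Kd = Kd, hill_h = hill_h,
                 concentrations = as.numeric(concentrations),
                 noise_sd = noise_sd, seed = seed),
            class = "binding_sim_spec")
}

#' Simulate a saturation-binding curve
#'
#' `A_i = Amax * L_i^h / (Kd^h + L_i^h) + e_i`, `e_i ~ N(0, noise_sd)`.
#' With `h = 1` this is the one-site model `A = Amax / (1 + Kd/L)`.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [binding_sim_spec()].
#' @return A [binding_curve] with columns `L` (nM) and `A` (OD).
#' @export
gen_binding_curve <- function(spec) {
  stopifnot(inherits(spec, "binding_sim_spec"))
  with_seed(spec$seed, {
    L <- spec$concentrations
    A <- model_one_site(L, spec$Amax, spec$Kd, spec$hill_h)
    if (spec$noise_sd > 0) A <- A + rnorm(length(L), 0, spec$noise_sd)
    binding_curve(L, A)
  })
}
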