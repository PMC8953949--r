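# Hierarchical subgroup partitioning with pattern selection.
#
# The statistic behind everything here is a hypergeometric ("ball in urn")
# contrast: how surprising is the foreground count of a residue set at a
# column, drawing without replacement from foreground + background. A +1
# pseudocount on the background keeps the tail finite when the background
# never shows the set.

encode_msa <- function(x) {
  m <- msa_matrix(x)
  M <- matrix(match(m, AA20, nomatch = 0L), nrow = nrow(m))
  rownames(M) <- x$ids
  M
}

# residue counts per column for a row subset: 20 x L integer matrix
col_counts <- function(M, rows) {
  L <- ncol(M)
  Ms <- M[rows, , drop = FALSE]
  idx <- Ms + 20L * (col(Ms) - 1L)
  counts <- tabulate(idx[Ms > 0L], nbins = 20L * L)
  matrix(counts, nrow = 20L, ncol = L)
}

#' Hypergeometric contrast score for a subgroup-distinguishing residue set
#'
#' Scores how strongly a residue set is enriched in a foreground relative
#' to a background at one alignment column:
#' `score = -log10 P(X >= fg_matches)` where `X` is hypergeometric with
#' `fg_total` draws from an urn holding `fg_matches + bg_matches` marked
#' balls out of `fg_total + bg_total`. A +1 pseudocount is added to
#' `bg_matches` and `bg_total` so the tail never vanishes. Vectorized.
#'
#' @param fg_matches,fg_total Foreground residue-set count and non-gap
#'   total at the column.
#' @param bg_matches,bg_total Background counts, likewise.
#' @return Non-negative score(s) in -log10 units.
#' @export
contrast_score <- function(fg_matches, fg_total, bg_matches, bg_total) {
  if (any(fg_total <= 0) || any(bg_total <= 0))
    stop("domain-error: totals must be positive", call. = FALSE)
  if (any(fg_matches > fg_total) || any(bg_matches > bg_total) ||
      any(fg_matches < 0) || any(bg_matches < 0))
    stop("domain-error: matches must lie in [0, total]", call. = FALSE)
  bgm <- bg_matches + 1
  bgt <- bg_total + 1
  K <- fg_matches + bgm
  N <- fg_total + bgt
  lp <- phyper(fg_matches - 1, K, N - K, fg_total,
               lower.tail = FALSE, log.p = TRUE)
  pmax(0, -lp / log(10))
}

#' Sampler configuration
#'
#' @param max_depth Maximum tree depth below the root (>= 1).
#' @param max_children Maximum children per node; 0 allows only the root.
#' @param min_node_size Smallest subgroup the sampler will create.
#' @param max_pattern_positions Pattern length cap per node.
#' @param pattern_penalty Score units charged per pattern position; a
#'   column enters a pattern only with score above this.
#' @param n_sweeps Sampler sweeps.
#' @param split_margin Held-out evidence (score units, excluding the
#'   column that seeded the proposal) a split must exceed to be accepted;
#'   this is the sampler's family-wise control against splits that look
#'   enriched only because the foreground was selected on that column.
#' @param n_split_candidates Split proposals per node per sweep.
#' @param refine_rounds Reassign/re-select iterations inside a proposal.
#' @param seed Integer seed; the sampler is deterministic given it.
#' @return A `sampler_config`.
#' @export
sampler_config <- function(max_depth = 3, max_children = 4,
                           min_node_size = 25, max_pattern_positions = 20,
                           pattern_penalty = 2.0, n_sweeps = 20,
                           split_margin = 5, n_split_candidates = 3,
                           refine_rounds = 3, seed = 1L) {
  if (max_depth < 1) stop("spec-error: max_depth must be >= 1", call. = FALSE)
  stopifnot(max_children >= 0, min_node_size >= 2,
            max_pattern_positions >= 1, pattern_penalty >= 0, n_sweeps >= 1,
            split_margin >= 0, n_split_candidates >= 1, refine_rounds >= 1)
  structure(list(max_depth = max_depth, max_children = max_children,
                 min_node_size = min_node_size,
                 max_pattern_positions = max_pattern_positions,
                 pattern_penalty = pattern_penalty, n_sweeps = n_sweeps,
                 split_margin = split_margin,
                 n_split_candidates = n_split_candidates,
                 refine_rounds = refine_rounds, seed = seed),
            class = "sampler_config")
}

# vectorized pattern selection over all columns; fg/bg are row indices
.select_pattern <- function(M, fg, bg, cfg) {
  nf <- length(fg); nb <- length(bg)
  fgc <- col_counts(M, fg)
  bgc <- col_counts(M, bg)
  fgt <- colSums(fgc)
  bgt <- colSums(bgc)
  # columns with > 50% foreground gaps are ineligible
  elig <- fgt >= nf / 2 & fgt > 0 & bgt > 0
  if (!any(elig)) return(empty_pattern())
  L <- ncol(M)
  mask <- matrix(FALSE, 20L, L)
  modal <- max.col(t(fgc), ties.method = "first")
  mask[cbind(modal, seq_len(L))] <- TRUE
  sc <- function(msk) {
    fgm <- colSums(fgc * msk); bgm <- colSums(bgc * msk)
    s <- rep(0, L)
    s[elig] <- contrast_score(fgm[elig], fgt[elig], bgm[elig], bgt[elig])
    s
  }
  # A residue set of size s is the best of ~C(20, s) candidates, so its
  # raw tail score is inflated by that selection; charge log10 C(20, s)
  # per column. Sets grow (cap 3) only while the adjusted score improves,
  # which keeps adversarial multi-residue sets off pure null columns.
  adj <- function(raw, msk) raw - log10(choose(20, colSums(msk)))
  score <- adj(sc(mask), mask)
  for (step in 2:3) {
    fgc_rest <- fgc
    fgc_rest[mask] <- -1L
    cand <- max.col(t(fgc_rest), ties.method = "first")
    mask2 <- mask
    mask2[cbind(cand, seq_len(L))] <- TRUE
    score2 <- adj(sc(mask2), mask2)
    grow <- score2 > score + 1e-9
    if (!any(grow)) break
    mask[cbind(cand[grow], which(grow))] <- TRUE
    score[grow] <- score2[grow]
  }
  keep <- which(elig & score > cfg$pattern_penalty)
  if (!length(keep)) return(empty_pattern())
  ord <- order(-score[keep], keep)
  keep <- keep[ord][seq_len(min(length(keep), cfg$max_pattern_positions))]
  fgm <- colSums(fgc * mask); bgm <- colSums(bgc * mask)
  data.frame(
    column = keep,
    residues = vapply(keep, function(j)
      paste(AA20[mask[, j]], collapse = ""), ""),
    score = score[keep],
    fg_matches = fgm[keep], fg_total = fgt[keep],
    bg_matches = bgm[keep], bg_total = bgt[keep],
    stringsAsFactors = FALSE)
}

empty_pattern <- function() {
  data.frame(column = integer(0), residues = character(0),
             score = numeric(0), fg_matches = integer(0),
             fg_total = integer(0), bg_matches = integer(0),
             bg_total = integer(0), stringsAsFactors = FALSE)
}

#' Select the pattern positions distinguishing a foreground from a background
#'
#' For each column the residue set is grown greedily from the modal
#' foreground residue (cap 3 residues) while the multiplicity-adjusted
#' contrast score increases. The reported score is the
#' [contrast_score()] of the set minus `log10 C(20, set size)` - the
#' cost of having picked that set out of all same-size sets - so a
#' column must carry real signal, not a lucky residue combination, to
#' clear the penalty. Columns with more than 50% foreground gaps are
#' ineligible. Returns at most `cfg$max_pattern_positions` columns, all
#' with adjusted score above `cfg$pattern_penalty`, sorted by descending
#' score with ties broken by ascending column.
#'
#' @param x An [msa].
#' @param fg,bg Disjoint, non-empty sets of sequence ids (or row indices).
#' @param cfg A [sampler_config()].
#' @return Data frame with `column`, `residues`, `score`, `fg_matches`,
#'   `fg_total`, `bg_matches`, `bg_total`.
#' @export
select_pattern <- function(x, fg, bg, cfg = sampler_config()) {
  stopifnot(inherits(x, "msa"))
  fg <- resolve_rows(x, fg); bg <- resolve_rows(x, bg)
  if (!length(fg) || !length(bg))
    stop("domain-error: foreground and background must be non-empty",
         call. = FALSE)
  if (length(intersect(fg, bg)))
    stop("domain-error: foreground and background overlap", call. = FALSE)
  .select_pattern(encode_msa(x), fg, bg, cfg)
}

resolve_rows <- function(x, who) {
  if (is.character(who)) {
    idx <- match(who, x$ids)
    if (anyNA(idx)) stop("unknown sequence id(s)", call. = FALSE)
    idx
  } else as.integer(who)
}

# Bernoulli set-membership log-odds of a pattern for each row, Laplace
# smoothed; gap positions contribute 0.
.logodds <- function(M, rows, pattern) {
  s <- numeric(length(rows))
  if (!nrow(pattern)) return(s)
  pf <- (pattern$fg_matches + 1) / (pattern$fg_total + 2)
  pb <- (pattern$bg_matches + 1) / (pattern$bg_total + 2)
  for (k in seq_len(nrow(pattern))) {
    setv <- match(strsplit(pattern$residues[k], "")[[1]], AA20)
    rv <- M[rows, pattern$column[k]]
    contrib <- ifelse(rv == 0L, 0,
                      ifelse(rv %in% setv, log(pf[k] / pb[k]),
                             log((1 - pf[k]) / (1 - pb[k]))))
    s <- s + contrib
  }
  s
}

# ---- hierarchy container -------------------------------------------------

new_hierarchy <- function(ids, members) {
  structure(list(
    nodes = list(`1` = list(id = 1L, parent = NA_integer_,
                            children = integer(0),
                            members = members, pattern = empty_pattern())),
    ids = ids, next_id = 2L, objective = 0, trace = numeric(0)),
    class = "hierarchy")
}

#' @export
print.hierarchy <- function(x, ...) {
  cat(sprintf("hierarchy: %d nodes over %d sequences, objective %.1f\n",
              length(x$nodes), length(x$ids), x$objective))
  for (nd in x$nodes)
    cat(sprintf("  node %d%s: %d direct members, %d pattern positions\n",
                nd$id,
                if (is.na(nd$parent)) " (root)"
                else sprintf(" (parent %d)", nd$parent),
                length(nd$members), nrow(nd$pattern)))
  invisible(x)
}

node_key <- function(id) as.character(id)

#' Foreground and background of a hierarchy node
#'
#' The foreground of a node is every sequence in its subtree; the
#' background is the parent's foreground minus the node's own.
#'
#' @param h A `hierarchy` from [sample_hierarchy()].
#' @param node_id Node id (root is 1).
#' @return Integer row indices into the alignment the hierarchy was
#'   built from.
#' @export
foreground_members <- function(h, node_id) {
  nd <- h$nodes[[node_key(node_id)]]
  if (is.null(nd)) stop("no node ", node_id, call. = FALSE)
  out <- nd$members
  for (ch in nd$children) out <- c(out, foreground_members(h, ch))
  sort(out)
}

#' @rdname foreground_members
#' @export
background_members <- function(h, node_id) {
  nd <- h$nodes[[node_key(node_id)]]
  if (is.null(nd)) stop("no node ", node_id, call. = FALSE)
  if (is.na(nd$parent))
    stop("domain-error: the root has no background", call. = FALSE)
  setdiff(foreground_members(h, nd$parent), foreground_members(h, node_id))
}

#' Node assignment of every sequence
#'
#' @param h A `hierarchy`.
#' @return Integer vector: for each sequence (in alignment order) the id
#'   of the node it is directly assigned to.
#' @export
leaf_assignment <- function(h) {
  out <- rep(NA_integer_, length(h$ids))
  for (nd in h$nodes) out[nd$members] <- nd$id
  out
}

validate_hierarchy <- function(h, n_seq) {
  all_members <- unlist(lapply(h$nodes, `[[`, "members"))
  if (anyDuplicated(all_members) || !setequal(all_members, seq_len(n_seq)))
    stop("domain-error: node memberships are not a partition", call. = FALSE)
  invisible(TRUE)
}

node_depth <- function(h, id) {
  d <- 0L
  while (!is.na(h$nodes[[node_key(id)]]$parent)) {
    id <- h$nodes[[node_key(id)]]$parent
    d <- d + 1L
  }
  d
}

#' Hierarchy objective
#'
#' Sum over non-root nodes of (pattern score sum - penalty x number of
#' pattern positions); higher is better. The root carries no pattern.
#'
#' @param x The [msa] the hierarchy was built from.
#' @param h A `hierarchy`.
#' @param cfg A [sampler_config()] (for the penalty).
#' @param recompute Re-select every node's pattern before scoring
#'   (default uses the stored patterns).
#' @return Numeric score in -log10 units.
#' @export
hierarchy_objective <- function(x, h, cfg = sampler_config(),
                                recompute = FALSE) {
  validate_hierarchy(h, n_sequences(x))
  if (recompute) h <- refresh_patterns(encode_msa(x), h, cfg)
  obj <- 0
  for (nd in h$nodes) {
    if (is.na(nd$parent)) next
    obj <- obj + sum(nd$pattern$score) -
      cfg$pattern_penalty * nrow(nd$pattern)
  }
  obj
}

refresh_patterns <- function(M, h, cfg) {
  for (k in names(h$nodes)) {
    nd <- h$nodes[[k]]
    if (is.na(nd$parent)) next
    fg <- foreground_members(h, nd$id)
    bg <- setdiff(foreground_members(h, nd$parent), fg)
    h$nodes[[k]]$pattern <-
      if (length(fg) && length(bg)) .select_pattern(M, fg, bg, cfg)
      else empty_pattern()
  }
  h
}

# ---- the sampler ---------------------------------------------------------

# candidate (column, residue) seeds for splitting a pool of rows:
# residues at intermediate frequency, ranked by split balance
split_candidates <- function(M, pool, n_cand) {
  pc <- col_counts(M, pool)
  n <- length(pool)
  frac <- pc / n
  ok <- which(frac >= 0.10 & frac <= 0.90, arr.ind = TRUE)
  if (!nrow(ok)) return(NULL)
  qual <- pc[ok] * (n - pc[ok])
  top <- ok[order(-qual)[seq_len(min(10L, nrow(ok)))], , drop = FALSE]
  pick <- if (nrow(top) <= n_cand) seq_len(nrow(top))
          else sample.int(nrow(top), n_cand)
  lapply(pick, function(i)
    list(column = top[i, 2L], residue = top[i, 1L]))
}

# score an already-chosen pattern (columns + residue sets) on fresh
# foreground/background rows; the held-out half of split validation
eval_pattern_objective <- function(M, pattern, fg, bg, cfg) {
  if (!nrow(pattern)) return(0)
  total <- 0; used <- 0L
  for (k in seq_len(nrow(pattern))) {
    setv <- match(strsplit(pattern$residues[k], "")[[1]], AA20)
    fv <- M[fg, pattern$column[k]]; bv <- M[bg, pattern$column[k]]
    fgt <- sum(fv > 0L); bgt <- sum(bv > 0L)
    if (fgt == 0 || bgt == 0) next
    total <- total + contrast_score(sum(fv %in% setv), fgt,
                                    sum(bv %in% setv), bgt)
    used <- used + 1L
  }
  total - cfg$pattern_penalty * used
}

# iterative pattern-selection / log-odds reassignment of fg within rows
refine_fg <- function(M, rows, fg, cfg, min_size) {
  for (r in seq_len(cfg$refine_rounds)) {
    bg <- setdiff(rows, fg)
    pat <- .select_pattern(M, fg, bg, cfg)
    if (!nrow(pat)) return(NULL)
    fg2 <- rows[.logodds(M, rows, pat) > 0]
    if (length(fg2) < min_size || length(rows) - length(fg2) < min_size)
      return(fg)
    if (setequal(fg2, fg)) return(fg2)
    fg <- fg2
  }
  fg
}

# refine a proposed split of `pool` (direct members of `node`) into a new
# child. Acceptance is decided on held-out evidence: the pattern is
# trained on a random half of the pool and scored on the other half
# (excluding the column that seeded the proposal), so splits that look
# enriched only because the foreground was selected on this data are
# rejected. Returns NULL or list(fg, pattern, heldout).
refine_split <- function(M, pool, seedcol, seedres, cfg) {
  fg <- pool[M[pool, seedcol] == seedres]
  if (length(fg) < cfg$min_node_size ||
      length(pool) - length(fg) < cfg$min_node_size) return(NULL)
  train <- sample(pool, floor(length(pool) / 2))
  test <- setdiff(pool, train)
  half_min <- max(5L, cfg$min_node_size %/% 4L)
  fg_tr <- intersect(fg, train)
  if (length(fg_tr) < half_min ||
      length(train) - length(fg_tr) < half_min) return(NULL)
  fg_tr <- refine_fg(M, train, fg_tr, cfg, half_min)
  if (is.null(fg_tr)) return(NULL)
  pat_tr <- .select_pattern(M, fg_tr, setdiff(train, fg_tr), cfg)
  pat_tr <- pat_tr[pat_tr$column != seedcol, , drop = FALSE]
  if (!nrow(pat_tr)) return(NULL)
  fg_te <- test[.logodds(M, test, pat_tr) > 0]
  bg_te <- setdiff(test, fg_te)
  if (length(fg_te) < half_min || length(bg_te) < half_min) return(NULL)
  heldout <- eval_pattern_objective(M, pat_tr, fg_te, bg_te, cfg)
  if (heldout <= cfg$split_margin) return(NULL)
  fg <- refine_fg(M, pool, fg, cfg, cfg$min_node_size)
  if (is.null(fg)) return(NULL)
  bg <- setdiff(pool, fg)
  if (length(fg) < cfg$min_node_size || length(bg) < cfg$min_node_size)
    return(NULL)
  pat <- .select_pattern(M, fg, bg, cfg)
  if (!nrow(pat)) return(NULL)
  list(fg = fg, pattern = pat, heldout = heldout)
}

# propose adopting ALL remaining direct members of a node (which already
# has children) as a child of their own, against the rest of the node's
# foreground; validated split-half like refine_split
adopt_proposal <- function(M, pool, bg_all, cfg) {
  if (length(pool) < cfg$min_node_size || length(bg_all) < 2) return(NULL)
  tr_fg <- sample(pool, floor(length(pool) / 2))
  tr_bg <- sample(bg_all, floor(length(bg_all) / 2))
  if (length(tr_fg) < 3 || length(tr_bg) < 3) return(NULL)
  pat_tr <- .select_pattern(M, tr_fg, tr_bg, cfg)
  if (!nrow(pat_tr)) return(NULL)
  te_fg <- setdiff(pool, tr_fg)
  te_bg <- setdiff(bg_all, tr_bg)
  heldout <- eval_pattern_objective(M, pat_tr, te_fg, te_bg, cfg)
  if (heldout <= cfg$split_margin) return(NULL)
  pat <- .select_pattern(M, pool, bg_all, cfg)
  if (!nrow(pat)) return(NULL)
  list(fg = pool, pattern = pat, heldout = heldout)
}

#' Partition an alignment into a hierarchy of pattern-defined subgroups
#'
#' Alternates, over `cfg$n_sweeps` sweeps: (a) split proposals - at each
#' node a candidate column/residue seeds a tentative child, which is
#' refined by a few rounds of pattern re-selection and log-odds
#' reassignment and accepted only if the pattern evidence *excluding the
#' seeding column* exceeds `cfg$split_margin`; (b) greedy reassignment of
#' each sequence between a node and its children by pattern-match
#' log-odds; (c) pattern re-selection at every node; (d) pruning of
#' children whose pattern contribution is no longer positive. The
#' best-scoring hierarchy over all sweeps is returned. Deterministic
#' given `cfg$seed`.
#'
#' @param x An [msa].
#' @param cfg A [sampler_config()].
#' @return A `hierarchy`: nodes with direct members and patterns, the
#'   `objective` reached, and the per-sweep best-objective `trace`.
#' @export
sample_hierarchy <- function(x, cfg = sampler_config()) {
  stopifnot(inherits(x, "msa"))
  M <- encode_msa(x)
  n <- nrow(M)
  if (n < 2 * cfg$min_node_size && cfg$max_children > 0)
    warning("alignment smaller than two minimum subgroups; ",
            "only the root can be populated", call. = FALSE)
  with_seed(cfg$seed, {
    h <- new_hierarchy(x$ids, seq_len(n))
    best <- h
    best_obj <- 0
    trace <- numeric(0)
    for (sweep in seq_len(cfg$n_sweeps)) {
      # (a) split proposals
      for (k in names(h$nodes)) {
        nd <- h$nodes[[k]]
        if (length(nd$children) >= cfg$max_children) next
        if (node_depth(h, nd$id) >= cfg$max_depth) next
        pool <- h$nodes[[k]]$members
        if (length(pool) < 2 * cfg$min_node_size) next
        cands <- split_candidates(M, pool, cfg$n_split_candidates)
        for (cd in cands) {
          pool <- h$nodes[[k]]$members
          if (length(pool) < 2 * cfg$min_node_size) break
          sp <- refine_split(M, pool, cd$column, cd$residue, cfg)
          if (is.null(sp) || sp$heldout <= cfg$split_margin) next
          id <- h$next_id
          h$next_id <- h$next_id + 1L
          h$nodes[[node_key(id)]] <-
            list(id = id, parent = nd$id, children = integer(0),
                 members = sp$fg, pattern = sp$pattern)
          h$nodes[[k]]$members <- setdiff(pool, sp$fg)
          h$nodes[[k]]$children <- c(h$nodes[[k]]$children, id)
          if (length(h$nodes[[k]]$children) >= cfg$max_children) break
        }
        # leftover direct members of a node that already has children may
        # form a coherent subgroup of their own (no mid-frequency column
        # can seed them once they are nearly pure): adopt them as a child
        nd2 <- h$nodes[[k]]
        if (length(nd2$children) > 0 &&
            length(nd2$children) < cfg$max_children &&
            length(nd2$members) >= cfg$min_node_size) {
          bg_all <- setdiff(foreground_members(h, nd2$id), nd2$members)
          ad <- adopt_proposal(M, nd2$members, bg_all, cfg)
          if (!is.null(ad)) {
            id <- h$next_id
            h$next_id <- h$next_id + 1L
            h$nodes[[node_key(id)]] <-
              list(id = id, parent = nd2$id, children = integer(0),
                   members = ad$fg, pattern = ad$pattern)
            h$nodes[[k]]$members <- integer(0)
            h$nodes[[k]]$children <- c(h$nodes[[k]]$children, id)
          }
        }
      }
      # (b) greedy reassignment between each node and its children
      for (k in names(h$nodes)) {
        nd <- h$nodes[[k]]
        if (!length(nd$children)) next
        pool <- nd$members
        for (ch in nd$children)
          pool <- c(pool, h$nodes[[node_key(ch)]]$members)
        if (!length(pool)) next
        lo <- vapply(nd$children, function(ch)
          .logodds(M, pool, h$nodes[[node_key(ch)]]$pattern),
          numeric(length(pool)))
        lo <- matrix(lo, nrow = length(pool))
        bestch <- max.col(lo, ties.method = "first")
        bestlo <- lo[cbind(seq_along(pool), bestch)]
        assign_to <- ifelse(bestlo > 0, nd$children[bestch], nd$id)
        h$nodes[[k]]$members <- pool[assign_to == nd$id]
        for (ch in nd$children)
          h$nodes[[node_key(ch)]]$members <- pool[assign_to == ch]
      }
      # (c) pattern re-selection
      h <- refresh_patterns(M, h, cfg)
      # (d) prune childless nodes that no longer pay for themselves
      repeat {
        pruned <- FALSE
        for (k in names(h$nodes)) {
          nd <- h$nodes[[k]]
          if (is.na(nd$parent) || length(nd$children)) next
          contrib <- sum(nd$pattern$score) -
            cfg$pattern_penalty * nrow(nd$pattern)
          fg_n <- length(nd$members)
          if (contrib <= 0 || fg_n < cfg$min_node_size) {
            pk <- node_key(nd$parent)
            h$nodes[[pk]]$members <- c(h$nodes[[pk]]$members, nd$members)
            h$nodes[[pk]]$children <- setdiff(h$nodes[[pk]]$children, nd$id)
            h$nodes[[k]] <- NULL
            pruned <- TRUE
            break
          }
        }
        if (!pruned) break
      }
      obj <- 0
      for (nd in h$nodes) {
        if (is.na(nd$parent)) next
        obj <- obj + sum(nd$pattern$score) -
          cfg$pattern_penalty * nrow(nd$pattern)
      }
      if (obj > best_obj) { best <- h; best_obj <- obj }
      trace <- c(trace, best_obj)
    }
    best$objective <- best_obj
    best$trace <- trace
    validate_hierarchy(best, n)
    best
  })
}

#' Classify a sequence down a hierarchy
#'
#' Greedy descent: at each node the sequence moves to the child with the
#' highest pattern-match log-odds if that log-odds is positive, otherwise
#' it stops. Returns the root-to-assignment path of node ids.
#'
#' @param h A `hierarchy`.
#' @param x The [msa] the hierarchy was built from (for column count).
#' @param seq An aligned sequence string over the same columns.
#' @return Integer vector of node ids from the root to the assigned node.
#' @export
classify_sequence <- function(h, x, seq) {
  seq <- toupper(gsub(".", "-", seq, fixed = TRUE))
  if (nchar(seq) != n_columns(x))
    stop("alignment-error: sequence length does not match alignment",
         call. = FALSE)
  v <- match(strsplit(seq, "")[[1]], AA20, nomatch = 0L)
  Mrow <- matrix(v, nrow = 1)
  path <- 1L
  cur <- 1L
  repeat {
    ch <- h$nodes[[node_key(cur)]]$children
    if (!length(ch)) break
    lo <- vapply(ch, function(c2)
      .logodds(Mrow, 1L, h$nodes[[node_key(c2)]]$pattern), 0)
    if (max(lo) <= 0) break
    cur <- ch[which.max(lo)]
    path <- c(path, cur)
  }
  path
}

# ---- serialization -------------------------------------------------------

#' Serialize a hierarchy
#'
#' `hierarchy_json()` gives the full nodes/members/patterns record;
#' `hierarchy_newick()` a topology-only Newick-like string (node ids as
#' labels); `pattern_table()` one row per pattern position across nodes.
#'
#' @param h A `hierarchy`.
#' @param path Optional file to write to.
#' @return JSON string / newick string / data frame.
#' @export
hierarchy_json <- function(h, path = NULL) {
  nodes <- lapply(h$nodes, function(nd) list(
    id = nd$id,
    parent = if (is.na(nd$parent)) NULL else nd$parent,
    members = h$ids[nd$members],
    pattern = nd$pattern))
  js <- jsonlite::toJSON(list(objective = h$objective,
                              nodes = unname(nodes)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @rdname hierarchy_json
#' @export
hierarchy_newick <- function(h) {
  rec <- function(id) {
    ch <- h$nodes[[node_key(id)]]$children
    if (!length(ch)) return(as.character(id))
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", id)
  }
  paste0(rec(1L), ";")
}

#' @rdname hierarchy_json
#' @export
pattern_table <- function(h, path = NULL) {
  out <- do.call(rbind, lapply(h$nodes, function(nd) {
    if (!nrow(nd$pattern)) return(NULL)
    cbind(node_id = nd$id, nd$pattern)
  }))
  if (is.null(out)) out <- cbind(node_id = integer(0), empty_pattern())
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
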