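# End-to-end orchestration: filter -> partition -> render -> (structure
# mapping + clustering tests) -> (binding fits), with one global seed,
# a manifest, and machine-readable results.

#' Pipeline configuration
#'
#' @param msa Path to the alignment (FASTA/Stockholm), or an [msa].
#' @param structure Optional PDB path or [structure3d]; enables the
#'   interface and core clustering stages.
#' @param chain,partner_chain Chains for the clustering stages.
#' @param binding Optional named list/vector of binding-curve TSV paths
#'   (see [read_binding_tsv()]).
#' @param filter A [filter_config()].
#' @param sampler A [sampler_config()]; its seed is overridden by
#'   `seed`.
#' @param n_perm Permutations for the clustering tests.
#' @param focal_nodes Node ids to render; `NULL` renders every non-root
#'   node.
#' @param n_representatives Representatives per contrast alignment.
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed; every stochastic stage consumes a child
#'   seed derived from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(msa, structure = NULL, chain = "A",
                            partner_chain = "B", binding = NULL,
                            filter = filter_config(),
                            sampler = sampler_config(), n_perm = 999,
                            focal_nodes = NULL, n_representatives = 5,
                            out_dir = "fdrscope_out", seed = 1L) {
  if (is.null(msa)) stop("config requires an msa", call. = FALSE)
  structure(list(msa = msa, structure = structure, chain = chain,
                 partner_chain = partner_chain, binding = binding,
                 filter = filter, sampler = sampler, n_perm = n_perm,
                 focal_nodes = focal_nodes,
                 n_representatives = n_representatives,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror [pipeline_config()] arguments; `filter` and
#' `sampler` are nested maps passed to [filter_config()] /
#' [sampler_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    msa = y$msa, structure = y$structure,
    chain = y$chain %||% "A", partner_chain = y$partner_chain %||% "B",
    binding = y$binding,
    filter = do.call(filter_config, y$filter %||% list()),
    sampler = do.call(sampler_config, y$sampler %||% list()),
    n_perm = y$n_perm %||% 999, focal_nodes = y$focal_nodes,
    n_representatives = y$n_representatives %||% 5,
    out_dir = y$out_dir %||% "fdrscope_out", seed = y$seed %||% 1L)
}

child_seed <- function(seed, k) (as.integer(seed) * 1103L + 7919L * k) %% 2147483629L

#' Run the full analysis pipeline
#'
#' Stages: read + filter the alignment; partition it into a hierarchy of
#' pattern-defined subgroups; write contrast alignments and PyMOL
#' scripts per focal node; if a structure is given, map the first
#' foreground sequence of each focal node onto it and run the interface
#' and core clustering tests; if binding curves are given, fit each.
#' A manifest (inputs, seeds, per-stage counts) and a results JSON are
#' written under `cfg$out_dir`. Rerunning with the same config and seed
#' reproduces the results byte for byte.
#'
#' @param cfg A [pipeline_config()] (or path to a YAML file).
#' @return Invisibly, a list with `hierarchy`, `views`, `cluster`
#'   (per focal node), `fits`, `manifest`, and the output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "msa_io"
  result <- tryCatch({
    x <- if (inherits(cfg$msa, "msa")) cfg$msa else read_msa(cfg$msa)
    n_in <- n_sequences(x)
    xf <- filter_msa(x, cfg$filter, quiet = TRUE)
    message(sprintf("[%s] kept %d / removed %d of %d sequences",
                    stage, n_sequences(xf), n_in - n_sequences(xf), n_in))

    stage <- "bpps_core"
    scfg <- cfg$sampler
    scfg$seed <- child_seed(cfg$seed, 1L)
    h <- sample_hierarchy(xf, scfg)
    hierarchy_json(h, file.path(cfg$out_dir, "hierarchy.json"))
    pattern_table(h, file.path(cfg$out_dir, "patterns.tsv"))
    writeLines(hierarchy_newick(h), file.path(cfg$out_dir, "hierarchy.nwk"))
    message(sprintf("[%s] %d nodes, objective %.1f",
                    stage, length(h$nodes), h$objective))

    stage <- "contrast_output"
    focal <- cfg$focal_nodes %||%
      setdiff(vapply(h$nodes, `[[`, 0L, "id"), 1L)
    views <- list()
    for (nid in focal) {
      v <- render_contrast_alignment(h, xf, nid, cfg$n_representatives)
      write_contrast_view(
        v,
        file.path(cfg$out_dir, sprintf("contrast_node%d.txt", nid)),
        file.path(cfg$out_dir, sprintf("contrast_node%d.html", nid)))
      views[[as.character(nid)]] <- v
    }

    stage <- "structure3d/sipris_core"
    cluster <- list()
    if (!is.null(cfg$structure)) {
      s <- if (inherits(cfg$structure, "structure3d")) cfg$structure
           else read_structure(cfg$structure)
      for (nid in focal) {
        nd <- h$nodes[[node_key(nid)]]
        if (!nrow(nd$pattern)) next
        fg1 <- foreground_members(h, nid)[1]
        ungapped <- gsub("-", "", xf$seqs[fg1], fixed = TRUE)
        rmap <- suppressWarnings(
          map_seq_to_structure(ungapped, s, cfg$chain))
        # pattern columns -> ungapped positions of the representative
        cum <- cumsum(strsplit(xf$seqs[fg1], "")[[1]] != "-")
        pos <- cum[nd$pattern$column]
        pos <- pos[strsplit(xf$seqs[fg1], "")[[1]][nd$pattern$column] != "-"]
        resid <- rmap$resid[match(pos, rmap$seq_pos)]
        resid <- resid[!is.na(resid)]
        if (!length(resid)) next
        emit_pymol_script(
          as.integer(sub("[A-Za-z]*$", "", resid)), cfg$chain,
          sprintf("node%d_pattern", nid),
          path = file.path(cfg$out_dir, sprintf("node%d.pml", nid)))
        iface <- interface_sipris(s, cfg$chain, cfg$partner_chain, resid,
                                  n_perm = cfg$n_perm,
                                  seed = child_seed(cfg$seed, 100L + nid))
        core <- core_clustering(s, cfg$chain, resid, n_perm = cfg$n_perm,
                                seed = child_seed(cfg$seed, 200L + nid))
        cluster[[as.character(nid)]] <-
          list(residues = resid,
               interface = list(adjusted_p = iface$adjusted_p,
                                raw_p = iface$raw_p, k_star = iface$k_star),
               core = list(adjusted_p = core$adjusted_p,
                           raw_p = core$raw_p, k_star = core$k_star))
        message(sprintf(
          "[%s] node %d: interface p = %.3g, core p = %.3g",
          stage, nid, iface$adjusted_p, core$adjusted_p))
      }
    }

    stage <- "binding_fit"
    fits <- list()
    if (!is.null(cfg$binding)) {
      for (nm in names(cfg$binding)) {
        curve <- read_binding_tsv(cfg$binding[[nm]])
        f <- fit_binding(curve, hill = FALSE)
        fits[[nm]] <- list(Kd = f$Kd, Amax = f$Amax,
                           converged = f$converged, n = f$n)
        message(sprintf("[%s] %s: Kd = %.4g nM", stage, nm, f$Kd))
      }
    }

    stage <- "report"
    manifest <- list(
      inputs = list(
        msa = if (is.character(cfg$msa)) cfg$msa else "<in-memory msa>",
        structure = if (is.character(cfg$structure)) cfg$structure
                    else if (is.null(cfg$structure)) NULL
                    else "<in-memory structure>",
        binding = cfg$binding),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("fdrscope")),
      counts = list(sequences_in = n_in,
                    sequences_kept = n_sequences(xf),
                    nodes = length(h$nodes),
                    pattern_positions = sum(vapply(
                      h$nodes, function(nd) nrow(nd$pattern), 0L)),
                    focal_nodes = length(focal),
                    cluster_tests = length(cluster),
                    binding_fits = length(fits)),
      defaults = list(filter = unclass(cfg$filter),
                      sampler = unclass(cfg$sampler),
                      n_perm = cfg$n_perm))
    results <- list(objective = h$objective,
                    newick = hierarchy_newick(h),
                    cluster = cluster, fits = fits)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(results, file.path(cfg$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(hierarchy = h, views = views, cluster = cluster, fits = fits,
         manifest = manifest, out_dir = cfg$out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
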