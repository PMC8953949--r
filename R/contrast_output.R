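# Human-readable views of a node's pattern: a contrast alignment (plain
# text + HTML) juxtaposing foreground representatives against background
# residue frequencies, and PyMOL selection scripts for structures.

#' Render a contrast alignment for a hierarchy node
#'
#' Shows representative foreground sequences with the node's pattern
#' columns uppercased (everything else lowercased), a marker row flagging
#' the pattern columns with `*`, and beneath each pattern column the
#' background frequency of the pattern residue set as a percentage.
#' Representatives are the first `n_representatives` foreground members
#' in id order, or a seeded random sample.
#'
#' @param h A `hierarchy` from [sample_hierarchy()].
#' @param x The [msa] it was built from.
#' @param node_id A non-root node id.
#' @param n_representatives How many foreground sequences to display.
#' @param seed If non-NULL, sample representatives at random with this
#'   seed instead of taking the first by id order.
#' @return A `contrast_view` list: `text` (plain-text block), `html`,
#'   `node_id`, `pattern`, `bg_freq` (named percentage vector).
#' @export
render_contrast_alignment <- function(h, x, node_id, n_representatives = 5,
                                      seed = NULL) {
  nd <- h$nodes[[node_key(node_id)]]
  if (is.null(nd)) stop("no node ", node_id, call. = FALSE)
  if (is.na(nd$parent))
    stop("domain-error: the root has no pattern to contrast", call. = FALSE)
  fg <- foreground_members(h, node_id)
  bg <- background_members(h, node_id)
  pat <- nd$pattern
  reps <- if (is.null(seed)) {
    fg[order(h$ids[fg])][seq_len(min(n_representatives, length(fg)))]
  } else {
    with_seed(seed, sort(sample(fg, min(n_representatives, length(fg)))))
  }
  L <- n_columns(x)
  patcols <- sort(pat$column)
  # background frequency of each pattern column's residue set
  m <- msa_matrix(x)
  bg_freq <- vapply(seq_len(nrow(pat)), function(k) {
    j <- pat$column[k]
    setv <- strsplit(pat$residues[k], "")[[1]]
    colv <- m[bg, j]
    nong <- colv != "-"
    if (!any(nong)) return(0)
    100 * sum(colv[nong] %in% setv) / sum(nong)
  }, 0)
  names(bg_freq) <- as.character(pat$column)
  # sequence rows: pattern columns uppercase, others lowercase
  fmt_row <- function(i) {
    v <- strsplit(tolower(x$seqs[i]), "")[[1]]
    v[patcols] <- toupper(v[patcols])
    paste(v, collapse = "")
  }
  idw <- max(c(nchar(h$ids[reps]), nchar("bg%")), 10)
  pad <- function(s) formatC(s, width = idw, flag = "-")
  marker <- rep(" ", L); marker[patcols] <- "*"
  lines <- c(
    sprintf("contrast alignment: node %d (%d foreground, %d background)",
            node_id, length(fg), length(bg)),
    paste0(pad(""), " ", paste(marker, collapse = "")),
    vapply(reps, function(i) paste0(pad(h$ids[i]), " ", fmt_row(i)), ""))
  if (nrow(pat)) {
    freq_lines <- sprintf("  col %4d  [%s]  bg %5.1f%%  score %6.2f",
                          pat$column, pat$residues, bg_freq, pat$score)
    lines <- c(lines, "background frequency of pattern set:", freq_lines)
  } else {
    lines <- c(lines, "(empty pattern)")
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  html <- contrast_html(h, x, reps, pat, patcols, bg_freq, node_id)
  structure(list(text = text, html = html, node_id = node_id,
                 pattern = pat, bg_freq = bg_freq,
                 representatives = h$ids[reps]),
            class = "contrast_view")
}

contrast_html <- function(h, x, reps, pat, patcols, bg_freq, node_id) {
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s))
  row_html <- function(i) {
    v <- strsplit(x$seqs[i], "")[[1]]
    cells <- vapply(seq_along(v), function(j) {
      if (j %in% patcols)
        sprintf("<span class=\"pat\">%s</span>", esc(v[j]))
      else esc(tolower(v[j]))
    }, "")
    sprintf("<div class=\"seq\"><span class=\"id\">%s</span>%s</div>",
            esc(h$ids[i]), paste(cells, collapse = ""))
  }
  freq_html <- if (nrow(pat)) {
    paste(sprintf("<li>col %d [%s]: bg %.1f%% (score %.2f)</li>",
                  pat$column, esc(pat$residues), bg_freq, pat$score),
          collapse = "")
  } else ""
  paste0(
    "<html><head><style>",
    ".seq{font-family:monospace;white-space:pre}",
    ".id{display:inline-block;min-width:12em}",
    ".pat{background:#fdd835;font-weight:bold}",
    "</style></head><body>",
    sprintf("<h3>Contrast alignment: node %d</h3>", node_id),
    paste(vapply(reps, row_html, ""), collapse = "\n"),
    "<ul>", freq_html, "</ul></body></html>")
}

#' @export
print.contrast_view <- function(x, ...) {
  cat(x$text)
  invisible(x)
}

#' Write a contrast view to files
#'
#' @param view A `contrast_view`.
#' @param path_txt,path_html Optional output paths.
#' @return The view, invisibly.
#' @export
write_contrast_view <- function(view, path_txt = NULL, path_html = NULL) {
  stopifnot(inherits(view, "contrast_view"))
  if (!is.null(path_txt)) cat(view$text, file = path_txt)
  if (!is.null(path_html)) writeLines(view$html, path_html)
  invisible(view)
}

#' Emit a PyMOL selection script for a residue set
#'
#' Produces exactly three lines (plus trailing newline):
#' `select <name>, chain <c> and resi r1+r2+...` with residues in
#' ascending order, then `show sticks, <name>`, then
#' `color <color>, <name>`. Byte-identical across invocations.
#'
#' @param positions Non-empty vector of structure residue numbers.
#' @param chain Chain id.
#' @param selection_name Name for the PyMOL selection.
#' @param color PyMOL color name (default `"hotpink"`).
#' @param path Optional file to write the script to.
#' @return The script as a single string, invisibly if `path` is given.
#' @export
emit_pymol_script <- function(positions, chain, selection_name,
                              color = "hotpink", path = NULL) {
  if (length(positions) == 0)
    stop("domain-error: empty residue list", call. = FALSE)
  resi <- paste(sort(unique(as.integer(positions))), collapse = "+")
  script <- paste0(
    sprintf("select %s, chain %s and resi %s\n", selection_name, chain, resi),
    sprintf("show sticks, %s\n", selection_name),
    sprintf("color %s, %s\n", color, selection_name))
  if (!is.null(path)) {
    cat(script, file = path)
    return(invisible(script))
  }
  script
}
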