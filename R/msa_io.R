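#' @keywords internal
#' @importFrom stats phyper setNames coef lm residuals rnorm runif uniroot
#' @importFrom utils read.delim write.table packageVersion
"_PACKAGE"

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
MSA_ALPHABET <- c(AA20, "-", "X")

#' Construct a multiple sequence alignment object
#'
#' An `msa` is the unit of partitioning throughout the package: a set of
#' equal-length rows over the 20 amino acids plus `-` (gap) and `X`
#' (unknown residue). Gap characters `.` are normalized to `-` on
#' construction.
#'
#' @param ids Character vector of unique, non-empty sequence identifiers.
#' @param seqs Character vector of aligned rows, all the same width.
#' @param desc Optional character vector of descriptions (recycled to "").
#' @return An object of class `msa` with fields `ids`, `seqs`, `desc` and
#'   attribute-free accessors [n_columns()] and [n_sequences()].
#' @export
msa <- function(ids, seqs, desc = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length", call. = FALSE)
  if (length(seqs) < 1L)
    stop("empty-input: an alignment needs at least one sequence", call. = FALSE)
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    stop("sequence ids must be non-empty and unique", call. = FALSE)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("alignment-error: rows have unequal lengths (",
         paste(unique(w), collapse = ", "), ")", call. = FALSE)
  if (w[1] < 1L) stop("alignment-error: zero-width alignment", call. = FALSE)
  bad <- grepl(sprintf("[^%sX-]", paste(AA20, collapse = "")), seqs)
  if (any(bad))
    stop("alignment-error: illegal characters in sequence(s) ",
         paste(ids[bad][seq_len(min(3, sum(bad)))], collapse = ", "),
         call. = FALSE)
  if (is.null(desc)) desc <- character(length(ids))
  structure(list(ids = ids, seqs = seqs,
                 desc = rep_len(as.character(desc), length(ids))),
            class = "msa")
}

#' @rdname msa
#' @param x An `msa`.
#' @export
n_columns <- function(x) nchar(x$seqs[1])

#' @rdname msa
#' @export
n_sequences <- function(x) length(x$seqs)

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n",
              n_sequences(x), n_columns(x)))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param x An `msa`.
#' @return Character matrix, one row per sequence, rownames = ids.
#' @export
msa_matrix <- function(x) {
  m <- matrix(unlist(strsplit(x$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(x$seqs), byrow = TRUE)
  rownames(m) <- x$ids
  m
}

#' Read an alignment from FASTA or Stockholm
#'
#' Both `.` and `-` are accepted as gaps on input; `-` is canonical
#' internally and on output.
#'
#' @param path File path.
#' @param format `"fasta"` or `"stockholm"`; defaults to a guess from the
#'   file extension (`.sto`/`.stk` means Stockholm).
#' @return An [msa] object.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("sto", "stk", "stockholm")) "stockholm" else "fasta"
  }
  if (file.size(path) == 0)
    stop("empty-input: ", path, call. = FALSE)
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("alignment-error: ", conditionMessage(e),
                             call. = FALSE))
  s <- as.character(Biostrings::unmasked(aln))
  if (length(s) == 0) stop("empty-input: no sequences in ", path, call. = FALSE)
  ids <- names(s)
  desc <- sub("^\\S+\\s*", "", ids)
  ids <- sub("\\s.*$", "", ids)
  msa(ids = ids, seqs = unname(s), desc = desc)
}

#' Write an alignment to FASTA
#'
#' @param x An [msa].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  hdr <- ifelse(nzchar(x$desc), paste(x$ids, x$desc), x$ids)
  writeLines(paste0(">", hdr, "\n", x$seqs), path)
  invisible(path)
}

#' Filtering configuration for fragments and redundancy
#'
#' @param max_deletion_fraction Rows with a gap fraction strictly greater
#'   than this are removed as fragments. Default 0.25.
#' @param identity_threshold Pairwise identity at or above which the later
#'   of two rows is removed as redundant. Default 0.98.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_deletion_fraction = 0.25,
                          identity_threshold = 0.98) {
  stopifnot(max_deletion_fraction >= 0, max_deletion_fraction <= 1,
            identity_threshold >= 0, identity_threshold <= 1)
  structure(list(max_deletion_fraction = max_deletion_fraction,
                 identity_threshold = identity_threshold),
            class = "filter_config")
}

#' Remove sequence fragments from an alignment
#'
#' A row's deletion fraction is its gap count divided by the total column
#' count (`X` counts as a residue). Rows with deletion fraction strictly
#' greater than `cfg$max_deletion_fraction` are removed; a row with exactly
#' the threshold fraction survives. Row order is preserved.
#'
#' @param x An [msa].
#' @param cfg A [filter_config()].
#' @return Filtered `msa` (possibly with zero rows, in which case an error
#'   is raised by the `msa` invariant only when all rows are removed; an
#'   empty survivor set returns a zero-row list-alike via `subset_msa`).
#' @export
filter_fragments <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "msa"))
  gapfrac <- deletion_fraction(x)
  keep <- gapfrac <= cfg$max_deletion_fraction
  subset_msa(x, keep)
}

#' @rdname filter_fragments
#' @export
deletion_fraction <- function(x) {
  ngap <- nchar(x$seqs) - nchar(gsub("-", "", x$seqs, fixed = TRUE))
  ngap / n_columns(x)
}

# keep = logical or integer index; allows empty survivor sets
subset_msa <- function(x, keep) {
  out <- list(ids = x$ids[keep], seqs = x$seqs[keep], desc = x$desc[keep])
  class(out) <- "msa"
  out
}

#' Pairwise identity between two aligned rows
#'
#' Identity = identical residues / columns where both rows are non-gap.
#' Returns 0 when the rows share no non-gap columns. `X` matches only `X`.
#'
#' @param a,b Aligned row strings of equal length (or single-sequence
#'   selections from the same `msa`).
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("alignment-error: length mismatch", call. = FALSE)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  both <- av != "-" & bv != "-"
  if (!any(both)) return(0)
  sum(av[both] == bv[both]) / sum(both)
}

#' Remove near-duplicate rows from an alignment
#'
#' Scans rows in input order; a row is dropped if its pairwise identity
#' with any previously retained row is at or above
#' `cfg$identity_threshold` (the boundary is inclusive: a pair at exactly
#' the threshold is deduplicated). The first member of each redundancy
#' group is kept; survivor order is the input order.
#'
#' @inheritParams filter_fragments
#' @return Deduplicated `msa`.
#' @export
dedupe <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "msa"))
  n <- n_sequences(x)
  if (n <= 1L) return(x)
  m <- msa_matrix(x)
  nong <- m != "-"
  keep_idx <- integer(0)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in keep_idx) {
      both <- nong[i, ] & nong[j, ]
      nb <- sum(both)
      ident <- if (nb == 0) 0 else sum(m[i, both] == m[j, both]) / nb
      if (ident >= cfg$identity_threshold) { dup <- TRUE; break }
    }
    if (!dup) keep_idx <- c(keep_idx, i)
  }
  subset_msa(x, keep_idx)
}

#' Apply both alignment filters
#'
#' Fragment removal followed by redundancy removal, as used to reduce a
#' raw superfamily alignment before partitioning. The composite is
#' idempotent.
#'
#' @inheritParams filter_fragments
#' @param quiet Suppress the kept/removed summary message.
#' @return Filtered `msa`.
#' @export
filter_msa <- function(x, cfg = filter_config(), quiet = FALSE) {
  n0 <- n_sequences(x)
  out <- dedupe(filter_fragments(x, cfg), cfg)
  n1 <- n_sequences(out)
  if (!quiet)
    message(sprintf("filter_msa: kept %d / removed %d of %d sequences",
                    n1, n0 - n1, n0))
  out
}
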