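#' Ranked taxonomic lineages
#'
#' A `ranked_lineage` is an ordered, root-first vector of taxon names,
#' optionally annotated with rank labels (domain, phylum, ...). It is the
#' unit of all taxonomic comparison in ampligold: classification scoring
#' ("ranks off") is arithmetic on positions in these vectors.
#'
#' Comparison between lineages is positional by taxon name, not by rank
#' label, because reference exports (NCBI, Silva) use ladders of different
#' depth; rank labels are carried as metadata only. Whitespace around the
#' delimiter is stripped on parsing; taxon names compare case-sensitively.
#'
#' @param taxonomy_string A single delimiter-separated, root-first taxonomy
#'   string, e.g. `"Bacteria;Firmicutes;Bacilli"`.
#' @param rank_labels Optional character vector of rank labels, one per
#'   field of `taxonomy_string` (after trimming trailing empties).
#' @param delim Field delimiter, default `";"`.
#' @return A `ranked_lineage`: a character vector of taxon names (root
#'   first) with an optional `ranks` attribute.
#' @examples
#' lin <- parse_lineage("Bacteria;Firmicutes;Bacilli")
#' lineage_depth(lin)
#' @export
parse_lineage <- function(taxonomy_string, rank_labels = NULL, delim = ";") {
  stopifnot(is.character(taxonomy_string), length(taxonomy_string) == 1L)
  fields <- trimws(strsplit(taxonomy_string, delim, fixed = TRUE)[[1]])
  # trailing empty fields (e.g. "Bacteria;;") are trimmed, internal ones are
  # malformed input
  while (length(fields) > 0L && fields[length(fields)] == "") {
    fields <- fields[-length(fields)]
  }
  if (length(fields) == 0L) stop("empty lineage")
  if (any(fields == "")) stop("gapped lineage: internal empty field in '",
                              taxonomy_string, "'")
  if (!is.null(rank_labels)) {
    if (length(rank_labels) != length(fields)) {
      stop("rank_labels length (", length(rank_labels),
           ") does not match lineage depth (", length(fields), ")")
    }
    if (anyDuplicated(rank_labels)) stop("duplicate rank label")
  }
  new_lineage(fields, rank_labels)
}

new_lineage <- function(names, ranks = NULL) {
  structure(names, ranks = ranks, class = "ranked_lineage")
}

#' @rdname parse_lineage
#' @param lineage A `ranked_lineage`.
#' @export
serialize_lineage <- function(lineage, delim = ";") {
  paste(unclass(lineage), collapse = delim)
}

#' @rdname parse_lineage
#' @export
lineage_depth <- function(lineage) length(lineage)

#' @export
print.ranked_lineage <- function(x, ...) {
  cat("<ranked_lineage depth ", length(x), "> ", serialize_lineage(x), "\n",
      sep = "")
  invisible(x)
}

#' Depth of the last common ancestor of two lineages
#'
#' Length of the longest common root-first prefix, comparing taxon names
#' positionally. Two lineages disjoint at the root have `lca_depth` 0.
#'
#' @param a,b `ranked_lineage` objects (or character vectors of taxon
#'   names, root first).
#' @return Integer prefix length, `0 <= lca_depth(a, b) <= min(depth)`.
#' @export
lca_depth <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  same <- a[seq_len(n)] == b[seq_len(n)]
  if (all(same)) n else which.min(same) - 1L
}

#' Is one lineage an ancestor of (or equal to) another?
#'
#' `TRUE` iff the entries of `a` are exactly the first `depth(a)` entries
#' of `b` (so every lineage is an ancestor of itself).
#'
#' @inheritParams lca_depth
#' @export
is_ancestor <- function(a, b) {
  length(a) <= length(b) && lca_depth(a, b) == length(a)
}

#' Truncate a lineage to a given depth
#'
#' @param lineage A `ranked_lineage`.
#' @param depth Target depth, `1 <= depth <= lineage_depth(lineage)`.
#' @keywords internal
truncate_lineage <- function(lineage, depth) {
  stopifnot(depth >= 1L, depth <= length(lineage))
  ranks <- attr(lineage, "ranks")
  new_lineage(unclass(lineage)[seq_len(depth)],
              if (!is.null(ranks)) ranks[seq_len(depth)])
}

#' Canonical seven-level rank ladder
#'
#' The domain-to-species ladder used by the fixture generator and, by
#' default, wherever a named rank (e.g. "order") must be located in a
#' lineage that carries no rank labels of its own.
#' @export
canonical_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

# Position of a named rank in a lineage. Uses the lineage's own rank labels
# when present; otherwise falls back to conventions: "species" is the leaf
# field, "genus" the one above it, and any other rank is located via
# `rank_labels` applied positionally from the root.
rank_position <- function(lineage, rank, rank_labels = canonical_ranks()) {
  ranks <- attr(lineage, "ranks")
  if (!is.null(ranks)) {
    pos <- match(rank, ranks)
    return(if (is.na(pos)) NA_integer_ else pos)
  }
  d <- length(lineage)
  if (rank == "species") return(d)
  if (rank == "genus") return(if (d >= 2L) d - 1L else NA_integer_)
  pos <- match(rank, rank_labels)
  if (is.na(pos) || pos > d) NA_integer_ else pos
}
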