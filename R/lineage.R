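#' Taxonomic lineages
#'
#' A lineage is represented as a character vector of taxon names ordered from
#' domain to species. It may terminate early when a read or genome is
#' classified only to a higher rank; a zero-length lineage means
#' "unclassified". On disk (hit tables, reports) lineages are
#' semicolon-delimited rank paths, e.g. `"Bacteria;Proteobacteria;..."`.
#'
#' @name lineage
NULL

#' Canonical rank names, domain to species
#' @export
LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")

#' Parse a semicolon-delimited lineage string
#'
#' @param x character scalar, e.g. `"Bacteria;Proteobacteria"`. Empty string,
#'   `NA`, or `"unclassified"` parse to the empty (unclassified) lineage.
#' @return character vector of taxon names, domain first.
#' @export
parse_lineage <- function(x) {
  if (length(x) != 1L) stop("parse_lineage() expects a single string")
  if (is.na(x) || !nzchar(x) || identical(x, "unclassified")) return(character(0))
  out <- strsplit(x, ";", fixed = TRUE)[[1L]]
  out <- trimws(out)
  out[nzchar(out)]
}

#' Serialize a lineage to its string form
#'
#' @param lin character vector as returned by [parse_lineage()].
#' @return character scalar; `"unclassified"` for the empty lineage.
#' @export
format_lineage <- function(lin) {
  if (length(lin) == 0L) "unclassified" else paste(lin, collapse = ";")
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the deepest lineage prefix shared by all inputs. Lineages are
#' compared positionally from the domain downward; the first rank at which
#' any pair disagrees (or at which any lineage has already ended) terminates
#' the shared prefix. The empty prefix (no shared domain) is the unclassified
#' lineage.
#'
#' @param lineages non-empty list of lineages (character vectors).
#' @return the shared-prefix lineage (character vector, possibly empty).
#' @export
#' @examples
#' lca(list(c("Bacteria", "P1", "C1"), c("Bacteria", "P1", "C2")))
lca <- function(lineages) {
  if (!is.list(lineages) || length(lineages) == 0L)
    stop("lca() requires a non-empty list of lineages")
  depth <- min(lengths(lineages))
  if (depth == 0L) return(character(0))
  first <- lineages[[1L]]
  k <- 0L
  for (i in seq_len(depth)) {
    if (all(vapply(lineages, function(l) l[[i]] == first[[i]], logical(1)))) {
      k <- i
    } else {
      break
    }
  }
  first[seq_len(k)]
}

#' Taxon name at a given rank, or NA if the lineage ends above it
#' @param lin lineage (character vector)
#' @param rank one of [LINEAGE_RANKS]
#' @return character scalar or `NA_character_`
#' @export
lineage_at <- function(lin, rank) {
  i <- match(rank, LINEAGE_RANKS)
  if (is.na(i)) stop("unknown rank: ", rank)
  if (length(lin) < i) NA_character_ else lin[[i]]
}
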