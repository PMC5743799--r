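#' Consensus taxonomy for paired reads from ranked hit tables
#'
#' Implements the unassembled-read classification procedure: per mate, hits
#' are filtered at an e-value cutoff, truncated to the top few, and every hit
#' whose e-value lies within a configurable window (default two orders of
#' magnitude, inclusive) of the best hit contributes to a lowest-common-
#' ancestor consensus. The two mates of a pair are then combined by a second
#' LCA step.
#'
#' @name read_taxonomy
NULL

order_hits <- function(hits) {
  hits[order(hits$evalue, -hits$bitscore, hits$subject_id), , drop = FALSE]
}

#' Classify a single mate from its ranked hits
#'
#' Drops hits with e-value above `evalue_cutoff`, keeps at most `max_hits`
#' best hits (ties broken by higher bitscore, then subject id), retains the
#' top hit plus every later hit with `evalue <= window * top evalue`
#' (inclusive boundary), and returns the LCA of the retained lineages.
#'
#' @param hits data frame with columns `evalue`, `bitscore`, `subject_id`,
#'   `lineage` (semicolon-delimited strings), all for one (read, mate).
#' @param evalue_cutoff maximum e-value for a hit to be considered.
#' @param window multiplicative e-value window relative to the top hit; hits
#'   within `window` times the best e-value join the consensus set.
#' @param max_hits hits retained after sorting, before the window is applied.
#' @return consensus lineage (character vector); empty when no hit survives.
#' @export
classify_read <- function(hits, evalue_cutoff = 0.001, window = 100,
                          max_hits = 5) {
  if (is.null(hits) || nrow(hits) == 0L) return(character(0))
  keep <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) return(character(0))
  keep <- order_hits(keep)
  if (nrow(keep) > max_hits) keep <- keep[seq_len(max_hits), , drop = FALSE]
  top <- keep$evalue[[1L]]
  # inclusive boundary, guarded against floating-point (100 * 1e-20 vs 1e-18)
  inset <- keep[keep$evalue <= window * top * (1 + 1e-9), , drop = FALSE]
  lca(lapply(inset$lineage, parse_lineage))
}

#' Combine the two mates of a read pair
#'
#' Both mates classified: LCA of the two. Exactly one classified: that
#' lineage is kept (set `require_both_mates = TRUE` to drop single-mate
#' returns instead). Neither classified: unclassified.
#'
#' @param mate1,mate2 lineages (character vectors; empty = unclassified).
#' @param require_both_mates drop pairs where only one mate returned a
#'   classification.
#' @return consensus lineage for the pair.
#' @export
classify_pair <- function(mate1, mate2, require_both_mates = FALSE) {
  c1 <- length(mate1) > 0L
  c2 <- length(mate2) > 0L
  if (c1 && c2) return(lca(list(mate1, mate2)))
  if (require_both_mates) return(character(0))
  if (c1) return(mate1)
  if (c2) return(mate2)
  character(0)
}

#' Classify every read pair in a hit table
#'
#' @param hit_table data frame with columns `read_id`, `mate` (1 or 2),
#'   `subject_id`, `evalue`, `bitscore`, `lineage` (see
#'   [read_hit_table()]).
#' @inheritParams classify_read
#' @inheritParams classify_pair
#' @return data frame with one row per read pair: `read_id`, `lineage`
#'   (string form), `depth` (number of resolved ranks).
#' @export
classify_hit_table <- function(hit_table, evalue_cutoff = 0.001, window = 100,
                               max_hits = 5, require_both_mates = FALSE) {
  stopifnot(all(c("read_id", "mate", "evalue", "bitscore", "subject_id",
                  "lineage") %in% names(hit_table)))
  ids <- unique(hit_table$read_id)
  chunks <- split(hit_table, factor(hit_table$read_id, levels = ids))
  res <- vapply(chunks, function(sub) {
    m1 <- classify_read(sub[sub$mate == 1L, , drop = FALSE],
                        evalue_cutoff, window, max_hits)
    m2 <- classify_read(sub[sub$mate == 2L, , drop = FALSE],
                        evalue_cutoff, window, max_hits)
    pair <- classify_pair(m1, m2, require_both_mates)
    c(format_lineage(pair), as.character(length(pair)))
  }, character(2))
  data.frame(read_id = ids, lineage = res[1L, ],
             depth = as.integer(res[2L, ]), row.names = NULL)
}

#' Rank-level community profile from pair assignments
#'
#' Counts assignments resolved at least to `rank`, grouped by the taxon at
#' that rank, divided by the chosen denominator. With
#' `denominator = "classified"` (default) the denominator is the number of
#' pairs with any classification; with `"total"` it is all pairs including
#' unclassified ones. Proportions within a rank therefore sum to at most 1;
#' the shortfall is the mass of pairs unresolved at that rank.
#'
#' @param assignments list of lineages, or the data frame returned by
#'   [classify_hit_table()].
#' @param rank one of `"genus"`, `"family"`, `"order"`.
#' @param denominator `"classified"` or `"total"`.
#' @return data frame with columns `rank`, `taxon`, `read_count`,
#'   `proportion`, sorted by descending proportion.
#' @export
taxon_profile <- function(assignments, rank = c("order", "family", "genus"),
                          denominator = c("classified", "total")) {
  rank <- match.arg(rank)
  denominator <- match.arg(denominator)
  if (is.data.frame(assignments)) {
    assignments <- lapply(assignments$lineage, parse_lineage)
  }
  if (length(assignments) == 0L) stop("no reads to profile")
  names(assignments) <- NULL
  n_classified <- sum(lengths(assignments) > 0L)
  denom <- switch(denominator,
                  classified = n_classified,
                  total = length(assignments))
  if (denom == 0L) stop("no classified reads to profile")
  at_rank <- vapply(assignments, lineage_at, character(1), rank = rank)
  at_rank <- at_rank[!is.na(at_rank)]
  counts <- table(at_rank)
  out <- data.frame(rank = rank,
                    taxon = names(counts),
                    read_count = as.integer(counts),
                    proportion = as.numeric(counts) / denom,
                    row.names = NULL)
  out[order(-out$proportion, out$taxon), , drop = FALSE]
}

#' Read a hit table TSV
#'
#' Expected columns: `read_id`, `mate`, `subject_id`, `evalue`, `bitscore`,
#' `lineage` (semicolon-delimited rank path) — a BLAST outfmt-6-like layout
#' reduced to the fields this pipeline uses, plus the lineage.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_hit_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character", mate = "integer",
                                   subject_id = "character",
                                   evalue = "numeric", bitscore = "numeric",
                                   lineage = "character"))
}
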