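#' Coverage-based bin-genome abundance and split-bin merging
#'
#' The average coverage depth of a bin genome in each sample is the
#' length-weighted mean of its contig depths; per-sample relative abundance
#' is depth normalized across bins. Clustering of pooled assemblies often
#' splits one organism's genome across several bins; the merge heuristic
#' reunites them when either their contigs map to the same reference genome
#' or their depth profiles co-vary across samples while their single-copy
#' marker inventories are disjoint and their taxonomies agree to at least
#' genus level.
#'
#' @name bin_abundance
NULL

#' Construct a bin genome record
#'
#' @param bin_id identifier; merged bins conventionally carry an `"m"`
#'   suffix.
#' @param contigs data frame with columns `contig_id`, `length_bp`.
#' @param depth numeric matrix, contigs x samples, mean fold-coverage.
#' @param markers character vector of single-copy marker gene identifiers
#'   (a multiset; duplicates indicate contamination or misassembly).
#' @param taxonomy lineage (character vector).
#' @param ref_map optional reference genome id the bin's contigs map to.
#' @return object of class `bin_genome`.
#' @export
bin_genome <- function(bin_id, contigs, depth, markers = character(0),
                       taxonomy = character(0), ref_map = NA_character_) {
  stopifnot(nrow(contigs) == nrow(depth))
  if (any(contigs$length_bp <= 0)) stop("contig lengths must be positive")
  if (any(depth < 0)) stop("depths must be >= 0")
  structure(list(bin_id = bin_id, contigs = contigs, depth = depth,
                 markers = markers, taxonomy = taxonomy, ref_map = ref_map),
            class = "bin_genome")
}

#' Read bin genomes from a coverage table
#'
#' @param coverage data frame or TSV path with columns `bin_id`,
#'   `contig_id`, `length_bp`, then one depth column per sample.
#' @param markers optional data frame or TSV path (`bin_id`, `marker_id`,
#'   `taxon`).
#' @param taxonomy optional named list of lineages keyed by bin id.
#' @param ref_map optional named character vector, bin id -> reference id.
#' @return list of [bin_genome()] objects, ordered by bin id.
#' @export
read_bins <- function(coverage, markers = NULL, taxonomy = NULL,
                      ref_map = NULL) {
  if (is.character(coverage)) {
    coverage <- utils::read.table(coverage, header = TRUE, sep = "\t",
                                  quote = "", stringsAsFactors = FALSE,
                                  check.names = FALSE)
  }
  if (is.character(markers)) {
    markers <- utils::read.table(markers, header = TRUE, sep = "\t",
                                 quote = "", stringsAsFactors = FALSE)
  }
  sample_cols <- setdiff(names(coverage), c("bin_id", "contig_id", "length_bp"))
  ids <- sort(unique(coverage$bin_id))
  lapply(ids, function(b) {
    sub <- coverage[coverage$bin_id == b, , drop = FALSE]
    dep <- as.matrix(sub[, sample_cols, drop = FALSE])
    rownames(dep) <- sub$contig_id
    mk <- if (!is.null(markers)) markers$marker_id[markers$bin_id == b]
          else character(0)
    tx <- if (!is.null(taxonomy) && !is.null(taxonomy[[b]])) taxonomy[[b]]
          else character(0)
    rm <- if (!is.null(ref_map) && b %in% names(ref_map)) ref_map[[b]]
          else NA_character_
    bin_genome(b, data.frame(contig_id = sub$contig_id,
                             length_bp = sub$length_bp, row.names = NULL),
               dep, mk, tx, rm)
  })
}

#' Length-weighted mean coverage depth of a bin
#'
#' Contigs shorter than `min_contig_len` are excluded from the depth
#' computation (they remain part of the bin record).
#'
#' @param bin a [bin_genome()].
#' @param sample sample id (column of the depth matrix); `NULL` returns the
#'   vector over all samples.
#' @param min_contig_len minimum contig length (bp) contributing to depth.
#' @return fold-coverage (scalar, or named vector when `sample` is `NULL`).
#' @export
bin_depth <- function(bin, sample = NULL, min_contig_len = 1000) {
  keep <- bin$contigs$length_bp >= min_contig_len
  if (!any(keep)) keep <- rep(TRUE, nrow(bin$contigs))  # all short: use all
  len <- bin$contigs$length_bp[keep]
  if (sum(len) <= 0) stop("bin ", bin$bin_id, " has zero total contig length")
  dep <- bin$depth[keep, , drop = FALSE]
  w <- len / sum(len)
  out <- colSums(dep * w)
  if (is.null(sample)) out else out[[sample]]
}

#' Coverage-based relative abundance matrix
#'
#' @param bins list of [bin_genome()] sharing a sample set.
#' @inheritParams bin_depth
#' @return matrix bins x samples; every column sums to 1.
#' @export
coverage_abundance <- function(bins, min_contig_len = 1000) {
  stopifnot(length(bins) >= 1L)
  depths <- t(vapply(bins, bin_depth, numeric(ncol(bins[[1L]]$depth)),
                     sample = NULL, min_contig_len = min_contig_len))
  rownames(depths) <- vapply(bins, `[[`, character(1), "bin_id")
  tot <- colSums(depths)
  zero <- tot <= 0
  if (any(zero))
    stop("all-zero depths in sample(s): ",
         paste(colnames(depths)[zero], collapse = ", "))
  sweep(depths, 2, tot, "/")
}

depth_profile_cor <- function(d1, d2, pseudocount = 0.1) {
  stats::cor(log(d1 + pseudocount), log(d2 + pseudocount))
}

#' Merge split bins
#'
#' Two bins qualify for merging when (a) they share the same `ref_map`
#' reference genome, or (b) the correlation of their log depth profiles
#' across samples is at least `coverage_corr_min`, their marker multisets
#' are disjoint (no single-copy gene would be duplicated by the merge), and
#' the LCA of their taxonomies is at genus rank or deeper. Merge groups are
#' the transitive closure of qualifying pairs, processed in bin-id order;
#' a merged bin concatenates contigs, unions markers, takes the taxonomy LCA
#' and carries the lexicographically first member's id suffixed `"m"`.
#'
#' @param bins list of [bin_genome()].
#' @param coverage_corr_min minimum depth-profile correlation (computed on
#'   `log(depth + 0.1)`).
#' @param min_contig_len passed to [bin_depth()].
#' @return list of [bin_genome()]; unchanged input when no pair qualifies.
#' @export
merge_split_bins <- function(bins, coverage_corr_min = 0.9,
                             min_contig_len = 1000) {
  n <- length(bins)
  if (n < 2L) return(bins)
  ids <- vapply(bins, `[[`, character(1), "bin_id")
  ord <- order(ids)
  bins <- bins[ord]
  ids <- ids[ord]
  depths <- lapply(bins, bin_depth, sample = NULL,
                   min_contig_len = min_contig_len)
  genus_i <- match("genus", LINEAGE_RANKS)

  qualifies <- function(i, j) {
    bi <- bins[[i]]; bj <- bins[[j]]
    if (!is.na(bi$ref_map) && !is.na(bj$ref_map) &&
        bi$ref_map == bj$ref_map) return(TRUE)
    if (length(intersect(bi$markers, bj$markers)) > 0L) return(FALSE)
    shared <- lca(list(bi$taxonomy, bj$taxonomy))
    if (length(shared) < genus_i) return(FALSE)
    r <- depth_profile_cor(depths[[i]], depths[[j]])
    !is.na(r) && r >= coverage_corr_min
  }

  # union-find over qualifying pairs (transitive closure)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (qualifies(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    members <- which(roots == r)
    if (length(members) == 1L) return(bins[[members]])
    grp <- bins[members]
    new_id <- paste0(ids[members][1L], "m")
    contigs <- do.call(rbind, lapply(grp, `[[`, "contigs"))
    depth <- do.call(rbind, lapply(grp, `[[`, "depth"))
    markers <- unlist(lapply(grp, `[[`, "markers"))
    tax <- lca(lapply(grp, `[[`, "taxonomy"))
    refs <- stats::na.omit(vapply(grp, `[[`, character(1), "ref_map"))
    bin_genome(new_id, contigs, depth, markers, tax,
               if (length(unique(refs)) == 1L) unique(refs)
               else NA_character_)
  })
  out
}
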