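#' Linking OTUs to long 16S references and bin genomes
#'
#' Region-specific OTUs are aligned to a library of full-length 16S
#' sequences; an OTU links to its best-identity reference at or above a 97%
#' identity threshold. OTUs linked to the same reference are summed,
#' references carry optional bin-genome assignments, per-region relative
#' abundances are computed against the total reads of each sample-region,
#' and regions are averaged per sample with a linked-fraction quality
#' control.
#'
#' @name otu_linking
NULL

identity_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

#' Percent identity of a query against a reference (semi-global)
#'
#' The query is aligned globally, the reference locally (query end-gaps are
#' free on the reference). Scoring: match +1, mismatch -1, gap opening 2,
#' gap extension 1 per gapped base. Identity is the number of matching
#' columns divided by the total number of alignment columns, times 100.
#'
#' @param query,ref nucleotide sequences (character); `nchar(query) <=
#'   nchar(ref)`.
#' @return list with `identity` (percent), `aln_length` (columns), `score`.
#' @export
percent_identity <- function(query, ref) {
  if (!nzchar(query) || !nzchar(ref)) stop("empty sequence")
  if (nchar(query) > nchar(ref)) stop("query longer than reference")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "global-local", substitutionMatrix = identity_submat(),
    gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  list(identity = 100 * Biostrings::nmatch(aln) / cols,
       aln_length = cols, score = Biostrings::score(aln))
}

# identity of many queries against one reference in a single call
batch_identity <- function(queries, ref) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(ref),
    type = "global-local", substitutionMatrix = identity_submat(),
    gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  data.frame(identity = 100 * Biostrings::nmatch(aln) / cols,
             aln_length = cols)
}

#' Read a FASTA file to a named character vector
#' @param path FASTA path.
#' @return named character vector of sequences (first header token as name).
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Link OTUs to their best-identity long reference
#'
#' Every OTU is aligned against every reference; it links to the reference
#' with the highest percent identity provided that identity meets
#' `threshold`. Ties are broken by longer alignment, then reference id.
#'
#' @param otu_seqs named character vector, otu id -> representative sequence.
#' @param ref_seqs named character vector, ref id -> full-length sequence.
#' @param threshold minimum percent identity (default 97).
#' @param ref_bins optional named character vector ref id -> bin id.
#' @return data frame (`otu_id`, `ref_id`, `identity`, `aln_length`,
#'   `bin_id`); unlinked OTUs have `NA` `ref_id`.
#' @export
link_otus <- function(otu_seqs, ref_seqs, threshold = 97, ref_bins = NULL) {
  stopifnot(length(otu_seqs) > 0L, length(ref_seqs) > 0L)
  per_ref <- lapply(names(ref_seqs), function(rid) {
    cbind(batch_identity(otu_seqs, ref_seqs[[rid]]),
          ref_id = rid, otu_id = names(otu_seqs))
  })
  all_hits <- do.call(rbind, per_ref)
  out <- do.call(rbind, lapply(names(otu_seqs), function(oid) {
    h <- all_hits[all_hits$otu_id == oid, , drop = FALSE]
    h <- h[order(-h$identity, -h$aln_length, h$ref_id), , drop = FALSE]
    best <- h[1L, ]
    if (best$identity >= threshold) {
      data.frame(otu_id = oid, ref_id = best$ref_id,
                 identity = best$identity, aln_length = best$aln_length,
                 row.names = NULL)
    } else {
      data.frame(otu_id = oid, ref_id = NA_character_,
                 identity = best$identity, aln_length = best$aln_length,
                 row.names = NULL)
    }
  }))
  out$bin_id <- if (!is.null(ref_bins)) unname(ref_bins[out$ref_id])
                else NA_character_
  out
}

#' Per-region relative abundance over linked references
#'
#' Counts of OTUs linked to the same reference are summed, then divided by
#' the total reads generated for that sample in that region (linked or not).
#' The unlinked mass is reported separately per sample. A sample-region with
#' zero total reads is flagged missing (`NA`), not zero.
#'
#' @param otu_counts data frame for one region: `otu_id`, `region`, then one
#'   count column per sample.
#' @param link_map data frame from [link_otus()].
#' @param totals optional named vector of total reads per sample; defaults to
#'   the column sums of `otu_counts`.
#' @param by `"ref_id"` or `"bin_id"`: row identity of the output.
#' @return list with `abundance` (matrix refs/bins x samples),
#'   `linked_fraction` (named vector per sample), `region`.
#' @export
region_abundance <- function(otu_counts, link_map, totals = NULL,
                             by = c("ref_id", "bin_id")) {
  by <- match.arg(by)
  region <- unique(otu_counts$region)
  stopifnot(length(region) == 1L)
  sample_cols <- setdiff(names(otu_counts), c("otu_id", "region"))
  cnt <- as.matrix(otu_counts[, sample_cols, drop = FALSE])
  rownames(cnt) <- otu_counts$otu_id
  if (is.null(totals)) totals <- colSums(cnt)
  totals <- totals[sample_cols]
  key <- link_map[[by]][match(otu_counts$otu_id, link_map$otu_id)]
  linked <- !is.na(key)
  groups <- sort(unique(key[linked]))
  ab <- matrix(NA_real_, length(groups), length(sample_cols),
               dimnames = list(groups, sample_cols))
  linked_counts <- rowsum(cnt[linked, , drop = FALSE], key[linked])
  pos <- totals > 0
  ab[, pos] <- sweep(linked_counts[groups, pos, drop = FALSE], 2,
                     totals[pos], "/")
  lf <- rep(NA_real_, length(sample_cols))
  names(lf) <- sample_cols
  lf[pos] <- colSums(cnt[linked, pos, drop = FALSE]) / totals[pos]
  list(abundance = ab, linked_fraction = lf, region = region)
}

#' Average per-region abundance matrices with linked-fraction QC
#'
#' For each (taxon, sample) cell, the unweighted mean over regions whose
#' linked fraction for that sample is at least `min_linked_fraction`
#' (a failed amplification or mapping run for one region-sample is thereby
#' excluded). Columns are renormalized to sum to 1. Set `weighted = TRUE`
#' to weight regions by their linked read mass instead.
#'
#' @param region_results list of [region_abundance()] results.
#' @param min_linked_fraction QC floor on the per-sample linked fraction.
#' @param weighted weight regions by linked fraction rather than equally.
#' @return list with `abundance` (matrix, columns sum to 1) and
#'   `regions_used` (matrix of region counts per sample).
#' @export
average_regions <- function(region_results, min_linked_fraction = 0.8,
                            weighted = FALSE) {
  stopifnot(length(region_results) >= 1L)
  taxa <- sort(unique(unlist(lapply(region_results,
                                    function(r) rownames(r$abundance)))))
  samples <- colnames(region_results[[1L]]$abundance)
  acc <- matrix(0, length(taxa), length(samples),
                dimnames = list(taxa, samples))
  wsum <- matrix(0, length(taxa), length(samples),
                 dimnames = list(taxa, samples))
  n_used <- stats::setNames(integer(length(samples)), samples)
  for (r in region_results) {
    for (s in samples) {
      lf <- r$linked_fraction[[s]]
      if (is.na(lf) || lf < min_linked_fraction) next
      n_used[s] <- n_used[s] + 1L
      w <- if (weighted) lf else 1
      vals <- r$abundance[, s]
      vals[is.na(vals)] <- 0
      acc[rownames(r$abundance), s] <- acc[rownames(r$abundance), s] + w * vals
      wsum[rownames(r$abundance), s] <- wsum[rownames(r$abundance), s] + w
    }
  }
  if (any(n_used == 0L))
    stop("no region passes QC for sample(s): ",
         paste(samples[n_used == 0L], collapse = ", "))
  mean_ab <- acc / ifelse(wsum > 0, wsum, 1)
  tot <- colSums(mean_ab)
  list(abundance = sweep(mean_ab, 2, tot, "/"), regions_used = n_used)
}

#' Split an OTU count table into per-region tables
#' @param otu_counts data frame with a `region` column (as emitted by
#'   [generate_dataset()]).
#' @return named list of per-region data frames.
#' @export
split_by_region <- function(otu_counts) {
  split(otu_counts, otu_counts$region)
}
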