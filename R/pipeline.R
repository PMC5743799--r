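#' End-to-end community quantification pipeline
#'
#' Orchestrates the stages on either a synthetic bundle or pre-existing
#' input files: paired-read consensus classification, coverage-based bin
#' abundance (with optional split-bin merging), OTU-to-reference linking and
#' cross-region averaging, copy-number reconciliation of the two abundance
#' estimates, and abundance-current correlation for both estimation routes.
#' All intermediates are written as plain-text tables; the run report
#' records parameters, file checksums and the headline correlation table,
#' and fully determines a rerun.
#'
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' Exactly one of `spec` (synthetic route) or `input_dir` (pre-existing
#' bundle in the synthetic generator's file layout) must be given.
#'
#' @param spec a [community_spec()] for the synthetic route.
#' @param input_dir directory holding an existing input bundle.
#' @param out_dir output directory.
#' @param evalue_cutoff,window,max_hits paired-read classification
#'   parameters (see [classify_read()]).
#' @param profile_rank rank for the read-based community profile.
#' @param merge_bins run [merge_split_bins()] before abundance.
#' @param coverage_corr_min merge heuristic depth-correlation threshold.
#' @param min_contig_len contig length floor for depth computation (bp).
#' @param link_threshold percent-identity threshold for OTU linking.
#' @param min_linked_fraction per-region QC floor for averaging.
#' @param copy_numbers optional data frame (`bin_id`, `copy_number`,
#'   `known`); when `NULL` on the synthetic route, the two largest
#'   non-dominant bins anchor the model with their true copy numbers and
#'   all other bins start unknown at 1 copy.
#' @param copy_bounds integer search interval for unknown copy numbers.
#' @param current_field metadata column used for correlation.
#' @param skip_amplicon run the WGS-only route (no linking, no
#'   reconciliation).
#' @param classify_reads classify the paired-read hit tables (the slowest
#'   stage on large bundles; profiles are informational).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, input_dir = NULL, out_dir,
                            evalue_cutoff = 0.001, window = 100,
                            max_hits = 5, profile_rank = "order",
                            merge_bins = TRUE, coverage_corr_min = 0.9,
                            min_contig_len = 1000,
                            link_threshold = 97, min_linked_fraction = 0.8,
                            copy_numbers = NULL, copy_bounds = c(1L, 13L),
                            current_field = "max_current_mA_m2",
                            skip_amplicon = FALSE, classify_reads = TRUE) {
  if (is.null(spec) == is.null(input_dir))
    stop("give exactly one of spec or input_dir")
  if (!is.null(spec)) stopifnot(inherits(spec, "community_spec"))
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  structure(as.list(environment()), class = "pipeline_config")
}

bundle_paths <- function(dir) {
  c(refs = file.path(dir, "refs.fasta"),
    ref_bins = file.path(dir, "ref_bins.tsv"),
    otu_counts = file.path(dir, "otu_counts.tsv"),
    otu_reps = file.path(dir, "otu_reps.fasta"),
    coverage = file.path(dir, "coverage.tsv"),
    bin_markers = file.path(dir, "bin_markers.tsv"),
    metadata = file.path(dir, "metadata.csv"))
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return the run report (list): `parameters`, `files` (with md5
#'   checksums), `warnings`, `profiles` (read-based rank profiles per
#'   sample), `genome_abundance`, `amplicon_abundance`, `copy_model`,
#'   `headline` (per-taxon correlation tables for each route), and `truth`
#'   when the synthetic route was used. The report (minus in-memory
#'   matrices) is also written to `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  # stage: inputs
  if (!is.null(config$spec)) {
    bundle <- generate_dataset(config$spec,
                               file.path(config$out_dir, "inputs"))
    paths <- bundle$files
    truth <- bundle$truth
    hit_paths <- paths[grepl("^hits", names(paths))]
  } else {
    paths <- bundle_paths(config$input_dir)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("stage inputs: missing file(s): ",
           paste(missing, collapse = ", "))
    truth <- NULL
    hit_paths <- list.files(config$input_dir, "^hits_.*\\.tsv$",
                            full.names = TRUE)
  }
  metadata <- utils::read.csv(paths[["metadata"]], stringsAsFactors = FALSE)

  # stage: paired-read consensus profiles
  profiles <- NULL
  if (config$classify_reads && length(hit_paths)) {
    profiles <- lapply(hit_paths, function(p) {
      tab <- read_hit_table(p)
      asg <- classify_hit_table(tab, config$evalue_cutoff, config$window,
                                config$max_hits)
      taxon_profile(asg, rank = config$profile_rank)
    })
    names(profiles) <- sub("^hits_(.*)\\.tsv$", "\\1", basename(hit_paths))
    prof_tab <- do.call(rbind, Map(cbind,
                                   sample_id = names(profiles), profiles))
    utils::write.table(prof_tab,
                       file.path(config$out_dir, "read_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage: bin abundance
  bins <- read_bins(paths[["coverage"]], paths[["bin_markers"]])
  if (config$merge_bins) {
    n0 <- length(bins)
    bins <- merge_split_bins(bins, config$coverage_corr_min,
                             config$min_contig_len)
    if (length(bins) < n0)
      note(sprintf("merged %d bins into %d", n0, length(bins)))
  }
  genome_abund <- coverage_abundance(bins, config$min_contig_len)
  utils::write.table(data.frame(bin_id = rownames(genome_abund),
                                genome_abund, check.names = FALSE),
                     file.path(config$out_dir, "genome_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  amplicon_abund <- NULL
  copy_model <- NULL
  if (!config$skip_amplicon) {
    # stage: OTU linking and cross-region averaging
    otu_seqs <- read_fasta_seqs(paths[["otu_reps"]])
    ref_seqs <- read_fasta_seqs(paths[["refs"]])
    ref_bin_tab <- utils::read.table(paths[["ref_bins"]], header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
    ref_bins <- stats::setNames(ref_bin_tab$bin_id, ref_bin_tab$ref_id)
    link_map <- link_otus(otu_seqs, ref_seqs, config$link_threshold,
                          ref_bins)
    utils::write.table(link_map,
                       file.path(config$out_dir, "link_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    otu_counts <- utils::read.table(paths[["otu_counts"]], header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE,
                                    check.names = FALSE)
    region_results <- lapply(split_by_region(otu_counts), region_abundance,
                             link_map = link_map, by = "bin_id")
    avg <- average_regions(region_results, config$min_linked_fraction)
    if (any(avg$regions_used < length(region_results)))
      note("region(s) excluded by linked-fraction QC for some samples")
    amplicon_abund <- avg$abundance
    utils::write.table(data.frame(bin_id = rownames(amplicon_abund),
                                  amplicon_abund, check.names = FALSE),
                       file.path(config$out_dir, "amplicon_abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # stage: copy-number reconciliation (on bins present in both routes)
    ga <- genome_abund
    if (!is.null(truth) && length(truth$twin_groups)) {
      ga <- sum_subclusters(ga, truth$twin_groups)
    }
    shared <- intersect(rownames(ga), rownames(amplicon_abund))
    if (length(shared) >= 2) {
      ga_s <- sweep(ga[shared, , drop = FALSE], 2,
                    colSums(ga[shared, , drop = FALSE]), "/")
      aa_s <- sweep(amplicon_abund[shared, , drop = FALSE], 2,
                    colSums(amplicon_abund[shared, , drop = FALSE]), "/")
      cn <- config$copy_numbers
      if (is.null(cn) && !is.null(truth)) {
        # anchor the two largest non-dominant bins with their true copy
        # numbers (the closed-genome bins of the emulated study design)
        ord <- shared[order(-rowMeans(ga_s))]
        anchors <- utils::head(setdiff(ord, ord[1L]), 2L)
        taxon_of_bin <- stats::setNames(names(truth$bin_of_taxon),
                                        truth$bin_of_taxon)
        cn <- data.frame(bin_id = shared,
                         copy_number = ifelse(
                           shared %in% anchors,
                           truth$copy_numbers[taxon_of_bin[shared]], 1L),
                         known = shared %in% anchors)
      }
      if (!is.null(cn)) {
        model <- copy_number_model(cn$bin_id, cn$copy_number, cn$known,
                                   config$copy_bounds)
        copy_model <- estimate_copy_numbers(ga_s, aa_s, model)
        if (!copy_model$converged) note("copy-number estimation hit max_iter")
        utils::write.csv(data.frame(bin_id = names(copy_model$copy_number),
                                    copy_number = copy_model$copy_number,
                                    known = copy_model$known,
                                    row.names = NULL),
                         file.path(config$out_dir,
                                   "copy_numbers_fitted.csv"),
                         row.names = FALSE, quote = FALSE)
      } else {
        note("no copy-number model available; reconciliation skipped")
      }
    } else {
      note("fewer than 2 bins shared between routes; reconciliation skipped")
    }
  }

  # stage: abundance-current correlation (both routes)
  headline <- list(wgs = rank_taxa(genome_abund, metadata,
                                   config$current_field))
  utils::write.table(headline$wgs,
                     file.path(config$out_dir, "correlation_wgs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(amplicon_abund) && nrow(amplicon_abund) >= 2) {
    headline$amplicon <- rank_taxa(amplicon_abund, metadata,
                                   config$current_field)
    utils::write.table(headline$amplicon,
                       file.path(config$out_dir, "correlation_16s.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  all_files <- c(paths,
                 list.files(config$out_dir, "\\.(tsv|csv)$",
                            full.names = TRUE))
  all_files <- unique(normalizePath(all_files[file.exists(all_files)]))
  checksums <- tools::md5sum(all_files)
  root <- paste0(normalizePath(config$out_dir), .Platform$file.sep)
  names(checksums) <- sub(root, "", names(checksums), fixed = TRUE)
  params <- config[!vapply(config, is.null, logical(1))]
  params$spec <- if (!is.null(config$spec)) unclass(config$spec) else NULL
  report <- list(parameters = params,
                 seed = if (!is.null(config$spec)) config$spec$seed else NA,
                 files = as.list(checksums),
                 warnings = warnings,
                 headline = lapply(headline, function(h)
                   h[, c("taxon", "r", "r_squared", "p_value", "n", "sign")]))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  c(report,
    list(profiles = profiles, genome_abundance = genome_abund,
         amplicon_abundance = amplicon_abund, copy_model = copy_model,
         truth = truth))
}
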