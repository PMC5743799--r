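#' Ground-truthed synthetic community generator
#'
#' Emulates the inputs of the full quantification pipeline for an
#' electrode-attached microbial community sampled across replicate
#' bioelectrochemical systems (BES): per-sample taxon abundances drawn from a
#' Dirichlet prior with one dominant organism, integer 16S rRNA gene copy
#' numbers, per-(taxon, region) multiplicative primer biases, full-length 16S
#' reference sequences with a controlled divergence floor, multinomial OTU
#' count tables for seven hypervariable-region primer sets, lognormal-noise
#' contig coverage depths, paired-read taxonomic hit tables with near-neighbor
#' decoy hits, and cathodic currents linearly coupled to the abundance of one
#' designated electrotrophic taxon. Every emitted identifier is recorded in a
#' truth record so downstream estimates can be scored against known values.
#'
#' @name synthetic_community
NULL

default_region_windows <- function(seq_length = 1500) {
  w <- list(V1V2 = c(0, 340), V3 = c(340, 530), V4 = c(530, 750),
            V5 = c(750, 900), V6 = c(900, 1070), V7V8 = c(1070, 1390),
            V9 = c(1390, 1500))
  if (seq_length != 1500) {
    w <- lapply(w, function(x) pmin(round(x * seq_length / 1500), seq_length))
  }
  w
}

#' Specification of a synthetic community experiment
#'
#' Defaults mirror the study design the pipeline targets: 8 replicate BES
#' samples, 20 taxa with one dominant organism at roughly 30-60% of the
#' community, 7 hypervariable-region amplicon libraries, 16S copy numbers in
#' 1..13.
#'
#' @param n_samples number of replicate samples (reactors).
#' @param n_taxa number of community members.
#' @param abundance_prior Dirichlet concentration vector of length `n_taxa`;
#'   the default makes taxon 1 dominant.
#' @param electro_taxon index of the taxon whose abundance drives current.
#' @param current_model list with `intercept` and `slope` (mA m-2 and
#'   mA m-2 per abundance unit; current is `-(intercept + slope * a)` plus
#'   noise, so currents are cathodic/negative), `noise_sd` (mA m-2), and
#'   optionally `target_r`: when set, `noise_sd` is derived per dataset so
#'   the planted abundance-|current| population correlation equals it.
#' @param copy_bounds integer interval for 16S copy numbers (lower >= 1).
#' @param region_windows named list of half-open `[start, end)` intervals on
#'   the 16S coordinate, one per primer set.
#' @param primer_bias_sd log-scale s.d. of the per-(taxon, region)
#'   multiplicative amplification bias; 0 disables bias.
#' @param seq_length length of the 16S reference sequences (bp).
#' @param min_divergence minimum pairwise fraction of differing sites between
#'   taxon references (twin pairs exempt).
#' @param reads_per_region amplicon reads per sample per region.
#' @param wgs_depth_mean mean fold-coverage scale for shotgun depth.
#' @param depth_noise_cv coefficient of variation of the lognormal coverage
#'   noise; 0 disables noise.
#' @param decoy_rate probability that a simulated read receives a
#'   near-neighbor (congeneric) decoy hit in addition to its true hit.
#' @param read_pairs_per_sample paired shotgun reads simulated per sample for
#'   the hit tables.
#' @param otu_mutation_rate per-base substitution rate applied to OTU
#'   representative sequences relative to their source reference.
#' @param twin_pairs optional list of integer pairs; each pair's references
#'   are made nearly identical (below the divergence floor) and represented
#'   by a single long 16S sequence, emulating sub-clusters of one species.
#' @param twin_divergence divergence used for twin pairs.
#' @param seed integer seed; every random draw derives from it.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(n_samples = 8, n_taxa = 20,
                           abundance_prior = NULL, electro_taxon = 1,
                           current_model = list(intercept = 2, slope = 60,
                                                noise_sd = 3,
                                                target_r = NULL),
                           copy_bounds = c(1L, 13L),
                           region_windows = NULL,
                           primer_bias_sd = 0.4,
                           seq_length = 1500, min_divergence = 0.05,
                           reads_per_region = 100000,
                           wgs_depth_mean = 50, depth_noise_cv = 0.1,
                           decoy_rate = 0.3,
                           read_pairs_per_sample = 2000,
                           otu_mutation_rate = 0.01,
                           twin_pairs = NULL, twin_divergence = 0.005,
                           seed = 1) {
  if (is.null(abundance_prior)) {
    abundance_prior <- if (n_taxa >= 4) {
      c(12, 6, 4, rep(0.6, n_taxa - 3))
    } else {
      rep(5, n_taxa)
    }
  }
  if (length(abundance_prior) != n_taxa)
    stop("abundance_prior must have length n_taxa")
  if (copy_bounds[1] < 1) stop("copy_bounds lower bound must be >= 1")
  if (copy_bounds[2] < copy_bounds[1]) stop("copy_bounds must be an interval")
  if (reads_per_region <= 0) stop("reads_per_region must be positive")
  if (read_pairs_per_sample <= 0) stop("read_pairs_per_sample must be positive")
  if (min(primer_bias_sd, depth_noise_cv,
          current_model$noise_sd %||% 0) < 0)
    stop("noise parameters must be >= 0")
  if (electro_taxon < 1 || electro_taxon > n_taxa)
    stop("electro_taxon out of range")
  if (is.null(region_windows)) region_windows <- default_region_windows(seq_length)
  bad <- vapply(region_windows,
                function(w) w[1] < 0 || w[2] > seq_length || w[2] <= w[1],
                logical(1))
  if (any(bad)) stop("each region window must fit in [0, seq_length)")
  if (!is.null(twin_pairs)) {
    idx <- unlist(twin_pairs)
    if (anyDuplicated(idx) || any(idx < 1) || any(idx > n_taxa))
      stop("twin_pairs must be disjoint pairs of taxon indices")
  }
  structure(list(n_samples = n_samples, n_taxa = n_taxa,
                 abundance_prior = abundance_prior,
                 electro_taxon = electro_taxon,
                 current_model = current_model,
                 copy_bounds = as.integer(copy_bounds),
                 region_windows = region_windows,
                 primer_bias_sd = primer_bias_sd,
                 seq_length = seq_length, min_divergence = min_divergence,
                 reads_per_region = reads_per_region,
                 wgs_depth_mean = wgs_depth_mean,
                 depth_noise_cv = depth_noise_cv,
                 decoy_rate = decoy_rate,
                 read_pairs_per_sample = read_pairs_per_sample,
                 otu_mutation_rate = otu_mutation_rate,
                 twin_pairs = twin_pairs, twin_divergence = twin_divergence,
                 seed = as.integer(seed)),
            class = "community_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

taxon_ids <- function(n) sprintf("T%02d", seq_len(n))

#' Synthetic taxonomy for the generated community
#'
#' Taxa are organized into a nested synthetic taxonomy: consecutive pairs
#' share an order, blocks of four share a class, blocks of eight a phylum;
#' every taxon has its own family, genus and species, so a congeneric decoy
#' differs only at species rank.
#'
#' @param n_taxa number of taxa.
#' @return named list of lineages (character vectors), one per taxon id.
#' @export
synthetic_taxonomy <- function(n_taxa) {
  ids <- taxon_ids(n_taxa)
  out <- lapply(seq_len(n_taxa), function(i) {
    c(domain = "Bacteria",
      phylum = sprintf("Phylum_%d", (i - 1) %/% 8 + 1),
      class = sprintf("Class_%d", (i - 1) %/% 4 + 1),
      order = sprintf("Order_%d", (i - 1) %/% 2 + 1),
      family = sprintf("Family_%d", i),
      genus = sprintf("Genus_%d", i),
      species = sprintf("Species_%d", i))
  })
  names(out) <- ids
  out
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# divergence-controlled substitution: exactly round(rate * length) sites
# change, so a "1% mutated" sequence is 1% divergent by construction
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n_mut <- round(rate * length(chars))
  if (n_mut == 0L) return(seq)
  hit <- sample.int(length(chars), n_mut)
  if (length(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    chars[hit] <- vapply(chars[hit], function(b) {
      k <- sample.int(3L, 1L)
      substring(alt[[b]], k, k)
    }, character(1))
  }
  paste(chars, collapse = "")
}

pairwise_divergence <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca != cb)
}

#' Generate divergence-controlled 16S reference sequences
#'
#' Draws one random full-length 16S analogue per taxon and enforces a minimum
#' pairwise divergence (fraction of differing sites) between all non-twin
#' pairs by redrawing violators. Twin pairs are instead copied from their
#' partner and mutated at `twin_divergence`, deliberately below the floor.
#'
#' @param spec a [community_spec()].
#' @return named character vector, taxon id -> sequence.
#' @export
generate_references <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n <- spec$n_taxa
  ids <- taxon_ids(n)
  seqs <- vapply(seq_len(n), function(i) random_seq(spec$seq_length),
                 character(1))
  names(seqs) <- ids
  twin_second <- integer(0)
  if (!is.null(spec$twin_pairs)) {
    twin_second <- vapply(spec$twin_pairs, `[[`, integer(1), 2L)
  }
  check_idx <- setdiff(seq_len(n), twin_second)
  for (attempt in seq_len(100L)) {
    ok <- TRUE
    if (length(check_idx) >= 2L) {
      for (i in utils::head(check_idx, -1L)) {
        for (j in check_idx[check_idx > i]) {
          if (pairwise_divergence(seqs[[i]], seqs[[j]]) < spec$min_divergence) {
            seqs[[j]] <- random_seq(spec$seq_length)
            ok <- FALSE
          }
        }
      }
    }
    if (ok) break
    if (attempt == 100L)
      stop("cannot satisfy min_divergence for this n_taxa/seq_length: ",
           "configuration error")
  }
  if (!is.null(spec$twin_pairs)) {
    for (p in spec$twin_pairs) {
      seqs[[p[[2L]]]] <- mutate_seq(seqs[[p[[1L]]]], spec$twin_divergence)
    }
  }
  seqs
}

rdirichlet_cols <- function(alpha, n_cols) {
  m <- vapply(seq_len(n_cols), function(j) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }, numeric(length(alpha)))
  matrix(m, nrow = length(alpha), ncol = n_cols)
}

write_fasta <- function(seqs, path, annot = NULL) {
  hdr <- names(seqs)
  if (!is.null(annot)) hdr <- paste(hdr, annot)
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Sample community abundances, copy numbers, biases and currents
#'
#' The statistical core of [generate_dataset()] without any file output:
#' per-sample taxon abundances from the Dirichlet prior, integer 16S copy
#' numbers, per-(taxon, region) primer biases, and currents coupled to the
#' electro-taxon's abundance through the linear current model.
#'
#' @param spec a [community_spec()].
#' @param seed seed applied before sampling; `NULL` continues the current
#'   RNG stream (used internally after reference generation).
#' @return list with `abundance` (taxa x samples, columns sum to 1),
#'   `copy_numbers`, `bias`, `max_current`, `current_at_sampling`,
#'   `noise_sd` (the value actually used, after any `target_r` derivation).
#' @export
sample_community <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "community_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_taxa
  ids <- taxon_ids(n)
  samples <- sprintf("BES%02d", seq_len(spec$n_samples))
  regions <- names(spec$region_windows)
  abund <- rdirichlet_cols(spec$abundance_prior, spec$n_samples)
  dimnames(abund) <- list(ids, samples)
  copies <- sample(seq(spec$copy_bounds[1], spec$copy_bounds[2]), n,
                   replace = TRUE)
  names(copies) <- ids
  # twin sub-clusters are near-identical genomes: one shared operon count
  for (p in spec$twin_pairs) copies[p[[2L]]] <- copies[p[[1L]]]
  bias <- matrix(1, n, length(regions), dimnames = list(ids, regions))
  if (spec$primer_bias_sd > 0) {
    bias[] <- exp(stats::rnorm(n * length(regions), 0, spec$primer_bias_sd))
  }
  cm <- spec$current_model
  a_e <- abund[spec$electro_taxon, ]
  noise_sd <- cm$noise_sd %||% 0
  if (!is.null(cm$target_r)) {
    r <- cm$target_r
    noise_sd <- if (r >= 1) 0 else cm$slope * stats::sd(a_e) * sqrt(1 / r^2 - 1)
  }
  max_current <- -(cm$intercept + cm$slope * a_e) +
    stats::rnorm(spec$n_samples, 0, noise_sd)
  current_at_sampling <- max_current +
    stats::rnorm(spec$n_samples, 0, noise_sd / 2)
  list(abundance = abund, copy_numbers = copies, bias = bias,
       max_current = stats::setNames(max_current, samples),
       current_at_sampling = stats::setNames(current_at_sampling, samples),
       noise_sd = noise_sd)
}

#' Generate the full synthetic dataset and its truth record
#'
#' Emits, under `dir`: `refs.fasta` (long 16S references, one per non-twin
#' taxon), `ref_bins.tsv` (reference -> bin genome map), `otu_counts.tsv`
#' (per-region OTU count table), `otu_reps.fasta` (OTU representative
#' sequences), `coverage.tsv` (per-bin per-contig depth by sample),
#' `bin_markers.tsv` (single-copy marker inventory per bin),
#' `hits_<sample>.tsv` (paired-read hit tables), `metadata.csv`, and
#' `truth.json`.
#'
#' Expected OTU counts are proportional to abundance x copy number x primer
#' bias and sampled multinomially at `reads_per_region` per sample, so every
#' count column sums exactly to the configured read total. Contig depth is
#' `wgs_depth_mean x abundance` under multiplicative lognormal noise with the
#' configured coefficient of variation (mean-corrected, so the expectation is
#' exact). Each simulated read pair's best hit is its true taxon; with
#' probability `decoy_rate` a congeneric decoy joins the hit list with an
#' e-value drawn log-uniformly within 1e4 of the best, straddling the
#' two-orders consensus window. Currents follow
#' `-(intercept + slope * abundance[electro_taxon]) + noise`.
#'
#' @param spec a [community_spec()].
#' @param dir output directory (created if missing).
#' @return list with `truth` (see below), `files` (named paths), and `spec`.
#'   `truth` holds `true_abundance` (taxa x samples, columns sum to 1),
#'   `copy_numbers`, `bias` (taxa x regions), `currents`, `max_currents`,
#'   `otu_origin`, `read_origin`, `ref_seqs`, `bin_of_taxon`, `twin_groups`.
#' @export
generate_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "community_spec"))
  if (spec$reads_per_region <= 0) stop("reads_per_region must be positive")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- generate_references(spec)   # seeds the RNG from spec$seed
  n <- spec$n_taxa
  ids <- taxon_ids(n)
  samples <- sprintf("BES%02d", seq_len(spec$n_samples))
  regions <- names(spec$region_windows)
  taxonomy <- synthetic_taxonomy(n)
  bins <- paste0("bin_", ids)

  draw <- sample_community(spec, seed = NULL)  # RNG already seeded by refs
  abund <- draw$abundance
  copies <- draw$copy_numbers
  bias <- draw$bias
  max_current <- draw$max_current
  current_at_sampling <- draw$current_at_sampling

  # twin handling: the second member of each pair shares the first's 16S
  twin_second <- integer(0)
  twin_first_of <- integer(0)
  if (!is.null(spec$twin_pairs)) {
    twin_second <- vapply(spec$twin_pairs, `[[`, integer(1), 2L)
    twin_first_of <- vapply(spec$twin_pairs, `[[`, integer(1), 1L)
  }
  otu_taxa <- setdiff(seq_len(n), twin_second)

  # amplicon weight of an emitted OTU: its own taxon plus any twin partner
  amp_weight <- function(s, r) {
    w <- abund[, s] * copies * bias[, r]
    for (k in seq_along(twin_second)) {
      w[twin_first_of[k]] <- w[twin_first_of[k]] + w[twin_second[k]]
    }
    w[otu_taxa]
  }

  otu_rows <- list()
  otu_seqs <- character(0)
  otu_origin <- character(0)
  for (r in regions) {
    win <- spec$region_windows[[r]]
    otu_ids <- sprintf("otu_%s_%02d", r, otu_taxa)
    counts <- vapply(samples, function(s) {
      as.integer(stats::rmultinom(1, spec$reads_per_region, amp_weight(s, r)))
    }, integer(length(otu_taxa)))
    counts <- matrix(counts, nrow = length(otu_taxa),
                     dimnames = list(otu_ids, samples))
    reps <- vapply(otu_taxa, function(t) {
      mutate_seq(substr(refs[[t]], win[1] + 1L, win[2]),
                 spec$otu_mutation_rate)
    }, character(1))
    names(reps) <- otu_ids
    otu_seqs <- c(otu_seqs, reps)
    origin <- ids[otu_taxa]
    names(origin) <- otu_ids
    otu_origin <- c(otu_origin, origin)
    otu_rows[[r]] <- data.frame(otu_id = otu_ids, region = r, counts,
                                check.names = FALSE, row.names = NULL)
  }
  otu_counts <- do.call(rbind, otu_rows)
  rownames(otu_counts) <- NULL

  # shotgun coverage: contigs per bin, lognormal depth noise
  sdlog <- sqrt(log(1 + spec$depth_noise_cv^2))
  cov_rows <- list()
  for (i in seq_len(n)) {
    n_contig <- sample(3:6, 1)
    lens <- sample(20000:400000, n_contig)
    depth <- vapply(samples, function(s) {
      mu <- spec$wgs_depth_mean * abund[i, s]
      if (sdlog > 0) {
        mu * stats::rlnorm(n_contig, -sdlog^2 / 2, sdlog)
      } else {
        rep(mu, n_contig)
      }
    }, numeric(n_contig))
    depth <- matrix(depth, nrow = n_contig)
    cov_rows[[i]] <- data.frame(bin_id = bins[i],
                                contig_id = sprintf("%s_c%02d", bins[i],
                                                    seq_len(n_contig)),
                                length_bp = lens, depth,
                                check.names = FALSE, row.names = NULL)
    colnames(cov_rows[[i]])[-(1:3)] <- samples
  }
  coverage <- do.call(rbind, cov_rows)

  # single-copy marker inventory: every bin carries the same universal set,
  # labelled with its own taxon (disjoint multisets across bins)
  marker_names <- sprintf("marker_%02d", 1:31)
  markers <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(bin_id = bins[i], marker_id = marker_names,
               taxon = taxonomy[[i]][["genus"]], row.names = NULL)
  }))

  # paired-read hit tables with congeneric decoys
  decoy_lineage <- function(i) {
    lin <- taxonomy[[i]]
    lin[["species"]] <- paste0(lin[["species"]], "_decoy")
    lin
  }
  read_origin <- list()
  hit_files <- character(0)
  for (s in samples) {
    npair <- spec$read_pairs_per_sample
    origin <- sample.int(n, npair, replace = TRUE, prob = abund[, s])
    rid <- sprintf("%s_read%05d", s, seq_len(npair))
    read_origin[[s]] <- stats::setNames(ids[origin], rid)
    rows <- vector("list", npair)
    for (k in seq_len(npair)) {
      i <- origin[k]
      lin_true <- format_lineage(taxonomy[[i]])
      mate_rows <- lapply(1:2, function(m) {
        e_best <- 10^-stats::runif(1, 20, 60)
        df <- data.frame(read_id = rid[k], mate = m,
                         subject_id = paste0("acc_", ids[i]),
                         evalue = e_best,
                         bitscore = round(50 - 1.8 * log10(e_best), 1),
                         lineage = lin_true, row.names = NULL)
        if (stats::runif(1) < spec$decoy_rate) {
          e_decoy <- e_best * 10^stats::runif(1, 0, 4)
          df <- rbind(df, data.frame(read_id = rid[k], mate = m,
                                     subject_id = paste0("acc_", ids[i], "d"),
                                     evalue = e_decoy,
                                     bitscore = round(50 - 1.8 * log10(e_decoy), 1),
                                     lineage = format_lineage(decoy_lineage(i)),
                                     row.names = NULL))
        }
        df
      })
      rows[[k]] <- do.call(rbind, mate_rows)
    }
    tab <- do.call(rbind, rows)
    path <- file.path(dir, sprintf("hits_%s.tsv", s))
    write_tsv(tab, path)
    hit_files[s] <- path
  }

  metadata <- data.frame(sample_id = samples,
                         current_mA_m2 = current_at_sampling,
                         max_current_mA_m2 = max_current,
                         hours = sample(240:350, spec$n_samples,
                                        replace = TRUE),
                         row.names = NULL)

  ref_ids <- paste0("ref_", ids[otu_taxa])
  ref_seq_out <- refs[otu_taxa]
  names(ref_seq_out) <- ref_ids
  ref_bins <- data.frame(ref_id = ref_ids, bin_id = bins[otu_taxa],
                         row.names = NULL)

  files <- c(refs = file.path(dir, "refs.fasta"),
             ref_bins = file.path(dir, "ref_bins.tsv"),
             otu_counts = file.path(dir, "otu_counts.tsv"),
             otu_reps = file.path(dir, "otu_reps.fasta"),
             coverage = file.path(dir, "coverage.tsv"),
             bin_markers = file.path(dir, "bin_markers.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(ref_seq_out, files[["refs"]])
  write_tsv(ref_bins, files[["ref_bins"]])
  write_tsv(otu_counts, files[["otu_counts"]])
  write_fasta(otu_seqs, files[["otu_reps"]])
  write_tsv(coverage, files[["coverage"]])
  write_tsv(markers, files[["bin_markers"]])
  utils::write.csv(metadata, files[["metadata"]], row.names = FALSE,
                   quote = FALSE)

  bin_of_taxon <- stats::setNames(bins, ids)
  twin_groups <- lapply(spec$twin_pairs, function(p) bins[p])
  truth <- list(true_abundance = abund, copy_numbers = copies, bias = bias,
                currents = stats::setNames(current_at_sampling, samples),
                max_currents = stats::setNames(max_current, samples),
                otu_origin = otu_origin,
                read_origin = unlist(unname(read_origin)),
                ref_seqs = stats::setNames(unname(refs), ids),
                bin_of_taxon = bin_of_taxon,
                taxonomy = taxonomy,
                twin_groups = twin_groups)
  jsonlite::write_json(
    list(true_abundance = as.data.frame(abund),
         copy_numbers = as.list(copies),
         bias = as.data.frame(bias),
         currents = as.list(truth$currents),
         max_currents = as.list(truth$max_currents),
         otu_origin = as.list(otu_origin),
         read_origin = as.list(truth$read_origin),
         ref_seqs = as.list(truth$ref_seqs)),
    files[["truth"]], auto_unbox = TRUE, digits = NA)

  list(truth = truth, files = c(files, hits = hit_files), spec = spec)
}
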