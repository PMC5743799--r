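mk_bin <- function(id, lens, depths, markers = character(0),
                   taxonomy = c("Bacteria", "P1", "C1", "O1", "F1", "G1"),
                   ref_map = NA_character_, samples = paste0("s", 1:ncol(depths))) {
  colnames(depths) <- samples
  bin_genome(id, data.frame(contig_id = paste0(id, "_c", seq_along(lens)),
                            length_bp = lens),
             depths, markers, taxonomy, ref_map)
}

test_that("bin_depth is the length-weighted mean of contig depths", {
  b <- mk_bin("b1", c(1000, 3000), matrix(c(10, 20), 2, 1))
  expect_equal(bin_depth(b, "s1"), 17.5)
  b1 <- mk_bin("b2", 5000, matrix(7.3, 1, 1))
  expect_equal(bin_depth(b1, "s1"), 7.3)
  # short contigs excluded from the depth computation
  b2 <- mk_bin("b3", c(500, 3000), matrix(c(100, 20), 2, 1))
  expect_equal(bin_depth(b2, "s1"), 20)
})

test_that("coverage_abundance normalizes depths per sample", {
  b1 <- mk_bin("b1", 2000, matrix(10, 1, 2))
  b2 <- mk_bin("b2", 2000, matrix(30, 1, 2))
  ab <- coverage_abundance(list(b1, b2))
  expect_equal(unname(ab[, 1]), c(0.25, 0.75))
  expect_equal(unname(coverage_abundance(list(b1))[1, ]), c(1, 1))
  # invariant to uniform rescaling of a sample's depths
  b1s <- mk_bin("b1", 2000, matrix(10 * 7, 1, 2))
  b2s <- mk_bin("b2", 2000, matrix(30 * 7, 1, 2))
  expect_equal(coverage_abundance(list(b1s, b2s)), ab)
  bz <- mk_bin("bz", 2000, matrix(0, 1, 2))
  expect_error(coverage_abundance(list(bz)), "s1")
})

test_that("bins sharing a reference genome merge; duplicated markers block", {
  d <- matrix(runif(8, 1, 5), 1)
  parts <- lapply(1:3, function(i)
    mk_bin(paste0("b", i), 2000, d, markers = paste0("m", i),
           ref_map = "CP1"))
  other <- mk_bin("b9", 2000, matrix(runif(8, 1, 5), 1),
                  markers = "m9", taxonomy = c("Bacteria", "P2"))
  merged <- merge_split_bins(c(parts, list(other)))
  expect_equal(length(merged), 2)
  ids <- vapply(merged, `[[`, character(1), "bin_id")
  expect_true("b1m" %in% ids)  # merged id carries the m suffix
  # same single-copy marker in both halves: merge refused
  dup1 <- mk_bin("d1", 2000, d, markers = c("m1", "m2"))
  dup2 <- mk_bin("d2", 2000, d, markers = c("m2", "m3"))
  expect_equal(length(merge_split_bins(list(dup1, dup2))), 2)
})

test_that("merging requires genus-level taxonomic agreement", {
  d <- matrix(seq(1, 8), 1)
  a <- mk_bin("a", 2000, d, markers = "m1",
              taxonomy = c("Bacteria", "P1", "C1", "O1", "F1", "G1"))
  b <- mk_bin("b", 2000, d * 1.01, markers = "m2",
              taxonomy = c("Bacteria", "P1", "C1", "O1", "F1", "G2"))
  expect_equal(length(merge_split_bins(list(a, b))), 2)
  b$taxonomy <- a$taxonomy
  expect_equal(length(merge_split_bins(list(a, b))), 1)
})

test_that("merging conserves contigs and markers and never adds bins", {
  set.seed(51)
  bins <- lapply(1:6, function(i)
    mk_bin(paste0("b", i), sample(2000:5000, 3),
           matrix(runif(3 * 4, 0, 10), 3),
           markers = paste0("m", i),
           taxonomy = c("Bacteria", "P1", "C1", "O1", "F1",
                        paste0("G", (i + 1) %/% 2))))
  merged <- merge_split_bins(bins, coverage_corr_min = 0.5)
  expect_lte(length(merged), length(bins))
  total_len <- function(bs) sum(unlist(lapply(bs, function(b)
    b$contigs$length_bp)))
  total_mk <- function(bs) length(unlist(lapply(bs, `[[`, "markers")))
  expect_equal(total_len(merged), total_len(bins))
  expect_equal(total_mk(merged), total_mk(bins))
})

test_that("a randomly partitioned genome is re-merged at the default threshold", {
  set.seed(52)
  recovered <- 0
  for (trial in 1:100) {
    # one true genome: 9 contigs sharing an abundance-driven depth profile
    profile <- runif(8, 2, 40)
    depths <- t(vapply(1:9, function(i)
      profile * rlnorm(8, 0, 0.05), numeric(8)))
    part <- sample(rep(1:3, 3))
    marker_split <- split(paste0("m", 1:9), part)
    bins <- lapply(1:3, function(g) {
      rows <- part == g
      mk_bin(paste0("p", g), rep(3000, sum(rows)),
             depths[rows, , drop = FALSE], markers = marker_split[[g]])
    })
    if (length(merge_split_bins(bins)) == 1) recovered <- recovered + 1
  }
  expect_gte(recovered, 95)
})

test_that("read_bins round-trips the generator's coverage table", {
  spec <- community_spec(n_taxa = 4, n_samples = 3, reads_per_region = 200,
                         read_pairs_per_sample = 20, depth_noise_cv = 0,
                         seed = 53)
  d <- generate_dataset(spec, file.path(tempdir(), "covrt"))
  bins <- read_bins(d$files[["coverage"]], d$files[["bin_markers"]])
  expect_equal(length(bins), 4)
  ab <- coverage_abundance(bins)
  # noise-free coverage: abundance equals the truth record exactly
  truth <- d$truth$true_abundance
  rownames(truth) <- paste0("bin_", rownames(truth))
  expect_equal(ab, truth[rownames(ab), colnames(ab)], tolerance = 1e-12)
})

test_that("bin depth stays within the lognormal noise envelope", {
  spec <- community_spec(n_taxa = 4, n_samples = 3, reads_per_region = 200,
                         read_pairs_per_sample = 20, depth_noise_cv = 0.1,
                         seed = 54)
  d <- generate_dataset(spec, file.path(tempdir(), "covnoise"))
  bins <- read_bins(d$files[["coverage"]])
  for (b in bins) {
    taxon <- sub("bin_", "", b$bin_id)
    expected <- 50 * d$truth$true_abundance[taxon, ]
    obs <- bin_depth(b)
    # length-weighted mean over >=3 contigs at cv=0.1: 5 relative sd is ample
    expect_true(all(abs(obs - expected) / expected < 5 * 0.1))
  }
})
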