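test_that("percent identity handles exact and substituted queries", {
  set.seed(61)
  ref <- random_dna(1500)
  q <- substr(ref, 501, 750)
  expect_equal(percent_identity(q, ref)$identity, 100)
  q3 <- mutate_subs(q, 3)
  expect_equal(percent_identity(q3, ref)$identity, 100 * 247 / 250)
  expect_error(percent_identity("", ref), "empty")
  expect_error(percent_identity(ref, q), "longer")
})

test_that("alignment scores match the Gotoh DP oracle on random pairs", {
  set.seed(62)
  for (i in 1:50) {
    ref <- random_dna(sample(60:120, 1))
    q <- random_dna(sample(25:40, 1))
    expect_equal(percent_identity(q, ref)$score, oracle_align(q, ref)$score)
  }
})

test_that("identity matches the DP oracle on substitution-only pairs", {
  set.seed(63)
  for (i in 1:30) {
    ref <- random_dna(300)
    start <- sample(1:100, 1)
    q <- mutate_subs(substr(ref, start, start + 79), sample(0:6, 1))
    got <- percent_identity(q, ref)
    want <- oracle_align(q, ref)
    expect_equal(got$score, want$score)
    expect_equal(got$identity, want$identity)
  }
})

test_that("link_otus links above threshold and leaves the rest unlinked", {
  set.seed(64)
  refs <- c(refA = random_dna(1000), refB = random_dna(1000))
  otus <- c(o_good = mutate_subs(substr(refs[["refA"]], 101, 350), 3),
            o_far = random_dna(250))
  lm <- link_otus(otus, refs, threshold = 97,
                  ref_bins = c(refA = "binA", refB = "binB"))
  expect_equal(lm$ref_id[lm$otu_id == "o_good"], "refA")
  expect_equal(lm$bin_id[lm$otu_id == "o_good"], "binA")
  expect_true(is.na(lm$ref_id[lm$otu_id == "o_far"]))
  # 96.8% best identity stays unlinked at the 97% bar
  o_8 <- mutate_subs(substr(refs[["refA"]], 101, 350), 8)
  lm8 <- link_otus(c(o = o_8), refs, threshold = 97)
  expect_true(is.na(lm8$ref_id[1]) || lm8$identity[1] >= 97)
})

test_that("raising the threshold never increases linked OTUs", {
  set.seed(65)
  refs <- setNames(replicate(3, random_dna(800)), c("r1", "r2", "r3"))
  otus <- setNames(c(vapply(refs, function(r)
    mutate_subs(substr(r, 201, 400), sample(2:12, 1)), character(1)),
    random_dna(200)), paste0("o", 1:4))
  n_linked <- function(th) sum(!is.na(link_otus(otus, refs, th)$ref_id))
  counts <- vapply(c(90, 94, 97, 99), n_linked, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # determinism / idempotence
  expect_identical(link_otus(otus, refs, 97), link_otus(otus, refs, 97))
})

test_that("generator OTUs link back to their generating reference", {
  spec <- community_spec(n_taxa = 8, n_samples = 2, reads_per_region = 500,
                         read_pairs_per_sample = 20, seed = 66)
  d <- generate_dataset(spec, file.path(tempdir(), "linkgen"))
  otus <- read_fasta_seqs(d$files[["otu_reps"]])
  refs <- read_fasta_seqs(d$files[["refs"]])
  lm <- link_otus(otus, refs, 97)
  expect_true(all(!is.na(lm$ref_id)))
  expect_equal(sub("ref_", "", lm$ref_id),
               unname(d$truth$otu_origin[lm$otu_id]))
})

test_that("region_abundance sums linked counts over shared references", {
  oc <- data.frame(otu_id = c("o1", "o2", "o3"), region = "V4",
                   s1 = c(30L, 20L, 950L), s2 = c(0L, 0L, 0L),
                   check.names = FALSE)
  lm <- data.frame(otu_id = c("o1", "o2", "o3"),
                   ref_id = c("rA", "rA", NA), identity = c(99, 98, 90),
                   aln_length = 250, bin_id = c("bA", "bA", NA))
  ra <- region_abundance(oc, lm, totals = c(s1 = 1000, s2 = 0))
  expect_equal(ra$abundance["rA", "s1"], 0.05)
  expect_true(is.na(ra$abundance["rA", "s2"]))  # zero total: missing, not 0
  expect_equal(ra$linked_fraction[["s1"]], 0.05)
  # by bin id
  rb <- region_abundance(oc, lm, totals = c(s1 = 1000, s2 = 0), by = "bin_id")
  expect_equal(rb$abundance["bA", "s1"], 0.05)
})

test_that("average_regions means passing regions and renormalizes", {
  mk <- function(v, lf) list(abundance = matrix(v, 2, 1,
                                                dimnames = list(c("a", "b"),
                                                                "s1")),
                             linked_fraction = c(s1 = lf), region = "x")
  rr <- list(mk(c(0.2, 0.7), 0.9), mk(c(0.3, 0.6), 0.95),
             mk(c(0.4, 0.5), 0.99))
  avg <- average_regions(rr, min_linked_fraction = 0.8)
  expect_equal(avg$abundance["a", "s1"], 0.3 / 0.9)  # mean then renormalize
  expect_equal(sum(avg$abundance[, "s1"]), 1)
  # a failed region-sample is excluded by QC
  rr_bad <- c(rr, list(mk(c(0.99, 0.0), 0.01)))
  avg2 <- average_regions(rr_bad, min_linked_fraction = 0.8)
  expect_equal(avg2$abundance, avg$abundance)
  expect_error(average_regions(list(mk(c(0.5, 0.5), 0.01))), "s1")
})

test_that("cross-region averaging beats the worst single region", {
  # per-region multiplicative bias; the average should be closer to truth
  # than the worst region in most random draws
  set.seed(67)
  wins <- 0
  for (trial in 1:50) {
    truth <- rgamma(6, 2); truth <- truth / sum(truth)
    regions <- lapply(1:5, function(r) {
      bias <- exp(rnorm(6, 0, 0.4))
      x <- truth * bias
      x / sum(x)
    })
    avg <- rowMeans(do.call(cbind, regions))
    avg <- avg / sum(avg)
    mae <- function(x) mean(abs(x - truth))
    if (mae(avg) <= max(vapply(regions, mae, numeric(1))))
      wins <- wins + 1
  }
  expect_gte(wins, 45)
})

test_that("linked fraction is high for generator data at paper-like settings", {
  spec <- community_spec(n_taxa = 10, n_samples = 3, reads_per_region = 2000,
                         read_pairs_per_sample = 20, seed = 68)
  d <- generate_dataset(spec, file.path(tempdir(), "lf"))
  otus <- read_fasta_seqs(d$files[["otu_reps"]])
  refs <- read_fasta_seqs(d$files[["refs"]])
  lm <- link_otus(otus, refs, 97)
  oc <- read.table(d$files[["otu_counts"]], header = TRUE, sep = "\t",
                   check.names = FALSE)
  rr <- lapply(split_by_region(oc), region_abundance, link_map = lm)
  lf <- unlist(lapply(rr, `[[`, "linked_fraction"))
  expect_true(all(lf >= 0.97))
})
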