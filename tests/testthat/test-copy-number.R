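abund_mat <- function(v, samples = paste0("s", 1:ncol(v))) {
  colnames(v) <- samples
  v
}

test_that("scale_abundance multiplies and renormalizes", {
  a <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("b1", "b2"), "s1"))
  out <- scale_abundance(a, c(b1 = 1, b2 = 3))
  expect_equal(unname(out[, 1]), c(0.25, 0.75))
  # equal copy numbers: normalization cancels the scaling entirely
  a2 <- matrix(runif(12), 4, 3,
               dimnames = list(paste0("b", 1:4), paste0("s", 1:3)))
  a2 <- sweep(a2, 2, colSums(a2), "/")
  expect_true(all(abs(scale_abundance(a2, setNames(rep(4, 4),
                                                   rownames(a2))) - a2)
                  <= 1e-12))
  expect_error(scale_abundance(a, c(b1 = 0, b2 = 3)), ">= 1")
  expect_error(scale_abundance(a, c(b1 = 2)), "b2")
})

test_that("scaled genome abundance reproduces bias-free amplicon truth", {
  spec <- community_spec(n_taxa = 6, n_samples = 4, primer_bias_sd = 0,
                         depth_noise_cv = 0, reads_per_region = 500,
                         read_pairs_per_sample = 20, seed = 71)
  d <- generate_dataset(spec, file.path(tempdir(), "scaleid"))
  g <- d$truth$true_abundance
  copies <- d$truth$copy_numbers
  expected_16s <- sweep(g * copies, 2, colSums(g * copies), "/")
  expect_equal(scale_abundance(g, copies), expected_16s, tolerance = 1e-12)
})

test_that("a single unknown copy number is recovered exactly without noise", {
  set.seed(72)
  g <- matrix(rgamma(5 * 4, 2), 5, 4,
              dimnames = list(paste0("b", 1:5), paste0("s", 1:4)))
  g <- sweep(g, 2, colSums(g), "/")
  copies <- c(b1 = 2, b2 = 1, b3 = 4, b4 = 7, b5 = 3)
  a <- scale_abundance(g, copies)
  known <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  m <- copy_number_model(rownames(g), ifelse(known, copies, 1L), known)
  fit <- estimate_copy_numbers(g, a, m)
  expect_equal(unname(fit$copy_number[["b3"]]), 4)
  expect_lt(fit$objective, 1e-20)
})

test_that("hold-out validation recovers known copy numbers exactly", {
  # the validation design: two anchors with known copies are re-estimated
  # as unknowns and must return their true values in noise-free data
  set.seed(73)
  g <- matrix(rgamma(8 * 6, 2), 8, 6,
              dimnames = list(paste0("b", 1:8), paste0("s", 1:6)))
  g <- sweep(g, 2, colSums(g), "/")
  copies <- setNames(sample(1:13, 8, replace = TRUE), rownames(g))
  a <- scale_abundance(g, copies)
  heldout <- c("b2", "b5")
  known <- !(rownames(g) %in% heldout)
  m <- copy_number_model(rownames(g), ifelse(known, copies, 1L), known)
  fit <- estimate_copy_numbers(g, a, m)
  expect_equal(fit$copy_number[heldout], copies[heldout])
})

test_that("estimation never worsens the starting objective", {
  set.seed(74)
  for (trial in 1:20) {
    g <- matrix(rgamma(6 * 5, 2), 6, 5,
                dimnames = list(paste0("b", 1:6), paste0("s", 1:5)))
    g <- sweep(g, 2, colSums(g), "/")
    copies <- setNames(sample(1:13, 6, replace = TRUE), rownames(g))
    noise <- matrix(rlnorm(30, 0, 0.2), 6, 5)
    a <- g * copies * noise
    a <- sweep(a, 2, colSums(a), "/")
    dimnames(a) <- dimnames(g)
    known <- c(TRUE, rep(FALSE, 5))
    m <- copy_number_model(rownames(g), ifelse(known, copies, 1L), known)
    fit <- suppressWarnings(estimate_copy_numbers(g, a, m))
    start <- setNames(ifelse(known, copies, 1), rownames(g))
    start_obj <- sum((scale_abundance(g, start) - a)^2)
    expect_lte(fit$objective, start_obj + 1e-12)
  }
})

test_that("estimation is invariant to bin and sample relabeling", {
  set.seed(75)
  g <- matrix(rgamma(6 * 5, 2), 6, 5,
              dimnames = list(paste0("b", 1:6), paste0("s", 1:5)))
  g <- sweep(g, 2, colSums(g), "/")
  copies <- setNames(sample(2:9, 6, replace = TRUE), rownames(g))
  a <- scale_abundance(g, copies)
  known <- c(TRUE, TRUE, rep(FALSE, 4))
  m <- copy_number_model(rownames(g), ifelse(known, copies, 1L), known)
  fit <- estimate_copy_numbers(g, a, m)
  perm_b <- sample(6); perm_s <- sample(5)
  g2 <- g[perm_b, perm_s]
  a2 <- a[perm_b, perm_s]
  m2 <- copy_number_model(rownames(g2),
                          ifelse(known[perm_b], copies[perm_b], 1L),
                          known[perm_b])
  fit2 <- estimate_copy_numbers(g2, a2, m2)
  expect_equal(fit2$copy_number[names(fit$copy_number)], fit$copy_number)
})

test_that("without an anchor the solution is scale-degenerate", {
  set.seed(76)
  g <- matrix(rgamma(4 * 3, 2), 4, 3,
              dimnames = list(paste0("b", 1:4), paste0("s", 1:3)))
  g <- sweep(g, 2, colSums(g), "/")
  a <- scale_abundance(g, setNames(c(1, 2, 3, 4), rownames(g)))
  c1 <- setNames(c(1, 2, 3, 4), rownames(g))
  obj <- function(cp) sum((scale_abundance(g, cp) - a)^2)
  expect_equal(obj(c1), obj(2 * c1))  # doubling all copies changes nothing
  m <- copy_number_model(rownames(g), rep(1L, 4), rep(FALSE, 4))
  expect_error(estimate_copy_numbers(g, a, m), "anchor")
})

test_that("sum_subclusters sums grouped rows and preserves column sums", {
  a <- matrix(c(0.1, 0.2, 0.7, 0.3, 0.3, 0.4), 3, 2,
              dimnames = list(c("b1", "b2", "b3"), c("s1", "s2")))
  out <- sum_subclusters(a, list(grp = c("b1", "b2")))
  expect_equal(unname(out["grp", ]), c(0.3, 0.6))
  expect_equal(colSums(out), colSums(a))
  expect_identical(sum_subclusters(a, list()), a)
  expect_error(sum_subclusters(a, list(c("b1", "b2"), c("b2", "b3"))),
               "overlap")
})

test_that("grouping twin sub-clusters lowers the reconciliation residual", {
  # two genome bins share one 16S sequence; the amplicon route sees their
  # combined signal, so reconciliation fits better after summing them
  spec <- community_spec(n_taxa = 6, n_samples = 5, primer_bias_sd = 0,
                         depth_noise_cv = 0, reads_per_region = 500,
                         read_pairs_per_sample = 20,
                         twin_pairs = list(c(2L, 3L)), seed = 77)
  d <- generate_dataset(spec, file.path(tempdir(), "twin"))
  g <- d$truth$true_abundance
  rownames(g) <- paste0("bin_", rownames(g))
  copies <- setNames(d$truth$copy_numbers, rownames(g))
  # amplicon truth as the linking route sees it: twins share T02's OTU
  amp <- g * copies
  amp["bin_T02", ] <- amp["bin_T02", ] + amp["bin_T03", ]
  amp <- amp[rownames(amp) != "bin_T03", ]
  amp <- sweep(amp, 2, colSums(amp), "/")
  obj_with <- {
    gg <- sum_subclusters(g, list(bin_T02 = c("bin_T02", "bin_T03")))
    gg <- gg[rownames(amp), ]
    sum((scale_abundance(gg, copies[rownames(gg)]) - amp)^2)
  }
  obj_without <- {
    gg <- g[rownames(amp), ]
    gg <- sweep(gg, 2, colSums(gg), "/")
    sum((scale_abundance(gg, copies[rownames(gg)]) - amp)^2)
  }
  expect_lt(obj_with, obj_without)
})
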