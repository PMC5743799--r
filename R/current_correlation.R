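#' Correlation of taxon abundance with cathodic current
#'
#' Cathodic currents are negative by sign convention; correlations are
#' computed against the current magnitude. The product-moment correlation r
#' is tested with the exact t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' on `n - 2` degrees of freedom, two-sided. Because relative abundances sum
#' to one within a sample, taxa are negatively dependent by construction;
#' reported correlations describe association with current, not causation.
#'
#' @name current_correlation
NULL

#' Correlate one taxon's abundance with current magnitude
#'
#' @param abundance numeric vector of relative abundances, named by sample.
#' @param metadata data frame with `sample_id` and current columns (mA m-2,
#'   negative = cathodic).
#' @param current_field `"max_current_mA_m2"` (default) or
#'   `"current_mA_m2"`.
#' @param taxon label carried into the result.
#' @return data frame row: `taxon`, `r`, `r_squared`, `p_value`, `n`,
#'   `sign`.
#' @export
correlate_taxon_current <- function(abundance, metadata,
                                    current_field = "max_current_mA_m2",
                                    taxon = NA_character_) {
  cur <- abs(metadata[[current_field]])
  names(cur) <- metadata$sample_id
  if (!is.null(names(abundance))) cur <- cur[names(abundance)]
  ok <- is.finite(abundance) & is.finite(cur)
  x <- abundance[ok]; y <- cur[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 samples with abundance and current")
  if (stats::sd(x) == 0) stop("constant abundance: correlation undefined")
  if (stats::sd(y) == 0) stop("constant current: correlation undefined")
  r <- stats::cor(x, y)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(taxon = taxon, r = r, r_squared = r^2, p_value = p, n = n,
             sign = if (r >= 0) "positive" else "negative",
             row.names = NULL)
}

#' Correlate every taxon with current and rank by R-squared
#'
#' Taxa whose correlation is undefined (constant abundance, or fewer than 3
#' samples with data) are returned as flagged rows with `NA` statistics
#' rather than dropped.
#'
#' @param abundance matrix taxa x samples.
#' @param metadata data frame with `sample_id` and current columns.
#' @inheritParams correlate_taxon_current
#' @param adjust apply Benjamini-Hochberg adjustment (`p_adjusted` column).
#' @return data frame sorted by descending `r_squared`.
#' @export
rank_taxa <- function(abundance, metadata,
                      current_field = "max_current_mA_m2", adjust = FALSE) {
  stopifnot(nrow(abundance) >= 2L)
  rows <- lapply(rownames(abundance), function(tx) {
    tryCatch(correlate_taxon_current(abundance[tx, ], metadata,
                                     current_field, taxon = tx),
             error = function(e) {
               data.frame(taxon = tx, r = NA_real_, r_squared = NA_real_,
                          p_value = NA_real_,
                          n = sum(is.finite(abundance[tx, ])),
                          sign = NA_character_, row.names = NULL)
             })
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[order(-ifelse(is.na(out$r_squared), -Inf, out$r_squared), out$taxon),
      , drop = FALSE]
}

#' Cross-method profile-agreement screen
#'
#' Selects taxa whose pooled mean abundance exceeds `abundance_floor` in
#' both profiles, keeps the `top_k` by pooled mean abundance, correlates
#' each taxon's abundance across samples between the two methods, and
#' counts taxa reaching `r2_min`. Defaults mirror a screen of the top 25
#' taxa above 0.5% with an agreement bar of R-squared >= 0.78.
#'
#' @param profile_a,profile_b matrices taxa x samples (shared sample set;
#'   taxa may differ — missing taxa count as absent).
#' @param abundance_floor minimum pooled mean abundance in each profile.
#' @param top_k taxa retained after the floor.
#' @param r2_min agreement threshold on R-squared.
#' @return list with `table` (per-taxon `r_squared` over the selected taxa)
#'   and `n_agreeing`.
#' @export
method_agreement <- function(profile_a, profile_b, abundance_floor = 0.005,
                             top_k = 25, r2_min = 0.78) {
  samples <- intersect(colnames(profile_a), colnames(profile_b))
  if (length(samples) < 3) stop("need at least 3 shared samples")
  taxa <- union(rownames(profile_a), rownames(profile_b))
  expand <- function(p) {
    m <- matrix(0, length(taxa), length(samples),
                dimnames = list(taxa, samples))
    have <- intersect(rownames(p), taxa)
    m[have, ] <- p[have, samples, drop = FALSE]
    m
  }
  a <- expand(profile_a); b <- expand(profile_b)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  eligible <- taxa[mean_a > abundance_floor & mean_b > abundance_floor]
  pooled <- (mean_a + mean_b)[eligible] / 2
  sel <- eligible[order(-pooled, eligible)]
  sel <- utils::head(sel, top_k)
  r2 <- vapply(sel, function(tx) {
    if (stats::sd(a[tx, ]) == 0 || stats::sd(b[tx, ]) == 0) return(NA_real_)
    stats::cor(a[tx, ], b[tx, ])^2
  }, numeric(1))
  tab <- data.frame(taxon = sel, mean_abundance = unname(pooled[sel]),
                    r_squared = unname(r2), row.names = NULL)
  tab <- tab[order(-ifelse(is.na(tab$r_squared), -Inf, tab$r_squared),
                   tab$taxon), , drop = FALSE]
  list(table = tab, n_agreeing = sum(!is.na(r2) & r2 >= r2_min))
}
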