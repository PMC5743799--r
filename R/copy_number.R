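#' 16S copy-number reconciliation of genome and amplicon abundance
#'
#' Amplicon read counts over-represent organisms with many rRNA operons.
#' Scaling genome (coverage-based) relative abundance by per-genome 16S copy
#' numbers and renormalizing yields the abundance an amplicon library should
#' observe. Copy numbers known from closed genomes act as anchors; unknown
#' integer copy numbers are estimated by coordinate descent, choosing for
#' each unknown bin the integer in bounds that minimizes the squared
#' disagreement between scaled genome abundance and the observed amplicon
#' abundance.
#'
#' @name copy_number
NULL

#' Construct a copy-number model
#'
#' @param bin_ids character vector.
#' @param copy_number integer vector (all >= 1); values for unknown bins are
#'   starting values (conventionally 1).
#' @param known logical vector; known entries are never modified by
#'   estimation.
#' @param bounds integer interval searched for unknown bins.
#' @return object of class `copy_number_model`.
#' @export
copy_number_model <- function(bin_ids, copy_number, known,
                              bounds = c(1L, 13L)) {
  stopifnot(length(bin_ids) == length(copy_number),
            length(bin_ids) == length(known))
  if (any(copy_number < 1)) stop("copy numbers must be >= 1")
  if (bounds[1] < 1) stop("bounds lower limit must be >= 1")
  structure(list(bin_ids = as.character(bin_ids),
                 copy_number = stats::setNames(as.integer(copy_number),
                                               bin_ids),
                 known = stats::setNames(as.logical(known), bin_ids),
                 bounds = as.integer(bounds)),
            class = "copy_number_model")
}

#' Read a copy-number CSV (`bin_id`, `copy_number`, `known`)
#' @param path CSV path.
#' @param bounds passed to [copy_number_model()].
#' @return a `copy_number_model`.
#' @export
read_copy_numbers <- function(path, bounds = c(1L, 13L)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  copy_number_model(df$bin_id, df$copy_number, as.logical(df$known), bounds)
}

#' Scale genome abundance by 16S copy number
#'
#' Each bin's abundance is multiplied by its copy number and each sample
#' column renormalized to sum to 1, giving the relative abundance an
#' amplicon library is expected to report.
#'
#' @param genome_abund matrix bins x samples, columns summing to 1.
#' @param model a [copy_number_model()] covering the matrix's bins, or a
#'   named numeric vector of copy numbers.
#' @return matrix of the same shape; columns sum to 1.
#' @export
scale_abundance <- function(genome_abund, model) {
  copies <- if (inherits(model, "copy_number_model")) model$copy_number
            else model
  if (any(copies < 1)) stop("copy numbers must be >= 1")
  missing <- setdiff(rownames(genome_abund), names(copies))
  if (length(missing))
    stop("no copy number for bin(s): ", paste(missing, collapse = ", "))
  v <- genome_abund * copies[rownames(genome_abund)]
  sweep(v, 2, colSums(v), "/")
}

reconcile_objective <- function(genome_abund, amplicon_abund, copies) {
  sum((scale_abundance(genome_abund, copies) - amplicon_abund)^2)
}

#' Estimate unknown 16S copy numbers by coordinate descent
#'
#' Unknown bins are visited in order of descending mean genome abundance
#' (ties by bin id); for each, every integer in bounds is tried and the one
#' minimizing the total squared difference between [scale_abundance()]
#' output and the amplicon abundance is kept. Passes repeat until a full
#' pass changes nothing or `max_iter` is reached. Because the scaled
#' abundance is renormalized, multiplying all copy numbers by a constant
#' leaves the objective unchanged; at least one known anchor is therefore
#' required to pin the scale.
#'
#' @param genome_abund,amplicon_abund matrices bins x samples with matching
#'   dimnames; columns sum to 1.
#' @param model a [copy_number_model()] with at least one known and one
#'   unknown entry.
#' @param max_iter maximum coordinate-descent passes.
#' @param objective `"squared"` (default) or `"log"` (squared error on
#'   `log(x + pseudocount)`).
#' @param pseudocount used by the log objective.
#' @return the fitted `copy_number_model`, with elements `objective` (final
#'   value), `residuals` (per-bin root-mean-square residual), `converged`,
#'   and `iterations` added.
#' @export
estimate_copy_numbers <- function(genome_abund, amplicon_abund, model,
                                  max_iter = 50,
                                  objective = c("squared", "log"),
                                  pseudocount = 1e-4) {
  objective <- match.arg(objective)
  stopifnot(inherits(model, "copy_number_model"))
  if (ncol(genome_abund) < 2) stop("need at least 2 samples")
  common <- intersect(rownames(genome_abund), rownames(amplicon_abund))
  if (length(common) < 2) stop("need at least 2 shared bins")
  ga <- genome_abund[common, colnames(amplicon_abund), drop = FALSE]
  aa <- amplicon_abund[common, , drop = FALSE]
  copies <- model$copy_number[common]
  known <- model$known[common]
  if (!any(known)) stop("at least one known copy number (anchor) is required")
  unknowns <- common[!known]
  if (length(unknowns) == 0L) stop("no unknown copy numbers to estimate")

  obj_fun <- if (objective == "squared") {
    function(cp) sum((scale_abundance(ga, cp) - aa)^2)
  } else {
    function(cp) sum((log(scale_abundance(ga, cp) + pseudocount) -
                        log(aa + pseudocount))^2)
  }

  # most-constrained (most abundant) unknowns first; ties by bin id
  ord <- unknowns[order(-rowMeans(ga[unknowns, , drop = FALSE]), unknowns)]
  grid <- seq(model$bounds[1], model$bounds[2])
  converged <- FALSE
  iters <- 0L
  for (pass in seq_len(max_iter)) {
    iters <- pass
    changed <- FALSE
    for (b in ord) {
      vals <- vapply(grid, function(k) {
        cp <- copies; cp[b] <- k; obj_fun(cp)
      }, numeric(1))
      best <- grid[which.min(vals)]
      if (best != copies[[b]]) {
        copies[b] <- best
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged)
    warning("copy-number estimation did not converge in ", max_iter,
            " passes")
  fitted <- model
  fitted$copy_number[common] <- copies
  fitted$objective <- obj_fun(copies)
  res <- scale_abundance(ga, copies) - aa
  fitted$residuals <- sqrt(rowMeans(res^2))
  fitted$converged <- converged
  fitted$iterations <- iters
  fitted
}

#' Sum abundance rows of grouped sub-cluster bins
#'
#' When one 16S sequence represents several genome sub-clusters, their
#' genome abundances are summed into a single row before reconciliation.
#' Groups must not overlap; ungrouped bins pass through unchanged, and
#' column sums are preserved.
#'
#' @param abundance matrix bins x samples.
#' @param groups list of character vectors of bin ids; each group is
#'   replaced by one row named after its first member (or the list name,
#'   when the list is named).
#' @return matrix with grouped rows summed.
#' @export
sum_subclusters <- function(abundance, groups) {
  if (length(groups) == 0L) return(abundance)
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) stop("overlapping groups")
  missing <- setdiff(all_ids, rownames(abundance))
  if (length(missing))
    stop("group member(s) not in matrix: ", paste(missing, collapse = ", "))
  gnames <- names(groups)
  if (is.null(gnames)) gnames <- rep(NA_character_, length(groups))
  keep <- setdiff(rownames(abundance), all_ids)
  rows <- abundance[keep, , drop = FALSE]
  grouped <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    nm <- if (!is.na(gnames[i]) && nzchar(gnames[i])) gnames[i] else g[[1L]]
    out <- matrix(colSums(abundance[g, , drop = FALSE]), nrow = 1,
                  dimnames = list(nm, colnames(abundance)))
    out
  }))
  out <- rbind(rows, grouped)
  out[order(rownames(out)), , drop = FALSE]
}
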