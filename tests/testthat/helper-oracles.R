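# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the LCA oracle walks ranks from the root, the
# alignment oracle is a plain Gotoh dynamic program, and the correlation
# oracle evaluates the raw-sum closed forms with the incomplete-beta p-value.

# brute-force rank walk: advance one rank at a time while all agree
oracle_lca <- function(lineages) {
  out <- character(0)
  i <- 1L
  repeat {
    if (any(lengths(lineages) < i)) break
    vals <- vapply(lineages, `[[`, character(1), i)
    if (length(unique(vals)) != 1L) break
    out <- c(out, vals[[1L]])
    i <- i + 1L
  }
  out
}

# a small random 4-level taxonomy: ranks filled top-down so prefixes nest
random_lineage_pool <- function(n_phyla = 3, n_per = 3) {
  pool <- list()
  for (p in seq_len(n_phyla)) {
    for (c in seq_len(n_per)) {
      for (o in seq_len(n_per)) {
        for (g in seq_len(n_per)) {
          pool[[length(pool) + 1L]] <-
            c(sprintf("P%d", p), sprintf("P%d.C%d", p, c),
              sprintf("P%d.C%d.O%d", p, c, o),
              sprintf("P%d.C%d.O%d.G%d", p, c, o, g))
        }
      }
    }
  }
  pool
}

# brute-force re-implementation of the per-mate consensus rule
oracle_classify <- function(hits, cutoff = 0.001, window = 100,
                            max_hits = 5) {
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(character(0))
  hits <- hits[order(hits$evalue, -hits$bitscore, hits$subject_id), ,
               drop = FALSE]
  hits <- head(hits, max_hits)
  keep <- hits$evalue <= window * hits$evalue[[1L]] * (1 + 1e-9)
  oracle_lca(lapply(hits$lineage[keep], parse_lineage))
}

oracle_pair <- function(m1, m2) {
  if (length(m1) && length(m2)) return(oracle_lca(list(m1, m2)))
  if (length(m1)) m1 else m2
}

# Gotoh affine-gap semi-global DP (query global, reference local);
# a gap of length L costs open + L * ext. Returns score and, via traceback,
# matches and alignment columns. NOTE: when several alignments share the
# optimal score the traceback picks one; callers comparing identity should
# use inputs whose optimum is unique (substitution-only pairs).
oracle_align <- function(q, r, open = 2, ext = 1) {
  qc <- strsplit(q, "")[[1L]]
  rc <- strsplit(r, "")[[1L]]
  m <- length(qc); n <- length(rc)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)   # best score, any state
  Ix <- matrix(NEG, m + 1, n + 1)  # query char against gap
  Iy <- matrix(NEG, m + 1, n + 1)  # ref char against gap
  M[1, ] <- 0                       # free reference prefix
  for (i in 2:(m + 1)) {
    Ix[i, 1] <- max(M[i - 1, 1] - open - ext, Ix[i - 1, 1] - ext)
    M[i, 1] <- Ix[i, 1]
    for (j in 2:(n + 1)) {
      s <- if (qc[i - 1] == rc[j - 1]) 1 else -1
      diag <- M[i - 1, j - 1] + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      M[i, j] <- max(diag, Ix[i, j], Iy[i, j])
    }
  }
  score <- max(M[m + 1, ])
  jend <- which.max(M[m + 1, ])
  # traceback for matches / columns
  i <- m + 1; j <- jend
  matches <- 0L; cols <- 0L
  state <- "M"
  while (i > 1) {
    if (state == "M" && M[i, j] == Ix[i, j]) state <- "Ix"
    if (state == "M" && j > 1 && M[i, j] == Iy[i, j]) state <- "Iy"
    if (state == "M") {
      s <- if (qc[i - 1] == rc[j - 1]) 1 else -1
      matches <- matches + as.integer(s == 1)
      cols <- cols + 1L
      i <- i - 1; j <- j - 1
      state <- "M"
    } else if (state == "Ix") {
      cols <- cols + 1L
      from_open <- M[i - 1, j] - open - ext
      state <- if (Ix[i, j] == from_open) "M" else "Ix"
      i <- i - 1
    } else {
      cols <- cols + 1L
      from_open <- M[i, j - 1] - open - ext
      state <- if (Iy[i, j] == from_open) "M" else "Iy"
      j <- j - 1
    }
  }
  list(score = score, matches = matches, cols = cols,
       identity = 100 * matches / cols)
}

# closed-form correlation from raw sums; p via the incomplete beta function
# (equivalent to the two-sided t test on n - 2 df, evaluated independently)
oracle_corr <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  p <- stats::pbeta(1 - r^2, (n - 2) / 2, 0.5)
  list(r = r, r_squared = r^2, p = p)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitution-only mutant (no indels): optimal alignment is unique, gapless
mutate_subs <- function(seq, k) {
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample(seq_along(chars), k)
  alt <- c(A = "C", C = "G", G = "T", T = "A")
  chars[pos] <- alt[chars[pos]]
  paste(chars, collapse = "")
}
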