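# Shared fixtures and independent brute-force oracles.  Oracles are
# deliberately written as plain loops, independent of the package's
# vectorized implementations.

tiny_genome <- function(nbins = 10, bin_size = 1000, n_chrom = 1) {
  BinnedGenome(setNames(rep(nbins * bin_size, n_chrom),
                        paste0("chr", seq_len(n_chrom))),
               binSize = bin_size)
}

cm_from_matrix <- function(m, stage = "raw", bin_size = 1000) {
  g <- tiny_genome(nrow(m), bin_size)
  ContactMatrix(g, list(chr1 = m), stage = stage)
}

# two-block checkerboard matrix: within = a, across = b
block_matrix <- function(n1, n2, within = 2, across = 0.5) {
  n <- n1 + n2
  grp <- c(rep(1, n1), rep(2, n2))
  outer(grp, grp, function(i, j) ifelse(i == j, within, across))
}

call_from_pc1 <- function(genome, pc1, orientation = "test") {
  label <- ifelse(is.na(pc1), "masked", ifelse(pc1 > 0, "A", "B"))
  new("CompartmentCall", genome = genome, pc1 = pc1, label = label,
      orientationTrack = orientation,
      eigenGap = setNames(rep(10, length(chromNames(genome))),
                          chromNames(genome)))
}

# expected-by-distance by exhaustive pair enumeration
oracle_expected <- function(m, mask = rep(FALSE, nrow(m))) {
  n <- nrow(m)
  e <- rep(NaN, n - 1)
  for (d in 1:(n - 1)) {
    vals <- c()
    for (i in 1:(n - d))
      if (!mask[i] && !mask[i + d]) vals <- c(vals, m[i, i + d])
    if (length(vals)) e[d] <- sum(vals) / length(vals)
  }
  e
}

# saddle strength by exhaustive enumeration over cis pairs
oracle_saddle_strength <- function(oe_mat, pc1, Q = 5, corner_frac = 0.2,
                                   d_min = 2) {
  n <- length(pc1)
  ord <- order(pc1, seq_len(n))
  grp <- integer(n)
  for (r in seq_len(n)) grp[ord[r]] <- floor((r - 1) * Q / n) + 1
  sums <- matrix(0, Q, Q); cnts <- matrix(0, Q, Q)
  for (i in 1:n) for (j in 1:n)
    if (abs(i - j) >= d_min && !is.na(oe_mat[i, j])) {
      sums[grp[i], grp[j]] <- sums[grp[i], grp[j]] + oe_mat[i, j]
      cnts[grp[i], grp[j]] <- cnts[grp[i], grp[j]] + 1
    }
  sad <- sums / cnts
  k <- max(1, round(corner_frac * Q))
  lo <- 1:k; hi <- (Q - k + 1):Q
  (mean(sad[lo, lo]) + mean(sad[hi, hi])) /
    (2 * mean(c(sad[lo, hi], sad[hi, lo])))
}

# insulation by exhaustive diamond enumeration (no masking)
oracle_insulation <- function(m, w) {
  n <- nrow(m)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    vals <- c()
    for (u in (i - w):(i - 1)) for (v in (i + 1):(i + w))
      vals <- c(vals, m[u, v])
    raw[i] <- mean(vals)
  }
  ok <- !is.na(raw) & raw > 0
  lg <- rep(NA_real_, n)
  lg[ok] <- log2(raw[ok]) - mean(log2(raw[ok]))
  lg
}

# segregation score by exhaustive enumeration (single chromosome)
oracle_segregation <- function(C_mat, track_vals, n_groups) {
  n <- length(track_vals)
  ord <- order(track_vals, seq_len(n))
  grp <- integer(n)
  for (r in seq_len(n)) grp[ord[r]] <- floor((r - 1) * n_groups / n) + 1
  same <- c(); far <- c()
  for (i in 1:n) for (j in 1:n) {
    if (i == j || is.na(C_mat[i, j])) next
    dg <- abs(grp[i] - grp[j])
    if (dg == 0) same <- c(same, C_mat[i, j])
    if (dg >= n_groups / 2) far <- c(far, C_mat[i, j])
  }
  mean(same) - mean(far)
}

# boundary-recovery F1 at a bin tolerance
boundary_f1 <- function(called, truth, tol = 1) {
  tp <- 0; used <- rep(FALSE, length(truth))
  for (b in called) {
    j <- which(!used & abs(truth - b) <= tol)
    if (length(j)) { tp <- tp + 1; used[j[1]] <- TRUE }
  }
  p <- if (length(called)) tp / length(called) else 0
  r <- tp / length(truth)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# planted boundary positions of a truth set on one chromosome
truth_boundaries <- function(truth, ch) {
  d <- truth@domains
  d <- d[d$chrom == ch, , drop = FALSE]
  c(d$start, d$end[nrow(d)])
}
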