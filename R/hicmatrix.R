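#' Bin a pairs file into a raw contact matrix
#'
#' Reads 4DN-style pairs text (columns: readID, chrom1, pos1, chrom2,
#' pos2, strand1, strand2; `#` comment lines ignored) and accumulates
#' each pair into its bin pair.  Positions are 0-based, so a position
#' equal to `k * binSize` falls in bin `k` (half-open bins).  Cis pairs
#' are stored per chromosome; trans pairs are kept only as a total tally.
#' Malformed lines (wrong field count, non-numeric or out-of-range
#' positions) are skipped, counted and reported in the
#' `n_malformed` attribute.
#'
#' @param pairsFile path to the pairs text file.
#' @param genome a [BinnedGenome-class].
#' @return a raw-stage [ContactMatrix-class]; attribute `n_malformed`
#'   carries the skipped-line count.
#' @export
binPairs <- function(pairsFile, genome) {
  lines <- readLines(pairsFile)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("pairs file is empty: ", pairsFile)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= 5L
  cl <- chromLengths(genome)
  c1 <- vapply(fields[ok], `[[`, "", 2L)
  p1 <- suppressWarnings(as.numeric(vapply(fields[ok], `[[`, "", 3L)))
  c2 <- vapply(fields[ok], `[[`, "", 4L)
  p2 <- suppressWarnings(as.numeric(vapply(fields[ok], `[[`, "", 5L)))
  bad_chrom <- unique(c(c1, c2)[!(c(c1, c2) %in% names(cl))])
  if (length(bad_chrom))
    stop("unknown chromosome(s) in pairs file: ",
         paste(bad_chrom, collapse = ", "))
  valid <- !is.na(p1) & !is.na(p2) &
    p1 >= 0 & p1 < cl[c1] & p2 >= 0 & p2 < cl[c2]
  n_malformed <- sum(!ok) + sum(!valid)
  c1 <- c1[valid]; p1 <- p1[valid]; c2 <- c2[valid]; p2 <- p2[valid]
  if (!length(c1)) stop("pairs file contains no valid pairs: ", pairsFile)

  bs <- binSize(genome)
  nb <- chromNbins(genome)
  mats <- lapply(nb, function(n) matrix(0, n, n))
  cis <- c1 == c2
  trans <- sum(!cis)
  for (ch in unique(c1[cis])) {
    sel <- cis & c1 == ch
    i <- floor(p1[sel] / bs) + 1L
    j <- floor(p2[sel] / bs) + 1L
    m <- mats[[ch]]
    for (k in seq_along(i)) {
      m[i[k], j[k]] <- m[i[k], j[k]] + 1
      if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + 1
    }
    mats[[ch]] <- m
  }
  out <- ContactMatrix(genome, mats, stage = "raw", trans = trans)
  if (n_malformed > 0)
    message(n_malformed, " malformed pair line(s) skipped")
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Mask low-coverage bins
#'
#' Masks, per chromosome, every bin whose marginal (row sum) is below
#' `minFrac` times the median marginal of that chromosome.  Masked rows
#' and columns are set to `NA` for all downstream stages.
#'
#' @param M a raw-stage [ContactMatrix-class].
#' @param minFrac fraction of the median marginal below which a bin is
#'   masked (default 0.1).
#' @return the matrix with an updated mask.
#' @export
maskLowCoverage <- function(M, minFrac = 0.1) {
  .require_stage(M, "raw", "maskLowCoverage")
  mask <- M@mask
  for (ch in names(mask)) {
    m <- M@matrices[[ch]]
    marg <- rowSums(m, na.rm = TRUE)
    med <- median(marg)
    # a zero median would make the threshold vacuous; zero-coverage bins
    # are still dead and get masked whenever masking is requested at all
    mask[[ch]] <- mask[[ch]] | (marg < minFrac * med) |
      (minFrac > 0 & med == 0 & marg == 0)
    if (all(mask[[ch]]))
      stop("all bins masked on chromosome ", ch,
           "; lower minFrac or inspect the matrix")
  }
  out <- M
  out@mask <- mask
  for (ch in names(mask)) {
    out@matrices[[ch]][mask[[ch]], ] <- NA_real_
    out@matrices[[ch]][, mask[[ch]]] <- NA_real_
  }
  validObject(out)
  out
}

#' Balance a contact matrix by iterative correction (ICE)
#'
#' Repeatedly divides rows and columns by their marginals rescaled to
#' unit mean until the maximum relative deviation of unmasked marginals
#' from their mean is below `tol`, or `maxIter` sweeps are reached (the
#' latter flags non-convergence with a warning, not an error).  The
#' accumulated per-bin divisors are stored as balancing weights, so
#' `balanced(i,j) = raw(i,j) / (w_i * w_j)`.
#'
#' @param M a raw-stage [ContactMatrix-class] (mask already applied).
#' @param tol convergence tolerance on marginal deviation (default 1e-5).
#' @param maxIter maximum sweeps (default 200).
#' @return a balanced-stage [ContactMatrix-class] with weights.
#' @export
balanceICE <- function(M, tol = 1e-5, maxIter = 200) {
  .require_stage(M, "raw", "balanceICE")
  weights <- list()
  converged <- logical(0)
  mats <- M@matrices
  for (ch in names(mats)) {
    ok <- !M@mask[[ch]]
    sub <- mats[[ch]][ok, ok, drop = FALSE]
    if (sum(sub, na.rm = TRUE) <= 0)
      stop("matrix for ", ch, " has zero total; cannot balance")
    b <- rep(1, nrow(sub))
    conv <- FALSE
    for (it in seq_len(maxIter)) {
      marg <- rowSums(sub)
      pos <- marg > 0
      s <- marg / mean(marg[pos])
      s[!pos] <- 1
      sub <- sub / outer(s, s)
      b <- b * s
      if (max(abs(s[pos] - 1)) < tol) { conv <- TRUE; break }
    }
    if (!conv)
      warning("ICE did not converge on ", ch, " within ", maxIter,
              " sweeps")
    w <- rep(NA_real_, length(ok))
    w[ok] <- b
    weights[[ch]] <- w
    converged[[ch]] <- conv
    full <- mats[[ch]]
    full[ok, ok] <- sub
    mats[[ch]] <- full
  }
  out <- new("ContactMatrix", genome = M@genome, matrices = mats,
             mask = M@mask, stage = "balanced", weights = weights,
             trans = M@trans)
  attr(out, "converged") <- converged
  out
}

#' Expected contact frequency by genomic separation
#'
#' For each chromosome, `E(d)` is the arithmetic mean of the matrix over
#' doubly-unmasked bin pairs at separation `d` bins, for
#' `d = 1 .. n_bins - 1`, together with the number of contributing pairs
#' `N(d)`.  Separations with no eligible pair yield `NaN` and `N = 0`.
#'
#' @param M a raw- or balanced-stage [ContactMatrix-class].
#' @return an `ExpectedProfile`: list with per-chromosome `E` and `N`.
#' @export
expectedByDistance <- function(M) {
  .require_stage(M, c("raw", "balanced"), "expectedByDistance")
  E <- list(); N <- list()
  for (ch in chromNames(M@genome)) {
    m <- M@matrices[[ch]]
    ok <- !M@mask[[ch]]
    n <- nrow(m)
    e <- rep(NaN, n - 1L)
    cnt <- integer(n - 1L)
    for (d in seq_len(n - 1L)) {
      i <- seq_len(n - d)
      use <- ok[i] & ok[i + d]
      cnt[d] <- sum(use)
      if (cnt[d] > 0)
        e[d] <- mean(m[cbind(i[use], i[use] + d)])
    }
    E[[ch]] <- e
    N[[ch]] <- cnt
  }
  structure(list(genome = M@genome, stage = M@stage, E = E, N = N),
            class = "ExpectedProfile")
}

#' Observed-over-expected transform
#'
#' Divides each cell by the expected value at its separation,
#' `OE(i,j) = M(i,j) / E(|i - j|)`.  Cells whose expected value is zero
#' or undefined become `NA`; the main diagonal (separation 0) is `NA`.
#' By construction the mean of OE over unmasked pairs at each separation
#' is exactly 1.
#'
#' @param M a raw- or balanced-stage [ContactMatrix-class].
#' @param expected optionally a precomputed [expectedByDistance()]
#'   profile from the same matrix stage and genome.
#' @return an oe-stage [ContactMatrix-class].
#' @export
observedOverExpected <- function(M, expected = NULL) {
  .require_stage(M, c("raw", "balanced"), "observedOverExpected")
  if (is.null(expected)) expected <- expectedByDistance(M)
  if (!.same_genome(M@genome, expected$genome))
    .stop_genome_mismatch("matrix and expected profile")
  .map_chrom(M, function(m, mask, ch) {
    n <- nrow(m)
    e <- expected$E[[ch]]
    d <- abs(row(m) - col(m))
    ed <- matrix(NA_real_, n, n)
    nz <- d > 0
    ed[nz] <- e[d[nz]]
    ed[!is.na(ed) & ed == 0] <- NA_real_
    m / ed
  }, stage = "oe")
}

#' Pearson correlation map of an O/E matrix
#'
#' `C(i,j)` is the Pearson correlation between columns `i` and `j` of
#' the O/E matrix restricted to unmasked rows (pairwise-complete cells,
#' so the undefined diagonal of O/E never contributes).  The diagonal is
#' set to 1 and the result is exactly symmetric with values in
#' \[-1, 1\].  Constant columns (zero variance) would give undefined
#' correlations; these are set to 0 with a warning.
#'
#' @param OE an oe-stage [ContactMatrix-class].
#' @return a pearson-stage [ContactMatrix-class].
#' @export
pearsonMap <- function(OE) {
  .require_stage(OE, "oe", "pearsonMap")
  .map_chrom(OE, function(m, mask, ch) {
    ok <- !mask
    if (sum(ok) < 3L)
      stop("fewer than 3 unmasked bins on ", ch,
           "; Pearson map undefined")
    sub <- m[ok, ok, drop = FALSE]
    C <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
    if (anyNA(C)) {
      warning("zero-variance columns on ", ch,
              "; their correlations set to 0")
      C[is.na(C)] <- 0
    }
    C <- (C + t(C)) / 2
    diag(C) <- 1
    C[C > 1] <- 1
    C[C < -1] <- -1
    full <- matrix(NA_real_, nrow(m), ncol(m))
    full[ok, ok] <- C
    full
  }, stage = "pearson")
}
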