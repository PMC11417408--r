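#' Insulation-score profile
#'
#' For each bin `i`, the raw insulation is the mean of the balanced
#' matrix over the diamond `{rows i-w .. i-1} x {cols i+1 .. i+w}`
#' using unmasked cells only; masked cells reduce the averaging count,
#' they never contribute zeros.  The reported score is
#' `log2(raw) - mean(log2(raw))` per chromosome (log2 of the ratio to
#' the chromosomal geometric mean), so the score of valid bins averages
#' to zero exactly.  Bins within `w` of a chromosome end, masked bins
#' and bins with an empty or non-positive diamond are invalid.
#'
#' @param M a balanced-stage [ContactMatrix-class].
#' @param w diamond half-width in bins (default 10, i.e. 500 kb at
#'   50 kb resolution).
#' @return an `InsulationProfile`: list with per-bin `score`, `valid`
#'   flags, `window` and the genome.
#' @export
insulationProfile <- function(M, w = 10) {
  .require_stage(M, "balanced", "insulationProfile")
  genome <- M@genome
  score <- rep(NA_real_, nbins(genome))
  valid <- rep(FALSE, nbins(genome))
  for (ch in chromNames(genome)) {
    idx <- binIndex(genome, ch)
    m <- M@matrices[[ch]]
    n <- nrow(m)
    if (w >= n / 2)
      stop("window w = ", w, " too large for ", ch, " (", n, " bins)")
    raw <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i - w < 1L || i + w > n || M@mask[[ch]][i]) next
      block <- m[(i - w):(i - 1L), (i + 1L):(i + w), drop = FALSE]
      vals <- block[!is.na(block)]
      if (length(vals)) raw[i] <- mean(vals)
    }
    ok <- !is.na(raw) & raw > 0
    lg <- rep(NA_real_, n)
    lg[ok] <- log2(raw[ok])
    lg[ok] <- lg[ok] - mean(lg[ok])
    score[idx] <- lg
    valid[idx] <- ok
  }
  structure(list(genome = genome, window = w, score = score,
                 valid = valid),
            class = "InsulationProfile")
}

# local minima (plateaus resolved leftward) among valid positions
.local_minima <- function(s, valid) {
  n <- length(s)
  out <- integer(0)
  for (i in which(valid)) {
    left <- if (i > 1 && valid[i - 1]) s[i - 1] else Inf
    right <- if (i < n && valid[i + 1]) s[i + 1] else Inf
    if (s[i] < left && s[i] <= right) out <- c(out, i)
  }
  out
}

#' Call insulation boundaries
#'
#' Boundaries are local minima of the insulation score whose prominence
#' - the smaller of the rises to the highest valid score within `w`
#' bins on either side - is at least `delta`.  Plateau ties resolve to
#' the leftmost bin.  Domains are derived as the intervals between
#' consecutive boundaries.
#'
#' @param prof an [insulationProfile()].
#' @param delta prominence threshold in log2 units (default 0.2).
#' @return a `DomainSet`: list with `boundaries` (chrom, bin,
#'   prominence), `domains` (chrom, start, end; 1-based closed bin
#'   intervals between boundaries) and `provenance = "called"`.
#' @export
callBoundaries <- function(prof, delta = 0.2) {
  stopifnot(inherits(prof, "InsulationProfile"))
  genome <- prof$genome
  w <- prof$window
  bnd <- list()
  dom <- list()
  for (ch in chromNames(genome)) {
    idx <- binIndex(genome, ch)
    s <- prof$score[idx]
    valid <- prof$valid[idx]
    keep <- integer(0)
    prom_kept <- numeric(0)
    for (i in .local_minima(s, valid)) {
      lwin <- max(1L, i - w):(i - 1L)
      rwin <- (i + 1L):min(length(s), i + w)
      lmax <- suppressWarnings(max(s[lwin][valid[lwin]], na.rm = TRUE))
      rmax <- suppressWarnings(max(s[rwin][valid[rwin]], na.rm = TRUE))
      prom <- min(lmax, rmax) - s[i]
      if (is.finite(prom) && prom >= delta) {
        keep <- c(keep, i)
        prom_kept <- c(prom_kept, prom)
      }
    }
    if (length(keep)) {
      bnd[[ch]] <- data.frame(chrom = ch, bin = keep,
                              prominence = prom_kept,
                              stringsAsFactors = FALSE)
      if (length(keep) > 1L)
        dom[[ch]] <- data.frame(chrom = ch,
                                start = utils::head(keep, -1),
                                end = keep[-1],
                                stringsAsFactors = FALSE)
    }
  }
  empty_b <- data.frame(chrom = character(0), bin = integer(0),
                        prominence = numeric(0))
  empty_d <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
  structure(list(
    boundaries = if (length(bnd)) do.call(rbind, unname(bnd)) else empty_b,
    domains = if (length(dom)) do.call(rbind, unname(dom)) else empty_d,
    provenance = "called"),
    class = "DomainSet")
}

# K x n fractional-overlap weight matrix for area-weighted rescaling
.rescale_weights <- function(n, K) {
  breaks <- seq(0, n, length.out = K + 1)
  W <- matrix(0, K, n)
  for (k in seq_len(K)) {
    lo <- breaks[k]; hi <- breaks[k + 1]
    b <- seq_len(n)
    W[k, ] <- pmax(0, pmin(hi, b) - pmax(lo, b - 1))
  }
  W
}

# area-weighted K x K block average of a square matrix, NA-aware
.rescale_matrix <- function(m, K) {
  W <- .rescale_weights(nrow(m), K)
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0
  num <- W %*% m0 %*% t(W)
  den <- W %*% obs %*% t(W)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Aggregate TAD analysis (ATA)
#'
#' Each domain, extended by flanks of half its length on both sides, is
#' cut from the O/E map and rescaled to a `K x K` matrix by
#' area-weighted block averaging; the rescaled submatrices are then
#' averaged element-wise over domains.  Domains whose flanked window
#' leaves the chromosome are skipped and counted.
#'
#' @param OE an oe-stage [ContactMatrix-class].
#' @param domains data.frame (chrom, start, end) of 1-based closed bin
#'   intervals (planted truth domains or [callBoundaries()] output).
#' @param K output size (default 30).
#' @return an `AggregateMap`: list with the `K x K` `map`, `n_regions`
#'   used, `n_skipped` and `value = "oe"`.
#' @export
aggregateTads <- function(OE, domains, K = 30) {
  .require_stage(OE, "oe", "aggregateTads")
  acc <- array(0, c(K, K))
  cnt <- array(0, c(K, K))
  used <- 0L; skipped <- 0L
  for (r in seq_len(nrow(domains))) {
    ch <- domains$chrom[r]
    m <- OE@matrices[[ch]]
    len <- domains$end[r] - domains$start[r] + 1L
    flank <- floor(len / 2)
    lo <- domains$start[r] - flank
    hi <- domains$end[r] + flank
    if (lo < 1L || hi > nrow(m)) { skipped <- skipped + 1L; next }
    sub <- .rescale_matrix(m[lo:hi, lo:hi, drop = FALSE], K)
    obs <- !is.na(sub)
    acc[obs] <- acc[obs] + sub[obs]
    cnt <- cnt + obs
    used <- used + 1L
  }
  if (used == 0L) stop("no usable domains for aggregation")
  map <- acc / cnt
  map[cnt == 0] <- NA_real_
  structure(list(map = map, n_regions = used, n_skipped = skipped,
                 K = K, value = "oe"),
            class = "AggregateMap")
}

#' Differential aggregate map
#'
#' Element-wise difference `mutant - wild type` of two aggregate maps of
#' equal size; negative central values indicate a loss of intra-domain
#' contacts in the mutant.
#'
#' @param A_wt,A_mut `AggregateMap`s of the same `K`.
#' @return an `AggregateMap` with `value = "diff"`.
#' @export
diffAggregate <- function(A_wt, A_mut) {
  stopifnot(inherits(A_wt, "AggregateMap"), inherits(A_mut, "AggregateMap"))
  if (A_wt$K != A_mut$K) stop("aggregate maps have different sizes")
  structure(list(map = A_mut$map - A_wt$map,
                 n_regions = c(wt = A_wt$n_regions, mut = A_mut$n_regions),
                 K = A_wt$K, value = "diff"),
            class = "AggregateMap")
}

#' Insulation signal around boundaries
#'
#' Stacks insulation-score windows of `flankBins` bins on either side
#' of each boundary (rows sorted by ascending center value) and returns
#' the column-mean profile.  Boundaries whose window leaves the
#' chromosome are dropped and counted.
#'
#' @param prof an [insulationProfile()].
#' @param boundaries data.frame (chrom, bin) of boundary bins.
#' @param flankBins half-width of the window (default 10).
#' @return list with the per-boundary `matrix` (one row per kept
#'   boundary), the `mean_profile` and `n_dropped`.
#' @export
boundarySignalMatrix <- function(prof, boundaries, flankBins = 10) {
  stopifnot(inherits(prof, "InsulationProfile"))
  genome <- prof$genome
  rows <- list(); centers <- numeric(0); dropped <- 0L
  for (r in seq_len(nrow(boundaries))) {
    ch <- boundaries$chrom[r]
    idx <- binIndex(genome, ch)
    b <- boundaries$bin[r]
    if (b - flankBins < 1L || b + flankBins > length(idx)) {
      dropped <- dropped + 1L
      next
    }
    s <- prof$score[idx][(b - flankBins):(b + flankBins)]
    rows[[length(rows) + 1L]] <- s
    centers <- c(centers, s[flankBins + 1L])
  }
  if (!length(rows)) stop("no boundary fits within its chromosome")
  mat <- do.call(rbind, rows)[order(centers), , drop = FALSE]
  colnames(mat) <- as.character(seq(-flankBins, flankBins))
  list(matrix = mat, mean_profile = colMeans(mat, na.rm = TRUE),
       n_dropped = dropped)
}
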