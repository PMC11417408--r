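#' Call A/B compartments from a Pearson map
#'
#' Computes, per chromosome, the leading eigenvector (PC1) of the
#' column-mean-centered Pearson correlation map over unmasked bins.
#' The eigenvector is unit length and its sign is flipped, per
#' chromosome, so that it correlates positively with the supplied
#' orientation track (gene density or an active mark such as H3K9ac):
#' positive PC1 then marks the active A compartment, non-positive PC1
#' the inactive B compartment.  The ratio of the two leading eigenvalue
#' magnitudes is reported as the eigen gap; a degenerate map (no
#' leading structure) is refused.
#'
#' @param C a pearson-stage [ContactMatrix-class].
#' @param orientation a [SignalTrack-class] on the same bins.
#' @return a [CompartmentCall-class].
#' @export
callCompartments <- function(C, orientation) {
  .require_stage(C, "pearson", "callCompartments")
  if (!.same_genome(C@genome, orientation@genome))
    .stop_genome_mismatch("Pearson map and orientation track")
  genome <- C@genome
  pc1 <- rep(NA_real_, nbins(genome))
  gap <- numeric(0)
  for (ch in chromNames(genome)) {
    idx <- binIndex(genome, ch)
    ok <- !C@mask[[ch]]
    sub <- C@matrices[[ch]][ok, ok, drop = FALSE]
    cen <- sweep(sub, 2, colMeans(sub))
    sym <- (cen + t(cen)) / 2
    ev <- eigen(sym, symmetric = TRUE)
    lam <- ev$values
    if (!is.finite(lam[1]) || abs(lam[1]) < 1e-10 * nrow(sub))
      stop("degenerate Pearson map on ", ch,
           " (no leading eigenvalue); cannot call compartments")
    v <- ev$vectors[, 1]
    ori <- trackValues(orientation)[idx][ok]
    r <- suppressWarnings(cor(v, ori))
    if (is.na(r) || r == 0)
      stop("orientation track is uninformative on ", ch,
           "; supply a track with a nonzero PC1 correlation ",
           "or flip the sign explicitly")
    if (r < 0) v <- -v
    pc1[idx[ok]] <- v
    gap[[ch]] <- abs(lam[1]) / max(abs(lam[2]), .Machine$double.eps)
  }
  label <- ifelse(is.na(pc1), "masked", ifelse(pc1 > 0, "A", "B"))
  new("CompartmentCall", genome = genome, pc1 = pc1, label = label,
      orientationTrack = trackName(orientation), eigenGap = gap)
}

# equal-size ascending groups of a numeric vector (ties by position)
.quantile_groups <- function(v, Q) {
  n <- length(v)
  g <- integer(n)
  g[order(v, seq_len(n))] <- floor((seq_len(n) - 1L) * Q / n) + 1L
  g
}

# accumulate OE cell sums/counts by group pair over cis pairs at
# separation >= dMin
.saddle_accumulate <- function(OE, groups, Q, dMin) {
  sums <- matrix(0, Q, Q)
  cnts <- matrix(0, Q, Q)
  for (ch in chromNames(OE@genome)) {
    idx <- binIndex(OE@genome, ch)
    g <- groups[idx]
    m <- OE@matrices[[ch]]
    n <- nrow(m)
    d <- abs(row(m) - col(m))
    sel <- which(d >= dMin & !is.na(m) & !is.na(g[row(m)]) &
                   !is.na(g[col(m)]))
    if (!length(sel)) next
    gi <- g[row(m)[sel]]
    gj <- g[col(m)[sel]]
    key <- (gi - 1L) * Q + gj
    s <- vapply(split(m[sel], factor(key, levels = seq_len(Q * Q))),
                sum, numeric(1))
    s[is.na(s)] <- 0
    sums <- sums + matrix(s, Q, Q, byrow = TRUE)
    cnts <- cnts + matrix(tabulate(key, Q * Q), Q, Q, byrow = TRUE)
  }
  list(sums = sums, counts = cnts)
}

#' Saddle plot and compartment strength
#'
#' Ranks unmasked bins by ascending PC1, cuts them into `Q` equal-size
#' groups and averages the O/E matrix over cis bin pairs of each group
#' pair at separations of at least `dMin` bins.  Compartment strength is
#' `(mean BB corner + mean AA corner) / (2 * mean AB corner)`, the
#' corners being the extreme `cornerFrac * Q` quantile blocks, so values
#' above 1 indicate preferential within-compartment contact.
#'
#' @param OE an oe-stage [ContactMatrix-class].
#' @param call a [CompartmentCall-class] on the same bins.
#' @param Q number of PC1 quantile groups (default 5).
#' @param cornerFrac fraction of groups forming each corner (default
#'   0.2).
#' @param dMin minimum pair separation in bins (default 2).
#' @return a `SaddleResult`: list with the `Q x Q` `saddle` matrix, the
#'   per-cell pair `counts`, and `strength`.
#' @export
saddleStrength <- function(OE, call, Q = 5, cornerFrac = 0.2, dMin = 2) {
  .require_stage(OE, "oe", "saddleStrength")
  if (!.same_genome(OE@genome, call@genome))
    .stop_genome_mismatch("O/E matrix and compartment call")
  pc1 <- call@pc1
  okv <- which(!is.na(pc1))
  if (length(okv) < Q)
    stop("fewer unmasked bins (", length(okv), ") than Q = ", Q)
  groups <- rep(NA_integer_, length(pc1))
  groups[okv] <- .quantile_groups(pc1[okv], Q)
  acc <- .saddle_accumulate(OE, groups, Q, dMin)
  saddle <- acc$sums / acc$counts
  k <- max(1L, round(cornerFrac * Q))
  lo <- seq_len(k); hi <- seq(Q - k + 1L, Q)
  m_bb <- mean(saddle[lo, lo], na.rm = TRUE)
  m_aa <- mean(saddle[hi, hi], na.rm = TRUE)
  m_ab <- mean(c(saddle[lo, hi], saddle[hi, lo]), na.rm = TRUE)
  structure(list(saddle = saddle, counts = acc$counts,
                 strength = (m_bb + m_aa) / (2 * m_ab),
                 Q = Q, corner_frac = cornerFrac, d_min = dMin),
            class = "SaddleResult")
}

# maximal same-label runs of unmasked bins, per chromosome
.label_intervals <- function(call) {
  out <- list()
  genome <- call@genome
  for (ch in chromNames(genome)) {
    idx <- binIndex(genome, ch)
    lab <- call@label[idx]
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values %in% c("A", "B")
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], label = r$values[keep],
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0)))
  do.call(rbind, unname(out))
}

#' Compartment-pair (pentad-style) O/E averages
#'
#' Segments the compartment call into maximal same-label intervals and
#' averages the O/E matrix over the rectangular blocks of every interval
#' pair (including each interval with itself), pooling cells into the
#' AA, BB and AB categories by label pair.  Cells closer than `dMin`
#' bins are excluded everywhere.  A category with no eligible area is
#' reported as absent (`NA` mean, zero count), not as zero.
#'
#' @param OE an oe-stage [ContactMatrix-class].
#' @param call a [CompartmentCall-class] on the same bins.
#' @param dMin minimum pair separation in bins (default 2).
#' @return a `PentadResult`: list with `means` and cell `counts` for
#'   AA/BB/AB and the interval table.
#' @export
compartmentPentad <- function(OE, call, dMin = 2) {
  .require_stage(OE, "oe", "compartmentPentad")
  if (!.same_genome(OE@genome, call@genome))
    .stop_genome_mismatch("O/E matrix and compartment call")
  iv <- .label_intervals(call)
  sums <- c(AA = 0, BB = 0, AB = 0)
  cnts <- c(AA = 0, BB = 0, AB = 0)
  for (ch in unique(iv$chrom)) {
    m <- OE@matrices[[ch]]
    d <- abs(row(m) - col(m))
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    for (p in seq_len(nrow(ivc))) for (q in p:nrow(ivc)) {
      rows <- ivc$start[p]:ivc$end[p]
      cols <- ivc$start[q]:ivc$end[q]
      block <- m[rows, cols, drop = FALSE]
      dist <- d[rows, cols, drop = FALSE]
      vals <- block[dist >= dMin & !is.na(block)]
      if (!length(vals)) next
      cat_ <- if (ivc$label[p] == ivc$label[q]) {
        if (ivc$label[p] == "A") "AA" else "BB"
      } else "AB"
      w <- if (p == q) 1 else 2  # off-diagonal blocks appear twice
      sums[cat_] <- sums[cat_] + w * sum(vals)
      cnts[cat_] <- cnts[cat_] + w * length(vals)
    }
  }
  means <- ifelse(cnts > 0, sums / cnts, NA_real_)
  structure(list(means = means, counts = cnts, intervals = iv,
                 d_min = dMin),
            class = "PentadResult")
}

#' Feature-sorted correlation map and segregation score
#'
#' Reorders each chromosome's Pearson map by ascending value of a
#' signal track (ties broken by bin id) and scores how strongly the map
#' segregates along that feature: the mean correlation over cis pairs
#' in the same track-quantile group minus the mean over pairs whose
#' groups differ by at least `nGroups / 2`.  Groups are assigned
#' genome-wide on the ascending track ranking.
#'
#' @param C a pearson-stage [ContactMatrix-class].
#' @param track a [SignalTrack-class] on the same bins.
#' @param nGroups number of quantile groups (default 10).
#' @return list with per-chromosome reordered `maps`, the bin `order`
#'   and `groups`, and the segregation `score`.
#' @export
featureSortedMap <- function(C, track, nGroups = 10) {
  .require_stage(C, "pearson", "featureSortedMap")
  if (!.same_genome(C@genome, track@genome))
    .stop_genome_mismatch("Pearson map and feature track")
  v <- trackValues(track)
  if (length(unique(v)) == 1L)
    warning("constant feature track; ordering falls back to bin id")
  genome <- C@genome
  masked <- rep(TRUE, nbins(genome))
  for (ch in chromNames(genome))
    masked[binIndex(genome, ch)] <- C@mask[[ch]]
  okv <- which(!masked)
  groups <- rep(NA_integer_, length(v))
  groups[okv] <- .quantile_groups(v[okv], nGroups)
  maps <- list()
  ord <- list()
  same_sum <- 0; same_n <- 0; far_sum <- 0; far_n <- 0
  half <- nGroups / 2
  for (ch in chromNames(genome)) {
    idx <- binIndex(genome, ch)
    o <- order(v[idx], seq_along(idx))
    ord[[ch]] <- o
    maps[[ch]] <- C@matrices[[ch]][o, o]
    g <- groups[idx]
    m <- C@matrices[[ch]]
    dg <- abs(outer(g, g, `-`))
    offdiag <- row(m) != col(m)
    same <- which(offdiag & dg == 0 & !is.na(m))
    far <- which(offdiag & dg >= half & !is.na(m))
    same_sum <- same_sum + sum(m[same]); same_n <- same_n + length(same)
    far_sum <- far_sum + sum(m[far]); far_n <- far_n + length(far)
  }
  list(maps = maps, order = ord, groups = groups,
       score = same_sum / same_n - far_sum / far_n)
}
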