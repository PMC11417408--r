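#' Build an anchor set from bp intervals
#'
#' Maps intervals (bp, 0-based half-open) to their center bins and
#' collapses duplicates.
#'
#' @param genome a [BinnedGenome-class].
#' @param intervals data.frame with `chrom`, `start`, `end` (bp).
#' @param label set label (e.g. `"K27me3_wt"`).
#' @return an `AnchorSet` data.frame (chrom, bin, label), `bin` being
#'   the 1-based bin index within its chromosome.
#' @export
anchorSet <- function(genome, intervals, label = "anchors") {
  nb <- chromNbins(genome)
  bad <- setdiff(unique(intervals$chrom), names(nb))
  if (length(bad))
    stop("anchor chromosome(s) not in genome: ", paste(bad, collapse = ", "))
  mid <- (intervals$start + intervals$end) / 2
  bin <- pmin(floor(mid / binSize(genome)) + 1L, nb[intervals$chrom])
  out <- unique(data.frame(chrom = intervals$chrom, bin = as.integer(bin),
                           label = label, stringsAsFactors = FALSE))
  out[order(out$chrom, out$bin), , drop = FALSE]
}

#' Aggregate O/E windows over anchor pairs (APA-style)
#'
#' Forms all same-chromosome pairs across two anchor sets whose bin
#' separation lies within `dRange` (self-pairs excluded), averages the
#' `(2W+1) x (2W+1)` O/E windows centered on each pair, and reports the
#' enrichment of the center cell over the mean of the four `3 x 3`
#' corner blocks.  Pairs whose window leaves the chromosome are skipped
#' and counted.
#'
#' @param OE an oe-stage [ContactMatrix-class].
#' @param set1,set2 `AnchorSet` data.frames from [anchorSet()] (or any
#'   data.frame with `chrom` and `bin`).
#' @param W window half-width in bins (default 5).
#' @param dRange pair separation range in bins (default `c(10, 100)`).
#' @return an `AggregateMap` with the window `map`, `n_regions` pairs
#'   used, `n_skipped` and `enrichment`.
#' @export
aggregateAnchorPairs <- function(OE, set1, set2, W = 5,
                                 dRange = c(10, 100)) {
  .require_stage(OE, "oe", "aggregateAnchorPairs")
  pairs <- list()
  for (ch in intersect(unique(set1$chrom), unique(set2$chrom))) {
    b1 <- set1$bin[set1$chrom == ch]
    b2 <- set2$bin[set2$chrom == ch]
    g <- expand.grid(i = b1, j = b2)
    g <- g[g$i != g$j, , drop = FALSE]
    lo <- pmin(g$i, g$j); hi <- pmax(g$i, g$j)
    d <- hi - lo
    keep <- d >= dRange[1] & d <= dRange[2]
    if (any(keep))
      pairs[[ch]] <- unique(data.frame(chrom = ch, bin1 = lo[keep],
                                       bin2 = hi[keep]))
  }
  if (!length(pairs)) stop("zero eligible anchor pairs")
  pairs <- do.call(rbind, unname(pairs))
  side <- 2L * W + 1L
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  used <- 0L; skipped <- 0L
  for (r in seq_len(nrow(pairs))) {
    m <- OE@matrices[[pairs$chrom[r]]]
    i <- pairs$bin1[r]; j <- pairs$bin2[r]
    if (i - W < 1L || j + W > nrow(m) || j - W < 1L || i + W > nrow(m)) {
      skipped <- skipped + 1L
      next
    }
    win <- m[(i - W):(i + W), (j - W):(j + W)]
    obs <- !is.na(win)
    acc[obs] <- acc[obs] + win[obs]
    cnt <- cnt + obs
    used <- used + 1L
  }
  if (used == 0L) stop("zero usable anchor pairs (all windows clipped)")
  map <- acc / cnt
  map[cnt == 0] <- NA_real_
  corner_idx <- list(1:3, (side - 2):side)
  corners <- c(map[corner_idx[[1]], corner_idx[[1]]],
               map[corner_idx[[1]], corner_idx[[2]]],
               map[corner_idx[[2]], corner_idx[[1]]],
               map[corner_idx[[2]], corner_idx[[2]]])
  structure(list(map = map, n_regions = used, n_skipped = skipped,
                 K = side, value = "oe",
                 enrichment = map[W + 1L, W + 1L] /
                   mean(corners, na.rm = TRUE)),
            class = "AggregateMap")
}

#' Distance-stratified Z-score differential interactions
#'
#' For every doubly-unmasked cis pair at separation up to `dMax` bins,
#' the log2 contact ratio `r = log2((OE_mut + eps) / (OE_wt + eps))` is
#' standardized within log-spaced separation strata:
#' `z = (r - mu_d) / sigma_d`.  Negative z marks WT-specific contacts,
#' positive z mutant-specific ones.  Strata with zero variance (or
#' fewer than 2 pairs) are dropped with a warning.  Results are sorted
#' by `|z|` descending.
#'
#' @param OE_wt,OE_mut oe-stage [ContactMatrix-class] objects on the
#'   same bin frame.
#' @param dMax maximum pair separation in bins (default 100).
#' @param bands number of log-spaced distance strata (default 8).
#' @param eps pseudocount guarding sparse O/E zeros (default 0.01).
#' @return data.frame (chrom, bin1, bin2, distance_bins, log2_ratio, z,
#'   direction) sorted by `|z|` descending.
#' @export
differentialInteractions <- function(OE_wt, OE_mut, dMax = 100,
                                     bands = 8, eps = 0.01) {
  .require_stage(OE_wt, "oe", "differentialInteractions")
  .require_stage(OE_mut, "oe", "differentialInteractions")
  if (!.same_genome(OE_wt@genome, OE_mut@genome))
    .stop_genome_mismatch("the two O/E matrices")
  rows <- list()
  for (ch in chromNames(OE_wt@genome)) {
    mw <- OE_wt@matrices[[ch]]
    mm <- OE_mut@matrices[[ch]]
    ut <- which(upper.tri(mw) & abs(row(mw) - col(mw)) <= dMax &
                  !is.na(mw) & !is.na(mm))
    if (!length(ut)) next
    rows[[ch]] <- data.frame(
      chrom = ch, bin1 = row(mw)[ut], bin2 = col(mw)[ut],
      distance_bins = col(mw)[ut] - row(mw)[ut],
      log2_ratio = log2((mm[ut] + eps) / (mw[ut] + eps)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no eligible pairs within dMax")
  df <- do.call(rbind, unname(rows))
  breaks <- unique(c(0, exp(seq(log(1), log(dMax),
                                length.out = bands + 1))[-1]))
  df$stratum <- cut(df$distance_bins, breaks = breaks,
                    include.lowest = FALSE)
  z <- rep(NA_real_, nrow(df))
  for (s in levels(df$stratum)) {
    sel <- which(!is.na(df$stratum) & df$stratum == s)
    if (length(sel) < 2L) next
    mu <- mean(df$log2_ratio[sel])
    sig <- sd(df$log2_ratio[sel])
    if (sig == 0) {
      if (mu == 0) {        # identical maps: every ratio is exactly 0
        z[sel] <- 0
      } else {
        warning("stratum ", s, " has zero variance; dropped")
      }
      next
    }
    z[sel] <- (df$log2_ratio[sel] - mu) / sig
  }
  df$z <- z
  df <- df[!is.na(df$z), , drop = FALSE]
  df$direction <- ifelse(df$z < 0, "wt_specific", "mut_specific")
  df$stratum <- as.character(df$stratum)
  df[order(-abs(df$z)), , drop = FALSE]
}
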