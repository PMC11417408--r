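#' Scale tracks to a common genome-wide mean
#'
#' Multiplies each track so its genome-wide mean is 1, making mark
#' levels comparable across samples before differential analysis.
#'
#' @param tracks a [SignalTrack-class] or list of them.
#' @return the scaled track(s), `normalization = "scaled"`.
#' @export
scaleTracks <- function(tracks) {
  one <- function(tr) {
    stopifnot(is(tr, "SignalTrack"))
    mu <- mean(trackValues(tr))
    if (!is.finite(mu) || mu == 0)
      stop("track '", trackName(tr), "' has zero mean; cannot scale")
    SignalTrack(tr@genome, trackName(tr), trackValues(tr) / mu,
                normalization = "scaled")
  }
  if (is(tracks, "SignalTrack")) one(tracks) else lapply(tracks, one)
}

# area-weighted mean of per-bin values over a bp interval
.region_mean <- function(genome, values, chrom, start, end) {
  nb <- chromNbins(genome)
  if (!chrom %in% names(nb))
    stop("region chromosome not in genome: ", chrom)
  if (start < 0 || end > chromLengths(genome)[[chrom]] || end <= start)
    stop("region outside genome: ", chrom, ":", start, "-", end)
  bs <- binSize(genome)
  b_lo <- floor(start / bs) + 1L
  b_hi <- min(ceiling(end / bs), nb[[chrom]])
  idx <- binIndex(genome, chrom)[b_lo:b_hi]
  b0 <- (seq(b_lo, b_hi) - 1) * bs
  w <- pmin(end, b0 + bs) - pmax(start, b0)
  sum(w * values[idx]) / sum(w)
}

#' Differential mark signal over regions
#'
#' For each region the mean scaled signal `s` is computed in both
#' samples (area-weighted over bins) and the log2 change
#' `delta = log2((s_mut + pseudo) / (s_wt + pseudo))` is thresholded
#' into `up` (`delta >= tUp`), `down` (`delta <= tDown`) or `nc`.  The
#' `low_flag` marks regions where both samples sit below the 25th
#' percentile of the pooled genome-wide bin values, i.e. regions where
#' the mark is essentially absent in both genotypes.
#'
#' @param wt,mut scaled [SignalTrack-class] objects of the same mark.
#' @param regions data.frame (chrom, start, end, optionally id) in bp,
#'   0-based half-open; `NULL` treats every bin as one region.
#' @param tUp,tDown log2 thresholds (defaults +0.5 / -0.5).
#' @param pseudo pseudocount (default 0.1).
#' @return a `MarkDelta` data.frame: region_id, mark, s_wt, s_mut,
#'   delta, status, low_flag.
#' @export
differentialSignal <- function(wt, mut, regions = NULL, tUp = 0.5,
                               tDown = -0.5, pseudo = 0.1) {
  stopifnot(is(wt, "SignalTrack"), is(mut, "SignalTrack"))
  if (!.same_genome(wt@genome, mut@genome))
    .stop_genome_mismatch("the two tracks")
  if (wt@normalization != "scaled" || mut@normalization != "scaled")
    warning("tracks are not scaled; run scaleTracks() first for ",
            "cross-sample comparability")
  genome <- wt@genome
  if (is.null(regions)) {
    bt <- binTable(genome)
    regions <- data.frame(chrom = bt$chrom, start = bt$start,
                          end = bt$end,
                          id = sprintf("bin%05d", bt$bin_id),
                          stringsAsFactors = FALSE)
  }
  if (is.null(regions$id))
    regions$id <- sprintf("region%05d", seq_len(nrow(regions)))
  vw <- trackValues(wt)
  vm <- trackValues(mut)
  s_wt <- mapply(.region_mean, regions$chrom, regions$start, regions$end,
                 MoreArgs = list(genome = genome, values = vw))
  s_mut <- mapply(.region_mean, regions$chrom, regions$start, regions$end,
                  MoreArgs = list(genome = genome, values = vm))
  delta <- log2((s_mut + pseudo) / (s_wt + pseudo))
  status <- ifelse(delta >= tUp, "up", ifelse(delta <= tDown, "down", "nc"))
  low_thr <- quantile(c(vw, vm), 0.25, names = FALSE)
  data.frame(region_id = regions$id, mark = trackName(wt),
             s_wt = s_wt, s_mut = s_mut, delta = delta, status = status,
             low_flag = pmax(s_wt, s_mut) < low_thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify H3K27me3 redistribution into three patterns
#'
#' Deterministic rules over the per-mark differential statuses of each
#' region, evaluated in order (the classes are disjoint by
#' construction):
#' \describe{
#'   \item{I}{H3K27me3 loss with a gain or no change of both H3K9me2
#'     and H3K27me1 (facultative heterochromatin lost, typically
#'     gene-associated).}
#'   \item{II}{H3K27me3 gain with losses of both H3K9me2 and H3K27me1
#'     (constitutive replaced by facultative heterochromatin).}
#'   \item{III}{H3K27me3 gain with reduced H3K27me1 and a stable but
#'     low H3K9me2 (status `nc` and `low_flag`).}
#' }
#' Everything else is `none`.  A gain of H3K27me3 therefore only occurs
#' on regions whose H3K9me2 is either decreasing or already low.
#'
#' @param dK27me3,dK9me2,dK27me1 `MarkDelta` data.frames from
#'   [differentialSignal()] for the three marks, same regions.
#' @return data.frame (region_id, class).
#' @export
classifyRedistribution <- function(dK27me3, dK9me2, dK27me1) {
  for (d in list(dK27me3, dK9me2, dK27me1))
    if (!all(c("region_id", "status", "low_flag") %in% names(d)))
      stop("missing mark delta table (need region_id, status, low_flag)")
  if (!identical(dK27me3$region_id, dK9me2$region_id) ||
      !identical(dK27me3$region_id, dK27me1$region_id))
    stop("mark delta tables cover different regions")
  k27 <- dK27me3$status
  k9 <- dK9me2$status
  k271 <- dK27me1$status
  cls <- rep("none", length(k27))
  cls[k27 == "down" & k9 %in% c("up", "nc") & k271 %in% c("up", "nc")] <- "I"
  is_ii <- k27 == "up" & k9 == "down" & k271 == "down"
  cls[cls == "none" & is_ii] <- "II"
  is_iii <- k27 == "up" & k9 == "nc" & dK9me2$low_flag & k271 == "down"
  cls[cls == "none" & is_iii] <- "III"
  data.frame(region_id = dK27me3$region_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Classify TEs as gene-rich or gene-poor by neighborhood gene density
#'
#' Gene density is the fraction of bp covered by (merged) genes in a
#' window of `windowBp` centered on each TE midpoint, clipped at
#' chromosome ends.  A TE is `gene_rich` iff its density is at least
#' the genome-wide median of per-TE densities (ties go to gene_rich),
#' else `gene_poor`.
#'
#' @param tes data.frame (chrom, start, end, id) in bp.
#' @param genes data.frame (chrom, start, end) in bp.
#' @param genome a [BinnedGenome-class] (for chromosome lengths).
#' @param windowBp window size (default 1e6).
#' @return data.frame (id, density, location).
#' @export
classifyTeLocation <- function(tes, genes, genome, windowBp = 1e6) {
  gr_genes <- GenomicRanges::reduce(GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end)))
  cl <- chromLengths(genome)
  mid <- (tes$start + tes$end) / 2
  lo <- pmax(0, mid - windowBp / 2)
  hi <- pmin(cl[tes$chrom], mid + windowBp / 2)
  win <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(lo + 1, hi))
  hits <- GenomicRanges::findOverlaps(win, gr_genes)
  pint <- GenomicRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                    gr_genes[S4Vectors::subjectHits(hits)])
  covered <- rep(0, length(win))
  if (length(hits)) {
    agg <- tapply(IRanges::width(pint), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- agg
  }
  density <- as.numeric(covered) / (hi - lo)
  med <- median(density)
  data.frame(id = tes$id, density = density,
             location = ifelse(density >= med, "gene_rich", "gene_poor"),
             stringsAsFactors = FALSE)
}

#' TE superfamily composition of a subset vs the genome
#'
#' Per-superfamily proportions in a TE subset and in the genome-wide TE
#' complement, with a two-proportion z statistic (pooled standard
#' error, no continuity correction) and two-sided p-value.
#' Superfamilies absent from both sets get `z = 0, p = 1`.
#'
#' @param te_subset,te_genome data.frames with a `superfamily` column.
#' @return data.frame (superfamily, n_subset, n_genome, p_subset,
#'   p_genome, z, p_value).
#' @export
superfamilyComposition <- function(te_subset, te_genome) {
  if (!nrow(te_subset)) stop("empty TE subset")
  if (nrow(te_subset) < 5)
    warning("TE subset has fewer than 5 elements; ",
            "proportion test is unreliable")
  fams <- sort(unique(c(te_subset$superfamily, te_genome$superfamily)))
  n1 <- nrow(te_subset); n2 <- nrow(te_genome)
  out <- lapply(fams, function(f) {
    x1 <- sum(te_subset$superfamily == f)
    x2 <- sum(te_genome$superfamily == f)
    p1 <- x1 / n1; p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    data.frame(superfamily = f, n_subset = x1, n_genome = x2,
               p_subset = p1, p_genome = p2, z = z,
               p_value = if (se == 0) 1 else 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Signal heatmap matrix over regions
#'
#' Rescales each region (plus optional flanks) to `K` columns by
#' area-weighted averaging of the per-bin track values and stacks the
#' rows, sorted by a key (default: descending row mean, i.e. ranked by
#' the mark's own signal).  Regions shorter than one bin are served by
#' their single bin.
#'
#' @param track a [SignalTrack-class].
#' @param regions data.frame (chrom, start, end, optionally id), bp.
#' @param flankBp flank added on both sides (default 0).
#' @param K number of columns (default 30).
#' @param sortBy `"mean_desc"` (default), `"mean_asc"` or a numeric key
#'   of one value per region.
#' @return list with the region-by-`K` `matrix` (rownames = region
#'   ids), `mean_profile` (column means) and the row `order` used.
#' @export
regionSignalMatrix <- function(track, regions, flankBp = 0, K = 30,
                               sortBy = "mean_desc") {
  stopifnot(is(track, "SignalTrack"))
  genome <- track@genome
  v <- trackValues(track)
  if (is.null(regions$id))
    regions$id <- sprintf("region%05d", seq_len(nrow(regions)))
  cl <- chromLengths(genome)
  mat <- matrix(NA_real_, nrow(regions), K)
  for (r in seq_len(nrow(regions))) {
    lo <- max(0, regions$start[r] - flankBp)
    hi <- min(cl[[regions$chrom[r]]], regions$end[r] + flankBp)
    edges <- seq(lo, hi, length.out = K + 1)
    mat[r, ] <- vapply(seq_len(K), function(k)
      .region_mean(genome, v, regions$chrom[r], edges[k], edges[k + 1]),
      numeric(1))
  }
  rownames(mat) <- regions$id
  key <- if (is.numeric(sortBy)) {
    stopifnot(length(sortBy) == nrow(regions))
    -sortBy
  } else switch(sortBy,
    mean_desc = -rowMeans(mat, na.rm = TRUE),
    mean_asc = rowMeans(mat, na.rm = TRUE),
    stop("unknown sortBy: ", sortBy))
  o <- order(key)
  list(matrix = mat[o, , drop = FALSE],
       mean_profile = colMeans(mat, na.rm = TRUE), order = o)
}

#' Cross-tabulate differential expression with chromatin status
#'
#' Joins a DE table (gene_id, status in up/down/nc) with per-gene mark
#' and methylation statuses and, within each DE status, counts each
#' status tuple; fractions sum to 1 per DE status.  Genes without a
#' chromatin entry are reported separately, not silently dropped.
#'
#' @param de data.frame with `gene_id` and `status`; duplicated gene
#'   ids are an error.
#' @param markStatus data.frame with `gene_id` plus one or more status
#'   columns (e.g. DNAme, H3K27me3, H3K9me2, H3K27me1).
#' @return list with `table` (de_status, the status columns, n,
#'   fraction) and `unjoined` (character vector of gene ids).
#' @export
integrateExpression <- function(de, markStatus) {
  if (anyDuplicated(de$gene_id))
    stop("duplicated gene ids in DE table")
  if (anyDuplicated(markStatus$gene_id))
    stop("duplicated gene ids in chromatin status table")
  joined <- merge(de, markStatus, by = "gene_id")
  unjoined <- setdiff(de$gene_id, markStatus$gene_id)
  cols <- setdiff(names(markStatus), "gene_id")
  tabs <- list()
  for (st in unique(joined$status)) {
    sub <- joined[joined$status == st, , drop = FALSE]
    key <- do.call(paste, c(sub[cols], sep = "\r"))
    tb <- table(key)
    parts <- do.call(rbind, strsplit(names(tb), "\r", fixed = TRUE))
    tab <- data.frame(de_status = st, parts, n = as.integer(tb),
                      fraction = as.integer(tb) / nrow(sub),
                      stringsAsFactors = FALSE)
    names(tab)[seq_along(cols) + 1L] <- cols
    tabs[[st]] <- tab
  }
  list(table = do.call(rbind, unname(tabs)), unjoined = unjoined)
}
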