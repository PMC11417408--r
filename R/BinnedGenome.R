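#' Construct a BinnedGenome
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param binSize bin width in bp (default 50000, i.e. 50 kb).
#' @return a [BinnedGenome-class] object.
#' @examples
#' bg <- BinnedGenome(c(chr1 = 1e7, chr2 = 1e7), binSize = 50000)
#' nbins(bg)
#' @export
BinnedGenome <- function(chromLengths, binSize = 50000) {
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  new("BinnedGenome", chromLengths = chromLengths, binSize = binSize)
}

#' @rdname BinnedGenome
#' @export
setMethod("chromNames", "BinnedGenome", function(x) names(x@chromLengths))

#' @rdname BinnedGenome
#' @export
setMethod("chromLengths", "BinnedGenome", function(x) x@chromLengths)

#' @rdname BinnedGenome
#' @export
setMethod("binSize", "BinnedGenome", function(x) x@binSize)

#' @rdname BinnedGenome
#' @export
setMethod("chromNbins", "BinnedGenome", function(x)
  setNames(as.integer(ceiling(x@chromLengths / x@binSize)),
           names(x@chromLengths)))

#' @rdname BinnedGenome
#' @export
setMethod("nbins", "BinnedGenome", function(x) sum(chromNbins(x)))

#' Bin table in cooler layout
#'
#' One row per bin: chromosome, 0-based half-open start/end (the last
#' bin is clipped to the chromosome length) and the global 0-based
#' `bin_id`.
#'
#' @rdname BinnedGenome
#' @export
setMethod("binTable", "BinnedGenome", function(x) {
  nb <- chromNbins(x)
  chrom <- rep(names(nb), nb)
  local_i <- unlist(lapply(nb, seq_len), use.names = FALSE) - 1L
  start <- local_i * x@binSize
  end <- pmin(start + x@binSize, rep(x@chromLengths, nb))
  data.frame(chrom = chrom, start = start, end = end,
             bin_id = seq_along(chrom) - 1L, stringsAsFactors = FALSE)
})

#' Global 1-based bin indices of one chromosome
#'
#' @rdname BinnedGenome
#' @export
setMethod("binIndex", "BinnedGenome", function(x, chrom) {
  nb <- chromNbins(x)
  if (!chrom %in% names(nb)) stop("unknown chromosome: ", chrom)
  off <- cumsum(c(0L, nb))[match(chrom, names(nb))]
  off + seq_len(nb[[chrom]])
})

#' Bins as a GRanges (for rtracklayer export)
#' @param x a BinnedGenome
#' @return a [GenomicRanges::GRanges] with one range per bin.
#' @export
binGRanges <- function(x) {
  bt <- binTable(x)
  gr <- GenomicRanges::GRanges(bt$chrom,
                               IRanges::IRanges(bt$start + 1L, bt$end))
  GenomeInfoDb::seqlengths(gr) <-
    chromLengths(x)[GenomeInfoDb::seqlevels(gr)]
  gr
}

setMethod("show", "BinnedGenome", function(object) {
  cat("BinnedGenome:", length(object@chromLengths), "chromosome(s),",
      "bin size", format(object@binSize, big.mark = ","), "bp,",
      nbins(object), "bins\n")
  for (ch in chromNames(object))
    cat(sprintf("  %s: %s bp (%d bins)\n", ch,
                format(object@chromLengths[[ch]], big.mark = ","),
                chromNbins(object)[[ch]]))
})

#' Check two objects share a bin frame
#' @keywords internal
#' @noRd
.same_genome <- function(a, b) {
  identical(chromLengths(a), chromLengths(b)) &&
    identical(binSize(a), binSize(b))
}

.stop_genome_mismatch <- function(what) {
  stop(what, " are defined on different bin frames (BinnedGenome mismatch)")
}
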