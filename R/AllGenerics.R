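#' @rdname BinnedGenome
#' @param object,x an object of the documented class.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname BinnedGenome
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname BinnedGenome
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinnedGenome
#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))

#' @rdname BinnedGenome
#' @export
setGeneric("chromNbins", function(x) standardGeneric("chromNbins"))

#' @rdname BinnedGenome
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' @rdname BinnedGenome
#' @param chrom chromosome name.
#' @export
setGeneric("binIndex", function(x, chrom) standardGeneric("binIndex"))

#' @rdname ContactMatrix
#' @export
setGeneric("matrixStage", function(x) standardGeneric("matrixStage"))

#' @rdname ContactMatrix
#' @export
setGeneric("contactMatrix", function(x, chrom) standardGeneric("contactMatrix"))

#' @rdname ContactMatrix
#' @export
setGeneric("binMask", function(x, chrom) standardGeneric("binMask"))

#' @rdname ContactMatrix
#' @export
setGeneric("balancingWeights", function(x, chrom)
  standardGeneric("balancingWeights"))

#' @rdname SignalTrack
#' @export
setGeneric("trackName", function(x) standardGeneric("trackName"))

#' @rdname SignalTrack
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
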