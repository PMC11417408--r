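#' Construct a ContactMatrix
#'
#' Wraps per-chromosome symmetric matrices on a shared bin frame.
#' Intended mainly for internal use and tests; analysis entry points are
#' [binPairs()], [readContactMatrix()] and [simulateContacts()].
#'
#' @param genome a [BinnedGenome-class].
#' @param matrices named list of square per-chromosome matrices (one per
#'   chromosome, genome order).  A single matrix is accepted for a
#'   single-chromosome genome.
#' @param stage processing stage, one of `raw`, `balanced`, `oe`,
#'   `pearson`.
#' @param mask optional named list of per-bin logical masks (`TRUE` =
#'   masked); defaults to all-unmasked.
#' @param weights optional named list of balancing weights.
#' @param trans total inter-chromosomal pair count (tally only).
#' @return a [ContactMatrix-class].
#' @export
ContactMatrix <- function(genome, matrices, stage = "raw", mask = NULL,
                          weights = list(), trans = 0) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  cn <- chromNames(genome)
  if (is.null(names(matrices)) && length(matrices) == length(cn))
    names(matrices) <- cn
  matrices <- matrices[cn]
  if (is.null(mask)) {
    mask <- lapply(chromNbins(genome), function(n) rep(FALSE, n))
  }
  mask <- mask[cn]
  new("ContactMatrix", genome = genome, matrices = matrices, mask = mask,
      stage = stage, weights = weights, trans = trans)
}

#' @rdname ContactMatrix
#' @param x a ContactMatrix.
#' @export
setMethod("matrixStage", "ContactMatrix", function(x) x@stage)

#' @rdname ContactMatrix
#' @param chrom chromosome name.
#' @export
setMethod("contactMatrix", "ContactMatrix", function(x, chrom) {
  if (!chrom %in% names(x@matrices)) stop("unknown chromosome: ", chrom)
  x@matrices[[chrom]]
})

#' @rdname ContactMatrix
#' @export
setMethod("binMask", "ContactMatrix", function(x, chrom) {
  if (!chrom %in% names(x@mask)) stop("unknown chromosome: ", chrom)
  x@mask[[chrom]]
})

#' @rdname ContactMatrix
#' @export
setMethod("balancingWeights", "ContactMatrix", function(x, chrom) {
  if (!length(x@weights)) stop("matrix has no balancing weights (stage: ",
                               x@stage, ")")
  x@weights[[chrom]]
})

#' @rdname BinnedGenome
#' @export
setMethod("chromNames", "ContactMatrix", function(x) chromNames(x@genome))

#' Genome accessor
#' @param x a ContactMatrix, SignalTrack, TruthSet or CompartmentCall.
#' @return the underlying [BinnedGenome-class].
#' @export
genomeOf <- function(x) {
  stopifnot(.hasSlot(x, "genome"))
  x@genome
}

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix [stage:", object@stage, "]\n")
  show(object@genome)
  nm <- sum(vapply(object@mask, sum, integer(1)))
  cat("  masked bins:", nm, "| trans pair tally:", object@trans, "\n")
})

# enforce the forward-only stage contract
.require_stage <- function(M, allowed, op) {
  if (!(M@stage %in% allowed))
    stop(sprintf("%s requires stage %s, got '%s'", op,
                 paste(sQuote(allowed), collapse = " or "), M@stage))
  invisible(TRUE)
}

# apply a per-chromosome transform, NA-ing masked rows/cols
.map_chrom <- function(M, f, stage, weights = NULL) {
  mats <- M@matrices
  for (ch in names(mats)) {
    m <- f(mats[[ch]], M@mask[[ch]], ch)
    m[M@mask[[ch]], ] <- NA_real_
    m[, M@mask[[ch]]] <- NA_real_
    mats[[ch]] <- m
  }
  new("ContactMatrix", genome = M@genome, matrices = mats, mask = M@mask,
      stage = stage,
      weights = if (is.null(weights)) M@weights else weights,
      trans = M@trans)
}
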