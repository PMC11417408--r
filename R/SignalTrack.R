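#' Construct a SignalTrack
#'
#' @param genome a [BinnedGenome-class].
#' @param name track name (mark or methylation context).
#' @param values numeric, one non-negative value per bin.
#' @param normalization `"raw"` (default) or `"scaled"`.
#' @return a [SignalTrack-class].
#' @export
SignalTrack <- function(genome, name, values, normalization = "raw") {
  new("SignalTrack", genome = genome, name = name,
      values = as.numeric(values), normalization = normalization)
}

#' @rdname SignalTrack
#' @param x a SignalTrack.
#' @export
setMethod("trackName", "SignalTrack", function(x) x@name)

#' @rdname SignalTrack
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

setMethod("show", "SignalTrack", function(object) {
  v <- object@values
  cat(sprintf("SignalTrack '%s' (%s): %d bins, mean %.4g, range [%.4g, %.4g]\n",
              object@name, object@normalization, length(v),
              mean(v, na.rm = TRUE), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nbins(object@genome), "bins\n")
  cat("  WT states: ",
      paste(names(table(object@stateWt)), table(object@stateWt),
            sep = "=", collapse = ", "), "\n", sep = "")
  if (length(object@stateMut))
    cat("  mutant states: ",
        paste(names(table(object@stateMut)), table(object@stateMut),
              sep = "=", collapse = ", "), "\n", sep = "")
  cat("  planted domains:", nrow(object@domains),
      "| anchor pairs:", nrow(object@anchors), "\n")
  cl <- table(factor(object@classLabel, c("I", "II", "III", "none")))
  cat("  class labels: ", paste(names(cl), cl, sep = "=", collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "CompartmentCall", function(object) {
  tb <- table(factor(object@label, c("A", "B", "masked")))
  cat("CompartmentCall (oriented by '", object@orientationTrack, "'): ",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  eigen gap per chromosome: ",
      paste(names(object@eigenGap), sprintf("%.2f", object@eigenGap),
            sep = "=", collapse = ", "), "\n", sep = "")
})

#' Per-bin accessors for compartment calls
#' @param x a [CompartmentCall-class].
#' @return `pc1Values`: numeric per bin; `compartmentLabels`: character
#'   per bin (`A`, `B` or `masked`).
#' @export
pc1Values <- function(x) x@pc1

#' @rdname pc1Values
#' @export
compartmentLabels <- function(x) x@label
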