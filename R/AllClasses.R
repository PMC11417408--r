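#' @import methods
#' @importFrom stats cor sd quantile median rpois rlnorm rnorm runif rbeta setNames prcomp
#' @importFrom utils read.table write.table head tail
NULL

#' BinnedGenome: a fixed-bin coordinate frame
#'
#' Chromosome names and lengths together with a bin size define the
#' coordinate frame shared by contact matrices, signal tracks and every
#' downstream result.  Bins tile each chromosome without gaps or overlaps
#' in 0-based half-open coordinates; the last bin of a chromosome may be
#' shorter than `binSize`.  Global bin ids are consecutive, chromosome by
#' chromosome, in the order of `chromLengths`.
#'
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot binSize numeric scalar, bin width in bp.
#' @export
setClass("BinnedGenome",
  slots = c(chromLengths = "numeric", binSize = "numeric"))

setValidity("BinnedGenome", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  if (length(object@chromLengths) < 1L)
    msg <- c(msg, "at least one chromosome required")
  if (is.null(names(object@chromLengths)) ||
      anyDuplicated(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must have unique names")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' ContactMatrix: per-chromosome symmetric cis contact maps
#'
#' Dense symmetric per-chromosome matrices of non-negative reals on a
#' [BinnedGenome], with a per-bin validity mask, a processing `stage`
#' (`raw`, `balanced`, `oe` or `pearson`) and, from the balanced stage
#' onward, the per-bin balancing weights.  Masked rows and columns hold
#' `NA`.  Stages only move forward: raw -> balanced -> oe -> pearson.
#'
#' @slot genome a [BinnedGenome].
#' @slot matrices named list of per-chromosome square matrices.
#' @slot mask named list of per-chromosome logical vectors (`TRUE` =
#'   masked / invalid bin).
#' @slot stage character scalar.
#' @slot weights named list of per-chromosome balancing-weight vectors
#'   (empty list before balancing).
#' @slot trans total inter-chromosomal pair count (kept as a scalar
#'   tally only; cis analyses ignore it).
#' @export
setClass("ContactMatrix",
  slots = c(genome = "BinnedGenome", matrices = "list", mask = "list",
            stage = "character", weights = "list", trans = "numeric"))

.cm_stages <- c("raw", "balanced", "oe", "pearson")

setValidity("ContactMatrix", function(object) {
  msg <- character()
  cn <- chromNames(object@genome)
  if (!identical(names(object@matrices), cn))
    msg <- c(msg, "matrices must be named by chromosome, in genome order")
  if (!identical(names(object@mask), cn))
    msg <- c(msg, "mask must be named by chromosome, in genome order")
  if (!(object@stage %in% .cm_stages))
    msg <- c(msg, sprintf("stage must be one of %s",
                          paste(.cm_stages, collapse = ", ")))
  for (ch in cn) {
    n <- chromNbins(object@genome)[[ch]]
    m <- object@matrices[[ch]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      msg <- c(msg, sprintf("matrix for %s must be %d x %d", ch, n, n))
      next
    }
    if (length(object@mask[[ch]]) != n)
      msg <- c(msg, sprintf("mask for %s must have length %d", ch, n))
    ok <- !object@mask[[ch]]
    sub <- m[ok, ok, drop = FALSE]
    if (any(is.infinite(sub)))
      msg <- c(msg, sprintf("infinite values among unmasked cells of %s", ch))
    if (!identical(is.na(sub), is.na(t(sub))))
      msg <- c(msg, sprintf("NA pattern of %s is not symmetric", ch))
    dif <- abs(sub - t(sub))
    if (length(dif) && !all(is.na(dif)) &&
        isTRUE(max(dif, na.rm = TRUE) >
               1e-8 * (1 + max(abs(sub), na.rm = TRUE))))
      msg <- c(msg, sprintf("matrix for %s is not symmetric", ch))
  }
  if (length(msg)) msg else TRUE
})

#' SignalTrack: a named per-bin signal
#'
#' A non-negative real value per genome bin for one mark or methylation
#' context (e.g. H3K27me3, CG).  `normalization` records whether the
#' track is raw or scaled to genome-wide mean 1.
#'
#' @slot genome a [BinnedGenome].
#' @slot name track name.
#' @slot values numeric, one value per bin.
#' @slot normalization `"raw"` or `"scaled"`.
#' @export
setClass("SignalTrack",
  slots = c(genome = "BinnedGenome", name = "character",
            values = "numeric", normalization = "character"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@values) != nbins(object@genome))
    msg <- c(msg, "values must have one entry per genome bin")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "signal values must be non-negative")
  if (!(object@normalization %in% c("raw", "scaled")))
    msg <- c(msg, "normalization must be 'raw' or 'scaled'")
  if (length(msg)) msg else TRUE
})

#' TruthSet: planted structure of a simulated dataset
#'
#' Per-bin chromatin states for the wild-type and (optionally) mutant
#' genotype, planted TAD intervals, planted boosted anchor pairs, the
#' per-bin redistribution class labels and the planted A/B compartment
#' labels.  Serves as the oracle for every downstream recovery test.
#'
#' States are `active`, `fac_het` (facultative heterochromatin, high
#' H3K27me3) and `const_het` (constitutive heterochromatin, high
#' H3K9me2/H3K27me1).  Domain and anchor coordinates are 1-based closed
#' bin indices within their chromosome.
#'
#' @slot genome a [BinnedGenome].
#' @slot stateWt,stateMut character per bin (stateMut empty until a
#'   mutant redistribution is applied).
#' @slot domains data.frame (chrom, start, end) of planted TADs, sorted
#'   and non-overlapping per chromosome.
#' @slot anchors data.frame (chrom, bin1, bin2, mut_only) of planted
#'   boosted pairs, `bin1 < bin2`.
#' @slot classLabel character per bin in `I`, `II`, `III`, `none`.
#' @slot compartmentLabel character per bin, `A` or `B` (A iff active).
#' @export
setClass("TruthSet",
  slots = c(genome = "BinnedGenome", stateWt = "character",
            stateMut = "character", domains = "data.frame",
            anchors = "data.frame", classLabel = "character",
            compartmentLabel = "character"))

.truth_states <- c("active", "fac_het", "const_het")

setValidity("TruthSet", function(object) {
  msg <- character()
  nb <- nbins(object@genome)
  if (length(object@stateWt) != nb)
    msg <- c(msg, "stateWt must cover every bin exactly once")
  if (!all(object@stateWt %in% .truth_states))
    msg <- c(msg, "unknown state in stateWt")
  if (length(object@stateMut) &&
      (length(object@stateMut) != nb ||
       !all(object@stateMut %in% .truth_states)))
    msg <- c(msg, "stateMut must be empty or cover every bin")
  if (length(object@classLabel) != nb ||
      !all(object@classLabel %in% c("I", "II", "III", "none")))
    msg <- c(msg, "classLabel must be per-bin in I/II/III/none")
  if (length(object@compartmentLabel) != nb ||
      !all(object@compartmentLabel %in% c("A", "B")))
    msg <- c(msg, "compartmentLabel must be per-bin A/B")
  d <- object@domains
  if (nrow(d)) {
    for (ch in unique(d$chrom)) {
      dc <- d[d$chrom == ch, , drop = FALSE]
      if (is.unsorted(dc$start, strictly = TRUE))
        msg <- c(msg, sprintf("domains on %s not sorted", ch))
      if (any(dc$end < dc$start) ||
          any(utils::head(dc$end, -1) >= dc$start[-1]))
        msg <- c(msg, sprintf("domains on %s overlap", ch))
    }
  }
  if (length(msg)) msg else TRUE
})

#' CompartmentCall: per-bin PC1 values and A/B labels
#'
#' The leading-eigenvector (PC1) compartment call of a Pearson contact
#' map.  The eigenvector sign is oriented per chromosome so that PC1
#' correlates positively with a user-supplied orientation track (gene
#' density or an active mark); the track's name is recorded.  A bins
#' have `pc1 > 0`, B bins `pc1 <= 0`; masked bins carry `NA` and the
#' label `masked`.
#'
#' @slot genome a [BinnedGenome].
#' @slot pc1 numeric per bin (NA where masked).
#' @slot label character per bin in `A`, `B`, `masked`.
#' @slot orientationTrack name of the track used to fix the sign.
#' @slot eigenGap named numeric, per-chromosome ratio of first to second
#'   eigenvalue magnitude.
#' @export
setClass("CompartmentCall",
  slots = c(genome = "BinnedGenome", pc1 = "numeric", label = "character",
            orientationTrack = "character", eigenGap = "numeric"))

setValidity("CompartmentCall", function(object) {
  msg <- character()
  nb <- nbins(object@genome)
  if (length(object@pc1) != nb || length(object@label) != nb)
    msg <- c(msg, "pc1 and label must be per-bin")
  ok <- !is.na(object@pc1)
  if (any(object@label[!ok] != "masked"))
    msg <- c(msg, "bins without pc1 must be labeled 'masked'")
  if (any(object@label[ok] != ifelse(object@pc1[ok] > 0, "A", "B")))
    msg <- c(msg, "label must be A iff pc1 > 0")
  if (length(msg)) msg else TRUE
})
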