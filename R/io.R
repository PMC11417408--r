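#' Write / read a contact matrix as COO triplets plus a bin table
#'
#' The cooler-compatible text layout: a bin table TSV (`chrom`, `start`,
#' `end`, 0-based half-open) and a COO TSV (`bin1_id`, `bin2_id`,
#' `count`) holding only upper-triangle (`bin1_id <= bin2_id`) non-zero
#' cis entries with global 0-based bin ids.
#'
#' @param M a raw-stage [ContactMatrix-class].
#' @param cooFile,binsFile output paths.
#' @export
writeContactMatrixCOO <- function(M, cooFile, binsFile) {
  bt <- binTable(M@genome)
  write.table(bt[c("chrom", "start", "end")], binsFile, sep = "\t",
              quote = FALSE, row.names = FALSE)
  rows <- list()
  for (ch in chromNames(M@genome)) {
    m <- M@matrices[[ch]]
    off <- binIndex(M@genome, ch)[1] - 1L
    sel <- which(upper.tri(m, diag = TRUE) & !is.na(m) & m != 0)
    if (!length(sel)) next
    rows[[ch]] <- data.frame(bin1_id = off + row(m)[sel] - 1L,
                             bin2_id = off + col(m)[sel] - 1L,
                             count = m[sel])
  }
  coo <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(bin1_id = integer(0), bin2_id = integer(0),
               count = numeric(0))
  coo <- coo[order(coo$bin1_id, coo$bin2_id), , drop = FALSE]
  write.table(coo, cooFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(coo = cooFile, bins = binsFile))
}

#' @rdname writeContactMatrixCOO
#' @return `readContactMatrixCOO`: a raw-stage [ContactMatrix-class]
#'   reconstructed from the two files.
#' @export
readContactMatrixCOO <- function(cooFile, binsFile) {
  bt <- read.table(binsFile, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  chroms <- unique(bt$chrom)
  lens <- vapply(chroms, function(ch) max(bt$end[bt$chrom == ch]),
                 numeric(1))
  genome <- BinnedGenome(setNames(lens, chroms),
                         binSize = bt$end[1] - bt$start[1])
  coo <- read.table(cooFile, header = TRUE, sep = "\t")
  nb <- chromNbins(genome)
  offs <- cumsum(c(0L, nb))
  mats <- lapply(nb, function(n) matrix(0, n, n))
  for (k in seq_along(chroms)) {
    sel <- coo$bin1_id >= offs[k] & coo$bin1_id < offs[k + 1]
    if (!any(sel)) next
    i <- coo$bin1_id[sel] - offs[k] + 1L
    j <- coo$bin2_id[sel] - offs[k] + 1L
    if (any(j > nb[k]))
      stop("COO entry crosses chromosomes; trans entries not supported")
    m <- mats[[k]]
    m[cbind(i, j)] <- coo$count[sel]
    m[cbind(j, i)] <- coo$count[sel]
    mats[[k]] <- m
  }
  ContactMatrix(genome, mats, stage = "raw")
}

#' Write / read a per-bin signal as bedGraph
#'
#' Values are written at full precision (`%.17g`), one line per bin in
#' 0-based half-open coordinates; reading goes through
#' [rtracklayer::import()].
#'
#' @param track a [SignalTrack-class].
#' @param file bedGraph path.
#' @export
writeSignalTrack <- function(track, file) {
  bt <- binTable(track@genome)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", trackName(track)),
             con)
  writeLines(sprintf("%s\t%d\t%d\t%.17g", bt$chrom, bt$start, bt$end,
                     trackValues(track)), con)
  invisible(file)
}

#' @rdname writeSignalTrack
#' @param genome the [BinnedGenome-class] the track lives on.
#' @param name track name (defaults to the file's base name).
#' @export
readSignalTrack <- function(file, genome, name = NULL) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  vals <- rep(NA_real_, nbins(genome))
  idx <- .bp_to_global_bin(genome, as.character(GenomicRanges::seqnames(gr)),
                           GenomicRanges::start(gr) - 1)
  vals[idx] <- gr$score
  if (anyNA(vals)) stop("bedGraph does not cover every bin of the genome")
  if (is.null(name))
    name <- sub("\\.bedGraph$", "", basename(file))
  SignalTrack(genome, name, vals)
}

#' Write / read gene intervals as BED6
#'
#' @param genes data.frame (chrom, start, end, id, strand), bp 0-based
#'   half-open.
#' @param file BED path.
#' @export
writeGenesBED <- function(genes, file) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end),
                               strand = genes$strand)
  gr$name <- genes$id
  gr$score <- 0L
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname writeGenesBED
#' @export
readGenesBED <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             id = gr$name,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read TE annotations as GFF3 with a superfamily attribute
#'
#' @param tes data.frame (chrom, start, end, id, superfamily), bp
#'   0-based half-open.
#' @param file GFF3 path.
#' @export
writeTEsGFF3 <- function(tes, file) {
  gr <- GenomicRanges::GRanges(tes$chrom,
                               IRanges::IRanges(tes$start + 1, tes$end))
  gr$type <- "transposable_element"
  gr$ID <- tes$id
  gr$superfamily <- tes$superfamily
  rtracklayer::export(gr, file, format = "GFF3")
  invisible(file)
}

#' @rdname writeTEsGFF3
#' @export
readTEsGFF3 <- function(file) {
  gr <- rtracklayer::import(file, format = "GFF3")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             id = gr$ID,
             superfamily = gr$superfamily,
             stringsAsFactors = FALSE)
}

# full-precision numeric TSV writer (round-trip-exact floats)
.write_tsv <- function(df, file) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits the cooler-style matrix triplets and bin table, bedGraph
#' tracks, BED6 genes, GFF3 TEs with `superfamily=` attributes, the DE
#' table, the truth tables and a YAML manifest echoing the
#' configuration.
#'
#' @param ds a dataset from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @param cfg the [simulationConfig()] used (echoed into the manifest).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(ds, dir, cfg = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stop("directory not writable: ", dir)
  write.table(binTable(ds$genome)[c("chrom", "start", "end")],
              file.path(dir, "bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (g in names(ds$contacts))
    writeContactMatrixCOO(ds$contacts[[g]],
                          file.path(dir, sprintf("matrix_%s.coo.tsv", g)),
                          file.path(dir, "bins.tsv"))
  for (g in names(ds$tracks))
    for (mk in names(ds$tracks[[g]]))
      writeSignalTrack(ds$tracks[[g]][[mk]],
                       file.path(dir, sprintf("track_%s_%s.bedGraph",
                                              g, mk)))
  writeGenesBED(ds$genes, file.path(dir, "genes.bed"))
  writeTEsGFF3(ds$tes, file.path(dir, "tes.gff3"))
  if (!is.null(ds$de))
    .write_tsv(ds$de, file.path(dir, "de.tsv"))
  tr <- ds$truth
  bt <- binTable(ds$genome)
  .write_tsv(data.frame(
    bin_id = bt$bin_id, chrom = bt$chrom, start = bt$start, end = bt$end,
    state_wt = tr@stateWt,
    state_mut = if (length(tr@stateMut)) tr@stateMut else NA,
    class_label = tr@classLabel,
    compartment_label = tr@compartmentLabel),
    file.path(dir, "truth_bins.tsv"))
  d <- tr@domains
  .write_tsv(data.frame(chrom = d$chrom, start_bin = d$start - 1L,
                        end_bin = d$end),
             file.path(dir, "truth_domains.tsv"))
  a <- tr@anchors
  .write_tsv(data.frame(chrom = a$chrom, bin1 = a$bin1 - 1L,
                        bin2 = a$bin2 - 1L, mut_only = a$mut_only),
             file.path(dir, "truth_anchors.tsv"))
  if (!is.null(cfg)) {
    manifest <- unclass(cfg)
    manifest$superfam_core <- as.list(manifest$superfam_core)
    manifest$superfam_arm <- as.list(manifest$superfam_arm)
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}

#' Read the truth tables written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param genome the [BinnedGenome-class] (e.g. from
#'   [readContactMatrixCOO()]).
#' @return a [TruthSet-class].
#' @export
readTruthSet <- function(dir, genome) {
  tb <- read.table(file.path(dir, "truth_bins.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  d <- read.table(file.path(dir, "truth_domains.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
  a <- read.table(file.path(dir, "truth_anchors.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
  new("TruthSet", genome = genome, stateWt = tb$state_wt,
      stateMut = if (all(is.na(tb$state_mut))) character(0) else
        tb$state_mut,
      domains = data.frame(chrom = d$chrom, start = d$start_bin + 1L,
                           end = d$end_bin, stringsAsFactors = FALSE),
      anchors = data.frame(chrom = a$chrom, bin1 = a$bin1 + 1L,
                           bin2 = a$bin2 + 1L, mut_only = a$mut_only,
                           stringsAsFactors = FALSE),
      classLabel = tb$class_label,
      compartmentLabel = tb$compartment_label)
}
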