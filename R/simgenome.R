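#' Simulation configuration
#'
#' Parameters of the synthetic 3D-genome generator.  The generator
#' emulates a small plant-like genome in which gene-rich chromosome arms
#' (active or Polycomb/facultative-heterochromatin bins) flank a
#' TE-rich pericentromeric core (constitutive heterochromatin), contacts
#' decay with genomic distance and are boosted between bins of the same
#' chromatin state (homotypic affinity), inside planted TAD-like domains
#' and between planted anchor pairs.  A "ddm1 mode" relocates H3K27me3:
#' a fraction of core bins gains the mark (losing H3K9me2/H3K27me1 and
#' DNA methylation; redistribution classes II and III) while a fraction
#' of arm Polycomb bins loses it (class I), and the cross-state contact
#' affinities are raised, weakening compartment segregation.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp; must be a multiple of
#'   `bin_size`.
#' @param bin_size bin width in bp (default 50 kb).
#' @param core_frac fraction of bins forming the central TE-rich core
#'   (default 0.4).
#' @param p_fac probability that an arm bin is facultative
#'   heterochromatin in the wild type (default 0.3).
#' @param alpha distance-decay exponent (> 0); contact rates scale as
#'   `d^-alpha`.
#' @param depth expected total cis counts per chromosome.
#' @param a_AA,a_FF,a_CC homotypic affinities of active, facultative and
#'   constitutive bins (default 1.6 each).
#' @param a_cross_rep facultative-constitutive affinity (default 0.8;
#'   `a_cross_rep_mut`, default 1.3, replaces it in ddm1 mode).
#' @param a_AB active-repressed affinity (default 0.5; `a_AB_mut`,
#'   default 1.1, replaces it in ddm1 mode: the mutant's near-neutral
#'   active-repressed affinity reproduces the heightened A-B contact
#'   and flattened PC1 of the DDM1-loss phenotype).
#' @param tau intra-TAD contact boost (default 1.5; `tau_mut`, default
#'   1.2, replaces it in ddm1 mode).
#' @param n_tads_per_chrom planted TAD-like domains tiling the repressed
#'   core (default 10).
#' @param n_anchor_bins anchor bins per chromosome marked in both
#'   genotypes (default 10): every pair of anchor bins within
#'   `anchor_d_range` is contact-boosted, emulating homotypic
#'   aggregation of H3K27me3-marked loci.
#' @param n_anchor_bins_mut additional anchor bins per chromosome
#'   marked in the mutant only (default 3); pairs involving them are
#'   boosted in the mutant dataset only.
#' @param anchor_d_range separation range (bins) of boosted anchor
#'   pairs (default `c(10, 100)`).
#' @param anchor_boost multiplicative contact boost at anchor pairs
#'   (default 3).
#' @param rho_relocate fraction of core (constitutive) bins gaining
#'   H3K27me3 in ddm1 mode (default 0.5).
#' @param rho_loss fraction of wild-type facultative bins losing
#'   H3K27me3 in ddm1 mode (default 0.5).
#' @param class3_frac fraction of relocated core bins assigned
#'   redistribution class III rather than II (default 0.5).
#' @param sigma_track lognormal noise sd of the mark tracks (default 0.3).
#' @param superfam_core,superfam_arm named categorical distributions of
#'   TE superfamilies in core and arm bins.
#' @param seed integer RNG seed; all stages derive their streams from it.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(n_chrom = 2, chrom_len = 1e7, bin_size = 5e4,
                             core_frac = 0.4, p_fac = 0.3,
                             alpha = 1.0, depth = 5e6,
                             a_AA = 1.6, a_FF = 1.6, a_CC = 1.6,
                             a_cross_rep = 0.8, a_AB = 0.5,
                             a_cross_rep_mut = 1.3, a_AB_mut = 1.1,
                             tau = 1.5, tau_mut = 1.2,
                             n_tads_per_chrom = 10,
                             n_anchor_bins = 10, n_anchor_bins_mut = 3,
                             anchor_d_range = c(10, 100),
                             anchor_boost = 3,
                             rho_relocate = 0.5, rho_loss = 0.5,
                             class3_frac = 0.5, sigma_track = 0.3,
                             superfam_core = c("LTR/Gypsy" = 0.45,
                                               "LTR/Copia" = 0.15,
                                               "DNA/MuDR" = 0.10,
                                               "LINE/L1" = 0.10,
                                               "DNA/hAT" = 0.05,
                                               "DNA/CMC-EnSpm" = 0.05,
                                               "RC/Helitron" = 0.05,
                                               "SINE" = 0.05),
                             superfam_arm = c("LTR/Copia" = 0.35,
                                              "LTR/Gypsy" = 0.15,
                                              "DNA/hAT" = 0.15,
                                              "DNA/MuDR" = 0.10,
                                              "RC/Helitron" = 0.10,
                                              "LINE/L1" = 0.05,
                                              "DNA/CMC-EnSpm" = 0.05,
                                              "SINE" = 0.05),
                             seed = 1) {
  cfg <- as.list(environment())
  aff <- c(a_AA, a_FF, a_CC, a_cross_rep, a_AB, a_cross_rep_mut, a_AB_mut,
           tau, tau_mut, anchor_boost)
  if (any(aff <= 0)) stop("all affinities and boosts must be > 0")
  fr <- c(core_frac, p_fac, rho_relocate, rho_loss, class3_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (chrom_len %% bin_size != 0)
    stop("bin_size must divide chrom_len")
  if (alpha <= 0) stop("alpha must be > 0")
  if (sigma_track < 0) stop("sigma_track must be >= 0")
  structure(cfg, class = "SimulationConfig")
}

# state of every bin of one chromosome, core centered
.layout_states <- function(n, cfg) {
  ncore <- round(cfg$core_frac * n)
  core_start <- floor((n - ncore) / 2) + 1L
  core <- seq(core_start, length.out = ncore)
  st <- rep("active", n)
  st[core] <- "const_het"
  arm <- setdiff(seq_len(n), core)
  fac <- arm[runif(length(arm)) < cfg$p_fac]
  st[fac] <- "fac_het"
  list(states = st, core = core)
}

#' Build the synthetic genome layout
#'
#' Lays out chromosomes with a centered constitutive-heterochromatin
#' core spanning `core_frac` of the bins (dense TE intervals, TE-biased
#' superfamily composition) and gene-dense arms whose bins are active or
#' facultative heterochromatin with probability `p_fac`.  TAD-like
#' domains tile the repressed core; anchor pairs are planted at
#' separations of 10-100 bins.  The planted compartment label is A for
#' active bins and B otherwise.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `genome` ([BinnedGenome-class]), `truth`
#'   ([TruthSet-class], wild type only), `genes` and `tes` interval
#'   data.frames (bp, 0-based half-open).
#' @export
buildGenomeLayout <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  n <- as.integer(cfg$chrom_len / cfg$bin_size)
  if (n < 10) stop("chromosome shorter than 10 bins; enlarge chrom_len")
  genome <- BinnedGenome(
    setNames(rep(cfg$chrom_len, cfg$n_chrom),
             paste0("chr", seq_len(cfg$n_chrom))),
    binSize = cfg$bin_size)
  set.seed(cfg$seed)

  states <- character(0)
  domains <- list()
  genes <- list()
  tes <- list()
  gid <- 0L
  tid <- 0L
  bs <- cfg$bin_size
  for (ch in chromNames(genome)) {
    lay <- .layout_states(n, cfg)
    states <- c(states, lay$states)
    # TAD-like domains tile the core in equal-size runs
    k <- min(cfg$n_tads_per_chrom, length(lay$core))
    if (k > 0) {
      cuts <- floor(seq(0, length(lay$core), length.out = k + 1))
      domains[[ch]] <- data.frame(
        chrom = ch,
        start = lay$core[cuts[-length(cuts)] + 1L],
        end = lay$core[cuts[-1L]],
        stringsAsFactors = FALSE)
    }
    for (b in seq_len(n)) {
      b0 <- (b - 1) * bs
      if (b %in% lay$core) {
        # one long pericentromeric element filling most of the bin
        tid <- tid + 1L
        tes[[length(tes) + 1L]] <- data.frame(
          chrom = ch, start = b0 + 0.1 * bs, end = b0 + 0.9 * bs,
          id = sprintf("TE%05d", tid),
          superfamily = sample(names(cfg$superfam_core), 1,
                               prob = cfg$superfam_core),
          stringsAsFactors = FALSE)
      } else {
        gid <- gid + 1L
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = ch, start = b0 + 0.2 * bs, end = b0 + 0.8 * bs,
          id = sprintf("gene%05d", gid), strand = "+",
          stringsAsFactors = FALSE)
        if (runif(1) < 0.75) {
          tid <- tid + 1L
          tes[[length(tes) + 1L]] <- data.frame(
            chrom = ch, start = b0 + 0.85 * bs, end = b0 + 0.98 * bs,
            id = sprintf("TE%05d", tid),
            superfamily = sample(names(cfg$superfam_arm), 1,
                                 prob = cfg$superfam_arm),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  anchors <- .plant_anchors(genome, cfg)
  truth <- new("TruthSet", genome = genome, stateWt = states,
               stateMut = character(0),
               domains = do.call(rbind, unname(domains)),
               anchors = anchors,
               classLabel = rep("none", length(states)),
               compartmentLabel = ifelse(states == "active", "A", "B"))
  list(genome = genome, truth = truth,
       genes = do.call(rbind, genes), tes = do.call(rbind, tes))
}

# sample k bins among 1..n with a minimum pairwise separation
.sample_spaced_bins <- function(n, k, min_sep = 8L, taken = integer(0)) {
  out <- integer(0)
  tries <- 0L
  while (length(out) < k && tries < 500L * max(k, 1L)) {
    tries <- tries + 1L
    b <- sample.int(n, 1L)
    if (all(abs(b - c(out, taken)) >= min_sep)) out <- c(out, b)
  }
  sort(out)
}

# anchor bins per chromosome (shared + mutant-only); boosted pairs are
# all anchor-bin pairs within anchor_d_range, flagged mut_only when a
# mutant-only bin is involved
.plant_anchors <- function(genome, cfg) {
  out <- list()
  for (ch in chromNames(genome)) {
    n <- chromNbins(genome)[[ch]]
    shared <- .sample_spaced_bins(n, cfg$n_anchor_bins)
    mut <- .sample_spaced_bins(n, cfg$n_anchor_bins_mut, taken = shared)
    bins <- c(shared, mut)
    is_mut <- c(rep(FALSE, length(shared)), rep(TRUE, length(mut)))
    if (length(bins) < 2L) next
    cmb <- utils::combn(seq_along(bins), 2L)
    b1 <- pmin(bins[cmb[1, ]], bins[cmb[2, ]])
    b2 <- pmax(bins[cmb[1, ]], bins[cmb[2, ]])
    d <- b2 - b1
    keep <- d >= cfg$anchor_d_range[1] & d <= cfg$anchor_d_range[2]
    if (!any(keep)) next
    out[[ch]] <- data.frame(
      chrom = ch, bin1 = b1[keep], bin2 = b2[keep],
      mut_only = (is_mut[cmb[1, ]] | is_mut[cmb[2, ]])[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), bin1 = integer(0),
                      bin2 = integer(0), mut_only = logical(0)))
  do.call(rbind, unname(out))
}

#' Anchor-bin sets of a truth set
#'
#' Derives from the planted boosted pairs the set of anchor bins shared
#' by both genotypes and the set marked in the mutant only - the inputs
#' for aggregate anchor-pair (APA) analysis.
#'
#' @param truth a [TruthSet-class].
#' @return list of two data.frames (`shared`, `mut_only`) with columns
#'   chrom and bin.
#' @export
anchorBinSets <- function(truth) {
  a <- truth@anchors
  shared <- unique(rbind(
    data.frame(chrom = a$chrom[!a$mut_only], bin = a$bin1[!a$mut_only]),
    data.frame(chrom = a$chrom[!a$mut_only], bin = a$bin2[!a$mut_only])))
  allb <- unique(rbind(data.frame(chrom = a$chrom, bin = a$bin1),
                       data.frame(chrom = a$chrom, bin = a$bin2)))
  key <- function(df) paste(df$chrom, df$bin)
  mut_only <- allb[!(key(allb) %in% key(shared)), , drop = FALSE]
  list(shared = shared[order(shared$chrom, shared$bin), , drop = FALSE],
       mut_only = mut_only[order(mut_only$chrom, mut_only$bin), ,
                           drop = FALSE])
}

#' Apply the ddm1-mode histone-mark redistribution to a truth set
#'
#' Relocates facultative heterochromatin into the core:
#' `round(rho_relocate * n_core)` constitutive bins become facultative
#' (H3K27me3 gain with H3K9me2/H3K27me1/DNA-methylation loss; class II,
#' or class III for a `class3_frac` share, where H3K9me2 was already
#' low and only H3K27me1 drops).  `round(rho_loss * n_fac)` wild-type
#' facultative bins become active-like with H3K27me3 loss (class I).
#' All other bins keep their state and the label `none`.
#'
#' @param truth a wild-type [TruthSet-class] from [buildGenomeLayout()].
#' @param cfg the matching [simulationConfig()].
#' @return the truth set with mutant states and class labels filled in.
#' @export
applyDdm1Redistribution <- function(truth, cfg) {
  stopifnot(is(truth, "TruthSet"), inherits(cfg, "SimulationConfig"))
  if (cfg$rho_relocate < 0 || cfg$rho_relocate > 1 ||
      cfg$rho_loss < 0 || cfg$rho_loss > 1)
    stop("rho_relocate and rho_loss must lie in [0, 1]")
  set.seed(cfg$seed + 1L)
  st_wt <- truth@stateWt
  st_mut <- st_wt
  cls <- rep("none", length(st_wt))

  const_bins <- which(st_wt == "const_het")
  n_rel <- round(cfg$rho_relocate * length(const_bins))
  rel <- sort(sample(const_bins, n_rel))
  st_mut[rel] <- "fac_het"
  n3 <- round(cfg$class3_frac * n_rel)
  iii <- if (n3 > 0) sort(sample(rel, n3)) else integer(0)
  cls[rel] <- "II"
  cls[iii] <- "III"

  fac_bins <- which(st_wt == "fac_het")
  n_loss <- round(cfg$rho_loss * length(fac_bins))
  loss <- sort(sample(fac_bins, n_loss))
  st_mut[loss] <- "active"
  cls[loss] <- "I"

  truth@stateMut <- st_mut
  truth@classLabel <- cls
  validObject(truth)
  truth
}

# per-pair state affinity
.affinity_lookup <- function(cfg, genotype) {
  a_cross <- if (genotype == "mut") cfg$a_cross_rep_mut else cfg$a_cross_rep
  a_ab <- if (genotype == "mut") cfg$a_AB_mut else cfg$a_AB
  A <- matrix(a_ab, 3, 3,
              dimnames = list(.truth_states, .truth_states))
  A["active", "active"] <- cfg$a_AA
  A["fac_het", "fac_het"] <- cfg$a_FF
  A["const_het", "const_het"] <- cfg$a_CC
  A["fac_het", "const_het"] <- a_cross
  A["const_het", "fac_het"] <- a_cross
  A
}

# per-bin TAD id (NA outside domains) for one chromosome
.tad_ids <- function(truth, ch, n) {
  ids <- rep(NA_integer_, n)
  d <- truth@domains
  d <- d[d$chrom == ch, , drop = FALSE]
  for (k in seq_len(nrow(d))) ids[d$start[k]:d$end[k]] <- k
  ids
}

#' Simulate a cis contact matrix from planted truth
#'
#' For bins `i < j` on one chromosome the count is Poisson with rate
#' `L * (j - i)^(-alpha) * A(s_i, s_j) * T_ij`, where `A` is the
#' chromatin-state affinity, `T_ij` multiplies in the intra-TAD boost
#' `tau` when both bins share a planted domain and the `anchor_boost`
#' when `(i, j)` is a planted anchor pair, and `L` is calibrated per
#' chromosome so that the expected total cis count equals `depth`.  The
#' matrix is symmetrized and the diagonal is 0.
#'
#' @param truth a [TruthSet-class]; mutant states must be present when
#'   `genotype = "mut"`.
#' @param cfg the matching [simulationConfig()].
#' @param genotype `"wt"` or `"mut"`; the mutant uses the mutant states,
#'   raised cross-affinities and the reduced `tau_mut`.
#' @param seed optional RNG seed override (defaults to a genotype-
#'   specific stream derived from `cfg$seed`).
#' @return a raw-stage [ContactMatrix-class].
#' @export
simulateContacts <- function(truth, cfg, genotype = c("wt", "mut"),
                             seed = NULL) {
  genotype <- match.arg(genotype)
  stopifnot(is(truth, "TruthSet"), inherits(cfg, "SimulationConfig"))
  if (cfg$depth <= 0) stop("depth must be > 0")
  if (genotype == "mut" && !length(truth@stateMut))
    stop("truth has no mutant states; run applyDdm1Redistribution first")
  set.seed(if (is.null(seed))
    cfg$seed + ifelse(genotype == "wt", 2L, 3L) else seed)
  genome <- truth@genome
  states <- if (genotype == "wt") truth@stateWt else truth@stateMut
  A <- .affinity_lookup(cfg, genotype)
  tau <- if (genotype == "mut") cfg$tau_mut else cfg$tau
  mats <- list()
  for (ch in chromNames(genome)) {
    idx <- binIndex(genome, ch)
    n <- length(idx)
    st <- states[idx]
    rate <- outer(seq_len(n), seq_len(n),
                  function(i, j) abs(j - i)^(-cfg$alpha)) *
      A[cbind(rep(st, n), rep(st, each = n))]
    diag(rate) <- 0
    tads <- .tad_ids(truth, ch, n)
    same_tad <- outer(tads, tads, function(a, b)
      !is.na(a) & !is.na(b) & a == b)
    rate[same_tad] <- rate[same_tad] * tau
    anc <- truth@anchors
    anc <- anc[anc$chrom == ch &
                 (!anc$mut_only | genotype == "mut"), , drop = FALSE]
    if (nrow(anc)) {
      ij <- cbind(anc$bin1, anc$bin2)
      rate[ij] <- rate[ij] * cfg$anchor_boost
      rate[ij[, 2:1, drop = FALSE]] <-
        rate[ij[, 2:1, drop = FALSE]] * cfg$anchor_boost
    }
    L <- cfg$depth / sum(rate[upper.tri(rate)])
    m <- matrix(0, n, n)
    up <- which(upper.tri(rate))
    m[up] <- rpois(length(up), L * rate[up])
    m <- m + t(m)
    mats[[ch]] <- m
  }
  ContactMatrix(genome, mats, stage = "raw")
}

# base signal per (state, mark); class III bins override H3K9me2 to a
# constitutively low level in both genotypes
.track_base <- function() {
  rbind(active    = c(H3K27me3 = 0.3, H3K9me2 = 0.2, H3K27me1 = 0.2,
                      H3K9ac = 2.0, CG = 0.3, CHG = 0.2, CHH = 0.2),
        fac_het   = c(H3K27me3 = 2.0, H3K9me2 = 0.2, H3K27me1 = 0.2,
                      H3K9ac = 0.3, CG = 0.3, CHG = 0.2, CHH = 0.2),
        const_het = c(H3K27me3 = 0.1, H3K9me2 = 2.0, H3K27me1 = 2.0,
                      H3K9ac = 0.2, CG = 2.0, CHG = 2.0, CHH = 2.0))
}

#' Simulate mark and methylation tracks (and a DE table)
#'
#' Each bin's value for a mark is the state-specific base level times
#' multiplicative lognormal noise `LogNormal(0, sigma_track)`.
#' Facultative bins are high in H3K27me3, constitutive bins in
#' H3K9me2/H3K27me1 and all three methylation contexts, active bins in
#' H3K9ac.  Bins carrying redistribution class III keep a constitutively
#' low H3K9me2 base in both genotypes.  When `genes` are supplied and
#' the truth carries mutant states, a differential-expression table is
#' drawn: genes on class I bins (H3K27me3 loss) are up-shifted
#' (`log2fc ~ N(2, 0.4)`, small adjusted p), all others are null.
#'
#' @param truth a [TruthSet-class].
#' @param cfg the matching [simulationConfig()].
#' @param genotype `"wt"` or `"mut"`.
#' @param marks subset of track names to simulate (default: all seven).
#' @param genes optional gene interval data.frame from
#'   [buildGenomeLayout()]; triggers the DE table.
#' @param seed optional RNG seed override.
#' @return list with `tracks` (named list of [SignalTrack-class]) and
#'   `de` (data.frame `gene_id, log2fc, padj, status`, or `NULL`).
#' @export
simulateTracks <- function(truth, cfg, genotype = c("wt", "mut"),
                           marks = NULL, genes = NULL, seed = NULL) {
  genotype <- match.arg(genotype)
  stopifnot(is(truth, "TruthSet"), inherits(cfg, "SimulationConfig"))
  base <- .track_base()
  if (is.null(marks)) marks <- colnames(base)
  unknown <- setdiff(marks, colnames(base))
  if (length(unknown))
    stop("unknown mark name(s): ", paste(unknown, collapse = ", "))
  if (genotype == "mut" && !length(truth@stateMut))
    stop("truth has no mutant states; run applyDdm1Redistribution first")
  set.seed(if (is.null(seed))
    cfg$seed + ifelse(genotype == "wt", 4L, 5L) else seed)
  genome <- truth@genome
  states <- if (genotype == "wt") truth@stateWt else truth@stateMut
  nb <- nbins(genome)
  tracks <- list()
  for (mk in marks) {
    b <- base[states, mk]
    if (mk == "H3K9me2") b[truth@classLabel == "III"] <- 0.08
    noise <- if (cfg$sigma_track > 0)
      rlnorm(nb, 0, cfg$sigma_track) else rep(1, nb)
    tracks[[mk]] <- SignalTrack(genome, mk, b * noise)
  }
  de <- NULL
  if (!is.null(genes) && length(truth@stateMut)) {
    mid_bin <- .bp_to_global_bin(genome, genes$chrom,
                                 (genes$start + genes$end) / 2)
    is_I <- truth@classLabel[mid_bin] == "I"
    lfc <- ifelse(is_I, rnorm(nrow(genes), 2, 0.4),
                  rnorm(nrow(genes), 0, 0.5))
    padj <- ifelse(is_I, 10^runif(nrow(genes), -6, -3),
                   runif(nrow(genes), 0.2, 1))
    status <- ifelse(padj < 0.05 & lfc > 1, "up",
                     ifelse(padj < 0.05 & lfc < -1, "down", "nc"))
    de <- data.frame(gene_id = genes$id, log2fc = lfc, padj = padj,
                     status = status, stringsAsFactors = FALSE)
  }
  list(tracks = tracks, de = de)
}

# bp positions -> global 1-based bin index
.bp_to_global_bin <- function(genome, chrom, pos) {
  nb <- chromNbins(genome)
  off <- setNames(cumsum(c(0L, nb))[seq_along(nb)], names(nb))
  off[chrom] + pmin(floor(pos / binSize(genome)), nb[chrom] - 1L) + 1L
}

#' Simulate a full matched WT / ddm1-mode dataset
#'
#' Convenience wrapper: layout, redistribution, contact matrices and
#' tracks for both genotypes, and the DE table.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `genome`, `truth`, `genes`, `tes`, `contacts`
#'   (list `wt`/`mut` of raw [ContactMatrix-class]), `tracks` (list
#'   `wt`/`mut` of named [SignalTrack-class] lists) and `de`.
#' @export
simulateDataset <- function(cfg = simulationConfig()) {
  lay <- buildGenomeLayout(cfg)
  truth <- applyDdm1Redistribution(lay$truth, cfg)
  wt_tr <- simulateTracks(truth, cfg, "wt", genes = lay$genes)
  mut_tr <- simulateTracks(truth, cfg, "mut", genes = lay$genes)
  list(genome = lay$genome, truth = truth, genes = lay$genes,
       tes = lay$tes,
       contacts = list(wt = simulateContacts(truth, cfg, "wt"),
                       mut = simulateContacts(truth, cfg, "mut")),
       tracks = list(wt = wt_tr$tracks, mut = mut_tr$tracks),
       de = mut_tr$de)
}
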