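test_that("layout plants a centered core and obeys the state fractions", {
  cfg <- simulationConfig(seed = 1)
  lay <- buildGenomeLayout(cfg)
  for (ch in chromNames(lay$genome)) {
    st <- lay$truth@stateWt[binIndex(lay$genome, ch)]
    core <- which(st == "const_het")
    expect_length(core, 80)                       # 0.4 * 200, centered
    expect_equal(core, seq(min(core), max(core)))
    expect_equal(min(core) - 1L, 200L - max(core))
  }
  # conservation: states cover every bin exactly once
  expect_length(lay$truth@stateWt, nbins(lay$genome))
  expect_true(all(lay$truth@stateWt %in%
                    c("active", "fac_het", "const_het")))
  # A label iff active
  expect_equal(lay$truth@compartmentLabel,
               ifelse(lay$truth@stateWt == "active", "A", "B"))

  # p_fac = 0 -> no facultative bins
  lay0 <- buildGenomeLayout(simulationConfig(p_fac = 0, seed = 2))
  expect_false(any(lay0$truth@stateWt == "fac_het"))

  # domains tile the core, sorted and non-overlapping
  d <- lay$truth@domains
  expect_equal(nrow(d), 20)
  expect_true(all(d$end >= d$start))

  expect_error(buildGenomeLayout(simulationConfig(chrom_len = 4e5)),
               "10 bins")
  expect_error(simulationConfig(core_frac = 1.4), "fractions")
  expect_error(simulationConfig(alpha = -1), "affinities|alpha")
  expect_error(simulationConfig(chrom_len = 1e7 + 1), "divide")
})

test_that("generation is deterministic given the config seed", {
  cfg <- simulationConfig(seed = 11)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(a$truth@stateWt, b$truth@stateWt)
  expect_identical(a$truth@anchors, b$truth@anchors)
  expect_identical(a$contacts$wt@matrices, b$contacts$wt@matrices)
  expect_identical(trackValues(a$tracks$mut$H3K27me3),
                   trackValues(b$tracks$mut$H3K27me3))
  expect_identical(a$de, b$de)
  # a different seed changes the draws
  c_ <- simulateDataset(simulationConfig(seed = 12))
  expect_false(identical(a$contacts$wt@matrices, c_$contacts$wt@matrices))
})

test_that("ddm1 redistribution relocates the configured bin fractions", {
  cfg <- simulationConfig(rho_relocate = 0.5, rho_loss = 0.5, seed = 3)
  lay <- buildGenomeLayout(cfg)
  truth <- applyDdm1Redistribution(lay$truth, cfg)
  n_core <- sum(lay$truth@stateWt == "const_het")
  n_fac <- sum(lay$truth@stateWt == "fac_het")
  expect_equal(sum(truth@classLabel %in% c("II", "III")),
               round(0.5 * n_core))
  expect_equal(sum(truth@classLabel == "I"), round(0.5 * n_fac))
  # class labels consistent with the state transitions
  ii <- truth@classLabel %in% c("II", "III")
  expect_true(all(lay$truth@stateWt[ii] == "const_het"))
  expect_true(all(truth@stateMut[ii] == "fac_het"))
  i <- truth@classLabel == "I"
  expect_true(all(truth@stateMut[i] == "active"))
  expect_true(all(truth@stateMut[truth@classLabel == "none"] ==
                    lay$truth@stateWt[truth@classLabel == "none"]))

  # rho = 0 leaves the truth unchanged; rho_relocate = 1 converts the core
  t0 <- applyDdm1Redistribution(lay$truth,
          simulationConfig(rho_relocate = 0, rho_loss = 0, seed = 3))
  expect_identical(t0@stateMut, lay$truth@stateWt)
  expect_true(all(t0@classLabel == "none"))
  t1 <- applyDdm1Redistribution(lay$truth,
          simulationConfig(rho_relocate = 1, seed = 3))
  expect_true(all(t1@stateMut[lay$truth@stateWt == "const_het"] ==
                    "fac_het"))
})

test_that("contact decay recovers the distance exponent", {
  # affinity-free, TAD-free simulation: mean count ratio d vs 2d ~ 2^alpha
  cfg <- simulationConfig(n_chrom = 1, a_AA = 1, a_FF = 1, a_CC = 1,
                          a_cross_rep = 1, a_AB = 1, tau = 1,
                          n_anchor_bins = 0, n_anchor_bins_mut = 0,
                          alpha = 1.0, seed = 4)
  lay <- buildGenomeLayout(cfg)
  truth <- applyDdm1Redistribution(lay$truth, cfg)
  m <- contactMatrix(simulateContacts(truth, cfg, "wt"), "chr1")
  n <- nrow(m)
  mean_at <- function(d) mean(m[cbind(seq_len(n - d), seq_len(n - d) + d)])
  for (d in c(5, 10, 20))
    expect_equal(mean_at(d) / mean_at(2 * d), 2^cfg$alpha,
                 tolerance = 0.15)
  # log-log regression over a decade of distances: slope -alpha +- 0.1
  ds <- 2:40
  fit <- lm(log(vapply(ds, mean_at, numeric(1))) ~ log(ds))
  expect_equal(unname(coef(fit)[2]), -cfg$alpha, tolerance = 0.1)

  expect_error(simulateContacts(truth, simulationConfig(depth = 0)),
               "depth")
})

test_that("homotypic state pairs out-contact cross-state pairs", {
  cfg <- simulationConfig(a_FF = 2, a_CC = 2, a_cross_rep = 0.5, seed = 6)
  lay <- buildGenomeLayout(cfg)
  truth <- applyDdm1Redistribution(lay$truth, cfg)
  OE <- observedOverExpected(simulateContacts(truth, cfg, "wt"))
  st <- truth@stateWt
  same <- c(); cross <- c()
  for (ch in chromNames(lay$genome)) {
    idx <- binIndex(lay$genome, ch)
    s <- st[idx]
    m <- contactMatrix(OE, ch)
    rep_ <- s %in% c("fac_het", "const_het")
    pair_state <- outer(s, s, paste)
    off <- abs(row(m) - col(m)) >= 2
    same <- c(same, m[off & outer(rep_, rep_, `&`) &
                        pair_state %in% c("fac_het fac_het",
                                          "const_het const_het")])
    cross <- c(cross, m[off & pair_state %in% c("fac_het const_het",
                                                "const_het fac_het")])
  }
  expect_gt(mean(same, na.rm = TRUE), mean(cross, na.rm = TRUE))
})

test_that("simulated tracks reflect the planted states", {
  cfg0 <- simulationConfig(sigma_track = 0, seed = 7)
  lay <- buildGenomeLayout(cfg0)
  truth <- applyDdm1Redistribution(lay$truth, cfg0)
  tr <- simulateTracks(truth, cfg0, "wt")$tracks
  v <- trackValues(tr$H3K27me3)
  # noise-free limit: values equal the base levels exactly
  expect_equal(unique(v[truth@stateWt == "fac_het"]), 2.0)
  expect_equal(unique(v[truth@stateWt == "active"]), 0.3)

  cfg <- simulationConfig(sigma_track = 0.3, seed = 7)
  trn <- simulateTracks(truth, cfg, "wt")$tracks
  vn <- trackValues(trn$H3K27me3)
  expect_gt(mean(vn[truth@stateWt == "fac_het"]),
            mean(vn[truth@stateWt == "active"]))
  expect_gt(mean(trackValues(trn$H3K9me2)[truth@stateWt == "const_het"]),
            mean(trackValues(trn$H3K9me2)[truth@stateWt == "fac_het"]))

  # same seed identical, different seed different
  expect_identical(vn, trackValues(simulateTracks(truth, cfg,
                                                  "wt")$tracks$H3K27me3))
  expect_false(identical(vn,
    trackValues(simulateTracks(truth, cfg, "wt",
                               seed = 99)$tracks$H3K27me3)))
  expect_error(simulateTracks(truth, cfg, "wt", marks = "H3K4me3"),
               "unknown mark")
})

test_that("written dataset files round-trip to the in-memory objects", {
  cfg <- simulationConfig(n_chrom = 1, chrom_len = 2e6, seed = 8)
  ds <- simulateDataset(cfg)
  d <- withr::local_tempdir()
  writeDataset(ds, d, cfg = cfg)

  M2 <- readContactMatrixCOO(file.path(d, "matrix_wt.coo.tsv"),
                             file.path(d, "bins.tsv"))
  expect_equal(M2@matrices, ds$contacts$wt@matrices)
  g2 <- genomeOf(M2)
  tr2 <- readSignalTrack(file.path(d, "track_mut_H3K27me3.bedGraph"), g2)
  expect_equal(trackValues(tr2), trackValues(ds$tracks$mut$H3K27me3))
  genes2 <- readGenesBED(file.path(d, "genes.bed"))
  expect_equal(genes2[c("chrom", "start", "end", "id")],
               ds$genes[c("chrom", "start", "end", "id")])
  tes2 <- readTEsGFF3(file.path(d, "tes.gff3"))
  expect_equal(tes2[c("chrom", "start", "end", "superfamily")],
               ds$tes[c("chrom", "start", "end", "superfamily")])
  tr_rt <- readTruthSet(d, g2)
  expect_identical(tr_rt@stateWt, ds$truth@stateWt)
  expect_identical(tr_rt@stateMut, ds$truth@stateMut)
  expect_identical(tr_rt@classLabel, ds$truth@classLabel)
  expect_equal(tr_rt@domains, ds$truth@domains)
  expect_equal(tr_rt@anchors, ds$truth@anchors)
  de2 <- read.table(file.path(d, "de.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(de2$log2fc, ds$de$log2fc)
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  expect_equal(yaml::read_yaml(file.path(d, "manifest.yaml"))$depth,
               cfg$depth)
})
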