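test_that("track scaling normalizes genome-wide means to one", {
  g <- tiny_genome(10)
  t1 <- SignalTrack(g, "m", rep(2, 10))
  t2 <- SignalTrack(g, "m", rep(5, 10))
  s1 <- scaleTracks(t1); s2 <- scaleTracks(t2)
  expect_equal(mean(trackValues(s1)), 1)
  expect_equal(mean(trackValues(s2)), 1)
  # scale invariance: x and 7x scale to the same track
  v <- runif(10, 0.1, 4)
  expect_equal(trackValues(scaleTracks(SignalTrack(g, "m", v))),
               trackValues(scaleTracks(SignalTrack(g, "m", 7 * v))))
  # already unit-mean track unchanged
  u <- v / mean(v)
  expect_equal(trackValues(scaleTracks(SignalTrack(g, "m", u))), u)
  expect_error(scaleTracks(SignalTrack(g, "m", rep(0, 10))), "zero mean")
})

test_that("differential signal thresholds log2 changes as specified", {
  g <- tiny_genome(4)
  wt <- SignalTrack(g, "H3K27me3", c(0.9, 1.0, 1.9, 1.0), "scaled")
  mut <- SignalTrack(g, "H3K27me3", c(1.9, 1.0, 0.9, 1.05), "scaled")
  d <- differentialSignal(wt, mut)
  # (0.9 + 0.1) -> (1.9 + 0.1): delta exactly 1 -> up
  expect_equal(d$delta[1], 1)
  expect_equal(d$status[1], "up")
  expect_equal(d$delta[2], 0)
  expect_equal(d$status[2], "nc")
  expect_equal(d$status[3], "down")
  expect_equal(d$status[4], "nc")
  # antisymmetry under sample swap
  d2 <- differentialSignal(mut, wt)
  expect_equal(d2$delta, -d$delta)
  expect_error(differentialSignal(wt, mut,
                 regions = data.frame(chrom = "chr1", start = 0,
                                      end = 99999)),
               "outside")
})

test_that("redistribution classes follow the rule table", {
  mk <- function(status, low = FALSE)
    data.frame(region_id = sprintf("r%d", seq_along(status)),
               status = status, low_flag = low)
  cases <- list(
    list(k27 = "down", k9 = "nc", k271 = "up", low = FALSE, cls = "I"),
    list(k27 = "down", k9 = "up", k271 = "nc", low = FALSE, cls = "I"),
    list(k27 = "up", k9 = "down", k271 = "down", low = FALSE, cls = "II"),
    list(k27 = "up", k9 = "nc", k271 = "down", low = TRUE, cls = "III"),
    list(k27 = "up", k9 = "nc", k271 = "down", low = FALSE, cls = "none"),
    list(k27 = "up", k9 = "up", k271 = "down", low = TRUE, cls = "none"),
    list(k27 = "down", k9 = "down", k271 = "nc", low = FALSE,
         cls = "none"),
    list(k27 = "nc", k9 = "down", k271 = "down", low = FALSE,
         cls = "none"))
  for (cs in cases) {
    got <- classifyRedistribution(mk(cs$k27), mk(cs$k9, cs$low),
                                  mk(cs$k271))
    expect_equal(got$class, cs$cls,
                 label = sprintf("(%s,%s,%s,low=%s)", cs$k27, cs$k9,
                                 cs$k271, cs$low))
  }
  # purity: same inputs, same classes; classes mutually exclusive
  st <- sample(c("up", "down", "nc"), 60, replace = TRUE)
  a <- classifyRedistribution(mk(st), mk(rev(st)), mk(st))
  b <- classifyRedistribution(mk(st), mk(rev(st)), mk(st))
  expect_identical(a, b)
  expect_error(classifyRedistribution(mk("up"),
                 data.frame(region_id = "r1", status = "up"), mk("up")),
               "missing mark")
})

test_that("classifier recovers planted classes (exact when noise-free)", {
  run_acc <- function(sigma, seed) {
    cfg <- simulationConfig(sigma_track = sigma, seed = seed)
    lay <- buildGenomeLayout(cfg)
    truth <- applyDdm1Redistribution(lay$truth, cfg)
    tw <- simulateTracks(truth, cfg, "wt")$tracks
    tm <- simulateTracks(truth, cfg, "mut")$tracks
    d <- lapply(c("H3K27me3", "H3K9me2", "H3K27me1"), function(mk)
      differentialSignal(scaleTracks(tw[[mk]]), scaleTracks(tm[[mk]])))
    cls <- classifyRedistribution(d[[1]], d[[2]], d[[3]])
    ch <- truth@classLabel != "none"
    mean(cls$class[ch] == truth@classLabel[ch])
  }
  expect_equal(run_acc(0, 1), 1)
  expect_gte(run_acc(0.2, 1), 0.9)
})

test_that("TE neighborhood density separates gene-rich from gene-poor", {
  cfg <- simulationConfig(seed = 4)
  lay <- buildGenomeLayout(cfg)
  loc <- classifyTeLocation(lay$tes, lay$genes, lay$genome)
  st <- lay$truth@stateWt
  mid_bin <- EpiContact:::.bp_to_global_bin(lay$genome, lay$tes$chrom,
                                            (lay$tes$start + lay$tes$end) / 2)
  in_core <- st[mid_bin] == "const_het"
  expect_gte(mean(loc$location[in_core] == "gene_poor"), 0.95)
  expect_gte(mean(ifelse(in_core, loc$location == "gene_poor",
                         loc$location == "gene_rich")), 0.95)
  # tie rule: identical densities all go to gene_rich
  tes_same <- data.frame(chrom = "chr1", start = c(5e6, 5.1e6),
                         end = c(5.01e6, 5.11e6),
                         id = c("a", "b"))
  loc2 <- classifyTeLocation(tes_same, lay$genes, lay$genome,
                             windowBp = 1e4)
  expect_true(all(loc2$location == "gene_rich"))
})

test_that("superfamily proportions match the textbook two-proportion test", {
  sub <- data.frame(superfamily = c(rep("LTR/Gypsy", 30),
                                    rep("LTR/Copia", 20)))
  gen <- data.frame(superfamily = c(rep("LTR/Gypsy", 100),
                                    rep("LTR/Copia", 300)))
  got <- superfamilyComposition(sub, gen)
  gy <- got[got$superfamily == "LTR/Gypsy", ]
  expect_equal(gy$p_subset, 0.6)
  expect_equal(gy$p_genome, 0.25)
  # hand arithmetic: pooled p = 130/450, z = 0.35 / se
  se <- sqrt((130 / 450) * (1 - 130 / 450) * (1 / 50 + 1 / 400))
  expect_equal(gy$z, 0.35 / se, tolerance = 1e-12)
  # cross-check against the chi-square equivalent (z^2)
  pt <- prop.test(c(30, 100), c(50, 400), correct = FALSE)
  expect_equal(gy$z^2, unname(pt$statistic), tolerance = 1e-10)
  # subset = genome: all z = 0, p = 1
  eq <- superfamilyComposition(gen, gen)
  expect_true(all(eq$z == 0) && all(eq$p_value == 1))
  # size-1 subset: proportions in {0,1}, small-sample warning
  expect_warning(one <- superfamilyComposition(
    data.frame(superfamily = "SINE"), gen), "fewer than 5")
  expect_true(all(one$p_subset %in% c(0, 1)))
  expect_error(superfamilyComposition(gen[0, , drop = FALSE], gen),
               "empty")
})

test_that("region signal matrices rescale and sort as documented", {
  g <- tiny_genome(10, bin_size = 1000)
  tr <- SignalTrack(g, "H3K27me3", c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  # constant track: all entries equal the constant
  cst <- SignalTrack(g, "x", rep(3, 10))
  rs <- regionSignalMatrix(cst, data.frame(chrom = "chr1", start = 0,
                                           end = 8000), K = 4)
  expect_true(all(rs$matrix == 3))
  # 6-bin region, K = 3: exact 2-bin block means
  rs2 <- regionSignalMatrix(tr, data.frame(chrom = "chr1", start = 2000,
                                           end = 8000, id = "r1"), K = 3)
  expect_equal(unname(rs2$matrix[1, ]), c(3.5, 5.5, 7.5))
  # rows sort by descending mean; column means invariant to row order
  regs <- data.frame(chrom = "chr1", start = c(0, 6000),
                     end = c(4000, 10000), id = c("lo", "hi"))
  rs3 <- regionSignalMatrix(tr, regs, K = 2)
  expect_equal(rownames(rs3$matrix), c("hi", "lo"))
  rs4 <- regionSignalMatrix(tr, regs[2:1, ], K = 2)
  expect_equal(rs3$mean_profile, rs4$mean_profile)
  # region shorter than a bin served by its single bin
  rs5 <- regionSignalMatrix(tr, data.frame(chrom = "chr1", start = 2100,
                                           end = 2300), K = 2)
  expect_true(all(rs5$matrix == 3))
})

test_that("expression cross-tabulation fractions sum to one per status", {
  de <- data.frame(gene_id = sprintf("g%02d", 1:12),
                   status = rep(c("up", "nc"), each = 6))
  ms <- data.frame(gene_id = sprintf("g%02d", 1:10),
                   K27me3 = c(rep("down", 4), rep("nc", 6)),
                   DNAme = "nc")
  got <- integrateExpression(de, ms)
  tab <- got$table
  for (st in unique(tab$de_status))
    expect_equal(sum(tab$fraction[tab$de_status == st]), 1,
                 tolerance = 1e-12)
  up <- tab[tab$de_status == "up", ]
  expect_setequal(up$fraction, c(4 / 6, 2 / 6))
  expect_equal(got$unjoined, c("g11", "g12"))
  expect_error(integrateExpression(rbind(de, de[1, ]), ms), "duplicated")
  # all-nc genes collapse to a single full-weight cell
  de2 <- data.frame(gene_id = c("a", "b"), status = "nc")
  ms2 <- data.frame(gene_id = c("a", "b"), K27me3 = "nc")
  expect_equal(integrateExpression(de2, ms2)$table$fraction, 1)
})

test_that("up-regulated genes concentrate in the K27me3-loss cell", {
  cfg <- simulationConfig(seed = 5)
  ds <- simulateDataset(cfg)
  deltas <- lapply(c("H3K27me3", "H3K9me2"), function(mk) {
    d <- differentialSignal(scaleTracks(ds$tracks$wt[[mk]]),
                            scaleTracks(ds$tracks$mut[[mk]]))
    d$status
  })
  mid_bin <- EpiContact:::.bp_to_global_bin(ds$genome, ds$genes$chrom,
                                  (ds$genes$start + ds$genes$end) / 2)
  ms <- data.frame(gene_id = ds$genes$id,
                   K27me3 = deltas[[1]][mid_bin],
                   K9me2 = deltas[[2]][mid_bin])
  got <- integrateExpression(ds$de, ms)
  up <- got$table[got$table$de_status == "up", ]
  modal <- up[which.max(up$n), ]
  expect_equal(modal$K27me3, "down")
})
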