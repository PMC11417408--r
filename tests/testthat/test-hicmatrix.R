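test_that("binPairs bins positions half-open and conserves mass", {
  g <- tiny_genome(10, bin_size = 50000)
  f <- withr::local_tempfile()
  writeLines(c("# pairs format v1.0",
               "r1\tchr1\t100\tchr1\t200\t+\t-",
               "r2\tchr1\t150\tchr1\t120\t+\t-",
               "r3\tchr1\t10\tchr1\t30\t+\t-",
               "r4\tchr1\t49999\tchr1\t50000\t+\t-"), f)
  M <- binPairs(f, g)
  m <- contactMatrix(M, "chr1")
  expect_equal(m[1, 1], 3)         # three pairs inside bin 1
  expect_equal(m[1, 2], 1)         # 49,999 -> bin 0; 50,000 -> bin 1
  expect_equal(m, t(m))

  # count conservation over random pairs
  set.seed(7)
  pos <- matrix(floor(runif(2000, 0, 5e5)), ncol = 2)
  writeLines(sprintf("r%d\tchr1\t%d\tchr1\t%d\t+\t+", seq_len(1000),
                     pos[, 1], pos[, 2]), f)
  M <- binPairs(f, g)
  m <- contactMatrix(M, "chr1")
  expect_equal(sum(m[upper.tri(m, diag = TRUE)]), 1000)

  writeLines(c("r1\tchrX\t5\tchr1\t10\t+\t+"), f)
  expect_error(binPairs(f, g), "chrX")
  writeLines(character(0), f)
  expect_error(binPairs(f, g), "empty")
})

test_that("malformed pair lines are skipped and counted", {
  g <- tiny_genome(10, bin_size = 50000)
  f <- withr::local_tempfile()
  writeLines(c("r1\tchr1\t100\tchr1\t200\t+\t-",
               "garbage line",
               "r2\tchr1\tNOTPOS\tchr1\t10\t+\t-",
               "r3\tchr1\t999999999\tchr1\t10\t+\t-"), f)
  expect_message(M <- binPairs(f, g), "3 malformed")
  expect_equal(attr(M, "n_malformed"), 3)
  expect_equal(sum(contactMatrix(M, "chr1")), 1)
})

test_that("low-coverage masking hits exactly the planted dead bins", {
  set.seed(1)
  n <- 30
  m <- matrix(rpois(n * n, 20), n, n)
  m <- m + t(m); diag(m) <- 0
  dead <- c(3, 11, 17, 22, 29)
  m[dead, ] <- 0; m[, dead] <- 0
  M <- maskLowCoverage(cm_from_matrix(m), minFrac = 0.1)
  expect_equal(which(binMask(M, "chr1")), dead)
  expect_true(all(is.na(contactMatrix(M, "chr1")[dead, ])))

  # minFrac = 0 masks nothing
  M0 <- maskLowCoverage(cm_from_matrix(m), minFrac = 0)
  expect_equal(sum(binMask(M0, "chr1")), 0)

  # an all-zero row is masked at any positive minFrac
  m2 <- matrix(5, 6, 6); diag(m2) <- 0; m2[4, ] <- 0; m2[, 4] <- 0
  expect_true(binMask(maskLowCoverage(cm_from_matrix(m2), 0.01), "chr1")[4])

  # degenerate zero matrix: every bin is dead, which is an error state
  expect_error(maskLowCoverage(cm_from_matrix(matrix(0, 5, 5)), 0.1),
               "all bins masked")
  # but with masking disabled the zero matrix passes through untouched
  expect_equal(sum(binMask(maskLowCoverage(cm_from_matrix(
    matrix(0, 5, 5)), 0), "chr1")), 0)
})

test_that("ICE balancing equalizes marginals and is idempotent", {
  set.seed(42)
  n <- 50
  m <- matrix(runif(n * n, 0.5, 3), n, n)
  m <- (m + t(m)) / 2
  B <- balanceICE(cm_from_matrix(m), tol = 1e-7)
  marg <- rowSums(contactMatrix(B, "chr1"))
  expect_lt(sd(marg) / mean(marg), 1e-4)

  # doubly-stochastic fixed point: unchanged, weights ~ 1
  ds <- matrix(1 / 6, 6, 6)
  B2 <- balanceICE(cm_from_matrix(ds))
  expect_equal(contactMatrix(B2, "chr1"), ds, tolerance = 1e-8)
  expect_equal(unname(balancingWeights(B2, "chr1")), rep(1, 6),
               tolerance = 1e-6)

  # idempotence: re-balancing moves weights by less than tol
  m_bal <- contactMatrix(B, "chr1")
  B3 <- balanceICE(cm_from_matrix(m_bal), tol = 1e-7)
  expect_lt(max(abs(balancingWeights(B3, "chr1") - 1)), 1e-6)

  # diagonal-only matrix converges, off-diagonals stay zero
  dg <- diag(6) * 4
  B4 <- balanceICE(cm_from_matrix(dg))
  expect_true(all(contactMatrix(B4, "chr1")[!diag(6)] == 0))

  expect_error(balanceICE(cm_from_matrix(matrix(0, 4, 4))), "zero total")
})

test_that("expected-by-distance matches hand enumeration and the oracle", {
  m <- matrix(c(0, 2, 4, 8,
                2, 0, 2, 4,
                4, 2, 0, 2,
                8, 4, 2, 0), 4, 4, byrow = TRUE)
  E <- expectedByDistance(cm_from_matrix(m))
  expect_equal(E$E$chr1, c(2, 4, 8))

  # constant matrix
  Ec <- expectedByDistance(cm_from_matrix(matrix(3, 5, 5)))
  expect_equal(Ec$E$chr1, rep(3, 4))

  # random matrices vs exhaustive oracle, with and without a mask
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    r <- matrix(runif(n * n), n, n); r <- r + t(r)
    M <- cm_from_matrix(r)
    expect_equal(expectedByDistance(M)$E$chr1, oracle_expected(r))
    mask <- rep(FALSE, n); mask[sample(n, 1)] <- TRUE
    rm <- r; rm[mask, ] <- NA; rm[, mask] <- NA
    Mm <- ContactMatrix(tiny_genome(n), list(chr1 = rm),
                        mask = list(chr1 = mask))
    expect_equal(expectedByDistance(Mm)$E$chr1, oracle_expected(r, mask))
  }
})

test_that("O/E has unit per-diagonal means and honors the 4x4 example", {
  m <- matrix(c(0, 2, 4, 8,
                2, 0, 2, 4,
                4, 2, 0, 2,
                8, 4, 2, 0), 4, 4, byrow = TRUE)
  OE <- observedOverExpected(cm_from_matrix(m))
  expect_equal(contactMatrix(OE, "chr1")[1, 4], 1)  # 8 / E(3) = 8/8

  cfg <- simulationConfig(n_chrom = 1, chrom_len = 2e6, seed = 3)
  lay <- buildGenomeLayout(cfg)
  truth <- applyDdm1Redistribution(lay$truth, cfg)
  OE2 <- observedOverExpected(simulateContacts(truth, cfg, "wt"))
  mo <- contactMatrix(OE2, "chr1")
  n <- nrow(mo)
  for (d in c(1, 2, 5, 17, n - 1)) {
    i <- seq_len(n - d)
    expect_equal(mean(mo[cbind(i, i + d)]), 1, tolerance = 1e-9)
  }
  expect_identical(matrixStage(OE2), "oe")
  # matrix equal to its own expectation -> OE of 1 off-diagonal
  cst <- matrix(5, 6, 6)
  OEc <- observedOverExpected(cm_from_matrix(cst))
  off <- abs(row(cst) - col(cst)) > 0
  expect_true(all(contactMatrix(OEc, "chr1")[off] == 1))
})

test_that("Pearson map is symmetric with unit diagonal and resolves blocks", {
  oe <- block_matrix(5, 5, within = 2, across = 0.5)
  C <- pearsonMap(cm_from_matrix(oe, stage = "oe"))
  cm <- contactMatrix(C, "chr1")
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), rep(1, 10))
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(cm[1, 3], 1)    # same block
  expect_equal(cm[1, 8], -1)   # across blocks
  expect_error(pearsonMap(cm_from_matrix(oe)), "stage")
  few <- ContactMatrix(tiny_genome(4), list(chr1 = block_matrix(2, 2)),
                       stage = "oe",
                       mask = list(chr1 = c(FALSE, FALSE, TRUE, TRUE)))
  expect_error(pearsonMap(few), "fewer than 3")
})

test_that("stages only move forward", {
  m <- block_matrix(3, 3)
  OE <- observedOverExpected(cm_from_matrix(m))
  expect_error(observedOverExpected(OE), "stage")
  expect_error(balanceICE(OE), "stage")
  C <- pearsonMap(OE)
  expect_error(pearsonMap(C), "stage")
})

test_that("COO round trip reproduces the matrix and the bin frame", {
  cfg <- simulationConfig(n_chrom = 2, chrom_len = 1.5e6, seed = 5)
  lay <- buildGenomeLayout(cfg)
  truth <- applyDdm1Redistribution(lay$truth, cfg)
  M <- simulateContacts(truth, cfg, "wt")
  d <- withr::local_tempdir()
  writeContactMatrixCOO(M, file.path(d, "m.coo.tsv"),
                        file.path(d, "bins.tsv"))
  # format contract: upper triangle only, 0-based half-open bins
  coo <- read.table(file.path(d, "m.coo.tsv"), header = TRUE)
  expect_true(all(coo$bin1_id <= coo$bin2_id))
  bt <- read.table(file.path(d, "bins.tsv"), header = TRUE)
  expect_equal(bt$start[1], 0)
  expect_equal(max(bt$end[bt$chrom == "chr1"]), 1.5e6)
  M2 <- readContactMatrixCOO(file.path(d, "m.coo.tsv"),
                             file.path(d, "bins.tsv"))
  expect_equal(M2@matrices, M@matrices)
  expect_equal(chromLengths(genomeOf(M2)), chromLengths(genomeOf(M)))
})
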