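#' Default pipeline configuration
#'
#' Per-stage parameter sections with the package defaults; any subset
#' can be overridden through `runPipeline(config = ...)` or a YAML file
#' with the same structure.
#'
#' @return nested list of stage parameters.
#' @export
pipelineDefaults <- function() {
  list(
    seed = 1L,
    genotypes = c("wt", "mut"),
    stages = c("simulate", "balance", "compartments", "saddle", "pentad",
               "sortmap", "insulation", "boundaries", "ata", "apa",
               "diffint", "marks"),
    sim = list(),
    mask = list(min_frac = 0),
    balance = list(tol = 1e-5, max_iter = 200),
    compartments = list(orientation = "H3K9ac"),
    saddle = list(Q = 5, corner_frac = 0.2, d_min = 2),
    sortmap = list(track = "H3K27me3", n_groups = 10),
    insulation = list(window = 4, delta = 0.2),
    ata = list(k = 30),
    apa = list(w = 5, d_min = 10, d_max = 100),
    diffint = list(d_max = 100, bands = 8, eps = 0.01, z_thresh = 1.96),
    marks = list(t_up = 0.5, t_down = -0.5, pseudo = 0.1))
}

.merge_config <- function(defaults, override) {
  for (k in names(override)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(override[[k]]))
      .merge_config(defaults[[k]], override[[k]]) else override[[k]]
  }
  defaults
}

.validate_config <- function(cfg) {
  stopifnot(cfg$mask$min_frac >= 0, cfg$mask$min_frac <= 1,
            cfg$balance$tol > 0, cfg$balance$max_iter >= 1,
            cfg$saddle$Q >= 2,
            cfg$saddle$corner_frac > 0, cfg$saddle$corner_frac <= 0.5,
            cfg$insulation$window >= 1, cfg$insulation$delta >= 0,
            cfg$ata$k >= 2, cfg$apa$w >= 2,
            cfg$diffint$eps > 0, cfg$diffint$bands >= 1)
  if ("diffint" %in% cfg$stages && !("mut" %in% cfg$genotypes))
    stop("stage 'diffint' requires the mutant genotype in `genotypes`")
  invisible(cfg)
}

# parameter-hash cache under <outdir>/cache; key is the md5 of the
# serialized (stage, params) pair
.cache_path <- function(outdir, stage, params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(stage = stage, params = params), tmp)
  key <- unname(tools::md5sum(tmp))
  file.path(outdir, "cache", sprintf("%s_%s.rds", stage, key))
}

.cached <- function(outdir, stage, params, fn, log) {
  if (is.null(outdir)) return(fn())
  p <- .cache_path(outdir, stage, params)
  if (file.exists(p)) {
    log(sprintf("stage %s: cache hit (%s)", stage, basename(p)))
    return(readRDS(p))
  }
  val <- fn()
  dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
  saveRDS(val, p)
  val
}

#' Run the full analysis pipeline on a simulated WT / mutant pair
#'
#' Simulates a matched dataset, normalizes both contact maps (mask,
#' ICE, O/E, Pearson), calls compartments, computes saddle strength and
#' pentad category means, the H3K27me3-sorted segregation score,
#' insulation profiles with WT boundary calls applied to both genotypes,
#' aggregate TAD and anchor-pair maps, distance-stratified differential
#' interactions and the mark-redistribution classification, and returns
#' a machine-readable summary.  Stage results are cached under
#' `<outdir>/cache`, keyed by a hash of each stage's parameters, so an
#' unchanged re-run reuses them; the summary JSON is written to
#' `<outdir>/summary.json`.
#'
#' @param config nested list overriding [pipelineDefaults()], or a path
#'   to a YAML file with the same structure.
#' @param outdir optional output directory (enables caching and the
#'   JSON summary on disk).
#' @param quiet suppress progress logging to stderr.
#' @return the summary as a named list (invisibly also written as
#'   JSON when `outdir` is set).
#' @export
runPipeline <- function(config = list(), outdir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .validate_config(.merge_config(pipelineDefaults(), config))
  log <- function(msg) if (!quiet)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sim_cfg <- do.call(simulationConfig,
                     c(cfg$sim, if (is.null(cfg$sim$seed))
                       list(seed = cfg$seed)))
  log("stage simulate: generating matched WT/mutant dataset")
  ds <- .cached(outdir, "simulate", sim_cfg, function()
    simulateDataset(sim_cfg), log)

  genos <- cfg$genotypes
  oe <- list(); pear <- list(); bal <- list()
  for (g in genos) {
    log(sprintf("stage balance/oe/pearson: %s", g))
    norm <- .cached(outdir, paste0("normalize_", g),
                    list(sim_cfg, cfg$mask, cfg$balance), function() {
      M <- ds$contacts[[g]]
      if (cfg$mask$min_frac > 0) M <- maskLowCoverage(M, cfg$mask$min_frac)
      b <- balanceICE(M, tol = cfg$balance$tol,
                      maxIter = cfg$balance$max_iter)
      o <- observedOverExpected(b)
      list(balanced = b, oe = o, pearson = pearsonMap(o))
    }, log)
    bal[[g]] <- norm$balanced; oe[[g]] <- norm$oe; pear[[g]] <- norm$pearson
  }

  report <- list(seed = cfg$seed, genotypes = genos)
  orientation <- ds$tracks$wt[[cfg$compartments$orientation]]
  calls <- list()
  for (g in genos) {
    calls[[g]] <- callCompartments(pear[[g]], orientation)
    sad <- saddleStrength(oe[[g]], calls[[g]], Q = cfg$saddle$Q,
                          cornerFrac = cfg$saddle$corner_frac,
                          dMin = cfg$saddle$d_min)
    pen <- compartmentPentad(oe[[g]], calls[[g]], dMin = cfg$saddle$d_min)
    srt <- featureSortedMap(pear[[g]], ds$tracks[[g]][[cfg$sortmap$track]],
                            nGroups = cfg$sortmap$n_groups)
    report[[paste0("strength_", g)]] <- sad$strength
    report[[paste0("pentad_", g)]] <- as.list(pen$means)
    report[[paste0("segregation_score_", g)]] <- srt$score
    tl <- calls[[g]]@label
    truth_ok <- tl != "masked"
    report[[paste0("compartment_agreement_", g)]] <-
      mean((tl == ds$truth@compartmentLabel)[truth_ok])
  }

  log("stage insulation/boundaries/ata")
  prof <- lapply(genos, function(g)
    insulationProfile(bal[[g]], w = cfg$insulation$window))
  names(prof) <- genos
  wt_bounds <- callBoundaries(prof$wt, delta = cfg$insulation$delta)
  report$n_boundaries_wt <- nrow(wt_bounds$boundaries)
  for (g in genos) {
    bsm <- boundarySignalMatrix(prof[[g]], wt_bounds$boundaries,
                                flankBins = cfg$insulation$window)
    p <- bsm$mean_profile
    report[[paste0("insulation_dip_", g)]] <-
      mean(p[c(1, length(p))]) - p[(length(p) + 1) / 2]
  }
  if (all(c("wt", "mut") %in% genos)) {
    ata <- lapply(genos, function(g)
      aggregateTads(oe[[g]], ds$truth@domains, K = cfg$ata$k))
    names(ata) <- genos
    dif <- diffAggregate(ata$wt, ata$mut)
    ctr <- seq(cfg$ata$k / 3 + 1, 2 * cfg$ata$k / 3)
    for (g in genos)
      report[[paste0("ata_central_", g)]] <-
        mean(ata[[g]]$map[ctr, ctr], na.rm = TRUE)
    report$ata_central_diff <- mean(dif$map[ctr, ctr], na.rm = TRUE)
  }

  log("stage apa/diffint")
  sets <- anchorBinSets(ds$truth)
  for (g in genos) {
    apa <- aggregateAnchorPairs(oe[[g]], sets$shared, sets$shared,
                                W = cfg$apa$w,
                                dRange = c(cfg$apa$d_min, cfg$apa$d_max))
    report[[paste0("apa_enrichment_", g)]] <- apa$enrichment
  }
  if (all(c("wt", "mut") %in% genos)) {
    di <- differentialInteractions(oe$wt, oe$mut,
                                   dMax = cfg$diffint$d_max,
                                   bands = cfg$diffint$bands,
                                   eps = cfg$diffint$eps)
    report$n_diff_interactions <-
      sum(abs(di$z) > cfg$diffint$z_thresh)
    report$frac_z_above_1.96 <- mean(abs(di$z) > 1.96)
  }

  log("stage marks: differential + classification")
  if (all(c("wt", "mut") %in% genos)) {
    cls_marks <- c("H3K27me3", "H3K9me2", "H3K27me1")
    deltas <- lapply(cls_marks, function(mk)
      differentialSignal(scaleTracks(ds$tracks$wt[[mk]]),
                         scaleTracks(ds$tracks$mut[[mk]]),
                         tUp = cfg$marks$t_up, tDown = cfg$marks$t_down,
                         pseudo = cfg$marks$pseudo))
    names(deltas) <- cls_marks
    cls <- classifyRedistribution(deltas$H3K27me3, deltas$H3K9me2,
                                  deltas$H3K27me1)
    for (k in c("I", "II", "III"))
      report[[paste0("n_class_", k)]] <- sum(cls$class == k)
    changed <- ds$truth@classLabel != "none"
    report$class_agreement_changed <-
      mean(cls$class[changed] == ds$truth@classLabel[changed])
  }

  if (!is.null(outdir)) {
    jsonlite::write_json(report, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log(sprintf("summary written to %s", file.path(outdir, "summary.json")))
  }
  report
}
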