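## Reproducible drivers for the simulation experiments.  Each driver takes
## a single master seed, derives per-run seeds deterministically, and
## returns plain data.frames / lists stamped with the seeds used.  Default
## chain lengths and repeat counts are scaled to desk-size runs; pass
## `full = TRUE` for the long versions.

#' Chain settings used by the experiment drivers
#' @noRd
.expChain <- function(full) {
  if (full) list(nSamples = 20000L, burnIn = 5000L)
  else list(nSamples = 4000L, burnIn = 1500L)
}

#' Posterior-distribution experiment on one high-SNR dataset
#'
#' Simulates `nVoxels` voxels at the default ground truth, averages them
#' (SNR ~ snrVox * sqrt(N)) and fits both the real-valued variant
#' (parameters ODI, dPar, c) and the magnitude variant (plus epsilon,
#' with both noise parameters constrained to a band around pure-noise
#' priors).  Returns the posterior samples for pair plots, the model-fit
#' residual summaries, and all seeds.
#'
#' @param nVoxels voxels to average (default 100, SNR ~ 165)
#' @param seed master seed
#' @param config optional [SimulationConfig-class] override
#' @param full use the long chains
#' @param chain optional list(nSamples, burnIn) overriding the chain
#'   lengths
#' @return list with `real` and `magnitude` ([PosteriorSamples-class]),
#'   `residuals` (data.frame per kind), `truth`, `seed`
#' @export
runPosteriorExperiment <- function(nVoxels = 100L, seed = 1L, config = NULL,
                                   full = FALSE, chain = NULL) {
  if (is.null(config))
    config <- SimulationConfig(nVoxels = nVoxels, seed = seed)
  ch <- if (is.null(chain)) .expChain(full) else chain
  sim <- simulateVoxels(config)
  orient <- FibreOrientation(config@theta, config@phi)
  avgR <- averageVoxels(sim$real)
  avgM <- averageVoxels(sim$magnitude)
  prior <- NoiseParams(c = config@c, epsilon = sim$sigma, sigma = sim$sigma)
  cfgR <- FitConfig("real", nSamples = ch$nSamples, burnIn = ch$burnIn,
                    seed = seed + 1000L)
  cfgM <- FitConfig("magnitude", nSamples = ch$nSamples, burnIn = ch$burnIn,
                    seed = seed + 2000L, noiseConstraint = "band",
                    priorNoise = prior)
  fitR <- mhFit(avgR, orient, cfgR)
  fitM <- mhFit(avgM, orient, cfgM)
  resid <- function(ds, ps, rician) {
    s <- posteriorSummary(ps)
    m <- setNames(s$mean, s$parameter)
    cfg <- FitConfig(dataKind(ds), minB = 3)
    ctx <- .fitContext(ds, orient, cfg)
    eps <- if ("epsilon" %in% names(m)) m[["epsilon"]] else 0
    sbar <- .sbarAt(ctx, m[["c"]], eps, rician)
    pred <- sbar[ctx$shell0 + 1L] *
      exp(.logStickRatio(.kappaOf(m[["odi"]]), ctx$b * m[["dPar"]], ctx$ct2)) /
      powderAverageModel(ctx$b, m[["dPar"]]) + m[["c"]]
    if (rician) pred <- sqrt(pred^2 + eps^2)
    data.frame(rmse = sqrt(mean((pred - ctx$Y)^2)),
               maxAbs = max(abs(pred - ctx$Y)),
               meanSignal = mean(ctx$Y))
  }
  list(real = fitR, magnitude = fitM,
       residuals = rbind(cbind(kind = "real", resid(avgR, fitR, FALSE)),
                         cbind(kind = "magnitude", resid(avgM, fitM, TRUE))),
       truth = config, seed = seed)
}

#' Precision and accuracy of the fit as a function of SNR
#'
#' For each voxel count N the ground-truth dataset is re-simulated with
#' fresh noise (`repeats` times, noise re-drawn only), averaged and
#' fitted; posterior means and stds of every parameter are tabulated.
#' SNR ~ snrVox * sqrt(N), so the default grid spans ~16.5 to ~520.
#'
#' @param nValues voxel counts to average over
#' @param repeats noise re-draws per N
#' @param kinds data kinds to fit
#' @param seed master seed
#' @param full long chains and the 20-repeat version
#' @param chain optional list(nSamples, burnIn) override
#' @param csvPath optional path to also write the table as CSV
#' @return data.frame: kind, N, repeat index, seed, posterior mean/std per
#'   parameter and the odi-dPar posterior correlation
#' @export
runSnrSweep <- function(nValues = c(1L, 25L, 100L, 400L, 1000L),
                        repeats = 5L, kinds = c("real", "magnitude"),
                        seed = 1L, full = FALSE, csvPath = NULL,
                        chain = NULL) {
  if (full) repeats <- max(repeats, 20L)
  ch <- if (is.null(chain)) .expChain(full) else chain
  rows <- list()
  for (N in nValues) {
    for (r in seq_len(repeats)) {
      simSeed <- seed + 131L * as.integer(N) + r
      config <- SimulationConfig(nVoxels = as.integer(N), seed = simSeed)
      sim <- simulateVoxels(config)
      orient <- FibreOrientation(config@theta, config@phi)
      prior <- NoiseParams(c = config@c, epsilon = sim$sigma,
                           sigma = sim$sigma)
      for (kind in kinds) {
        ds <- averageVoxels(if (kind == "real") sim$real else sim$magnitude)
        cfg <- if (kind == "real")
          FitConfig("real", nSamples = ch$nSamples, burnIn = ch$burnIn,
                    seed = simSeed + 7L)
        else
          FitConfig("magnitude", nSamples = ch$nSamples, burnIn = ch$burnIn,
                    seed = simSeed + 8L, noiseConstraint = "band",
                    priorNoise = prior)
        ps <- mhFit(ds, orient, cfg)
        s <- posteriorSummary(ps)
        row <- data.frame(kind = kind, N = N, rep = r, seed = simSeed,
                          snr = snrOfAverage(config@snrVox, N),
                          odi_dPar_corr = posteriorCorrelation(ps))
        for (p in s$parameter) {
          row[[paste0(p, "_mean")]] <- s$mean[s$parameter == p]
          row[[paste0(p, "_std")]] <- s$std[s$parameter == p]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  allCols <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(allCols, names(r))] <- NA_real_
    r[allCols]
  }))
  if (!is.null(csvPath)) write.table(out, csvPath, sep = ",",
                                     row.names = FALSE, quote = FALSE)
  out
}

#' Bias from misspecified noise parameters
#'
#' Two sweeps mirroring the misspecification experiment: (a) real-valued
#' data simulated with offset c = 10, fitted with the offset clamped to
#' each value in `cValues`; (b) magnitude data simulated with c = 0,
#' fitted with the noise floor clamped to each value in `epsFactors *
#' sigma` (0 = assume Gaussian noise).  A third single run fits the
#' Rician-family model (epsilon free) to the real-valued data, where the
#' floor should collapse toward zero.
#'
#' @param nVoxels voxels averaged (default 100, SNR ~ 165)
#' @param cValues assumed offsets for sweep (a); truth is 10
#' @param epsFactors assumed floors for sweep (b), as multiples of the
#'   generating complex-noise std
#' @param seed master seed
#' @param full long chains
#' @param chain optional list(nSamples, burnIn) override
#' @return list of data.frames `offsetSweep`, `floorSweep`,
#'   `realWithRician`, plus `sigma` and `seed`
#' @export
runMisspecificationSweep <- function(nVoxels = 100L,
                                     cValues = c(0, 5, 8, 10, 12, 15, 20),
                                     epsFactors = c(0, 0.5, 0.8, 1, 1.2, 1.5),
                                     seed = 1L, full = FALSE, chain = NULL) {
  ch <- if (is.null(chain)) .expChain(full) else chain
  orient <- FibreOrientation(0, 0)
  # (a) real-valued data with c = 10, fixed-offset fits
  cfgA <- SimulationConfig(nVoxels = nVoxels, seed = seed)
  simA <- simulateVoxels(cfgA)
  dsA <- averageVoxels(simA$real)
  fitCfgA <- FitConfig("real", nSamples = ch$nSamples, burnIn = ch$burnIn,
                       seed = seed + 11L)
  offsetSweep <- fixedNoiseSweep(dsA, orient, "c", cValues, fitCfgA)
  # (b) magnitude data with c = 0, fixed-floor fits (c clamped at 0 too,
  # matching the single-noise-parameter convention)
  cfgB <- SimulationConfig(nVoxels = nVoxels, seed = seed + 1L, c = 0)
  simB <- simulateVoxels(cfgB)
  dsB <- averageVoxels(simB$magnitude)
  fitCfgB <- FitConfig("magnitude", nSamples = ch$nSamples,
                       burnIn = ch$burnIn, seed = seed + 12L)
  floorSweep <- fixedNoiseSweep(dsB, orient, "epsilon",
                                epsFactors * simB$sigma, fitCfgB,
                                other = "zero")
  floorSweep$epsFactor <- epsFactors
  # (c) Rician family on real-valued data: epsilon should collapse to 0
  fitCfgC <- FitConfig("real", nSamples = ch$nSamples, burnIn = ch$burnIn,
                       seed = seed + 13L, epsilonFree = TRUE)
  psC <- mhFit(dsA, orient, fitCfgC)
  sC <- posteriorSummary(psC)
  list(offsetSweep = offsetSweep, floorSweep = floorSweep,
       realWithRician = sC, sigma = simA$sigma, seed = seed)
}

#' Parameter-recovery experiment at the default ground truth
#'
#' The headline simulation check: `nSeeds` independent datasets of
#' `nVoxels` voxels at the default ground truth (dPar = 2.2 um^2/ms,
#' ODI = 0.03, c = 10, SNRvox = 16.5), each averaged and fitted to the
#' real-valued variant; reports per-seed posterior means and the
#' across-seed means, to compare against the generating values.
#'
#' @param nSeeds independent simulation/fit repeats
#' @param nVoxels voxels averaged per repeat
#' @param seed master seed
#' @param full long chains
#' @param chain optional list(nSamples, burnIn) override
#' @return list with `perSeed` (data.frame) and `means` (named vector of
#'   across-seed mean posterior means)
#' @export
runRecoveryExperiment <- function(nSeeds = 10L, nVoxels = 100L, seed = 1L,
                                  full = FALSE, chain = NULL) {
  ch <- if (is.null(chain)) .expChain(full) else chain
  rows <- lapply(seq_len(nSeeds), function(i) {
    simSeed <- seed + 977L * i
    config <- SimulationConfig(nVoxels = nVoxels, seed = simSeed)
    sim <- simulateVoxels(config)
    ds <- averageVoxels(sim$real)
    cfg <- FitConfig("real", nSamples = ch$nSamples, burnIn = ch$burnIn,
                     seed = simSeed + 1L)
    ps <- mhFit(ds, FibreOrientation(config@theta, config@phi), cfg)
    s <- posteriorSummary(ps)
    data.frame(seed = simSeed,
               dPar = s$mean[s$parameter == "dPar"],
               odi = s$mean[s$parameter == "odi"],
               c = s$mean[s$parameter == "c"],
               dPar_std = s$std[s$parameter == "dPar"])
  })
  perSeed <- do.call(rbind, rows)
  list(perSeed = perSeed,
       means = c(dPar = mean(perSeed$dPar), odi = mean(perSeed$odi),
                 c = mean(perSeed$c)),
       seed = seed)
}
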