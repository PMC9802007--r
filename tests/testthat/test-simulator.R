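test_that("scheme construction: counts, determinism, uniformity, antipodal invariance", {
  cfg <- SimulationConfig(seed = 3)
  sch <- makeScheme(cfg)
  expect_equal(sum(bValues(sch) > 0), 3 * 64)
  expect_equal(sum(bValues(sch) == 0), 6)
  expect_identical(makeScheme(cfg), makeScheme(SimulationConfig(seed = 3)))
  # per-shell first spherical moment close to zero
  for (s in unique(shellIds(sch)[bValues(sch) > 0])) {
    g <- gradients(sch)[shellIds(sch) == s, ]
    expect_lt(sqrt(sum(colSums(g)^2)) / nrow(g), 0.1)
  }
  # duplicating a direction set antipodally leaves every prediction unchanged
  w <- bValues(sch) > 0
  schDup <- AcquisitionScheme(c(bValues(sch)[w], bValues(sch)[w]),
                              rbind(gradients(sch)[w, ], -gradients(sch)[w, ]))
  p <- groundTruthParams(cfg)
  pred <- predictSignalFull(p, schDup)
  V <- sum(w)
  expect_equal(pred[seq_len(V)], pred[V + seq_len(V)])
})

test_that("simulated voxels: noise structure, matched draws, SNR definition", {
  cfg <- SimulationConfig(nVoxels = 50, seed = 12)
  sim <- simulateVoxels(cfg)
  expect_identical(signalMatrix(simulateVoxels(cfg)$magnitude),
                   signalMatrix(sim$magnitude))
  # magnitude and real channels share the underlying complex draws
  expect_true(all(signalMatrix(sim$magnitude) >= abs(signalMatrix(sim$real)) - 1e-12))
  expect_equal(sim$sigma, 100 / 16.5)
  # empirical S0/sigma from the real-channel b0 volumes
  b0 <- bValues(sim$scheme) == 0
  resid <- signalMatrix(sim$real)[, b0] - (100 + cfg@c)
  empSigma <- sd(as.numeric(resid))
  n <- length(resid)
  expect_lt(abs(empSigma - sim$sigma), 4 * sim$sigma / sqrt(2 * n))
  # noiseless limit: both kinds collapse onto signal + offset
  hi <- simulateVoxels(SimulationConfig(nVoxels = 2, seed = 12, snrVox = 1e9))
  expect_equal(signalMatrix(hi$real)[1, ], hi$noiseless, tolerance = 1e-6)
  expect_equal(signalMatrix(hi$magnitude)[1, ], hi$noiseless, tolerance = 1e-6)
})

test_that("pure-noise magnitude volumes follow the Rayleigh/Rician law", {
  cfgN <- SimulationConfig(nVoxels = 60, seed = 7, fIn = 0, c = 0)
  sim <- simulateVoxels(cfgN)
  w <- bValues(sim$scheme) > 0   # zero signal there (F = 0, c = 0)
  y <- as.numeric(signalMatrix(sim$magnitude)[, w])
  y <- y[seq_len(10000)]
  # Rayleigh mean sigma * sqrt(pi / 2)
  expect_equal(mean(y), sim$sigma * sqrt(pi / 2),
               tolerance = 4 * sd(y) / sqrt(length(y)) / mean(y))
  # Kolmogorov-Smirnov against the fitted Rician
  fit <- fitPureNoise(y, "rician")
  ks <- suppressWarnings(
    ks.test(y, function(q) pRician(q, fit$estimate["c"],
                                   fit$estimate["epsilon"])))
  expect_gt(ks$p.value, 0.01)
})

test_that("voxel averaging: identity at n = 1, sqrt(n) noise reduction, Jensen", {
  cfg <- SimulationConfig(nVoxels = 100, seed = 9)
  sim <- simulateVoxels(cfg)
  one <- averageVoxels(sim$real, 1)
  expect_equal(signalMatrix(one)[1, ], signalMatrix(sim$real)[1, ])
  avg <- averageVoxels(sim$real, 100)
  expect_equal(nVoxels(avg), 1)
  # residual std around the noiseless signal shrinks ~ sqrt(100)
  resid1 <- signalMatrix(sim$real) -
    matrix(sim$noiseless, 100, length(sim$noiseless), byrow = TRUE)
  residAvg <- signalMatrix(avg)[1, ] - sim$noiseless
  ratio <- sd(as.numeric(resid1)) / sd(residAvg)
  expect_gt(ratio, 7); expect_lt(ratio, 14)
  # Jensen: averaged magnitude keeps the noise floor that the magnitude of
  # the averaged complex signal would not have
  cfg0 <- SimulationConfig(nVoxels = 400, seed = 10, fIn = 0, c = 0)
  sim0 <- simulateVoxels(cfg0)
  w <- bValues(sim0$scheme) > 0
  avgMag <- colMeans(signalMatrix(sim0$magnitude)[, w])      # -> sigma sqrt(pi/2)
  magAvgRe <- colMeans(signalMatrix(sim0$real)[, w])          # -> 0
  expect_gt(mean(avgMag), 5 * abs(mean(magAvgRe)))
})

test_that("concatenation with rotation aligns axes and preserves recovery", {
  # voxels with different fibre axes, rotated into a common frame
  cfgBase <- SimulationConfig(nVoxels = 1, seed = 20, snrVox = 60)
  axes <- list(FibreOrientation(0.3, 1.0), FibreOrientation(1.2, -0.5),
               FibreOrientation(0.8, 2.2), FibreOrientation(0.1, 0))
  dss <- lapply(seq_along(axes), function(i) {
    cfg <- SimulationConfig(nVoxels = 1, seed = 20 + i, snrVox = 60,
                            theta = axes[[i]]@theta, phi = axes[[i]]@phi)
    simulateVoxels(cfg)$real
  })
  cat1 <- concatenateWithRotation(dss, axes, seed = 5)
  expect_equal(nVoxels(cat1), 1)
  g <- gradients(acquisitionScheme(cat1))
  w <- bValues(acquisitionScheme(cat1)) > 0
  expect_equal(sqrt(rowSums(g[w, ]^2)), rep(1, sum(w)), tolerance = 1e-9)
  expect_error(concatenateWithRotation(dss, list(FibreOrientation(0, 0),
    axes[[2]], axes[[3]], new("FibreOrientation", theta = 0, phi = 0,
                              mu = c(0, 0, 1.5)))), "unit")
  # after rotation the common fibre axis is +z: a fit with mu = z recovers
  # dPar consistently for 6 vs 12 concatenated voxels
  mkcat <- function(n, seedOff) {
    axs <- lapply(seq_len(n), function(i)
      FibreOrientation(runif(1, 0, pi / 2), runif(1, -pi, pi)))
    ds <- lapply(seq_len(n), function(i) {
      a <- axs[[i]]
      simulateVoxels(SimulationConfig(nVoxels = 1, seed = seedOff + i,
                                      snrVox = 40, theta = a@theta,
                                      phi = a@phi))$real
    })
    concatenateWithRotation(ds, axs, seed = seedOff)
  }
  set.seed(77)
  fitOf <- function(ds, seed) {
    ps <- mhFit(ds, FibreOrientation(0, 0),
                FitConfig("real", nSamples = 1500, burnIn = 600, seed = seed))
    s <- posteriorSummary(ps)
    c(mean = s$mean[s$parameter == "dPar"], std = s$std[s$parameter == "dPar"])
  }
  fA <- fitOf(mkcat(6, 300), 1)
  fB <- fitOf(mkcat(12, 400), 2)
  expect_lt(abs(fA["mean"] - fB["mean"]),
            3 * sqrt(fA["std"]^2 + fB["std"]^2) + 0.05)
})
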