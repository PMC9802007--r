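test_that("tensor fit: isotropic, stick, closed-form FA", {
  # isotropic mono-exponential signal
  sch <- makeScheme(SimulationConfig(shells = c(0.3, 1), nDir = 16L,
                                     nB0 = 4L, seed = 2))
  yIso <- 100 * exp(-bValues(sch) * 0.8)
  iso <- dtiFit(VoxelDataset(yIso, "real", 100, sch))
  expect_lt(iso$FA[1], 1e-6)
  expect_equal(iso$MD[1], 0.8, tolerance = 1e-9)
  # prolate tensor with principal axis along x: analytic signal, closed-form FA
  lam <- c(2.2, 0.2, 0.2)
  D <- diag(lam)
  g <- gradients(sch)
  yTen <- 100 * exp(-bValues(sch) * rowSums((g %*% D) * g))
  fit <- dtiFit(VoxelDataset(yTen, "real", 100, sch))
  expect_equal(abs(fit$V1[1, 1]), 1, tolerance = 1e-6)
  faRef <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(fit$FA[1], faRef, tolerance = 1e-9)
  expect_equal(fit$S0[1], 100, tolerance = 1e-9)
  # too few volumes rejected
  schTiny <- AcquisitionScheme(c(0, 1, 1), rbind(0, c(1, 0, 0), c(0, 1, 0)))
  expect_error(dtiFit(VoxelDataset(c(100, 40, 40), "real", 100, schTiny)),
               "7 volumes")
})

test_that("voxel selection by FA and S0 window", {
  fa <- c(0.9, 0.9, 0.9, 0.5, 0.9, 0.9, 0.2, 0.9, 0.9, 0.9)
  s0 <- c(100, 100, 100, 100, 100, 100, 100, 100, 100, 100)
  # equal S0: FA threshold alone decides
  expect_identical(selectVoxels(fa, s0, faThreshold = 0.7),
                   c(1L, 2L, 3L, 5L, 6L, 8L, 9L, 10L))
  # closed interval: S0 exactly at 1.1 * mean is kept
  fa2 <- rep(0.9, 5)
  s02 <- c(100, 100, 100, 100, 100)
  s02[5] <- 1.1 * mean(s02) / (1 + 0.1 * 0.2)  # still inside after mean shift
  expect_true(5L %in% selectVoxels(fa2, s02))
  # hand-enumerated toy: FA >= 0.7 AND S0 within +/-10% of masked mean
  fa3 <- c(0.8, 0.9, 0.6, 0.95, 0.75, 0.9, 0.3, 0.85, 0.9, 0.7)
  s03 <- c(100, 150, 100, 101, 99, 55, 100, 100, 160, 100)
  # masked mean = 106.5; window [95.85, 117.15]; FA rule drops 3, 7
  expect_identical(selectVoxels(fa3, s03), c(1L, 4L, 5L, 8L, 10L))
  expect_error(selectVoxels(fa3, s03, mask = integer(0)), "empty mask")
  expect_warning(selectVoxels(fa3, s03, faThreshold = 0.99), "no voxels")
})

test_that("MH sampler reproduces an analytic Gaussian posterior", {
  # quadratic toy log-likelihood: posterior N(mu, Sigma), wide bounds
  mu <- c(1.5, -0.5)
  prec <- matrix(c(4, 1, 1, 2), 2, 2)
  logPost <- function(p) -0.5 * as.numeric(t(p - mu) %*% prec %*% (p - mu))
  res <- mhSample(logPost, init = c(a = 0, b = 0), lower = c(-20, -20),
                  upper = c(20, 20), scale = c(0.5, 0.5),
                  nSamples = 20000L, burnIn = 3000L, seed = 4)
  Sigma <- solve(prec)
  m <- colMeans(res$draws)
  s <- apply(res$draws, 2, sd)
  # MC error allowance accounts for chain autocorrelation (~x5 iid)
  expect_lt(abs(m[1] - mu[1]), 5 * sqrt(Sigma[1, 1] / 20000) * 5)
  expect_lt(abs(m[2] - mu[2]), 5 * sqrt(Sigma[2, 2] / 20000) * 5)
  expect_equal(unname(s[1]), sqrt(Sigma[1, 1]), tolerance = 0.05)
  expect_equal(unname(s[2]), sqrt(Sigma[2, 2]), tolerance = 0.05)
  expect_true(all(res$acceptance > 0.1 & res$acceptance < 0.7))
  # bounds respected by rejection
  resB <- mhSample(logPost, init = c(a = 1.5, b = 0.2), lower = c(1, 0),
                   upper = c(2, 0.4), scale = c(0.3, 0.1),
                   nSamples = 4000L, burnIn = 500L, seed = 5)
  expect_true(all(resB$draws[, 1] >= 1 & resB$draws[, 1] <= 2))
  expect_true(all(resB$draws[, 2] >= 0 & resB$draws[, 2] <= 0.4))
  # pathological scales trigger the zero-acceptance diagnostic
  expect_error(
    mhSample(function(p) -1e8 * sum((p - 0.5)^2), init = c(x = 0.5),
             lower = 0, upper = 1, scale = 1e6, nSamples = 200L,
             burnIn = 0L, seed = 6, adaptEvery = 1000L),
    "zero acceptance")
})

test_that("grid search returns the generating node on noiseless grid data", {
  cfg <- SimulationConfig(nVoxels = 1, seed = 31)
  sch <- makeScheme(cfg)
  fc <- quickFitConfig("real", gridN = 17L, gridNoiseN = 11L)
  # pick exact grid nodes: odi grid = seq(0,1,len 17), dPar = seq(0,4,len 17),
  # c grid = seq(0, 50, len 11)
  odi0 <- 0.0625; dp0 <- 2.25; c0 <- 10
  p <- WatsonStickParams(DispersionIndex(odi = odi0), dp0,
                         FibreOrientation(0, 0), F = 60)
  S <- predictSignalFull(p, sch)
  S[bValues(sch) == 0] <- 100
  ds <- VoxelDataset(S + c0, "real", 100, sch)
  init <- gridSearchInit(ds, FibreOrientation(0, 0), fc)
  expect_equal(unname(init["odi"]), odi0, tolerance = 1e-12)
  expect_equal(unname(init["dPar"]), dp0, tolerance = 1e-12)
  expect_equal(unname(init["c"]), c0, tolerance = 1e-12)
  # residual RSS at the generating node reflects only the 64-direction shell
  # mean vs analytic powder-average quadrature gap, tiny vs the signal energy
  expect_lt(attr(init, "objective"), 1e-5 * sum(signalMatrix(ds)^2))
})

test_that("mhFit recovers the ground truth and is seed-reproducible", {
  cfg <- SimulationConfig(nVoxels = 100, seed = 42)
  sim <- simulateVoxels(cfg)
  ds <- averageVoxels(sim$real)
  orient <- FibreOrientation(0, 0)
  fc <- quickFitConfig("real", seed = 7)
  ps <- mhFit(ds, orient, fc)
  s <- posteriorSummary(ps)
  m <- setNames(s$mean, s$parameter)
  expect_lt(abs(m["dPar"] - 2.2), 0.15)
  expect_lt(abs(m["odi"] - 0.03), 0.005)
  expect_lt(abs(m["c"] - 10), 0.5)
  expect_true(all(acceptanceRate(ps) > 0.05))
  # bitwise reproducibility given the seed
  ps2 <- mhFit(ds, orient, fc)
  expect_identical(posteriorDraws(ps), posteriorDraws(ps2))
  # summaries recompute from draws
  expect_equal(s$mean, unname(colMeans(posteriorDraws(ps))), tolerance = 1e-12)
})

test_that("magnitude estimates exceed real-valued ones on matched noise draws", {
  # the rectified-floor correction overshoots the powder average, pushing
  # dPar up relative to the matched real-valued fit; clearest at moderate N,
  # where the floor is still comparable to the high-shell signal
  diffs <- vapply(1:4, function(i) {
    cfg <- SimulationConfig(nVoxels = 25, seed = 50 + i)
    sim <- simulateVoxels(cfg)
    orient <- FibreOrientation(0, 0)
    prior <- NoiseParams(c = 10, epsilon = sim$sigma, sigma = sim$sigma)
    fr <- mhFit(averageVoxels(sim$real), orient,
                quickFitConfig("real", seed = i))
    fm <- mhFit(averageVoxels(sim$magnitude), orient,
                quickFitConfig("magnitude", seed = i,
                               noiseConstraint = "band", priorNoise = prior))
    sr <- posteriorSummary(fr); sm <- posteriorSummary(fm)
    sm$mean[sm$parameter == "dPar"] - sr$mean[sr$parameter == "dPar"]
  }, 0)
  expect_gt(mean(diffs), -0.05)
})

test_that("posterior samples stay within bounds and expose the c-eps ridge", {
  cfg <- SimulationConfig(nVoxels = 100, seed = 61)
  sim <- simulateVoxels(cfg)
  prior <- NoiseParams(c = 10, epsilon = sim$sigma, sigma = sim$sigma)
  fm <- mhFit(averageVoxels(sim$magnitude), FibreOrientation(0, 0),
              quickFitConfig("magnitude", seed = 3,
                             noiseConstraint = "band", priorNoise = prior))
  d <- posteriorDraws(fm)
  expect_true(all(d[, "odi"] >= 0 & d[, "odi"] <= 1))
  expect_true(all(d[, "dPar"] >= 0 & d[, "dPar"] <= 4))
  expect_true(all(d[, "c"] >= 5 & d[, "c"] <= 15))
  expect_lt(posteriorCorrelation(fm, "c", "epsilon"), -0.5)
})
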