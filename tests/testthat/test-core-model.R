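test_that("ODI/kappa conversion: closed form, limits, round trip, monotonicity", {
  expect_equal(kappaToOdi(1), 0.5)
  expect_equal(kappaToOdi(0), 1)      # isotropic fibre distribution
  expect_equal(kappaToOdi(Inf), 0)    # perfectly aligned
  expect_lt(kappaToOdi(1e8), 1e-7)
  expect_equal(odiToKappa(0.03), 1 / tan(0.015 * pi), tolerance = 1e-12)
  for (o in c(0.01, 0.03, 0.2, 0.5, 0.97, 1))
    expect_equal(kappaToOdi(odiToKappa(o)), o, tolerance = 1e-9)
  k <- c(0, 0.5, 1, 21.2, 636)
  expect_true(all(diff(kappaToOdi(k)) < 0))
  expect_error(odiToKappa(-0.1))
  expect_error(odiToKappa(1.2))
  expect_error(kappaToOdi(-1))
  expect_warning(odiToKappa(0), class = "hibnoddi_infinite_kappa")
  expect_equal(odiKappaConvert(1, "kappa_to_odi"), 0.5)
  expect_equal(odiKappaConvert(0.5, "odi_to_kappa"), 1, tolerance = 1e-12)
})

test_that("matrix-argument 1F1: identities, closed forms, input checks", {
  expect_equal(hyp1f1Sym3(matrix(0, 3, 3)), 1, tolerance = 1e-12)
  for (lam in c(-2, 0.7, 1.3, 4))
    expect_equal(hyp1f1Sym3(diag(3) * lam), exp(lam), tolerance = 1e-9)
  # scalar argument reduces to sqrt(pi) erf(sqrt(t)) / (2 sqrt(t)) at -t
  t <- 4.2
  expect_equal(hyp1f1Sym3(diag(c(-t, 0, 0))),
               sqrt(pi) * (2 * pnorm(sqrt(2 * t)) - 1) / (2 * sqrt(t)),
               tolerance = 1e-7)
  expect_error(hyp1f1Sym3(matrix(rnorm(9), 3, 3)), "symmetric")
  expect_error(hyp1f1Sym3(diag(3), order = 4), "order")
})

test_that("1F1 agrees with Monte-Carlo sphere integration and is rotation invariant", {
  set.seed(11)
  # MC oracle: (1/4pi) * integral of exp(x' X x) over the unit sphere
  n <- 2e5
  u <- runif(n, -1, 1); ph <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  X3 <- cbind(s * cos(ph), s * sin(ph), u)
  for (rep in 1:5) {
    X <- randomSym3(scale = 2)
    q <- exp(rowSums((X3 %*% X) * X3))
    expect_equal(hyp1f1Sym3(X), mean(q), tolerance = 3 * sd(q) / sqrt(n) / mean(q))
    R <- randomRotation()
    expect_equal(hyp1f1Sym3(R %*% X %*% t(R), log = TRUE),
                 hyp1f1Sym3(X, log = TRUE), tolerance = 1e-8)
  }
  # the positive scalar case diag(t, 0, 0), t = 4.2, against the same oracle
  X <- diag(c(4.2, 0, 0))
  q <- exp(rowSums((X3 %*% X) * X3))
  expect_equal(hyp1f1Sym3(X), mean(q), tolerance = 3 * sd(q) / sqrt(n) / mean(q))
})

test_that("Watson normaliser: uniform limit, axis independence, quadrature oracle", {
  expect_equal(watsonNormaliser(0), 4 * pi, tolerance = 1e-10)
  expect_equal(watsonNormaliser(21.2, FibreOrientation(0, 0)),
               watsonNormaliser(21.2, FibreOrientation(pi / 2, 0)))
  # independent latitude quadrature of the azimuthal-symmetric integrand
  for (k in c(1, 5, 21.2)) {
    ref <- 2 * pi * integrate(function(th) exp(k * cos(th)^2) * sin(th),
                              0, pi, rel.tol = 1e-12)$value
    expect_equal(watsonNormaliser(k), ref, tolerance = 1e-9)
  }
})

test_that("Watson density integrates to 1 on the sphere", {
  for (k in c(0, 1, 21.2, 100)) {
    cw <- watsonNormaliser(k)
    v <- 2 * pi * integrate(function(th) exp(k * cos(th)^2) * sin(th) / cw,
                            0, pi, rel.tol = 1e-10)$value
    expect_equal(v, 1, tolerance = 1e-6)
  }
})

test_that("forward signal: b0 value, stick limit, symmetry, monotone decay", {
  sch <- smallScheme()
  disp <- DispersionIndex(odi = 0.03)
  mu <- FibreOrientation(0.4, 1.1)
  p <- WatsonStickParams(disp, 2.2, mu, F = 60)
  s <- predictSignalFull(p, sch)
  expect_true(all(s >= 0))
  expect_true(all(s <= 60 + 1e-9))
  expect_equal(s[bValues(sch) == 0], rep(60, sum(bValues(sch) == 0)))
  # aligned stick: odi = 0, g parallel to mu
  b <- 9.85
  gpar <- matrix(fibreAxis(mu), 1)
  schPar <- AcquisitionScheme(b, gpar)
  pStick <- WatsonStickParams(DispersionIndex(odi = 0), 2.2, mu, F = 60)
  expect_equal(predictSignalFull(pStick, schPar), 60 * exp(-b * 2.2),
               tolerance = 1e-9)
  # antipodal symmetry in g and in mu
  schNeg <- AcquisitionScheme(bValues(sch), -gradients(sch))
  expect_equal(predictSignalFull(p, sch), predictSignalFull(p, schNeg))
  pNeg <- WatsonStickParams(disp, 2.2, fibreFromVector(-fibreAxis(mu)), F = 60)
  expect_equal(predictSignalFull(p, sch), predictSignalFull(pNeg, sch),
               tolerance = 1e-8)
  # decreasing in b along any fixed direction
  g1 <- c(0.6, 0.64, sqrt(1 - 0.6^2 - 0.64^2))
  bs <- c(0, 2, 6.75, 9.85, 13.5)
  schB <- AcquisitionScheme(bs, matrix(g1, length(bs), 3, byrow = TRUE))
  expect_true(all(diff(predictSignalFull(p, schB)) < 0))
})

test_that("forward signal matches the Monte-Carlo convolution oracle", {
  set.seed(21)
  sch <- smallScheme(nDir = 8L, nB0 = 1L)
  z <- c()
  for (rep in 1:6) {
    p <- WatsonStickParams(DispersionIndex(odi = runif(1, 0.03, 0.9)),
                           runif(1, 0.5, 3.5),
                           FibreOrientation(runif(1, 0, pi),
                                            runif(1, -pi, pi)),
                           F = runif(1, 10, 100))
    mc <- numericConvolutionOracle(p, sch, nSamples = 4e4, seed = 100 + rep)
    an <- predictSignalFull(p, sch)
    z <- c(z, abs(an - mc$estimate) / pmax(mc$se, 1e-12))
  }
  # pointwise 3-SE agreement up to the expected Gaussian tail over ~150
  # comparisons; nothing may stray beyond 5 SE
  expect_gt(mean(z <= 3), 0.98)
  expect_true(all(z <= 5))
  # kappa = 0: every direction equals the powder average
  pIso <- WatsonStickParams(DispersionIndex(kappa = 0), 2.2,
                            FibreOrientation(0, 0), F = 60)
  mc <- numericConvolutionOracle(pIso, sch, nSamples = 5e4, seed = 9)
  pw <- 60 * powderAverageModel(bValues(sch), 2.2)
  expect_true(all(abs(mc$estimate - pw) <= 3 * pmax(mc$se, 1e-12)))
})

test_that("powder average: limits, monotonicity, closed form, ODF independence", {
  expect_equal(powderAverageModel(0, 2.2), 1)
  expect_equal(powderAverageModel(1e-14, 3), 1 - 3e-14)
  x <- 29.7   # b = 13.5, dPar = 2.2
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  expect_equal(powderAverageModel(13.5, 2.2),
               sqrt(pi) * erf(sqrt(x)) / (2 * sqrt(x)), tolerance = 1e-12)
  expect_gt(powderAverageModel(9.85, 2.2), powderAverageModel(13.5, 2.2))
  bs <- seq(0.1, 15, length.out = 40)
  expect_true(all(diff(powderAverageModel(bs, 2.2)) < 0))
  # sphere mean of the full model equals the powder average for any ODI
  g <- fibDirections(10000)
  for (o in c(0.05, 0.37, 0.8)) {
    p <- WatsonStickParams(DispersionIndex(odi = o), 2.2,
                           FibreOrientation(0.9, 0.3), F = 1)
    for (b in c(6.75, 13.5)) {
      schD <- AcquisitionScheme(rep(b, nrow(g)), g)
      expect_equal(mean(predictSignalFull(p, schD)),
                   powderAverageModel(b, 2.2), tolerance = 2e-4)
    }
  }
})

test_that("ratio-form prediction: isotropic case, stick limit, self-consistency", {
  sch <- smallScheme(nDir = 24L, nB0 = 0L)
  wsch <- AcquisitionScheme(bValues(sch)[bValues(sch) > 0],
                            gradients(sch)[bValues(sch) > 0, ])
  mu <- FibreOrientation(0, 0)
  sbar <- c(0.9, 0.5, 0.3)
  # isotropic dispersion: the prediction is sbar for every direction
  predIso <- predictSignalRatio(sbar, DispersionIndex(kappa = 0), 2.2, mu, wsch)
  ids <- shellIds(wsch)
  # quadrature vs closed-form powder average agree to the I0-polynomial limit
  expect_equal(predIso, sbar[match(ids, sort(unique(ids)))], tolerance = 1e-6)
  # aligned stick limit along the fibre
  b <- 9.85; d <- 2.2; bd <- b * d
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  schPar <- AcquisitionScheme(c(6.75, b), rbind(c(0, 0, 1), c(0, 0, 1)))
  pr <- predictSignalRatio(c(1, 1), DispersionIndex(odi = 0), d, mu, schPar)
  expect_equal(pr[2], 2 * sqrt(bd) * exp(-bd) / (sqrt(pi) * erf(sqrt(bd))),
               tolerance = 1e-9)
  # consistency with the full model divided by its own sphere mean
  g <- fibDirections(4000)
  b1 <- 9.85
  schD <- AcquisitionScheme(rep(b1, nrow(g)), g)
  p <- WatsonStickParams(DispersionIndex(odi = 0.03), 2.2, mu, F = 1)
  full <- predictSignalFull(p, schD)
  viaRatio <- predictSignalRatio(1, DispersionIndex(odi = 0.03), 2.2, mu, schD)
  expect_equal(viaRatio, full / powderAverageModel(b1, 2.2), tolerance = 1e-8)
  # sphere mean of ratio predictions returns the supplied sbar
  for (o in c(0.03, 0.4)) {
    m <- mean(predictSignalRatio(0.77, DispersionIndex(odi = o), 2.2, mu, schD))
    expect_equal(m, 0.77, tolerance = 1e-4 * 0.77)
  }
  expect_error(predictSignalRatio(c(`0` = 1), DispersionIndex(odi = 0.1),
                                  2.2, mu, wsch), "missing sbar")
})
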