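#' FitConfig: settings for the grid-search-initialised MH fit
#'
#' The estimated parameters are always ODI in \[0, 1\] and dPar in
#' \[0, 4\] um^2/ms, plus the signal offset c unless fixed and, when the
#' Rician family is in play, the noise floor epsilon unless fixed.  The
#' noise family follows the data kind: real-valued data use the
#' offset-only forward model Y = S + c, magnitude data the rectified-floor
#' model Y = sqrt((S + c)^2 + eps^2); `epsilonFree` overrides this (e.g.
#' freeing epsilon on real-valued data to check that it collapses to 0).
#'
#' Noise-parameter constraints are either a box \[0, 0.5 * S0\] per
#' parameter (the default, used when a single noise parameter is
#' estimated) or, when both c and epsilon are free and prior estimates
#' are available (e.g. from [fitPureNoise()] on ventricle-like voxels), a
#' band of 50--150% of those priors, which tames the strong c--epsilon
#' degeneracy.
#'
#' @slot dataKind "real" or "magnitude"
#' @slot minB only shells with b >= minB (ms/um^2) enter the fit; lower
#'   shells are reserved for the tensor fit
#' @slot nSamples,burnIn post-burn-in chain length and burn-in sweeps
#' @slot seed chain RNG seed
#' @slot gridN,gridNoiseN grid-search resolution per shape / noise
#'   parameter
#' @slot cFixed,epsilonFixed NA to estimate, or the value to hold fixed
#' @slot epsilonFree NA for the data-kind default, or TRUE/FALSE override
#' @slot noiseConstraint "box" or "band"
#' @slot priorNoise a [NoiseParams-class] (required for "band") or NULL
#' @slot bandRange relative band around the priors, default c(0.5, 1.5)
#' @slot sbarPolicy powder-average policy, see [correctedPowderAverage()]
#' @exportClass FitConfig
setClass("FitConfig",
  representation(dataKind = "character", minB = "numeric",
                 nSamples = "integer", burnIn = "integer", seed = "integer",
                 gridN = "integer", gridNoiseN = "integer",
                 cFixed = "numeric", epsilonFixed = "numeric",
                 epsilonFree = "logical", noiseConstraint = "character",
                 priorNoise = "ANY", bandRange = "numeric",
                 sbarPolicy = "character"))

setValidity("FitConfig", function(object) {
  msg <- character()
  if (!object@dataKind %in% c("real", "magnitude"))
    msg <- c(msg, "dataKind must be 'real' or 'magnitude'")
  if (!object@noiseConstraint %in% c("box", "band"))
    msg <- c(msg, "noiseConstraint must be 'box' or 'band'")
  if (object@noiseConstraint == "band" && !is(object@priorNoise, "NoiseParams"))
    msg <- c(msg, "the 'band' constraint requires priorNoise estimates")
  if (object@nSamples < 1 || object@burnIn < 0)
    msg <- c(msg, "invalid chain lengths")
  if (length(msg)) msg else TRUE
})

#' @param dataKind,minB,nSamples,burnIn,seed,gridN,gridNoiseN,cFixed,epsilonFixed,epsilonFree,noiseConstraint,priorNoise,bandRange,sbarPolicy
#'   see the class documentation.
#' @rdname FitConfig-class
#' @examples
#' FitConfig("real", nSamples = 5000, burnIn = 1000, seed = 7)
#' @export
FitConfig <- function(dataKind = c("real", "magnitude"), minB = 3,
                      nSamples = 20000L, burnIn = 5000L, seed = 1L,
                      gridN = 32L, gridNoiseN = 32L,
                      cFixed = NA_real_, epsilonFixed = NA_real_,
                      epsilonFree = NA, noiseConstraint = c("box", "band"),
                      priorNoise = NULL, bandRange = c(0.5, 1.5),
                      sbarPolicy = "correct_first") {
  new("FitConfig", dataKind = match.arg(dataKind), minB = minB,
      nSamples = as.integer(nSamples), burnIn = as.integer(burnIn),
      seed = as.integer(seed), gridN = as.integer(gridN),
      gridNoiseN = as.integer(gridNoiseN),
      cFixed = as.numeric(cFixed), epsilonFixed = as.numeric(epsilonFixed),
      epsilonFree = as.logical(epsilonFree),
      noiseConstraint = match.arg(noiseConstraint), priorNoise = priorNoise,
      bandRange = bandRange, sbarPolicy = sbarPolicy)
}

#' Hard parameter bounds of the dispersed-stick fit
#' @noRd
.odiBounds <- c(0, 1)
.dParBounds <- c(0, 4)

#' Resolve which parameters are free and their bounds
#' @noRd
.fitLayout <- function(config, s0) {
  epsFamily <- if (is.na(config@epsilonFree))
    config@dataKind == "magnitude" else config@epsilonFree
  epsInPlay <- epsFamily || (!is.na(config@epsilonFixed) && config@epsilonFixed > 0)
  pars <- c("odi", "dPar")
  lower <- c(.odiBounds[1], .dParBounds[1])
  upper <- c(.odiBounds[2], .dParBounds[2])
  cFree <- is.na(config@cFixed)
  epsFree <- epsFamily && is.na(config@epsilonFixed)
  if (cFree) {
    pars <- c(pars, "c")
    if (config@noiseConstraint == "band") {
      c0 <- offsetC(config@priorNoise)
      lower <- c(lower, config@bandRange[1] * c0)
      upper <- c(upper, config@bandRange[2] * c0)
    } else {
      lower <- c(lower, 0)
      upper <- c(upper, 0.5 * s0)
    }
  }
  if (epsFree) {
    pars <- c(pars, "epsilon")
    if (config@noiseConstraint == "band") {
      e0 <- ricianEpsilon(config@priorNoise)
      lower <- c(lower, config@bandRange[1] * e0)
      upper <- c(upper, config@bandRange[2] * e0)
    } else {
      lower <- c(lower, 0)
      upper <- c(upper, 0.5 * s0)
    }
  }
  list(pars = pars, lower = setNames(lower, pars), upper = setNames(upper, pars),
       cFree = cFree, epsFree = epsFree, rician = epsInPlay,
       cFixed = if (cFree) NA_real_ else config@cFixed,
       epsFixed = if (epsFree) NA_real_ else
         ifelse(is.na(config@epsilonFixed), 0, config@epsilonFixed))
}

#' Internal: per-volume fit context (high-b shells only)
#' @noRd
.fitContext <- function(dataset, orientation, config) {
  stopifnot(is(dataset, "VoxelDataset"), is(orientation, "FibreOrientation"))
  if (nVoxels(dataset) != 1)
    stop("mhFit expects a single (averaged or concatenated) voxel; ",
         "see averageVoxels() / concatenateWithRotation()")
  sch <- acquisitionScheme(dataset)
  keep <- bValues(sch) >= config@minB
  if (!any(keep)) stop("no shells with b >= ", config@minB)
  b <- bValues(sch)[keep]
  ids <- shellIds(sch)[keep]
  uid <- sort(unique(ids))
  if (length(uid) < 2) stop("need at least 2 high-b shells")
  shell0 <- match(ids, uid) - 1L
  mu <- fibreAxis(orientation)
  ct2 <- as.numeric(gradients(sch)[keep, , drop = FALSE] %*% mu)^2
  Y <- as.numeric(signalMatrix(dataset)[1, keep])
  # per-shell data split for fast sbar recomputation
  yByShell <- split(Y, shell0)
  list(b = b, ct2 = ct2, Y = Y, shell0 = shell0, nShells = length(uid),
       shellB = vapply(as.character(sort(unique(shell0))),
                       function(s) b[shell0 == as.integer(s)][1], 0),
       yByShell = yByShell, s0 = s0Values(dataset)[1], V = length(Y))
}

#' Corrected powder average per shell at given noise parameters
#' @noRd
.sbarAt <- function(ctx, cOff, eps, rician) {
  vapply(ctx$yByShell, function(y) {
    if (rician) mean(sqrt(pmax(y^2 - eps^2, 0))) - cOff else mean(y) - cOff
  }, 0)
}

#' Internal quiet odi -> kappa (no boundary warning)
#' @noRd
.kappaOf <- function(odi) if (odi <= 0) Inf else 1 / tan(pi * odi / 2)

#' Grid search initialisation for the dispersed-stick fit
#'
#' Exhaustive evaluation of the profiled-Gaussian objective (residual sum
#' of squares) over a regular grid within the parameter bounds: `gridN`
#' points per shape parameter (ODI, dPar) and `gridNoiseN` per free noise
#' parameter.  Ties are broken toward smaller dPar, then smaller ODI.
#'
#' @param dataset single-voxel [VoxelDataset-class]
#' @param orientation fixed fibre axis ([FibreOrientation-class])
#' @param config a [FitConfig-class]
#' @return named numeric vector of the best grid node, with attributes
#'   `objective` (its RSS) and `layout`
#' @export
gridSearchInit <- function(dataset, orientation, config) {
  ctx <- .fitContext(dataset, orientation, config)
  lay <- .fitLayout(config, ctx$s0)
  odiG <- seq(.odiBounds[1], .odiBounds[2], length.out = config@gridN)
  dpG <- seq(.dParBounds[1], .dParBounds[2], length.out = config@gridN)
  shape <- expand.grid(odi = odiG, dPar = dpG)  # odi varies fastest
  ratio <- matrix(NA_real_, ctx$V, nrow(shape))
  for (i in seq_len(nrow(shape))) {
    lr <- .logStickRatio(.kappaOf(shape$odi[i]), ctx$b * shape$dPar[i], ctx$ct2)
    ratio[, i] <- exp(lr) / powderAverageModel(ctx$b, shape$dPar[i])
  }
  cG <- if (lay$cFree)
    seq(lay$lower["c"], lay$upper["c"], length.out = config@gridNoiseN)
  else lay$cFixed
  eG <- if (lay$epsFree)
    seq(lay$lower["epsilon"], lay$upper["epsilon"],
        length.out = config@gridNoiseN)
  else lay$epsFixed
  noise <- expand.grid(c = cG, epsilon = eG)
  sbar <- vapply(seq_len(nrow(noise)),
                 function(i) .sbarAt(ctx, noise$c[i], noise$epsilon[i],
                                     lay$rician),
                 numeric(ctx$nShells))
  sbar <- matrix(sbar, nrow = ctx$nShells)
  rss <- gridRssCpp(ratio, ctx$shell0, sbar, noise$c, noise$epsilon,
                    ctx$Y, lay$rician)
  best <- which(rss == min(rss), arr.ind = TRUE)
  if (nrow(best) > 1) {   # ties: smaller dPar, then smaller odi
    ord <- order(shape$dPar[best[, 1]], shape$odi[best[, 1]], best[, 2])
    best <- best[ord[1], , drop = FALSE]
  }
  gi <- best[1, 1]; ni <- best[1, 2]
  init <- c(odi = shape$odi[gi], dPar = shape$dPar[gi])
  if (lay$cFree) init <- c(init, c = noise$c[ni])
  if (lay$epsFree) init <- c(init, epsilon = noise$epsilon[ni])
  structure(init[lay$pars], objective = min(rss), layout = lay)
}

#' Componentwise random-walk Metropolis sampler
#'
#' Generic bounded MH sampler used by all fits (and directly testable
#' against analytic posteriors).  One sweep updates each coordinate in
#' turn with a Gaussian proposal; proposals outside the bounds are
#' rejected.  Proposal scales are adapted toward a 20--50% acceptance
#' rate during burn-in only, so the recorded chain is a valid MH chain.
#'
#' @param logPost function of the full parameter vector returning the
#'   (unnormalised) log posterior
#' @param init,lower,upper,scale numeric vectors of equal length
#' @param nSamples,burnIn chain lengths (post-burn-in sweeps recorded)
#' @param seed RNG seed (chains are bitwise reproducible given the seed)
#' @param adaptEvery adaptation interval (burn-in sweeps)
#' @return list with `draws` (nSamples x k), `acceptance` (per
#'   coordinate, post-burn-in) and the final `scale`
#' @export
mhSample <- function(logPost, init, lower, upper, scale,
                     nSamples = 20000L, burnIn = 5000L, seed = 1L,
                     adaptEvery = 100L) {
  k <- length(init)
  stopifnot(length(lower) == k, length(upper) == k, length(scale) == k)
  set.seed(seed)
  p <- init
  lp <- logPost(p)
  if (!is.finite(lp)) stop("initial point has non-finite log posterior")
  draws <- matrix(NA_real_, nSamples, k,
                  dimnames = list(NULL, names(init)))
  accPost <- propPost <- numeric(k)
  accWin <- propWin <- numeric(k)
  total <- burnIn + nSamples
  for (it in seq_len(total)) {
    for (j in seq_len(k)) {
      step <- rnorm(1, 0, scale[j])
      propWin[j] <- propWin[j] + 1
      if (it > burnIn) propPost[j] <- propPost[j] + 1
      pj <- p[j] + step
      if (pj < lower[j] || pj > upper[j]) next
      prop <- p
      prop[j] <- pj
      lpp <- logPost(prop)
      if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
        p <- prop
        lp <- lpp
        accWin[j] <- accWin[j] + 1
        if (it > burnIn) accPost[j] <- accPost[j] + 1
      }
    }
    if (it <= burnIn && it %% adaptEvery == 0) {
      r <- accWin / pmax(propWin, 1)
      scale[r < 0.2] <- scale[r < 0.2] / 1.5
      scale[r > 0.5] <- scale[r > 0.5] * 1.5
      accWin[] <- 0
      propWin[] <- 0
    }
    if (it > burnIn) draws[it - burnIn, ] <- p
  }
  if (all(accPost == 0))
    stop("zero acceptance after burn-in: proposal scales are misconfigured")
  list(draws = draws, acceptance = accPost / pmax(propPost, 1), scale = scale)
}

#' Fit the dispersed-stick model by grid-search-initialised MH
#'
#' Fits the ratio-form high b-value model with the offset (real-valued)
#' or rectified-floor (magnitude) forward model to a single averaged or
#' concatenated voxel, holding the fibre orientation fixed.  The
#' likelihood is independent Gaussian residuals between the data and the
#' forward prediction with the residual variance profiled out
#' analytically, giving `logL = -(V/2) log RSS`.  The per-shell powder
#' averages are recomputed from the offset/floor-corrected data at every
#' proposal's noise parameters, so c and epsilon shape the objective; a
#' corrected powder average that is non-positive in any shell marks the
#' proposal as over-corrected (rejected; an error at the initial point).
#'
#' @param dataset single-voxel [VoxelDataset-class]
#' @param orientation fixed fibre axis, typically V1 from [dtiFit()] (or
#'   the known axis for synthetic data)
#' @param config a [FitConfig-class]
#' @param init optional named start vector (default: [gridSearchInit()])
#' @return a [PosteriorSamples-class]
#' @export
mhFit <- function(dataset, orientation, config, init = NULL) {
  ctx <- .fitContext(dataset, orientation, config)
  lay <- .fitLayout(config, ctx$s0)
  if (is.null(init)) init <- gridSearchInit(dataset, orientation, config)
  init <- init[lay$pars]
  stopifnot(!anyNA(init))

  # two-entry cache for the (odi, dPar) kernel, the expensive part
  k1 <- k2 <- ""
  v1 <- v2 <- NULL
  ratioFor <- function(odiV, dpV) {
    key <- paste(odiV, dpV, sep = "|")
    if (key == k1) return(v1)
    if (key == k2) {
      tmp <- v2; tk <- k2
      k2 <<- k1; v2 <<- v1; k1 <<- tk; v1 <<- tmp
      return(tmp)
    }
    val <- exp(.logStickRatio(.kappaOf(odiV), ctx$b * dpV, ctx$ct2)) /
      powderAverageModel(ctx$b, dpV)
    k2 <<- k1; v2 <<- v1
    k1 <<- key; v1 <<- val
    val
  }

  halfV <- ctx$V / 2
  logPost <- function(p) {
    cOff <- if (lay$cFree) p[["c"]] else lay$cFixed
    eps <- if (lay$epsFree) p[["epsilon"]] else lay$epsFixed
    sbar <- .sbarAt(ctx, cOff, eps, lay$rician)
    if (any(sbar <= 0)) return(-Inf)
    pred <- sbar[ctx$shell0 + 1L] * ratioFor(p[["odi"]], p[["dPar"]]) + cOff
    if (lay$rician) pred <- sqrt(pred^2 + eps^2)
    -halfV * log(sum((pred - ctx$Y)^2))
  }

  sbar0 <- .sbarAt(ctx,
                   if (lay$cFree) init[["c"]] else lay$cFixed,
                   if (lay$epsFree) init[["epsilon"]] else lay$epsFixed,
                   lay$rician)
  if (any(sbar0 <= 0))
    stop("initial noise parameters over-correct the powder average ",
         "(sbar <= 0 in some shell)")

  scale <- (lay$upper - lay$lower) / 50
  scale[!is.finite(scale) | scale == 0] <- 0.02
  res <- mhSample(logPost, init, lay$lower, lay$upper, scale,
                  nSamples = config@nSamples, burnIn = config@burnIn,
                  seed = config@seed)
  new("PosteriorSamples", draws = res$draws,
      acceptanceRate = setNames(res$acceptance, lay$pars),
      seed = config@seed, lower = unname(lay$lower),
      upper = unname(lay$upper))
}

#' Posterior correlation between two parameters
#'
#' @param x a [PosteriorSamples-class]
#' @param p1,p2 parameter names
#' @return Pearson correlation of the draws
#' @export
posteriorCorrelation <- function(x, p1 = "odi", p2 = "dPar") {
  d <- posteriorDraws(x)
  stats::cor(d[, p1], d[, p2])
}

#' Sweep a fixed noise parameter and refit
#'
#' Refits the model with one noise parameter clamped to each value in
#' turn -- the misspecification experiment: simulate with known noise,
#' then fit assuming some fixed offset or noise floor (0 = ignore it
#' entirely, i.e. assume Gaussian noise when sweeping epsilon on
#' magnitude data).  The other noise parameter follows `other`: `"free"`
#' to estimate it, `"zero"` to clamp it at 0, or a number.
#'
#' @param dataset single-voxel [VoxelDataset-class]
#' @param orientation fixed fibre axis
#' @param fixed which parameter is swept: "c" or "epsilon"
#' @param values the fixed values
#' @param config a [FitConfig-class] (its cFixed/epsilonFixed are
#'   overridden per run)
#' @param other policy for the non-swept noise parameter
#' @return data.frame: one row per fixed value with posterior mean/std of
#'   odi, dPar and (if free) the remaining noise parameter
#' @export
fixedNoiseSweep <- function(dataset, orientation, fixed = c("c", "epsilon"),
                            values, config, other = "free") {
  fixed <- match.arg(fixed)
  rows <- lapply(values, function(v) {
    cfg <- config
    if (fixed == "c") {
      cfg@cFixed <- v
      if (identical(other, "zero")) cfg@epsilonFixed <- 0
      else if (is.numeric(other)) cfg@epsilonFixed <- other
    } else {
      cfg@epsilonFixed <- v
      if (identical(other, "zero")) cfg@cFixed <- 0
      else if (is.numeric(other)) cfg@cFixed <- other
    }
    ps <- mhFit(dataset, orientation, cfg)
    s <- posteriorSummary(ps)
    out <- data.frame(fixedParam = fixed, fixedValue = v)
    for (p in s$parameter) {
      out[[paste0(p, "_mean")]] <- s$mean[s$parameter == p]
      out[[paste0(p, "_std")]] <- s$std[s$parameter == p]
    }
    out$odi_dPar_corr <- posteriorCorrelation(ps)
    out
  })
  # rows may differ in free-parameter columns; align on the union
  allCols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    r[setdiff(allCols, names(r))] <- NA_real_
    r[allCols]
  }))
}
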