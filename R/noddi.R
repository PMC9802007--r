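#' NoddiParams: the three-compartment NODDI model parameters
#'
#' The classic model: an isotropic ball (free water, d_iso = 3 um^2/ms),
#' a Watson-dispersed zeppelin (extra-axonal space, radial diffusivity
#' from the tortuosity model d_perp = d_par (1 - f_in)) and a
#' Watson-dispersed stick (intra-axonal space), with the axial
#' diffusivity d_par an assumed input, not a fitted parameter.  The five
#' free parameters are f_in, f_iso, the fibre axis (theta, phi) and ODI.
#' f_aniso = 1 - f_iso is the gross anisotropic signal fraction.
#'
#' @slot fIn intra-axonal signal fraction of the anisotropic compartment
#' @slot fIso isotropic signal fraction
#' @slot orientation a [FibreOrientation-class]
#' @slot dispersion a [DispersionIndex-class]
#' @slot dParFixed assumed axial diffusivity, um^2/ms
#' @exportClass NoddiParams
setClass("NoddiParams",
  representation(fIn = "numeric", fIso = "numeric",
                 orientation = "FibreOrientation",
                 dispersion = "DispersionIndex", dParFixed = "numeric"))

setValidity("NoddiParams", function(object) {
  msg <- character()
  if (object@fIn < 0 || object@fIn > 1) msg <- c(msg, "fIn must be in [0, 1]")
  if (object@fIso < 0 || object@fIso > 1) msg <- c(msg, "fIso must be in [0, 1]")
  if (object@dParFixed < 0) msg <- c(msg, "dParFixed must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param fIn,fIso,orientation,dispersion,dParFixed see slots.
#' @rdname NoddiParams-class
#' @export
NoddiParams <- function(fIn, fIso, orientation, dispersion, dParFixed = 1.7) {
  new("NoddiParams", fIn = fIn, fIso = fIso, orientation = orientation,
      dispersion = dispersion, dParFixed = dParFixed)
}

#' @rdname NoddiParams-class
#' @param x a NoddiParams
#' @export
noddiDerived <- function(x) {
  stopifnot(is(x, "NoddiParams"))
  c(dPerp = x@dParFixed * (1 - x@fIn), dIso = 3, fAniso = 1 - x@fIso)
}

#' @rdname param-accessors
#' @export
setMethod("fibreAxis", "NoddiParams", function(x) x@orientation@mu)

setMethod("show", "NoddiParams", function(object) {
  d <- noddiDerived(object)
  cat(sprintf(paste0("NoddiParams: fIn = %.3g, fIso = %.3g, ODI = %.3g, ",
                     "dPar (assumed) = %.3g\n  derived: dPerp = %.3g, ",
                     "dIso = 3, fAniso = %.3g\n"),
              object@fIn, object@fIso, odi(object@dispersion),
              object@dParFixed, d["dPerp"], d["fAniso"]))
})

#' Three-compartment NODDI forward signal
#'
#' `S/S0 = f_iso exp(-3 b) + (1 - f_iso) [f_in A_stick + (1 - f_in) A_zeppelin]`
#' with both anisotropic kernels convolved with the same Watson ODF via
#' the hypergeometric sphere quadrature.  The zeppelin convolution
#' factors as `exp(-b d_perp)` times a stick convolution with effective
#' axial diffusivity `d_par - d_perp` (the axisymmetric tensor kernel
#' splits into an isotropic radial part and an axial excess).
#' S(b = 0)/S0 = 1 by construction.
#'
#' @param params a [NoddiParams-class]
#' @param scheme an [AcquisitionScheme-class]
#' @param s0 scaling of the returned signal (default 1 = attenuation)
#' @return numeric vector, one value per volume
#' @export
noddiForward <- function(params, scheme, s0 = 1) {
  stopifnot(is(params, "NoddiParams"), is(scheme, "AcquisitionScheme"))
  b <- bValues(scheme)
  mu <- fibreAxis(params@orientation)
  ct2 <- as.numeric(gradients(scheme) %*% mu)^2
  kap <- watsonKappa(params@dispersion)
  dPar <- params@dParFixed
  dPerp <- dPar * (1 - params@fIn)
  aStick <- exp(.logStickRatio(kap, b * dPar, ct2))
  aZepp <- exp(-b * dPerp) * exp(.logStickRatio(kap, b * (dPar - dPerp), ct2))
  s0 * (params@fIso * exp(-3 * b) +
          (1 - params@fIso) * (params@fIn * aStick +
                                 (1 - params@fIn) * aZepp))
}

#' HCP-like three-shell scheme for the sensitivity experiment
#'
#' b = 1, 2, 3 ms/um^2 with 90 directions per shell and 18 b = 0 volumes.
#'
#' @param seed RNG seed for the per-shell direction rotations
#' @return an [AcquisitionScheme-class]
#' @export
hcpLikeScheme <- function(seed = 1L) {
  makeScheme(SimulationConfig(shells = c(1, 2, 3), nDir = 90L, nB0 = 18L,
                              seed = seed))
}

#' Fit the NODDI model with a fixed assumed axial diffusivity
#'
#' MH posterior over (f_in, f_iso, theta, phi, ODI) with d_par clamped to
#' `dParFixed`, fitted to the attenuation Y/S0 with the same
#' profiled-Gaussian likelihood as [mhFit()].  Initialised by a coarse
#' grid over (f_in, f_iso, ODI) with the orientation from the tensor fit
#' (or `orientationInit`).
#'
#' @param dataset single-voxel [VoxelDataset-class] including low-b shells
#' @param dParFixed assumed axial diffusivity, um^2/ms (e.g. 1.7, 2.3, 3)
#' @param config a [FitConfig-class] (chain lengths and seed are used)
#' @param orientationInit optional [FibreOrientation-class] start; default
#'   V1 from [dtiFit()]
#' @param nGrid grid resolution per fraction/dispersion parameter
#' @return a [PosteriorSamples-class] over (fIn, fIso, theta, phi, odi)
#' @export
noddiFitFixedDpar <- function(dataset, dParFixed, config,
                              orientationInit = NULL, nGrid = 12L) {
  stopifnot(nVoxels(dataset) == 1)
  sch <- acquisitionScheme(dataset)
  y <- as.numeric(signalMatrix(dataset)[1, ]) / s0Values(dataset)[1]
  if (is.null(orientationInit)) {
    v1 <- dtiFit(dataset)$V1[1, ]
    orientationInit <- fibreFromVector(v1)
  }
  b <- bValues(sch)
  G <- gradients(sch)
  halfV <- length(y) / 2
  forward <- function(fIn, fIso, theta, phi, odiV) {
    mu <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    ct2 <- as.numeric(G %*% mu)^2
    kap <- .kappaOf(odiV)
    dPerp <- dParFixed * (1 - fIn)
    aS <- exp(.logStickRatio(kap, b * dParFixed, ct2))
    aZ <- exp(-b * dPerp) *
      exp(.logStickRatio(kap, b * (dParFixed - dPerp), ct2))
    fIso * exp(-3 * b) + (1 - fIso) * (fIn * aS + (1 - fIn) * aZ)
  }
  logPost <- function(p) {
    -halfV * log(sum((forward(p[["fIn"]], p[["fIso"]], p[["theta"]],
                              p[["phi"]], p[["odi"]]) - y)^2))
  }
  # coarse init grid over the bounded parameters at the tensor orientation
  gv <- seq(0.02, 0.98, length.out = nGrid)
  th0 <- orientationInit@theta
  ph0 <- orientationInit@phi
  best <- NULL
  bestRss <- Inf
  for (fi in gv) for (fo in gv) for (od in gv) {
    rss <- sum((forward(fi, fo, th0, ph0, od) - y)^2)
    if (rss < bestRss) {
      bestRss <- rss
      best <- c(fIn = fi, fIso = fo, theta = th0, phi = ph0, odi = od)
    }
  }
  lower <- c(fIn = 0, fIso = 0, theta = th0 - pi / 2, phi = ph0 - pi, odi = 0)
  upper <- c(fIn = 1, fIso = 1, theta = th0 + pi / 2, phi = ph0 + pi, odi = 1)
  scale <- c(0.02, 0.02, 0.02, 0.02, 0.02)
  res <- mhSample(logPost, best, lower, upper, scale,
                  nSamples = config@nSamples, burnIn = config@burnIn,
                  seed = config@seed)
  new("PosteriorSamples", draws = res$draws,
      acceptanceRate = setNames(res$acceptance, names(best)),
      seed = config@seed, lower = unname(lower), upper = unname(upper))
}

#' Sensitivity of fitted NODDI parameters to the assumed axial diffusivity
#'
#' Given per-voxel posterior-mean tables fitted with different assumed
#' d_par on the same voxels, reports each parameter under the comparison
#' diffusivity as a percentage of its value under the reference (e.g.
#' d_par = 3 vs 1.7 um^2/ms), with across-voxel distribution summaries.
#' Ratios with a zero reference are flagged undefined (NA), not Inf.
#'
#' @param fits named list of data.frames (one row per voxel, one column
#'   per parameter), names = assumed d_par values
#' @param ref,comp names of the reference and comparison entries
#' @return data.frame: parameter, mean/median/quartiles of the percentage
#'   ratio, and the count of undefined voxel ratios
#' @export
sensitivityReport <- function(fits, ref = "1.7", comp = "3") {
  stopifnot(ref %in% names(fits), comp %in% names(fits))
  a <- fits[[ref]]
  z <- fits[[comp]]
  if (nrow(a) != nrow(z)) stop("mismatched voxel sets")
  pars <- intersect(names(a), names(z))
  out <- lapply(pars, function(p) {
    r <- ifelse(a[[p]] == 0, NA_real_, 100 * z[[p]] / a[[p]])
    data.frame(parameter = p,
               meanPct = mean(r, na.rm = TRUE),
               medianPct = median(r, na.rm = TRUE),
               q25 = quantile(r, 0.25, na.rm = TRUE, names = FALSE),
               q75 = quantile(r, 0.75, na.rm = TRUE, names = FALSE),
               nUndefined = sum(is.na(r)))
  })
  do.call(rbind, out)
}
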