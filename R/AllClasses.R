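## Central S4 containers.  All diffusivities are in um^2/ms and b-values in
## ms/um^2 so that b * d is dimensionless; constructors enforce this at the
## boundary (an s/mm^2 bvals file must be read with convert = TRUE).

#' AcquisitionScheme: multi-shell diffusion acquisition
#'
#' Holds one b-value (ms/um^2) and one unit gradient direction per volume,
#' plus an integer shell label.  Shells are inferred by clustering b-values
#' to a tolerance (default 0.1 ms/um^2) and every b-value is snapped to its
#' shell mean, so volumes sharing a shell label have identical b.  Pulse
#' timings delta/Delta are carried as metadata only; the signal models here
#' are diffusion-time independent.
#'
#' @slot b numeric vector of b-values, ms/um^2
#' @slot g numeric matrix (volumes x 3) of unit gradient directions
#' @slot shellId integer shell label per volume (0 = b ~ 0)
#' @slot deltaSmall,deltaBig pulse duration/separation in ms (metadata)
#' @exportClass AcquisitionScheme
setClass("AcquisitionScheme",
  representation(b = "numeric", g = "matrix", shellId = "integer",
                 deltaSmall = "numeric", deltaBig = "numeric"))

setValidity("AcquisitionScheme", function(object) {
  msg <- character()
  V <- length(object@b)
  if (nrow(object@g) != V || ncol(object@g) != 3)
    msg <- c(msg, "g must be a (volumes x 3) matrix matching length(b)")
  if (any(object@b < 0)) msg <- c(msg, "all b-values must be >= 0")
  if (length(object@shellId) != V)
    msg <- c(msg, "one shellId per volume required")
  # the lowest (b ~ 0) cluster may carry arbitrary bvecs; only meaningfully
  # weighted volumes need unit directions
  dw <- object@b > 0.1
  if (any(dw)) {
    nrm <- sqrt(rowSums(object@g[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "gradient directions of weighted volumes must be unit vectors")
  }
  for (s in unique(object@shellId)) {
    bs <- object@b[object@shellId == s]
    if (diff(range(bs)) > 1e-9)
      msg <- c(msg, "b-values within a shell must agree to 1e-9")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionScheme
#'
#' @param b b-values, one per volume.  In ms/um^2 unless `bUnit = "s/mm2"`,
#'   in which case they are divided by 1000.
#' @param g gradient directions, a (volumes x 3) matrix (rows normalised for
#'   weighted volumes) or a (3 x volumes) matrix as stored in FSL bvecs.
#' @param shellTol b-value clustering tolerance in ms/um^2.
#' @param deltaSmall,deltaBig optional pulse timings (ms), metadata only.
#' @return An [AcquisitionScheme-class] object.
#' @examples
#' sch <- AcquisitionScheme(c(0, 1, 1), rbind(c(0,0,0), c(1,0,0), c(0,1,0)))
#' bValues(sch)
#' @export
AcquisitionScheme <- function(b, g, shellTol = 0.1, bUnit = c("ms/um2", "s/mm2"),
                              deltaSmall = NA_real_, deltaBig = NA_real_) {
  bUnit <- match.arg(bUnit)
  b <- as.numeric(b)
  if (bUnit == "s/mm2") b <- b / 1000
  if (is.matrix(g) && nrow(g) == 3 && ncol(g) == length(b) && length(b) != 3)
    g <- t(g)
  g <- as.matrix(g)
  storage.mode(g) <- "double"
  nrm <- sqrt(rowSums(g^2))
  renorm <- b > 0 & nrm > 0
  g[renorm, ] <- g[renorm, , drop = FALSE] / nrm[renorm]
  shellId <- .inferShells(b, shellTol)
  # snap b to the shell mean so within-shell b-values are exactly equal
  for (s in unique(shellId)) {
    idx <- shellId == s
    b[idx] <- mean(b[idx])
  }
  new("AcquisitionScheme", b = b, g = g, shellId = shellId,
      deltaSmall = as.numeric(deltaSmall), deltaBig = as.numeric(deltaBig))
}

#' @noRd
.inferShells <- function(b, tol) {
  ord <- order(b)
  id <- integer(length(b))
  lastB <- -Inf
  cur <- -1L
  for (i in ord) {
    if (b[i] - lastB > tol) cur <- cur + 1L
    id[i] <- cur
    lastB <- b[i]
  }
  # label 0 reserved for the lowest-b (b ~ 0) cluster
  id
}

#' FibreOrientation: an axis on the sphere
#'
#' Antipodally symmetric fibre axis, stored as polar/azimuthal angles with
#' the derived unit vector.  `mu` and `-mu` denote the same fibre.
#'
#' @slot theta,phi polar and azimuthal angles (radians)
#' @slot mu derived unit 3-vector
#' @exportClass FibreOrientation
setClass("FibreOrientation",
  representation(theta = "numeric", phi = "numeric", mu = "numeric"))

setValidity("FibreOrientation", function(object) {
  if (abs(sqrt(sum(object@mu^2)) - 1) > 1e-9) "mu must be a unit vector" else TRUE
})

#' @param theta,phi polar/azimuthal angles in radians.
#' @rdname FibreOrientation-class
#' @examples
#' FibreOrientation(pi / 2, 0)          # x-axis
#' fibreFromVector(c(0, 0, -1))         # same fibre as +z
#' @export
FibreOrientation <- function(theta, phi) {
  mu <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  new("FibreOrientation", theta = theta, phi = phi, mu = mu)
}

#' @param v a non-zero 3-vector along the fibre axis (normalised internally).
#' @rdname FibreOrientation-class
#' @export
fibreFromVector <- function(v) {
  stopifnot(length(v) == 3, sum(v^2) > 0)
  v <- v / sqrt(sum(v^2))
  FibreOrientation(acos(pmin(1, pmax(-1, v[3]))), atan2(v[2], v[1]))
}

#' DispersionIndex: Watson concentration and its ODI reparameterisation
#'
#' The orientation dispersion index ODI = 2/pi * atan(1/kappa) maps the
#' Watson concentration kappa in [0, Inf] onto [0, 1], with ODI = 1 an
#' isotropic fibre distribution and ODI = 0 perfectly aligned fibres
#' (kappa = Inf, handled as a documented limit: the stick closed form is
#' used whenever kappa exceeds `stickKappaLimit()`).
#'
#' @slot odi orientation dispersion index in [0, 1]
#' @slot kappa Watson concentration parameter, >= 0 (possibly Inf)
#' @exportClass DispersionIndex
setClass("DispersionIndex", representation(odi = "numeric", kappa = "numeric"))

setValidity("DispersionIndex", function(object) {
  msg <- character()
  if (object@odi < 0 || object@odi > 1) msg <- c(msg, "odi must lie in [0, 1]")
  if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
  o <- if (is.infinite(object@kappa)) 0 else 2 / pi * atan(1 / object@kappa)
  if (abs(o - object@odi) > 1e-9)
    msg <- c(msg, "odi and kappa are inconsistent")
  if (length(msg)) msg else TRUE
})

#' @param odi,kappa exactly one of the two parameterisations.
#' @rdname DispersionIndex-class
#' @examples
#' DispersionIndex(odi = 0.03)
#' DispersionIndex(kappa = 1)   # odi = 0.5
#' @export
DispersionIndex <- function(odi = NULL, kappa = NULL) {
  if (is.null(odi) == is.null(kappa))
    stop("supply exactly one of 'odi' or 'kappa'")
  if (is.null(kappa)) {
    kappa <- if (odi == 0) Inf else suppressWarnings(odiToKappa(odi))
  } else {
    odi <- kappaToOdi(kappa)
  }
  new("DispersionIndex", odi = odi, kappa = kappa)
}

#' WatsonStickParams: free parameters of the dispersed-stick signal model
#'
#' @slot dispersion a [DispersionIndex-class]
#' @slot dPar intra-axonal axial diffusivity, um^2/ms, in [0, 4]
#' @slot orientation a [FibreOrientation-class]
#' @slot F non-attenuated intra-axonal signal f_in * S0 (signal units)
#' @exportClass WatsonStickParams
setClass("WatsonStickParams",
  representation(dispersion = "DispersionIndex", dPar = "numeric",
                 orientation = "FibreOrientation", F = "numeric"))

setValidity("WatsonStickParams", function(object) {
  msg <- character()
  if (object@dPar < 0 || object@dPar > 4)
    msg <- c(msg, "dPar must lie in [0, 4] um^2/ms")
  if (object@F < 0) msg <- c(msg, "F must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param dispersion a [DispersionIndex-class].
#' @param dPar axial diffusivity, um^2/ms.
#' @param orientation a [FibreOrientation-class].
#' @param F non-attenuated intra-axonal signal f_in * S0.
#' @rdname WatsonStickParams-class
#' @export
WatsonStickParams <- function(dispersion, dPar, orientation, F = 1) {
  new("WatsonStickParams", dispersion = dispersion, dPar = dPar,
      orientation = orientation, F = F)
}

#' NoiseParams: signal offset, Rician scale and complex-noise std
#'
#' `c` is a diffusion-weighting-independent background signal (sometimes
#' interpreted as a dot compartment); `epsilon` is the Rician scale of
#' magnitude data, equal to the standard deviation of the Gaussian noise in
#' the underlying complex data; `sigma` is the Gaussian std for real-valued
#' data.  Unused components may be NA.
#'
#' @slot c signal offset (signal units), >= 0
#' @slot epsilon Rician scale (signal units), >= 0
#' @slot sigma Gaussian std (signal units), > 0 where used
#' @exportClass NoiseParams
setClass("NoiseParams",
  representation(c = "numeric", epsilon = "numeric", sigma = "numeric"))

setValidity("NoiseParams", function(object) {
  msg <- character()
  if (!is.na(object@c) && object@c < 0) msg <- c(msg, "offset c must be >= 0")
  if (!is.na(object@epsilon) && object@epsilon < 0)
    msg <- c(msg, "epsilon must be >= 0")
  if (!is.na(object@sigma) && object@sigma <= 0)
    msg <- c(msg, "sigma must be > 0 where used")
  if (length(msg)) msg else TRUE
})

#' @param c,epsilon,sigma see slot documentation.
#' @rdname NoiseParams-class
#' @export
NoiseParams <- function(c = 0, epsilon = 0, sigma = NA_real_) {
  new("NoiseParams", c = as.numeric(c), epsilon = as.numeric(epsilon),
      sigma = as.numeric(sigma))
}

#' VoxelDataset: per-voxel diffusion-weighted signals
#'
#' A (voxels x volumes) signal matrix tagged as real-valued or magnitude,
#' with the per-voxel non-diffusion-weighted signal S0 and the acquisition
#' scheme.  Magnitude data must be non-negative.
#'
#' @slot Y numeric matrix, voxels x volumes
#' @slot kind "real" or "magnitude"
#' @slot S0 numeric vector of per-voxel S0, > 0
#' @slot scheme an [AcquisitionScheme-class]
#' @exportClass VoxelDataset
setClass("VoxelDataset",
  representation(Y = "matrix", kind = "character", S0 = "numeric",
                 scheme = "AcquisitionScheme"))

setValidity("VoxelDataset", function(object) {
  msg <- character()
  if (!object@kind %in% c("real", "magnitude"))
    msg <- c(msg, "kind must be 'real' or 'magnitude'")
  if (ncol(object@Y) != length(object@scheme@b))
    msg <- c(msg, "ncol(Y) must equal the number of scheme volumes")
  if (length(object@S0) != nrow(object@Y))
    msg <- c(msg, "one S0 per voxel required")
  if (any(object@S0 <= 0)) msg <- c(msg, "S0 must be > 0")
  if (object@kind == "magnitude" && any(object@Y < 0))
    msg <- c(msg, "magnitude data must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param Y signal matrix (voxels x volumes); a vector is taken as one voxel.
#' @param kind "real" or "magnitude".
#' @param S0 per-voxel non-diffusion-weighted signal.
#' @param scheme an [AcquisitionScheme-class].
#' @rdname VoxelDataset-class
#' @export
VoxelDataset <- function(Y, kind, S0, scheme) {
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  new("VoxelDataset", Y = Y, kind = kind, S0 = as.numeric(S0), scheme = scheme)
}

#' PosteriorSamples: Metropolis-Hastings draws for one fit
#'
#' Post-burn-in draws per parameter with the realised acceptance rate and
#' the RNG seed used.  Summaries (mean, std, quantiles) are recomputed from
#' the stored draws by [posteriorSummary()].
#'
#' @slot draws numeric matrix, samples x parameters (named columns)
#' @slot acceptanceRate realised post-burn-in acceptance rate per parameter
#' @slot seed integer RNG seed of the chain
#' @slot lower,upper parameter bounds used by the sampler
#' @exportClass PosteriorSamples
setClass("PosteriorSamples",
  representation(draws = "matrix", acceptanceRate = "numeric",
                 seed = "integer", lower = "numeric", upper = "numeric"))

setValidity("PosteriorSamples", function(object) {
  d <- object@draws
  low <- rep_len(object@lower, ncol(d))
  upp <- rep_len(object@upper, ncol(d))
  ok <- all(t(d) >= low - 1e-12) && all(t(d) <= upp + 1e-12)
  if (!ok) "draws outside the sampler bounds" else TRUE
})
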