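#' SimulationConfig: ground truth and protocol for synthetic data
#'
#' Defaults reproduce the reference simulation conditions: ground truth
#' dPar = 2.2 um^2/ms, ODI = 0.03, f_in = 0.6, offset c = 10; three shells
#' at b = 6.75, 9.85 and 13.5 ms/um^2 with 64 directions each plus 6 b = 0
#' volumes; S0 = 100 signal units (only S0/sigma matters, so S0 is fixed
#' and c = 10 is 10% of S0) and per-voxel SNR S0/sigma = 16.5.  The fibre
#' axis defaults to +z.
#'
#' @slot dPar,odi,fIn,c ground-truth model parameters
#' @slot s0 non-diffusion-weighted signal (signal units)
#' @slot snrVox per-voxel SNR S0/sigma of the complex noise
#' @slot shells weighted shell b-values, ms/um^2
#' @slot nDir gradient directions per weighted shell
#' @slot nB0 number of b = 0 volumes
#' @slot theta,phi ground-truth fibre axis (radians)
#' @slot nVoxels voxels to simulate
#' @slot seed RNG seed, recorded in all outputs
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(dPar = "numeric", odi = "numeric", fIn = "numeric",
                 c = "numeric", s0 = "numeric", snrVox = "numeric",
                 shells = "numeric", nDir = "integer", nB0 = "integer",
                 theta = "numeric", phi = "numeric",
                 nVoxels = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@snrVox <= 0) msg <- c(msg, "snrVox must be > 0")
  if (!length(object@shells) || any(object@shells <= 0))
    msg <- c(msg, "shells must be non-empty and positive")
  if (object@fIn < 0 || object@fIn > 1) msg <- c(msg, "fIn must be in [0, 1]")
  if (object@nVoxels < 1) msg <- c(msg, "nVoxels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param dPar,odi,fIn,c,s0,snrVox,shells,nDir,nB0,theta,phi,nVoxels,seed
#'   see the class documentation; all have the default study values.
#' @rdname SimulationConfig-class
#' @examples
#' cfg <- SimulationConfig(nVoxels = 10, seed = 1)
#' @export
SimulationConfig <- function(dPar = 2.2, odi = 0.03, fIn = 0.6, c = 10,
                             s0 = 100, snrVox = 16.5,
                             shells = c(6.75, 9.85, 13.5),
                             nDir = 64L, nB0 = 6L,
                             theta = 0, phi = 0,
                             nVoxels = 1L, seed = 1L) {
  new("SimulationConfig", dPar = dPar, odi = odi, fIn = fIn, c = c,
      s0 = s0, snrVox = snrVox, shells = shells,
      nDir = as.integer(nDir), nB0 = as.integer(nB0),
      theta = theta, phi = phi,
      nVoxels = as.integer(nVoxels), seed = as.integer(seed))
}

#' @rdname SimulationConfig-class
#' @param object a SimulationConfig
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: dPar = %.3g, ODI = %.3g, fIn = %.3g, ",
                     "c = %.3g, S0 = %.3g, SNRvox = %.3g\n",
                     "  shells: %s ms/um^2 x %d dirs + %d b0; ",
                     "%d voxel(s), seed %d\n"),
              object@dPar, object@odi, object@fIn, object@c, object@s0,
              object@snrVox, paste(object@shells, collapse = "/"),
              object@nDir, object@nB0, object@nVoxels, object@seed))
})

#' Ground-truth stick parameters of a simulation config
#'
#' @param config a [SimulationConfig-class]
#' @return a [WatsonStickParams-class] with F = fIn * S0
#' @export
groundTruthParams <- function(config) {
  WatsonStickParams(DispersionIndex(odi = config@odi), config@dPar,
                    FibreOrientation(config@theta, config@phi),
                    F = config@fIn * config@s0)
}

#' Spherical Fibonacci lattice of n directions
#' @noRd
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Uniform random rotation matrix (uses the current RNG stream)
#' @noRd
.randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build the multi-shell acquisition scheme of a simulation config
#'
#' b = 0 volumes come first, then each weighted shell with `nDir`
#' directions from a spherical Fibonacci lattice given an independent
#' seeded random rotation (near-uniform coverage; the first spherical
#' moment of each shell's directions is close to zero).  Deterministic
#' given `config@seed`.
#'
#' @param config a [SimulationConfig-class]
#' @return an [AcquisitionScheme-class]
#' @export
makeScheme <- function(config) {
  set.seed(config@seed)
  b <- rep(0, config@nB0)
  g <- matrix(0, config@nB0, 3)
  base <- .fibonacciSphere(config@nDir)
  for (bs in config@shells) {
    R <- .randomRotation()
    g <- rbind(g, base %*% t(R))
    b <- c(b, rep(bs, config@nDir))
  }
  AcquisitionScheme(b, g)
}

#' Simulate matched real-valued and magnitude voxel data
#'
#' The noiseless signal is the dispersed-stick forward model at the
#' ground-truth parameters for weighted volumes and S0 at b = 0, plus the
#' signal offset c.  Complex Gaussian noise of std sigma = S0/snrVox is
#' added to both quadratures (the noiseless signal is taken as the real
#' channel, i.e. perfect phase removal).  The magnitude dataset is the
#' complex modulus (Rician); the real dataset is the real channel
#' (Gaussian).  Both derive from identical noise draws.
#'
#' @param config a [SimulationConfig-class]
#' @param scheme optional pre-built scheme (defaults to
#'   `makeScheme(config)`)
#' @return list with elements `real` and `magnitude`
#'   ([VoxelDataset-class]), `noiseless` (signal + offset, per volume),
#'   `scheme`, `sigma` and `seed`
#' @export
simulateVoxels <- function(config, scheme = NULL) {
  if (is.null(scheme)) scheme <- makeScheme(config)
  truth <- groundTruthParams(config)
  S <- predictSignalFull(truth, scheme)
  S[bValues(scheme) == 0] <- config@s0
  Sc <- applyOffset(S, config@c)
  sigma <- config@s0 / config@snrVox
  set.seed(config@seed + 1L)
  V <- nVolumes(scheme)
  reNoise <- matrix(rnorm(config@nVoxels * V, 0, sigma), config@nVoxels, V)
  imNoise <- matrix(rnorm(config@nVoxels * V, 0, sigma), config@nVoxels, V)
  re <- sweep(reNoise, 2, Sc, "+")
  mag <- sqrt(re^2 + imNoise^2)
  s0vox <- rep(config@s0, config@nVoxels)
  list(real = VoxelDataset(re, "real", s0vox, scheme),
       magnitude = VoxelDataset(mag, "magnitude", s0vox, scheme),
       noiseless = Sc, scheme = scheme, sigma = sigma, seed = config@seed)
}

#' Average the signal across voxels
#'
#' Averages the first `n` voxels of a dataset sharing one scheme and fibre
#' orientation into a single voxel; the noise std shrinks by sqrt(n).
#' Note that averaging magnitude voxels is not the magnitude of the
#' averaged complex signal: the per-voxel Rician floor survives the mean.
#'
#' @param dataset a [VoxelDataset-class]
#' @param n voxels to average (default all)
#' @return a single-voxel [VoxelDataset-class]
#' @export
averageVoxels <- function(dataset, n = nVoxels(dataset)) {
  stopifnot(n >= 1, n <= nVoxels(dataset))
  Y <- signalMatrix(dataset)[seq_len(n), , drop = FALSE]
  VoxelDataset(colMeans(Y), dataKind(dataset),
               mean(s0Values(dataset)[seq_len(n)]),
               acquisitionScheme(dataset))
}

#' Concatenate voxel signals after aligning fibre orientations
#'
#' For each voxel the gradient directions (not the signals) are rotated so
#' that the voxel's fibre axis maps to +z with a random azimuthal roll
#' (the Watson model is symmetric about the primary axis, so the roll is
#' irrelevant to the model but de-correlates residual direction structure).
#' Signals are concatenated unmodified -- no interpolation is involved.
#'
#' @param datasets list of single-voxel [VoxelDataset-class] objects
#'   sharing kind
#' @param orientations list of [FibreOrientation-class], one per dataset
#' @param seed RNG seed for the azimuthal rolls
#' @return a single-voxel [VoxelDataset-class] whose scheme holds the
#'   rotated directions of all input volumes
#' @export
concatenateWithRotation <- function(datasets, orientations, seed = 1L) {
  stopifnot(length(datasets) == length(orientations))
  set.seed(seed)
  bAll <- c(); gAll <- NULL; yAll <- c(); s0All <- c()
  kind <- dataKind(datasets[[1]])
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    stopifnot(nVoxels(d) == 1, dataKind(d) == kind)
    mu <- fibreAxis(orientations[[i]])
    if (abs(sqrt(sum(mu^2)) - 1) > 1e-6) stop("orientations must be unit vectors")
    roll <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(roll), -sin(roll), 0,
                   sin(roll), cos(roll), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    R <- Rz %*% t(.rotationToAxis(mu))   # mu -> +z, then random roll
    sch <- acquisitionScheme(d)
    gAll <- rbind(gAll, gradients(sch) %*% t(R))
    bAll <- c(bAll, bValues(sch))
    yAll <- c(yAll, as.numeric(signalMatrix(d)))
    s0All <- c(s0All, s0Values(d))
  }
  VoxelDataset(yAll, kind, mean(s0All), AcquisitionScheme(bAll, gAll))
}
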