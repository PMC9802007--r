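#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares on log signal restricted to low-b volumes
#' (default b <= 1 ms/um^2 shells plus b = 0), the standard pipeline step
#' that supplies the fibre orientation for the dispersed-stick fit: V1,
#' the unit eigenvector of the largest tensor eigenvalue, and the
#' fractional anisotropy.  Non-positive signals are excluded from the log
#' fit voxelwise; a rank-deficient design (fewer than 7 usable volumes or
#' degenerate directions) is an error.
#'
#' @param dataset a [VoxelDataset-class]
#' @param bMax largest b-value (ms/um^2) admitted to the tensor fit
#' @return a list with `tensors` (list of 3x3 matrices), `V1` (voxels x 3),
#'   `FA`, `MD` (um^2/ms) and `S0` (fitted) vectors
#' @export
dtiFit <- function(dataset, bMax = 1) {
  stopifnot(is(dataset, "VoxelDataset"))
  sch <- acquisitionScheme(dataset)
  keep <- bValues(sch) <= bMax
  if (sum(keep) < 7)
    stop("need at least 7 volumes (incl. b0) with b <= ", bMax)
  b <- bValues(sch)[keep]
  g <- gradients(sch)[keep, , drop = FALSE]
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  if (qr(X)$rank < 7) stop("rank-deficient tensor design")
  Y <- signalMatrix(dataset)[, keep, drop = FALSE]
  nv <- nrow(Y)
  tensors <- vector("list", nv)
  V1 <- matrix(NA_real_, nv, 3)
  FA <- MD <- S0 <- numeric(nv)
  for (v in seq_len(nv)) {
    y <- Y[v, ]
    pos <- y > 0
    if (sum(pos) < 7 || qr(X[pos, , drop = FALSE])$rank < 7)
      stop("voxel ", v, ": too few positive signals for the tensor fit")
    beta <- qr.solve(X[pos, , drop = FALSE], log(y[pos]))
    D <- matrix(c(beta[2], beta[5], beta[6],
                  beta[5], beta[3], beta[7],
                  beta[6], beta[7], beta[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    tensors[[v]] <- D
    V1[v, ] <- e$vectors[, 1]
    FA[v] <- faFromEigenvalues(e$values)
    MD[v] <- mean(e$values)
    S0[v] <- exp(beta[1])
  }
  list(tensors = tensors, V1 = V1, FA = FA, MD = MD, S0 = S0)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, clamped to \[0, 1\].
#'
#' @param lambda numeric vector of 3 eigenvalues
#' @return FA in \[0, 1\]
#' @export
faFromEigenvalues <- function(lambda) {
  stopifnot(length(lambda) == 3)
  den <- sqrt(sum(lambda^2))
  if (den == 0) return(0)
  min(1, max(0, sqrt(3 / 2) * sqrt(sum((lambda - mean(lambda))^2)) / den))
}

#' Select single-fibre voxels by FA and S0 consistency
#'
#' Within a mask, keeps voxels with FA above a threshold and S0 within
#' +/- 10% (closed interval) of the masked S0 mean -- the selection rule
#' used to pool corpus-callosum voxels before concatenation.  Ordering of
#' the returned indices is deterministic (increasing voxel index).
#'
#' @param fa per-voxel fractional anisotropy
#' @param s0 per-voxel non-diffusion-weighted signal
#' @param mask logical vector or integer index vector of candidate voxels
#' @param faThreshold minimum FA (default 0.7, a high-FA selection)
#' @param s0Window half-width of the relative S0 window (default 0.1)
#' @return sorted integer indices of selected voxels; an empty mask is an
#'   error while an empty selection returns `integer(0)` with a warning
#' @export
selectVoxels <- function(fa, s0, mask = seq_along(fa), faThreshold = 0.7,
                         s0Window = 0.1) {
  stopifnot(length(fa) == length(s0))
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (!length(idx)) stop("empty mask")
  mS0 <- mean(s0[idx])
  sel <- idx[fa[idx] >= faThreshold &
               s0[idx] >= (1 - s0Window) * mS0 &
               s0[idx] <= (1 + s0Window) * mS0]
  sel <- sort(sel)
  if (!length(sel)) warning("no voxels pass the FA/S0 selection")
  sel
}
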