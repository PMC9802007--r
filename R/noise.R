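#' Forward noise models: signal offset and rectified Rician floor
#'
#' `applyOffset` adds a diffusion-weighting-independent background signal,
#' `Y = S + c`.  `applyRicianFloor` applies the rectified-noise-floor
#' approximation for magnitude data, `Y = sqrt((S + c)^2 + epsilon^2)`
#' (Koay-style), which reduces to the plain offset at epsilon = 0 and
#' satisfies `Y >= max(S + c, epsilon)`.
#'
#' @param S noiseless signal (any shape; preserved)
#' @param c signal offset, >= 0
#' @param epsilon Rician scale, >= 0
#' @return expected data Y, same shape as S
#' @examples
#' applyRicianFloor(3, 0, 4)  # 5
#' @export
applyOffset <- function(S, c) {
  stopifnot(c >= 0)
  S + c
}

#' @rdname applyOffset
#' @export
applyRicianFloor <- function(S, c, epsilon) {
  stopifnot(c >= 0, epsilon >= 0)
  # epsilon = 0 is exactly the offset-only model (not |S + c|: the identity
  # must hold for any real-valued input signal)
  if (epsilon == 0) return(S + c)
  sqrt((S + c)^2 + epsilon^2)
}

#' Invert the noise forward model on measured data
#'
#' Converts data Y back to signal S before averaging: for magnitude data
#' `S = Re(sqrt(Y^2 - epsilon^2)) - c` (the real part clamps the root to 0
#' wherever Y < epsilon, before the offset is removed), for real-valued
#' data `S = Y - c`.
#'
#' @param Y measured data
#' @param noise a [NoiseParams-class]
#' @param kind "real" or "magnitude"
#' @return corrected signal, same shape as Y
#' @export
invertNoiseModel <- function(Y, noise, kind = c("real", "magnitude")) {
  kind <- match.arg(kind)
  if (kind == "real") return(Y - offsetC(noise))
  eps <- ricianEpsilon(noise)
  sqrt(pmax(Y^2 - eps^2, 0)) - offsetC(noise)
}

#' Noise-corrected powder average per shell
#'
#' Each measurement is first converted from data Y to signal S with
#' [invertNoiseModel()] and then averaged within its weighted shell
#' (correct-then-average, the order that matters because the rectifying
#' square root does not commute with the mean).  An opt-in
#' `"average_first"` policy averages the raw shell data before applying
#' the correction.
#'
#' @param dataset a [VoxelDataset-class]
#' @param noise a [NoiseParams-class]; with multiple voxels a list of one
#'   NoiseParams per voxel is also accepted (per-voxel correction)
#' @param policy `"correct_first"` (default) or `"average_first"`
#' @return a (voxels x weighted shells) matrix of powder averages, with
#'   shell ids as column names
#' @export
correctedPowderAverage <- function(dataset, noise,
                                   policy = c("correct_first", "average_first")) {
  policy <- match.arg(policy)
  stopifnot(is(dataset, "VoxelDataset"))
  sch <- acquisitionScheme(dataset)
  ids <- shellIds(sch)
  wids <- sort(unique(ids[bValues(sch) > 0]))
  if (!length(wids)) stop("no weighted shells in the dataset")
  Y <- signalMatrix(dataset)
  nv <- nrow(Y)
  noiseList <- if (is(noise, "NoiseParams")) rep(list(noise), nv) else noise
  stopifnot(length(noiseList) == nv)
  out <- matrix(NA_real_, nv, length(wids),
                dimnames = list(NULL, as.character(wids)))
  for (v in seq_len(nv)) {
    for (j in seq_along(wids)) {
      y <- Y[v, ids == wids[j]]
      if (!length(y)) stop("empty shell ", wids[j])
      out[v, j] <- if (policy == "correct_first")
        mean(invertNoiseModel(y, noiseList[[v]], dataKind(dataset)))
      else
        invertNoiseModel(mean(y), noiseList[[v]], dataKind(dataset))
    }
  }
  out
}

#' SNR of an averaged or concatenated signal
#'
#' Averaging (or concatenating) the signal of n voxels with per-voxel SNR
#' `snrVox` raises the effective SNR to `snrVox * sqrt(n)`.
#'
#' @param snrVox per-voxel SNR (S0 / sigma)
#' @param n number of voxels combined, >= 1
#' @return the combined SNR
#' @examples
#' snrOfAverage(16.5, 100)  # 165
#' @export
snrOfAverage <- function(snrVox, n) {
  stopifnot(all(n >= 1))
  snrVox * sqrt(n)
}

#' Rician log-likelihood (nu = non-centrality, sigma = scale)
#' @noRd
.ricianLogLik <- function(y, nu, sigma) {
  if (sigma <= 0 || nu < 0) return(-Inf)
  z <- y * nu / sigma^2
  sum(log(y) - 2 * log(sigma) - (y^2 + nu^2) / (2 * sigma^2) +
        z + log(besselI(z, 0, expon.scaled = TRUE)))
}

#' Characterise pure-noise samples
#'
#' Fits a noise distribution to samples assumed to contain no diffusion
#' signal (e.g. high b-value ventricle voxels).  For `family = "rician"`
#' the non-centrality nu (reported as the offset c) and scale sigma
#' (reported as epsilon) are estimated by maximum likelihood, started from
#' method-of-moments values; for `family = "gaussian"` the mean (offset c)
#' and standard deviation are closed-form ML estimates.  Standard errors
#' come from the observed information (Rician) or the usual closed forms
#' (Gaussian).
#'
#' @param samples numeric vector of pure-noise measurements (>= 100)
#' @param family "rician" or "gaussian"
#' @return a list with `params` (a [NoiseParams-class]), `estimate`,
#'   `se` (named vectors) and `family`
#' @export
fitPureNoise <- function(samples, family = c("rician", "gaussian")) {
  family <- match.arg(family)
  if (length(samples) < 100)
    stop("at least 100 pure-noise samples are required")
  if (family == "gaussian") {
    m <- mean(samples)
    s <- sd(samples)
    est <- c(c = m, sigma = s)
    se <- c(c = s / sqrt(length(samples)), sigma = s / sqrt(2 * length(samples)))
    return(list(params = NoiseParams(c = max(m, 0), epsilon = 0, sigma = s),
                estimate = est, se = se, family = family,
                n = length(samples)))
  }
  if (any(samples <= 0))
    stop("rician samples must be strictly positive")
  # method-of-moments start: E[Y^2] = nu^2 + 2 sigma^2, Var ~ sigma^2 (high SNR)
  m2 <- mean(samples^2)
  s0 <- sd(samples)
  nu0 <- sqrt(max(m2 - 2 * s0^2, 1e-6))
  fit <- optim(c(nu0, s0),
               function(p) -.ricianLogLik(samples, p[1], p[2]),
               method = "L-BFGS-B",
               lower = c(0, 1e-8), upper = c(Inf, Inf), hessian = TRUE)
  est <- c(c = fit$par[1], epsilon = fit$par[2])
  seh <- tryCatch(sqrt(diag(solve(fit$hessian))),
                  error = function(e) rep(NA_real_, 2))
  se <- c(c = seh[1], epsilon = seh[2])
  list(params = NoiseParams(c = fit$par[1], epsilon = fit$par[2],
                            sigma = fit$par[2]),
       estimate = est, se = se, family = family, n = length(samples))
}

#' Rician distribution function
#'
#' CDF of the Rician distribution, by numerical integration of the density
#' on a fine grid (adequate for goodness-of-fit testing).
#'
#' @param q quantiles
#' @param nu non-centrality parameter
#' @param sigma scale parameter
#' @return P(Y <= q)
#' @export
pRician <- function(q, nu, sigma) {
  hi <- max(q, nu + 12 * sigma)
  grid <- seq(0, hi, length.out = 8192)
  z <- grid * nu / sigma^2
  dens <- grid / sigma^2 * exp(-(grid^2 + nu^2) / (2 * sigma^2) + z) *
    besselI(z, 0, expon.scaled = TRUE)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- pmin(cdf / max(cdf[length(cdf)], 1e-300), 1)
  approx(grid, cdf, xout = pmax(q, 0), rule = 2)$y
}

#' JSON report of fitted noise parameters
#'
#' @param fit result of [fitPureNoise()]
#' @param path output file
#' @return the path, invisibly
#' @export
writeNoiseReport <- function(fit, path) {
  jsonlite::write_json(
    list(family = fit$family,
         estimate = as.list(fit$estimate),
         se = as.list(fit$se),
         n = fit$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
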