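#' Forward signal of the Watson-dispersed stick model
#'
#' Predicted intra-axonal signal per volume,
#' `S(b, g) = F * 1F1(1/2;3/2; kappa mu mu' - b d g g') / 1F1(1/2;3/2; kappa mu mu')`,
#' i.e. the spherical convolution of a stick response (Gaussian diffusion
#' along the axis, none across) with a Watson orientation distribution,
#' scaled by the non-attenuated intra-axonal signal F = f_in * S0.
#' At b = 0 the ratio is 1 and the prediction equals F.  The prediction is
#' invariant under g -> -g and mu -> -mu and never exceeds F.
#'
#' @param params a [WatsonStickParams-class]
#' @param scheme an [AcquisitionScheme-class]
#' @param order optional quadrature order override
#' @return numeric vector, one non-negative value per volume
#' @seealso [predictSignalRatio()] for the F- and S0-free ratio form,
#'   [numericConvolutionOracle()] for a Monte-Carlo check
#' @export
predictSignalFull <- function(params, scheme, order = NULL) {
  stopifnot(is(params, "WatsonStickParams"), is(scheme, "AcquisitionScheme"))
  mu <- fibreAxis(params)
  bd <- bValues(scheme) * params@dPar
  ct2 <- as.numeric(gradients(scheme) %*% mu)^2
  params@F * exp(.logStickRatio(watsonKappa(params), bd, ct2, order))
}

#' Powder-averaged (spherical mean) stick attenuation
#'
#' Mean attenuation over all gradient directions at one b-value for
#' stick-like diffusion convolved with any fibre orientation distribution:
#' `sqrt(pi) * erf(sqrt(b d)) / (2 sqrt(b d))`, returned per unit
#' f_in * S0.  Independent of the orientation distribution, strictly
#' decreasing in b*d, with limit 1 as b*d -> 0 (the series
#' 1 - bd/3 + O(bd^2) is used below bd = 1e-12 to avoid 0/0).
#'
#' @param b b-value(s), ms/um^2
#' @param dPar axial diffusivity, um^2/ms
#' @return attenuation in (0, 1]
#' @examples
#' powderAverageModel(13.5, 2.2)
#' @export
powderAverageModel <- function(b, dPar) {
  stopifnot(all(b >= 0), all(dPar >= 0))
  x <- b * dPar
  out <- ifelse(x <= 1e-12,
                1 - x / 3,
                {
                  sx <- sqrt(pmax(x, 1e-300))
                  sqrt(pi) * .erf(sx) / (2 * sx)
                })
  as.numeric(out)
}

#' @noRd
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Ratio-form signal prediction from per-shell powder averages
#'
#' The high b-value model actually fitted: dividing the dispersed-stick
#' signal by the powder average of the same shell removes F = f_in * S0,
#' leaving only ODI and dPar as free parameters,
#' `S(b, g) = sbar_b * [2 sqrt(bd) / (sqrt(pi) erf(sqrt(bd)))] * ratio(b, g)`.
#' For each shell, the mean of the predictions over a dense uniform
#' direction set returns the supplied `sbar` (self-consistency of the
#' ratio model).
#'
#' @param sbarPerShell named or ordered numeric vector with one powder
#'   average per weighted shell of `scheme` (names = shell ids; unnamed
#'   vectors are matched to the weighted shells in increasing id order)
#' @param dispersion a [DispersionIndex-class]
#' @param dPar axial diffusivity, um^2/ms
#' @param orientation a [FibreOrientation-class]
#' @param scheme an [AcquisitionScheme-class]; all volumes must belong to
#'   weighted (b > 0) shells
#' @param order optional quadrature order override
#' @return numeric vector, one prediction per volume
#' @export
predictSignalRatio <- function(sbarPerShell, dispersion, dPar, orientation,
                               scheme, order = NULL) {
  stopifnot(is(dispersion, "DispersionIndex"),
            is(orientation, "FibreOrientation"),
            is(scheme, "AcquisitionScheme"))
  b <- bValues(scheme)
  if (any(b <= 0)) stop("ratio-form prediction requires b > 0 volumes only")
  ids <- shellIds(scheme)
  uid <- sort(unique(ids))
  if (!is.null(names(sbarPerShell))) {
    miss <- setdiff(as.character(uid), names(sbarPerShell))
    if (length(miss)) stop("missing sbar for shell(s): ",
                           paste(miss, collapse = ", "))
    sbar <- sbarPerShell[as.character(uid)]
  } else {
    if (length(sbarPerShell) != length(uid))
      stop("need one sbar per weighted shell")
    sbar <- sbarPerShell
  }
  sbarVol <- sbar[match(ids, uid)]
  mu <- fibreAxis(orientation)
  bd <- b * dPar
  ct2 <- as.numeric(gradients(scheme) %*% mu)^2
  ratio <- exp(.logStickRatio(watsonKappa(dispersion), bd, ct2, order))
  as.numeric(sbarVol * ratio / powderAverageModel(b, dPar))
}

#' Monte-Carlo oracle for the dispersed-stick convolution integral
#'
#' Evaluates the defining spherical convolution
#' `S(b, g) = F / C_W * \oint exp(kappa (mu.x)^2) exp(-b d (g.x)^2) dx`
#' by exact rejection sampling from the Watson distribution followed by an
#' unbiased sample mean of the stick attenuation.  Used in tests as an
#' implementation-independent check of [predictSignalFull()].
#'
#' @param params a [WatsonStickParams-class]
#' @param scheme an [AcquisitionScheme-class]
#' @param nSamples number of Watson draws (>= 1e4)
#' @param seed RNG seed
#' @return data.frame with columns `estimate` and `se` (one row per volume)
#' @export
numericConvolutionOracle <- function(params, scheme, nSamples = 1e5,
                                     seed = 1L) {
  stopifnot(nSamples >= 1e4)
  set.seed(seed)
  x <- rWatson(nSamples, fibreAxis(params), watsonKappa(params))
  bd <- bValues(scheme) * params@dPar
  G <- gradients(scheme)
  est <- se <- numeric(nVolumes(scheme))
  for (v in seq_along(bd)) {
    a <- exp(-bd[v] * as.numeric(x %*% G[v, ])^2)
    est[v] <- params@F * mean(a)
    se[v] <- params@F * sd(a) / sqrt(nSamples)
  }
  data.frame(estimate = est, se = se)
}

#' Draw axes from a Watson distribution
#'
#' Exact rejection sampling: the polar cosine u has density proportional to
#' exp(kappa u^2) on \[-1, 1\], bounded by exp(kappa), and the azimuth is
#' uniform; samples are then rotated so the +z pole maps to `mu`.
#' Acceptance degrades as 1/(2 kappa), which is acceptable at the
#' concentrations used in tests.
#'
#' @param n number of draws
#' @param mu unit axis 3-vector
#' @param kappa concentration >= 0 (finite)
#' @return an (n x 3) matrix of unit vectors
#' @export
rWatson <- function(n, mu, kappa) {
  stopifnot(kappa >= 0, is.finite(kappa))
  u <- numeric(0)
  while (length(u) < n) {
    m <- min(5e6, max(1000L, ceiling((n - length(u)) * max(3, 3 * kappa))))
    cand <- runif(m, -1, 1)
    keep <- runif(m) < exp(kappa * (cand^2 - 1))
    u <- c(u, cand[keep])
  }
  u <- u[seq_len(n)]
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - u^2))
  xyz <- cbind(s * cos(phi), s * sin(phi), u)
  xyz %*% t(.rotationToAxis(mu))
}

#' Rotation matrix taking +z to the given unit axis
#' @noRd
.rotationToAxis <- function(mu) {
  mu <- mu / sqrt(sum(mu^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * mu[3] - z[3] * mu[2],
         z[3] * mu[1] - z[1] * mu[3],
         z[1] * mu[2] - z[2] * mu[1])
  cth <- sum(z * mu)
  if (abs(cth + 1) < 1e-12) return(diag(c(1, -1, -1)))  # mu = -z
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}
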