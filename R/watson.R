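#' Convert between the orientation dispersion index and Watson concentration
#'
#' The orientation dispersion index is ODI = 2/pi * atan(1/kappa), a
#' monotone decreasing map of the Watson concentration kappa onto [0, 1]:
#' ODI = 1 is an isotropic fibre distribution (kappa = 0) and ODI = 0
#' perfectly aligned fibres (kappa = Inf).
#'
#' `odiToKappa(0)` signals the infinite-concentration limit with a warning
#' of class `hibnoddi_infinite_kappa` and returns `Inf`; downstream signal
#' code switches to the pure-stick closed form beyond [stickKappaLimit()].
#'
#' @param odi orientation dispersion index in \[0, 1\] (vectorised)
#' @param kappa Watson concentration >= 0 (vectorised)
#' @return the other parameterisation, same length as the input
#' @examples
#' kappaToOdi(1)            # 0.5
#' odiToKappa(kappaToOdi(21.2))
#' @export
odiToKappa <- function(odi) {
  if (any(odi < 0 | odi > 1)) stop("odi must lie in [0, 1]")
  if (any(odi == 0)) {
    warning(structure(
      class = c("hibnoddi_infinite_kappa", "warning", "condition"),
      list(message = "odi = 0 corresponds to the infinite-concentration limit (kappa = Inf)",
           call = sys.call())))
  }
  # 1 / tan(pi * odi / 2); tan(pi/2) overflows cleanly to Inf only at odi = 1
  ifelse(odi == 0, Inf, 1 / tan(pi * odi / 2))
}

#' @rdname odiToKappa
#' @export
kappaToOdi <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  ifelse(is.infinite(kappa), 0, 2 / pi * atan2(1, kappa))
}

#' @rdname odiToKappa
#' @param value value to convert
#' @param direction `"odi_to_kappa"` or `"kappa_to_odi"`
#' @export
odiKappaConvert <- function(value, direction = c("odi_to_kappa", "kappa_to_odi")) {
  direction <- match.arg(direction)
  if (direction == "odi_to_kappa") odiToKappa(value) else kappaToOdi(value)
}

#' Concentration beyond which the aligned-stick closed form is used
#'
#' For kappa above this limit the Watson distribution is numerically a
#' delta function on the sphere and resolving the polar quadrature would
#' need O(sqrt(kappa)) nodes, so the dispersed-stick attenuation is
#' replaced by the aligned-stick closed form exp(-b d (g.mu)^2).  The
#' relative error of that replacement is O(b d / kappa), i.e. at most
#' ~3e-4 at the highest shell used here (b d ~ 30), far below the noise
#' level at which such concentrations arise.
#'
#' @return the kappa threshold (1e5)
#' @export
stickKappaLimit <- function() 1e5

#' Quadrature order used for the matrix-argument 1F1
#'
#' The polar Gauss-Legendre rule must resolve an integrand concentrated
#' within ~1/sqrt(lambda_max) of the poles, which needs O(sqrt(lambda_max))
#' nodes; 6*sqrt(lambda_max) with a floor of 64 keeps the log value
#' accurate to ~1e-8 across the concentrations the fits reach (the Watson
#' normalisation is exact to well below 1e-6 up to kappa ~ 1000 and
#' beyond).  Capped at 2048 nodes; beyond that [stickKappaLimit()] takes
#' over.
#'
#' @param maxEig largest absolute eigenvalue of the matrix argument
#' @param floorOrder minimum order
#' @return an integer quadrature order
#' @noRd
.quadOrder <- function(maxEig, floorOrder = 64L) {
  min(2048L, max(floorOrder, as.integer(ceiling(6 * sqrt(max(0, maxEig))))))
}

#' Confluent hypergeometric function 1F1(1/2; 3/2; X) of a symmetric 3x3
#' matrix argument
#'
#' Evaluated through the sphere-integral identity
#' `1F1(1/2; 3/2; X) = (1/4pi) \oint exp(x' X x) dx` in the eigenbasis of
#' X: the azimuthal integral is done exactly (a modified Bessel I0 factor)
#' and the polar integral by Gauss-Legendre quadrature, in log space.  The
#' result depends on X only through its eigenvalues, so it is exactly
#' rotation invariant.
#'
#' @param X symmetric 3x3 matrix (symmetry checked to 1e-9)
#' @param order quadrature order; the default grows as sqrt of the largest
#'   eigenvalue magnitude with a floor of 64 nodes
#' @param log return the logarithm
#' @return a positive scalar (or its log)
#' @examples
#' hyp1f1Sym3(diag(3) * 0)      # 1
#' hyp1f1Sym3(diag(3) * 1.3)    # exp(1.3)
#' @export
hyp1f1Sym3 <- function(X, order = NULL, log = FALSE) {
  if (!is.matrix(X) || any(dim(X) != c(3, 3)))
    stop("X must be a 3x3 matrix")
  if (max(abs(X - t(X))) > 1e-9) stop("X must be symmetric (tolerance 1e-9)")
  lam <- eigen((X + t(X)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (is.null(order)) order <- .quadOrder(max(abs(lam)))
  if (order < 8) stop("quadrature order below the supported minimum (8)")
  rule <- .glRule(order)
  lv <- logHyp1f1EigsCpp(matrix(lam, nrow = 1), rule$x, rule$w)
  if (log) lv else exp(lv)
}

#' Watson normalising constant
#'
#' C_W = 4 pi 1F1(1/2; 3/2; kappa mu mu'), the integral of
#' exp(kappa (mu.x)^2) over the unit sphere.  Depends on mu only through
#' its single non-zero eigenvalue kappa, so any (or no) axis may be given.
#'
#' @param kappa Watson concentration, >= 0
#' @param mu optional [FibreOrientation-class] (ignored up to rotation)
#' @param order quadrature order override
#' @return the normalising constant (4 pi at kappa = 0)
#' @examples
#' watsonNormaliser(0)   # 4 * pi
#' @export
watsonNormaliser <- function(kappa, mu = NULL, order = NULL) {
  stopifnot(kappa >= 0)
  if (is.null(order)) order <- .quadOrder(kappa)
  rule <- .glRule(order)
  lv <- logHyp1f1EigsCpp(matrix(c(0, 0, kappa), nrow = 1), rule$x, rule$w)
  4 * pi * exp(lv)
}

#' Per-volume log attenuation ratio of the Watson-dispersed stick
#'
#' log[1F1(1/2;3/2; kappa mu mu' - b d g g') / 1F1(1/2;3/2; kappa mu mu')]
#' with the rank-2 eigenvalues in closed form.  Above [stickKappaLimit()]
#' (including kappa = Inf from odi = 0) the aligned-stick form
#' -b d (g.mu)^2 is used.
#'
#' @param kappa concentration; @param bd b*dPar per volume;
#' @param ct2 squared cosine between gradient and fibre axis per volume
#' @noRd
.logStickRatio <- function(kappa, bd, ct2, order = NULL) {
  if (kappa >= stickKappaLimit()) return(-bd * ct2)
  if (is.null(order)) order <- .quadOrder(kappa + max(bd, 0))
  rule <- .glRule(order)
  watsonStickLogRatioCpp(kappa, bd, ct2, rule$x, rule$w)
}
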