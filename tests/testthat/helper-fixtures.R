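# Shared fixtures: everything is generated in code at test time.

# short MH chains for test-speed fits; posterior means at these lengths are
# accurate to well within the tolerances asserted
quickChain <- list(nSamples = 3000L, burnIn = 1000L)

quickFitConfig <- function(kind = "real", seed = 1L, ...) {
  FitConfig(kind, nSamples = quickChain$nSamples,
            burnIn = quickChain$burnIn, seed = seed, ...)
}

# small three-shell scheme (the study shells, fewer directions)
smallScheme <- function(nDir = 16L, nB0 = 2L, seed = 1L) {
  makeScheme(SimulationConfig(nDir = nDir, nB0 = nB0, seed = seed))
}

# deterministic near-uniform direction set
fibDirections <- function(n) hibnoddi:::.fibonacciSphere(n)

# random symmetric 3x3 matrix with entries of the given scale
randomSym3 <- function(scale = 5) {
  A <- matrix(rnorm(9, sd = scale), 3, 3)
  (A + t(A)) / 2
}

# random rotation matrix
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
           2*(x*y+w*z), 1 - 2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y), 2*(y*z+w*x), 1 - 2*(x^2+y^2)), 3, 3, byrow = TRUE)
}
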