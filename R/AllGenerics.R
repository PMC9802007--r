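## Accessor generics and show methods.  Slots are never reached into from
## user code; these accessors are the supported surface.

#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @export
setGeneric("gradients", function(x) standardGeneric("gradients"))
#' @export
setGeneric("shellIds", function(x) standardGeneric("shellIds"))
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @export
setGeneric("shellTable", function(x) standardGeneric("shellTable"))
#' @export
setGeneric("odi", function(x) standardGeneric("odi"))
#' @export
setGeneric("watsonKappa", function(x) standardGeneric("watsonKappa"))
#' @export
setGeneric("fibreAxis", function(x) standardGeneric("fibreAxis"))
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @export
setGeneric("dataKind", function(x) standardGeneric("dataKind"))
#' @export
setGeneric("s0Values", function(x) standardGeneric("s0Values"))
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @export
setGeneric("acquisitionScheme", function(x) standardGeneric("acquisitionScheme"))
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))
#' @export
setGeneric("acceptanceRate", function(x) standardGeneric("acceptanceRate"))
#' @export
setGeneric("posteriorSummary", function(x, ...) standardGeneric("posteriorSummary"))

#' Accessors for AcquisitionScheme
#'
#' @param x an [AcquisitionScheme-class]
#' @return `bValues`: numeric b-values (ms/um^2); `gradients`: (volumes x 3)
#'   matrix; `shellIds`: integer labels (0 = lowest-b cluster); `nVolumes`:
#'   volume count; `shellTable`: data.frame of shell id, b and volume count.
#' @name scheme-accessors
#' @aliases bValues gradients shellIds nVolumes shellTable
NULL

#' @rdname scheme-accessors
#' @export
setMethod("bValues", "AcquisitionScheme", function(x) x@b)
#' @rdname scheme-accessors
#' @export
setMethod("gradients", "AcquisitionScheme", function(x) x@g)
#' @rdname scheme-accessors
#' @export
setMethod("shellIds", "AcquisitionScheme", function(x) x@shellId)
#' @rdname scheme-accessors
#' @export
setMethod("nVolumes", "AcquisitionScheme", function(x) length(x@b))
#' @rdname scheme-accessors
#' @export
setMethod("shellTable", "AcquisitionScheme", function(x) {
  ids <- sort(unique(x@shellId))
  data.frame(shell = ids,
             b = vapply(ids, function(s) x@b[x@shellId == s][1], 0),
             n = vapply(ids, function(s) sum(x@shellId == s), 0L))
})

#' Accessors for dispersion, orientation and noise parameters
#'
#' @param x a [DispersionIndex-class], [WatsonStickParams-class],
#'   [FibreOrientation-class] or [NoiseParams-class]
#' @name param-accessors
#' @aliases odi watsonKappa fibreAxis
NULL

#' @rdname param-accessors
#' @export
setMethod("odi", "DispersionIndex", function(x) x@odi)
#' @rdname param-accessors
#' @export
setMethod("watsonKappa", "DispersionIndex", function(x) x@kappa)
#' @rdname param-accessors
#' @export
setMethod("odi", "WatsonStickParams", function(x) x@dispersion@odi)
#' @rdname param-accessors
#' @export
setMethod("watsonKappa", "WatsonStickParams", function(x) x@dispersion@kappa)
#' @rdname param-accessors
#' @export
setMethod("fibreAxis", "FibreOrientation", function(x) x@mu)
#' @rdname param-accessors
#' @export
setMethod("fibreAxis", "WatsonStickParams", function(x) x@orientation@mu)

#' @rdname param-accessors
#' @export
dPar <- function(x) {
  stopifnot(is(x, "WatsonStickParams"))
  x@dPar
}

#' @rdname param-accessors
#' @export
intraSignal <- function(x) {
  stopifnot(is(x, "WatsonStickParams"))
  x@F
}

#' @rdname param-accessors
#' @export
offsetC <- function(x) {
  stopifnot(is(x, "NoiseParams"))
  x@c
}

#' @rdname param-accessors
#' @export
ricianEpsilon <- function(x) {
  stopifnot(is(x, "NoiseParams"))
  x@epsilon
}

#' @rdname param-accessors
#' @export
gaussianSigma <- function(x) {
  stopifnot(is(x, "NoiseParams"))
  x@sigma
}

#' Accessors for VoxelDataset
#'
#' @param x a [VoxelDataset-class]
#' @name dataset-accessors
#' @aliases signalMatrix dataKind s0Values nVoxels acquisitionScheme
NULL

#' @rdname dataset-accessors
#' @export
setMethod("signalMatrix", "VoxelDataset", function(x) x@Y)
#' @rdname dataset-accessors
#' @export
setMethod("dataKind", "VoxelDataset", function(x) x@kind)
#' @rdname dataset-accessors
#' @export
setMethod("s0Values", "VoxelDataset", function(x) x@S0)
#' @rdname dataset-accessors
#' @export
setMethod("nVoxels", "VoxelDataset", function(x) nrow(x@Y))
#' @rdname dataset-accessors
#' @export
setMethod("acquisitionScheme", "VoxelDataset", function(x) x@scheme)

#' Accessors for PosteriorSamples
#'
#' @param x a [PosteriorSamples-class]
#' @param ... unused
#' @return `posteriorDraws`: the samples x parameters matrix;
#'   `acceptanceRate`: per-parameter realised acceptance rates;
#'   `posteriorSummary`: data.frame with mean, std and quantiles per
#'   parameter, recomputed from the stored draws.
#' @name posterior-accessors
#' @aliases posteriorDraws acceptanceRate posteriorSummary
NULL

#' @rdname posterior-accessors
#' @export
setMethod("posteriorDraws", "PosteriorSamples", function(x) x@draws)
#' @rdname posterior-accessors
#' @export
setMethod("acceptanceRate", "PosteriorSamples", function(x) x@acceptanceRate)
#' @rdname posterior-accessors
#' @export
setMethod("posteriorSummary", "PosteriorSamples", function(x, ...) {
  d <- x@draws
  data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    std = apply(d, 2, sd),
    q025 = apply(d, 2, quantile, 0.025),
    q50 = apply(d, 2, quantile, 0.5),
    q975 = apply(d, 2, quantile, 0.975),
    row.names = NULL)
})

setMethod("show", "AcquisitionScheme", function(object) {
  tab <- shellTable(object)
  cat("AcquisitionScheme:", nVolumes(object), "volumes,",
      nrow(tab), "shells\n")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  shell %d: b = %.3g ms/um^2, %d volumes\n",
                tab$shell[i], tab$b[i], tab$n[i]))
})

setMethod("show", "DispersionIndex", function(object) {
  cat(sprintf("DispersionIndex: ODI = %.4g (kappa = %.4g)\n",
              object@odi, object@kappa))
})

setMethod("show", "WatsonStickParams", function(object) {
  cat(sprintf(paste0("WatsonStickParams: ODI = %.4g, dPar = %.4g um^2/ms, ",
                     "F = %.4g\n  fibre axis: [%.3f, %.3f, %.3f]\n"),
              odi(object), object@dPar, object@F,
              object@orientation@mu[1], object@orientation@mu[2],
              object@orientation@mu[3]))
})

setMethod("show", "NoiseParams", function(object) {
  cat(sprintf("NoiseParams: c = %.4g, epsilon = %.4g, sigma = %.4g\n",
              object@c, object@epsilon, object@sigma))
})

setMethod("show", "VoxelDataset", function(object) {
  cat(sprintf("VoxelDataset (%s): %d voxel(s) x %d volumes, mean S0 = %.4g\n",
              object@kind, nrow(object@Y), ncol(object@Y), mean(object@S0)))
})

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples:", nrow(object@draws), "draws of",
      ncol(object@draws), "parameters (seed", object@seed, ")\n")
  print(posteriorSummary(object), digits = 4)
})
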