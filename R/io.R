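## FSL-style gradient-table text formats: bvals is a single
## whitespace-separated row, bvecs three rows (x, y, z) of unit vectors.

#' Read and write FSL-style bvals/bvecs files
#'
#' `readBvals` accepts b-values in ms/um^2 or, with `bUnit = "s/mm2"`, in
#' s/mm^2 (divided by 1000 on read).  `readScheme` combines both files
#' into an [AcquisitionScheme-class], inferring shells by clustering
#' b-values to `shellTol` (default 0.1 ms/um^2).
#'
#' @param path file to read or write
#' @param bUnit unit of the stored b-values
#' @return `readBvals`: numeric vector; `readBvecs`: (volumes x 3) matrix;
#'   `readScheme`: an [AcquisitionScheme-class]
#' @export
readBvals <- function(path, bUnit = c("ms/um2", "s/mm2")) {
  bUnit <- match.arg(bUnit)
  b <- scan(path, quiet = TRUE)
  if (bUnit == "s/mm2") b <- b / 1000
  b
}

#' @rdname readBvals
#' @export
readBvecs <- function(path) {
  m <- as.matrix(read.table(path))
  if (nrow(m) != 3) stop("bvecs must have exactly 3 rows")
  unname(t(m))
}

#' @rdname readBvals
#' @param bvalsPath,bvecsPath the two gradient-table files
#' @param shellTol shell clustering tolerance, ms/um^2
#' @export
readScheme <- function(bvalsPath, bvecsPath, bUnit = c("ms/um2", "s/mm2"),
                       shellTol = 0.1) {
  AcquisitionScheme(readBvals(bvalsPath, bUnit), readBvecs(bvecsPath),
                    shellTol = shellTol)
}

#' @rdname readBvals
#' @param scheme an [AcquisitionScheme-class] to write
#' @export
writeBvals <- function(scheme, path, bUnit = c("ms/um2", "s/mm2")) {
  bUnit <- match.arg(bUnit)
  b <- bValues(scheme)
  if (bUnit == "s/mm2") b <- b * 1000
  writeLines(paste(format(b, trim = TRUE), collapse = " "), path)
  invisible(path)
}

#' @rdname readBvals
#' @export
writeBvecs <- function(scheme, path) {
  g <- t(gradients(scheme))
  write.table(format(g, trim = TRUE), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write or read a voxel dataset as plain-text files
#'
#' `writeVoxelDataset` writes `<prefix>.bvals`, `<prefix>.bvecs`,
#' `<prefix>.csv` (voxels x volumes signal matrix) and `<prefix>.json`
#' (kind, per-voxel S0 and optional seed stamp).  `readVoxelDataset`
#' reads them back.
#'
#' @param dataset a [VoxelDataset-class]
#' @param prefix path prefix for the four files
#' @param seed optional seed to stamp into the JSON sidecar
#' @return the prefix, invisibly (write) or a [VoxelDataset-class] (read)
#' @export
writeVoxelDataset <- function(dataset, prefix, seed = NULL) {
  writeBvals(acquisitionScheme(dataset), paste0(prefix, ".bvals"))
  writeBvecs(acquisitionScheme(dataset), paste0(prefix, ".bvecs"))
  write.table(signalMatrix(dataset), paste0(prefix, ".csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(kind = dataKind(dataset), S0 = s0Values(dataset), seed = seed),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname writeVoxelDataset
#' @export
readVoxelDataset <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  sch <- readScheme(paste0(prefix, ".bvals"), paste0(prefix, ".bvecs"))
  Y <- as.matrix(read.table(paste0(prefix, ".csv"), sep = ","))
  dimnames(Y) <- NULL
  VoxelDataset(Y, meta$kind, meta$S0, sch)
}
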