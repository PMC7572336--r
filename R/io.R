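# NIfTI-1 and sidecar I/O for phantoms and parcellations.

#' Write a phantom as NIfTI volumes with a JSON sidecar
#'
#' One `.nii.gz` per channel and label volume (t1, flair, fse, tissue,
#' lobes, lesion), all sharing the affine implied by the voxel size, plus a
#' JSON sidecar carrying the generating spec.
#'
#' @param phantom A `brain_phantom`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "brain_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vols <- c(phantom$channels,
            list(tissue = phantom$tissue, lobes = phantom$lobes,
                 lesion = phantom$lesion * 1L))
  paths <- vapply(names(vols), function(nm) {
    path <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    img <- RNifti::asNifti(vols[[nm]])
    RNifti::pixdim(img) <- phantom$voxel_size
    RNifti::writeNifti(img, path)
    path
  }, "")
  spec <- phantom$spec
  spec$class_intensity_means <- as.data.frame(spec$class_intensity_means)
  sidecar <- file.path(dir, paste0(prefix, "_spec.json"))
  jsonlite::write_json(unclass(spec), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, spec = sidecar))
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir Directory holding the volumes.
#' @param prefix File name prefix used at write time.
#' @return A `brain_phantom`.
#' @export
read_phantom <- function(dir, prefix = "phantom") {
  vol <- function(nm) {
    img <- RNifti::readNifti(file.path(dir, paste0(prefix, "_", nm, ".nii.gz")))
    array(as.numeric(img), dim(img))
  }
  sidecar <- file.path(dir, paste0(prefix, "_spec.json"))
  spec <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  spec$class_intensity_means <- as.matrix(spec$class_intensity_means)
  class(spec) <- "phantom_spec"
  structure(
    list(channels = list(t1 = vol("t1"), flair = vol("flair"), fse = vol("fse")),
         tissue = array(as.integer(vol("tissue")), dim(vol("tissue"))),
         lobes = array(as.integer(vol("lobes")), dim(vol("lobes"))),
         lesion = vol("lesion") > 0.5,
         voxel_size = as.numeric(spec$voxel_size), spec = spec),
    class = "brain_phantom"
  )
}

#' Write a parcellation as a NIfTI volume plus a CSV lookup table
#'
#' @param parc A `bullseye_parcellation`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @param voxel_size Voxel size (mm) for the NIfTI header.
#' @return Invisibly, the written paths.
#' @export
write_parcellation <- function(parc, dir, prefix = "bullseye",
                               voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(parc, "bullseye_parcellation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- parc$labels
  labs[is.na(labs)] <- -1L
  img <- RNifti::asNifti(labs)
  RNifti::pixdim(img) <- voxel_size
  nii <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  RNifti::writeNifti(img, nii)
  csv <- file.path(dir, paste0(prefix, "_lookup.csv"))
  utils::write.csv(parc$lookup, csv, row.names = FALSE)
  invisible(c(labels = nii, lookup = csv))
}
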