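# NIfTI and gradient-table I/O.  Volumes go through RNifti; gradient tables
# use the FSL text dialect: .bval is one row of K b-values, .bvec three rows
# (x, y, z) of K direction components, zero columns marking b = 0 volumes.

#' Read a diffusion-weighted dataset
#'
#' Loads a 4-D NIfTI volume together with FSL-style `.bval` / `.bvec`
#' gradient tables.  Directions whose norm deviates from one by more than
#' 1e-3 are renormalized with a warning; zero vectors (b = 0 reference
#' volumes) are accepted as-is.
#'
#' @param path path to the 4-D NIfTI image.
#' @param bval_path,bvec_path paths to the gradient table; default to
#'   `path` with extensions `.bval` / `.bvec`.
#' @param mask_path optional NIfTI mask.
#' @return a `dwi_dataset` (see [simulate_dwi()]).
#' @export
read_dwi <- function(path, bval_path = NULL, bvec_path = NULL,
                     mask_path = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  bval_path <- bval_path %||% paste0(stem, ".bval")
  bvec_path <- bvec_path %||% paste0(stem, ".bvec")
  img <- RNifti::readNifti(path)
  data <- unclass(as.array(img))
  if (length(dim(data)) != 4L) stop("expected a 4-D NIfTI volume")
  bvals <- as.numeric(scan(bval_path, quiet = TRUE))
  bvecs <- as.matrix(utils::read.table(bvec_path))
  dimnames(bvecs) <- NULL
  if (nrow(bvecs) != 3L) stop("'.bvec' must have 3 rows (x, y, z)")
  n_vol <- dim(data)[4]
  if (length(bvals) != n_vol || ncol(bvecs) != n_vol)
    stop("gradient table length does not match the number of volumes")
  nrm <- sqrt(colSums(bvecs^2))
  weighted <- bvals > 0
  bad <- weighted & abs(nrm - 1) > 1e-3
  if (any(bad)) {
    warning(sum(bad), " direction(s) renormalized (|g| off by > 1e-3)")
    bvecs[, bad] <- sweep(bvecs[, bad, drop = FALSE], 2L, nrm[bad], "/")
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- unclass(as.array(RNifti::readNifti(mask_path))) > 0
    if (!identical(dim(mask), dim(data)[1:3]))
      stop("mask grid does not match the image")
  }
  structure(list(data = data, bvals = bvals, bvecs = bvecs, mask = mask,
                 voxel_size = RNifti::pixdim(img)[1:3],
                 affine = RNifti::xform(img)),
            class = "dwi_dataset")
}

#' Write a diffusion-weighted dataset
#'
#' Writes the 4-D volume as NIfTI, the gradient table as FSL `.bval` /
#' `.bvec`, the mask (if any) as a label NIfTI, and a JSON sidecar
#' recording the acquisition protocol and seed.
#'
#' @param dwi a `dwi_dataset`.
#' @param prefix output path prefix (files `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`, `<prefix>_mask.nii.gz`,
#'   `<prefix>.json`).
#' @return invisibly, the paths written.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  paths <- c(image = paste0(prefix, ".nii.gz"),
             bval = paste0(prefix, ".bval"),
             bvec = paste0(prefix, ".bvec"))
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, paths["image"])
  writeLines(paste(format(dwi$bvals, trim = TRUE), collapse = " "),
             paths["bval"])
  writeLines(apply(dwi$bvecs, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")),
    paths["bvec"])
  if (!is.null(dwi$mask)) {
    paths["mask"] <- paste0(prefix, "_mask.nii.gz")
    mimg <- RNifti::asNifti(array(as.integer(dwi$mask), dim(dwi$mask)))
    RNifti::pixdim(mimg) <- dwi$voxel_size
    RNifti::writeNifti(mimg, paths["mask"])
  }
  paths["sidecar"] <- paste0(prefix, ".json")
  proto <- dwi$protocol
  sidecar <- list(
    n_volumes = dim(dwi$data)[4],
    voxel_size_mm = dwi$voxel_size,
    coordinate_convention = "voxel indices 1-based (R); NIfTI affine for world coordinates",
    protocol = if (!is.null(proto))
      proto[c("bvalue", "n_directions", "n_b0", "te", "tr", "n_pe",
              "bandwidth", "bandwidth_pe", "accel", "seed")])
  jsonlite::write_json(sidecar, paths["sidecar"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write a scalar map as NIfTI
#'
#' @param map numeric array (NA outside the region of interest).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge lengths in mm.
#' @param na_value value substituted for `NA` voxels.
#' @return invisibly, `path`.
#' @export
write_map <- function(map, path, voxel_size = c(1.3, 1.3, 1.3),
                      na_value = 0) {
  m <- as.array(map)
  m[!is.finite(m)] <- na_value
  img <- RNifti::asNifti(m)
  RNifti::pixdim(img) <- voxel_size[seq_len(min(3, length(dim(m))))]
  RNifti::writeNifti(img, path)
  invisible(path)
}
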