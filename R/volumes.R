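#' Create a 3D scalar volume with voxel geometry and modality tag
#'
#' Container for one midbrain image volume. Intensities are arbitrary units
#' (a.u.) for neuromelanin-sensitive, SWI-magnitude and SMWI images, and parts
#' per billion (ppb) for quantitative susceptibility maps (QSM).
#'
#' @param data numeric 3D array of voxel values; all values must be finite.
#' @param voxel_dims numeric length-3 vector of voxel dimensions in mm
#'   (x, y, z); all positive.
#' @param modality one of `"NM"`, `"QSM"`, `"SWI_MAG"`, `"SMWI"`.
#' @return An object of class `volume_image`: the data array with
#'   `voxel_dims`, `modality` and `units` attributes.
#' @examples
#' v <- volume_image(array(1, c(4, 4, 2)), c(0.5, 0.5, 3), "NM")
#' voxel_dims(v)
#' @export
volume_image <- function(data, voxel_dims, modality = c("NM", "QSM", "SWI_MAG", "SMWI")) {
  modality <- match.arg(modality)
  nq_assert(is.array(data) && length(dim(data)) == 3L,
            "`data` must be a 3D array")
  nq_assert(all(is.finite(data)), "volume contains non-finite voxels")
  nq_assert(length(voxel_dims) == 3L && all(voxel_dims > 0),
            "`voxel_dims` must be three positive mm values")
  structure(data,
            voxel_dims = as.numeric(voxel_dims),
            modality = modality,
            units = if (modality == "QSM") "ppb" else "a.u.",
            class = c("volume_image", "array"))
}

#' @rdname volume_image
#' @param x a `volume_image` or mask array.
#' @export
voxel_dims <- function(x) attr(x, "voxel_dims")

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_image> %s [%s], %d x %d x %d voxels of %s mm\n",
              attr(x, "modality"), attr(x, "units"), d[1], d[2], d[3],
              paste(signif(voxel_dims(x), 3), collapse = " x ")))
  invisible(x)
}

#' Bundle SN and background masks with the analysis-slice convention
#'
#' Substantia-nigra (SN) segmentation in this workflow is restricted to three
#' representative axial slices per modality (chosen just below the inferior
#' pole of the red nucleus on iron-sensitive images, and through the
#' interpeduncular fossa on neuromelanin-sensitive images). The SN mask covers
#' both hemispheres on those slices; the background mask is a reference region
#' used for signal normalisation and threshold derivation.
#'
#' @param sn_mask binary (0/1) 3D array delineating the bilateral SN.
#' @param background_mask binary 3D array of the background reference region,
#'   disjoint from `sn_mask`.
#' @param analysis_slices integer vector of three slice (third-dimension)
#'   indices that carry the SN mask.
#' @param voxel_dims optional numeric length-3 voxel dimensions in mm carried
#'   with the masks.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(sn_mask, background_mask, analysis_slices,
                     voxel_dims = NULL) {
  nq_assert(is.array(sn_mask) && length(dim(sn_mask)) == 3L,
            "`sn_mask` must be a 3D array")
  nq_assert(identical(dim(sn_mask), dim(background_mask)),
            "SN and background masks must share a grid")
  sn_mask <- sn_mask != 0
  background_mask <- background_mask != 0
  if (!any(sn_mask))
    nq_stop("SN mask is empty", "nigraquant_degenerate_mask")
  if (!any(background_mask))
    nq_stop("background mask is empty", "nigraquant_degenerate_mask")
  nq_assert(!any(sn_mask & background_mask),
            "SN and background masks overlap")
  analysis_slices <- sort(unique(as.integer(analysis_slices)))
  slice_has_sn <- apply(sn_mask, 3, any)
  nq_assert(all(which(slice_has_sn) %in% analysis_slices),
            "SN mask voxels fall outside the declared analysis slices")
  structure(list(sn_mask = sn_mask,
                 background_mask = background_mask,
                 analysis_slices = analysis_slices,
                 voxel_dims = if (is.null(voxel_dims)) NULL else as.numeric(voxel_dims)),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> SN %d voxels, background %d voxels, slices %s\n",
              sum(x$sn_mask), sum(x$background_mask),
              paste(x$analysis_slices, collapse = ",")))
  invisible(x)
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti} that preserve the voxel geometry and the
#' modality tag used throughout the package. Masks are written as uint8,
#' images as float32.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag to attach on read (NIfTI does not store it).
#' @return `read_volume` returns a [volume_image]; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, modality = c("NM", "QSM", "SWI_MAG", "SMWI")) {
  img <- RNifti::readNifti(path)
  vd <- RNifti::pixdim(img)[seq_len(3)]
  volume_image(array(as.numeric(img), dim = dim(img)[seq_len(3)]),
               vd, match.arg(modality))
}

#' @rdname read_volume
#' @param volume a [volume_image] (or binary mask array for `write_mask`).
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(unclass(volume) * 1.0, datatype = "float")
  RNifti::pixdim(img) <- voxel_dims(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param mask binary 3D array.
#' @param voxel_dims voxel dimensions in mm for the mask grid.
#' @export
write_mask <- function(mask, path, voxel_dims) {
  img <- RNifti::asNifti(array(as.integer(mask != 0), dim = dim(mask)),
                         datatype = "uint8")
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  list(mask = array(as.numeric(img) != 0, dim = dim(img)[seq_len(3)]),
       voxel_dims = RNifti::pixdim(img)[seq_len(3)])
}
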