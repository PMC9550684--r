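#' Tissue label codes
#'
#' Fixed five-class coding for segmentation volumes:
#' 0 = background, 1 = fat, 2 = fibroglandular, 3 = vessel, 4 = tumor.
#'
#' @format Named integer vector.
#' @export
TISSUE_LABELS <- c(background = 0L, fat = 1L, fibroglandular = 2L,
                   vessel = 3L, tumor = 4L)

#' Build a tissue lattice from a labeled volume
#'
#' Constructs the cubic-voxel simulation substrate from a 3D integer label
#' volume (the output of a segmentation step). Voxels are cube-shaped with
#' side `voxel_side` mm; physical placement is carried by a NIfTI-style
#' 4x4 affine. Voxel indices are 0-based in physical-space computations and
#' fields are cell-centered.
#'
#' @param labels_volume integer 3D array using the coding in [TISSUE_LABELS].
#' @param voxel_side voxel edge length in mm (> 0).
#' @param affine 4x4 affine mapping voxel indices to mm; defaults to a
#'   diagonal scaling by `voxel_side`.
#' @return An object of class `tissue_lattice` with elements `labels`,
#'   `shape`, `voxel_side`, `affine`, `n_tumor_voxels`.
#' @export
build_lattice <- function(labels_volume, voxel_side, affine = NULL) {
  if (!is.numeric(voxel_side) || length(voxel_side) != 1L || voxel_side <= 0)
    stop("voxel_side must be a single positive length in mm", call. = FALSE)
  if (length(dim(labels_volume)) != 3L)
    stop("labels_volume must be a 3D array", call. = FALSE)
  lv <- labels_volume
  if (any(lv != round(lv)))
    stop("labels_volume must be integer-valued", call. = FALSE)
  storage.mode(lv) <- "integer"
  bad <- setdiff(unique(as.vector(lv)), unname(TISSUE_LABELS))
  if (length(bad))
    stop("unknown tissue label code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_side, voxel_side, voxel_side, 1))
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  n_tumor <- sum(lv == TISSUE_LABELS[["tumor"]])
  if (n_tumor == 0L)
    warning("lattice contains no tumor voxels", call. = FALSE)
  structure(list(
    labels = lv,
    shape = dim(lv),
    voxel_side = as.numeric(voxel_side),
    affine = affine,
    n_tumor_voxels = n_tumor
  ), class = "tissue_lattice")
}

#' @export
print.tissue_lattice <- function(x, ...) {
  cat(sprintf("tissue_lattice: %d x %d x %d voxels, side %.3g mm, %d tumor voxels\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_side,
              x$n_tumor_voxels))
  invisible(x)
}

#' Create a per-voxel tumor cell-density field
#'
#' Density is stored in cells/mm^3 against a carrying capacity `rho_max`.
#' The imaging-equivalent ("detectable") volume counts voxels whose density
#' is at least `rho_detect * rho_max`, mirroring how a predicted volume is
#' compared to an MRI segmentation rather than to total cell mass.
#'
#' @param rho 3D array of densities, same shape as the lattice.
#' @param rho_max carrying capacity (cells/mm^3), default 1e6.
#' @param rho_detect detection threshold fraction in (0, 1), default 0.10.
#' @param lattice optional `tissue_lattice` for shape validation.
#' @return Object of class `cell_density_field`.
#' @export
cell_density_field <- function(rho, rho_max = 1e6, rho_detect = 0.10,
                               lattice = NULL) {
  if (length(dim(rho)) != 3L)
    stop("rho must be a 3D array", call. = FALSE)
  if (rho_max <= 0) stop("rho_max must be positive", call. = FALSE)
  if (rho_detect <= 0 || rho_detect >= 1)
    stop("rho_detect must lie strictly in (0, 1)", call. = FALSE)
  if (any(rho < 0) || any(rho > rho_max + 1e-9 * rho_max))
    stop("rho must lie in [0, rho_max]", call. = FALSE)
  if (!is.null(lattice) && !all(dim(rho) == lattice$shape))
    stop("rho shape does not match lattice shape", call. = FALSE)
  structure(list(rho = rho, rho_max = rho_max, rho_detect = rho_detect),
            class = "cell_density_field")
}

#' Detectable tumor volume in cm^3
#'
#' Volume is the count of voxels whose density reaches the detection
#' threshold `rho_detect * rho_max`, times the voxel volume, in cm^3
#' (1 mm^3 = 1e-3 cm^3).
#'
#' @param density a `cell_density_field`.
#' @param lattice the `tissue_lattice` the field lives on.
#' @return volume in cm^3 (non-negative scalar).
#' @export
tumor_volume <- function(density, lattice) {
  stopifnot(inherits(density, "cell_density_field"),
            inherits(lattice, "tissue_lattice"))
  if (!all(dim(density$rho) == lattice$shape))
    stop("density and lattice shapes differ", call. = FALSE)
  v_vox_cm3 <- (lattice$voxel_side^3) * 1e-3
  n <- sum(density$rho >= density$rho_detect * density$rho_max)
  n * v_vox_cm3
}

#' Read a NIfTI label volume
#'
#' Reads an integer NIfTI-1 volume and returns the label array, the voxel
#' side (mm) and the affine. Anisotropic spacing is accepted with a warning;
#' the voxel side is then the geometric mean of the three spacings and the
#' result is flagged.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return list with `labels_volume`, `voxel_side`, `affine`,
#'   `anisotropic` flag.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (any(arr != round(arr)))
    stop("NIfTI volume is not integer-valued; expected a label mask",
         call. = FALSE)
  arr <- array(as.integer(arr), dim(arr))
  pd <- RNifti::pixdim(img)[1:3]
  aniso <- max(pd) / min(pd) > 1 + 1e-6
  if (aniso) {
    warning("anisotropic voxel spacing; using geometric mean as voxel_side",
            call. = FALSE)
  }
  list(labels_volume = arr,
       voxel_side = if (aniso) exp(mean(log(pd))) else pd[1],
       affine = structure(RNifti::xform(img), class = "matrix"),
       anisotropic = aniso)
}

#' Write a tissue lattice as a NIfTI label volume
#'
#' Integer labels round-trip bit-exactly through [read_mask_nifti()]. A JSON
#' sidecar with the lattice metadata is written next to the volume.
#'
#' @param lattice a `tissue_lattice`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param sidecar write the JSON metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(lattice, path, sidecar = TRUE) {
  stopifnot(inherits(lattice, "tissue_lattice"))
  arr <- lattice$labels
  attr(arr, "pixdim") <- rep(lattice$voxel_side, 3)
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  if (sidecar) {
    meta <- list(shape = lattice$shape, voxel_side = lattice$voxel_side,
                 n_tumor_voxels = lattice$n_tumor_voxels,
                 label_coding = as.list(TISSUE_LABELS))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
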