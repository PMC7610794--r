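# NIfTI-1 input/output for volumes, warps and displacement fields.
#
# Geometry convention: only axis-aligned grids are supported. The sform
# (and qform) is the diagonal voxel-size matrix with the origin in the
# translation column; displacement fields are stored as 4D NIfTI with the
# fourth dimension holding the x/y/z components in world mm.

#' Read / write a 3D NIfTI volume
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [image_volume()]; voxel size and origin come from the NIfTI
#'   transform (axis-aligned grids only).
#' @export
read_image <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4L && d[4] == 1L) { d <- d[1:3]; dim(im) <- d }
  if (length(d) != 3L)
    stop("read_image: expected a 3D scalar volume, got ",
         length(d), "D: ", path)
  xf <- RNifti::xform(im)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(rot)))
    stop("read_image: only axis-aligned (diagonal transform) NIfTI grids ",
         "are supported: ", path)
  image_volume(array(as.numeric(im), d),
               voxel_size = abs(diag(rot)), origin = xf[1:3, 4])
}

#' @rdname read_image
#' @param vol an [image_volume()] (for `write_image`).
#' @param datatype NIfTI on-disk type; `"double"` round-trips exactly.
#' @export
write_image <- function(vol, path, datatype = "double") {
  write_nifti_array(vol$data, vol$voxel_size, vol$origin, path, datatype)
}

write_nifti_array <- function(arr, voxel_size, origin, path,
                              datatype = "double") {
  im <- RNifti::asNifti(arr)
  m <- diag(c(voxel_size, 1))
  m[1:3, 4] <- origin
  RNifti::sform(im) <- structure(m, code = 2L)
  RNifti::qform(im) <- structure(m, code = 2L)
  RNifti::pixdim(im) <- c(voxel_size, rep(1, length(dim(arr)) - 3L))
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' Serialise / load a spline warp
#'
#' The warp is written as two files: `<path>` is a 4D NIfTI whose fourth
#' dimension holds the three coefficient grids (mm, double precision, so
#' the round trip is bit-exact), and `<path>.json` records the knot
#' spacing and the reference geometry. The NIfTI transform of the
#' coefficient file stores the knot lattice (spacing as voxel size, first
#' knot position as origin).
#'
#' @param warp a [spline_warp()].
#' @param path output `.nii`/`.nii.gz` path; the sidecar gets `.json`
#'   appended.
#' @return `read_warp`: a [spline_warp()]; `write_warp`: `path`, invisibly.
#' @export
write_warp <- function(warp, path) {
  co <- array(0, c(warp$K, 3L))
  for (i in 1:3) co[, , , i] <- warp$coeffs[[i]]
  knot0 <- warp$ref_geom$origin - warp$knot_spacing
  im <- RNifti::asNifti(co)
  m <- diag(c(warp$knot_spacing, 1))
  m[1:3, 4] <- knot0
  RNifti::sform(im) <- structure(m, code = 2L)
  RNifti::qform(im) <- structure(m, code = 2L)
  RNifti::pixdim(im) <- c(warp$knot_spacing, 1)
  RNifti::writeNifti(im, path, datatype = "double")
  meta <- list(format = "warpreg_spline_warp", version = 1L,
               knot_spacing = warp$knot_spacing,
               ref_shape = warp$ref_geom$shape,
               ref_voxel_size = warp$ref_geom$voxel_size,
               ref_origin = warp$ref_geom$origin)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_warp
#' @export
read_warp <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "warpreg_spline_warp"))
    stop("read_warp: ", path, ".json is not a warp sidecar")
  co <- RNifti::readNifti(path)
  d <- dim(co)
  if (length(d) != 4L || d[4] != 3L)
    stop("read_warp: expected a 4D coefficient file with 3 components")
  geom <- vol_geometry(meta$ref_shape, meta$ref_voxel_size, meta$ref_origin)
  co <- array(as.numeric(co), d)
  spline_warp(list(co[, , , 1], co[, , , 2], co[, , , 3]),
              meta$knot_spacing, geom)
}

#' Write / read a dense displacement field
#'
#' 4D NIfTI (3 components, world mm) on the reference grid: the
#' interoperable export of a warp. `write_displacement` evaluates the
#' spline on its reference grid (or accepts a precomputed 4D array).
#'
#' @param warp a [spline_warp()], or a list with fields `displacement`
#'   (4D array) and `geom` as returned by [invert_warp()].
#' @param path output path.
#' @export
write_displacement <- function(warp, path) {
  if (inherits(warp, "spline_warp")) {
    disp <- evaluate_displacement(warp)
    geom <- warp$ref_geom
  } else {
    disp <- warp$displacement
    geom <- geometry_of(warp$geom)
  }
  write_nifti_array(disp, c(geom$voxel_size), geom$origin, path,
                    datatype = "double")
}

#' @rdname write_displacement
#' @return `read_displacement`: list with `displacement` (4D array, mm)
#'   and `geom`.
#' @export
read_displacement <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L || d[4] != 3L)
    stop("read_displacement: expected 4D NIfTI with 3 components")
  xf <- RNifti::xform(im)
  list(displacement = array(as.numeric(im), d),
       geom = vol_geometry(d[1:3], abs(diag(xf[1:3, 1:3])), xf[1:3, 4]))
}

# JSON-serialisable form of a quality report (histograms trimmed of the
# dense maps).
report_to_list <- function(rep) {
  out <- list(jacdet = list(summary = as.list(rep$jacdet$summary),
                            all_positive = rep$jacdet$all_positive,
                            n = rep$jacdet$n),
              cvar = rep$cvar)
  if (!is.null(rep$jacdet$log_summary))
    out$jacdet$log_summary <- as.list(rep$jacdet$log_summary)
  if (!is.null(rep$overlap)) out$overlap <- rep$overlap
  out
}

#' Write a warp-audit report as JSON
#'
#' Serialises a [warp_quality_report()] (summary statistics and overlap
#' table; the dense maps are omitted) together with a provenance block.
#'
#' @param rep a `warp_quality_report`.
#' @param path output `.json` path.
#' @param provenance optional named list (config, seed, ...) stored
#'   verbatim.
#' @export
write_report <- function(rep, path, provenance = NULL) {
  out <- report_to_list(rep)
  out$provenance <- c(list(package = "warpreg",
                           version = as.character(utils::packageVersion("warpreg")),
                           r_version = R.version.string,
                           date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                      provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
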