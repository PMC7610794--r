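#' 3D scalar volumes with voxel geometry
#'
#' An `image_volume` couples a 3D numeric array with its voxel geometry:
#' voxel size in mm and the world (mm) coordinate of the centre of the
#' first voxel. World coordinates follow
#' `world = origin + voxel_index * voxel_size` with 0-based voxel indices,
#' so the grid is axis-aligned in mm.
#'
#' @param data 3D numeric array of finite values.
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of voxel (0,0,0).
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 8)), voxel_size = c(2, 2, 2))
#' voxel_volume(v)
#' @export
image_volume <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("image_volume: 'voxel_size' must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: 'origin' must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    stop("image_volume: 'data' contains non-finite values")
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(format(x$voxel_size), collapse = " x "),
      " mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  cat("  intensity range [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' Grid geometry of a volume or warp reference
#'
#' @param shape integer length-3 number of voxels per axis.
#' @param voxel_size,origin as in [image_volume()].
#' @return A `vol_geometry` list with fields `shape`, `voxel_size`, `origin`.
#' @export
vol_geometry <- function(shape, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "vol_geometry")
}

#' @rdname vol_geometry
#' @param x an `image_volume` or `vol_geometry`.
#' @export
geometry_of <- function(x) {
  if (inherits(x, "vol_geometry")) return(x)
  if (inherits(x, "image_volume"))
    return(vol_geometry(dim(x$data), x$voxel_size, x$origin))
  if (inherits(x, "spline_warp")) return(x$ref_geom)
  stop("no geometry available for class ", paste(class(x), collapse = "/"))
}

same_geometry <- function(a, b, tol = 1e-8) {
  a <- geometry_of(a); b <- geometry_of(b)
  all(a$shape == b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Voxel volume in cubic mm
#'
#' The per-sample integration weight `v` used by the regularisation
#' penalties: the product of the voxel edge lengths.
#'
#' @param x an `image_volume` or `vol_geometry`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(x) prod(geometry_of(x)$voxel_size)

# World mm coordinates of voxel centres along one axis.
axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$shape[axis]) - 1) * geom$voxel_size[axis]
}

# Apply a (sparse or dense) matrix M (m x n_axis) along one axis of a 3D
# array: tensor-mode product. Returns an array whose extent along `axis`
# is nrow(M). Workhorse for separable spline evaluation and smoothing.
apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dim(a) <- c(d[axis], prod(d[-axis]))
  out <- as.matrix(M %*% a)
  dim(out) <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(out, order(perm))
}

# Truncated, renormalised Gaussian convolution matrix for one axis.
gauss_band <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(Matrix::Diagonal(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  i <- rep(seq_len(n), each = 2L * r + 1L)
  j <- i + rep(-r:r, times = n)
  w <- rep(k, times = n)
  keep <- j >= 1L & j <= n
  M <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = w[keep],
                            dims = c(n, n))
  # renormalise rows so constants are preserved at the boundary
  Matrix::Diagonal(x = 1 / Matrix::rowSums(M)) %*% M
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with the kernel width given as full width
#' at half maximum in mm (the convention used for the registration pyramid).
#' Truncated at 3 sigma and renormalised at the boundary so that constants
#' are preserved.
#'
#' @param vol an [image_volume()].
#' @param fwhm scalar or length-3, mm; `0` is a no-op.
#' @return smoothed `image_volume` on the same grid.
#' @export
smooth_volume <- function(vol, fwhm) {
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))   # FWHM -> sd
  out <- vol$data
  for (ax in 1:3) {
    sv <- sigma[ax] / vol$voxel_size[ax]
    if (sv > 1e-8)
      out <- apply_axis(out, gauss_band(dim(out)[ax], sv), ax)
  }
  image_volume(out, vol$voxel_size, vol$origin)
}

#' Subsample a volume by integer factors
#'
#' Keeps every `factor`-th voxel starting at the first, so the origin is
#' unchanged and the voxel size is multiplied by the factor. Smoothing is
#' the caller's responsibility (the pyramid smooths before subsampling).
#'
#' @param vol an [image_volume()].
#' @param factor integer scalar or length-3 subsampling factor.
#' @return subsampled `image_volume`.
#' @export
subsample_volume <- function(vol, factor) {
  factor <- rep_len(as.integer(factor), 3L)
  stopifnot(all(factor >= 1L))
  d <- dim(vol$data)
  idx <- lapply(1:3, function(a) seq(1L, d[a], by = factor[a]))
  image_volume(vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               vol$voxel_size * factor, vol$origin)
}
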