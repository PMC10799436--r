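#' 3D intensity volume
#'
#' Lightweight container for a single 3D scalar image: a numeric array plus a
#' 4x4 voxel-to-mm affine (NIfTI convention: the affine maps 0-based voxel
#' indices to world coordinates; R-side voxel indices are 1-based, so voxel
#' `(i,j,k)` maps through the affine applied to `(i-1, j-1, k-1)`).
#'
#' @param data numeric 3D array of voxel intensities.
#' @param affine 4x4 voxel-to-mm transform; identity by default.
#' @return An object of class `adfuse_volume` with fields `data` and `affine`.
#' @examples
#' v <- volume(array(runif(27), c(3, 3, 3)))
#' dim(v$data)
#' @export
volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop(sprintf("volume: expected a 3D array, got %d dimension(s)",
                 length(dim(data))))
  if (any(dim(data) < 1L)) stop("volume: all dimensions must be >= 1")
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(list(data = data, affine = affine), class = "adfuse_volume")
}

#' @export
print.adfuse_volume <- function(x, ...) {
  cat(sprintf("<adfuse_volume> %s, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

as_volume <- function(x) {
  if (inherits(x, "adfuse_volume")) x else volume(x)
}

#' Min-max intensity normalization
#'
#' Rescales a volume to `[0, 1]` by `z = (x - min) / (max - min)`. The
#' transform is affine in intensity, so voxel ordering is preserved; it is
#' idempotent on volumes already spanning `[0, 1]`.
#'
#' @param vol an [volume()] object (or bare 3D array, returned as given).
#' @return Volume of the same shape with intensities in `[0, 1]`.
#' @examples
#' v <- volume(array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2)))
#' range(normalize_minmax(v)$data)
#' @export
normalize_minmax <- function(vol) {
  bare <- !inherits(vol, "adfuse_volume")
  v <- as_volume(vol)
  lo <- min(v$data)
  hi <- max(v$data)
  if (hi - lo <= 0)
    stop("normalize_minmax: degenerate input, volume is constant (max == min)")
  v$data <- (v$data - lo) / (hi - lo)
  if (bare) v$data else v
}

#' Read a volume from a NIfTI file
#'
#' @param path a `.nii` or `.nii.gz` file containing a 3D image.
#' @return An [volume()] object. When the file stores no transform, the
#'   affine defaults to identity.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("read_volume: cannot read '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) != 3L)
    stop(sprintf("read_volume: '%s' is %dD, expected a 3D volume",
                 path, length(dim(img))))
  a <- array(as.numeric(img), dim(img))  # strip RNifti attributes
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  aff <- matrix(as.numeric(aff), 4, 4)
  volume(a, aff)
}

#' Write a volume to a NIfTI file
#'
#' Stores the data as float64 with the affine in the sform (code 2), so a
#' write/read round trip preserves data to float precision and the affine
#' exactly.
#'
#' @param vol an [volume()] object.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  img <- RNifti::asNifti(vol$data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Down-sample a volume by block averaging
#'
#' Each target voxel is the mean of the source voxels whose index bins map to
#' it, so output intensities stay within the source range. Requesting more
#' voxels than the source has along any axis is an error (this routine only
#' reduces resolution). The affine is rescaled by the per-axis factors.
#'
#' @param vol an [volume()] object.
#' @param target integer triple `(nx, ny, nz)` of output voxel counts.
#' @return Down-sampled [volume()].
#' @examples
#' v <- volume(array(0.7, c(8, 8, 8)))
#' dim(downsample_volume(v, c(4, 4, 4))$data)
#' @export
downsample_volume <- function(vol, target) {
  vol <- as_volume(vol)
  src <- dim(vol$data)
  target <- as.integer(target)
  if (length(target) != 3L || any(target < 1L))
    stop("downsample_volume: target must be three positive integers")
  if (any(target > src))
    stop(sprintf("downsample_volume: target (%s) exceeds source (%s); upsampling is out of contract",
                 paste(target, collapse = "x"), paste(src, collapse = "x")))
  bins <- lapply(1:3, function(k) {
    # bin i of axis k collects source indices j with floor((j-1)*t/n) == i-1
    floor((seq_len(src[k]) - 1) * target[k] / src[k]) + 1L
  })
  sums <- rowsum(matrix(vol$data, nrow = src[1]), bins[[1]], reorder = TRUE)
  d1 <- array(sums, c(target[1], src[2], src[3]))
  m2 <- aperm(d1, c(2, 1, 3))
  sums <- rowsum(matrix(m2, nrow = src[2]), bins[[2]], reorder = TRUE)
  d2 <- aperm(array(sums, c(target[2], target[1], src[3])), c(2, 1, 3))
  m3 <- aperm(d2, c(3, 1, 2))
  sums <- rowsum(matrix(m3, nrow = src[3]), bins[[3]], reorder = TRUE)
  d3 <- aperm(array(sums, c(target[3], target[1], target[2])), c(2, 3, 1))
  counts <- outer(outer(tabulate(bins[[1]], target[1]),
                        tabulate(bins[[2]], target[2])),
                  tabulate(bins[[3]], target[3]))
  out <- d3 / counts
  # new voxel v sits at old (fractional) voxel v*fac + (fac-1)/2
  fac <- src / target
  aff <- vol$affine
  aff[1:3, 4] <- aff[1:3, 4] + vol$affine[1:3, 1:3] %*% ((fac - 1) / 2)
  aff[, 1:3] <- aff[, 1:3] %*% diag(fac)
  volume(out, aff)
}
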