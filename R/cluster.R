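#' Threshold a salience volume and report surviving clusters
#'
#' Keeps voxels at or above the `(100 - top_pct)` intensity percentile,
#' labels the connected components of the surviving mask, discards
#' components whose voxel count does not exceed `min_size`, and reports each
#' surviving cluster's peak voxel (1-based index and, through the affine,
#' mm coordinates), peak intensity, and size, sorted by size descending.
#'
#' @param sal a `salience_volume` (or any [volume()] / 3D array).
#' @param top_pct percentage of voxels retained by the intensity threshold.
#' @param min_size clusters must exceed this many voxels to be reported.
#' @param connectivity 26 (faces, edges, corners; default) or 6 (faces).
#' @return A `cluster_report`: data frame with columns `rank`,
#'   `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `peak_i`, `peak_j`, `peak_k`,
#'   `peak_intensity`, `voxels`; filter settings stored as attributes.
#' @examples
#' a <- array(0, c(10, 10, 10)); a[3:5, 3:5, 3:5] <- 1
#' threshold_and_cluster(volume(a), top_pct = 5, min_size = 10)
#' @export
threshold_and_cluster <- function(sal, top_pct = 1, min_size = 100,
                                  connectivity = 26L) {
  v <- as_volume(sal)
  x <- v$data
  if (max(x) - min(x) <= 0)
    stop("threshold_and_cluster: degenerate (constant) salience map, no threshold exists")
  if (!connectivity %in% c(6L, 26L))
    stop("threshold_and_cluster: connectivity must be 6 or 26")
  cutoff <- quantile(x, 1 - top_pct / 100, names = FALSE, type = 7)
  mask <- x >= cutoff
  lab <- cpp_label_components(mask, dim(x), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes > min_size)
  rows <- lapply(keep, function(cl) {
    idx <- which(lab == cl)
    peak <- idx[which.max(x[idx])]
    ijk <- arrayInd(peak, dim(x))
    mm <- v$affine %*% c(ijk - 1, 1)
    data.frame(peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
               peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
               peak_intensity = x[peak], voxels = sizes[cl])
  })
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0), peak_i = integer(0),
               peak_j = integer(0), peak_k = integer(0),
               peak_intensity = numeric(0), voxels = integer(0))
  rep <- rep[order(-rep$voxels), , drop = FALSE]
  if (nrow(rep)) rep$rank <- seq_len(nrow(rep))
  else rep$rank <- integer(0)
  rep <- rep[, c("rank", setdiff(names(rep), "rank"))]
  rownames(rep) <- NULL
  attr(rep, "top_pct") <- top_pct
  attr(rep, "min_size") <- min_size
  attr(rep, "connectivity") <- connectivity
  attr(rep, "cutoff") <- cutoff
  class(rep) <- c("cluster_report", class(rep))
  rep
}

#' Write a cluster report to CSV
#' @param report a `cluster_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
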