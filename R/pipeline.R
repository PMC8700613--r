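#' Discard initial volumes of a 4D image
#'
#' Drops the first `n_discard` volumes (time points) of a 4D image, the
#' usual guard against T1-equilibration effects at the start of an fMRI
#' run; with the default acquisition of 197 volumes and `n_discard = 7`,
#' 190 volumes remain for analysis.
#'
#' @param image 4D numeric array (x, y, z, t) or `nifti_image`.
#' @param n_discard number of leading volumes to drop (default 7).
#' @return same type as the input, with `n_discard` fewer volumes.
#' @export
discard_initial_volumes <- function(image, n_discard = 7L) {
  wrap <- inherits(image, "nifti_image")
  arr <- if (wrap) image$data else image
  if (!is.array(arr) || length(dim(arr)) != 4L)
    stop("image must be a 4D array")
  nt <- dim(arr)[4L]
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("n_discard must be >= 0")
  if (nt <= n_discard)
    stop("image has ", nt, " volumes; cannot discard ", n_discard)
  out <- arr[, , , (n_discard + 1L):nt, drop = FALSE]
  if (wrap) { image$data <- out; image } else out
}

#' Polynomial detrending of a series
#'
#' Removes the least-squares polynomial trend of the given order from a
#' series (0 = mean removal, 1 = linear, 2 = quadratic). Residuals are
#' orthogonal to the polynomial basis. Off by default in the pipeline:
#' inputs are assumed already nuisance-regressed upstream.
#'
#' @param x numeric series.
#' @param order polynomial order, >= 0.
#' @return detrended series of the same length.
#' @export
detrend_series <- function(x, order = 1L) {
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  n <- length(x)
  if (n <= order + 1L)
    stop("series length (", n, ") must exceed order + 1 (", order + 1L, ")")
  tt <- seq_len(n)
  basis <- outer(tt - mean(tt), 0:order, `^`)
  stats::lm.fit(basis, x)$residuals
}

check_same_grid <- function(image, atlas) {
  di <- dim(image)[1:3]
  da <- dim(atlas)
  if (length(da) != 3L || any(di != da))
    stop("image grid (", paste(di, collapse = "x"),
         ") does not match atlas grid (", paste(da, collapse = "x"), ")")
}

#' Voxelwise AAPE map
#'
#' Computes AAPE for the time series of every voxel carrying a positive
#' atlas label. Voxels with zero temporal variance (background or constant
#' signal) carry no dynamics and are marked invalid (`NA`) rather than
#' contributing entropy 0, so they cannot bias regional means downward.
#'
#' @param image 4D numeric array (x, y, z, t) or `nifti_image`; assumed
#'   already truncated with [discard_initial_volumes] if applicable.
#' @param atlas 3D integer label array (or `nifti_image`) on the same grid;
#'   0 = background.
#' @param config an [aape_config].
#' @param detrend polynomial order for per-voxel detrending before entropy
#'   (`NULL`, the default, means none).
#' @return 3D numeric array of AAPE values; unlabeled or zero-variance
#'   voxels are `NA`.
#' @export
voxelwise_aape <- function(image, atlas, config = aape_config(),
                           detrend = NULL) {
  if (inherits(image, "nifti_image")) image <- image$data
  if (inherits(atlas, "nifti_image")) atlas <- atlas$data
  if (!is.array(image) || length(dim(image)) != 4L)
    stop("image must be a 4D array")
  check_same_grid(image, atlas)
  nt <- dim(image)[4L]
  vox <- which(atlas > 0)
  map <- array(NA_real_, dim = dim(atlas))
  if (!length(vox)) return(map)
  X <- matrix(aperm(image, c(4L, 1L, 2L, 3L)), nrow = nt)[, vox, drop = FALSE]
  X <- t(X)                                    # voxels x time
  if (!is.null(detrend))
    X <- t(apply(X, 1L, detrend_series, order = detrend))
  v <- apply(X, 1L, stats::var)
  ok <- is.finite(v) & v > 0
  if (any(ok)) {
    h <- suppressWarnings(aape(X[ok, , drop = FALSE], config))
    map[vox[ok]] <- h
  }
  map
}

#' Regional entropy profile
#'
#' Averages a voxelwise AAPE map within each atlas region. Regions without
#' any valid voxel are reported with `NA` mean and voxel count 0 (and a
#' message), never silently dropped: a missing region is data.
#'
#' @param aape_map 3D numeric array from [voxelwise_aape] (`NA` = invalid).
#' @param atlas 3D integer label array (or `nifti_image`) on the same grid.
#' @param roi_names optional character vector naming labels `1..length`.
#' @return data.frame with columns `roi_id`, `roi_name`, `mean_aape`,
#'   `n_voxels` (count of valid voxels entering the mean).
#' @export
regional_profile <- function(aape_map, atlas, roi_names = NULL) {
  if (inherits(atlas, "nifti_image")) atlas <- atlas$data
  check_same_grid(aape_map, atlas)
  labels <- sort(unique(as.vector(atlas[atlas > 0])))
  res <- lapply(labels, function(l) {
    vals <- aape_map[atlas == l]
    ok <- is.finite(vals)
    data.frame(roi_id = l,
               mean_aape = if (any(ok)) mean(vals[ok]) else NA_real_,
               n_voxels = sum(ok))
  })
  out <- do.call(rbind, res)
  out$roi_name <- if (!is.null(roi_names)) roi_names[out$roi_id]
                  else sprintf("ROI%03d", out$roi_id)
  empty <- out$roi_id[out$n_voxels == 0L]
  if (length(empty))
    message("regions with no valid voxel (mean reported NA): ",
            paste(empty, collapse = ", "))
  out[, c("roi_id", "roi_name", "mean_aape", "n_voxels")]
}

#' Subject-level pipeline: image to regional profile
#'
#' Convenience wrapper chaining [discard_initial_volumes], [voxelwise_aape]
#' and [regional_profile] for one subject.
#'
#' @inheritParams voxelwise_aape
#' @param subject_id identifier copied into the output.
#' @param n_discard leading volumes to drop (default 7).
#' @param roi_names optional ROI names.
#' @return data.frame: `subject_id`, `roi_id`, `roi_name`, `mean_aape`,
#'   `n_voxels`.
#' @export
subject_profile <- function(image, atlas, subject_id = "subj",
                            config = aape_config(), n_discard = 7L,
                            detrend = NULL, roi_names = NULL) {
  image <- discard_initial_volumes(image, n_discard)
  map <- voxelwise_aape(image, atlas, config, detrend = detrend)
  prof <- regional_profile(map, atlas, roi_names)
  cbind(subject_id = subject_id, prof)
}

#' Write / read regional profiles as TSV
#'
#' Long-format interchange between the imaging stage and the statistics
#' stage: one row per (subject, region).
#'
#' @param profiles data.frame with columns `subject_id`, `roi_id`,
#'   `roi_name`, `mean_aape`, `n_voxels`.
#' @param path TSV path.
#' @return `path` (write) or the profiles data.frame (read).
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
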