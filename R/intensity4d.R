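# 4D intensity lacunarity: each ROI voxel's intensity becomes a coordinate on
# a fourth axis, so intensity texture turns into geometric occupancy that the
# same sliding-window engine can measure. Full 4D enumeration is expensive, so
# window contents can be randomly subsampled (default 1 cell in 100).

#' Quantize ROI intensities to discrete levels
#'
#' Linear map of the ROI intensity range onto `0 .. n_levels - 1`. A constant
#' ROI maps entirely to level 0. Levels outside the mask are undefined (NA).
#'
#' @param volume a [voxel_volume()] (or 3D array).
#' @param mask a [binary_mask()] delimiting the ROI.
#' @param n_levels number of levels, >= 2.
#' @return Integer array of the volume's shape; NA outside the mask.
#' @export
quantize_intensities <- function(volume, mask, n_levels) {
  v <- if (inherits(volume, "voxel_volume")) volume$data else volume
  m <- mask_data(mask)
  if (!identical(dim(v), dim(m))) stop("volume and mask shapes differ")
  if (n_levels < 2) stop("n_levels must be >= 2")
  inside <- m > 0
  if (!any(inside)) stop("mask is empty")
  vals <- v[inside]
  lo <- min(vals); hi <- max(vals)
  lev <- array(NA_integer_, dim(v))
  if (hi == lo) {
    lev[inside] <- 0L
  } else {
    q <- floor((vals - lo) / (hi - lo) * n_levels)
    lev[inside] <- as.integer(pmin(q, n_levels - 1))
  }
  lev
}

default_n_levels <- function(roi_shape) {
  as.integer(min(max(max(roi_shape), 16L), 256L))
}

#' Lift an intensity ROI to a 4D occupancy set
#'
#' Each ROI voxel (x, y, z) with quantized level l occupies the single 4D
#' cell (x, y, z, l); the 4D bounding shape is the ROI bounding box times
#' `n_levels`. The occupied-cell count therefore equals the ROI voxel count.
#'
#' @inheritParams quantize_intensities
#' @param n_levels intensity levels; default clamps the largest ROI extent
#'   into 16..256 so fourth-axis cells stay commensurate with spatial cells.
#' @return An object of class `occupancy_4d`: the 0/1 `occ` array, `n_levels`,
#'   the intensity `source_range`, and the ROI `box`.
#' @export
lift_to_4d <- function(volume, mask, n_levels = NULL) {
  v <- if (inherits(volume, "voxel_volume")) volume$data else volume
  m <- mask_data(mask)
  if (!identical(dim(v), dim(m))) stop("volume and mask shapes differ")
  box <- roi_bounding_box(if (inherits(mask, "binary_mask")) mask else
                            binary_mask(m))
  sel <- lapply(1:3, function(ax) seq.int(box[ax, 1] + 1L, box[ax, 2]))
  vroi <- v[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  mroi <- m[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  if (is.null(n_levels)) n_levels <- default_n_levels(dim(mroi))
  lev <- quantize_intensities(vroi, mroi, n_levels)
  d4 <- c(dim(mroi), n_levels)
  occ <- array(0L, d4)
  idx <- which(mroi > 0, arr.ind = TRUE)
  lin <- idx[, 1] + d4[1] * ((idx[, 2] - 1) + d4[2] * ((idx[, 3] - 1) +
           d4[3] * as.numeric(lev[mroi > 0])))
  occ[lin] <- 1L
  structure(list(occ = occ, n_levels = as.integer(n_levels),
                 source_range = range(vroi[mroi > 0]), box = box),
            class = "occupancy_4d")
}

#' @export
print.occupancy_4d <- function(x, ...) {
  cat(sprintf("<occupancy_4d> %s cells, %d occupied, %d levels over [%g, %g]\n",
              paste(dim(x$occ), collapse = "x"), sum(x$occ), x$n_levels,
              x$source_range[1], x$source_range[2]))
  invisible(x)
}

#' 4D lacunarity index with random subsampling
#'
#' Gliding hypercubic windows of edge `s` over the 4D occupancy set. At
#' `rate = 1` every cell of every window is enumerated exactly (via the
#' integral-image engine). At `rate < 1` each window of n cells is estimated
#' from `max(min_cells, floor(rate * n))` cells drawn uniformly without
#' replacement; the draw is keyed to (seed, window index), so results are
#' bit-reproducible and independent of worker count. Windows whose sample
#' contains no occupied cell are dropped from the average -- the sampled
#' analogue of the empty-window rule. Lambda(s) = 1 + mean CV^2; the index is
#' the log-log slope across scales.
#'
#' @param occ an `occupancy_4d` from [lift_to_4d()] (or a 4D 0/1 array).
#' @param scales window sizes (>= 2); default [default_scales()] of the 4D
#'   shape in gliding mode.
#' @param rate fraction of window cells evaluated, in (0, 1]; default 0.01
#'   (1 cell in 100).
#' @param seed integer seed for the subsampling streams.
#' @param min_cells floor on cells sampled per window (default 1).
#' @param stride_mode `"gliding"` (default) or `"grid"`.
#' @param method `"auto"` routes rate 1 to the exact engine and rate < 1 to
#'   the sampler; `"exact"` and `"sample"` force a path (the sampler at
#'   rate 1 enumerates every cell and must agree with the exact engine).
#' @param workers worker count; results are identical for any value.
#' @return A `slope_fit`; the intensity lacunarity index is its `slope`.
#' @export
lacunarity_4d <- function(occ, scales = NULL, rate = 0.01, seed = 1L,
                          min_cells = 1L, stride_mode = "gliding",
                          method = c("auto", "exact", "sample"), workers = 1) {
  method <- match.arg(method)
  stride_mode <- match.arg(stride_mode, c("grid", "gliding"))
  a <- if (inherits(occ, "occupancy_4d")) occ$occ else occ
  if (length(dim(a)) != 4) stop("expected a 4D occupancy array")
  if (rate <= 0 || rate > 1) stop("subsampling rate must be in (0, 1]")
  if (sum(a) == 0) stop("occupancy set is empty")
  if (is.null(scales))
    scales <- default_scales(dim(a), stride_mode = stride_mode)
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 2)) stop("lacunarity scales must all be >= 2")
  if (method == "auto") method <- if (rate == 1) "exact" else "sample"

  lam <- vapply(scales, function(s)
    lacunarity_4d_at_scale(a, s, rate = rate, seed = seed,
                           min_cells = min_cells, stride_mode = stride_mode,
                           method = method, workers = workers),
    numeric(1))
  fit_loglog_slope(scales, lam, statistic = "lacunarity")
}

#' 4D lacunarity coefficient at a single scale
#'
#' The per-scale statistic underlying [lacunarity_4d()]: Lambda(s) of a 4D
#' occupancy set, exactly or from per-window random cell samples.
#'
#' @inheritParams lacunarity_4d
#' @param s window edge length, `>= 2`.
#' @return Lambda(s).
#' @export
lacunarity_4d_at_scale <- function(occ, s, rate = 0.01, seed = 1L,
                                   min_cells = 1L, stride_mode = "gliding",
                                   method = c("auto", "exact", "sample"),
                                   workers = 1) {
  method <- match.arg(method)
  stride_mode <- match.arg(stride_mode, c("grid", "gliding"))
  a <- if (inherits(occ, "occupancy_4d")) occ$occ else occ
  if (length(dim(a)) != 4) stop("expected a 4D occupancy array")
  if (s < 2) stop("lacunarity needs window size >= 2")
  if (rate <= 0 || rate > 1) stop("subsampling rate must be in (0, 1]")
  if (method == "auto") method <- if (rate == 1) "exact" else "sample"
  if (method == "exact") {
    return(window_lacunarity(a, s, stride_mode = stride_mode,
                             statistic = "literal", normalize = TRUE,
                             workers = workers))
  }
  d <- dim(a)
  stride <- stride_of(stride_mode, s)
  n_win <- cpp_n_windows(d, as.integer(s), stride)
  parts <- apply_chunks(n_win, workers, function(lo, hi)
    cpp_lacunarity_sub(a, d, as.integer(s), stride, lo, hi,
                       rate, as.integer(min_cells), as.numeric(seed)))
  m <- Reduce(`+`, parts)
  if (m[1] == 0)
    stop("no window sampled an occupied cell; raise the subsampling rate")
  1 + m[2] / m[1]
}

#' Measure the per-patient fractal feature set
#'
#' Convenience wrapper producing the feature vector consumed by the scoring
#' system: box-counting FD of the segmentation mask, intensity lacunarity
#' index of the FLAIR signal inside the mask (4D lift, subsampled), and the
#' physical tumor volume. The cystic flag is a radiological reading and is
#' left for manual entry.
#'
#' @param mask the ceT1 tumor segmentation, a [binary_mask()].
#' @param flair the coregistered FLAIR volume, a [voxel_volume()].
#' @param scales_fd,scales_li optional scale ladders (defaults per measure).
#' @param rate,seed,n_levels passed to [lacunarity_4d()] / [lift_to_4d()].
#' @param workers worker count.
#' @return A one-row data frame: `fd`, `flair_li`, `cystic` (NA), `volume_cm3`.
#' @export
measure_patient <- function(mask, flair, scales_fd = NULL, scales_li = NULL,
                            rate = 0.01, seed = 1L, n_levels = NULL,
                            workers = 1) {
  check_grid_compatible(flair, mask)
  fd <- fractal_dimension(mask, scales = scales_fd, workers = workers)
  occ <- lift_to_4d(flair, mask, n_levels = n_levels)
  li <- lacunarity_4d(occ, scales = scales_li, rate = rate, seed = seed,
                      workers = workers)
  data.frame(fd = fd$slope, flair_li = li$slope, cystic = NA_real_,
             volume_cm3 = mask_volume_cm3(mask))
}
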