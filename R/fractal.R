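# Box-counting fractal dimension and gliding-box lacunarity index.

#' Ordinary least-squares fit of a log-log scale curve
#'
#' Regresses `log(y)` on `log(1/s)`. This is the common estimator behind both
#' the box-counting dimension (y = box count) and the lacunarity index
#' (y = Lambda(s)). When all y are equal the slope is 0 and R^2 is defined as
#' 1 (a perfectly explained flat line).
#'
#' @param sizes integer window sizes (>= 3 of them).
#' @param y positive statistics, one per size.
#' @param statistic label stored on the fit (`"box_count"` or `"lacunarity"`).
#' @return An object of class `slope_fit`: `slope`, `intercept`, `r_squared`,
#'   `n_points`, and the underlying `curve` data frame.
#' @export
fit_loglog_slope <- function(sizes, y, statistic = "statistic") {
  sizes <- as.numeric(sizes); y <- as.numeric(y)
  if (length(sizes) != length(y)) stop("sizes and y differ in length")
  if (length(y) < 3) stop("a slope fit needs at least 3 points")
  if (any(!is.finite(y)) || any(y <= 0))
    stop("all curve values must be finite and > 0 to take logs")
  x <- log(1 / sizes)
  ly <- log(y)
  if (max(ly) - min(ly) == 0) {
    fit <- list(slope = 0, intercept = ly[1], r_squared = 1)
  } else {
    f <- lm.fit(cbind(1, x), ly)
    res <- f$residuals
    r2 <- 1 - sum(res^2) / sum((ly - mean(ly))^2)
    fit <- list(slope = unname(f$coefficients[2]),
                intercept = unname(f$coefficients[1]),
                r_squared = r2)
  }
  structure(c(fit, list(n_points = length(y),
                        curve = data.frame(size = sizes, value = y),
                        statistic = statistic)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<slope_fit> %s: slope %.*f (intercept %.*f, R^2 %.*f, %d scales %s)\n",
              x$statistic, digits, x$slope, digits, x$intercept, digits,
              x$r_squared, x$n_points,
              paste(x$curve$size, collapse = ",")))
  invisible(x)
}

#' @export
coef.slope_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
plot.slope_fit <- function(x, ...) {
  lx <- log(1 / x$curve$size); ly <- log(x$curve$value)
  graphics::plot(lx, ly, xlab = "log(1/s)", ylab = sprintf("log %s", x$statistic),
                 main = sprintf("slope = %.4f, R^2 = %.4f", x$slope, x$r_squared),
                 ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Box count of a mask at one scale
#'
#' Counts windows of edge `s` holding at least one occupied voxel. For a
#' [binary_mask()] the mask is first cropped to its tight bounding box so
#' that grid-mode tiling starts at the ROI's low corner (making the count
#' translation invariant); a plain array is counted as-is.
#'
#' @param mask a [binary_mask()] or occupancy array (any dimension 2--4).
#' @param s window edge length.
#' @param stride_mode `"grid"` (tiling, the box-counting default) or
#'   `"gliding"`.
#' @param workers worker count; results are identical for any value.
#' @return Integer count of non-empty windows.
#' @export
box_count <- function(mask, s, stride_mode = "grid", workers = 1) {
  a <- if (inherits(mask, "binary_mask"))
    crop_to_box(mask, roi_bounding_box(mask))$data else mask_data(mask)
  window_box_count(a, s, stride_mode = stride_mode, workers = workers)
}

#' Lacunarity coefficient of a mask or value array at one scale
#'
#' See [window_lacunarity()] for the statistic definitions. A
#' [binary_mask()] is measured on its raw grid (crop beforehand with
#' [crop_to_box()] if ROI-local measurement is wanted).
#'
#' @inheritParams window_lacunarity
#' @param values a [binary_mask()], [voxel_volume()] or plain array.
#' @return Lambda(s).
#' @export
lacunarity_at_scale <- function(values, s, stride_mode = "gliding",
                                statistic = c("literal", "glidingbox"),
                                normalize = TRUE, workers = 1) {
  a <- if (inherits(values, "binary_mask")) values$data
       else if (inherits(values, "voxel_volume")) values$data
       else values
  window_lacunarity(a, s, stride_mode = stride_mode, statistic = statistic,
                    normalize = normalize, workers = workers)
}

#' Box-counting fractal dimension
#'
#' Crops the mask to its ROI bounding box, counts non-empty windows at each
#' scale, and fits the log-log slope of count against inverse window size.
#' A solid 3D body approaches slope 3, a thin slab 2, a line 1; truly fractal
#' sets land in between (Menger sponge: log 20 / log 3 = 2.7268).
#'
#' @param mask a [binary_mask()] or occupancy array.
#' @param scales integer window sizes; default [default_scales()] of the
#'   cropped ROI shape.
#' @param stride_mode `"grid"` (default) or `"gliding"`.
#' @param workers worker count.
#' @return A `slope_fit`; the fractal dimension is its `slope`.
#' @export
fractal_dimension <- function(mask, scales = NULL, stride_mode = "grid",
                              workers = 1) {
  a <- if (inherits(mask, "binary_mask"))
    crop_to_box(mask, roi_bounding_box(mask))$data else mask_data(mask)
  if (is.null(scales))
    scales <- default_scales(dim(a), stride_mode = stride_mode)
  scales <- sort(unique(as.integer(scales)))
  counts <- vapply(scales, function(s)
    window_box_count(a, s, stride_mode = stride_mode, workers = workers),
    numeric(1))
  fit_loglog_slope(scales, counts, statistic = "box_count")
}

#' Lacunarity index
#'
#' Lambda(s) at each scale (gliding stride-1 windows by default), then the
#' log-log slope of Lambda against inverse window size. With the normalized
#' convention (Lambda = 1 + mean CV^2) a homogeneous mask gives Lambda = 1 at
#' every scale and an index of exactly 0.
#'
#' @inheritParams lacunarity_at_scale
#' @param scales integer window sizes (all >= 2); default [default_scales()]
#'   of the array shape in gliding mode.
#' @return A `slope_fit`; the lacunarity index is its `slope`.
#' @export
lacunarity_index <- function(values, scales = NULL, stride_mode = "gliding",
                             statistic = c("literal", "glidingbox"),
                             normalize = TRUE, workers = 1) {
  statistic <- match.arg(statistic)
  a <- if (inherits(values, "binary_mask")) values$data
       else if (inherits(values, "voxel_volume")) values$data
       else values
  if (is.null(scales))
    scales <- default_scales(dim(a), stride_mode = stride_mode)
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 2)) stop("lacunarity scales must all be >= 2")
  lam <- vapply(scales, function(s)
    window_lacunarity(a, s, stride_mode = stride_mode, statistic = statistic,
                      normalize = normalize, workers = workers),
    numeric(1))
  fit_loglog_slope(scales, lam, statistic = "lacunarity")
}
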