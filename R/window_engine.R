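# R-side wrappers over the compiled sliding-window engine.
#
# Every reduction runs over window-index ranges [lo, hi) so work can be split
# across workers; per-window results never depend on the chunking, so output
# is identical for any worker count (bit-exact for counts, and for lacunarity
# the per-chunk partial sums are combined in fixed chunk order).

stride_of <- function(stride_mode, s) {
  stride_mode <- match.arg(stride_mode, c("grid", "gliding"))
  if (stride_mode == "grid") s else 1L
}

check_scale <- function(shape, s, stride_mode) {
  if (s < 1) stop("window size must be >= 1")
  lim <- if (stride_mode == "grid") max(shape) else max(shape)
  if (s > lim)
    stop(sprintf("window size %d exceeds the grid (dims %s)", s,
                 paste(shape, collapse = "x")))
  invisible(TRUE)
}

# split [0, n) into `workers` contiguous chunks
chunk_ranges <- function(n, workers) {
  workers <- max(1L, min(as.integer(workers), as.integer(max(1, n))))
  cuts <- floor(seq(0, n, length.out = workers + 1))
  cuts <- unique(cuts)
  cbind(lo = cuts[-length(cuts)], hi = cuts[-1])
}

apply_chunks <- function(n_win, workers, fun) {
  rg <- chunk_ranges(n_win, workers)
  runner <- if (nrow(rg) > 1 && workers > 1 && .Platform$OS.type == "unix") {
    function(idx) parallel::mclapply(idx, function(i) fun(rg[i, 1], rg[i, 2]),
                                     mc.cores = workers)
  } else {
    function(idx) lapply(idx, function(i) fun(rg[i, 1], rg[i, 2]))
  }
  runner(seq_len(nrow(rg)))
}

#' Count non-empty windows of an occupancy array
#'
#' Low-level box counter on a plain N-dimensional array (2--4 dims). In
#' `grid` mode windows of edge `s` tile the array from its low corner and
#' partial edge windows are clipped and kept; in `gliding` mode every
#' stride-1 placement is evaluated (axes shorter than `s` collapse to one
#' clipped window).
#'
#' @param a numeric/integer/logical array; any value > 0 marks occupancy.
#' @param s integer window edge length (voxels).
#' @param stride_mode `"grid"` (stride = s) or `"gliding"` (stride = 1).
#' @param workers worker count; the result is identical for any value.
#' @return Number of windows containing at least one occupied cell.
#' @export
window_box_count <- function(a, s, stride_mode = "grid", workers = 1) {
  stride_mode <- match.arg(stride_mode, c("grid", "gliding"))
  d <- dim(a); check_scale(d, s, stride_mode)
  stride <- stride_of(stride_mode, s)
  av <- as.numeric(a > 0)
  S <- cpp_integral(av, d)
  if (sum(av) == 0) stop("mask is empty")
  n_win <- cpp_n_windows(d, as.integer(s), stride)
  parts <- apply_chunks(n_win, workers, function(lo, hi)
    cpp_box_count(S, d, as.integer(s), stride, lo, hi))
  sum(unlist(parts))
}

#' Per-scale lacunarity of an array
#'
#' Computes the lacunarity coefficient at a single window size. The default
#' `"literal"` statistic takes, for each window whose mean over voxel values
#' is positive, the squared coefficient of variation of the values inside the
#' window (population variance), and averages those CV^2 over all such
#' windows. The `"glidingbox"` statistic is the classical gliding-box
#' alternative: CV^2 of the window *masses* across all window positions.
#'
#' @param a numeric array of non-negative voxel values (a 0/1 mask or scalars).
#' @param s window edge length, `>= 2`.
#' @param stride_mode `"gliding"` (stride 1, the default for lacunarity) or
#'   `"grid"`.
#' @param statistic `"literal"` or `"glidingbox"`.
#' @param normalize if `TRUE` (default) returns `1 + mean CV^2` so the
#'   homogeneous limit is exactly 1 and logs are always defined; if `FALSE`
#'   returns the raw mean CV^2.
#' @param workers worker count (results are worker-count independent).
#' @return The lacunarity coefficient Lambda(s).
#' @export
window_lacunarity <- function(a, s, stride_mode = "gliding",
                              statistic = c("literal", "glidingbox"),
                              normalize = TRUE, workers = 1) {
  stride_mode <- match.arg(stride_mode, c("grid", "gliding"))
  statistic <- match.arg(statistic)
  if (s < 2) stop("lacunarity needs window size >= 2 (a 1-voxel window has no variation)")
  d <- dim(a); check_scale(d, s, stride_mode)
  stride <- stride_of(stride_mode, s)
  av <- as.numeric(a)
  if (any(av < 0)) stop("lacunarity is defined for non-negative values")
  S <- cpp_integral(av, d)
  n_win <- cpp_n_windows(d, as.integer(s), stride)
  if (statistic == "literal") {
    S2 <- cpp_integral(av * av, d)
    parts <- apply_chunks(n_win, workers, function(lo, hi)
      cpp_lacunarity_cv2(S, S2, d, as.integer(s), stride, lo, hi))
    m <- Reduce(`+`, parts)
    if (m[1] == 0) stop("all windows are empty")
    cv2 <- m[2] / m[1]
  } else {
    parts <- apply_chunks(n_win, workers, function(lo, hi)
      cpp_mass_moments(S, d, as.integer(s), stride, lo, hi))
    m <- Reduce(`+`, parts)
    mu <- m[2] / m[1]
    if (mu == 0) stop("all windows are empty")
    cv2 <- (m[3] / m[1] - mu * mu) / (mu * mu)
    if (cv2 < 0) cv2 <- 0
  }
  if (normalize) 1 + cv2 else cv2
}

#' Default scale ladder for a grid
#'
#' Powers of 2 from 2 upward by default, or the base-3 ladder
#' (1, 3, 9, 27, ...) used with exactly self-similar fixtures such as the
#' Menger sponge. In `grid` mode the ladder is bounded by the largest grid
#' extent (edge windows are clipped, so flat objects like a one-voxel-thick
#' slab remain measurable); in `gliding` mode by the smallest extent, since a
#' gliding window must fit the grid. At least 3 scales are required for any
#' slope fit.
#'
#' @param shape integer grid extents.
#' @param base 2 (default) or 3.
#' @param stride_mode `"grid"` or `"gliding"`.
#' @param include_unit include s = 1 (meaningful for box counts only;
#'   automatically `TRUE` for the base-3 ladder in grid mode).
#' @return Increasing integer vector of window sizes.
#' @export
default_scales <- function(shape, base = 2, stride_mode = "grid",
                           include_unit = (base == 3 && stride_mode == "grid")) {
  stride_mode <- match.arg(stride_mode, c("grid", "gliding"))
  stopifnot(base %in% c(2, 3))
  lim <- if (stride_mode == "grid") max(shape) else min(shape)
  if (base == 2) {
    top <- floor(lim / 2)
    if (top < 2) stop("grid too small for a scale ladder; pad the input")
    sizes <- 2^(1:floor(log2(top)))
  } else {
    kmax <- floor(log(lim) / log(3) + 1e-9)
    sizes <- 3^(0:kmax)
    if (!include_unit) sizes <- sizes[sizes >= 3]
  }
  sizes <- as.integer(sizes[sizes <= lim])
  if (length(sizes) < 3)
    stop(sprintf("only %d usable scales (%s); a slope fit needs >= 3 -- pad the input",
                 length(sizes), paste(sizes, collapse = ", ")))
  sizes
}
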