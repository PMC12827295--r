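# Interobserver agreement: voxel-wise Cohen's kappa between two segmentations
# and ICC(2,1) between two raters' derived measurements.

#' Cohen's kappa between two segmentation masks
#'
#' Voxel-wise chance-corrected agreement over a support region. Evaluating
#' over the whole volume would inflate agreement with shared empty
#' background, so the default support is the padded bounding box of the union
#' of the two masks.
#'
#' @param mask_a,mask_b [binary_mask()]s (or 0/1 arrays) on the same grid.
#' @param pad padding (voxels) around the union bounding box, default 5.
#' @param n_boot bootstrap draws over voxels for a percentile CI; 0 (default)
#'   skips the CI.
#' @param seed RNG seed for the bootstrap.
#' @return List: `kappa`, observed and chance agreement (`p_o`, `p_e`),
#'   the 2x2 `table`, and `ci` when bootstrapped.
#' @export
cohens_kappa <- function(mask_a, mask_b, pad = 5, n_boot = 0, seed = 1L) {
  a <- mask_data(mask_a); b <- mask_data(mask_b)
  if (!identical(dim(a), dim(b))) stop("masks are on different grids")
  u <- binary_mask(array(as.integer(a > 0 | b > 0), dim(a)))
  box <- roi_bounding_box(u, pad = pad)
  av <- as.vector(crop_to_box(a, box)) > 0
  bv <- as.vector(crop_to_box(b, box)) > 0
  k <- kappa_stat(av, bv)
  out <- list(kappa = k$kappa, p_o = k$p_o, p_e = k$p_e, table = k$table)
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(av)
    ks <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      kappa_stat(av[idx], bv[idx])$kappa
    }, numeric(1))
    out$ci <- quantile(ks, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  }
  out
}

kappa_stat <- function(av, bv) {
  n <- length(av)
  n11 <- sum(av & bv); n10 <- sum(av & !bv)
  n01 <- sum(!av & bv); n00 <- sum(!av & !bv)
  p_o <- (n11 + n00) / n
  pa <- (n11 + n10) / n; pb <- (n11 + n01) / n
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (p_e == 1) {
    if (p_o == 1) 1 else stop("kappa undefined: both raters constant")
  } else (p_o - p_e) / (1 - p_e)
  list(kappa = kappa, p_o = p_o, p_e = p_e,
       table = matrix(c(n11, n01, n10, n00), 2, 2,
                      dimnames = list(a = c("1", "0"), b = c("1", "0"))))
}

#' ICC(2,1): two-way random effects, absolute agreement, single rater
#'
#' Mean-squares decomposition of the n-subjects-by-2-raters table. Absolute
#' agreement penalizes systematic rater shifts (unlike consistency ICC).
#'
#' @param ratings_a,ratings_b per-subject measurements of raters A and B
#'   (>= 3 subjects).
#' @param n_boot bootstrap draws over subjects for a percentile CI; 0 skips.
#' @param seed RNG seed for the bootstrap.
#' @return List: `icc`, the mean squares (`msr`, `msc`, `mse`), and `ci`
#'   when bootstrapped.
#' @export
icc_2_1 <- function(ratings_a, ratings_b, n_boot = 0, seed = 1L) {
  stopifnot(length(ratings_a) == length(ratings_b))
  n <- length(ratings_a)
  if (n < 3) stop("ICC needs at least 3 subjects")
  icc <- icc_stat(ratings_a, ratings_b)
  out <- icc
  if (n_boot > 0) {
    set.seed(seed)
    vs <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(icc_stat(ratings_a[idx], ratings_b[idx])$icc,
               error = function(e) NA_real_)
    }, numeric(1))
    out$ci <- quantile(vs, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  }
  out
}

icc_stat <- function(a, b) {
  n <- length(a); k <- 2
  M <- cbind(a, b)
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((M - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0) stop("ICC undefined: no between-subject variance")
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, msr = msr, msc = msc, mse = mse)
}
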