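# Voxelwise reproducibility statistics over repetition stacks.
# A "stack" is a 4-D array (x, y, z, repetition) or a matrix
# (repetition x voxel); an optional logical mask selects voxels.

stack_matrix <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 4L)
  d <- dim(stack)
  t(matrix(stack, prod(d[1:3]), d[4]))
}

stack_reshape <- function(v, stack) {
  if (is.matrix(stack)) v else array(v, dim(stack)[1:3])
}

#' Voxelwise temporal standard error
#'
#' Sample standard deviation across repetitions divided by sqrt(n), per
#' voxel.
#'
#' @param stack 4-D array (x, y, z, rep) or matrix (rep x voxel) with at
#'   least two repetitions.
#' @param mask Optional logical mask (voxels outside become `NA`).
#' @return SE per voxel, in the input's spatial layout.
#' @export
voxel_se <- function(stack, mask = NULL) {
  m <- stack_matrix(stack)
  n <- nrow(m)
  if (n < 2) stop("at least two repetitions are required")
  mu <- colMeans(m)
  sdv <- sqrt(colSums((m - rep(mu, each = n))^2) / (n - 1))
  se <- sdv / sqrt(n)
  if (!is.null(mask)) se[!as.vector(mask)] <- NA_real_
  stack_reshape(se, stack)
}

#' Voxelwise coefficient of variation
#'
#' `CoV = 100 * SE / mean` per voxel, in percent. Voxels whose mean
#' magnitude falls below `mean_threshold` are invalid (`NA`) to avoid
#' division blow-up.
#'
#' @inheritParams voxel_se
#' @param mean_threshold Minimum |mean| for a voxel to be valid.
#' @return CoV (percent) per voxel.
#' @export
voxel_cov <- function(stack, mask = NULL, mean_threshold = 1e-6) {
  m <- stack_matrix(stack)
  if (nrow(m) < 2) stop("at least two repetitions are required")
  n <- nrow(m)
  mu <- colMeans(m)
  se <- sqrt(colSums((m - rep(mu, each = n))^2) / (n - 1)) / sqrt(n)
  cv <- 100 * se / mu
  cv[abs(mu) < mean_threshold] <- NA_real_
  if (!is.null(mask)) cv[!as.vector(mask)] <- NA_real_
  stack_reshape(cv, stack)
}

#' Split-half spatial Spearman correlation
#'
#' Splits the repetition stack into first and second halves in acquisition
#' order, maps each half to a summary image (by default the voxelwise
#' mean; supply `map_fun` to run e.g. a CBF pipeline on each half), and
#' returns the Spearman rank correlation between the two maps over masked
#' voxels. Rank correlation makes the coefficient insensitive to outlier
#' voxels and to any monotone rescaling of the maps.
#'
#' @inheritParams voxel_se
#' @param map_fun Function taking a (rep x voxel) matrix and returning one
#'   value per voxel; default `colMeans`.
#' @return Spearman correlation (scalar); `NA` with a warning if either
#'   map is constant.
#' @export
split_half_rs <- function(stack, mask = NULL, map_fun = colMeans) {
  m <- stack_matrix(stack)
  n <- nrow(m)
  if (n < 2) stop("at least two repetitions are required")
  h <- floor(n / 2)
  a <- map_fun(m[seq_len(h), , drop = FALSE])
  b <- map_fun(m[seq(h + 1, n), , drop = FALSE])
  if (!is.null(mask)) { a <- a[as.vector(mask)]; b <- b[as.vector(mask)] }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("split-half maps constant or too small; Rs undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Normalized histogram of voxelwise CoV values
#'
#' Density-normalized histogram (area 1) of the masked, finite CoV values.
#'
#' @param cov_image CoV image (array or vector), e.g. from [voxel_cov()].
#' @param bin_width Bin width in CoV percent.
#' @param mask Optional logical mask.
#' @return A data frame with columns `mid`, `density`, `count`.
#' @export
cov_histogram <- function(cov_image, bin_width = 1, mask = NULL) {
  v <- as.vector(cov_image)
  if (!is.null(mask)) v <- v[as.vector(mask)]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite masked CoV values to bin")
  breaks <- seq(floor(min(v) / bin_width) * bin_width,
                ceiling(max(v) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, density = h$density, count = h$counts)
}
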