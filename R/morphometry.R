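#' Binary 2-D mask with physical pixel size
#'
#' @param mask A matrix of 0/1 (or logical) values; rows = y, columns = x.
#' @param pixel_size Physical pixel edge lengths `(dy, dx)`, e.g. mm.
#' @return An object of class `image_mask2d`.
#' @export
image_mask2d <- function(mask, pixel_size = c(1, 1)) {
  if (!is.matrix(mask)) stop_cfg("'mask' must be a matrix")
  m <- mask * 1
  if (!all(m %in% c(0, 1))) stop_cfg("mask values must be binary (0/1)")
  if (length(pixel_size) != 2L || any(pixel_size <= 0))
    stop_cfg("'pixel_size' must be two positive lengths (dy, dx)")
  structure(list(mask = m, pixel_size = as.numeric(pixel_size)),
            class = "image_mask2d")
}

#' Binary 3-D stack with physical voxel size
#'
#' @param stack A 3-D array of 0/1 (or logical) values, ordered (z, y, x).
#' @param voxel_size Physical voxel edge lengths `(dz, dy, dx)`, e.g. mm.
#' @return An object of class `image_stack3d`.
#' @export
image_stack3d <- function(stack, voxel_size = c(1, 1, 1)) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop_cfg("'stack' must be a 3-D array (z, y, x)")
  s <- stack * 1
  if (!all(s %in% c(0, 1))) stop_cfg("stack values must be binary (0/1)")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_cfg("'voxel_size' must be three positive lengths (dz, dy, dx)")
  structure(list(stack = s, voxel_size = as.numeric(voxel_size)),
            class = "image_stack3d")
}

#' Projected area of a binary mask
#'
#' Foreground pixel count times pixel area. An empty mask yields area 0 with
#' a warning.
#'
#' @param mask An [image_mask2d()].
#' @return Area in squared physical units (e.g. mm^2).
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "image_mask2d"))
  n <- sum(mask$mask)
  if (n == 0) warning("empty mask: area is 0")
  n * prod(mask$pixel_size)
}

#' Volume of a binary voxel stack
#'
#' Foreground voxel count times voxel volume. An empty stack yields 0 with a
#' warning.
#'
#' @param stack An [image_stack3d()].
#' @return Volume in cubed physical units (e.g. mm^3).
#' @export
stack_volume <- function(stack) {
  stopifnot(inherits(stack, "image_stack3d"))
  n <- sum(stack$stack)
  if (n == 0) warning("empty stack: volume is 0")
  n * prod(stack$voxel_size)
}

#' Area of the middle z-plane of a stack
#'
#' The middle plane is the 0-based index `floor(n_z / 2)`, i.e. 1-based
#' `floor(n_z / 2) + 1`: a fixed convention so results are reproducible for
#' even plane counts.
#'
#' @param stack An [image_stack3d()].
#' @return Area of the middle section in squared physical units.
#' @export
middle_section_area <- function(stack) {
  stopifnot(inherits(stack, "image_stack3d"))
  nz <- dim(stack$stack)[1L]
  if (nz < 1L) stop_cfg("stack must have at least one z-plane")
  plane <- stack$stack[nz %/% 2L + 1L, , , drop = TRUE]
  if (!is.matrix(plane)) plane <- matrix(plane, nrow = dim(stack$stack)[2L])
  sum(plane) * prod(stack$voxel_size[2:3])
}

#' Ordinary least-squares calibration line
#'
#' Simple linear regression of `y` on `x` (e.g. organoid volume on
#' middle-section area), reporting slope, intercept, R-squared, the F
#' statistic with (1, n-2) degrees of freedom and its two-sided p-value.
#' For simple regression these satisfy R^2 = F / (F + df2).
#'
#' @param x,y Numeric vectors of equal length, n >= 3; `x` non-constant.
#' @return An object of class `linear_fit`.
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_cfg("'x' and 'y' lengths differ")
  if (length(x) < 3L) stop_cfg("need at least 3 points")
  if (stats::var(x) == 0) stop_cfg("'x' is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exact fit; R^2/F are well-defined here (F = Inf)
  sm <- suppressWarnings(summary(fit))
  df2 <- fit$df.residual
  r2 <- sm$r.squared
  # F from R^2 directly so a perfect fit gives F = Inf, p = 0 cleanly
  f <- if (r2 >= 1) Inf else r2 / (1 - r2) * df2
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, f_stat = f, df1 = 1L, df2 = df2,
                 p_value = p, n = length(x), lm = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear calibration fit (OLS)\n")
  cat(sprintf("  y = %.4g + %.4g * x   (n = %d)\n", x$intercept, x$slope, x$n))
  cat(sprintf("  R^2 = %.4g, F(%d, %d) = %.4g, p = %.4g\n",
              x$r_squared, x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.linear_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  object$intercept + object$slope * as.numeric(newdata)
}

#' @export
residuals.linear_fit <- function(object, ...) stats::residuals(object$lm)

#' Gray-matter fraction of total brain volume
#'
#' GM / (GM + WM) from segmented tissue voxel counts; the voxel volume
#' cancels, so only the counts matter.
#'
#' @param gm_voxels,wm_voxels Non-negative voxel counts for gray and white
#'   matter.
#' @return The GM/TBV fraction.
#' @export
gray_matter_ratio <- function(gm_voxels, wm_voxels) {
  gm <- check_nonneg(gm_voxels, "gm_voxels")
  wm <- check_nonneg(wm_voxels, "wm_voxels")
  if (gm + wm == 0) stop_cfg("gm + wm must be positive")
  gm / (gm + wm)
}
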