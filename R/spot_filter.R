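#' Laplacian-of-Gaussian filter parameters
#'
#' Scales are given in micrometres and converted per-axis to voxels using the
#' stack's voxel size, so the kernel is isotropic in physical space even on a
#' 0.04/0.3 um grid. Defaults approximate the confocal point-spread function
#' at high-NA oil objectives.
#'
#' @param sigma_xy lateral Gaussian scale, um.
#' @param sigma_z axial Gaussian scale, um.
#' @param truncation kernel half-extent in units of sigma per axis; the
#'   discrete kernel spans `2*ceiling(truncation*sigma_vox) + 1` taps (always
#'   odd).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(sigma_xy = 0.13, sigma_z = 0.4, truncation = 4) {
  if (sigma_xy <= 0 || sigma_z <= 0) stop("sigmas must be positive")
  if (truncation <= 0) stop("truncation must be positive")
  structure(list(sigma_xy = sigma_xy, sigma_z = sigma_z,
                 truncation = truncation), class = "filter_params")
}

# 1-D taps. Gaussian taps sum to 1. Second-derivative taps are sampled from
# the analytic d2/dx2 of the (unit-sum-normalized) Gaussian and then mean-
# subtracted so they sum to exactly 0: this makes the full 3D kernel respond
# exactly zero to constant backgrounds, removing the truncation-tail residual.
gauss_taps <- function(sigma_vox, truncation) {
  h <- max(1L, as.integer(ceiling(truncation * sigma_vox)))
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma_vox^2))
  s <- sum(g)
  g2 <- (x^2 / sigma_vox^4 - 1 / sigma_vox^2) * g / s
  list(g = g / s, d2 = g2 - mean(g2))
}

sigma_vox3 <- function(params, vs) {
  c(z = params$sigma_z / vs$dz, y = params$sigma_xy / vs$dy,
    x = params$sigma_xy / vs$dx)
}

#' Discrete negated-LoG kernel
#'
#' Builds the full (non-separable) 3D kernel that [log_filter()] applies:
#' the negated Laplacian of a physically isotropic Gaussian, sampled on the
#' voxel grid. Mainly useful for inspecting the filter and for verifying the
#' separable implementation; the entries sum to (numerically) zero.
#'
#' @inheritParams log_filter
#' @param voxel_size a [voxel_size()] giving the grid the kernel is sampled
#'   on.
#' @return 3D array `(z, y, x)`, odd extent per axis.
#' @export
log_kernel <- function(params, voxel_size) {
  sv <- sigma_vox3(params, voxel_size)
  tz <- gauss_taps(sv["z"], params$truncation)
  ty <- gauss_taps(sv["y"], params$truncation)
  tx <- gauss_taps(sv["x"], params$truncation)
  k <- outer(outer(tz$d2, ty$g), tx$g) +
       outer(outer(tz$g, ty$d2), tx$g) +
       outer(outer(tz$g, ty$g), tx$d2)
  -k
}

#' 3D Laplacian-of-Gaussian spot enhancement
#'
#' Convolves the stack with the negated LoG kernel so diffraction-limited
#' dots become positive peaks and smooth background is suppressed (the kernel
#' integrates to zero). Boundaries are handled by mirror reflection, which
#' avoids rim artifacts that would spawn spurious components at high
#' thresholds. The convolution is computed as three separable passes (second
#' derivative along one axis times Gaussians along the others), identical to
#' convolving with [log_kernel()].
#'
#' @param stack a raw (not yet normalized) [image_stack()].
#' @param params a [filter_params()].
#' @return A filtered [image_stack()] of the same shape, not yet normalized;
#'   values may be negative. Pass to [normalize_filtered()] before
#'   thresholding.
#' @export
log_filter <- function(stack, params = filter_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "filter_params"))
  if (stack$normalized)
    stop("log_filter expects a raw stack, not a normalized one")
  sv <- sigma_vox3(params, stack$voxel_size)
  if (any(sv < 0.5))
    stop(sprintf(
      "sigma under half a voxel (voxels: z=%.3f y=%.3f x=%.3f); undersampled kernel",
      sv["z"], sv["y"], sv["x"]))
  tz <- gauss_taps(sv["z"], params$truncation)
  ty <- gauss_taps(sv["y"], params$truncation)
  tx <- gauss_taps(sv["x"], params$truncation)
  d <- dim(stack$voxels)
  v <- as.numeric(stack$voxels)
  conv <- function(x, taps, axis) conv1d_axis_cpp(x, d, taps, axis)
  sx  <- conv(v, tx$g, 2L)               # shared Gaussian pass along x
  t1 <- conv(conv(conv(v, tx$d2, 2L), ty$g, 1L), tz$g, 0L)
  t2 <- conv(conv(sx, ty$d2, 1L), tz$g, 0L)
  t3 <- conv(conv(sx, ty$g, 1L), tz$d2, 0L)
  out <- array(-(t1 + t2 + t3), dim = d)
  image_stack(out, stack$voxel_size, channel = stack$channel,
              normalized = FALSE)
}

#' Rescale a filtered stack to the common [0, 1] scale
#'
#' Clips negative LoG responses to zero and divides by the global maximum, so
#' the strongest response maps to exactly 1. This shared scale is what makes
#' a fixed intensity threshold (e.g. 0.25) and a uniform 100-point threshold
#' grid comparable across equally filtered images.
#'
#' @param filtered output of [log_filter()].
#' @return A normalized [image_stack()] with values in `[0, 1]`.
#' @section Errors: a stack with no positive response anywhere raises a
#'   condition of class `smfishq_no_signal`; callers counting spots may treat
#'   it as "0 spots".
#' @export
normalize_filtered <- function(filtered) {
  stopifnot(inherits(filtered, "image_stack"))
  v <- pmax(filtered$voxels, 0)
  m <- max(v)
  if (m <= 0)
    stop(structure(class = c("smfishq_no_signal", "error", "condition"),
                   list(message = "no positive filter response in stack",
                        call = sys.call())))
  out <- array(v / m, dim = dim(filtered$voxels))
  image_stack(out, filtered$voxel_size, channel = filtered$channel,
              normalized = TRUE)
}
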